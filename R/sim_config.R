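#' Simulation configuration
#'
#' Describes a synthetic two-genotype, four-fraction membrane proteomics and
#' lipidomics experiment with planted ground truth: a proportion of proteins
#' whose DRM/DSF partitioning shifts in the mutant, a proportion of proteins
#' co-purifying from the SP or IM fraction, and a set of lipid species with
#' planted log2 fold changes. Intensity noise is multiplicative log-normal;
#' missingness follows an intensity-dependent logistic dropout model.
#'
#' @param n_proteins number of simulated proteins.
#' @param peptides_per_protein integer range (length-2) of peptides drawn
#'   uniformly per protein.
#' @param genotypes character vector of genotype labels; the first is the
#'   wildtype reference.
#' @param n_replicates biological replicates per genotype x fraction.
#' @param frac_shifted proportion of proteins with a true DRM/DSF shift in the
#'   mutant (sign of the shift is randomized per protein).
#' @param shift_log2 magnitude (log2 units) of the planted DRM intensity shift.
#' @param frac_copurifying proportion of proteins whose highest true abundance
#'   lies in SP or IM.
#' @param noise_cv coefficient of variation of multiplicative log-normal
#'   intensity noise (0 disables noise).
#' @param missing_model list with elements `enabled`, `midpoint` (log10
#'   intensity at which dropout probability is 0.5) and `steepness` (logistic
#'   slope per log10 unit). Dropout probability decreases with intensity.
#' @param n_lipids_per_class species simulated per lipid class.
#' @param n_lipid_replicates lipid samples per genotype.
#' @param n_diff_lipids number of lipid species with a planted fold change.
#' @param lipid_fc_log2 planted log2 fold change magnitude; scalar or vector
#'   of length `n_diff_lipids` (signs randomized unless given negative values).
#' @param focal_lipid_class optional class label; when set, the first planted
#'   differential lipid is drawn from this class (used to concentrate
#'   lipid-protein coupling on e.g. one GlcCer species).
#' @param coupling logical; when TRUE, planted protein shifts and planted
#'   lipid fold changes share a per-replicate latent genotype-effect factor,
#'   so that true lipid-protein pairs carry detectable combined scores.
#' @param coupling_sd standard deviation of the shared latent factor.
#' @param seed integer RNG seed; identical configurations with identical seeds
#'   reproduce byte-identical tables.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_proteins = 200,
                       peptides_per_protein = c(2L, 8L),
                       genotypes = c("wildtype", "mutant"),
                       n_replicates = 4L,
                       frac_shifted = 0.10,
                       shift_log2 = 2,
                       frac_copurifying = 0.15,
                       noise_cv = 0.2,
                       missing_model = list(enabled = TRUE, midpoint = 4.5,
                                            steepness = 2),
                       n_lipids_per_class = 5L,
                       n_lipid_replicates = 5L,
                       n_diff_lipids = 6L,
                       lipid_fc_log2 = 1,
                       focal_lipid_class = NULL,
                       coupling = TRUE,
                       coupling_sd = 0.1,
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              peptides_per_protein = as.integer(peptides_per_protein),
              genotypes = as.character(genotypes),
              fractions = FRACTIONS,
              n_replicates = as.integer(n_replicates),
              frac_shifted = frac_shifted,
              shift_log2 = shift_log2,
              frac_copurifying = frac_copurifying,
              noise_cv = noise_cv,
              missing_model = missing_model,
              n_lipids_per_class = as.integer(n_lipids_per_class),
              n_lipid_replicates = as.integer(n_lipid_replicates),
              n_diff_lipids = as.integer(n_diff_lipids),
              lipid_fc_log2 = lipid_fc_log2,
              focal_lipid_class = focal_lipid_class,
              coupling = isTRUE(coupling),
              coupling_sd = coupling_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  props <- c(frac_shifted = cfg$frac_shifted,
             frac_copurifying = cfg$frac_copurifying)
  bad <- props < 0 | props > 1 | !is.finite(props)
  if (any(bad))
    stop_config("proportions must lie in [0, 1]: %s",
                paste(names(props)[bad], collapse = ", "))
  if (cfg$n_replicates < 2L)
    stop_config("n_replicates must be >= 2 (got %d)", cfg$n_replicates)
  if (cfg$n_lipid_replicates < 2L)
    stop_config("n_lipid_replicates must be >= 2")
  if (length(cfg$genotypes) < 2L)
    stop_config("need at least two genotypes (first = wildtype)")
  if (!all(is.finite(c(cfg$shift_log2, cfg$lipid_fc_log2))))
    stop_config("effect sizes must be finite")
  if (cfg$noise_cv < 0 || !is.finite(cfg$noise_cv))
    stop_config("noise_cv must be a finite non-negative number")
  if (length(cfg$peptides_per_protein) != 2L ||
      any(cfg$peptides_per_protein < 1L) ||
      cfg$peptides_per_protein[1] > cfg$peptides_per_protein[2])
    stop_config("peptides_per_protein must be an increasing range of counts")
  fc <- cfg$lipid_fc_log2
  if (!(length(fc) %in% c(1L, cfg$n_diff_lipids)))
    stop_config("lipid_fc_log2 must be scalar or length n_diff_lipids")
  if (!is.null(cfg$focal_lipid_class) &&
      !cfg$focal_lipid_class %in% LIPID_CLASSES)
    stop_config("unknown focal_lipid_class '%s'", cfg$focal_lipid_class)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic membrane-fraction experiment\n")
  cat(sprintf("  %d proteins (%d-%d peptides), genotypes: %s\n",
              x$n_proteins, x$peptides_per_protein[1],
              x$peptides_per_protein[2], paste(x$genotypes, collapse = ", ")))
  cat(sprintf("  %d replicates x fractions {%s}\n", x$n_replicates,
              paste(x$fractions, collapse = ", ")))
  cat(sprintf("  planted: %.0f%% shifted (|log2|=%.2g), %.0f%% co-purifying\n",
              100 * x$frac_shifted, x$shift_log2, 100 * x$frac_copurifying))
  cat(sprintf("  noise CV %.2g, seed %d\n", x$noise_cv, x$seed))
  invisible(x)
}

# sdlog of a log-normal with a given coefficient of variation
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

# Shared latent genotype-effect factors, one per (mutant genotype, replicate).
# Both the evidence and the lipid simulators perturb their planted log2
# effects by (1 + eps), so coupled protein/lipid pairs co-vary. Derived
# deterministically from the config seed on a private RNG stream.
coupling_latents <- function(cfg) {
  n_rep <- max(cfg$n_replicates, cfg$n_lipid_replicates)
  if (!cfg$coupling || cfg$coupling_sd <= 0)
    return(matrix(0, length(cfg$genotypes) - 1L, n_rep))
  withr_seed(cfg$seed %% 1000000L + 777L, {
    matrix(rnorm((length(cfg$genotypes) - 1L) * n_rep, 0, cfg$coupling_sd),
           length(cfg$genotypes) - 1L, n_rep)
  })
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
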