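#' Simulate positive/negative-mode lipid intensity tables
#'
#' Builds two mode-specific lipid tables with overlapping but non-identical
#' species sets across the class vocabulary (PC, PE, PG, PI, PS, Cer, GlcCer,
#' DAG, MGDG, DGDG, SQDG, TAG). Each class has a primary ionization mode;
#' roughly 10% of species are detected in both modes. Planted log2 fold
#' changes multiply mutant-sample intensities; when coupling is enabled the
#' planted effects share the per-replicate latent factor of
#' [simulate_evidence()], so coupled lipid/protein pairs co-vary. TAG species
#' are always present so the TAG-exclusion normalization rule is exercised.
#'
#' @param config a [sim_config()] object.
#' @return list with `pos` and `neg` [lipid_table()] objects, `design`
#'   (sample_id, genotype, replicate) and `truth` (`differential_lipids`:
#'   lipid_id, class, fc_log2).
#' @export
simulate_lipids <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed + 1L)

  genos <- cfg$genotypes
  n_rep <- cfg$n_lipid_replicates
  design <- expand.grid(replicate = seq_len(n_rep), genotype = genos,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_lip_r%d", design$genotype, design$replicate)
  design <- design[, c("sample_id", "genotype", "replicate")]

  meta <- make_lipid_species(cfg$n_lipids_per_class)
  n_lip <- nrow(meta)

  # planted fold changes; the focal class (if any) contributes the first
  # planted species so coupling can be concentrated on e.g. one GlcCer
  n_diff <- min(cfg$n_diff_lipids, n_lip)
  fc_mag <- rep_len(cfg$lipid_fc_log2, n_diff)
  cand <- seq_len(n_lip)
  diff_idx <- integer(0)
  if (!is.null(cfg$focal_lipid_class) && n_diff > 0) {
    focal_pool <- which(meta$class == cfg$focal_lipid_class)
    diff_idx <- sample(focal_pool, 1L)
    cand <- setdiff(cand, diff_idx)
  }
  diff_idx <- c(diff_idx, sample(cand, n_diff - length(diff_idx)))
  fc_sign <- ifelse(fc_mag < 0, 1, sample(c(-1, 1), n_diff, replace = TRUE))
  fc <- setNames(numeric(n_lip), meta$lipid_id)
  fc[diff_idx] <- fc_sign * fc_mag

  eps <- coupling_latents(cfg)
  mutants <- genos[-1]

  baseline <- rlnorm(n_lip, meanlog = log(1e5), sdlog = 1)
  sdlog <- cv_to_sdlog(cfg$noise_cv)
  intensity <- matrix(0, n_lip, nrow(design),
                      dimnames = list(meta$lipid_id, design$sample_id))
  for (s in seq_len(nrow(design))) {
    geno <- design$genotype[s]
    mu <- baseline
    if (geno != genos[1]) {
      gi <- match(geno, mutants)
      lat <- 1 + eps[gi, design$replicate[s]]
      mu <- mu * 2^(fc * lat)
    }
    noise <- if (sdlog > 0) exp(rnorm(n_lip, 0, sdlog)) else 1
    intensity[, s] <- mu * noise
  }

  # mode assignment: class-typical primary mode plus ~10% dual-mode species
  pos_classes <- c("PC", "PE", "DAG", "TAG", "Cer", "GlcCer")
  primary_pos <- meta$class %in% pos_classes
  dual <- runif(n_lip) < 0.10
  in_pos <- primary_pos | dual
  in_neg <- !primary_pos | dual

  pos <- lipid_table(meta[in_pos, , drop = FALSE],
                     intensity[in_pos, , drop = FALSE], mode = "positive")
  neg <- lipid_table(meta[in_neg, , drop = FALSE],
                     intensity[in_neg, , drop = FALSE], mode = "negative")

  truth <- list(differential_lipids = data.frame(
    lipid_id = meta$lipid_id[diff_idx],
    class = meta$class[diff_idx],
    fc_log2 = fc[diff_idx],
    stringsAsFactors = FALSE))

  list(pos = pos, neg = neg, design = design, truth = truth)
}

make_lipid_species <- function(n_per_class) {
  carbons <- list(PC = seq(32, 40, 2), PE = seq(32, 40, 2),
                  PG = seq(32, 36, 2), PI = seq(32, 36, 2),
                  PS = seq(36, 42, 2), Cer = seq(40, 44, 2),
                  GlcCer = seq(40, 44, 2), DAG = seq(32, 36, 2),
                  MGDG = seq(34, 36, 2), DGDG = seq(34, 36, 2),
                  SQDG = seq(32, 36, 2), TAG = seq(50, 54, 2))
  rows <- lapply(LIPID_CLASSES, function(cl) {
    nc <- sample(carbons[[cl]], n_per_class, replace = TRUE)
    db <- sample(0:6, n_per_class, replace = TRUE)
    hyd <- if (cl %in% c("Cer", "GlcCer"))
      sample(0:1, n_per_class, replace = TRUE) else rep(NA_integer_,
                                                        n_per_class)
    data.frame(class = cl, acyl_carbons = nc, double_bonds = db,
               hydroxylation = hyd, stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, rows)
  meta$lipid_id <- make.unique(sprintf("%s %d:%d%s", meta$class,
                                       meta$acyl_carbons, meta$double_bonds,
                                       ifelse(is.na(meta$hydroxylation) |
                                                meta$hydroxylation == 0, "",
                                              "-OH")), sep = "_")
  meta[, c("lipid_id", "class", "acyl_carbons", "double_bonds",
           "hydroxylation")]
}
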