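#' Simulate a peptide evidence table with planted ground truth
#'
#' Generates a long-format peptide evidence table mimicking a minimal
#' MaxQuant-style export (one row per observed peptide x sample), together
#' with the sample design and the planted ground truth. Protein baseline
#' abundances are log-normal; each peptide has a constant ionization
#' efficiency across samples; replicate noise is multiplicative log-normal at
#' `noise_cv`. Planted shifts multiply only the DRM intensities of shifted
#' proteins in mutant genotypes by `2^(sign * shift_log2)`. Dropout
#' probability is a decreasing logistic function of log10 intensity; dropped
#' observations are absent from the table, as in a real evidence export.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements
#'   \describe{
#'     \item{evidence}{data.frame: `peptide_id`, `protein_id`, `sample_id`,
#'       `intensity` (observed rows only).}
#'     \item{design}{data.frame: `sample_id`, `genotype`, `fraction`,
#'       `replicate`.}
#'     \item{truth}{list: `shifted_proteins` (protein_id, shift_log2),
#'       `copurifying_proteins` (protein_id, top_fraction), `dropout`
#'       (expected rate, its standard error, and potential observation
#'       count), and `expected_log2_drmdsf` per protein x genotype.}
#'   }
#' @export
simulate_evidence <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)

  n_prot <- cfg$n_proteins
  prot_ids <- sprintf("P%04d", seq_len(n_prot))
  genos <- cfg$genotypes
  mutants <- genos[-1]
  n_rep <- cfg$n_replicates

  design <- expand.grid(replicate = seq_len(n_rep), fraction = cfg$fractions,
                        genotype = genos, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  design <- design[, c("genotype", "fraction", "replicate")]
  design$sample_id <- sprintf("%s_%s_r%d", design$genotype, design$fraction,
                              design$replicate)
  design <- design[, c("sample_id", "genotype", "fraction", "replicate")]

  # planted status: shifted and co-purifying sets may overlap
  n_shift <- round(cfg$frac_shifted * n_prot)
  n_copur <- round(cfg$frac_copurifying * n_prot)
  shifted <- sample(prot_ids, n_shift)
  shift_sign <- sample(c(-1, 1), n_shift, replace = TRUE)
  copur <- sample(prot_ids, n_copur)
  copur_top <- sample(c("SP", "IM"), n_copur, replace = TRUE)

  # fraction weight profile per protein: membrane proteins put 80% of their
  # mass in DRM+DSF (random split), co-purifying proteins put 60% in their
  # top soluble/intracellular fraction
  w <- matrix(0, n_prot, 4, dimnames = list(prot_ids, cfg$fractions))
  mem_split <- rgamma(n_prot, 3)
  mem_split <- mem_split / (mem_split + rgamma(n_prot, 3))
  w[, "DRM"] <- 0.8 * mem_split
  w[, "DSF"] <- 0.8 * (1 - mem_split)
  sp_split <- runif(n_prot, 0.3, 0.7)
  w[, "SP"] <- 0.2 * sp_split
  w[, "IM"] <- 0.2 * (1 - sp_split)
  if (n_copur > 0) {
    for (k in seq_len(n_copur)) {
      i <- match(copur[k], prot_ids)
      wi <- w[i, ]
      wi <- wi / sum(wi) * 0.4
      wi[copur_top[k]] <- 0.6
      w[i, ] <- wi
    }
  }

  baseline <- rlnorm(n_prot, meanlog = log(1e6), sdlog = 1)
  n_pep <- sample(seq(cfg$peptides_per_protein[1], cfg$peptides_per_protein[2]),
                  n_prot, replace = TRUE)
  pep_protein <- rep(prot_ids, n_pep)
  pep_ids <- make_peptide_ids(sum(n_pep))
  pep_eff <- rlnorm(sum(n_pep), 0, 0.7)

  eps <- coupling_latents(cfg)  # mutants x replicates latent factors

  # expected intensity grid: peptide x sample
  n_samp <- nrow(design)
  shift_of <- setNames(numeric(n_prot), prot_ids)
  shift_of[shifted] <- shift_sign * cfg$shift_log2

  pep_base <- baseline[match(pep_protein, prot_ids)] * pep_eff
  mu <- matrix(0, length(pep_ids), n_samp,
               dimnames = list(pep_ids, design$sample_id))
  for (s in seq_len(n_samp)) {
    frac <- design$fraction[s]
    geno <- design$genotype[s]
    fac <- w[match(pep_protein, prot_ids), frac]
    if (frac == "DRM" && geno != genos[1]) {
      gi <- match(geno, mutants)
      lat <- 1 + eps[gi, design$replicate[s]]
      fac <- fac * 2^(shift_of[pep_protein] * lat)
    }
    mu[, s] <- pep_base * fac
  }

  sdlog <- cv_to_sdlog(cfg$noise_cv)
  x <- if (sdlog > 0) mu * exp(matrix(rnorm(length(mu), 0, sdlog),
                                      nrow(mu))) else mu

  mm <- cfg$missing_model
  if (isTRUE(mm$enabled)) {
    p_drop <- plogis(mm$steepness * (mm$midpoint - log10(x)))
    keep <- matrix(runif(length(x)) >= p_drop, nrow(x))
    dropout <- list(expected_rate = mean(p_drop),
                    se = sqrt(sum(p_drop * (1 - p_drop))) / length(p_drop),
                    n_potential = length(p_drop))
  } else {
    keep <- matrix(TRUE, nrow(x), ncol(x))
    dropout <- list(expected_rate = 0, se = 0, n_potential = length(x))
  }

  obs <- which(keep, arr.ind = TRUE)
  evidence <- data.frame(
    peptide_id = pep_ids[obs[, 1]],
    protein_id = pep_protein[obs[, 1]],
    sample_id = design$sample_id[obs[, 2]],
    intensity = x[keep],
    stringsAsFactors = FALSE)
  evidence <- evidence[order(evidence$peptide_id, evidence$sample_id), ]
  rownames(evidence) <- NULL

  # noiseless expected log2 DRM/DSF ratio per protein x genotype (latents
  # averaged out), for ground-truth consistency checks
  exp_ratio <- expand.grid(protein_id = prot_ids, genotype = genos,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  exp_ratio$log2_drmdsf <- log2(w[exp_ratio$protein_id, "DRM"] /
                                  w[exp_ratio$protein_id, "DSF"]) +
    ifelse(exp_ratio$genotype == genos[1], 0, shift_of[exp_ratio$protein_id])

  truth <- list(
    shifted_proteins = data.frame(protein_id = shifted,
                                  shift_log2 = shift_sign * cfg$shift_log2,
                                  stringsAsFactors = FALSE),
    copurifying_proteins = data.frame(protein_id = copur,
                                      top_fraction = copur_top,
                                      stringsAsFactors = FALSE),
    dropout = dropout,
    expected_log2_drmdsf = exp_ratio)

  list(evidence = evidence, design = design, truth = truth)
}

# pseudo-tryptic peptide sequences: distinct, ending in K/R
make_peptide_ids <- function(n) {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]
  len <- sample(8:14, n, replace = TRUE)
  body <- vapply(len, function(l)
    paste(sample(aa, l, replace = TRUE), collapse = ""), "")
  seqs <- paste0(body, sample(c("K", "R"), n, replace = TRUE))
  make.unique(seqs, sep = "")
}
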