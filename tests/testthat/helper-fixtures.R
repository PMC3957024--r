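# shared fixtures and independent brute-force oracles

quiet <- function(expr) suppressWarnings(expr)

small_cfg <- function(...) {
  args <- utils::modifyList(list(n_proteins = 40L, n_replicates = 4L,
                                 noise_cv = 0.2, seed = 1L), list(...))
  do.call(sim_config, args)
}

# hand-built protein_quant from a named abundance matrix
make_pqm <- function(ab, design) {
  structure(list(abundance = ab,
                 n_peptides = matrix(1L, nrow(ab), ncol(ab),
                                     dimnames = dimnames(ab)),
                 design = design),
            class = "protein_quant")
}

make_design <- function(n_rep = 3, genotypes = c("wildtype", "mutant"),
                        fractions = c("DRM", "DSF", "SP", "IM")) {
  d <- expand.grid(replicate = seq_len(n_rep), fraction = fractions,
                   genotype = genotypes, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  d$sample_id <- sprintf("%s_%s_r%d", d$genotype, d$fraction, d$replicate)
  d[, c("sample_id", "genotype", "fraction", "replicate")]
}

random_evidence <- function(design, n_pep = 8, n_prot = 3,
                            p_present = 0.6) {
  peps <- sprintf("pep%02d", seq_len(n_pep))
  prot <- sample(sprintf("prot%d", seq_len(n_prot)), n_pep, replace = TRUE)
  rows <- expand.grid(peptide_id = peps, sample_id = design$sample_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$protein_id <- prot[match(rows$peptide_id, peps)]
  rows$intensity <- stats::runif(nrow(rows), 1, 100)
  rows[stats::runif(nrow(rows)) < p_present,
       c("peptide_id", "protein_id", "sample_id", "intensity")]
}

# oracle: per-peptide per-fraction presence scan, straight loops
bf_filter <- function(evidence, design, min_presence = 0.7) {
  keep <- character(0)
  for (pep in unique(evidence$peptide_id)) {
    ok <- FALSE
    for (f in unique(design$fraction)) {
      samp <- design$sample_id[design$fraction == f]
      seen <- unique(evidence$sample_id[evidence$peptide_id == pep &
                                          !is.na(evidence$intensity)])
      if (length(intersect(seen, samp)) / length(samp) >= min_presence)
        ok <- TRUE
    }
    if (ok) keep <- c(keep, pep)
  }
  sort(keep)
}

# oracle: spreadsheet-style aggregation, one protein at a time
bf_aggregate <- function(evidence, design) {
  samples <- design$sample_id
  prots <- sort(unique(evidence$protein_id))
  out <- matrix(NA_real_, length(prots), length(samples),
                dimnames = list(prots, samples))
  for (pr in prots) {
    ev <- evidence[evidence$protein_id == pr, ]
    peps <- unique(ev$peptide_id)
    scaled <- matrix(NA_real_, length(peps), length(samples))
    scales <- numeric(length(peps))
    for (j in seq_along(peps)) {
      v <- rep(NA_real_, length(samples))
      sel <- ev$peptide_id == peps[j]
      v[match(ev$sample_id[sel], samples)] <- ev$intensity[sel]
      scales[j] <- stats::median(v, na.rm = TRUE)
      scaled[j, ] <- v / scales[j]
    }
    for (s in seq_along(samples)) {
      col <- scaled[, s]
      if (any(!is.na(col)))
        out[pr, s] <- stats::median(col, na.rm = TRUE) *
          stats::median(scales)
    }
  }
  out
}

# oracle: co-purification rule with a textbook Welch statistic
bf_copurify <- function(ab, design, alpha = 0.01) {
  welch_greater <- function(a, b) {
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(if (mean(a) > mean(b)) 0 else 1)
    va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
    tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    stats::pt(tstat, df, lower.tail = FALSE)
  }
  vapply(rownames(ab), function(pr) {
    vals <- lapply(c("DRM", "DSF", "SP", "IM"), function(f)
      ab[pr, design$sample_id[design$fraction == f]])
    names(vals) <- c("DRM", "DSF", "SP", "IM")
    means <- vapply(vals, mean, numeric(1))
    top <- names(means)[which.max(means)]
    ref <- if (means[["DRM"]] >= means[["DSF"]]) vals$DRM else vals$DSF
    top %in% c("SP", "IM") ||
      welch_greater(vals$SP, ref) < alpha ||
      welch_greater(vals$IM, ref) < alpha
  }, logical(1))
}

# oracle: all-pairs tolerance scan for the peak matcher
bf_match <- function(peaks, library, ppm_tol = 5, rt_tol = 0.5) {
  hits <- data.frame(peak = integer(0), name = character(0))
  for (i in seq_len(nrow(peaks))) {
    best <- NULL; best_ppm <- Inf; best_drt <- Inf
    for (j in seq_len(nrow(library))) {
      ppm <- abs(peaks$mz[i] - library$mz[j]) / library$mz[j] * 1e6
      drt <- abs(peaks$rt[i] - library$rt[j])
      if (ppm <= ppm_tol && drt <= rt_tol &&
          (ppm < best_ppm || (ppm == best_ppm && drt < best_drt))) {
        best <- library$name[j]; best_ppm <- ppm; best_drt <- drt
      }
    }
    if (!is.null(best))
      hits <- rbind(hits, data.frame(peak = i, name = best))
  }
  hits
}

# oracle: reference-set lipid normalization, longhand
bf_normalize_lipids <- function(meta, x) {
  cv <- apply(x, 1, function(r) stats::sd(r) / mean(r))
  ref <- meta$class != "TAG" & cv < stats::median(cv)
  if (!any(ref)) ref <- meta$class != "TAG" & cv <= stats::median(cv)
  if (!any(ref)) ref <- meta$class != "TAG"
  denom <- colSums(x[ref, , drop = FALSE])
  sweep(x, 2, denom, "/")
}
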