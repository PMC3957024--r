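#' Bootstrap log2 DRM/DSF ratios
#'
#' Draws `n_boot` log2 ratios, each formed by independently resampling (with
#' replacement) one DRM and one DSF replicate abundance. This is the
#' building block of the ratio-shift statistic; see
#' [test_partition_shift()] for the full procedure.
#'
#' @param drm,dsf numeric vectors of strictly positive replicate abundances.
#' @param n_boot number of bootstrap draws.
#' @return numeric vector of length `n_boot`, or NULL when either input is
#'   empty (the caller marks such proteins untestable).
#' @export
bootstrap_ratios <- function(drm, dsf, n_boot = 1000) {
  if (!length(drm) || !length(dsf)) return(NULL)
  if (any(drm <= 0) || any(dsf <= 0))
    stop_config("abundances must be > 0 (apply a pseudo-floor first)")
  log2(drm[sample.int(length(drm), n_boot, replace = TRUE)]) -
    log2(dsf[sample.int(length(dsf), n_boot, replace = TRUE)])
}

#' Ratio-shift score from two bootstrap samples
#'
#' The signed score is the difference of bootstrap-median log2 ratios
#' (mutant minus wildtype) standardized by a pooled, interquartile-range
#' based spread: `sqrt((s_wt^2 + s_mut^2)/2)` with `s = IQR/1.349`. The
#' score is zero-centered under the null and monotone in the true log2
#' shift at fixed noise. Zero pooled spread with unequal medians yields a
#' signed infinite sentinel.
#'
#' @param wt_boot,mut_boot bootstrap log2-ratio samples of equal length.
#' @return a single signed score.
#' @export
partition_score <- function(wt_boot, mut_boot) {
  stopifnot(length(wt_boot) == length(mut_boot))
  s_wt <- stats::IQR(wt_boot) / 1.349
  s_mut <- stats::IQR(mut_boot) / 1.349
  spread <- sqrt((s_wt^2 + s_mut^2) / 2)
  d <- median(mut_boot) - median(wt_boot)
  if (spread == 0) {
    if (d == 0) return(0)
    return(sign(d) * Inf)
  }
  d / spread
}

#' Calibrate per-tail FDR thresholds from a permutation null
#'
#' For each tail, candidate thresholds are the observed scores. The
#' estimated FDR at threshold t is (expected null exceedances among the
#' candidates) / (observed exceedances), where the expectation scales the
#' null pool's strict-exceedance tail proportion up to the number of
#' candidate statistics. The threshold is the smallest |t| whose estimated
#' FDR is below `fdr`; with no qualifying candidate the tail's threshold is
#' infinite (nothing called in that tail). Null exceedances are counted
#' strictly above t: a permutation that happens to reassemble an observed
#' configuration produces an exact tie with its own candidate, which must
#' not count as evidence against it.
#'
#' @param obs observed scores, one per candidate (finite values are used as
#'   thresholds; infinite observed scores always exceed any finite
#'   threshold).
#' @param null_scores numeric vector or matrix of permutation-null scores;
#'   its total size need not equal `length(obs) * n_perm` — the tail
#'   proportion is rescaled to the candidate count.
#' @param n_perm number of permutation rounds (diagnostic; the scaling uses
#'   the pool and candidate sizes directly).
#' @param fdr target false discovery rate (default 0.01).
#' @return list with `lower` and `upper` thresholds and the `null` pool.
#' @export
calibrate_fdr_threshold <- function(obs, null_scores, n_perm, fdr = 0.01) {
  null <- as.numeric(null_scores)
  null <- null[!is.na(null)]
  n_cand <- sum(!is.na(obs))
  list(upper = tail_threshold(obs, null, n_cand, fdr),
       lower = -tail_threshold(-obs, -null, n_cand, fdr),
       null = null)
}

# smallest positive threshold t with n_cand * P_null(> t) / (#obs >= t) < fdr
tail_threshold <- function(obs, null, n_cand, fdr) {
  cand <- sort(obs[is.finite(obs) & obs > 0], decreasing = TRUE)
  if (!length(cand) || !length(null)) return(Inf)
  sn <- sort(null[is.finite(null)])
  n_inf <- sum(is.infinite(null) & null > 0)
  # strict exceedances among finite nulls via binary search; +Inf nulls
  # always exceed
  n_gt <- length(sn) - findInterval(cand, sn) + n_inf
  k <- seq_along(cand)  # observed exceedances at each candidate
  fdr_hat <- n_cand * (n_gt / length(null)) / k
  ok <- which(fdr_hat < fdr)
  if (!length(ok)) return(Inf)
  cand[max(ok)]
}

#' Test proteins for genotype-dependent DRM/DSF partitioning shifts
#'
#' For every testable protein (at least `min_rep` quantified replicates in
#' each of DRM and DSF for both genotypes) a bootstrap distribution of log2
#' DRM/DSF ratios is built per genotype and summarized by the standardized
#' median-difference score of [partition_score()]. Significance thresholds
#' are calibrated per tail from randomized data: genotype labels are
#' permuted within each fraction's pooled replicate values and scores
#' recomputed, `n_perm` rounds, targeting the given FDR. The default
#' `perm = "balanced"` scheme draws half of each pseudo-genotype from each
#' true genotype, so genuine shifts cancel instead of contaminating the
#' null score tail; `perm = "full"` is the naive pooled shuffle, which is
#' conservative when many proteins carry large true shifts. Because
#' fraction-of-total normalization makes per-sample abundances
#' compositional, a cohort of genuinely shifted proteins biases every
#' other protein's apparent ratio in the opposite direction; by default
#' (`center = TRUE`) the across-protein median of the raw median
#' differences is subtracted before standardizing, identically for the
#' observed data and for each permutation round. Zero abundances are
#' raised to a pseudo-floor (half the smallest positive abundance) so
#' ratios stay finite. No further multiple-testing correction is applied.
#'
#' @param pqm a `protein_quant` object (see [aggregate_protein()]).
#' @param design design data.frame; must contain fractions DRM and DSF for
#'   the wildtype and exactly one mutant genotype (use `mutant` to select
#'   one of several).
#' @param fdr target false discovery rate (default 0.01).
#' @param n_boot bootstrap draws per genotype (default 1000).
#' @param n_perm label-permutation rounds (default 200).
#' @param wildtype,mutant genotype labels; `mutant` defaults to the single
#'   non-wildtype genotype.
#' @param perm permutation scheme for the null: "balanced" (default) or
#'   "full".
#' @param center subtract the across-protein median ratio difference
#'   (compositional-bias correction); default TRUE.
#' @param min_rep minimum quantified replicates per fraction per genotype.
#' @param pseudo_floor replacement for non-positive abundances; default half
#'   the smallest positive abundance in the matrix.
#' @param seed optional RNG seed for reproducibility.
#' @return a data.frame of class `shift_result`, one row per protein:
#'   `protein_id`, `score`, `log2_ratio_wt`, `log2_ratio_mut`,
#'   `significant`, `direction` (enriched/depleted/none, relative to DRM),
#'   `testable`, `n_boot`. Thresholds and the null score population are in
#'   attributes `thresholds` and `null_scores`.
#' @export
test_partition_shift <- function(pqm, design = pqm$design, fdr = 0.01,
                                 n_boot = 1000, n_perm = 200,
                                 wildtype = "wildtype", mutant = NULL,
                                 perm = c("balanced", "full"),
                                 center = TRUE,
                                 min_rep = 2L, pseudo_floor = NULL,
                                 seed = NULL) {
  perm <- match.arg(perm)
  stopifnot(inherits(pqm, "protein_quant"))
  design <- check_design(design)
  if (!all(c("DRM", "DSF") %in% design$fraction))
    stop_config("design must contain DRM and DSF fractions")
  genos <- unique(design$genotype)
  if (!wildtype %in% genos)
    stop_config("wildtype genotype '%s' absent from design", wildtype)
  mutant <- mutant %||% setdiff(genos, wildtype)
  if (length(mutant) != 1L)
    stop_config("exactly one mutant genotype required (got: %s)",
                paste(mutant, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  ab <- pqm$abundance
  floor_val <- pseudo_floor %||% (min(ab[ab > 0], na.rm = TRUE) / 2)

  grab <- function(geno, frac) {
    s <- design$sample_id[design$genotype == geno & design$fraction == frac]
    s <- intersect(s, colnames(ab))
    m <- ab[, s, drop = FALSE]
    m[!is.na(m) & m <= 0] <- floor_val
    m
  }
  m_wt_drm <- grab(wildtype, "DRM"); m_wt_dsf <- grab(wildtype, "DSF")
  m_mu_drm <- grab(mutant, "DRM"); m_mu_dsf <- grab(mutant, "DSF")

  vals <- function(m, i) { v <- m[i, ]; v[!is.na(v)] }
  n <- nrow(ab)
  testable <- logical(n)
  lw <- vector("list", n); lx <- vector("list", n)
  ly <- vector("list", n); lz <- vector("list", n)
  for (i in seq_len(n)) {
    lw[[i]] <- vals(m_wt_drm, i); lx[[i]] <- vals(m_wt_dsf, i)
    ly[[i]] <- vals(m_mu_drm, i); lz[[i]] <- vals(m_mu_dsf, i)
    testable[i] <- min(lengths(list(lw[[i]], lx[[i]], ly[[i]],
                                    lz[[i]]))) >= min_rep
  }
  idx <- which(testable)
  res <- data.frame(protein_id = rownames(ab), score = NA_real_,
                    log2_ratio_wt = NA_real_, log2_ratio_mut = NA_real_,
                    significant = FALSE,
                    direction = "none", testable = testable,
                    n_boot = n_boot, stringsAsFactors = FALSE)
  thresholds <- list(lower = -Inf, upper = Inf)
  null_pool <- numeric(0)
  if (length(idx)) {
    cpp <- shift_scores_cpp(lw[idx], lx[idx], ly[idx], lz[idx],
                            as.integer(n_boot), as.integer(n_perm),
                            perm == "balanced")
    d_obs <- cpp$diff
    if (center) d_obs <- d_obs - median(d_obs, na.rm = TRUE)
    res$score[idx] <- standardize_diff(d_obs, cpp$spread)
    res$log2_ratio_wt[idx] <- cpp$log2_ratio_wt
    res$log2_ratio_mut[idx] <- cpp$log2_ratio_mut
    d_null <- cpp$null_diff
    if (center && ncol(d_null) > 0)
      d_null <- sweep(d_null, 2, apply(d_null, 2, median, na.rm = TRUE))
    null_scores <- standardize_diff(d_null, cpp$null_spread)
    thr <- calibrate_fdr_threshold(res$score[idx], null_scores, n_perm, fdr)
    thresholds <- thr[c("lower", "upper")]
    null_pool <- thr$null
    if (length(idx) < 100L)
      warning("fewer than 100 testable proteins; permutation null may be unstable")
    sig <- !is.na(res$score) &
      ((is.finite(thr$upper) & res$score >= thr$upper) |
         (is.finite(thr$lower) & res$score <= thr$lower))
    res$significant <- sig
    res$direction <- ifelse(sig & res$score > 0, "enriched",
                            ifelse(sig & res$score < 0, "depleted", "none"))
  }
  attr(res, "thresholds") <- thresholds
  attr(res, "null_scores") <- null_pool
  attr(res, "params") <- list(fdr = fdr, n_boot = n_boot, n_perm = n_perm,
                              wildtype = wildtype, mutant = mutant,
                              perm = perm, center = center,
                              pseudo_floor = floor_val)
  class(res) <- c("shift_result", "data.frame")
  res
}

# d / spread with signed-infinite sentinels where the spread degenerates
standardize_diff <- function(d, spread) {
  out <- d / spread
  zero <- !is.na(spread) & spread == 0
  out[zero] <- ifelse(d[zero] == 0, 0, sign(d[zero]) * Inf)
  out
}
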