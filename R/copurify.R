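#' Flag proteins co-purifying from soluble or intracellular-membrane fractions
#'
#' A protein is called co-purifying when its highest mean abundance lies in
#' the SP or IM fraction, or when a one-sided Welch t-test finds SP or IM
#' significantly higher than the best membrane fraction (the larger-mean of
#' DRM and DSF) at level `alpha`. The two rules are OR-combined and no
#' multiple-testing correction is applied — the statistic is used to filter
#' contaminants, so uncorrected tests are the more stringent choice.
#' Replicates are pooled across genotypes by default.
#'
#' @param pqm a `protein_quant` object.
#' @param design design data.frame with all four fractions.
#' @param alpha significance level of the one-sided tests (default 0.01).
#' @param per_genotype evaluate within a single genotype's samples instead
#'   of pooling (pass the genotype label); default pooled.
#' @return data.frame of class `copurify_calls`: `protein_id`,
#'   `top_fraction`, `p_vs_SP`, `p_vs_IM`, `copurifying`, `testable`,
#'   `reason`.
#' @export
flag_copurifying <- function(pqm, design = pqm$design, alpha = 0.01,
                             per_genotype = NULL) {
  stopifnot(inherits(pqm, "protein_quant"))
  design <- check_design(design)
  if (!all(FRACTIONS %in% design$fraction))
    stop_config("design must contain all four fractions (%s)",
                paste(FRACTIONS, collapse = ", "))
  if (!is.null(per_genotype))
    design <- design[design$genotype == per_genotype, , drop = FALSE]
  ab <- pqm$abundance
  frac_samples <- lapply(FRACTIONS, function(f)
    intersect(design$sample_id[design$fraction == f], colnames(ab)))
  names(frac_samples) <- FRACTIONS

  n <- nrow(ab)
  out <- data.frame(protein_id = rownames(ab),
                    top_fraction = NA_character_,
                    p_vs_SP = NA_real_, p_vs_IM = NA_real_,
                    copurifying = FALSE, testable = TRUE,
                    reason = "", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    vals <- lapply(frac_samples, function(s) {
      v <- ab[i, s]; v[!is.na(v)]
    })
    means <- vapply(vals, function(v)
      if (length(v)) mean(v) else NA_real_, numeric(1))
    if (all(is.na(means))) {
      out$testable[i] <- FALSE
      out$reason[i] <- "no quantified fraction"
      next
    }
    top <- names(means)[which.max(means)]
    out$top_fraction[i] <- top
    mem <- if (isTRUE(means[["DRM"]] >= means[["DSF"]]) ||
               is.na(means[["DSF"]])) "DRM" else "DSF"
    ref <- vals[[mem]]
    enough <- vapply(vals, length, 1L) >= 2L
    if (!all(enough)) {
      out$testable[i] <- FALSE
      out$reason[i] <- sprintf("fraction(s) with <2 replicates: %s",
                               paste(FRACTIONS[!enough], collapse = ","))
    } else {
      out$p_vs_SP[i] <- welch_p_greater(vals$SP, ref)
      out$p_vs_IM[i] <- welch_p_greater(vals$IM, ref)
    }
    test_hit <- (!is.na(out$p_vs_SP[i]) && out$p_vs_SP[i] < alpha) ||
      (!is.na(out$p_vs_IM[i]) && out$p_vs_IM[i] < alpha)
    if (top %in% c("SP", "IM")) {
      out$copurifying[i] <- TRUE
      out$reason[i] <- paste0("highest abundance in ", top)
    } else if (test_hit) {
      out$copurifying[i] <- TRUE
      out$reason[i] <- "SP/IM significantly above best membrane fraction"
    }
  }
  class(out) <- c("copurify_calls", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

# one-sided Welch t-test p-value for mean(a) > mean(b)
welch_p_greater <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  if (sd(a) == 0 && sd(b) == 0)
    return(if (mean(a) > mean(b)) 0 else 1)
  tryCatch(t.test(a, b, alternative = "greater")$p.value,
           error = function(e) NA_real_)
}

#' Remove co-purifying proteins from ratio-shift results
#'
#' Significant proteins flagged as co-purifying are moved to an excluded
#' list — retained for reporting, not silently dropped. Proteins in the
#' results that are absent from the calls table (or vice versa for
#' significant proteins) raise an explicit join error listing the orphans.
#'
#' @param results a `shift_result` table (see [test_partition_shift()]).
#' @param calls a `copurify_calls` table.
#' @return list with `filtered` (results minus excluded proteins) and
#'   `excluded` (co-purifying significant proteins, with call columns).
#' @export
filter_copurifying <- function(results, calls) {
  orphans <- setdiff(results$protein_id, calls$protein_id)
  if (length(orphans))
    stop_config("proteins missing from co-purification calls: %s",
                paste(utils::head(orphans, 10), collapse = ", "))
  cop <- calls$protein_id[calls$copurifying]
  drop <- results$significant & results$protein_id %in% cop
  info_cols <- intersect(c("protein_id", "top_fraction", "reason"),
                         names(calls))
  excluded <- merge(results[drop, , drop = FALSE],
                    calls[, info_cols, drop = FALSE], by = "protein_id")
  filtered <- results[!drop, , drop = FALSE]
  rownames(filtered) <- NULL
  list(filtered = filtered, excluded = excluded)
}
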