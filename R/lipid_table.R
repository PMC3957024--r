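#' Lipid intensity table
#'
#' A light container pairing per-species metadata (class, acyl carbons,
#' double bonds, optional hydroxylation for Cer/GlcCer) with a species x
#' sample intensity matrix. Class labels come from a controlled vocabulary;
#' TAG is carried but excluded from normalization denominators.
#'
#' @param meta data.frame with columns `lipid_id`, `class`, `acyl_carbons`,
#'   `double_bonds`, `hydroxylation`.
#' @param intensity numeric matrix, rows matching `meta$lipid_id`.
#' @param mode ionization mode label ("positive", "negative", or "mixed").
#' @return an object of class `lipid_table`.
#' @export
lipid_table <- function(meta, intensity, mode = "mixed") {
  stopifnot(is.data.frame(meta), "lipid_id" %in% names(meta),
            "class" %in% names(meta))
  intensity <- as.matrix(intensity)
  if (nrow(meta) != nrow(intensity))
    stop_config("meta and intensity row counts differ")
  if (any(intensity < 0, na.rm = TRUE))
    stop_config("lipid intensities must be non-negative")
  unknown <- setdiff(unique(meta$class), LIPID_CLASSES)
  if (length(unknown))
    stop_config("unknown lipid classes: %s", paste(unknown, collapse = ", "))
  rownames(intensity) <- meta$lipid_id
  if (!"mode" %in% names(meta)) meta$mode <- rep(mode, nrow(meta))
  structure(list(meta = meta, intensity = intensity),
            class = "lipid_table")
}

#' @export
print.lipid_table <- function(x, ...) {
  cat(sprintf("lipid_table: %d species x %d samples (%d classes)\n",
              nrow(x$intensity), ncol(x$intensity),
              length(unique(x$meta$class))))
  invisible(x)
}

#' @export
dim.lipid_table <- function(x) dim(x$intensity)

#' Combine positive- and negative-mode lipid tables
#'
#' Positive- and negative-mode detections are combined into a single table
#' before normalization. A species detected in both modes is kept as two
#' distinct rows whose ids are suffixed with the mode. A species id present
#' in both inputs with conflicting class metadata is an error.
#'
#' @param pos,neg `lipid_table` objects (either may be empty).
#' @return a combined `lipid_table` with mode recorded per row.
#' @export
merge_modes <- function(pos, neg) {
  stopifnot(inherits(pos, "lipid_table"), inherits(neg, "lipid_table"))
  if (nrow(pos$intensity) == 0) return(neg)
  if (nrow(neg$intensity) == 0) return(pos)
  if (!identical(colnames(pos$intensity), colnames(neg$intensity)))
    stop_config("mode tables must share an identical sample set")
  shared <- intersect(pos$meta$lipid_id, neg$meta$lipid_id)
  for (id in shared) {
    a <- pos$meta[pos$meta$lipid_id == id,
                  c("class", "acyl_carbons", "double_bonds")]
    b <- neg$meta[neg$meta$lipid_id == id,
                  c("class", "acyl_carbons", "double_bonds")]
    if (!isTRUE(all.equal(as.list(a), as.list(b), check.attributes = FALSE)))
      stop_config("conflicting class metadata for '%s' across modes", id)
  }
  pm <- pos$meta; nm <- neg$meta
  pm$lipid_id <- ifelse(pm$lipid_id %in% shared,
                        paste0(pm$lipid_id, " [pos]"), pm$lipid_id)
  nm$lipid_id <- ifelse(nm$lipid_id %in% shared,
                        paste0(nm$lipid_id, " [neg]"), nm$lipid_id)
  meta <- rbind(pm, nm)
  inten <- rbind(pos$intensity, neg$intensity)
  rownames(inten) <- meta$lipid_id
  out <- lipid_table(meta, inten, mode = "mixed")
  out$meta$mode <- c(pm$mode, nm$mode)
  out
}

#' Normalize a lipid table to fraction-of-total ion intensity
#'
#' The per-sample denominator is the intensity sum over a low-variation
#' reference set: non-TAG species whose coefficient of variation across all
#' samples is strictly below the median CV of all species. Every species
#' (including TAG) is then divided by its sample's denominator. If the strict
#' rule leaves the reference set empty (ties at the median, e.g. several
#' zero-variance species), the non-strict rule (CV at most the median) is
#' used with a warning; should that also be empty, all non-TAG species are
#' used.
#'
#' @param table a `lipid_table` (modes already combined).
#' @param variation how per-species variation is measured: coefficient of
#'   variation (default) or standard deviation.
#' @return a normalized `lipid_table`; the reference species ids are stored
#'   in `attr(, "reference_set")`.
#' @export
normalize_lipids <- function(table, variation = c("cv", "sd")) {
  stopifnot(inherits(table, "lipid_table"))
  variation <- match.arg(variation)
  x <- table$intensity
  non_tag <- table$meta$class != "TAG"
  if (sum(non_tag) < 2)
    stop_config("need at least two non-TAG lipids to normalize")
  v <- apply(x, 1, function(r) {
    m <- mean(r, na.rm = TRUE)
    s <- sd(r, na.rm = TRUE)
    if (variation == "cv") (if (m > 0) s / m else NA_real_) else s
  })
  med_v <- median(v, na.rm = TRUE)
  ref <- non_tag & !is.na(v) & v < med_v
  if (!any(ref)) {
    warning("strict low-variation reference set empty; falling back to CV <= median")
    ref <- non_tag & !is.na(v) & v <= med_v
    if (!any(ref)) ref <- non_tag
  }
  denom <- colSums(x[ref, , drop = FALSE], na.rm = TRUE)
  if (any(denom <= 0))
    stop_config("non-positive normalization denominator in sample(s): %s",
                paste(colnames(x)[denom <= 0], collapse = ", "))
  out <- table
  out$intensity <- sweep(x, 2, denom, "/")
  attr(out, "reference_set") <- table$meta$lipid_id[ref]
  out
}

#' Z-scale and log2-transform a normalized lipid table
#'
#' Each species is z-scaled across samples, all values are shifted by a
#' single global constant `c = |min(z)| + 1` so the minimum maps to 1, and
#' log2 is applied. The shift constant is recorded in
#' `attr(, "shift_constant")`. Species with zero variance get a zero z-score
#' vector and are flagged in `attr(, "constant_lipids")`.
#'
#' @param table a normalized `lipid_table`.
#' @return a transformed `lipid_table` of log2 z-scores.
#' @export
transform_lipids <- function(table) {
  stopifnot(inherits(table, "lipid_table"))
  x <- table$intensity
  mu <- rowMeans(x, na.rm = TRUE)
  sdv <- apply(x, 1, sd, na.rm = TRUE)
  flat <- !is.na(sdv) & sdv == 0
  z <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  z[flat, ] <- 0
  cshift <- abs(min(z, na.rm = TRUE)) + 1
  out <- table
  out$intensity <- log2(z + cshift)
  attr(out, "shift_constant") <- cshift
  attr(out, "constant_lipids") <- table$meta$lipid_id[flat]
  out
}

#' Differential lipid abundance between genotypes
#'
#' Per-species Welch t-tests compare mutant against wildtype on the
#' log2-transformed z-scores; log2 fold changes are computed on the
#' normalized (pre-transform) intensities. The same procedure is applied to
#' per-sample class sums of normalized intensities for a class-level table.
#' No multiple-testing correction is applied to the significance call by
#' default; a Benjamini-Hochberg column is emitted for reference.
#'
#' @param table a normalized (untransformed) `lipid_table`.
#' @param design data.frame with `sample_id` and `genotype`; the wildtype
#'   label is taken from `wildtype`.
#' @param alpha species-level significance level for the Welch test.
#' @param wildtype reference genotype label.
#' @param mutant mutant genotype label; defaults to the single non-wildtype
#'   genotype in the design.
#' @return list of data.frames `species` and `class`, each with `log2_fc`,
#'   `p_value`, `p_adj`, `significant` (p < alpha) and `fold_change_flag`
#'   (|log2FC| > 1).
#' @export
differential_lipids <- function(table, design, alpha = 0.05,
                                wildtype = "wildtype", mutant = NULL) {
  stopifnot(inherits(table, "lipid_table"))
  design <- as.data.frame(design)
  if (!all(c("sample_id", "genotype") %in% names(design)))
    stop_config("design needs sample_id and genotype columns")
  genos <- unique(design$genotype)
  if (!wildtype %in% genos)
    stop_config("wildtype genotype '%s' absent from design", wildtype)
  mutant <- mutant %||% setdiff(genos, wildtype)
  if (length(mutant) != 1L)
    stop_config("exactly one mutant genotype required (got: %s)",
                paste(mutant, collapse = ", "))
  wt_s <- design$sample_id[design$genotype == wildtype]
  mu_s <- design$sample_id[design$genotype == mutant]
  if (length(wt_s) < 2 || length(mu_s) < 2)
    stop_config("need >=2 replicates per genotype")
  missing_cols <- setdiff(c(wt_s, mu_s), colnames(table$intensity))
  if (length(missing_cols))
    stop_config("samples absent from lipid table: %s",
                paste(missing_cols, collapse = ", "))

  trans <- transform_lipids(table)
  species <- diff_test_matrix(table$intensity, trans$intensity, wt_s, mu_s,
                              alpha)
  species <- cbind(data.frame(lipid_id = table$meta$lipid_id,
                              class = table$meta$class,
                              stringsAsFactors = FALSE), species)

  cls_norm <- rowsum_by_class(table$intensity, table$meta$class)
  cls_tab <- lipid_table(data.frame(lipid_id = rownames(cls_norm),
                                    class = rownames(cls_norm),
                                    acyl_carbons = NA_integer_,
                                    double_bonds = NA_integer_,
                                    hydroxylation = NA_integer_,
                                    stringsAsFactors = FALSE), cls_norm)
  cls_trans <- transform_lipids(cls_tab)
  cls <- diff_test_matrix(cls_norm, cls_trans$intensity, wt_s, mu_s, alpha)
  cls <- cbind(data.frame(class = rownames(cls_norm),
                          stringsAsFactors = FALSE), cls)

  list(species = species, class = cls)
}

rowsum_by_class <- function(x, classes) {
  out <- rowsum(x, group = classes, na.rm = TRUE)
  out[order(rownames(out)), , drop = FALSE]
}

diff_test_matrix <- function(norm, trans, wt_s, mu_s, alpha) {
  n <- nrow(norm)
  res <- data.frame(log2_fc = numeric(n), p_value = numeric(n))
  for (i in seq_len(n)) {
    wt_n <- norm[i, wt_s]; mu_n <- norm[i, mu_s]
    res$log2_fc[i] <- log2(mean(mu_n, na.rm = TRUE) /
                             mean(wt_n, na.rm = TRUE))
    wt_t <- trans[i, wt_s]; mu_t <- trans[i, mu_s]
    res$p_value[i] <- welch_p(mu_t, wt_t)
  }
  res$p_adj <- stats::p.adjust(res$p_value, "BH")
  res$significant <- !is.na(res$p_value) & res$p_value < alpha
  res$fold_change_flag <- !is.na(res$log2_fc) & abs(res$log2_fc) > 1
  res
}

welch_p <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  if (sd(a) == 0 && sd(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  tryCatch(t.test(a, b)$p.value, error = function(e) NA_real_)
}
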