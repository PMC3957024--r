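#' Filter peptides by per-fraction presence
#'
#' A peptide is retained if and only if there is at least one fraction in
#' which it was quantified in at least `min_presence` of that fraction's
#' samples. By default presence is pooled across genotypes; with
#' `per_genotype = TRUE` the rule is evaluated within each genotype x
#' fraction cell. The alternative reading of the exclusion rule — require
#' sufficient presence in every fraction — is available via
#' `scope = "all_fractions"`, but discards fraction-specific proteins and is
#' not the default.
#'
#' @param evidence data.frame with `peptide_id`, `protein_id`, `sample_id`,
#'   `intensity` (rows are observations; missing values may appear as NA or
#'   as absent rows).
#' @param design data.frame with `sample_id`, `genotype`, `fraction`.
#' @param min_presence minimum quantified proportion (default 0.70).
#' @param scope retain on >= min_presence in any one fraction (default) or
#'   require it in all fractions.
#' @param per_genotype evaluate presence within genotype x fraction cells.
#' @return the retained evidence subset; removed peptides (with their best
#'   presence proportion) are in `attr(, "removed")`.
#' @export
filter_peptides <- function(evidence, design, min_presence = 0.70,
                            scope = c("any_fraction", "all_fractions"),
                            per_genotype = FALSE) {
  scope <- match.arg(scope)
  check_evidence(evidence)
  design <- check_design(design, evidence)
  if (nrow(evidence) == 0) {
    out <- evidence
    attr(out, "removed") <- data.frame(peptide_id = character(0),
                                       best_presence = numeric(0))
    return(out)
  }
  obs <- evidence[!is.na(evidence$intensity), , drop = FALSE]
  cell <- if (per_genotype)
    paste(design$genotype, design$fraction) else design$fraction
  cell_size <- table(cell)
  obs_cell <- cell[match(obs$sample_id, design$sample_id)]
  # presence proportion per peptide x cell, counting distinct samples
  key <- paste(obs$peptide_id, obs_cell, sep = "\r")
  key <- key[!duplicated(paste(key, obs$sample_id, sep = "\r"))]
  counts <- table(key)
  split_key <- strsplit(names(counts), "\r", fixed = TRUE)
  pep <- vapply(split_key, `[`, "", 1L)
  cl <- vapply(split_key, `[`, "", 2L)
  prop <- as.numeric(counts) / as.numeric(cell_size[cl])
  agg_fun <- if (scope == "any_fraction") max else min
  # peptides absent from some cell have presence 0 there; under
  # "all_fractions" that forces removal unless seen in every cell
  best <- tapply(prop, pep, agg_fun)
  if (scope == "all_fractions") {
    n_cells <- length(cell_size)
    seen_cells <- tapply(cl, pep, function(z) length(unique(z)))
    best[seen_cells < n_cells] <- 0
  }
  all_pep <- unique(evidence$peptide_id)
  best_all <- setNames(numeric(length(all_pep)), all_pep)
  best_all[names(best)] <- best
  keep <- names(best_all)[best_all >= min_presence]
  out <- evidence[evidence$peptide_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- data.frame(
    peptide_id = setdiff(all_pep, keep),
    best_presence = unname(best_all[setdiff(all_pep, keep)]),
    stringsAsFactors = FALSE)
  out
}

#' Normalize peptide intensities to fraction of total ion intensity
#'
#' Within each sample, every intensity is divided by the sum of quantified
#' intensities in that sample, so retained peptide values sum to one per
#' sample. Samples with no quantified peptide are dropped with a warning.
#'
#' @param evidence filtered evidence data.frame.
#' @return evidence with `intensity` replaced by per-sample fractions.
#' @export
normalize_total_ion <- function(evidence) {
  check_evidence(evidence)
  if (nrow(evidence) == 0) return(evidence)
  sums <- tapply(evidence$intensity, evidence$sample_id, sum, na.rm = TRUE)
  dead <- names(sums)[!is.finite(sums) | sums <= 0]
  if (length(dead)) {
    warning(sprintf("dropping sample(s) with no quantified peptides: %s",
                    paste(dead, collapse = ", ")))
    evidence <- evidence[!evidence$sample_id %in% dead, , drop = FALSE]
    sums <- sums[setdiff(names(sums), dead)]
  }
  evidence$intensity <- evidence$intensity /
    as.numeric(sums[evidence$sample_id])
  rownames(evidence) <- NULL
  evidence
}

#' Aggregate normalized peptide intensities to protein abundances
#'
#' Two-step reduction: (1) median scaling — each peptide's profile is
#' divided by the median of its quantified values across samples, removing
#' peptide-specific ionization efficiency; (2) median averaging — a
#' protein's abundance in a sample is the median over its peptides' scaled
#' values there, multiplied back by the protein-level median of the peptide
#' scales so units remain fraction-of-total. Cells with no contributing
#' peptide are NA.
#'
#' @param evidence normalized evidence data.frame.
#' @param design sample design data.frame.
#' @return a `protein_quant` object: list with `abundance` (protein x
#'   sample matrix), `n_peptides` (contributing peptide counts per cell)
#'   and `design`.
#' @export
aggregate_protein <- function(evidence, design) {
  check_evidence(evidence)
  design <- check_design(design, evidence)
  samples <- design$sample_id
  prot_split <- split(evidence, evidence$protein_id)
  prots <- names(prot_split)
  ab <- matrix(NA_real_, length(prots), length(samples),
               dimnames = list(prots, samples))
  np <- matrix(0L, length(prots), length(samples),
               dimnames = list(prots, samples))
  for (p in seq_along(prot_split)) {
    ev <- prot_split[[p]]
    m <- matrix(NA_real_, length(unique(ev$peptide_id)), length(samples),
                dimnames = list(unique(ev$peptide_id), samples))
    m[cbind(match(ev$peptide_id, rownames(m)),
            match(ev$sample_id, samples))] <- ev$intensity
    scale_j <- apply(m, 1, median, na.rm = TRUE)
    scaled <- m / scale_j
    prot_scale <- median(scale_j, na.rm = TRUE)
    ab[p, ] <- apply(scaled, 2, median, na.rm = TRUE) * prot_scale
    np[p, ] <- colSums(!is.na(scaled))
  }
  ab[is.nan(ab)] <- NA_real_
  structure(list(abundance = ab, n_peptides = np, design = design),
            class = "protein_quant")
}

#' @export
print.protein_quant <- function(x, ...) {
  cat(sprintf("protein_quant: %d proteins x %d samples\n",
              nrow(x$abundance), ncol(x$abundance)))
  invisible(x)
}

#' Average technical injections into biological replicates
#'
#' When the design carries an `injection` column, evidence rows are averaged
#' (mean of quantified intensities) over injections of the same biological
#' sample before any statistics, and the design is collapsed accordingly.
#'
#' @param evidence evidence data.frame whose `sample_id` refers to
#'   injection-level samples.
#' @param design design with columns `sample_id`, `genotype`, `fraction`,
#'   `replicate`, `injection`.
#' @return list with collapsed `evidence` and `design`.
#' @export
average_injections <- function(evidence, design) {
  if (!"injection" %in% names(design))
    return(list(evidence = evidence, design = design))
  design$bio_id <- sprintf("%s_%s_r%d", design$genotype, design$fraction,
                           design$replicate)
  evidence$bio_id <- design$bio_id[match(evidence$sample_id,
                                         design$sample_id)]
  agg <- aggregate(intensity ~ peptide_id + protein_id + bio_id,
                   data = evidence, FUN = mean, na.rm = TRUE,
                   na.action = stats::na.pass)
  names(agg)[names(agg) == "bio_id"] <- "sample_id"
  new_design <- unique(design[, c("bio_id", "genotype", "fraction",
                                  "replicate")])
  names(new_design)[1] <- "sample_id"
  rownames(new_design) <- NULL
  list(evidence = agg[, c("peptide_id", "protein_id", "sample_id",
                          "intensity")],
       design = new_design)
}

check_evidence <- function(evidence) {
  need <- c("peptide_id", "protein_id", "sample_id", "intensity")
  miss <- setdiff(need, names(evidence))
  if (length(miss))
    stop_config("evidence lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(evidence$intensity < 0, na.rm = TRUE))
    stop_config("negative intensities in evidence")
  invisible(evidence)
}

check_design <- function(design, evidence = NULL) {
  design <- as.data.frame(design)
  need <- c("sample_id", "genotype", "fraction")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop_config("design lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop_config("duplicate sample_id in design")
  if (!is.null(evidence) && nrow(evidence)) {
    orphan <- setdiff(unique(evidence$sample_id), design$sample_id)
    if (length(orphan))
      stop_config("evidence samples missing from design: %s",
                  paste(orphan, collapse = ", "))
  }
  design
}
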