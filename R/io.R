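#' Read a MaxQuant-style evidence table
#'
#' Reads a tab-separated evidence export and maps its columns onto the
#' canonical evidence layout (`peptide_id`, `protein_id`, `sample_id`,
#' `intensity`). The default mapping matches a minimal MaxQuant
#' `evidence.txt` dialect (Sequence, Proteins, Raw file, Intensity).
#'
#' @param path TSV file path.
#' @param col_map named character vector mapping canonical names to file
#'   column names.
#' @return canonical evidence data.frame.
#' @export
read_evidence <- function(path,
                          col_map = c(peptide_id = "Sequence",
                                      protein_id = "Proteins",
                                      sample_id = "Raw.file",
                                      intensity = "Intensity")) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = TRUE)
  miss <- setdiff(unname(col_map), names(raw))
  if (length(miss))
    stop_config("evidence file lacks column(s): %s",
                paste(miss, collapse = ", "))
  out <- data.frame(peptide_id = raw[[col_map[["peptide_id"]]]],
                    protein_id = raw[[col_map[["protein_id"]]]],
                    sample_id = raw[[col_map[["sample_id"]]]],
                    intensity = as.numeric(raw[[col_map[["intensity"]]]]),
                    stringsAsFactors = FALSE)
  check_evidence(out)
  out
}

#' Write evidence in the minimal MaxQuant dialect
#' @param evidence canonical evidence data.frame.
#' @param path output TSV path.
#' @export
write_evidence <- function(evidence, path) {
  check_evidence(evidence)
  out <- data.frame(Sequence = evidence$peptide_id,
                    Proteins = evidence$protein_id,
                    `Raw file` = evidence$sample_id,
                    Intensity = evidence$intensity,
                    check.names = FALSE)
  write_tsv(out, path)
}

#' Write a data.frame as deterministic TSV
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Write a lipid table (metadata + intensities) as TSV
#' @param table a `lipid_table`.
#' @param path output path.
#' @export
write_lipid_table <- function(table, path) {
  stopifnot(inherits(table, "lipid_table"))
  write_tsv(cbind(table$meta, as.data.frame(table$intensity)), path)
}

#' Read a lipid table written by [write_lipid_table()]
#' @param path TSV path.
#' @return a `lipid_table`.
#' @export
read_lipid_table <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("lipid_id", "class", "acyl_carbons", "double_bonds",
                 "hydroxylation", "mode")
  meta_cols <- intersect(meta_cols, names(raw))
  inten <- as.matrix(raw[, setdiff(names(raw), meta_cols), drop = FALSE])
  out <- lipid_table(raw[, meta_cols, drop = FALSE], inten)
  out
}

#' Write protein quantities as TSV
#' @param pqm a `protein_quant`.
#' @param path output path.
#' @export
write_protein_quant <- function(pqm, path) {
  stopifnot(inherits(pqm, "protein_quant"))
  df <- data.frame(protein_id = rownames(pqm$abundance),
                   as.data.frame(pqm$abundance), check.names = FALSE)
  write_tsv(df, path)
}
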