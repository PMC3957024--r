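#' End-to-end pipeline run
#'
#' Executes the full inference chain — simulate (or load) inputs, peptide
#' filtering and normalization, protein aggregation, ratio-shift testing,
#' co-purification filtering, lipid normalization and differential testing,
#' combined-score network with permutation FDR — writing every intermediate
#' table, a manifest (package version, parameters, seed, file checksums)
#' and a human-readable summary to `out_dir`. With a fixed seed two runs
#' produce byte-identical outputs.
#'
#' @param config either a [sim_config()] (simulation mode) or a list with
#'   paths `evidence`, `design`, `lipids_pos`, `lipids_neg`,
#'   `lipid_design`.
#' @param out_dir output directory (created if needed).
#' @param params list of stage parameters overriding the defaults:
#'   `min_presence` (0.70), `fdr_protein` (0.01), `alpha_copurify` (0.01),
#'   `alpha_lipid` (0.05), `fdr_edges` (0.01), `n_boot` (1000), `n_perm`
#'   (200), `seed` (1).
#' @param skip_lipids if TRUE, the lipid stage is skipped; the network
#'   stage then refuses to run unless `run_network = FALSE` as well.
#' @param run_network whether the network stage is requested (default TRUE).
#' @param annotations optional protein annotation data.frame passed to
#'   [build_graph()].
#' @return the manifest (invisibly), a list describing the run.
#' @export
run_pipeline <- function(config, out_dir, params = list(),
                         skip_lipids = FALSE, run_network = TRUE,
                         annotations = NULL) {
  p <- utils::modifyList(list(min_presence = 0.70, fdr_protein = 0.01,
                              alpha_copurify = 0.01, alpha_lipid = 0.05,
                              fdr_edges = 0.01, n_boot = 1000,
                              n_perm = 200, seed = 1L), params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  simulate <- inherits(config, "sim_config")
  if (simulate) {
    sim <- stage("simulate", simulate_evidence(config))
    evidence <- sim$evidence; design <- sim$design
    write_evidence(evidence, file.path(out_dir, "evidence.tsv"))
    write_tsv(design, file.path(out_dir, "design.tsv"))
    jsonlite::write_json(sim$truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    evidence <- stage("load", read_evidence(config$evidence))
    design <- stage("load", read.delim(config$design,
                                       stringsAsFactors = FALSE))
  }

  ev <- stage("filter_peptides",
              filter_peptides(evidence, design, p$min_presence))
  write_tsv(attr(ev, "removed"),
            file.path(out_dir, "removed_peptides.tsv"))
  ev <- stage("normalize", normalize_total_ion(ev))
  pqm <- stage("aggregate", aggregate_protein(ev, design))
  write_protein_quant(pqm, file.path(out_dir, "protein_quant.tsv"))

  shift <- stage("shift_test",
                 test_partition_shift(pqm, design, fdr = p$fdr_protein,
                                      n_boot = p$n_boot, n_perm = p$n_perm,
                                      seed = p$seed))
  write_tsv(as.data.frame(shift), file.path(out_dir, "shift_results.tsv"))

  calls <- stage("copurify", flag_copurifying(pqm, design,
                                              alpha = p$alpha_copurify))
  write_tsv(as.data.frame(calls), file.path(out_dir, "copurify_calls.tsv"))
  filt <- stage("copurify", filter_copurifying(shift, calls))
  write_tsv(filt$filtered, file.path(out_dir, "shift_results_filtered.tsv"))
  write_tsv(filt$excluded, file.path(out_dir, "excluded_proteins.tsv"))

  lipid_res <- NULL; graph <- NULL; edges <- NULL
  if (!skip_lipids) {
    if (simulate) {
      lip <- stage("simulate_lipids", simulate_lipids(config))
      lipid_design <- lip$design
      write_lipid_table(lip$pos, file.path(out_dir, "lipids_pos.tsv"))
      write_lipid_table(lip$neg, file.path(out_dir, "lipids_neg.tsv"))
      pos <- lip$pos; neg <- lip$neg
    } else {
      pos <- stage("load", read_lipid_table(config$lipids_pos))
      neg <- stage("load", read_lipid_table(config$lipids_neg))
      lipid_design <- read.delim(config$lipid_design,
                                 stringsAsFactors = FALSE)
    }
    merged <- stage("merge_modes", merge_modes(pos, neg))
    norm <- stage("normalize_lipids", normalize_lipids(merged))
    write_lipid_table(norm, file.path(out_dir, "lipids_normalized.tsv"))
    lipid_res <- stage("differential_lipids",
                       differential_lipids(norm, lipid_design,
                                           alpha = p$alpha_lipid))
    write_tsv(lipid_res$species, file.path(out_dir, "lipid_results.tsv"))
    write_tsv(lipid_res$class, file.path(out_dir, "lipid_class_results.tsv"))

    if (run_network) {
      edges <- stage("network", score_edges(filt$filtered,
                                            lipid_res$species))
      enough <- length(unique(edges$protein_id)) >= 2 &&
        length(unique(edges$lipid_id)) >= 2
      if (nrow(edges) > 0 && !enough) {
        warning("too few significant proteins/lipids for an edge null; no edges called")
        edges$significant <- FALSE
      }
      if (nrow(edges) > 0 && enough) {
        edges <- stage("network",
                       edge_fdr_threshold(edges, fdr = p$fdr_edges,
                                          n_perm = p$n_perm,
                                          seed = p$seed + 1L))
        graph <- stage("network",
                       build_graph(edges, filt$filtered, lipid_res$species,
                                   annotations))
        igraph::write_graph(graph, file.path(out_dir, "network.graphml"),
                            format = "graphml")
      }
      write_tsv(as.data.frame(edges), file.path(out_dir, "edges.tsv"))
    }
  } else if (run_network) {
    stop("pipeline stage 'network' failed: network stage requires lipid results; rerun without skip_lipids or set run_network = FALSE",
         call. = FALSE)
  }

  summary_lines <- pipeline_summary(shift, filt, lipid_res, edges, graph)
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "raftomics",
    version = as.character(packageVersion("raftomics")),
    mode = if (simulate) "simulation" else "files",
    params = p,
    seed = p$seed,
    sim_seed = if (simulate) config$seed else NULL,
    skip_lipids = skip_lipids,
    checksums = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

pipeline_summary <- function(shift, filt, lipid_res, edges, graph) {
  lines <- c("raftomics pipeline summary", "==========================")
  n_sig <- sum(shift$significant)
  lines <- c(lines,
             sprintf("proteins tested: %d of %d", sum(shift$testable),
                     nrow(shift)),
             sprintf("significant DRM/DSF shifts: %d (enriched %d, depleted %d)",
                     n_sig, sum(shift$direction == "enriched"),
                     sum(shift$direction == "depleted")),
             sprintf("co-purifying (excluded from interpretation): %d",
                     nrow(filt$excluded)))
  if (!is.null(lipid_res)) {
    sp <- lipid_res$species
    sig_cls <- table(sp$class[sp$significant])
    lines <- c(lines,
               sprintf("significant lipids: %d of %d%s", sum(sp$significant),
                       nrow(sp),
                       if (length(sig_cls))
                         paste0(" (", paste(names(sig_cls), sig_cls,
                                            sep = ":", collapse = ", "), ")")
                       else ""))
  }
  if (!is.null(edges) && nrow(edges) && "significant" %in% names(edges))
    lines <- c(lines, sprintf("network edges: %d significant of %d candidates",
                              sum(edges$significant), nrow(edges)))
  if (!is.null(graph)) {
    vt <- igraph::V(graph)$type
    if (any(vt)) {
      deg <- igraph::V(graph)$degree[vt]
      top <- igraph::V(graph)$name[vt][which.max(deg)]
      lines <- c(lines,
                 sprintf("network: %d protein and %d lipid nodes; top-degree lipid: %s (degree %d)",
                         sum(!vt), sum(vt), top, max(deg)))
    }
  }
  lines
}
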