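#' Combined lipid-protein edge scores
#'
#' For every protein called significant in the ratio-shift analysis and
#' every lipid with a defined log2 fold change, the combined score is the
#' product of the lipid's log2 fold change (mutant vs wildtype) and the
#' protein's ratio-shift score. Only significantly altered proteins enter
#' the cross.
#'
#' @param shift_results a `shift_result` table.
#' @param lipid_results species-level data.frame from
#'   [differential_lipids()] (needs `lipid_id` and `log2_fc`).
#' @return data.frame of class `edge_scores`: `protein_id`, `lipid_id`,
#'   `score`, `sign`.
#' @export
score_edges <- function(shift_results, lipid_results) {
  sig <- shift_results[shift_results$significant &
                         is.finite(shift_results$score), , drop = FALSE]
  lip <- lipid_results[is.finite(lipid_results$log2_fc), , drop = FALSE]
  if (nrow(sig) == 0) {
    warning("no significant proteins; empty edge table")
    out <- data.frame(protein_id = character(0), lipid_id = character(0),
                      score = numeric(0), sign = character(0))
    class(out) <- c("edge_scores", "data.frame")
    return(out)
  }
  out <- expand.grid(protein_id = sig$protein_id, lipid_id = lip$lipid_id,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$score <- sig$score[match(out$protein_id, sig$protein_id)] *
    lip$log2_fc[match(out$lipid_id, lip$lipid_id)]
  out$sign <- ifelse(out$score > 0, "positive",
                     ifelse(out$score < 0, "negative", "zero"))
  attr(out, "protein_scores") <- setNames(sig$score, sig$protein_id)
  attr(out, "lipid_fcs") <- setNames(lip$log2_fc, lip$lipid_id)
  class(out) <- c("edge_scores", "data.frame")
  out
}

#' Permutation FDR threshold for edge scores
#'
#' The null score population is built by independently shuffling (without
#' replacement) the protein score vector and the lipid fold-change vector
#' and pairing them positionally (the shorter vector recycled), `n_perm`
#' rounds; each round's factor marginals are exact permutations of the
#' observed ones while the pairing is broken. Per-tail thresholds follow
#' the same expected-exceedance rule as the protein-level calibration,
#' with the null tail proportion scaled to the candidate edge count. Edges
#' below threshold are flagged non-significant (all candidates are
#' returned).
#'
#' @param edges an `edge_scores` table from [score_edges()].
#' @param fdr target FDR (default 0.01; the stricter 1e-4 reading is a
#'   supported alternative).
#' @param n_perm shuffle rounds (default 200).
#' @param seed optional RNG seed.
#' @return `edges` with a `significant` column; thresholds in
#'   `attr(, "thresholds")`.
#' @export
edge_fdr_threshold <- function(edges, fdr = 0.01, n_perm = 200,
                               seed = NULL) {
  stopifnot(inherits(edges, "edge_scores"))
  if (!is.null(seed)) set.seed(seed)
  pscores <- attr(edges, "protein_scores")
  fcs <- attr(edges, "lipid_fcs")
  if (length(pscores) < 2 || length(fcs) < 2)
    stop_config("need at least two proteins and two lipids for a null")
  len <- max(length(pscores), length(fcs))
  recycle <- function(x) x[((seq_len(len) - 1L) %% length(x)) + 1L]
  null <- replicate(n_perm,
                    recycle(sample(pscores)) * recycle(sample(fcs)))
  if (all(null == 0)) {
    warning("degenerate (all-zero) null; retaining all candidate edges")
    edges$significant <- TRUE
    attr(edges, "thresholds") <- list(lower = -Inf, upper = Inf)
    return(edges)
  }
  thr <- calibrate_fdr_threshold(edges$score, null, n_perm, fdr)
  edges$significant <-
    (is.finite(thr$upper) & edges$score >= thr$upper) |
    (is.finite(thr$lower) & edges$score <= thr$lower)
  attr(edges, "thresholds") <- thr[c("lower", "upper")]
  attr(edges, "null_scores") <- as.numeric(null)
  edges
}

#' Build the bipartite lipid-protein network
#'
#' Significant edges become a bipartite igraph graph: protein nodes carry
#' subcellular localization, DRM/DSF direction, protein-group label and PTM
#' flags; lipid nodes carry class and fold-change direction. Missing
#' annotations default to "unknown". Node degree (count of incident
#' significant edges) is stored as a vertex attribute.
#'
#' @param edges an `edge_scores` table with a `significant` column.
#' @param shift_results optional `shift_result` table supplying protein
#'   direction.
#' @param lipid_results optional species table supplying lipid class and
#'   fold-change direction.
#' @param annotations optional data.frame keyed by `protein_id` with any of
#'   `localization`, `group`, `ptm`.
#' @return an igraph object; vertex attribute `type` is TRUE for lipids
#'   (igraph bipartite convention).
#' @export
build_graph <- function(edges, shift_results = NULL, lipid_results = NULL,
                        annotations = NULL) {
  sig <- edges[isTRUE_vec(edges$significant), , drop = FALSE]
  key <- paste(sig$protein_id, sig$lipid_id, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate edges collapsed (keeping first occurrence)")
    sig <- sig[!duplicated(key), , drop = FALSE]
  }
  prot <- unique(sig$protein_id)
  lip <- unique(sig$lipid_id)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(prot), name = prot, type = FALSE)
  g <- igraph::add_vertices(g, length(lip), name = lip, type = TRUE)
  if (nrow(sig))
    g <- igraph::add_edges(g, rbind(match(sig$protein_id, c(prot, lip)),
                                    match(sig$lipid_id, c(prot, lip)) ),
                           score = sig$score, sign = sig$sign)
  ann_of <- function(tbl, key_col, ids, col, default = "unknown") {
    if (is.null(tbl) || !col %in% names(tbl))
      return(rep(default, length(ids)))
    v <- tbl[[col]][match(ids, tbl[[key_col]])]
    ifelse(is.na(v), default, as.character(v))
  }
  vt <- igraph::V(g)$type
  ids <- igraph::V(g)$name
  igraph::V(g)$localization <-
    ifelse(vt, NA, ann_of(annotations, "protein_id", ids, "localization"))
  igraph::V(g)$group <-
    ifelse(vt, NA, ann_of(annotations, "protein_id", ids, "group",
                          default = NA_character_))
  igraph::V(g)$ptm <-
    ifelse(vt, NA, ann_of(annotations, "protein_id", ids, "ptm",
                          default = ""))
  igraph::V(g)$direction <-
    ifelse(vt, ann_of(lipid_results, "lipid_id", ids, "direction_fc"),
           ann_of(shift_results, "protein_id", ids, "direction"))
  if (!is.null(lipid_results) && "log2_fc" %in% names(lipid_results)) {
    fc <- lipid_results$log2_fc[match(ids, lipid_results$lipid_id)]
    igraph::V(g)$direction[vt] <-
      ifelse(fc[vt] > 0, "increased", "decreased")
  }
  igraph::V(g)$class <-
    ifelse(vt, ann_of(lipid_results, "lipid_id", ids, "class"), NA)
  igraph::V(g)$degree <- igraph::degree(g)
  g
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Extract direction-split subnetworks over shared protein groups
#'
#' Given one network per mutant and a map of proteins to hand-curated
#' groups, edges are kept when the protein's group has at least one member
#' among the protein nodes of both networks. Each mutant's retained
#' subnetwork is then split by the protein's DRM/DSF direction (enriched /
#' depleted). Proteins absent from the map are treated as singleton groups.
#'
#' @param graph_a,graph_b igraph networks from [build_graph()] for the two
#'   mutants.
#' @param group_map data.frame with `protein_id` and `group`.
#' @return list with per-mutant subnetworks (`a`, `b`, each split into
#'   `enriched` and `depleted`), the shared `groups`, and a `report`
#'   data.frame of group and member counts per mutant.
#' @export
extract_subnetworks <- function(graph_a, graph_b, group_map) {
  stopifnot(all(c("protein_id", "group") %in% names(group_map)))
  if (anyDuplicated(group_map$protein_id))
    stop_config("group_map assigns some protein to more than one group")
  prot_nodes <- function(g) igraph::V(g)$name[!igraph::V(g)$type]
  grp <- function(ids) {
    g <- group_map$group[match(ids, group_map$protein_id)]
    ifelse(is.na(g), paste0("singleton:", ids), g)
  }
  pa <- prot_nodes(graph_a); pb <- prot_nodes(graph_b)
  shared <- intersect(unique(grp(pa)), unique(grp(pb)))
  split_one <- function(g, keep_prot) {
    sub <- function(dir) {
      vkeep <- igraph::V(g)$name %in% keep_prot &
        igraph::V(g)$direction == dir & !igraph::V(g)$type
      sg <- igraph::induced_subgraph(
        g, which(vkeep | igraph::V(g)$type))
      igraph::delete_vertices(sg, which(igraph::degree(sg) == 0 &
                                          igraph::V(sg)$type))
    }
    list(enriched = sub("enriched"), depleted = sub("depleted"))
  }
  keep_a <- pa[grp(pa) %in% shared]
  keep_b <- pb[grp(pb) %in% shared]
  report <- data.frame(
    mutant = c("a", "b"),
    shared_groups = length(shared),
    members = c(length(keep_a), length(keep_b)))
  list(a = split_one(graph_a, keep_a), b = split_one(graph_b, keep_b),
       groups = shared, members_a = keep_a, members_b = keep_b,
       report = report)
}
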