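# Three-metric TLR-closeness score ---------------------------------------
#
# Quantifies the functional proximity of each panel gene to the TLR set:
# (1) TLR neighbours of the gene in the p < 0.05 co-expression network,
# (2) neighbours shared with the TLR set treated as one merged node
#     (excluding the probe gene and the TLRs themselves),
# (3) TLRs in the gene's cut-height cluster.
# One gene per metric is one point; the score is the plain sum.

#' TLR genes co-expressed with a gene
#'
#' `|neighbors(gene) intersect tlr_set|` in the given network.
#'
#' @param net A [build_network()] result (conventionally the p < 0.05
#'   network, which is what admits weaker co-expressions like r ~ 0.7,
#'   p ~ 0.04).
#' @param gene Gene name (must be a node).
#' @param tlr_set Character vector of TLR gene names.
#' @return Integer count.
#' @export
metric_coexpressed_tlrs <- function(net, gene, tlr_set) {
  if (!gene %in% net$nodes) stop(gene, " is not a node of the network")
  adj <- .adjacency(net)
  length(intersect(adj[[gene]], tlr_set))
}

#' Neighbours shared between a gene and the pooled TLR node
#'
#' All TLRs are merged into one node; the count is the size of the
#' intersection of the gene's neighbours and the pooled TLR neighbours,
#' after removing the probe gene itself and all TLR genes from both sets.
#'
#' @inheritParams metric_coexpressed_tlrs
#' @return Integer count.
#' @export
metric_common_neighbors <- function(net, gene, tlr_set) {
  if (!gene %in% net$nodes) stop(gene, " is not a node of the network")
  adj <- .adjacency(net)
  mine <- setdiff(adj[[gene]], c(tlr_set, gene))
  tlrs <- setdiff(unique(unlist(adj[intersect(tlr_set, names(adj))])),
                  c(tlr_set, gene))
  length(intersect(mine, tlrs))
}

#' TLRs sharing a gene's cut-height cluster
#'
#' @param assignment A [cut_tree()] result whose leaves cover `gene` and
#'   the TLR set.
#' @inheritParams metric_coexpressed_tlrs
#' @return Integer count.
#' @export
metric_tlrs_in_cluster <- function(assignment, gene, tlr_set) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  cl <- assignment$assignment
  if (!gene %in% names(cl)) stop(gene, " is not assigned to a cluster")
  sum(names(cl) %in% setdiff(tlr_set, gene) & cl == cl[[gene]])
}

#' Closeness table over a gene panel
#'
#' Per-gene components of the three metrics and their total, sorted by
#' decreasing total then gene name.  TLR genes themselves are excluded
#' from the scored set.
#'
#' @param net Co-expression network (p < 0.05 convention).
#' @param assignment [cut_tree()] assignment at the module cut height
#'   (1.0 by convention).
#' @param tlr_set TLR gene names.
#' @param genes Genes to score; defaults to all non-TLR network nodes.
#' @return Data frame: `gene`, `coexpressed_tlrs`, `common_neighbors`,
#'   `tlrs_in_cluster`, `total`.
#' @export
closeness_table <- function(net, assignment, tlr_set = default_tlr_set(),
                            genes = NULL) {
  if (is.null(genes)) genes <- setdiff(net$nodes, tlr_set)
  rows <- lapply(genes, function(g) {
    data.frame(gene = g,
               coexpressed_tlrs = metric_coexpressed_tlrs(net, g, tlr_set),
               common_neighbors = metric_common_neighbors(net, g, tlr_set),
               tlrs_in_cluster = metric_tlrs_in_cluster(assignment, g, tlr_set),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$total <- out$coexpressed_tlrs + out$common_neighbors +
    out$tlrs_in_cluster
  out <- out[order(-out$total, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
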