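# File formats ----------------------------------------------------------
# Cq and expression matrices travel as TSV with genes as rows and a first
# column named "gene"; sample tables as CSV; networks as Cytoscape SIF
# plus a TSV edge-attribute table or JSON.

#' Write a gene x sample matrix as TSV
#'
#' @param x Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_cq_matrix <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene x sample TSV matrix
#'
#' @param path TSV with a first column `gene` and one column per sample.
#' @return Numeric matrix, genes as rows.
#' @export
read_cq_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") stop("first column must be named 'gene'")
  if (anyDuplicated(df$gene)) stop("duplicate gene names in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicate sample names in ", path)
  storage.mode(m) <- "double"
  rownames(m) <- df$gene
  m
}

#' Write a co-expression network as SIF plus an edge-attribute TSV
#'
#' SIF lines are `GENE1 co GENE2`; the companion `<path>.attrs.tsv` holds
#' `r`, `p` and the correlation sign.
#'
#' @param net A [build_network()] result.
#' @param path Output SIF path.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "coexpression_network"))
  e <- net$edges
  lines <- if (nrow(e)) sprintf("%s co %s", e$gene_a, e$gene_b) else character(0)
  iso <- setdiff(net$nodes, unique(c(e$gene_a, e$gene_b)))
  writeLines(c(lines, iso), path)
  attrs <- data.frame(gene_a = e$gene_a, gene_b = e$gene_b,
                      r = e$r, p = e$p, sign = e$sign)
  utils::write.table(attrs, paste0(path, ".attrs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a co-expression network as JSON
#'
#' @param net A [build_network()] result.
#' @param path Output path.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "coexpression_network"))
  jsonlite::write_json(
    list(nodes = net$nodes, edges = net$edges,
         threshold = net$threshold, method = net$method,
         condition = net$condition),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are merge-height differences, so root-to-leaf path
#' lengths equal the final merge height.
#'
#' @param hc An `hclust` object (e.g. from [hierarchical_cluster()]).
#' @param path Output path.
#' @export
write_newick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
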