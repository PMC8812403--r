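# Condition-wise co-expression networks ---------------------------------

# p-value of a correlation via the t distribution with n - 2 df.
# |r| = 1 (perfect correlation) is reported as p = 0: on continuous data
# it is below any representable tail mass.
.cor_p <- function(r, n) {
  if (is.na(r) || n < 3) return(NA_real_)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * pt(-abs(t), df = n - 2)
}

#' All pairwise gene-gene correlations within one condition
#'
#' Pearson or Spearman correlations over all gene pairs, with p from the
#' t distribution on n - 2 df (Spearman uses the same t approximation on
#' the rank correlation; ties receive average ranks).  Pairs are reported
#' with `gene_a < gene_b` in the panel's canonical (alphabetical) order.
#'
#' @param expr Expression matrix, genes x samples.
#' @param method `"pearson"` or `"spearman"`.
#' @param condition_samples Optional sample ids restricting the columns.
#' @return Data frame: `gene_a`, `gene_b`, `method`, `r`, `p`, `n`.
#'   Zero-variance genes yield NA correlations for their pairs.
#' @export
pairwise_correlation <- function(expr, method = c("pearson", "spearman"),
                                 condition_samples = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(expr))
  if (!is.null(condition_samples)) {
    missing <- setdiff(condition_samples, colnames(expr))
    if (length(missing)) stop("unknown samples: ", paste(missing, collapse = ", "))
    expr <- expr[, condition_samples, drop = FALSE]
  }
  genes <- sort(rownames(expr))
  expr <- expr[genes, , drop = FALSE]
  pairs <- combn(genes, 2)
  res <- apply(pairs, 2, function(pr) {
    x <- expr[pr[1], ]; y <- expr[pr[2], ]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3) return(c(NA_real_, NA_real_, n))
    x <- x[ok]; y <- y[ok]
    if (sd(x) == 0 || sd(y) == 0) return(c(NA_real_, NA_real_, n))
    if (method == "spearman") { x <- rank(x); y <- rank(y) }
    r <- cor(x, y)
    c(r, .cor_p(r, n), n)
  })
  data.frame(gene_a = pairs[1, ], gene_b = pairs[2, ], method = method,
             r = res[1, ], p = res[2, ], n = as.integer(res[3, ]),
             stringsAsFactors = FALSE)
}

#' Build a co-expression network from thresholded correlations
#'
#' Edges are exactly the pairs with `p < p_max` and, when `r_min` is
#' given, `|r| > r_min` (a conjunctive rule).  Isolated genes are kept as
#' nodes so topology metrics are computed over the full panel.
#'
#' @param correlations A [pairwise_correlation()] result from a single
#'   method and condition.
#' @param p_max Significance threshold (default 0.05).
#' @param r_min Optional absolute-correlation threshold (e.g. 0.73).
#' @param nodes Node universe; defaults to all genes in `correlations`.
#' @param condition Optional condition label carried on the network.
#' @return Object of class `coexpression_network`: list with `nodes`,
#'   `edges` (data frame `gene_a`, `gene_b`, `r`, `p`, `sign`),
#'   `threshold`, `method`, `condition`.
#' @export
build_network <- function(correlations, p_max = 0.05, r_min = NULL,
                          nodes = NULL, condition = NULL) {
  if (length(unique(correlations$method)) > 1)
    stop("mixed-method correlation input")
  if (is.null(nodes))
    nodes <- sort(unique(c(correlations$gene_a, correlations$gene_b)))
  keep <- !is.na(correlations$p) & correlations$p < p_max
  if (!is.null(r_min))
    keep <- keep & !is.na(correlations$r) & abs(correlations$r) > r_min
  e <- correlations[keep, c("gene_a", "gene_b", "r", "p"), drop = FALSE]
  e$sign <- ifelse(e$r >= 0, "positive", "negative")
  rownames(e) <- NULL
  structure(list(nodes = nodes, edges = e,
                 threshold = list(p_max = p_max, r_min = r_min),
                 method = if (nrow(correlations)) correlations$method[1] else NA_character_,
                 condition = condition),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("co-expression network (%s%s): %d nodes, %d edges [p < %g%s]\n",
              x$method,
              if (is.null(x$condition)) "" else paste0(", ", x$condition),
              length(x$nodes), nrow(x$edges), x$threshold$p_max,
              if (is.null(x$threshold$r_min)) ""
              else sprintf(", |r| > %g", x$threshold$r_min)))
  invisible(x)
}

# adjacency list of a network over its node universe
.adjacency <- function(net) {
  adj <- setNames(vector("list", length(net$nodes)), net$nodes)
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$gene_a[i]; b <- net$edges$gene_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, unique)
}

# BFS shortest paths from one source over an adjacency list;
# unreachable nodes get Inf
.bfs <- function(adj, src) {
  dist <- setNames(rep(Inf, length(adj)), names(adj))
  dist[src] <- 0
  frontier <- src
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Topology metrics of a co-expression network
#'
#' Shortest paths by breadth-first search; the characteristic path length
#' and diameter average/maximize over connected (finite-distance) node
#' pairs only, so disconnected networks still yield finite values.  The
#' clustering coefficient is the mean over all nodes of the local
#' coefficient, with nodes of degree < 2 contributing 0 (the convention
#' of Cytoscape's network analyzer).
#'
#' @param net A [build_network()] result.
#' @return List of class `topology_metrics`: `nodes`, `edges`,
#'   `average_neighbors`, `diameter`, `clustering_coefficient`,
#'   `characteristic_path_length`.
#' @export
topology <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  adj <- .adjacency(net)
  nodes <- net$nodes
  n <- length(nodes)
  deg <- vapply(adj, length, integer(1))
  local_cc <- vapply(nodes, function(v) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0L
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      if (nb[j] %in% adj[[nb[i]]]) links <- links + 1L
    2 * links / (k * (k - 1))
  }, numeric(1))
  dists <- c()
  diam <- 0
  if (nrow(net$edges)) {
    for (v in nodes) {
      d <- .bfs(adj, v)
      d <- d[names(d) != v]
      d <- d[is.finite(d)]
      dists <- c(dists, d)
      if (length(d)) diam <- max(diam, max(d))
    }
  }
  structure(list(
    nodes = n, edges = nrow(net$edges),
    average_neighbors = mean(deg),
    diameter = diam,
    clustering_coefficient = mean(local_cc),
    characteristic_path_length = if (length(dists)) mean(dists) else 0
  ), class = "topology_metrics")
}

#' @export
print.topology_metrics <- function(x, ...) {
  cat(sprintf(paste0("nodes %d | edges %d | avg neighbors %.3f | diameter %g",
                     " | clustering coeff %.3f | char path length %.3f\n"),
              x$nodes, x$edges, x$average_neighbors, x$diameter,
              x$clustering_coefficient, x$characteristic_path_length))
  invisible(x)
}

.edge_keys <- function(net) {
  if (!nrow(net$edges)) return(character(0))
  paste(net$edges$gene_a, net$edges$gene_b, sep = "|")
}

.check_same_nodes <- function(nets) {
  base <- nets[[1]]$nodes
  for (net in nets[-1]) {
    d <- union(setdiff(base, net$nodes), setdiff(net$nodes, base))
    if (length(d))
      stop("node-set mismatch; symmetric difference: ",
           paste(sort(d), collapse = ", "))
  }
}

#' Gained and lost edges between two networks on the same node universe
#'
#' Edge identity is the unordered gene pair; the correlation sign is
#' carried along but does not enter identity.
#'
#' @param netA,netB [build_network()] results over identical node sets.
#' @return List with data frames `gained` (edges of B absent from A) and
#'   `lost` (edges of A absent from B).
#' @export
differential_edges <- function(netA, netB) {
  .check_same_nodes(list(netA, netB))
  ka <- .edge_keys(netA); kb <- .edge_keys(netB)
  gained <- netB$edges[!(kb %in% ka), , drop = FALSE]
  lost <- netA$edges[!(ka %in% kb), , drop = FALSE]
  rownames(gained) <- rownames(lost) <- NULL
  list(gained = gained, lost = lost)
}

#' Edge membership across a set of networks
#'
#' For every edge present in any network, a presence/absence indicator per
#' network, plus counts per intersection region (the Venn regions).
#'
#' @param networks Named list of >= 2 [build_network()] results on the
#'   same node universe.
#' @return List with `membership` (data frame: `gene_a`, `gene_b`, one
#'   logical column per network) and `region_counts` (named count per
#'   distinct presence pattern, names like `"A&B"`).
#' @export
edge_overlap <- function(networks) {
  if (length(networks) < 2) stop("need at least 2 networks")
  if (is.null(names(networks)))
    names(networks) <- paste0("net", seq_along(networks))
  .check_same_nodes(networks)
  keys <- lapply(networks, .edge_keys)
  all_keys <- sort(unique(unlist(keys)))
  memb <- vapply(keys, function(k) all_keys %in% k,
                 logical(length(all_keys)))
  memb <- matrix(memb, nrow = length(all_keys),
                 dimnames = list(NULL, names(networks)))
  parts <- strsplit(all_keys, "|", fixed = TRUE)
  df <- data.frame(gene_a = vapply(parts, `[`, "", 1),
                   gene_b = vapply(parts, `[`, "", 2),
                   memb, check.names = FALSE, stringsAsFactors = FALSE)
  pattern <- apply(memb, 1, function(row)
    paste(names(networks)[row], collapse = "&"))
  list(membership = df,
       region_counts = if (length(pattern)) table(pattern) else table(character(0)))
}
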