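# Hierarchical clustering with correlation distance ----------------------

#' Correlation distance matrix
#'
#' `d = 1 - r`, range [0, 2].  The sign-sensitive form (not `1 - |r|`) is
#' deliberate: strongly anti-correlated gene blocks must land in separate
#' top-level clusters.
#'
#' @param x Either an expression matrix (genes x samples; rows are
#'   clustered) or a square correlation matrix when
#'   `input = "correlation"`.
#' @param method Correlation type for the expression input.
#' @param input `"expression"` or `"correlation"`.
#' @return A `dist` object over rows of `x`.
#' @export
correlation_distance <- function(x, method = c("pearson", "spearman"),
                                 input = c("expression", "correlation")) {
  method <- match.arg(method)
  input <- match.arg(input)
  if (input == "expression") {
    r <- cor(t(x), method = method, use = "pairwise.complete.obs")
  } else {
    r <- as.matrix(x)
    if (!isTRUE(all.equal(r, t(r), tolerance = 1e-8)))
      stop("correlation matrix must be symmetric")
  }
  if (anyNA(r)) {
    bad <- which(is.na(r) & upper.tri(r), arr.ind = TRUE)
    stop("undefined correlations for pairs: ",
         paste(sprintf("%s-%s", rownames(r)[bad[, 1]],
                       colnames(r)[bad[, 2]]), collapse = ", "))
  }
  d <- 1 - r
  diag(d) <- 0
  as.dist(d)
}

#' Complete-linkage hierarchical clustering with a deterministic tie rule
#'
#' Standard agglomerative complete linkage.  Leaves are ordered
#' alphabetically before merging so that distance ties resolve by the
#' lexicographically smallest leaf name on every platform.
#'
#' @param distance A `dist` object (or symmetric matrix) with leaf labels.
#' @param linkage Agglomeration method; only `"complete"` is supported.
#' @return An `hclust` object.
#' @export
hierarchical_cluster <- function(distance, linkage = "complete") {
  if (linkage != "complete") stop("only complete linkage is supported")
  if (!inherits(distance, "dist")) {
    m <- as.matrix(distance)
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
      stop("distance matrix must be symmetric")
    distance <- as.dist(m)
  }
  m <- as.matrix(distance)
  if (is.null(rownames(m)))
    rownames(m) <- colnames(m) <- paste0("L", seq_len(nrow(m)))
  ord <- order(rownames(m))
  hclust(as.dist(m[ord, ord]), method = "complete")
}

#' Cut a dendrogram at a height
#'
#' Clusters are the connected components after removing all merges above
#' `height`.  Cluster ids are renumbered in order of first appearance of
#' their alphabetically first member.
#'
#' @param hc An `hclust` object.
#' @param height Cut height (>= 0).
#' @return List of class `cluster_assignment`: `assignment` (named
#'   integer), `cut_height`, `n_clusters`.
#' @export
cut_tree <- function(hc, height) {
  stopifnot(inherits(hc, "hclust"), height >= 0)
  cl <- cutree(hc, h = height)
  structure(list(assignment = cl, cut_height = height,
                 n_clusters = length(unique(cl))),
            class = "cluster_assignment")
}

# leaf index sets of every internal node of an hclust tree
.subtree_leaves <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pick <- function(v) if (v < 0) -v else sets[[v]]
    sets[[i]] <- c(pick(hc$merge[i, 1]), pick(hc$merge[i, 2]))
  }
  sets
}

#' Fraction of one class isolated in pure subtrees
#'
#' Samples are clustered by sign-sensitive correlation distance between
#' their expression profiles (complete linkage).  A subtree is "pure" when
#' all its leaves belong to the focal class; a pure subtree is maximal
#' when its parent is impure.  The reported fraction counts focal-class
#' samples lying in maximal pure subtrees of at least 2 leaves (a
#' singleton leaf is trivially pure and does not count as separation),
#' divided by the class size.  With a single class present the fraction
#' is 1 by convention.
#'
#' @param expr Expression matrix, genes x samples.
#' @param classes Class labels per sample (character/factor, two classes).
#' @param focal Label of the class whose separation is scored; defaults to
#'   the first class level.
#' @param method Correlation type for the sample-sample distance.
#' @return List: `fraction`, `n_isolated`, `n_class`, `subtrees` (leaf
#'   name sets of the maximal pure subtrees counted).
#' @export
sample_separation <- function(expr, classes, focal = NULL,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.matrix(expr), length(classes) == ncol(expr))
  classes <- as.character(classes)
  lv <- unique(classes)
  if (is.null(focal)) focal <- lv[1]
  if (!focal %in% lv) stop("focal class absent")
  n_class <- sum(classes == focal)
  if (length(lv) < 2)
    return(list(fraction = 1, n_isolated = n_class, n_class = n_class,
                subtrees = list(colnames(expr))))
  if (n_class < 2) stop("focal class has fewer than 2 samples")
  d <- correlation_distance(t(expr), method = method)
  hc <- hierarchical_cluster(d)
  labs <- hc$labels
  cls <- classes[match(labs, colnames(expr))]
  sets <- .subtree_leaves(hc)
  pure <- vapply(sets, function(s) all(cls[s] == focal), logical(1))
  parent <- integer(length(sets))
  for (i in seq_along(sets)) for (k in 1:2) {
    v <- hc$merge[i, k]
    if (v > 0) parent[v] <- i
  }
  maximal <- which(pure & vapply(seq_along(sets), function(i) {
    p <- parent[i]
    p == 0 || !pure[p]
  }, logical(1)))
  subtrees <- lapply(maximal, function(i) labs[sets[[i]]])
  n_isolated <- sum(lengths(subtrees))
  list(fraction = n_isolated / n_class, n_isolated = n_isolated,
       n_class = n_class, subtrees = subtrees)
}
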