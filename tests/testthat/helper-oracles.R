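# Independent brute-force oracles used across the suite.  These stay
# deliberately naive (loops, enumeration) and separate from the package's
# own algorithms.

# --- graph oracles ------------------------------------------------------

# random undirected graph as an edge data frame over `nodes`
random_graph <- function(nodes, p_edge = 0.3) {
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  data.frame(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
             r = runif(sum(keep), -1, 1), p = runif(sum(keep), 0, 0.04),
             stringsAsFactors = FALSE)
}

as_network <- function(edges, nodes) {
  edges$sign <- ifelse(edges$r >= 0, "positive", "negative")
  structure(list(nodes = nodes, edges = edges,
                 threshold = list(p_max = 0.05, r_min = NULL),
                 method = "pearson", condition = NULL),
            class = "coexpression_network")
}

adj_matrix <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  for (i in seq_len(nrow(net$edges))) {
    A[net$edges$gene_a[i], net$edges$gene_b[i]] <- 1L
    A[net$edges$gene_b[i], net$edges$gene_a[i]] <- 1L
  }
  A
}

# Floyd-Warshall all-pairs shortest paths
oracle_topology <- function(net) {
  A <- adj_matrix(net)
  n <- nrow(A)
  D <- ifelse(A == 1, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  finite <- D[upper.tri(D)][is.finite(D[upper.tri(D)]) & D[upper.tri(D)] > 0]
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] == 1)
    k <- length(nb)
    if (k < 2) { cc[v] <- 0; next }
    links <- sum(A[nb, nb]) / 2
    cc[v] <- 2 * links / (k * (k - 1))
  }
  list(average_neighbors = mean(rowSums(A)),
       diameter = if (length(finite)) max(finite) else 0,
       clustering_coefficient = mean(cc),
       characteristic_path_length = if (length(finite)) mean(finite) else 0)
}

# --- clustering oracles -------------------------------------------------

# naive O(n^3) complete-linkage agglomeration; returns merge heights and
# the n x n cophenetic matrix
oracle_complete_linkage <- function(d) {
  m <- as.matrix(d)
  labs <- rownames(m)
  clusters <- as.list(labs)
  coph <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- max(m[clusters[[i]], clusters[[j]]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    coph[clusters[[best[1]]], clusters[[best[2]]]] <- best_d
    coph[clusters[[best[2]]], clusters[[best[1]]]] <- best_d
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best[2]]
  }
  list(heights = sort(heights), cophenetic = coph)
}

# union-find over cophenetic links at or below a height
oracle_cut <- function(coph, height) {
  labs <- rownames(coph)
  parent <- seq_along(labs)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(labs)) for (j in seq_along(labs))
    if (i < j && coph[i, j] <= height) parent[find(j)] <- find(i)
  roots <- vapply(seq_along(labs), find, integer(1))
  setNames(match(roots, unique(roots)), labs)
}

# --- statistics oracles -------------------------------------------------

# full enumeration permutation Mann-Whitney (two-sided, symmetric tail)
oracle_mw_exact <- function(a, b) {
  n1 <- length(a); N <- n1 + length(b)
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- combn(N, n1)
  Us <- apply(idx, 2, function(s) sum(r[s])) - n1 * (n1 + 1) / 2
  mu <- n1 * (N - n1) / 2
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
}

# SPSS-style 2*(1-sided exact) from enumeration of the tie-free null
oracle_mw_2tail <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_min <- floor(min(U_obs, n1 * n2 - U_obs))
  idx <- combn(N, n1)
  Us <- apply(idx, 2, function(s) sum(rank(seq_len(N))[s])) - n1 * (n1 + 1) / 2
  min(1, 2 * mean(Us <= u_min))
}

# max ECDF gap against a fitted normal
oracle_ks_D <- function(x) {
  x <- sort(x); n <- length(x)
  Fx <- pnorm(x, mean(x), sd(x))
  max(abs(c(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n)))
}

# exhaustive Youden search over every observed score as a candidate cut
oracle_youden <- function(scores, labels, positive = TRUE) {
  pos <- labels == positive
  best_J <- -Inf
  for (th in sort(unique(c(scores - 1e-9, scores + 1e-9)))) {
    called <- scores > th
    J <- sum(called & pos) / sum(pos) + sum(!called & !pos) / sum(!pos) - 1
    best_J <- max(best_J, J)
  }
  best_J
}

# --- closeness oracle ---------------------------------------------------

oracle_closeness <- function(net, assignment, tlr_set, gene) {
  A <- adj_matrix(net)
  nb <- function(g) colnames(A)[A[g, ] == 1]
  m1 <- length(intersect(nb(gene), tlr_set))
  mine <- setdiff(nb(gene), c(tlr_set, gene))
  pooled <- character(0)
  for (t in intersect(tlr_set, rownames(A))) pooled <- union(pooled, nb(t))
  pooled <- setdiff(pooled, c(tlr_set, gene))
  m2 <- length(intersect(mine, pooled))
  cl <- assignment$assignment
  m3 <- sum(names(cl) %in% setdiff(tlr_set, gene) & cl == cl[[gene]])
  c(m1, m2, m3)
}

# --- misc fixtures ------------------------------------------------------

# small random Cq matrix
random_cq <- function(n_genes = 4, n_samples = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, 25, 2), n_genes, n_samples,
              dimnames = list(paste0("G", seq_len(n_genes)),
                              paste0("S", seq_len(n_samples))))
  m
}

# treated-subgroup vectors of the packaged clinical table: rows 1-9 vs
# rows 10-20 of the treated block
table1_groups <- function(variable) {
  tab <- load_clinical_table()
  treated <- tab[tab$condition == "treated", ]
  list(g1 = treated[[variable]][1:9], g2 = treated[[variable]][10:20])
}
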