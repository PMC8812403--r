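# Reference-gene stability and 2^-ddCq quantification -------------------
#
# All three stability methods operate on raw Cq values.  With a fixed
# amplification efficiency of 2, log2 expression is -Cq up to a per-gene
# constant, so Cq differences are log2 expression ratios directly.

#' geNorm expression-stability measure M with stepwise exclusion
#'
#' For candidate j, `M_j` is the mean over partners k of the standard
#' deviation across samples of the pairwise log2 expression ratio, i.e. of
#' `Cq_k - Cq_j`.  The iterative procedure repeatedly removes the gene
#' with the highest M (ties broken by reverse-alphabetical name so the
#' alphabetically earlier gene survives) until two remain.
#'
#' @param cq Numeric matrix of Cq values, candidate genes x samples.
#' @return List with `M` (named vector over the full panel),
#'   `exclusion_order` (genes in removal order) and `final_pair`.
#' @export
genorm_stability <- function(cq) {
  stopifnot(is.matrix(cq))
  if (nrow(cq) < 3) stop("geNorm needs at least 3 candidate genes")
  if (ncol(cq) < 2) stop("geNorm needs at least 2 samples")
  if (any(rowSums(!is.na(cq)) == 0)) stop("a candidate gene is entirely missing")
  genorm_m <- function(x) {
    g <- nrow(x)
    vapply(seq_len(g), function(j) {
      mean(vapply(setdiff(seq_len(g), j), function(k) {
        sd(x[k, ] - x[j, ], na.rm = TRUE)
      }, numeric(1)))
    }, numeric(1))
  }
  M_full <- setNames(genorm_m(cq), rownames(cq))
  panel <- cq
  order_out <- character(0)
  while (nrow(panel) > 2) {
    M <- setNames(genorm_m(panel), rownames(panel))
    ties <- names(M)[M == max(M)]
    worst <- sort(ties, decreasing = TRUE)[1]
    order_out <- c(order_out, worst)
    panel <- panel[setdiff(rownames(panel), worst), , drop = FALSE]
  }
  list(M = M_full, exclusion_order = order_out,
       final_pair = sort(rownames(panel)))
}

#' NormFinder-style stability from a variance decomposition
#'
#' Cq values are centred per sample across the candidate panel (removing
#' the sample loading effect); for each gene the measure combines the
#' absolute intergroup bias of the centred group means with the intragroup
#' sampling noise: `stability_i = mean_g(|d_ig| + sqrt(v_ig / n_g))`,
#' where `d_ig` is the deviation of the group-g mean from the gene's
#' size-weighted grand mean and `v_ig` the within-group variance.  Lower
#' is more stable.  With a single group the intergroup term vanishes and
#' the result is flagged `intragroup_only`.
#'
#' @param cq Candidate Cq matrix, genes x samples.
#' @param groups Factor/character of group labels per sample.
#' @return List with `stability` (named, >= 0), `intergroup` and
#'   `intragroup` components, and `intragroup_only` flag.
#' @export
normfinder_stability <- function(cq, groups) {
  stopifnot(is.matrix(cq), length(groups) == ncol(cq))
  groups <- as.factor(droplevels(as.factor(groups)))
  single <- nlevels(groups) < 2
  if (!single && any(table(groups) < 2))
    stop("each group needs at least 2 samples")
  z <- sweep(cq, 2, colMeans(cq, na.rm = TRUE))
  lv <- levels(groups)
  n_g <- as.numeric(table(groups))
  means <- vapply(lv, function(g) rowMeans(z[, groups == g, drop = FALSE],
                                           na.rm = TRUE),
                  numeric(nrow(cq)))
  vars <- vapply(lv, function(g) apply(z[, groups == g, drop = FALSE], 1,
                                       var, na.rm = TRUE),
                 numeric(nrow(cq)))
  means <- matrix(means, nrow = nrow(cq),
                  dimnames = list(rownames(cq), lv))
  vars <- matrix(vars, nrow = nrow(cq),
                 dimnames = list(rownames(cq), lv))
  grand <- as.numeric(means %*% n_g) / sum(n_g)
  d <- means - grand
  inter <- rowMeans(abs(d))
  intra <- rowMeans(sqrt(sweep(vars, 2, n_g, "/")))
  stab <- if (single) sqrt(vars[, 1]) else inter + intra
  list(stability = setNames(as.numeric(stab), rownames(cq)),
       intergroup = setNames(as.numeric(inter), rownames(cq)),
       intragroup = setNames(as.numeric(intra), rownames(cq)),
       intragroup_only = single)
}

#' BestKeeper descriptive stability statistics
#'
#' The BestKeeper index is the per-sample mean Cq of all candidates (the
#' geometric mean of expression).  For each candidate the Cq standard
#' deviation, coefficient of variation, and Pearson correlation with the
#' index are reported; genes with SD above 1 cycle are flagged by the
#' conventional advisory threshold.
#'
#' @param cq Candidate Cq matrix, genes x samples.
#' @param sd_threshold Advisory SD threshold in cycles (default 1.0).
#' @return Data frame with `gene`, `sd`, `cv`, `index_r`, `index_p`,
#'   `flagged`.
#' @export
bestkeeper_stats <- function(cq, sd_threshold = 1.0) {
  stopifnot(is.matrix(cq))
  if (nrow(cq) < 2) stop("BestKeeper needs at least 2 candidates")
  index <- colMeans(cq, na.rm = TRUE)
  sds <- apply(cq, 1, sd, na.rm = TRUE)
  cvs <- 100 * sds / rowMeans(cq, na.rm = TRUE)
  rp <- t(apply(cq, 1, function(x) {
    ok <- !is.na(x) & !is.na(index)
    if (sum(ok) < 3 || sd(x[ok]) == 0) return(c(NA_real_, NA_real_))
    r <- cor(x[ok], index[ok])
    c(r, .cor_p(r, sum(ok)))
  }))
  data.frame(gene = rownames(cq), sd = as.numeric(sds), cv = as.numeric(cvs),
             index_r = rp[, 1], index_p = rp[, 2],
             flagged = as.numeric(sds) > sd_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Combined stability report over candidate reference genes
#'
#' Runs all three stability methods and aggregates their per-method ranks
#' (1 = most stable) as a plain mean.
#'
#' @param cq Candidate Cq matrix, genes x samples.
#' @param groups Optional group labels for NormFinder; without them the
#'   intragroup-only variant is used.
#' @return Object of class `stability_report`: data frame with per-method
#'   statistics, per-method ranks and `aggregate_rank`.
#' @export
stability_report <- function(cq, groups = NULL) {
  gn <- genorm_stability(cq)
  nf <- if (is.null(groups)) normfinder_stability(cq, rep("all", ncol(cq)))
        else normfinder_stability(cq, groups)
  bk <- bestkeeper_stats(cq)
  genes <- rownames(cq)
  df <- data.frame(
    gene = genes,
    genorm_M = as.numeric(gn$M[genes]),
    normfinder_stability = as.numeric(nf$stability[genes]),
    bestkeeper_sd = bk$sd[match(genes, bk$gene)],
    bestkeeper_r = bk$index_r[match(genes, bk$gene)],
    stringsAsFactors = FALSE)
  df$rank_genorm <- rank(df$genorm_M, ties.method = "average")
  df$rank_normfinder <- rank(df$normfinder_stability, ties.method = "average")
  df$rank_bestkeeper <- rank(df$bestkeeper_sd, ties.method = "average")
  df$aggregate_rank <- rowMeans(df[, c("rank_genorm", "rank_normfinder",
                                       "rank_bestkeeper")])
  df <- df[order(df$aggregate_rank, df$genorm_M, df$gene), ]
  rownames(df) <- NULL
  class(df) <- c("stability_report", "data.frame")
  df
}

#' Select the two most stable reference genes
#'
#' The two candidates with the best aggregate rank; ties broken by lower
#' geNorm M, then alphabetical gene name.
#'
#' @param report A [stability_report()].
#' @return Character vector of two gene names (alphabetical order).
#' @export
select_reference_pair <- function(report) {
  stopifnot(inherits(report, "stability_report"))
  if (nrow(report) < 3) stop("need a report over at least 3 candidates")
  ord <- order(report$aggregate_rank, report$genorm_M, report$gene)
  sort(report$gene[ord][1:2])
}

#' Relative expression by the 2^-ddCq method
#'
#' `dCq = Cq_target - mean(Cq of the two reference genes)` per sample;
#' `ddCq = dCq - mean(dCq over the calibrator samples)` per gene;
#' expression is `2^-ddCq` (amplification efficiency fixed at 2).
#'
#' @param cq Cq matrix, genes x samples (targets and references).
#' @param targets Target gene names.
#' @param reference_pair Two reference gene names present in `cq`.
#' @param calibrator_samples Sample ids forming the calibrator (for a
#'   cohort, typically the healthy-control group); their mean dCq defines
#'   expression 1.
#' @return Object of class `expression_matrix`: targets x samples matrix
#'   of positive relative expression values, with attributes
#'   `reference_pair` and `calibrator_samples`.  A sample with a missing
#'   reference Cq yields NA for all its targets, with a warning.
#' @export
relative_expression <- function(cq, targets, reference_pair,
                                calibrator_samples) {
  stopifnot(is.matrix(cq))
  if (!all(reference_pair %in% rownames(cq)))
    stop("reference genes not present in the Cq matrix")
  if (length(reference_pair) != 2)
    stop("reference_pair must name exactly 2 genes")
  if (length(calibrator_samples) == 0)
    stop("calibrator set must be non-empty")
  if (!all(calibrator_samples %in% colnames(cq)))
    stop("unknown calibrator samples")
  if (!all(targets %in% rownames(cq)))
    stop("unknown target genes: ",
         paste(setdiff(targets, rownames(cq)), collapse = ", "))
  ref <- colMeans(cq[reference_pair, , drop = FALSE])
  if (anyNA(ref))
    warning("missing reference Cq in sample(s) ",
            paste(colnames(cq)[is.na(ref)], collapse = ", "),
            "; their expression values are NA")
  dcq <- sweep(cq[targets, , drop = FALSE], 2, ref)
  cal <- rowMeans(dcq[, calibrator_samples, drop = FALSE], na.rm = TRUE)
  expr <- 2^(-(dcq - cal))
  structure(expr, class = c("expression_matrix", class(expr)),
            reference_pair = sort(reference_pair),
            calibrator_samples = calibrator_samples)
}
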