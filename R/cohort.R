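# Synthetic cohort generation -------------------------------------------
#
# The generator emulates the study design the downstream analysis assumes:
# 29 target genes in two functional blocks (a TLR-signalling block and a
# T-cell activation/differentiation block), five condition groups, strong
# negative between-block correlation in the inactive-treated group only,
# candidate reference genes of controlled stability, and clinical
# covariates with the group contrasts seen in routine vasculitis panels.
# Correlations are induced on the dCq (log2 expression) scale.

#' Default gene panel: two functional blocks of 29 genes
#'
#' Block A is the TLR-signalling cluster (13 genes), block B the T-cell
#' activation/differentiation cluster (16 genes).  Block membership follows
#' the largest co-expression modules observed in inactive-treated disease.
#'
#' @return Named list of two character vectors, `tlr` and `tcell`.
#' @export
default_gene_blocks <- function() {
  list(
    tlr = c("TLR1", "TLR2", "TLR4", "TLR6", "TLR8", "BCL6", "NR4A1",
            "IkBa", "LAG3", "TIM3", "TIGIT", "PD-1", "CD40"),
    tcell = c("TCR", "CD28", "T-bet", "GATA3", "FOXP3", "CCL5", "CD3",
              "CD40L", "CTLA4", "PD-L2", "RORC", "PD-L1", "p50", "p65",
              "CD83", "TNF")
  )
}

#' Default TLR gene set used by the closeness score
#' @return Character vector of the panel's five TLR genes.
#' @export
default_tlr_set <- function() c("TLR1", "TLR2", "TLR4", "TLR6", "TLR8")

#' Default candidate reference genes with stability standard deviations
#'
#' Nine housekeeping candidates commonly profiled in PBMC panels.  The
#' `stability_sd` is the per-sample Cq standard deviation the generator
#' uses; B2M and YWHAZ are planted as the most stable pair.
#'
#' @return Data frame with columns `gene` and `stability_sd` (Cq cycles).
#' @export
default_reference_spec <- function() {
  data.frame(
    gene = c("ACTB", "B2M", "GAPDH", "GUSB", "HPRT1", "PGK1", "RPL13A",
             "SDHA", "YWHAZ"),
    stability_sd = c(0.55, 0.12, 0.45, 0.50, 0.25, 0.35, 0.40, 0.22, 0.15),
    stringsAsFactors = FALSE
  )
}

.conditions <- function() {
  c("HC", "untreated-inactive", "untreated-active",
    "treated-inactive", "treated-active")
}

#' Configuration for a synthetic qPCR cohort
#'
#' @param group_sizes Named integer vector of samples per condition.
#'   Defaults to the study design: 10 healthy controls, 3/4
#'   untreated-inactive/active, 9/11 treated-inactive/active.
#' @param gene_blocks Named list of two disjoint gene vectors (see
#'   [default_gene_blocks()]).
#' @param within_block_r Within-block pairwise correlation of dCq values,
#'   either a single value in `[0, 1]` or a named per-condition vector.
#' @param between_block_r Named per-condition between-block correlation in
#'   `[-1, 1]` (a scalar is recycled).  The default plants the inverse
#'   TLR-vs-T-cell structure only in the inactive-treated group.
#' @param noise_sd Technical Cq noise, cycles.
#' @param baseline_cq Baseline Cq added to every target gene.
#' @param delta_mean,delta_sd Mean and marginal SD of the dCq signal
#'   (cycles).
#' @param reference_gene_spec Data frame with `gene` and `stability_sd`
#'   columns; see [default_reference_spec()].
#' @param clinical_spec Optional list overriding per-covariate,
#'   per-condition distribution parameters (see [generate_clinical()]).
#' @param missing_rate Fraction of clinical covariate entries set missing.
#' @param seed Integer seed; all generators are deterministic given it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c("HC" = 10,
                                          "untreated-inactive" = 3,
                                          "untreated-active" = 4,
                                          "treated-inactive" = 9,
                                          "treated-active" = 11),
                          gene_blocks = default_gene_blocks(),
                          within_block_r = c("HC" = 0.35,
                                             "untreated-inactive" = 0.35,
                                             "untreated-active" = 0.35,
                                             "treated-inactive" = 0.90,
                                             "treated-active" = 0.80),
                          between_block_r = c("HC" = 0.10,
                                              "untreated-inactive" = 0.10,
                                              "untreated-active" = 0.10,
                                              "treated-inactive" = -0.85,
                                              "treated-active" = 0.55),
                          noise_sd = 0.25,
                          baseline_cq = 22,
                          delta_mean = 4,
                          delta_sd = 1,
                          reference_gene_spec = default_reference_spec(),
                          clinical_spec = list(),
                          missing_rate = 0,
                          seed = 1L) {
  conds <- names(group_sizes)
  if (is.null(conds) || anyDuplicated(conds))
    stop("group_sizes must be uniquely named by condition")
  if (any(group_sizes < 2))
    stop("all group sizes must be >= 2")
  if (length(gene_blocks) != 2L || is.null(names(gene_blocks)))
    stop("gene_blocks must be a named list of two gene vectors")
  if (length(intersect(gene_blocks[[1]], gene_blocks[[2]])) > 0)
    stop("gene blocks must be disjoint")
  expand <- function(x, what, lo, hi) {
    if (length(x) == 1L && is.null(names(x))) x <- setNames(rep(x, length(conds)), conds)
    if (!all(conds %in% names(x)))
      stop(sprintf("%s must name every condition", what))
    x <- x[conds]
    if (any(x < lo | x > hi))
      stop(sprintf("%s must lie in [%g, %g]", what, lo, hi))
    x
  }
  within_block_r <- expand(within_block_r, "within_block_r", 0, 1)
  between_block_r <- expand(between_block_r, "between_block_r", -1, 1)
  if (!all(c("gene", "stability_sd") %in% names(reference_gene_spec)))
    stop("reference_gene_spec needs 'gene' and 'stability_sd' columns")
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must be in [0, 1]")
  structure(
    list(group_sizes = group_sizes, gene_blocks = gene_blocks,
         within_block_r = within_block_r, between_block_r = between_block_r,
         noise_sd = noise_sd, baseline_cq = baseline_cq,
         delta_mean = delta_mean, delta_sd = delta_sd,
         reference_gene_spec = reference_gene_spec,
         clinical_spec = clinical_spec, missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "cohort_config")
}

# Two-block equicorrelation matrix; repaired by eigenvalue clipping when the
# requested (within, between) combination is not positive semi-definite.
# Returns the matrix with attributes recording any repair.
block_correlation <- function(n_a, n_b, within_a, within_b, between,
                              tol = 1e-8) {
  n <- n_a + n_b
  R <- matrix(between, n, n)
  R[seq_len(n_a), seq_len(n_a)] <- within_a
  R[n_a + seq_len(n_b), n_a + seq_len(n_b)] <- within_b
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  repaired <- FALSE
  max_delta <- 0
  if (min(ev$values) < -tol) {
    vals <- pmax(ev$values, tol)
    R2 <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    d <- sqrt(diag(R2))
    R2 <- R2 / tcrossprod(d)
    max_delta <- max(abs(R2 - R))
    R <- R2
    repaired <- TRUE
  }
  diag(R) <- 1
  attr(R, "repaired") <- repaired
  attr(R, "max_repair_delta") <- max_delta
  R
}

# Draw n samples from N(mu, sigma^2 * R) via Cholesky (with PSD fallback).
rmvn_corr <- function(n, p, R, mean, sd) {
  L <- tryCatch(chol(R), error = function(e) {
    ev <- eigen(R, symmetric = TRUE)
    t(ev$vectors %*% diag(sqrt(pmax(ev$values, 0))))
  })
  Z <- matrix(rnorm(n * p), n, p)
  mean + sd * (Z %*% L)
}

#' Generate a synthetic cohort of Cq values and sample labels
#'
#' Per condition, target-gene dCq values are drawn from a multivariate
#' normal whose correlation matrix has `within_block_r` inside each block
#' and the condition's `between_block_r` across blocks (repaired by
#' eigenvalue clipping if not positive semi-definite; the repair is
#' messaged and recorded).  Candidate reference genes are drawn
#' independently with their configured stability SD.
#' `Cq = baseline + dCq signal + technical noise`.
#'
#' @param config A [cohort_config()].
#' @return List with `cq` (gene x sample Cq matrix including reference
#'   genes), `delta` (the latent correlated dCq signal before technical
#'   noise, for moment checks — observed Cq correlations are attenuated
#'   by `1 / (1 + noise_sd^2 / delta_sd^2)` relative to the configured
#'   values), `samples` (data frame with `sample_id`, `condition`,
#'   `activity`, `group`), and `repairs` (per-condition PSD repair log).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  blocks <- config$gene_blocks
  genes <- c(blocks[[1]], blocks[[2]])
  n_a <- length(blocks[[1]])
  n_b <- length(blocks[[2]])
  refs <- config$reference_gene_spec
  conds <- names(config$group_sizes)

  sample_id <- character(0)
  condition <- character(0)
  cq_cols <- list()
  delta_cols <- list()
  repairs <- list()
  counter <- 0L
  for (cd in conds) {
    n <- config$group_sizes[[cd]]
    R <- block_correlation(n_a, n_b,
                           within_a = config$within_block_r[[cd]],
                           within_b = config$within_block_r[[cd]],
                           between = config$between_block_r[[cd]])
    if (attr(R, "repaired")) {
      message(sprintf(
        "condition %s: correlation matrix repaired by eigenvalue clipping (max |delta r| = %.4g)",
        cd, attr(R, "max_repair_delta")))
      if (attr(R, "max_repair_delta") > 0.1)
        stop(sprintf("condition %s: requested correlations infeasible (repair delta %.3f > 0.1)",
                     cd, attr(R, "max_repair_delta")))
    }
    repairs[[cd]] <- list(repaired = attr(R, "repaired"),
                          max_delta = attr(R, "max_repair_delta"))
    delta <- rmvn_corr(n, n_a + n_b, R,
                       mean = config$delta_mean, sd = config$delta_sd)
    ref_cq <- vapply(refs$stability_sd,
                     function(s) rnorm(n, 0, s), numeric(n))
    if (n == 1L) ref_cq <- matrix(ref_cq, nrow = 1L)
    noise <- matrix(rnorm(n * (n_a + n_b), 0, config$noise_sd),
                    n, n_a + n_b)
    cq <- cbind(config$baseline_cq + delta + noise,
                config$baseline_cq + ref_cq)
    ids <- sprintf("S%02d", counter + seq_len(n))
    counter <- counter + n
    rownames(cq) <- rownames(delta) <- ids
    cq_cols[[cd]] <- cq
    delta_cols[[cd]] <- delta
    sample_id <- c(sample_id, ids)
    condition <- c(condition, rep(cd, n))
  }
  cq_all <- t(do.call(rbind, cq_cols))
  rownames(cq_all) <- c(genes, refs$gene)
  colnames(cq_all) <- sample_id
  delta_all <- t(do.call(rbind, delta_cols))
  rownames(delta_all) <- genes
  colnames(delta_all) <- sample_id
  activity <- ifelse(condition == "HC", "not-applicable",
                     sub("^.*-", "", condition))
  treat <- ifelse(condition == "HC", "HC", sub("-.*$", "", condition))
  samples <- data.frame(sample_id = sample_id, condition = treat,
                        activity = activity, group = condition,
                        stringsAsFactors = FALSE)
  list(cq = cq_all, delta = delta_all, samples = samples, repairs = repairs)
}

# Built-in clinical covariate distributions, loosely calibrated to the
# magnitudes of a treated/untreated vasculitis cohort.  Each entry is a
# function(n) on a per-condition parameter list.
.default_clinical_spec <- function() {
  ln <- function(meanlog, sdlog) list(dist = "lnorm", meanlog = meanlog, sdlog = sdlog)
  nm <- function(mean, sd) list(dist = "norm", mean = mean, sd = sd)
  all_conds <- function(x) setNames(rep(list(x), 5), .conditions())
  spec <- list(
    age = all_conds(nm(37, 9)),
    duration = all_conds(ln(3.5, 1.2)),
    ESR = list("HC" = ln(2.0, 0.5),
               "untreated-inactive" = ln(2.1, 0.5),
               "untreated-active" = ln(4.0, 0.7),
               "treated-inactive" = ln(2.4, 0.45),
               "treated-active" = ln(2.6, 0.75)),
    hsCRP = list("HC" = ln(-0.6, 0.8),
                 "untreated-inactive" = ln(-1.2, 0.6),
                 "untreated-active" = ln(4.2, 0.9),
                 "treated-inactive" = ln(-0.4, 1.0),
                 "treated-active" = ln(1.1, 1.2)),
    IL6 = list("HC" = ln(0.8, 0.4),
               "untreated-inactive" = ln(1.2, 1.0),
               "untreated-active" = ln(2.3, 0.7),
               "treated-inactive" = ln(0.85, 0.25),
               "treated-active" = ln(1.2, 0.55)),
    TNFa = list("HC" = ln(1.6, 0.35),
                "untreated-inactive" = ln(1.5, 0.25),
                "untreated-active" = ln(1.8, 0.25),
                "treated-inactive" = ln(1.8, 0.35),
                "treated-active" = ln(1.9, 0.5)),
    prednisone = list("HC" = nm(0, 0),
                      "untreated-inactive" = nm(0, 0),
                      "untreated-active" = nm(0, 0),
                      "treated-inactive" = ln(2.3, 0.9),
                      "treated-active" = ln(2.7, 0.8))
  )
  spec
}

.draw_cov <- function(par, n) {
  switch(par$dist,
         lnorm = rlnorm(n, par$meanlog, par$sdlog),
         norm = rnorm(n, par$mean, par$sd),
         stop("unknown distribution tag: ", par$dist))
}

#' Attach synthetic clinical covariates to a sample table
#'
#' Covariates are drawn from per-condition distributions; by default hs-CRP
#' and ESR have higher locations in active groups.  Entries are blanked at
#' `config$missing_rate` (sex, condition and activity are never blanked).
#'
#' @param config A [cohort_config()]; `config$clinical_spec` entries
#'   override the built-in distributions per covariate/condition.
#' @param samples Sample table from [generate_cohort()].
#' @return The sample table with covariate columns added.
#' @export
generate_clinical <- function(config, samples) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed + 1L)
  spec <- .default_clinical_spec()
  for (nm in names(config$clinical_spec)) {
    if (!nm %in% names(spec))
      stop("unknown covariate name: ", nm)
    for (cd in names(config$clinical_spec[[nm]]))
      spec[[nm]][[cd]] <- config$clinical_spec[[nm]][[cd]]
  }
  out <- samples
  grp <- samples$group
  out$sex <- ifelse(runif(nrow(out)) < 0.9, "F", "M")
  for (cov in names(spec)) {
    v <- numeric(nrow(out))
    for (cd in unique(grp)) {
      idx <- grp == cd
      par <- spec[[cov]][[cd]]
      if (is.null(par)) stop("no clinical spec for condition ", cd)
      v[idx] <- .draw_cov(par, sum(idx))
    }
    out[[cov]] <- round(v, 2)
  }
  if (config$missing_rate > 0) {
    for (cov in names(spec)) {
      miss <- runif(nrow(out)) < config$missing_rate
      out[[cov]][miss] <- NA
    }
  }
  out
}

#' Generate a random miRNA -> target-gene map
#'
#' @param n_mirnas Number of miRNAs.
#' @param genes Character vector of candidate target genes (or a count, in
#'   which case genes are named `G1..Gn`).
#' @param degree_lambda Mean of the (zero-truncated) Poisson target-set
#'   size.
#' @param family_spec Optional named list: family id -> character vector of
#'   member miRNA ids (members are created if absent).
#' @param seed Integer seed.
#' @return A [mirna_target_map()] object.
#' @export
generate_mirna_targets <- function(n_mirnas, genes, degree_lambda = 2,
                                   family_spec = NULL, seed = 1L) {
  if (n_mirnas < 1) stop("n_mirnas must be positive")
  if (is.numeric(genes)) {
    if (genes < 1) stop("gene count must be positive")
    genes <- sprintf("G%d", seq_len(genes))
  }
  set.seed(seed)
  ids <- sprintf("miR-%04d", seq_len(n_mirnas))
  fam <- setNames(rep(NA_character_, n_mirnas), ids)
  if (!is.null(family_spec)) {
    extra <- setdiff(unlist(family_spec), ids)
    ids <- c(ids, extra)
    fam <- c(fam, setNames(rep(NA_character_, length(extra)), extra))
    for (f in names(family_spec)) fam[family_spec[[f]]] <- f
  }
  targets <- lapply(ids, function(m) {
    k <- max(1L, min(length(genes), stats::rpois(1, degree_lambda)))
    sort(sample(genes, k))
  })
  names(targets) <- ids
  mirna_target_map(targets, family = fam)
}

#' Load the packaged clinical table of the 27-patient cohort
#'
#' Individual demographic and laboratory data of the treated (n = 20) and
#' untreated (n = 7) patients, as printed, with missing entries encoded as
#' `NA`.  The treated-subgroup partition used throughout the in-package
#' reproductions is rows 1-9 versus rows 10-20 of the treated block, which
#' is invariant to the inactive/active header labelling.
#'
#' @return Data frame of 27 patients.
#' @export
load_clinical_table <- function() {
  path <- system.file("extdata", "table1_clinical.csv", package = "takcoex")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Load the packaged co-expression cluster membership lists
#'
#' The two largest correlation-heatmap clusters of the inactive-treated and
#' active-treated groups, as printed.
#'
#' @return Data frame with columns `condition`, `cluster`, `gene`.
#' @export
load_cluster_table <- function() {
  path <- system.file("extdata", "coexpression_clusters.tsv",
                      package = "takcoex")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Load the packaged closeness-score component table (inactive-treated)
#'
#' Printed per-gene component counts of the three-metric TLR-closeness
#' score under Pearson and Spearman networks.
#'
#' @return Data frame with per-gene metric components and totals.
#' @export
load_closeness_components <- function() {
  path <- system.file("extdata", "table3_closeness_inactive.tsv",
                      package = "takcoex")
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
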