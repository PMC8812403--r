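# Group-comparison statistics -------------------------------------------

#' Two-sided Mann-Whitney U test
#'
#' `U` is computed from the rank sum of group `a` (average ranks for
#' ties).  Two p-value modes are available:
#'
#' * `"exact"` (default): twice the lower tail of the tie-free exact null
#'   distribution of U at `floor(min(U, n1*n2 - U))`, clamped at 1 — the
#'   "2*(1-sided exact)" convention of legacy clinical statistics software,
#'   which reproduces the printed demographic comparisons of small-cohort
#'   studies.  With ties present the tie-free distribution is an
#'   approximation; this is recorded in the `note` field.
#' * `"normal"`: normal approximation with tie-corrected variance and a
#'   0.5 continuity correction.
#'
#' Missing values are dropped per group.
#'
#' @param a,b Numeric vectors.
#' @param mode `"exact"` or `"normal"`.
#' @return List of class `takcoex_test` with `statistic` (U for group
#'   `a`), `p_value`, `n` (per-group sizes after NA removal), `method`,
#'   `ties` flag and `note`.
#' @export
mann_whitney <- function(a, b, mode = c("exact", "normal")) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("a group is entirely missing")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (mode == "exact") {
    u_min <- min(U, n1 * n2 - U)
    p <- min(1, 2 * pwilcox(floor(u_min), n1, n2))
    note <- if (ties) "ties present; exact p uses the tie-free null" else ""
  } else {
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    mu <- n1 * n2 / 2
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu)
      z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
    note <- if (ties) "tie-corrected variance" else ""
  }
  structure(list(statistic = U, p_value = p, n = c(n1, n2),
                 method = paste0("mann-whitney-", mode),
                 ties = ties, note = note),
            class = "takcoex_test")
}

#' Pearson chi-square test on a 2x2 table, no continuity correction
#'
#' Uses the closed form `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with 1
#' degree of freedom.  Yates correction is deliberately not applied: the
#' uncorrected statistic is what reproduces printed sex-ratio comparisons
#' in small cohorts.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return List of class `takcoex_test` with `statistic` (chi-square),
#'   `p_value`, `n` (total count).
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in the 2x2 table")
  n <- sum(tab)
  num <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2
  den <- prod(rowSums(tab)) * prod(colSums(tab))
  stat <- unname(num / den)
  structure(list(statistic = stat, p_value = pchisq(stat, df = 1,
                                                    lower.tail = FALSE),
                 n = n, method = "chi-square", ties = FALSE,
                 note = "no continuity correction, df = 1"),
            class = "takcoex_test")
}

#' Kolmogorov-Smirnov normality check against fitted mean/SD
#'
#' One-sample KS statistic against a normal with the sample mean and SD,
#' with the asymptotic Kolmogorov p-value.  Because the parameters are
#' estimated from the same data the p-value is anti-conservative
#' (Lilliefors caveat); this is recorded in `note`.
#'
#' @param values Numeric vector, at least 5 non-missing values.
#' @return List of class `takcoex_test` with `statistic` (D), `p_value`.
#' @export
ks_normality <- function(values) {
  x <- sort(values[!is.na(values)])
  n <- length(x)
  if (n < 5) stop("need at least 5 values")
  if (sd(x) == 0) stop("constant input")
  Fx <- pnorm(x, mean(x), sd(x))
  D <- max(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n)
  # asymptotic Kolmogorov tail: 2 * sum_k (-1)^(k-1) exp(-2 k^2 n D^2)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * n * D^2))
  p <- min(1, max(0, p))
  structure(list(statistic = D, p_value = p, n = n,
                 method = "ks-normality", ties = anyDuplicated(x) > 0,
                 note = "parameters fitted from data (Lilliefors caveat)"),
            class = "takcoex_test")
}

#' @export
print.takcoex_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)%s\n",
              x$method, x$statistic, x$p_value,
              paste(x$n, collapse = "/"),
              if (nzchar(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

#' Per-gene differential expression between two sample groups
#'
#' A two-sided Mann-Whitney test per gene, with group means and fold
#' direction.  Raw p-values are reported by default (no multiplicity
#' adjustment); set `adjust = "BH"` for Benjamini-Hochberg.
#'
#' @param expr Expression matrix, genes x samples.
#' @param samples Sample table with `sample_id` and the grouping column.
#' @param contrast Character of length 2: the two group labels, compared
#'   as `contrast[1]` vs `contrast[2]`.
#' @param group_col Column of `samples` holding the group labels.
#' @param mode Passed to [mann_whitney()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame: `gene`, `U`, `p_value` (and `p_adjusted` if
#'   requested), `mean_a`, `mean_b`, `direction` (`up` if group a higher).
#' @export
differential_expression <- function(expr, samples, contrast,
                                    group_col = "group",
                                    mode = c("exact", "normal"),
                                    adjust = c("none", "BH")) {
  mode <- match.arg(mode); adjust <- match.arg(adjust)
  stopifnot(is.matrix(expr), length(contrast) == 2)
  grp <- samples[[group_col]][match(colnames(expr), samples$sample_id)]
  ids_a <- colnames(expr)[grp %in% contrast[1]]
  ids_b <- colnames(expr)[grp %in% contrast[2]]
  if (!length(ids_a) || !length(ids_b))
    stop("contrast group absent from metadata: ",
         paste(contrast[c(!length(ids_a), !length(ids_b))], collapse = ", "))
  res <- lapply(rownames(expr), function(g) {
    a <- expr[g, ids_a]; b <- expr[g, ids_b]
    t <- mann_whitney(a, b, mode = mode)
    data.frame(gene = g, U = t$statistic, p_value = t$p_value,
               mean_a = mean(a, na.rm = TRUE), mean_b = mean(b, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$direction <- ifelse(out$mean_a >= out$mean_b, "up", "down")
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}
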