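# Regression-residual (M-value) disease-activity score -------------------
#
# Highly co-expressed pairs of a reference group (inactive-treated) define
# least-squares lines; a patient's M-value for a pair is the relative
# error of their observed y expression against the line's prediction.
# Small M = inactive-like.

#' Select highly co-expressed gene pairs
#'
#' Pairs with `|r| > r_min` and `p < alpha` (conjunctive), ordered by
#' decreasing `|r|`.
#'
#' @param correlations A [pairwise_correlation()] result for the fit
#'   group.
#' @param r_min Absolute correlation cutoff (default 0.73).
#' @param alpha Significance cutoff (default 0.01).
#' @return Data frame of qualifying rows, strongest first.
#' @export
select_pairs <- function(correlations, r_min = 0.73, alpha = 0.01) {
  keep <- !is.na(correlations$r) & !is.na(correlations$p) &
    abs(correlations$r) > r_min & correlations$p < alpha
  out <- correlations[keep, , drop = FALSE]
  out <- out[order(-abs(out$r), out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ordinary least squares line for a gene pair in a fit group
#'
#' Regresses `y_gene` on `x_gene` over the fit-group samples.  The
#' orientation follows the naming: for "relating TLR6 to TLR4",
#' `y_gene = "TLR6"`, `x_gene = "TLR4"`.
#'
#' @param expr Expression matrix, genes x samples.
#' @param x_gene,y_gene Gene names.
#' @param fit_samples Sample ids of the fit group (>= 3 complete
#'   observations required).
#' @return Object of class `pair_model`: `x_gene`, `y_gene`, `slope`,
#'   `intercept`, `r`, `p`, `n`, `fit_samples`.
#' @export
fit_pair_regression <- function(expr, x_gene, y_gene, fit_samples) {
  stopifnot(is.matrix(expr))
  if (!all(c(x_gene, y_gene) %in% rownames(expr)))
    stop("pair genes absent from expression matrix")
  x <- expr[x_gene, fit_samples]
  y <- expr[y_gene, fit_samples]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need >= 3 complete observations in the fit group")
  x <- x[ok]; y <- y[ok]
  sxx <- sum((x - mean(x))^2)
  if (sxx < .Machine$double.eps * length(x))
    stop("zero variance in x gene ", x_gene, " within the fit group")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  r <- cor(x, y)
  structure(list(x_gene = x_gene, y_gene = y_gene,
                 slope = slope, intercept = intercept,
                 r = r, p = .cor_p(r, length(x)), n = length(x),
                 fit_samples = names(x)),
            class = "pair_model")
}

#' @export
print.pair_model <- function(x, ...) {
  cat(sprintf("%s = %.4g * %s + %.4g  (fit n = %d, r = %.3f, p = %.3g)\n",
              x$y_gene, x$slope, x$x_gene, x$intercept, x$n, x$r, x$p))
  invisible(x)
}

#' M-value: relative error of a sample against a pair model
#'
#' `M = |(y_predicted - y_observed) / y_observed|`.
#'
#' @param model A [fit_pair_regression()] result.
#' @param expr Expression matrix, genes x samples.
#' @param sample Sample id (vectorised over several ids).
#' @return Data frame: `sample_id`, `pair`, `y_predicted`, `y_observed`,
#'   `AE`, `M`.  `y_observed == 0` yields NA with a warning.
#' @export
m_value <- function(model, expr, sample) {
  stopifnot(inherits(model, "pair_model"))
  x <- expr[model$x_gene, sample]
  y <- expr[model$y_gene, sample]
  pred <- model$slope * x + model$intercept
  ae <- abs(pred - y)
  m <- ae / abs(y)
  if (any(!is.na(y) & y == 0)) {
    warning("observed y of 0: M undefined for sample(s) ",
            paste(sample[!is.na(y) & y == 0], collapse = ", "))
    m[!is.na(y) & y == 0] <- NA_real_
  }
  data.frame(sample_id = sample,
             pair = paste(model$x_gene, model$y_gene, sep = "-"),
             y_predicted = as.numeric(pred), y_observed = as.numeric(y),
             AE = as.numeric(ae), M = as.numeric(m),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Youden-index threshold over a score
#'
#' All cut points between consecutive sorted unique scores (midpoints,
#' plus one below the minimum and one above the maximum) are evaluated;
#' the threshold maximizing `J = sensitivity + specificity - 1` is
#' returned.  Ties prefer higher sensitivity, then the lower threshold.
#'
#' @param scores Numeric scores.
#' @param labels Logical or two-level labels; `positive` marks cases.
#' @param positive The positive-class label (default `TRUE`).
#' @param direction `">"` if positives score high (a case is called when
#'   `score > threshold`), `"<"` if positives score low.
#' @return List: `threshold`, `J`, and the [roc_summary()] at that
#'   threshold.
#' @export
youden_threshold <- function(scores, labels, positive = TRUE,
                             direction = c(">", "<")) {
  direction <- match.arg(direction)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  best <- NULL
  for (th in cand) {
    called <- if (direction == ">") scores > th else scores < th
    sens <- sum(called & pos) / sum(pos)
    spec <- sum(!called & !pos) / sum(!pos)
    J <- sens + spec - 1
    if (is.null(best) || J > best$J + 1e-12 ||
        (abs(J - best$J) <= 1e-12 && (sens > best$sens + 1e-12 ||
         (abs(sens - best$sens) <= 1e-12 && th < best$threshold)))) {
      best <- list(threshold = th, J = J, sens = sens, spec = spec)
    }
  }
  list(threshold = best$threshold, J = best$J,
       roc = roc_summary(scores, labels, positive = positive,
                         direction = direction,
                         threshold = best$threshold))
}

#' ROC/confusion summary of a score
#'
#' AUC is the rank-concordance probability that a random positive
#' outranks a random negative (ties count one half) — identical to the
#' normalized Mann-Whitney U.  Confusion metrics are evaluated at
#' `threshold` (or the Youden-optimal one when omitted).
#'
#' @inheritParams youden_threshold
#' @param threshold Decision threshold; calls a case when `score >
#'   threshold` (direction `">"`) or `< threshold` (`"<"`).
#' @return Object of class `roc_summary`: `auc`, `threshold`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `youden_j`, `n`.
#' @export
roc_summary <- function(scores, labels, positive = TRUE,
                        direction = c(">", "<"), threshold = NULL) {
  direction <- match.arg(direction)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  s <- if (direction == ">") scores else -scores
  r <- rank(s)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (is.null(threshold)) {
    yt <- youden_threshold(scores, labels, positive = positive,
                           direction = direction)
    return(yt$roc)
  }
  called <- if (direction == ">") scores > threshold else scores < threshold
  tp <- sum(called & pos); fp <- sum(called & !pos)
  fn <- sum(!called & pos); tn <- sum(!called & !pos)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  structure(list(auc = auc, threshold = threshold,
                 sensitivity = sens, specificity = spec,
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
                 youden_j = sens + spec - 1, n = c(positive = n1, negative = n0)),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf(paste0("AUC %.3f | threshold %.4g | sens %.1f%% | spec %.1f%%",
                     " | PPV %.1f%% | NPV %.1f%% | J %.3f\n"),
              x$auc, x$threshold, 100 * x$sensitivity, 100 * x$specificity,
              100 * x$ppv, 100 * x$npv, x$youden_j))
  invisible(x)
}

#' Combined multi-pair M-value score card
#'
#' For each sample and fitted pair model, the M-value is compared with the
#' pair's threshold; a score of 1 means inactive-like (`M < threshold`).
#' The total is the sum over pairs with available expression (missing
#' pairs are flagged); the final classification is `inactive` when the
#' total reaches `total_threshold`.
#'
#' @param models List of [fit_pair_regression()] results.
#' @param pair_thresholds Numeric vector of per-pair M thresholds (same
#'   order/length as `models`).
#' @param expr Expression matrix, genes x samples.
#' @param samples Sample ids to score.
#' @param total_threshold Total-score cutoff; `total >= total_threshold`
#'   classifies inactive.  `NULL` leaves classification out.
#' @return Object of class `score_card`: data frame with one row per
#'   sample: per-pair scores, `total`, `n_pairs_used`, and
#'   `classification` when a total threshold is supplied.  The per-sample
#'   M-values are attached as attribute `"m_values"`.
#' @export
combined_score <- function(models, pair_thresholds, expr, samples,
                           total_threshold = NULL) {
  stopifnot(length(models) == length(pair_thresholds))
  pair_names <- vapply(models, function(m)
    paste(m$x_gene, m$y_gene, sep = "-"), character(1))
  mvals <- matrix(NA_real_, length(samples), length(models),
                  dimnames = list(samples, pair_names))
  for (j in seq_along(models))
    mvals[, j] <- suppressWarnings(m_value(models[[j]], expr, samples)$M)
  scores <- (mvals < matrix(pair_thresholds, nrow(mvals), ncol(mvals),
                            byrow = TRUE)) * 1
  total <- rowSums(scores, na.rm = TRUE)
  used <- rowSums(!is.na(scores))
  if (any(used < length(models)))
    warning("missing expression: some samples scored on fewer pairs")
  out <- data.frame(sample_id = samples, scores, total = total,
                    n_pairs_used = used, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(total_threshold))
    out$classification <- ifelse(total >= total_threshold,
                                 "inactive", "active")
  structure(out, class = c("score_card", "data.frame"), m_values = mvals)
}
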