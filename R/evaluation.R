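# Refractive prediction-error summaries and paired method comparisons.

#' Refractive prediction error
#'
#' `achieved - predicted` spherical equivalent, in diopters. Positive values
#' are hyperopic surprises — the classic failure mode of standard keratometry
#' after myopic laser surgery.
#'
#' @param actual_se Achieved postoperative spherical equivalent, diopters.
#' @param predicted_se Predicted spherical equivalent, diopters.
#' @return Prediction error in diopters (vectorised).
#' @export
prediction_error <- function(actual_se, predicted_se) {
  if (any(!is.finite(actual_se)) || any(!is.finite(predicted_se))) {
    stop("prediction_error requires finite inputs", call. = FALSE)
  }
  actual_se - predicted_se
}

#' Percentage of eyes within a prediction-error threshold
#'
#' Inclusive bounds: an eye with |PE| exactly equal to the threshold counts as
#' within it.
#'
#' @param pe Numeric vector of prediction errors, diopters.
#' @param threshold Threshold in diopters (e.g. 0.5, 1.0).
#' @return Percentage in \[0, 100\].
#' @export
pct_within <- function(pe, threshold) {
  stopifnot(length(pe) >= 1, threshold >= 0)
  100 * mean(abs(pe) <= threshold)
}

#' Summarise prediction errors for one method
#'
#' The standard benchmarking row for an IOL formula: mean and SD (and
#' variance) of the numeric PE, mean and median absolute PE, and the
#' percentage of eyes within 0.5 D and 1.0 D (inclusive). Both mean and
#' median absolute error are carried because method comparisons in this
#' literature use either.
#'
#' @param pe Numeric vector of prediction errors, diopters (n >= 1).
#' @param label Method label.
#' @return A one-row data.frame of class `iol_error_summary` with columns
#'   `method_label`, `n`, `mean_numeric_pe`, `sd_numeric_pe`,
#'   `variance_numeric_pe`, `mean_absolute_pe`, `median_absolute_pe`,
#'   `pct_within_0_50`, `pct_within_1_00`.
#' @examples
#' summarize_errors(c(0.4, -0.4, 0.6, -1.2), "demo")
#' @export
summarize_errors <- function(pe, label = "method") {
  if (length(pe) == 0) stop("empty prediction-error list", call. = FALSE)
  if (any(!is.finite(pe))) stop("prediction errors must be finite", call. = FALSE)
  s <- if (length(pe) > 1) stats::sd(pe) else 0
  out <- data.frame(method_label = label,
                    n = length(pe),
                    mean_numeric_pe = mean(pe),
                    sd_numeric_pe = s,
                    variance_numeric_pe = s^2,
                    mean_absolute_pe = mean(abs(pe)),
                    median_absolute_pe = stats::median(abs(pe)),
                    pct_within_0_50 = pct_within(pe, 0.5),
                    pct_within_1_00 = pct_within(pe, 1.0),
                    stringsAsFactors = FALSE)
  class(out) <- c("iol_error_summary", "data.frame")
  out
}

# exact McNemar test on a pair of paired binary indicators: binomial test on
# the discordant pairs; defined (p = 1) when there is no discordance, where
# the chi-square version is NaN
.mcnemar_exact <- function(a, b) {
  n01 <- sum(!a & b)
  n10 <- sum(a & !b)
  if (n01 + n10 == 0) {
    return(list(p = 1, note = "no discordant pairs"))
  }
  list(p = stats::binom.test(n10, n01 + n10, p = 0.5)$p.value, note = "")
}

.safe_test <- function(expr) {
  tryCatch(list(p = expr, note = ""),
           error = function(e) list(p = NA_real_,
                                    note = paste("not computable:",
                                                 conditionMessage(e))))
}

#' Paired statistical comparison of IOL calculation methods
#'
#' Runs the benchmarking battery on a paired eyes-by-methods matrix of
#' prediction errors:
#' \itemize{
#'   \item per method, a one-sample t test of the mean numeric PE against zero;
#'   \item a one-way ANOVA across methods on the numeric PE (omnibus), plus
#'     pairwise two-sided variance-ratio F tests;
#'   \item a Friedman omnibus test on the absolute PE with pairwise Wilcoxon
#'     signed-rank post hoc tests;
#'   \item exact McNemar tests on the paired within-0.5 D and within-1.0 D
#'     indicators.
#' }
#' All pairwise p-values are Bonferroni-adjusted (multiplied by the number of
#' pairwise comparisons, capped at 1). Degenerate inputs (zero variance, no
#' discordant pairs) yield explicit "not computable" notes or p = 1 rather
#' than errors. Significance is flagged at alpha = 0.05.
#'
#' @param pe_matrix Numeric matrix or data.frame, one row per eye and one
#'   column per method (paired: same eyes in every column).
#' @param labels Method labels; defaults to column names.
#' @return A list of class `iol_method_comparison` with elements
#'   `per_method`, `anova_numeric_pe_p`, `friedman_absolute_pe_p`,
#'   `pairwise` (data.frame with raw and Bonferroni-adjusted p-values),
#'   `n_comparisons`, `alpha`.
#' @export
compare_methods <- function(pe_matrix, labels = colnames(pe_matrix)) {
  pe <- as.matrix(pe_matrix)
  if (ncol(pe) < 2) stop("need at least 2 methods to compare", call. = FALSE)
  if (is.null(labels)) labels <- paste0("method", seq_len(ncol(pe)))
  if (any(!is.finite(pe))) {
    stop("pairing error: prediction-error matrix must be complete and finite",
         call. = FALSE)
  }
  m <- ncol(pe); n <- nrow(pe)
  alpha <- 0.05

  per_method <- do.call(rbind, lapply(seq_len(m), function(j) {
    tt <- .safe_test(stats::t.test(pe[, j], mu = 0)$p.value)
    if (tt$note == "" && !is.finite(tt$p)) {
      tt <- list(p = NA_real_, note = "not computable: degenerate (zero variance)")
    }
    data.frame(method_label = labels[j],
               mean_numeric_pe = mean(pe[, j]),
               t_p = tt$p,
               t_significant = isTRUE(tt$p < alpha),
               note = tt$note,
               stringsAsFactors = FALSE)
  }))

  long <- data.frame(pe = as.vector(pe),
                     method = factor(rep(labels, each = n)))
  anova_p <- .safe_test(summary(stats::aov(pe ~ method, data = long))[[1]][
    "method", "Pr(>F)"])$p

  fried <- .safe_test(stats::friedman.test(abs(pe))$p.value)
  if (is.finite(fried$p) == FALSE && fried$note == "") {
    fried <- list(p = 1, note = "no variation across methods")
  }
  if (!is.na(fried$p) && is.nan(fried$p)) {
    fried <- list(p = 1, note = "no variation across methods")
  }

  pairs <- utils::combn(m, 2)
  n_comp <- ncol(pairs)
  pairwise <- do.call(rbind, lapply(seq_len(n_comp), function(idx) {
    i <- pairs[1, idx]; j <- pairs[2, idx]
    f <- .safe_test(stats::var.test(pe[, i], pe[, j])$p.value)
    d <- abs(pe[, i]) - abs(pe[, j])
    w <- if (all(d == 0)) {
      list(p = NA_real_, note = "no variation in |PE| differences")
    } else {
      .safe_test(stats::wilcox.test(abs(pe[, i]), abs(pe[, j]),
                                    paired = TRUE, exact = FALSE)$p.value)
    }
    m05 <- .mcnemar_exact(abs(pe[, i]) <= 0.5, abs(pe[, j]) <= 0.5)
    m10 <- .mcnemar_exact(abs(pe[, i]) <= 1.0, abs(pe[, j]) <= 1.0)
    data.frame(method_1 = labels[i], method_2 = labels[j],
               f_variance_p = f$p,
               wilcoxon_abs_pe_p = w$p,
               mcnemar_within_0_50_p = m05$p,
               mcnemar_within_1_00_p = m10$p,
               note = trimws(paste(f$note, w$note, m05$note, m10$note)),
               stringsAsFactors = FALSE)
  }))
  adjust <- function(p) pmin(p * n_comp, 1)
  for (col in c("f_variance_p", "wilcoxon_abs_pe_p",
                "mcnemar_within_0_50_p", "mcnemar_within_1_00_p")) {
    pairwise[[paste0(col, "_adj")]] <- adjust(pairwise[[col]])
  }

  structure(list(per_method = per_method,
                 anova_numeric_pe_p = anova_p,
                 friedman_absolute_pe_p = fried$p,
                 friedman_note = fried$note,
                 pairwise = pairwise,
                 n_comparisons = n_comp,
                 alpha = alpha),
            class = "iol_method_comparison")
}

#' @export
print.iol_method_comparison <- function(x, ...) {
  cat("Paired IOL method comparison (alpha =", x$alpha, ")\n\n")
  cat("Per-method one-sample t vs 0:\n")
  print(x$per_method, row.names = FALSE)
  cat(sprintf("\nANOVA on numeric PE: p = %.4g\n", x$anova_numeric_pe_p))
  cat(sprintf("Friedman on absolute PE: p = %.4g %s\n",
              x$friedman_absolute_pe_p,
              if (nzchar(x$friedman_note)) paste0("(", x$friedman_note, ")") else ""))
  cat(sprintf("\nPairwise tests (Bonferroni x%d in *_adj columns):\n",
              x$n_comparisons))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
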