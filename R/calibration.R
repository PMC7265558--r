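# Krd regression calibration: published presets, OLS fitting, and the
# cohort-level calibration chain.

#' Krd regression objects and the published presets
#'
#' A `krd_regression` is a slope/intercept pair mapping a measured Scheimpflug
#' corneal power to the refraction-derived corneal power (Krd) that should be
#' entered into the Haigis formula, together with fit diagnostics.
#'
#' `krd_paper_regression()` returns the published Group-I calibrations for the
#' 4.0 mm zone maps, shipped as frozen constants:
#' \describe{
#'   \item{`"tcrp4"`}{Krd = 0.989 * K_TCRP + 0.179 (Pearson r = 0.873, n = 50)}
#'   \item{`"trp4"`}{Krd = 0.974 * K_TRP + 0.882 (Pearson r = 0.898, n = 50)}
#' }
#' Calibration with [fit_krd_regression()] never overwrites these presets.
#'
#' @param slope Dimensionless slope.
#' @param intercept Intercept in diopters.
#' @param pearson_r Pearson product-moment correlation of the fitted pairs.
#' @param n Number of eyes behind the fit.
#' @param k_source `"tcrp4"` or `"trp4"`.
#' @param se_slope,se_intercept Optional OLS standard errors.
#' @param provenance Free-text provenance string.
#' @return An object of class `krd_regression`.
#' @export
krd_regression <- function(slope, intercept, pearson_r = NA_real_,
                           n = NA_integer_, k_source = c("tcrp4", "trp4"),
                           se_slope = NA_real_, se_intercept = NA_real_,
                           provenance = "user-specified") {
  k_source <- match.arg(k_source)
  stopifnot(is.finite(slope), is.finite(intercept))
  if (is.finite(pearson_r) && (pearson_r < -1 || pearson_r > 1)) {
    stop("pearson_r must lie in [-1, 1]", call. = FALSE)
  }
  if (is.finite(n) && n < 3) {
    stop("a fitted regression needs n >= 3 eyes", call. = FALSE)
  }
  structure(list(slope = as.numeric(slope), intercept = as.numeric(intercept),
                 pearson_r = as.numeric(pearson_r), n = as.integer(n),
                 k_source = k_source,
                 se_slope = as.numeric(se_slope),
                 se_intercept = as.numeric(se_intercept),
                 provenance = provenance),
            class = "krd_regression")
}

#' @rdname krd_regression
#' @export
krd_paper_regression <- function(k_source = c("tcrp4", "trp4")) {
  k_source <- match.arg(k_source)
  if (k_source == "tcrp4") {
    krd_regression(0.989, 0.179, pearson_r = 0.873, n = 50L, k_source = "tcrp4",
                   provenance = "published Group-I calibration, Scheimpflug TCRP 4 mm (Haigis)")
  } else {
    krd_regression(0.974, 0.882, pearson_r = 0.898, n = 50L, k_source = "trp4",
                   provenance = "published Group-I calibration, Scheimpflug TRP 4 mm (Haigis)")
  }
}

#' @export
print.krd_regression <- function(x, ...) {
  cat(sprintf("Krd regression [%s]: Krd = %.6g * K %+.6g\n",
              x$k_source, x$slope, x$intercept))
  if (is.finite(x$pearson_r)) cat(sprintf("  Pearson r = %.4g", x$pearson_r))
  if (is.finite(x$n)) cat(sprintf(", n = %d", x$n))
  cat("\n  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Apply a Krd correction to measured corneal powers
#'
#' Returns `slope * k_measured + intercept` — the corrected corneal power to
#' enter into the Haigis formula for a post-myopic-LASIK eye.
#'
#' @param k_measured Measured corneal power in diopters (vectorised).
#' @param regression A [krd_regression] object, e.g. [krd_paper_regression()].
#' @return Corrected corneal power in diopters.
#' @examples
#' apply_krd(39.24, krd_paper_regression("tcrp4"))
#' @export
apply_krd <- function(k_measured, regression) {
  stopifnot(inherits(regression, "krd_regression"))
  if (any(!is.finite(k_measured))) {
    stop("k_measured must be finite", call. = FALSE)
  }
  regression$slope * k_measured + regression$intercept
}

#' Fit a Krd regression by ordinary least squares
#'
#' OLS of the refraction-derived K on the measured K, with the Pearson
#' product-moment correlation attached. Unweighted by default and with no
#' outlier rejection; per-point weights are accepted for forward
#' compatibility.
#'
#' @param k_measured Measured corneal powers, diopters.
#' @param k_rd Refraction-derived corneal powers, diopters.
#' @param k_source `"tcrp4"` or `"trp4"` (recorded in the result).
#' @param weights Optional non-negative per-point weights.
#' @return A [krd_regression] with OLS standard errors attached.
#' @export
fit_krd_regression <- function(k_measured, k_rd,
                               k_source = c("tcrp4", "trp4"), weights = NULL) {
  k_source <- match.arg(k_source)
  ok <- is.finite(k_measured) & is.finite(k_rd)
  x <- k_measured[ok]; y <- k_rd[ok]
  w <- if (is.null(weights)) NULL else weights[ok]
  if (length(x) < 3) {
    stop("need at least 3 finite (k_measured, k_rd) pairs to fit", call. = FALSE)
  }
  if (stats::var(x) < .Machine$double.eps) {
    stop("degenerate fit: zero variance in k_measured", call. = FALSE)
  }
  fit <- if (is.null(w)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = w)
  cf <- stats::coef(fit)
  # noiseless calibration chains fit exactly; the "essentially perfect fit"
  # warning from summary.lm is expected there, not a defect
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  krd_regression(slope = unname(cf[2]), intercept = unname(cf[1]),
                 pearson_r = stats::cor(x, y), n = length(x),
                 k_source = k_source,
                 se_slope = unname(se[2]), se_intercept = unname(se[1]),
                 provenance = sprintf("fitted by OLS on %d eyes", length(x)))
}

#' Calibrate a Krd regression from a cohort
#'
#' The full Group-I style calibration chain: for every eye, back-calculate the
#' refraction-derived K from the implanted IOL power and achieved
#' postoperative refraction via the Haigis engine, pair it with the measured K
#' of the chosen Scheimpflug source, and fit the OLS regression. Equal to the
#' composition of [cohort_krd()] and [fit_krd_regression()], and invariant to
#' the order of the records.
#'
#' @inheritParams cohort_krd
#' @return A [krd_regression].
#' @export
calibrate_from_cohort <- function(cohort, constants,
                                  k_source = c("tcrp4", "trp4"),
                                  mode = c("direct", "reindex")) {
  k_source <- match.arg(k_source)
  mode <- match.arg(mode)
  pairs <- cohort_krd(cohort, constants, k_source = k_source, mode = mode)
  usable <- is.finite(pairs$k_measured) & is.finite(pairs$k_rd)
  if (sum(usable) < 3) {
    stop("degenerate fit: fewer than 3 usable eyes for k_source = ", k_source,
         call. = FALSE)
  }
  fit_krd_regression(pairs$k_measured[usable], pairs$k_rd[usable],
                     k_source = k_source)
}

#' Write or read a Krd regression as JSON
#'
#' @param regression A [krd_regression].
#' @param path JSON file path.
#' @return `write_krd_regression()` returns `path` invisibly;
#'   `read_krd_regression()` returns a [krd_regression].
#' @export
write_krd_regression <- function(regression, path) {
  stopifnot(inherits(regression, "krd_regression"))
  jsonlite::write_json(unclass(regression), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_krd_regression
#' @export
read_krd_regression <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  krd_regression(cfg$slope, cfg$intercept,
                 pearson_r = if (is.null(cfg$pearson_r)) NA_real_ else cfg$pearson_r,
                 n = if (is.null(cfg$n)) NA_integer_ else cfg$n,
                 k_source = cfg$k_source,
                 se_slope = if (is.null(cfg$se_slope)) NA_real_ else cfg$se_slope,
                 se_intercept = if (is.null(cfg$se_intercept)) NA_real_ else cfg$se_intercept,
                 provenance = if (is.null(cfg$provenance)) "file" else cfg$provenance)
}
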