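# Seeded synthetic post-myopic-LASIK cohorts.
#
# The generator emulates the published two-group study design: biometry drawn
# from the reported marginal distributions (truncated normals inside the
# reported ranges), a latent "true" effective corneal power linked to the
# measured Scheimpflug K through the reported regression line plus Gaussian
# residual, implanted IOL powers chosen by the Haigis formula from the
# measured K and rounded to clinical half-diopter steps, and postoperative
# refractions produced by forward vergence simulation from the latent truth.

# ---- truncated normal primitives (inverse-CDF sampling + analytic moments) --

.rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Analytic moments of a truncated normal
#'
#' Mean and standard deviation of a Normal(mean, sd) truncated to
#' `[lower, upper]` — the distribution the cohort generator samples from.
#' Used to state (and test) the generator's realised biometry moments without
#' simulation: truncation to an asymmetric range shifts the mean and shrinks
#' the spread relative to the nominal parameters.
#'
#' @param mean,sd Nominal (untruncated) parameters.
#' @param lower,upper Truncation bounds.
#' @return A list with elements `mean` and `sd`.
#' @export
truncnorm_moments <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  mu <- mean + sd * (da - db) / z
  v <- sd^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  list(mean = mu, sd = sqrt(v))
}

#' Residual SD implied by a regression slope, predictor SD and correlation
#'
#' For y = slope * x + intercept + e with e ~ Normal(0, sigma) and
#' sd(x) = sd_x, the population Pearson correlation is
#' r = slope * sd_x / sqrt(slope^2 * sd_x^2 + sigma^2). Solving for sigma
#' gives `slope * sd_x * sqrt(1/r^2 - 1)`. The generator presets derive their
#' residual SDs from the published slope, K SD and correlation coefficient
#' this way, so the simulated scattergrams have the reported tightness.
#'
#' @param slope Regression slope.
#' @param sd_x SD of the predictor.
#' @param r Target Pearson correlation (0 < |r| < 1).
#' @return Residual SD, same units as y.
#' @examples
#' residual_sd_from_correlation(0.989, 2.38, 0.873)
#' @export
residual_sd_from_correlation <- function(slope, sd_x, r) {
  stopifnot(abs(r) > 0, abs(r) < 1, sd_x > 0)
  abs(slope) * sd_x * sqrt(1 / r^2 - 1)
}

# ---- cohort specification ---------------------------------------------------

#' Specify a synthetic post-LASIK cohort
#'
#' Defaults reproduce the published Group-I conditions: axial length
#' 28.08 +/- 2.50 mm (range 22.55--31.62), anterior chamber depth
#' 3.63 +/- 0.34 mm (2.83--4.30), Scheimpflug K_TCRP 39.24 +/- 2.38 D and
#' K_TRP 39.13 +/- 2.49 D (range 34.45--45.96), linked to the latent true
#' corneal power through the published calibration lines
#' (0.989 x + 0.179 for TCRP, 0.974 x + 0.882 for TRP) with residual SDs
#' derived from the published correlations (0.873, 0.898) via
#' [residual_sd_from_correlation()]. Biometry variables are drawn
#' independently (no covariance is reported); see the package vignette for
#' what this does and does not emulate.
#'
#' @param n Number of eyes (>= 1).
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   spec, so equal specs give identical cohorts.
#' @param k_source Which Scheimpflug map the simulated surgeon measures and
#'   the calibration targets: `"tcrp4"` (default) or `"trp4"`.
#' @param preset `"group1"` (calibration group, default) or `"group2"`
#'   (validation group: AL 28.21 +/- 2.24 mm in 24.03--31.25, ACD
#'   3.61 +/- 0.32 mm in 3.17--4.49, mean K 38.83 +/- 2.94 D in 37.38--45.96).
#' @param al_mean,al_sd,al_range Axial length distribution, mm.
#' @param acd_mean,acd_sd,acd_range Anterior chamber depth distribution, mm.
#' @param k_mean,k_sd,k_range Measured K distribution for `k_source`, D.
#' @param true_slope,true_intercept The generating calibration line mapping
#'   measured K to the latent true corneal power.
#' @param residual_sd SD of the Gaussian residual around that line, D.
#' @param target_refraction Surgeon's target SE, D (default -0.5, the usual
#'   mildly myopic target after myopic laser surgery).
#' @param iol_step IOL labelling step, D (default 0.5).
#' @param measurement_noise_sd SD of additional noise on the postoperative
#'   manifest SE, D (default 0: the refraction reflects the latent optics
#'   exactly).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n, seed, k_source = c("tcrp4", "trp4"),
                        preset = c("group1", "group2"),
                        al_mean = NULL, al_sd = NULL, al_range = NULL,
                        acd_mean = NULL, acd_sd = NULL, acd_range = NULL,
                        k_mean = NULL, k_sd = NULL, k_range = NULL,
                        true_slope = NULL, true_intercept = NULL,
                        residual_sd = NULL,
                        target_refraction = -0.5, iol_step = 0.5,
                        measurement_noise_sd = 0) {
  k_source <- match.arg(k_source)
  preset <- match.arg(preset)
  stopifnot(n >= 1, is.finite(seed))

  if (preset == "group1") {
    defaults <- list(al_mean = 28.08, al_sd = 2.50, al_range = c(22.55, 31.62),
                     acd_mean = 3.63, acd_sd = 0.34, acd_range = c(2.83, 4.30))
    k_def <- if (k_source == "tcrp4") {
      list(k_mean = 39.24, k_sd = 2.38, k_range = c(34.45, 45.96),
           true_slope = 0.989, true_intercept = 0.179, r = 0.873)
    } else {
      list(k_mean = 39.13, k_sd = 2.49, k_range = c(34.45, 45.96),
           true_slope = 0.974, true_intercept = 0.882, r = 0.898)
    }
  } else {
    defaults <- list(al_mean = 28.21, al_sd = 2.24, al_range = c(24.03, 31.25),
                     acd_mean = 3.61, acd_sd = 0.32, acd_range = c(3.17, 4.49))
    k_def <- if (k_source == "tcrp4") {
      list(k_mean = 38.83, k_sd = 2.94, k_range = c(37.38, 45.96),
           true_slope = 0.989, true_intercept = 0.179, r = 0.873)
    } else {
      list(k_mean = 38.83, k_sd = 2.94, k_range = c(37.38, 45.96),
           true_slope = 0.974, true_intercept = 0.882, r = 0.898)
    }
  }

  pick <- function(x, d) if (is.null(x)) d else x
  spec <- list(
    n = as.integer(n), seed = as.integer(seed),
    k_source = k_source, preset = preset,
    al_mean = pick(al_mean, defaults$al_mean),
    al_sd = pick(al_sd, defaults$al_sd),
    al_range = pick(al_range, defaults$al_range),
    acd_mean = pick(acd_mean, defaults$acd_mean),
    acd_sd = pick(acd_sd, defaults$acd_sd),
    acd_range = pick(acd_range, defaults$acd_range),
    k_mean = pick(k_mean, k_def$k_mean),
    k_sd = pick(k_sd, k_def$k_sd),
    k_range = pick(k_range, k_def$k_range),
    true_slope = pick(true_slope, k_def$true_slope),
    true_intercept = pick(true_intercept, k_def$true_intercept),
    residual_sd = pick(residual_sd,
                       residual_sd_from_correlation(k_def$true_slope,
                                                    k_def$k_sd, k_def$r)),
    target_refraction = target_refraction,
    iol_step = iol_step,
    measurement_noise_sd = measurement_noise_sd)
  stopifnot(spec$al_sd > 0, spec$acd_sd > 0, spec$k_sd > 0,
            spec$residual_sd >= 0, spec$measurement_noise_sd >= 0)
  # truncation bounds must keep every generated eye inside the validity ranges
  stopifnot(spec$al_range[1] >= .AL_RANGE[1], spec$al_range[2] <= .AL_RANGE[2],
            spec$acd_range[1] >= .ACD_RANGE[1], spec$acd_range[2] <= .ACD_RANGE[2],
            spec$k_range[1] >= .K_RANGE[1], spec$k_range[2] <= .K_RANGE[2])
  class(spec) <- "cohort_spec"
  spec
}

# run expr under a local RNG state so generation never perturbs the caller's
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic post-LASIK cohort
#'
#' Per eye: draw axial length, anterior chamber depth and measured K from
#' independent truncated normals; draw the latent true corneal power
#' `K_true = slope * K_measured + intercept + Normal(0, residual_sd)`; select
#' the implanted IOL power with [iol_power_for_target()] from the *measured*
#' K (what a surgeon without the latent truth would do) and round it to the
#' labelling step; then simulate the achieved postoperative spherical
#' equivalent with [predict_refraction()] from `K_true` and the implanted
#' power, plus optional measurement noise. With zero residual SD and zero
#' measurement noise the chain is exactly invertible:
#' [back_calculated_k()] recovers `K_true` to machine precision.
#'
#' @param spec A [cohort_spec].
#' @param constants An [iol_constants] object (default
#'   [example_iol_constants()]).
#' @return A list with elements `cohort` (an `iol_cohort` data.frame in the
#'   [load_cohort()] schema) and `truth` (data.frame `eye_id`, `k_true` — the
#'   hidden truth table for recovery tests). Deterministic for a fixed spec.
#' @examples
#' g1 <- generate_cohort(cohort_spec(n = 50, seed = 42))
#' head(g1$cohort)
#' @export
generate_cohort <- function(spec, constants = example_iol_constants()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(constants, "iol_constants"))
  .with_seed(spec$seed, {
    n <- spec$n
    draw <- function(m) {
      list(al = .rtruncnorm(m, spec$al_mean, spec$al_sd,
                            spec$al_range[1], spec$al_range[2]),
           acd = .rtruncnorm(m, spec$acd_mean, spec$acd_sd,
                             spec$acd_range[1], spec$acd_range[2]),
           k = .rtruncnorm(m, spec$k_mean, spec$k_sd,
                           spec$k_range[1], spec$k_range[2]))
    }
    simulate <- function(b) {
      k_true <- spec$true_slope * b$k + spec$true_intercept +
        stats::rnorm(length(b$k), 0, spec$residual_sd)
      elp <- haigis_elp(b$acd, b$al, constants)
      p_exact <- iol_power_for_target(b$k, spec$target_refraction,
                                      b$al, elp, constants)
      p <- round_iol_power(p_exact, spec$iol_step)
      se <- predict_refraction(k_true, p, b$al, elp, constants) +
        stats::rnorm(length(b$k), 0, spec$measurement_noise_sd)
      list(k_true = k_true, p = p, se = se)
    }
    valid <- function(b, s) {
      is.finite(s$se) & abs(s$se) <= .SE_MAX &
        s$p >= .IOL_RANGE[1] & s$p <= .IOL_RANGE[2] &
        k_in_range(s$k_true)
    }
    k_in_range <- function(k) is.finite(k) & k >= .K_RANGE[1] & k <= .K_RANGE[2]

    b <- draw(n); s <- simulate(b)
    ok <- valid(b, s)
    tries <- 0
    while (any(!ok)) {
      tries <- tries + 1
      if (tries > 100) {
        stop("cohort spec repeatedly produced invalid optics; check parameters",
             call. = FALSE)
      }
      m <- sum(!ok)
      nb <- draw(m); ns <- simulate(nb)
      for (f in names(b)) b[[f]][!ok] <- nb[[f]]
      for (f in names(s)) s[[f]][!ok] <- ns[[f]]
      ok <- valid(b, s)
    }

    eye_id <- sprintf("syn%05d", seq_len(n))
    is_tcrp <- spec$k_source == "tcrp4"
    cohort <- data.frame(
      eye_id = eye_id,
      axial_length_mm = b$al,
      acd_mm = b$acd,
      k_tcrp_4mm_d = if (is_tcrp) b$k else NA_real_,
      k_trp_4mm_d = if (is_tcrp) NA_real_ else b$k,
      implanted_power_d = s$p,
      target_se_d = spec$target_refraction,
      postop_sphere_d = s$se,
      postop_cylinder_d = 0,
      stringsAsFactors = FALSE)
    class(cohort) <- c("iol_cohort", "data.frame")
    list(cohort = cohort,
         truth = data.frame(eye_id = eye_id, k_true = s$k_true,
                            stringsAsFactors = FALSE))
  })
}
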