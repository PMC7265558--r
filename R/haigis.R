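# Haigis thin-lens vergence optics.
#
# The Haigis formula models the pseudophakic eye as two thin refracting
# elements, cornea (power D_c) and IOL (power P), separated by the effective
# lens position d = a0 + a1*ACD + a2*AL, in an aqueous medium of index n.
# Vergence bookkeeping, with lengths in metres:
#
#   z   = n / (d + n / (n/(L - d) - P))     (required corneal-plane total power)
#   R_c = z - D_c                            (corneal-plane refraction)
#   R_x = R_c / (1 + R_c * dx)               (spectacle-plane refraction)
#
# Every operation below is an exact algebraic rearrangement of this one chain,
# so predicted refraction, IOL power for a target, and back-calculated corneal
# power are mutual inverses by construction; the round-trip identities are the
# normative contract and are enforced by the test suite.

.assert_denominator <- function(x, step) {
  if (any(!is.finite(x)) || any(abs(x) < 1e-12)) {
    stop("optical singularity: vanishing denominator in ", step, call. = FALSE)
  }
  invisible(TRUE)
}

#' Haigis effective lens position
#'
#' Predicted distance from cornea to IOL plane, `d = a0 + a1*ACD + a2*AL`, in
#' millimetres. The Haigis ELP depends on the preoperative anterior chamber
#' depth and axial length only (not on corneal power), which is what makes the
#' corneal-power back-calculation closed-form.
#'
#' @param acd Anterior chamber depth in millimetres (vectorised).
#' @param axial_length Axial length in millimetres (vectorised).
#' @param constants An [iol_constants] object.
#' @return ELP in millimetres. It is a hard error for the predicted ELP to
#'   fall outside the open interval (0, axial length): that geometry puts the
#'   lens outside the eye and means the constants do not match the biometry.
#' @examples
#' cst <- iol_constants(a0 = 1, a1 = 0.4, a2 = 0.1)
#' haigis_elp(acd = 3.63, axial_length = 28.08, cst)  # 5.260
#' @export
haigis_elp <- function(acd, axial_length, constants) {
  stopifnot(inherits(constants, "iol_constants"))
  d <- constants$a0 + constants$a1 * acd + constants$a2 * axial_length
  bad <- !is.finite(d) | d <= 0 | d >= axial_length
  if (any(bad)) {
    stop(sprintf(paste0("invalid geometry: ELP %g mm not inside (0, AL = %g mm) ",
                        "for constants (a0=%g, a1=%g, a2=%g)%s"),
                 d[bad][1], axial_length[bad][1],
                 constants$a0, constants$a1, constants$a2,
                 if (nzchar(constants$label)) paste0(" [", constants$label, "]") else ""),
         call. = FALSE)
  }
  d
}

#' Corneal power as entered into the vergence formula
#'
#' Scheimpflug TCRP/TRP values are ray-traced (or two-surface) total corneal
#' powers and by default are entered into the Haigis formula as-is
#' (`mode = "direct"`). `mode = "reindex"` applies the classical
#' keratometric-index conversion for K readings calibrated to index 1.3375
#' when the formula expects the 1.3315 convention: the radius is recovered as
#' `r = 337.5/K` and the power recomputed as `331.5/r`, i.e. a rescale by
#' 331.5/337.5.
#'
#' @param k Corneal power in diopters (vectorised).
#' @param mode `"direct"` (default) or `"reindex"`.
#' @return Corneal power in diopters.
#' @examples
#' corneal_power(40)                      # 40
#' corneal_power(33.75, mode = "reindex") # 33.15 (r = 10 mm exactly)
#' @export
corneal_power <- function(k, mode = c("direct", "reindex")) {
  mode <- match.arg(mode)
  if (any(!is.finite(k) | k <= 0)) {
    stop("corneal power must be positive and finite", call. = FALSE)
  }
  if (mode == "direct") k else k * 331.5 / 337.5
}

# shared vergence step: corneal-plane power required to focus IOL power P on
# the retina (all arguments in D / mm; returns D)
.required_corneal_plane_power <- function(iol_power, axial_length, elp, constants) {
  n <- constants$n_aqueous
  L <- axial_length / 1000
  d <- elp / 1000
  .assert_denominator(L - d, "vitreous path length (AL - ELP)")
  v_behind <- n / (L - d) - iol_power
  .assert_denominator(v_behind, "vergence entering the IOL")
  inner <- d + n / v_behind
  .assert_denominator(inner, "vergence transfer IOL to cornea")
  n / inner
}

#' Predicted spectacle refraction for an implanted IOL
#'
#' Closed-form Haigis vergence inversion: given the corneal power entered as K,
#' the IOL power, the axial length and the effective lens position, returns
#' the spherical-equivalent refraction at the spectacle plane. No iteration is
#' involved.
#'
#' @param k Corneal power entered into the formula, diopters (see
#'   [corneal_power()] for keratometric handling).
#' @param iol_power Implanted or candidate IOL power, diopters.
#' @param axial_length Axial length, millimetres.
#' @param elp Effective lens position, millimetres (from [haigis_elp()]).
#' @param constants An [iol_constants] object (supplies the aqueous index and
#'   vertex distance).
#' @return Spectacle-plane spherical equivalent, diopters. All arguments are
#'   vectorised and recycled.
#' @seealso [iol_power_for_target()] and [back_calculated_k()], its exact
#'   algebraic inverses.
#' @export
predict_refraction <- function(k, iol_power, axial_length, elp, constants) {
  stopifnot(inherits(constants, "iol_constants"))
  z <- .required_corneal_plane_power(iol_power, axial_length, elp, constants)
  r_c <- z - k
  dx <- constants$vertex_distance / 1000
  denom <- 1 + r_c * dx
  .assert_denominator(denom, "corneal-to-spectacle plane conversion")
  r_c / denom
}

#' IOL power for a target refraction
#'
#' Exact algebraic inverse of [predict_refraction()]: the IOL power whose
#' predicted spectacle refraction equals `target_se`.
#'
#' @inheritParams predict_refraction
#' @param target_se Targeted postoperative spherical equivalent at the
#'   spectacle plane, diopters.
#' @return IOL power in diopters, as an exact real number; see
#'   [round_iol_power()] for clinical half-diopter labelling.
#' @export
iol_power_for_target <- function(k, target_se, axial_length, elp, constants) {
  stopifnot(inherits(constants, "iol_constants"))
  n <- constants$n_aqueous
  dx <- constants$vertex_distance / 1000
  L <- axial_length / 1000
  d <- elp / 1000
  denom <- 1 - target_se * dx
  .assert_denominator(denom, "spectacle-to-corneal plane conversion")
  z <- k + target_se / denom
  .assert_denominator(z, "required corneal-plane power")
  inner <- n / z - d
  .assert_denominator(inner, "vergence transfer cornea to IOL")
  .assert_denominator(L - d, "vitreous path length (AL - ELP)")
  n / (L - d) - n / inner
}

#' Back-calculate the corneal power from an observed refraction (Krd)
#'
#' The refraction-derived K: the corneal power that, entered into the Haigis
#' formula together with the implanted IOL power, reproduces the achieved
#' postoperative spherical equivalent exactly. Because the Haigis ELP does not
#' depend on K, the inversion is closed-form. This is the quantity regressed
#' against measured Scheimpflug K to calibrate post-refractive-surgery
#' corrections (see [calibrate_from_cohort()]).
#'
#' @inheritParams predict_refraction
#' @param postop_se Achieved postoperative spherical equivalent at the
#'   spectacle plane, diopters.
#' @param k_measured Optional measured corneal power, diopters; when supplied,
#'   a back-calculated K differing from it by more than 5 D raises a
#'   suspicious-record warning (likely data entry or pairing error).
#' @return Refraction-derived corneal power (Krd) in diopters, with logical
#'   attribute `suspicious` when `k_measured` was supplied.
#' @export
back_calculated_k <- function(postop_se, iol_power, axial_length, elp,
                              constants, k_measured = NULL) {
  stopifnot(inherits(constants, "iol_constants"))
  z <- .required_corneal_plane_power(iol_power, axial_length, elp, constants)
  dx <- constants$vertex_distance / 1000
  denom <- 1 - postop_se * dx
  .assert_denominator(denom, "spectacle-to-corneal plane conversion")
  krd <- z - postop_se / denom
  if (!is.null(k_measured)) {
    suspicious <- is.finite(k_measured) & abs(krd - k_measured) > 5
    if (any(suspicious)) {
      warning(sprintf("%d record(s) with |Krd - measured K| > 5 D flagged as suspicious",
                      sum(suspicious)), call. = FALSE)
    }
    attr(krd, "suspicious") <- suspicious
  }
  krd
}

#' Round an exact IOL power to the clinical labelling step
#'
#' IOLs are labelled in half-diopter steps. Rounds to the nearest step; exact
#' ties go upward in power, i.e. toward a slightly more myopic (more minus)
#' predicted refraction, the conventional conservative choice after myopic
#' laser surgery.
#'
#' @param p IOL power in diopters (vectorised).
#' @param step Labelling step in diopters (default 0.5).
#' @return Rounded power in diopters.
#' @examples
#' round_iol_power(16.24)  # 16.0
#' round_iol_power(16.25)  # 16.5 (tie goes up)
#' @export
round_iol_power <- function(p, step = 0.5) {
  stopifnot(step > 0)
  floor(p / step + 0.5) * step
}

#' Per-eye refraction-derived K for a cohort
#'
#' Applies [haigis_elp()] and [back_calculated_k()] to every row of a cohort
#' data.frame (schema of [load_cohort()]), pairing each back-calculated value
#' with the measured K of the chosen Scheimpflug source.
#'
#' @param cohort A cohort data.frame (see [load_cohort()]).
#' @param constants An [iol_constants] object.
#' @param k_source `"tcrp4"` or `"trp4"`: which measured K column to pair with.
#' @param mode Keratometric handling for the measured K ([corneal_power()]).
#' @return A data.frame with columns `eye_id`, `k_measured`, `k_rd`,
#'   `suspicious`.
#' @export
cohort_krd <- function(cohort, constants, k_source = c("tcrp4", "trp4"),
                       mode = c("direct", "reindex")) {
  k_source <- match.arg(k_source)
  mode <- match.arg(mode)
  k_col <- if (k_source == "tcrp4") "k_tcrp_4mm_d" else "k_trp_4mm_d"
  elp <- haigis_elp(cohort$acd_mm, cohort$axial_length_mm, constants)
  se <- spherical_equivalent(cohort$postop_sphere_d, cohort$postop_cylinder_d)
  k_meas <- cohort[[k_col]]
  krd <- back_calculated_k(se, cohort$implanted_power_d,
                           cohort$axial_length_mm, elp, constants)
  suspicious <- is.finite(k_meas) & abs(krd - k_meas) > 5
  if (any(suspicious)) {
    warning(sprintf("%d record(s) with |Krd - measured K| > 5 D flagged as suspicious",
                    sum(suspicious)), call. = FALSE)
  }
  data.frame(eye_id = cohort$eye_id,
             k_measured = k_meas,
             k_rd = as.numeric(krd),
             suspicious = suspicious,
             stringsAsFactors = FALSE)
}

#' Predicted refractions and prediction errors for a cohort
#'
#' For each eye, predicts the postoperative spherical equivalent from the
#' implanted IOL power and the chosen corneal power (measured K, optionally
#' corrected through a Krd regression), and pairs it with the achieved
#' refraction. The per-eye prediction error is `achieved - predicted`
#' (positive = hyperopic surprise).
#'
#' @inheritParams cohort_krd
#' @param regression Optional [krd_regression] correction applied to the
#'   measured K before prediction (e.g. [krd_paper_regression()]).
#' @param label Method label attached to the output.
#' @return A data.frame with columns `eye_id`, `method_label`, `k_entered`,
#'   `predicted_se_d`, `actual_se_d`, `pe_d`.
#' @export
cohort_predictions <- function(cohort, constants,
                               k_source = c("tcrp4", "trp4"),
                               regression = NULL,
                               mode = c("direct", "reindex"),
                               label = NULL) {
  k_source <- match.arg(k_source)
  mode <- match.arg(mode)
  k_col <- if (k_source == "tcrp4") "k_tcrp_4mm_d" else "k_trp_4mm_d"
  k <- corneal_power(cohort[[k_col]], mode)
  if (!is.null(regression)) k <- apply_krd(k, regression)
  if (is.null(label)) {
    label <- sprintf("%s 4 mm %s", toupper(sub("4$", "", k_source)),
                     if (is.null(regression)) "K" else "Krd")
  }
  elp <- haigis_elp(cohort$acd_mm, cohort$axial_length_mm, constants)
  predicted <- predict_refraction(k, cohort$implanted_power_d,
                                  cohort$axial_length_mm, elp, constants)
  actual <- spherical_equivalent(cohort$postop_sphere_d, cohort$postop_cylinder_d)
  data.frame(eye_id = cohort$eye_id,
             method_label = label,
             k_entered = k,
             predicted_se_d = predicted,
             actual_se_d = actual,
             pe_d = prediction_error(actual, predicted),
             stringsAsFactors = FALSE)
}
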