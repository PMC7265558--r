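# Domain types, units and validation.
#
# Units are fixed package-wide: millimetres for lengths, diopters for powers
# and refractions. There is no auto-detection of units, only validation with
# actionable errors, because silent unit coercion is the dominant failure mode
# in IOL software.

.AL_RANGE  <- c(15, 40)   # axial length, mm
.ACD_RANGE <- c(1.5, 6)   # anterior chamber depth, mm
.K_RANGE   <- c(25, 60)   # corneal power, D
.IOL_RANGE <- c(-10, 40)  # labelled IOL power, D
.TARGET_MAX <- 10         # |target SE|, D
.SE_MAX     <- 15         # |postoperative SE|, D

.check_range <- function(value, range, field, row = NULL, unit = "") {
  bad <- is.finite(value) & (value < range[1] | value > range[2])
  if (!any(bad)) return(invisible(TRUE))
  v <- value[bad][1]
  hint <- ""
  # a length three orders of magnitude too small almost always means metres
  if (unit == "mm" && v < 1) {
    hint <- " (values this small suggest metres rather than millimetres; check units)"
  }
  where <- if (is.null(row)) "" else sprintf(" at row %d", row[bad][1])
  stop(sprintf("%s = %g outside valid range [%g, %g] %s%s%s",
               field, v, range[1], range[2], unit, where, hint), call. = FALSE)
}

#' Construct a validated eye biometry record
#'
#' One eye's preoperative measurements as used by the Haigis effective lens
#' position model: axial length and anterior chamber depth (corneal epithelium
#' to lens front, the optical biometer convention), plus Scheimpflug corneal
#' powers for the 4.0 mm zone. At least one of the two corneal power maps
#' (total corneal refractive power, TCRP, or total refractive power, TRP)
#' must be supplied.
#'
#' @param eye_id Opaque identifier.
#' @param axial_length Axial length in millimetres (15--40).
#' @param acd Anterior chamber depth in millimetres (1.5--6).
#' @param k_tcrp_4mm TCRP 4.0 mm zone corneal power in diopters (25--60), or `NA`.
#' @param k_trp_4mm TRP 4.0 mm zone corneal power in diopters (25--60), or `NA`.
#' @return An object of class `eye_biometry`.
#' @examples
#' eye_biometry("eye1", axial_length = 28.08, acd = 3.63, k_tcrp_4mm = 39.24)
#' @export
eye_biometry <- function(eye_id, axial_length, acd,
                         k_tcrp_4mm = NA_real_, k_trp_4mm = NA_real_) {
  .check_range(axial_length, .AL_RANGE, "axial_length", unit = "mm")
  .check_range(acd, .ACD_RANGE, "acd", unit = "mm")
  if (is.na(k_tcrp_4mm) && is.na(k_trp_4mm)) {
    stop("at least one of k_tcrp_4mm / k_trp_4mm must be present", call. = FALSE)
  }
  if (!is.na(k_tcrp_4mm)) .check_range(k_tcrp_4mm, .K_RANGE, "k_tcrp_4mm", unit = "D")
  if (!is.na(k_trp_4mm))  .check_range(k_trp_4mm, .K_RANGE, "k_trp_4mm", unit = "D")
  structure(list(eye_id = as.character(eye_id),
                 axial_length = as.numeric(axial_length),
                 acd = as.numeric(acd),
                 k_tcrp_4mm = as.numeric(k_tcrp_4mm),
                 k_trp_4mm = as.numeric(k_trp_4mm)),
            class = "eye_biometry")
}

#' Construct a Haigis IOL constants object
#'
#' The Haigis effective lens position model `d = a0 + a1*ACD + a2*AL` needs a
#' lens-specific triple (a0, a1, a2), conventionally optimised per IOL model
#' (e.g. the ULIB community constants). The optical constants bundled here are
#' the aqueous refractive index used in the vergence algebra and the vertex
#' distance at which manifest refractions are expressed. The a-constants must
#' have been optimised for the same anterior chamber depth convention used by
#' the biometer (epithelium to lens front).
#'
#' @param a0,a1,a2 Dimensionless Haigis constants.
#' @param n_aqueous Refractive index of aqueous/vitreous (default 1.336).
#' @param vertex_distance Spectacle vertex distance in millimetres (default 12).
#' @param label Free-text label, e.g. the lens model.
#' @return An object of class `iol_constants`.
#' @examples
#' iol_constants(a0 = -1.302, a1 = 0.210, a2 = 0.251, label = "ZCB00 (ULIB)")
#' @export
iol_constants <- function(a0, a1, a2, n_aqueous = 1.336,
                          vertex_distance = 12, label = "") {
  stopifnot(is.finite(a0), is.finite(a1), is.finite(a2))
  if (!is.finite(n_aqueous) || n_aqueous <= 1) {
    stop("n_aqueous must be a refractive index > 1", call. = FALSE)
  }
  if (!is.finite(vertex_distance) || vertex_distance < 0 || vertex_distance > 20) {
    stop("vertex_distance must be in [0, 20] mm", call. = FALSE)
  }
  structure(list(a0 = as.numeric(a0), a1 = as.numeric(a1), a2 = as.numeric(a2),
                 n_aqueous = as.numeric(n_aqueous),
                 vertex_distance = as.numeric(vertex_distance),
                 label = as.character(label)),
            class = "iol_constants")
}

#' @export
print.iol_constants <- function(x, ...) {
  cat(sprintf("Haigis IOL constants%s\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  cat(sprintf("  a0 = %g, a1 = %g, a2 = %g\n", x$a0, x$a1, x$a2))
  cat(sprintf("  n_aqueous = %g, vertex distance = %g mm\n",
              x$n_aqueous, x$vertex_distance))
  invisible(x)
}

#' Generic monofocal IOL constants for simulation and examples
#'
#' A plausible monofocal a-triple derived from an ACD constant of 5.20 via the
#' classical untuned coefficients a1 = 0.4, a2 = 0.1
#' (a0 = 5.20 - 0.4*3.37 - 0.1*23.39). Real analyses should supply the
#' optimised constants for the implanted lens; these exist so that the
#' synthetic cohort generator and the examples are self-contained.
#'
#' @inheritParams iol_constants
#' @return An `iol_constants` object.
#' @export
example_iol_constants <- function(n_aqueous = 1.336, vertex_distance = 12) {
  iol_constants(a0 = 1.513, a1 = 0.4, a2 = 0.1,
                n_aqueous = n_aqueous, vertex_distance = vertex_distance,
                label = "generic monofocal (ACD constant 5.20)")
}

#' Manifest refraction and spherical equivalent
#'
#' `refraction()` stores a sphere/cylinder pair; only the spherical equivalent
#' `sphere + cylinder/2` is consumed downstream, so the cylinder sign
#' convention (plus or minus cylinder) is deliberately not interpreted: the
#' spherical equivalent is invariant under cross-cylinder transposition.
#'
#' @param sphere Sphere in diopters.
#' @param cylinder Cylinder in diopters (signed; convention-agnostic).
#' @return `refraction()` returns an object of class `refraction`;
#'   `spherical_equivalent()` returns diopters (vectorised);
#'   `transpose_refraction()` returns the transposed (sphere, cylinder) pair.
#' @examples
#' spherical_equivalent(-1.5, -0.5)                  # -1.75
#' spherical_equivalent(refraction(-1.5, -0.5))
#' transpose_refraction(-1.5, -0.5)                  # (-2.0, +0.5)
#' @export
refraction <- function(sphere, cylinder = 0) {
  stopifnot(is.finite(sphere), is.finite(cylinder))
  structure(list(sphere = as.numeric(sphere), cylinder = as.numeric(cylinder)),
            class = "refraction")
}

#' @rdname refraction
#' @export
spherical_equivalent <- function(sphere, cylinder = 0) {
  if (inherits(sphere, "refraction")) {
    return(sphere$sphere + sphere$cylinder / 2)
  }
  sphere + cylinder / 2
}

#' @rdname refraction
#' @export
transpose_refraction <- function(sphere, cylinder) {
  list(sphere = sphere + cylinder, cylinder = -cylinder)
}

#' Construct a validated cataract surgery outcome record
#'
#' The implanted IOL's labelled power, the spherical-equivalent refraction
#' targeted at surgery, and the manifest refraction observed postoperatively
#' (conventionally at three months).
#'
#' @param implanted_power Labelled IOL power in diopters (-10 to 40).
#' @param target_refraction Targeted postoperative SE in diopters (|x| <= 10).
#' @param postop_sphere,postop_cylinder Postoperative manifest refraction in
#'   diopters; the derived SE must satisfy |SE| <= 15.
#' @return An object of class `surgery_outcome`.
#' @export
surgery_outcome <- function(implanted_power, target_refraction,
                            postop_sphere, postop_cylinder = 0) {
  .check_range(implanted_power, .IOL_RANGE, "implanted_power", unit = "D")
  .check_range(target_refraction, c(-.TARGET_MAX, .TARGET_MAX),
               "target_refraction", unit = "D")
  se <- spherical_equivalent(postop_sphere, postop_cylinder)
  .check_range(se, c(-.SE_MAX, .SE_MAX), "postoperative spherical equivalent",
               unit = "D")
  structure(list(implanted_power = as.numeric(implanted_power),
                 target_refraction = as.numeric(target_refraction),
                 postop_refraction = refraction(postop_sphere, postop_cylinder)),
            class = "surgery_outcome")
}
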