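# CSV cohort input/output and JSON constants configuration.

.COHORT_COLUMNS <- c("eye_id", "axial_length_mm", "acd_mm", "k_tcrp_4mm_d",
                     "k_trp_4mm_d", "implanted_power_d", "target_se_d",
                     "postop_sphere_d", "postop_cylinder_d")

.validate_cohort_row <- function(row, i) {
  # delegate range checks to the record constructors; return NULL when valid
  msg <- tryCatch({
    eye_biometry(row$eye_id, row$axial_length_mm, row$acd_mm,
                 row$k_tcrp_4mm_d, row$k_trp_4mm_d)
    surgery_outcome(row$implanted_power_d, row$target_se_d,
                    row$postop_sphere_d, row$postop_cylinder_d)
    NULL
  }, error = function(e) conditionMessage(e))
  if (is.null(msg)) NULL else data.frame(row = i, message = msg)
}

#' Read and validate a cohort CSV
#'
#' One eye per row with the fixed schema: `eye_id, axial_length_mm, acd_mm,
#' k_tcrp_4mm_d, k_trp_4mm_d, implanted_power_d, target_se_d,
#' postop_sphere_d, postop_cylinder_d`. Lengths are millimetres and powers
#' diopters; no unit auto-detection is performed. Every row is validated
#' through [eye_biometry()] and [surgery_outcome()]; rows that fail are
#' dropped with a warning naming the row, field and value, and the dropped
#' rows are attached as the `"rejected"` attribute.
#'
#' @param path Path to a CSV file with the documented header.
#' @return A data.frame of class `iol_cohort` containing the valid rows, with
#'   attribute `rejected` (a data.frame with columns `row`, `message`).
#' @seealso [write_cohort()], [generate_cohort()]
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.COHORT_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("cohort CSV is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[.COHORT_COLUMNS]
  for (col in setdiff(.COHORT_COLUMNS, "eye_id")) {
    df[[col]] <- as.numeric(df[[col]])   # all-NA columns parse as logical
  }
  df$eye_id <- as.character(df$eye_id)
  rejects <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    .validate_cohort_row(df[i, , drop = FALSE], i)
  }))
  if (is.null(rejects)) {
    rejects <- data.frame(row = integer(), message = character())
  } else {
    warning(sprintf("%d of %d rows rejected during validation (see attr(, 'rejected')); first: %s",
                    nrow(rejects), nrow(df), rejects$message[1]), call. = FALSE)
  }
  keep <- setdiff(seq_len(nrow(df)), rejects$row)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejects
  class(out) <- c("iol_cohort", "data.frame")
  out
}

#' Write a cohort to CSV
#'
#' Inverse of [load_cohort()]: writing then re-reading a valid cohort
#' reproduces it field for field.
#'
#' @param cohort A cohort data.frame with the documented columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  missing <- setdiff(.COHORT_COLUMNS, names(cohort))
  if (length(missing) > 0) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(as.data.frame(cohort)[.COHORT_COLUMNS], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read or write an IOL constants configuration file
#'
#' JSON key-value configuration with keys `a0, a1, a2` (required),
#' `n_aqueous`, `vertex_distance_mm`, `k_mode` (`"direct"` or `"reindex"`,
#' see [corneal_power()]) and `label` (optional). The configuration must state
#' which anterior chamber depth convention its a-constants assume; this
#' package follows the optical-biometer convention (epithelium to lens front).
#'
#' @param path Path to a JSON file.
#' @return `read_iol_constants()` returns a list with elements `constants`
#'   (an [iol_constants] object) and `k_mode`; `write_iol_constants()` returns
#'   `path` invisibly.
#' @export
read_iol_constants <- function(path) {
  if (!file.exists(path)) stop("constants file not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path)
  for (key in c("a0", "a1", "a2")) {
    if (is.null(cfg[[key]])) {
      stop("constants config is missing required key: ", key, call. = FALSE)
    }
  }
  k_mode <- if (is.null(cfg$k_mode)) "direct" else match.arg(cfg$k_mode,
                                                             c("direct", "reindex"))
  list(constants = iol_constants(
         a0 = cfg$a0, a1 = cfg$a1, a2 = cfg$a2,
         n_aqueous = if (is.null(cfg$n_aqueous)) 1.336 else cfg$n_aqueous,
         vertex_distance = if (is.null(cfg$vertex_distance_mm)) 12 else cfg$vertex_distance_mm,
         label = if (is.null(cfg$label)) "" else cfg$label),
       k_mode = k_mode)
}

#' @rdname read_iol_constants
#' @param constants An [iol_constants] object.
#' @param k_mode Keratometric handling mode to record (`"direct"` default).
#' @export
write_iol_constants <- function(constants, path, k_mode = "direct") {
  stopifnot(inherits(constants, "iol_constants"))
  jsonlite::write_json(
    list(a0 = constants$a0, a1 = constants$a1, a2 = constants$a2,
         n_aqueous = constants$n_aqueous,
         vertex_distance_mm = constants$vertex_distance,
         k_mode = k_mode, label = constants$label,
         acd_convention = "corneal epithelium to lens front"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
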