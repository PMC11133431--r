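#' Subject tables
#'
#' A subject table is a plain data.frame with one row per participant:
#' `subject_id`, `bmi` (kg/m^2, or a precomputed standardized score such
#' as a BMI standard-deviation score), optional covariates (`age`, `sex`,
#' `site`, `education`, `ses`, `scan_date`) and one cortical-thickness
#' column (mm) per parcel, named exactly by parcel_id. The `bmi_units`
#' attribute distinguishes raw kg/m^2 (`"kgm2"`) from standardized scores
#' (`"sds"`); the range-based inclusion filter applies only to the former.
#'
#' @param path CSV path with a header row; required columns
#'   `subject_id`, `bmi`.
#' @param bmi_units `"kgm2"` (default) or `"sds"`.
#' @return data.frame with attribute `bmi_units`.
#' @export
read_subject_table <- function(path, bmi_units = c("kgm2", "sds")) {
  bmi_units <- match.arg(bmi_units)
  tab <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "bmi") %in% names(tab))) {
    stop("subject table needs columns subject_id, bmi")
  }
  attr(tab, "bmi_units") <- bmi_units
  tab
}

#' Cohort inclusion filter
#'
#' Removes subjects with outlying body-mass index (below 10 or above
#' 50 kg/m^2). When the `bmi` column holds standardized scores
#' (`bmi_units == "sds"`) the range filter does not apply and the table is
#' returned unchanged with a notice.
#'
#' @param subjects a subject table (see [read_subject_table()]).
#' @return the filtered table; the number of removals is reported via
#'   `message()` and stored in attribute `n_excluded`.
#' @export
apply_inclusion_filters <- function(subjects) {
  units <- attr(subjects, "bmi_units") %||% "kgm2"
  if (identical(units, "sds")) {
    message("bmi column holds standardized scores; range filter skipped")
    attr(subjects, "n_excluded") <- 0L
    return(subjects)
  }
  keep <- subjects$bmi >= 10 & subjects$bmi <= 50 & !is.na(subjects$bmi)
  n_out <- sum(!keep)
  if (all(!keep)) stop("inclusion filter removed every subject (empty cohort)")
  message("inclusion filter: removed ", n_out, " of ", length(keep),
          " subjects with BMI outside [10, 50]")
  out <- subjects[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bmi_units") <- units
  attr(out, "n_excluded") <- n_out
  out
}
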