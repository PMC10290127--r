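#' Default indicator level sets for a colorectal-registry cohort
#'
#' @return named list mapping each indicator column to its allowed levels.
#' @export
default_levels <- function() {
  list(
    age_group = c("18-44", "45-69", "70+"),
    sex = c("Female", "Male"),
    race = c("NH White", "NH Black", "Hispanic", "Other"),
    site = c("Right colon", "Left colon", "Rectum"),
    stage = c("I", "II", "III", "IV")
  )
}

#' Validate a patient-level cohort table
#'
#' Checks indicator values against their declared level sets, follow-up
#' times for non-negativity and event codes against \{0, 1, 2\}. Rows
#' failing any check are dropped and counted; per-row diagnostics name the
#' offending column and value.
#'
#' @param data a data.frame with indicator columns, \code{time_months} and
#'   \code{event} (plus optional \code{patient_id}, \code{subtype},
#'   \code{true_class}).
#' @param levels named list of allowed levels per indicator column; defaults
#'   to the indicator columns found among \code{\link{default_levels}}.
#' @return list with elements \code{cohort} (validated data.frame, indicator
#'   columns as factors with the declared levels), \code{n_rejected}, and
#'   \code{problems} (data.frame of row, column, value).
#' @export
validate_cohort <- function(data, levels = NULL) {
  if (is.null(levels)) {
    levels <- default_levels()
    levels <- levels[intersect(names(levels), names(data))]
    if (length(levels) == 0L)
      stop2("no known indicator columns found; supply `levels`")
  }
  missing_cols <- setdiff(c(names(levels), "time_months", "event"), names(data))
  if (length(missing_cols))
    stop2("cohort is missing columns: ", paste(missing_cols, collapse = ", "))

  bad <- rep(FALSE, nrow(data))
  problems <- list()
  note <- function(rows, col, vals) {
    if (any(rows)) problems[[length(problems) + 1L]] <<- data.frame(
      row = which(rows), column = col, value = as.character(vals[rows]),
      stringsAsFactors = FALSE)
  }
  for (col in names(levels)) {
    v <- as.character(data[[col]])
    ok <- !is.na(v) & v %in% levels[[col]]
    note(!ok, col, v)
    bad <- bad | !ok
  }
  tm <- suppressWarnings(as.numeric(data$time_months))
  ok <- !is.na(tm) & tm >= 0
  note(!ok, "time_months", data$time_months)
  bad <- bad | !ok
  ev <- suppressWarnings(as.integer(data$event))
  ok <- !is.na(ev) & ev %in% 0:2
  note(!ok, "event", data$event)
  bad <- bad | !ok

  out <- data[!bad, , drop = FALSE]
  for (col in names(levels))
    out[[col]] <- factor(as.character(out[[col]]), levels = levels[[col]])
  out$time_months <- as.numeric(out$time_months)
  out$event <- as.integer(out$event)
  if (is.null(out$patient_id))
    out$patient_id <- sprintf("P%06d", seq_len(nrow(out)))
  rownames(out) <- NULL
  list(cohort = out,
       n_rejected = sum(bad),
       problems = if (length(problems)) do.call(rbind, problems) else
         data.frame(row = integer(), column = character(),
                    value = character(), stringsAsFactors = FALSE))
}

#' Read a cohort CSV, validating against a schema of level sets
#'
#' @param path CSV file with a header row.
#' @param levels named list of allowed levels per indicator column (default:
#'   the standard colorectal indicators present in the file).
#' @param max_reject_frac hard-error threshold on the rejected-row fraction.
#' @return validated cohort data.frame; the rejected-row count is reported
#'   via \code{message} and attached as attribute \code{n_rejected}.
#' @export
read_cohort <- function(path, levels = NULL, max_reject_frac = 0.1) {
  if (!file.exists(path)) stop2("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  v <- validate_cohort(raw, levels)
  if (v$n_rejected > 0) {
    message(v$n_rejected, " row(s) rejected during cohort validation")
    if (v$n_rejected > max_reject_frac * nrow(raw))
      stop2(v$n_rejected, " of ", nrow(raw), " rows rejected (> ",
            100 * max_reject_frac, "%); first problem: row ",
            v$problems$row[1], ", column '", v$problems$column[1],
            "', value '", v$problems$value[1], "'")
  }
  structure(v$cohort, n_rejected = v$n_rejected)
}

#' Write a cohort table as CSV
#'
#' @param cohort data.frame as returned by \code{\link{simulate_cohort}} or
#'   \code{\link{read_cohort}}.
#' @param path output file.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
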