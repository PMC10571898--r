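#' Survival cohort objects
#'
#' A cohort is a validated data frame with one row per patient and columns
#' `id` (unique character), `time` (months of follow-up since the start of
#' radiotherapy, positive), `event` (1 = grade >= 2 late fibrosis observed at
#' `time`, 0 = right-censored), `rila` (baseline radiation-induced CD8
#' T-lymphocyte apoptosis, percent in \[0, 100\]), and the binary covariates
#' `tobacco` (active/former smoker = 1 vs never = 0) and `ht` (adjuvant
#' hormonotherapy yes = 1 / no = 0). `tobacco` and `ht` may be `NA`.
#'
#' @param time positive event/censoring times in months.
#' @param event 0/1 event indicators.
#' @param rila baseline marker values in \[0, 100\].
#' @param tobacco,ht binary covariates, `NA` allowed.
#' @param id optional unique identifiers; defaults to `"P1", "P2", ...`.
#' @return An object of class `cohort` (a data frame).
#' @export
cohort <- function(time, event, rila, tobacco = NA, ht = NA, id = NULL) {
  n <- length(time)
  if (is.null(id)) id <- paste0("P", seq_len(n))
  df <- data.frame(id = as.character(id), time = as.numeric(time),
                   event = as.integer(event), rila = as.numeric(rila),
                   tobacco = as.integer(rep_len(tobacco, n)),
                   ht = as.integer(rep_len(ht, n)),
                   stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' @rdname cohort
#' @param x a data frame with the cohort columns.
#' @export
validate_cohort <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("id", "time", "event", "rila", "tobacco", "ht")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  x <- x[, need]
  n <- nrow(x)
  if (n < 2L) stop("a cohort needs at least 2 patients, got ", n)
  if (anyDuplicated(x$id)) {
    stop("duplicate patient id(s): ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  }
  bad_row <- function(ok, what) {
    if (any(!ok)) {
      stop(what, " in row(s): ", paste(which(!ok), collapse = ", "),
           call. = FALSE)
    }
  }
  bad_row(is.finite(x$time), "non-numeric or missing time")
  bad_row(x$time > 0, "time must be > 0")
  bad_row(x$event %in% c(0L, 1L), "event must be 0 or 1")
  bad_row(is.finite(x$rila) & x$rila >= 0 & x$rila <= 100,
          "rila must lie in [0, 100]")
  bad_row(is.na(x$tobacco) | x$tobacco %in% c(0L, 1L),
          "tobacco must be 0, 1 or missing")
  bad_row(is.na(x$ht) | x$ht %in% c(0L, 1L), "ht must be 0, 1 or missing")
  class(x) <- c("cohort", "data.frame")
  x
}

#' Read a cohort from CSV
#'
#' The on-disk format is UTF-8 CSV with header
#' `id,time_months,event,rila,tobacco,ht`, comma separator, decimal point,
#' and empty fields for missing values. Other column names can be mapped via
#' `column_map`.
#'
#' @param path path to a CSV file.
#' @param column_map optional named character vector mapping the canonical
#'   names (`id`, `time_months`, `event`, `rila`, `tobacco`, `ht`) to the
#'   names actually used in the file.
#' @return A validated [cohort] object.
#' @export
load_cohort <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                         colClasses = "character")
  canon <- c(id = "id", time_months = "time_months", event = "event",
             rila = "rila", tobacco = "tobacco", ht = "ht")
  if (!is.null(column_map)) canon[names(column_map)] <- column_map
  miss <- canon[!canon %in% names(raw)]
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  }
  num <- function(col, what) {
    v <- raw[[canon[[col]]]]
    out <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(out)
    if (any(bad)) {
      stop("non-numeric ", what, " in row(s): ",
           paste(which(bad), collapse = ", "))
    }
    out
  }
  validate_cohort(data.frame(
    id = raw[[canon[["id"]]]],
    time = num("time_months", "time"),
    event = as.integer(num("event", "event")),
    rila = num("rila", "rila"),
    tobacco = as.integer(num("tobacco", "tobacco")),
    ht = as.integer(num("ht", "ht")),
    stringsAsFactors = FALSE))
}

#' Write a cohort to CSV
#'
#' Inverse of [load_cohort()]: `load_cohort(write_cohort(x, path))` restores
#' `x` exactly (missing values become empty fields).
#'
#' @param x a [cohort].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  x <- validate_cohort(x)
  out <- data.frame(id = x$id, time_months = x$time, event = x$event,
                    rila = x$rila, tobacco = x$tobacco, ht = x$ht)
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Restrict a cohort to complete cases for a covariate set
#'
#' Composite-marker analyses need `tobacco` and `ht`; patients missing either
#' are excluded and the exclusion count is reported via `message()`.
#'
#' @param x a [cohort].
#' @param covariates covariate columns that must be non-missing.
#' @return The complete-case sub-cohort.
#' @export
complete_cases <- function(x, covariates = c("rila", "tobacco", "ht")) {
  x <- validate_cohort(x)
  keep <- stats::complete.cases(as.data.frame(x)[, covariates, drop = FALSE])
  if (any(!keep)) {
    message(sum(!keep), " of ", nrow(x),
            " patients excluded (missing ", paste(covariates, collapse = "/"),
            "); ", sum(keep), " analysed")
  }
  validate_cohort(as.data.frame(x)[keep, , drop = FALSE])
}

#' Marker series
#'
#' A scalar marker value per patient together with an orientation flag. The
#' convention throughout the package is that *higher marker values mean higher
#' risk*; raw RILA has the opposite direction, so it enters analyses negated
#' ([negate_marker()]) and thresholds are reported back on the original
#' percent scale via the orientation flag.
#'
#' @param values numeric marker values, no missing entries.
#' @param orientation `"raw"` or `"negated"`.
#' @param label marker name used in reports.
#' @return An object of class `marker_series`.
#' @export
marker_series <- function(values, orientation = c("raw", "negated"),
                          label = "marker") {
  orientation <- match.arg(orientation)
  values <- as.numeric(values)
  if (anyNA(values)) {
    stop("marker contains missing values in position(s): ",
         paste(which(is.na(values)), collapse = ", "),
         "; exclude those patients upstream (see complete_cases)")
  }
  structure(list(values = values, orientation = orientation, label = label),
            class = "marker_series")
}

#' Negate a marker so that low raw values mean high risk
#'
#' Multiplies marker values by -1 and toggles the orientation flag, so that a
#' protective marker (such as RILA, where low apoptosis predicts fibrosis) can
#' be analysed under the higher-is-riskier convention. An involution:
#' negating twice restores the original series.
#'
#' @param x a `marker_series` or numeric vector (treated as raw).
#' @param label label for the resulting series.
#' @return A `marker_series` with orientation toggled.
#' @export
negate_marker <- function(x, label = NULL) {
  if (!inherits(x, "marker_series")) x <- marker_series(x, label = label %||% "marker")
  flipped <- if (x$orientation == "raw") "negated" else "raw"
  marker_series(-x$values, orientation = flipped, label = label %||% x$label)
}

#' Report a threshold on the marker's original scale
#'
#' @param threshold threshold on the analysis scale.
#' @param marker the `marker_series` the threshold refers to.
#' @return The threshold back-transformed to the original scale (negated
#'   markers: multiplied by -1).
#' @export
original_scale <- function(threshold, marker) {
  stopifnot(inherits(marker, "marker_series"))
  if (marker$orientation == "negated") -threshold else threshold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
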