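#' Read a cohort from delimited long-format tables
#'
#' Reads the three CSV tables written by [write_long_table()]:
#' a measurements table (\code{subject_id,variable,time,value}), an events
#' table (\code{subject_id,state,entry_time,exit_time,next_state}; blank
#' \code{next_state} = censored) and a baseline table
#' (\code{subject_id,sex,age_at_gada,fdr,dq_group}).
#'
#' Values in the measurements file are raw (original units); the per-variable
#' log(1 + x) transform is applied on read unless \code{transformed = TRUE},
#' in which case values are taken to be on the analysis scale already.
#'
#' @param measurements,events,baseline paths to the three CSV files
#' @param transformed logical; are measurement values already on the
#'   analysis scale?
#' @param validate logical; stop if [validate_cohort()] reports violations
#' @return a [cohort()]
#' @export
read_long_table <- function(measurements, events, baseline,
                            transformed = FALSE, validate = TRUE) {
  read1 <- function(path, cols, what) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = NA, na.strings = c("NA", ""))
    miss <- setdiff(cols, names(d))
    if (length(miss) > 0) {
      stop(sprintf("%s file '%s' is missing column(s): %s", what, path,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    d
  }
  meas <- read1(measurements, c("subject_id", "variable", "time", "value"),
                "measurements")
  ev <- read1(events,
              c("subject_id", "state", "entry_time", "exit_time",
                "next_state"), "events")
  bl <- read1(baseline,
              c("subject_id", "sex", "age_at_gada", "fdr", "dq_group"),
              "baseline")
  meas$subject_id <- as.character(meas$subject_id)
  ev$subject_id <- as.character(ev$subject_id)
  bl$subject_id <- as.character(bl$subject_id)

  check_num <- function(x, col, what) {
    y <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(y))
    if (length(bad) > 0) {
      stop(sprintf("%s: non-numeric %s at row %d ('%s')", what, col, bad[1],
                   x[bad[1]]), call. = FALSE)
    }
    y
  }
  meas$time <- check_num(meas$time, "time", "measurements")
  meas$value <- check_num(meas$value, "value", "measurements")
  ev$entry_time <- check_num(ev$entry_time, "entry_time", "events")
  ev$exit_time <- check_num(ev$exit_time, "exit_time", "events")
  ev$state <- as.integer(ev$state)
  ev$next_state <- suppressWarnings(as.integer(ev$next_state))

  reg <- variable_registry()
  unk <- which(!(meas$variable %in% reg$variable))
  if (length(unk) > 0) {
    stop(sprintf("measurements: unknown variable '%s' at row %d",
                 meas$variable[unk[1]], unk[1]), call. = FALSE)
  }
  dup <- which(duplicated(meas[c("subject_id", "variable", "time")]))
  if (length(dup) > 0) {
    stop(sprintf("measurements: duplicate (subject, variable, time) at row %d",
                 dup[1]), call. = FALSE)
  }
  if (!transformed) meas$value <- apply_transform(meas$value, meas$variable)

  out <- cohort(bl, meas, ev)
  if (validate) {
    rep <- validate_cohort(out)
    if (nrow(rep) > 0) {
      stop("cohort validation failed:\n",
           paste(utils::head(sprintf("  [%s] %s: %s", rep$check,
                                     rep$subject_id, rep$message), 10),
                 collapse = "\n"),
           if (nrow(rep) > 10) sprintf("\n  ... and %d more", nrow(rep) - 10)
           else "",
           call. = FALSE)
    }
  }
  out
}

#' Write a cohort to delimited long-format tables
#'
#' Writes \code{measurements.csv}, \code{events.csv} and \code{baseline.csv}
#' under \code{dir}. Measurement values are back-transformed to raw units
#' unless \code{transformed = TRUE}. Times are written with full precision
#' so that a read/write round trip reproduces every numeric field.
#'
#' @param cohort a [cohort()]
#' @param dir output directory (created if needed)
#' @param transformed logical; write analysis-scale values as-is
#' @return invisibly, a named character vector of the three file paths
#' @export
write_long_table <- function(cohort, dir, transformed = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meas <- cohort$longitudinal
  if (!transformed && nrow(meas) > 0) {
    reg <- variable_registry()
    flag <- reg$transform[match(meas$variable, reg$variable)]
    meas$value[flag] <- inv_log1p_transform(meas$value[flag])
  }
  paths <- c(
    measurements = file.path(dir, "measurements.csv"),
    events = file.path(dir, "events.csv"),
    baseline = file.path(dir, "baseline.csv")
  )
  fmt <- function(d) {
    num <- vapply(d, is.numeric, logical(1)) &
      !vapply(d, is.integer, logical(1))
    d[num] <- lapply(d[num], function(x) formatC(x, digits = 15,
                                                 format = "g"))
    d
  }
  utils::write.csv(fmt(meas[c("subject_id", "variable", "time", "value")]),
                   paths["measurements"], row.names = FALSE, quote = FALSE,
                   na = "")
  utils::write.csv(fmt(cohort$events[c("subject_id", "state", "entry_time",
                                       "exit_time", "next_state")]),
                   paths["events"], row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(fmt(cohort$baseline[c("subject_id", "sex", "age_at_gada",
                                         "fdr", "dq_group")]),
                   paths["baseline"], row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(paths)
}
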