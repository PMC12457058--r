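#' Construct a cohort object
#'
#' A cohort bundles three long-format tables:
#' \describe{
#'   \item{baseline}{one row per subject: \code{subject_id}, \code{sex}
#'     ("male"/"female"), \code{age_at_gada} (years, > 0), \code{fdr} (0/1),
#'     \code{dq_group} ("DQ2/8", "DQ8/X", "DQ2/X").}
#'   \item{longitudinal}{\code{subject_id}, \code{variable}, \code{time}
#'     (years since confirmed GADA positivity), \code{value} (analysis
#'     scale).}
#'   \item{events}{\code{subject_id}, \code{state}, \code{entry_time},
#'     \code{exit_time}, \code{next_state} (NA when the sojourn ends in
#'     censoring).}
#' }
#' All times are measured in decimal years since confirmed GADA positivity;
#' every subject starts in state 1 at time 0.
#'
#' @param baseline,longitudinal,events data.frames as described above
#' @param metadata optional list (provenance, seed, ground-truth parameters)
#' @return an object of class \code{cohort}
#' @export
cohort <- function(baseline, longitudinal, events, metadata = list()) {
  need <- list(
    baseline = c("subject_id", "sex", "age_at_gada", "fdr", "dq_group"),
    longitudinal = c("subject_id", "variable", "time", "value"),
    events = c("subject_id", "state", "entry_time", "exit_time", "next_state")
  )
  tabs <- list(baseline = baseline, longitudinal = longitudinal,
               events = events)
  for (nm in names(tabs)) {
    miss <- setdiff(need[[nm]], names(tabs[[nm]]))
    if (length(miss) > 0) {
      stop(sprintf("%s table is missing column(s): %s", nm,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  if (anyDuplicated(baseline$subject_id)) {
    stop("duplicate subject ids in baseline table", call. = FALSE)
  }
  structure(
    list(baseline = baseline, longitudinal = longitudinal, events = events,
         metadata = metadata),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "GADA-first cohort: %d subjects, %d longitudinal records, %d sojourns\n",
    nrow(x$baseline), nrow(x$longitudinal), nrow(x$events)))
  st <- final_states(x)
  tab <- table(factor(st, levels = 1:4))
  cat("Last observed state:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort a \code{cohort}
#' @return integer
#' @export
n_subjects <- function(cohort) nrow(cohort$baseline)

#' Last observed state per subject
#' @param cohort a \code{cohort}
#' @return named integer vector indexed by subject id
#' @export
final_states <- function(cohort) {
  ev <- cohort$events
  out <- vapply(split(ev, ev$subject_id), function(d) {
    d <- d[order(d$entry_time), , drop = FALSE]
    last <- d[nrow(d), ]
    if (!is.na(last$next_state)) as.integer(last$next_state)
    else as.integer(last$state)
  }, integer(1))
  out[as.character(cohort$baseline$subject_id)]
}

#' Baseline design row (fixed covariates) for modelling
#'
#' Encodes the time-invariant covariates as used in every hazard model:
#' \code{fdr} indicator, \code{age} at confirmed GADA positivity (years),
#' and two HLA indicators \code{dq8x}, \code{dq2x} with DQ2/8 as the
#' reference group. \code{sex} is carried as a male indicator.
#'
#' @param baseline baseline data.frame (rows subset as needed)
#' @return data.frame with columns subject_id, male, fdr, age, dq8x, dq2x
#' @export
baseline_design <- function(baseline) {
  data.frame(
    subject_id = baseline$subject_id,
    male = as.numeric(baseline$sex == "male"),
    fdr = as.numeric(baseline$fdr),
    age = as.numeric(baseline$age_at_gada),
    dq8x = as.numeric(baseline$dq_group == "DQ8/X"),
    dq2x = as.numeric(baseline$dq_group == "DQ2/X"),
    stringsAsFactors = FALSE
  )
}

#' Validate a cohort against the model invariants
#'
#' Checks, per subject: sojourn records are contiguous and non-overlapping,
#' start in state 1 at time 0, successive states follow the allowed
#' transition set, no activity after absorption in state 4; longitudinal
#' record times are non-negative, unique per (subject, variable, time) and
#' do not extend past the end of follow-up; baseline fields are valid.
#'
#' @param cohort a \code{cohort}
#' @return data.frame of violations (\code{subject_id}, \code{check},
#'   \code{message}); zero rows when the cohort is valid
#' @export
validate_cohort <- function(cohort) {
  bad <- list()
  note <- function(id, check, msg) {
    bad[[length(bad) + 1]] <<- data.frame(
      subject_id = as.character(id), check = check, message = msg,
      stringsAsFactors = FALSE)
  }
  bl <- cohort$baseline
  for (i in seq_len(nrow(bl))) {
    if (!bl$sex[i] %in% c("male", "female"))
      note(bl$subject_id[i], "baseline", paste("invalid sex:", bl$sex[i]))
    if (!is.finite(bl$age_at_gada[i]) || bl$age_at_gada[i] <= 0)
      note(bl$subject_id[i], "baseline", "age_at_gada must be finite and > 0")
    if (!bl$dq_group[i] %in% c("DQ2/8", "DQ8/X", "DQ2/X"))
      note(bl$subject_id[i], "baseline",
           paste("invalid dq_group:", bl$dq_group[i]))
    if (!bl$fdr[i] %in% c(0, 1))
      note(bl$subject_id[i], "baseline", "fdr must be 0/1")
  }

  reg <- variable_registry()
  lng <- cohort$longitudinal
  if (nrow(lng) > 0) {
    unk <- !(lng$variable %in% reg$variable)
    for (i in which(unk)) {
      note(lng$subject_id[i], "longitudinal",
           paste("unknown variable:", lng$variable[i]))
    }
    neg <- is.finite(lng$time) & lng$time < 0
    for (i in which(neg)) {
      note(lng$subject_id[i], "longitudinal",
           sprintf("negative observation time %.4g (%s)", lng$time[i],
                   lng$variable[i]))
    }
    dup <- duplicated(lng[c("subject_id", "variable", "time")])
    for (i in which(dup)) {
      note(lng$subject_id[i], "longitudinal",
           sprintf("duplicate record for %s at t=%.6g", lng$variable[i],
                   lng$time[i]))
    }
  }

  ev <- cohort$events
  ids <- bl$subject_id
  ev_by <- split(ev, factor(ev$subject_id, levels = ids))
  lng_by <- if (nrow(lng) > 0) split(lng, factor(lng$subject_id, levels = ids))
            else NULL
  tol <- 1e-8
  for (id in as.character(ids)) {
    d <- ev_by[[id]]
    if (is.null(d) || nrow(d) == 0) {
      note(id, "path", "no state records")
      next
    }
    d <- d[order(d$entry_time), , drop = FALSE]
    if (d$state[1] != 1 || abs(d$entry_time[1]) > tol)
      note(id, "path", "path must start in state 1 at time 0")
    if (any(d$exit_time < d$entry_time - tol))
      note(id, "path", "sojourn with exit_time < entry_time")
    if (nrow(d) > 1) {
      gaps <- abs(d$entry_time[-1] - d$exit_time[-nrow(d)]) > tol
      if (any(gaps)) note(id, "path", "non-contiguous sojourns")
      hop_ok <- d$next_state[-nrow(d)] == d$state[-1]
      if (any(!hop_ok | is.na(hop_ok)))
        note(id, "path", "next_state does not match following sojourn")
    }
    moved <- !is.na(d$next_state)
    if (any(moved)) {
      ok <- is_allowed_transition(d$state[moved], d$next_state[moved])
      for (i in which(!ok)) {
        mi <- which(moved)[i]
        note(id, "path", sprintf("disallowed transition %d->%d",
                                 d$state[mi], d$next_state[mi]))
      }
    }
    if (any(d$state == 4))
      note(id, "path", "sojourn recorded in absorbing state 4")
    # longitudinal activity must not extend beyond end of follow-up
    if (!is.null(lng_by)) {
      l <- lng_by[[id]]
      if (!is.null(l) && nrow(l) > 0) {
        end <- max(d$exit_time)
        late <- l$time > end + tol
        if (any(late))
          note(id, "longitudinal",
               sprintf("%d record(s) after end of follow-up (t=%.4g)",
                       sum(late), end))
      }
    }
  }
  orphans <- setdiff(unique(c(ev$subject_id, lng$subject_id)), ids)
  for (id in orphans) note(id, "baseline", "subject missing from baseline")
  if (length(bad) == 0) {
    data.frame(subject_id = character(0), check = character(0),
               message = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, bad)
  }
}

#' Extract one subject's history up to a landmark time
#'
#' Returns the information set used for dynamic prediction: baseline
#' covariates, longitudinal records observed at or before \code{landmark},
#' and the state path truncated at \code{landmark} (the current sojourn is
#' right-truncated; the subject is known to still be in its current state at
#' the landmark).
#'
#' @param cohort a \code{cohort}
#' @param id subject id
#' @param landmark landmark time s in years since GADA positivity
#'   (default: end of the subject's follow-up)
#' @return an object of class \code{subject_history} with components
#'   \code{id}, \code{baseline} (one-row data.frame), \code{longitudinal},
#'   \code{path}, \code{landmark} and \code{current_state}
#' @export
subject_history <- function(cohort, id, landmark = NULL) {
  bl <- cohort$baseline[cohort$baseline$subject_id == id, , drop = FALSE]
  if (nrow(bl) != 1) stop("unknown subject id: ", id, call. = FALSE)
  lng <- cohort$longitudinal[cohort$longitudinal$subject_id == id, ,
                             drop = FALSE]
  ev <- cohort$events[cohort$events$subject_id == id, , drop = FALSE]
  ev <- ev[order(ev$entry_time), , drop = FALSE]
  if (is.null(landmark)) landmark <- max(ev$exit_time)
  keep <- ev$entry_time < landmark + 1e-12
  ev <- ev[keep, , drop = FALSE]
  cur <- ev[nrow(ev), ]
  if (cur$exit_time > landmark) {
    ev$exit_time[nrow(ev)] <- landmark
    ev$next_state[nrow(ev)] <- NA_integer_
  } else if (!is.na(cur$next_state) && cur$next_state == 4) {
    # absorbed before the landmark; prediction requests must reject this
  }
  current_state <- {
    last <- ev[nrow(ev), ]
    if (!is.na(last$next_state) && last$exit_time <= landmark)
      as.integer(last$next_state)
    else as.integer(last$state)
  }
  structure(
    list(id = id, baseline = bl,
         longitudinal = lng[lng$time <= landmark + 1e-12, , drop = FALSE],
         path = ev, landmark = landmark, current_state = current_state),
    class = "subject_history"
  )
}

#' @export
print.subject_history <- function(x, ...) {
  cat(sprintf(
    "Subject %s: landmark %.3g y, current state %d, %d longitudinal records\n",
    x$id, x$landmark, x$current_state, nrow(x$longitudinal)))
  invisible(x)
}
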