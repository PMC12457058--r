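#' Four-state progression model state space
#'
#' The disease process is described by four states indexed by the integers
#' 1--4: (1) single GADA positive, (2) multiple islet autoantibodies without
#' IA-2A, (3) multiple islet autoantibodies with IA-2A, and (4) type 1
#' diabetes. Six forward transitions are allowed: 1->2, 1->3, 1->4, 2->3,
#' 2->4 and 3->4. State 4 is absorbing and the transition graph is acyclic.
#'
#' @return An object of class \code{state_space} with components
#'   \code{states} (named integer vector), \code{labels},
#'   \code{transitions} (two-column integer matrix of allowed from/to pairs)
#'   and \code{absorbing} (integer vector of absorbing states).
#' @examples
#' ss <- state_space()
#' nrow(ss$transitions)  # 6
#' @export
state_space <- function() {
  labels <- c(
    "single GADA",
    "multiple without IA-2A",
    "multiple with IA-2A",
    "type 1 diabetes"
  )
  transitions <- cbind(
    from = c(1L, 1L, 1L, 2L, 2L, 3L),
    to   = c(2L, 3L, 4L, 3L, 4L, 4L)
  )
  structure(
    list(
      states = stats::setNames(1:4, labels),
      labels = labels,
      transitions = transitions,
      absorbing = 4L
    ),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat("Four-state islet autoantibody progression model\n")
  for (i in seq_along(x$labels)) {
    cat(sprintf("  %d: %s\n", i, x$labels[i]))
  }
  cat("Allowed transitions:",
      paste(sprintf("%d->%d", x$transitions[, 1], x$transitions[, 2]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Transition identifiers
#'
#' Transitions are referred to throughout the package by strings of the form
#' \code{"1->2"}.
#'
#' @param from,to state indices
#' @return character vector of transition ids
#' @export
transition_id <- function(from, to) sprintf("%d->%d", from, to)

#' All allowed transition ids, in canonical order
#' @return character vector of length 6
#' @export
all_transitions <- function() {
  tr <- state_space()$transitions
  transition_id(tr[, 1], tr[, 2])
}

#' Test whether a from/to pair is an allowed transition
#' @param from,to state indices (vectorised)
#' @return logical vector
#' @export
is_allowed_transition <- function(from, to) {
  transition_id(from, to) %in% all_transitions()
}
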