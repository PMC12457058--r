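#' Spline specification for a longitudinal trajectory
#'
#' Metabolic trajectories are smooth and are modelled with natural cubic
#' splines; autoantibody titers show abrupt shifts and are modelled with
#' piecewise linear splines (hinge bases).
#'
#' @param kind "polynomial" (natural cubic), "piecewise_linear", or
#'   "constant" (intercept-only; degenerate basis used for toy models)
#' @param knots interior knot positions (years), strictly increasing and
#'   inside \code{boundary}
#' @param degree polynomial degree (only cubic natural splines are
#'   implemented; retained for the spec surface)
#' @param boundary length-2 numeric, boundary of the basis; evaluation is
#'   linear beyond the boundary
#' @return an object of class \code{spline_spec}
#' @export
spline_spec <- function(kind = c("polynomial", "piecewise_linear",
                                 "constant"),
                        knots = numeric(0), degree = 3,
                        boundary = c(0, 15)) {
  kind <- match.arg(kind)
  knots <- as.numeric(knots)
  if (length(knots) > 0) {
    if (is.unsorted(knots, strictly = TRUE))
      stop("interior knots must be strictly increasing", call. = FALSE)
    if (any(knots <= boundary[1]) || any(knots >= boundary[2]))
      stop("interior knots must lie strictly inside the boundary",
           call. = FALSE)
  }
  structure(list(kind = kind, knots = knots, degree = degree,
                 boundary = as.numeric(boundary)),
            class = "spline_spec")
}

#' Basis dimension of a spline specification (including intercept)
#' @param spec a [spline_spec()]
#' @return integer
#' @export
basis_dim <- function(spec) {
  if (spec$kind == "constant") 1L
  else 2L + length(spec$knots)  # both kinds: intercept + (nknots + 1) df
}

#' Evaluate a spline design matrix
#'
#' Row i is the basis evaluated at \code{times[i]}; the first column is an
#' intercept. For \code{kind = "polynomial"} the remaining columns are a
#' natural cubic spline basis (via \code{splines::ns}) with the given
#' interior and boundary knots, hence linear extrapolation beyond the
#' boundary. For \code{kind = "piecewise_linear"} the columns are
#' \code{t} and hinge terms \code{(t - k)+} for each interior knot.
#'
#' @param times numeric vector of evaluation times
#' @param spec a [spline_spec()]
#' @return numeric matrix, \code{length(times)} rows by [basis_dim()] columns
#' @export
build_basis <- function(times, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  times <- as.numeric(times)
  if (length(times) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = basis_dim(spec)))
  }
  if (spec$kind == "constant") {
    out <- matrix(1, length(times), 1,
                  dimnames = list(NULL, "(Intercept)"))
    return(out)
  }
  if (spec$kind == "piecewise_linear") {
    cols <- list(`(Intercept)` = rep(1, length(times)), t = times)
    for (k in spec$knots) cols[[sprintf("h(%g)", k)]] <- pmax(times - k, 0)
    out <- do.call(cbind, cols)
  } else {
    if (length(spec$knots) > 0) {
      ns <- splines::ns(times, knots = spec$knots,
                        Boundary.knots = spec$boundary)
    } else {
      ns <- splines::ns(times, df = 1, Boundary.knots = spec$boundary)
    }
    out <- cbind(`(Intercept)` = 1, ns)
    colnames(out) <- c("(Intercept)", paste0("ns", seq_len(ncol(ns))))
  }
  rownames(out) <- NULL
  out
}
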