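#' Default longitudinal model specifications
#'
#' One specification per registry variable: natural cubic splines with
#' interior knots at 1.5 and 5 years for the smooth metabolic variables,
#' piecewise linear splines with hinge knots at 1 and 3 years post-GADA for
#' the autoantibody titers (to capture abrupt titer shifts). Random effects
#' are carried on the intercept and the first non-intercept basis column of
#' each variable.
#'
#' @param boundary follow-up window for the bases (years)
#' @return named list of per-variable specs, each a list with elements
#'   \code{variable}, \code{spline} (a [spline_spec()]) and
#'   \code{random_terms} (column indices of the basis carrying random
#'   effects)
#' @export
default_longitudinal_specs <- function(boundary = c(0, 15)) {
  reg <- variable_registry()
  out <- lapply(seq_len(nrow(reg)), function(i) {
    if (reg$kind[i] == "metabolic") {
      sp <- spline_spec("polynomial", knots = c(1.5, 5), boundary = boundary)
    } else {
      sp <- spline_spec("piecewise_linear", knots = c(1, 3),
                        boundary = boundary)
    }
    list(variable = reg$variable[i], spline = sp, random_terms = c(1L, 2L))
  })
  stats::setNames(out, reg$variable)
}

# Target population mean curves on the analysis scale, anchored at the
# Table-1-style baseline medians (log(1+x) scale for all but HbA1c).
.mean_curve_fun <- function(variable) {
  switch(variable,
    fasting_glu = function(t) 4.489 + 0.006 * t,
    glu_2h      = function(t) 4.673 + 0.012 * t,
    fasting_cp  = function(t) 0.683 + 0.040 * t,
    cp_2h       = function(t) 1.562 + 0.030 * t,
    hba1c       = function(t) 5.200 + 0.020 * t,
    gada_z      = function(t) 0.349 + 0.15 * pmin(t, 1) + 0.02 *
                    pmax(pmin(t, 3) - 1, 0) - 0.01 * pmax(t - 3, 0),
    ia2a_z      = function(t) -0.091 + 0.02 * t + 0.03 * pmax(t - 1, 0),
    iaa_z       = function(t) -0.388 + 0.010 * t + 0.01 * pmax(t - 1, 0),
    znt8a_z     = function(t) -0.111 + 0.02 * t + 0.03 * pmax(t - 1, 0) -
                    0.01 * pmax(t - 3, 0),
    stop("no mean curve for variable ", variable)
  )
}

# Project a target mean curve onto a basis (least squares on a dense grid);
# used once at config-building time to express the ground-truth fixed
# effects in the fitting basis.
.project_curve <- function(fun, spec, grid = seq(0, 12, by = 0.05)) {
  X <- build_basis(grid, spec)
  as.numeric(qr.solve(X, fun(grid)))
}

#' Ground-truth longitudinal parameters for the simulator
#'
#' Per-variable fixed-effect vectors (the mean-curve coefficients in the
#' default spline bases), residual SDs, and a shared random-effects
#' covariance over (intercept, slope) pairs. The covariance is block
#' diagonal by variable plus two rank-one cross-variable factors (an
#' "autoimmunity" factor loading on titer intercepts and a "dysglycemia"
#' factor loading on glucose/HbA1c intercepts), so it is positive
#' semidefinite by construction.
#'
#' @param specs output of [default_longitudinal_specs()]
#' @return list with \code{beta} (named list of vectors), \code{sigma}
#'   (named residual SDs), \code{Sigma_b} (2v x 2v matrix, v = number of
#'   variables) and \code{re_index} (data.frame mapping covariance rows to
#'   variable/term)
#' @export
default_truth_longitudinal <- function(specs = default_longitudinal_specs()) {
  vars <- names(specs)
  beta <- lapply(vars, function(v)
    .project_curve(.mean_curve_fun(v), specs[[v]]$spline))
  names(beta) <- vars
  sd_tab <- rbind(
    fasting_glu = c(0.060, 0.015, 0.050),
    glu_2h      = c(0.115, 0.030, 0.100),
    fasting_cp  = c(0.200, 0.040, 0.120),
    cp_2h       = c(0.250, 0.050, 0.200),
    hba1c       = c(0.200, 0.030, 0.150),
    gada_z      = c(0.430, 0.080, 0.200),
    ia2a_z      = c(0.100, 0.100, 0.150),
    iaa_z       = c(0.080, 0.050, 0.100),
    znt8a_z     = c(0.100, 0.080, 0.120)
  )
  colnames(sd_tab) <- c("int", "slope", "resid")
  re_index <- data.frame(
    variable = rep(vars, each = 2),
    term = rep(c("intercept", "slope"), length(vars)),
    stringsAsFactors = FALSE
  )
  q <- nrow(re_index)
  Sigma <- matrix(0, q, q)
  rho_is <- 0.2  # within-variable intercept-slope correlation
  for (i in seq_along(vars)) {
    s <- sd_tab[vars[i], ]
    blk <- matrix(c(s["int"]^2, rho_is * s["int"] * s["slope"],
                    rho_is * s["int"] * s["slope"], s["slope"]^2), 2, 2)
    idx <- (2 * i - 1):(2 * i)
    Sigma[idx, idx] <- blk
  }
  L <- matrix(0, q, 2)
  load1 <- c(gada_z = 0.15, ia2a_z = 0.04, iaa_z = 0.03, znt8a_z = 0.05)
  load2 <- c(fasting_glu = 0.020, glu_2h = 0.050, hba1c = 0.080)
  int_row <- function(v) which(re_index$variable == v &
                               re_index$term == "intercept")
  for (v in names(load1)) L[int_row(v), 1] <- load1[[v]]
  for (v in names(load2)) L[int_row(v), 2] <- load2[[v]]
  Sigma <- Sigma + L %*% t(L)
  rn <- paste(re_index$variable, re_index$term, sep = ".")
  dimnames(Sigma) <- list(rn, rn)
  list(beta = beta,
       sigma = stats::setNames(sd_tab[vars, "resid"], vars),
       Sigma_b = Sigma, re_index = re_index)
}

#' Ground-truth transition model parameters
#'
#' Coefficients are the published point estimates for each
#' transition-specific covariate roster; zeros mark covariates excluded by
#' LASSO in the source analysis and are kept as exact zeros. Covariates of
#' type "longitudinal" refer to the current (latent) analysis-scale value of
#' the named variable; "fixed" covariates are baseline. Each hazard is
#' \deqn{h_k(t) = h0_k(t) \exp(\gamma_k' (w - w_0) + \alpha_k' (m(t) - c))}
#' with centering constants \code{c} (mean analysis-scale values at t = 0,
#' age centered at 5.8 y) absorbed into the baseline so that simulated
#' hazards are on an interpretable scale; centering does not change the
#' coefficients, which is what estimation targets.
#'
#' Baseline hazards are piecewise constant with a single cut at 3 years,
#' with levels chosen so that a simulated cohort has all four states
#' occupied at 10 years (non-degenerate occupancy).
#'
#' @return list with \code{coefficients} (data.frame: transition, covariate,
#'   type, coefficient), \code{baseline} (named list of lists with
#'   \code{cuts} and \code{levels}), \code{centering} (named numeric vector)
#' @export
default_truth_transitions <- function() {
  co <- function(transition, covariate, coefficient) {
    data.frame(transition = transition, covariate = covariate,
               coefficient = coefficient, stringsAsFactors = FALSE)
  }
  coefficients <- rbind(
    co("1->2", c("gada_z", "fdr", "age", "dq8x", "dq2x"),
       c(0.995, 0.126, -0.124, -0.0625, -0.665)),
    co("1->3", c("gada_z", "fdr", "age", "dq8x", "dq2x"),
       c(1.27, 0.306, -0.121, 0, -0.615)),
    co("1->4", c("hba1c", "gada_z", "fdr", "age", "dq8x", "dq2x"),
       c(3.89, 1.48, 0.678, -0.140, 0, 1.08)),
    co("2->3", c("fasting_glu", "glu_2h", "fasting_cp", "cp_2h", "hba1c",
                 "gada_z", "iaa_z", "znt8a_z", "fdr", "age", "dq8x", "dq2x"),
       c(0, 3.48, 0, -1.14, 0, 0.156, 0.616, 1.28, 0.216, 0, 0.0556, -1.22)),
    co("2->4", c("fasting_glu", "glu_2h", "fasting_cp", "cp_2h", "hba1c",
                 "gada_z", "iaa_z", "znt8a_z", "fdr", "age", "dq8x", "dq2x"),
       c(8.66, 1.51, 0, -2.68, 7.14, 0, 0.389, 0.655, -0.678, 0, 0, 0.830)),
    co("3->4", c("fasting_glu", "glu_2h", "fasting_cp", "cp_2h", "hba1c",
                 "gada_z", "ia2a_z", "iaa_z", "znt8a_z", "fdr", "age",
                 "dq8x", "dq2x"),
       c(2.13, 4.71, -0.00169, 0, 2.01, -0.224, 0, 0, -0.260, 1.17,
         -0.0702, 0, 0))
  )
  reg <- variable_registry()
  coefficients$type <- ifelse(coefficients$covariate %in% reg$variable,
                              "longitudinal", "fixed")
  centering <- c(
    fasting_glu = 4.489, glu_2h = 4.673, fasting_cp = 0.683, cp_2h = 1.562,
    hba1c = 5.2, gada_z = 0.349, ia2a_z = -0.091, iaa_z = -0.388,
    znt8a_z = -0.111, age = 5.8, fdr = 0, dq8x = 0, dq2x = 0
  )
  baseline <- list(
    `1->2` = list(cuts = 3, levels = c(0.100, 0.070)),
    `1->3` = list(cuts = 3, levels = c(0.035, 0.030)),
    `1->4` = list(cuts = 3, levels = c(0.006, 0.006)),
    `2->3` = list(cuts = 3, levels = c(0.100, 0.080)),
    `2->4` = list(cuts = 3, levels = c(0.006, 0.008)),
    `3->4` = list(cuts = 3, levels = c(0.050, 0.080))
  )
  list(coefficients = coefficients, baseline = baseline,
       centering = centering)
}

#' Simulation configuration for a TEDDY-like GADA-first cohort
#'
#' Defaults reproduce the study conditions: baseline covariate frequencies
#' (female 45.9\%, FDR 17.4\%, DQ2/8 48.8\%, DQ8/X 29.6\%, DQ2/X 21.6\%),
#' an age-at-GADA distribution anchored at median 5.1 years with IQR
#' (2.4, 9.0), the published transition coefficients as hazard ground
#' truth, quarterly visits with titers at every visit, HbA1c from the first
#' post-seroconversion visit onward, OGTT biannually from age 3 while in a
#' multiple-autoantibody state, and follow-up to age 15.
#'
#' @param n_subjects number of subjects (study size: 379)
#' @param seed master seed; per-subject substreams are derived from it
#' @param covariate_freqs named proportions \code{female}, \code{fdr},
#'   \code{dq2_8}, \code{dq8_x}, \code{dq2_x} (DQ proportions must sum to 1)
#' @param age_anchors quantile anchors (probabilities/values) defining the
#'   age-at-GADA distribution, sampled by inverse-CDF monotone interpolation
#' @param specs longitudinal model specifications
#' @param truth_longitudinal,truth_transitions ground-truth parameter sets
#' @param visit_interval scheduled visit spacing (years)
#' @param ogtt_interval OGTT spacing (years) while eligible
#' @param ogtt_min_age minimum age (years) for OGTT
#' @param visit_jitter_sd half-width (years) of the uniform jitter around
#'   scheduled visits (0 disables; default +/- 2 weeks)
#' @param max_followup_age administrative censoring age (years)
#' @return an object of class \code{sim_config}
#' @export
sim_config <- function(n_subjects = 379, seed = 1,
                       covariate_freqs = c(female = 0.459, fdr = 0.174,
                                           dq2_8 = 0.488, dq8_x = 0.296,
                                           dq2_x = 0.216),
                       age_anchors = list(p = c(0.001, 0.25, 0.5, 0.75,
                                                0.999),
                                          q = c(0.3, 2.4, 5.1, 9.0, 14.5)),
                       specs = default_longitudinal_specs(),
                       truth_longitudinal = default_truth_longitudinal(specs),
                       truth_transitions = default_truth_transitions(),
                       visit_interval = 0.25, ogtt_interval = 0.5,
                       ogtt_min_age = 3, visit_jitter_sd = 2 / 52,
                       max_followup_age = 15) {
  if (n_subjects < 0) stop("n_subjects must be >= 0", call. = FALSE)
  f <- covariate_freqs
  if (any(f < 0 | f > 1)) stop("covariate frequencies must be in [0,1]",
                               call. = FALSE)
  if (abs(sum(f[c("dq2_8", "dq8_x", "dq2_x")]) - 1) > 1e-6)
    stop("DQ group frequencies must sum to 1", call. = FALSE)
  ev <- eigen(truth_longitudinal$Sigma_b, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("random-effects covariance is not positive semidefinite",
         call. = FALSE)
  if (is.unsorted(age_anchors$p, strictly = TRUE) ||
      is.unsorted(age_anchors$q, strictly = TRUE))
    stop("age quantile anchors must be strictly increasing", call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         covariate_freqs = f, age_anchors = age_anchors, specs = specs,
         truth_longitudinal = truth_longitudinal,
         truth_transitions = truth_transitions,
         visit_interval = visit_interval, ogtt_interval = ogtt_interval,
         ogtt_min_age = ogtt_min_age, visit_jitter_sd = visit_jitter_sd,
         max_followup_age = max_followup_age),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic GADA-first cohort config: n=%d, seed=%d, follow-up to age %g\n",
    x$n_subjects, x$seed, x$max_followup_age))
  invisible(x)
}

# Deterministic per-subject substream seed below 2^31 (Knuth-style mixing).
subject_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 48271 + index * 2654435761) %%
               2147483399) + 1L
}

#' Inverse-CDF sampler for the age-at-GADA distribution
#'
#' Monotone (Hyman) spline interpolation of the quantile anchors; draws are
#' uniform probabilities clamped to the anchored range, so sampled ages stay
#' within (0, 15) and the anchored quartiles are reproduced exactly in
#' distribution.
#'
#' @param n number of draws
#' @param anchors list with increasing \code{p} and \code{q}
#' @return numeric vector of ages (years)
#' @export
sample_age_at_gada <- function(n, anchors) {
  qf <- stats::splinefun(anchors$p, anchors$q, method = "hyman")
  p <- stats::runif(n, min = min(anchors$p), max = max(anchors$p))
  qf(p)
}
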