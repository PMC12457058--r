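# Shared fixtures: built in code at test time, memoized per session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# A small simulated cohort under the default study configuration.
default_cohort_small <- function(n = 60, seed = 101) {
  memo(sprintf("default_%d_%d", n, seed),
       simulate_cohort(sim_config(n_subjects = n, seed = seed)))
}

# Hand-built two-subject cohort exercising both event and censoring paths.
tiny_cohort <- function() {
  baseline <- data.frame(
    subject_id = c("A", "B"), sex = c("male", "female"),
    age_at_gada = c(4.2, 7.5), fdr = c(0, 1),
    dq_group = c("DQ2/8", "DQ2/X"), stringsAsFactors = FALSE)
  longitudinal <- data.frame(
    subject_id = c("A", "A", "A", "B", "B"),
    variable = c("gada_z", "gada_z", "hba1c", "gada_z", "iaa_z"),
    time = c(0, 0.5, 1, 0, 0.25),
    value = c(log1p(0.4), log1p(0.9), 5.3, log1p(0.2), log1p(-0.3)),
    stringsAsFactors = FALSE)
  events <- data.frame(
    subject_id = c("A", "A", "B"),
    state = c(1L, 2L, 1L),
    entry_time = c(0, 1.5, 0),
    exit_time = c(1.5, 4, 6),
    next_state = c(2L, NA_integer_, NA_integer_),
    stringsAsFactors = FALSE)
  cohort(baseline, longitudinal, events)
}

# 1-D toy joint model: one variable, random intercept only; used for the
# likelihood cross-method checks and posterior sampling tests.
toy_joint_1d <- function(alpha = 0.8, h0 = 0.1, tau2 = 0.25,
                         sigma = 0.2) {
  sp <- spline_spec("piecewise_linear", knots = numeric(0),
                    boundary = c(0, 15))
  specs <- list(gada_z = longitudinal_spec("gada_z", sp,
                                           random_terms = 1L))
  longfit <- structure(list(
    beta = list(gada_z = c(0.3, 0.05)),
    beta_se = list(gada_z = c(NA, NA)),
    sigma = c(gada_z = sigma),
    Sigma_b = matrix(tau2, 1, 1,
                     dimnames = list("gada_z.intercept",
                                     "gada_z.intercept")),
    re_index = data.frame(variable = "gada_z", term = "intercept",
                          stringsAsFactors = FALSE),
    specs = specs, loglik = NA_real_, converged = TRUE,
    method = "manual"), class = "longitudinal_fit")
  msmodel <- transition_model(
    coefficients = data.frame(
      transition = "1->2", covariate = "gada_z", type = "longitudinal",
      coefficient = alpha, stringsAsFactors = FALSE),
    baseline = list(`1->2` = list(cuts = numeric(0), levels = h0)))
  list(longfit = longfit, msmodel = msmodel)
}

toy_subject <- function(event_time = 4.2, event = TRUE,
                        rec_times = c(0.5, 1.5, 2.5),
                        rec_values = c(0.6, 0.7, 0.9)) {
  list(
    events = data.frame(
      subject_id = "a", state = 1L, entry_time = 0,
      exit_time = event_time,
      next_state = if (event) 2L else NA_integer_,
      stringsAsFactors = FALSE),
    w = c(fdr = 0, age = 5, dq8x = 0, dq2x = 0),
    records = if (length(rec_times) > 0) data.frame(
      subject_id = "a", variable = "gada_z", time = rec_times,
      value = rec_values, stringsAsFactors = FALSE) else
        data.frame(subject_id = character(0), variable = character(0),
                   time = numeric(0), value = numeric(0)))
}

# Reduced two-variable study configuration: much faster to simulate and
# fit than the nine-variable default, used for joint-model experiments.
reduced_config <- function(n = 150, seed = 1, alpha_gada = 0.9,
                           alpha_hba1c = 2.0, sd_int_gada = 0.45,
                           sd_int_hba1c = 0.25, visit_interval = 0.25) {
  specs <- list(
    gada_z = longitudinal_spec(
      "gada_z", spline_spec("piecewise_linear", knots = c(1, 3),
                            boundary = c(0, 15))),
    hba1c = longitudinal_spec(
      "hba1c", spline_spec("polynomial", knots = c(1.5, 5),
                           boundary = c(0, 15))))
  grid <- seq(0, 12, by = 0.1)
  Xh <- build_basis(grid, specs$hba1c$spline)
  beta_h <- as.numeric(qr.solve(Xh, 5.2 + 0.02 * grid))
  tl <- list(
    beta = list(gada_z = c(0.349, 0.15, -0.13, -0.03), hba1c = beta_h),
    sigma = c(gada_z = 0.2, hba1c = 0.15),
    Sigma_b = diag(c(sd_int_gada, 0.08, sd_int_hba1c, 0.03)^2),
    re_index = data.frame(
      variable = rep(c("gada_z", "hba1c"), each = 2),
      term = rep(c("intercept", "slope"), 2), stringsAsFactors = FALSE))
  rn <- paste(tl$re_index$variable, tl$re_index$term, sep = ".")
  dimnames(tl$Sigma_b) <- list(rn, rn)
  coefs <- rbind(
    data.frame(transition = "1->2",
               covariate = c("gada_z", "age"),
               coefficient = c(alpha_gada, -0.12)),
    data.frame(transition = "1->3",
               covariate = c("gada_z"), coefficient = alpha_gada),
    data.frame(transition = "1->4",
               covariate = c("hba1c", "fdr"),
               coefficient = c(alpha_hba1c, 0.5)),
    data.frame(transition = "2->3",
               covariate = c("gada_z"), coefficient = 0.3),
    data.frame(transition = "2->4",
               covariate = c("hba1c"), coefficient = alpha_hba1c),
    data.frame(transition = "3->4",
               covariate = c("hba1c", "fdr"),
               coefficient = c(alpha_hba1c, 0.8)))
  coefs$type <- ifelse(coefs$covariate %in% c("gada_z", "hba1c"),
                       "longitudinal", "fixed")
  tt <- list(
    coefficients = coefs,
    baseline = list(
      `1->2` = list(cuts = 3, levels = c(0.10, 0.07)),
      `1->3` = list(cuts = 3, levels = c(0.035, 0.03)),
      `1->4` = list(cuts = 3, levels = c(0.006, 0.006)),
      `2->3` = list(cuts = 3, levels = c(0.10, 0.08)),
      `2->4` = list(cuts = 3, levels = c(0.01, 0.012)),
      `3->4` = list(cuts = 3, levels = c(0.05, 0.08))),
    centering = c(gada_z = 0.349, hba1c = 5.2, age = 5.8, fdr = 0,
                  dq8x = 0, dq2x = 0))
  sim_config(n_subjects = n, seed = seed, specs = specs,
             truth_longitudinal = tl, truth_transitions = tt,
             visit_interval = visit_interval)
}

# A covariate path with constant longitudinal values (default 0).
flat_path <- function(values = NULL, w = c(fdr = 0, age = 5.8, dq8x = 0,
                                           dq2x = 0)) {
  vars <- variable_registry()$variable
  if (is.null(values)) values <- stats::setNames(rep(0, length(vars)),
                                                 vars)
  covariate_path(w = w, m = function(times) {
    matrix(rep(values, each = length(times)), nrow = length(times),
           dimnames = list(NULL, names(values)))
  })
}
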