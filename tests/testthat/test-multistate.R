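test_that("hazard composes baseline and proportional terms", {
  model <- transition_model(
    coefficients = data.frame(
      transition = "1->2", covariate = "gada_z", type = "longitudinal",
      coefficient = 0.995, stringsAsFactors = FALSE),
    baseline = list(`1->2` = list(cuts = 3, levels = c(0.2, 0.1))))
  p0 <- flat_path(values = c(gada_z = 0))
  p1 <- flat_path(values = c(gada_z = 1))
  # all coefficients zero on the reference path: hazard = h0
  expect_equal(hazard(model, p0, "1->2", 1), 0.2)
  # beyond the last cut point the last level extends
  expect_equal(hazard(model, p0, "1->2", 10), 0.1)
  # a unit increase in log GADA-z multiplies the hazard by exp(0.995)
  expect_equal(hazard(model, p1, "1->2", 1) /
                 hazard(model, p0, "1->2", 1), exp(0.995))
  expect_error(hazard(model, p0, "2->1", 1), "not an allowed transition")
  expect_error(transition_model(
    data.frame(transition = "2->1", covariate = "x", type = "fixed",
               coefficient = 1), list()), "disallowed")
  expect_error(transition_model(
    model$coefficients,
    list(`1->2` = list(cuts = 3, levels = c(-0.1, 0.2)))), ">= 0")
})

test_that("multistate log-likelihood matches closed forms and quadrature", {
  # empty cohort
  empty <- simulate_cohort(sim_config(0, seed = 1))
  model <- constant_hazard_model(c("1->2" = 0.3))
  expect_equal(multistate_log_likelihood(model, empty, list()), 0)
  # one subject, constant hazard, event at T: log(lambda) - lambda T
  bl <- data.frame(subject_id = "A", sex = "male", age_at_gada = 5,
                   fdr = 0, dq_group = "DQ2/8", stringsAsFactors = FALSE)
  lng <- data.frame(subject_id = character(0), variable = character(0),
                    time = numeric(0), value = numeric(0))
  ev <- data.frame(subject_id = "A", state = 1L, entry_time = 0,
                   exit_time = 4.5, next_state = 2L,
                   stringsAsFactors = FALSE)
  ch <- cohort(bl, lng, ev)
  paths <- list(A = flat_path())
  expect_equal(multistate_log_likelihood(model, ch, paths),
               log(0.3) - 0.3 * 4.5, tolerance = 1e-10)
  # random instance with a time-varying covariate vs trapezoid quadrature
  set.seed(12)
  model2 <- transition_model(
    coefficients = data.frame(
      transition = c("1->2", "1->4"),
      covariate = c("gada_z", "hba1c"),
      type = "longitudinal", coefficient = c(0.8, 0.5),
      stringsAsFactors = FALSE),
    baseline = list(`1->2` = list(cuts = 2, levels = c(0.25, 0.12)),
                    `1->4` = list(cuts = numeric(0), levels = 0.05)))
  mfun <- function(times) {
    cbind(gada_z = 0.3 + 0.25 * sin(times),
          hba1c = 5 + 0.1 * times - 0.05 * cos(2 * times))
  }
  path2 <- covariate_path(w = c(fdr = 0, age = 5, dq8x = 0, dq2x = 0),
                          m = mfun)
  ev2 <- data.frame(subject_id = "A", state = 1L, entry_time = 0,
                    exit_time = 3.7, next_state = 2L,
                    stringsAsFactors = FALSE)
  ch2 <- cohort(bl, lng, ev2)
  ll <- multistate_log_likelihood(model2, ch2, list(A = path2),
                                  subgrid = 1e-3)
  # oracle: fine trapezoid integral of each intensity, integrating each
  # constant-baseline segment separately (discontinuity at the cut)
  trap_seg <- function(lo, hi, lev, coef, col) {
    u <- seq(lo, hi, by = 1e-4)
    if (u[length(u)] < hi) u <- c(u, hi)
    h <- lev * exp(coef * mfun(u)[, col])
    sum((h[-1] + h[-length(h)]) / 2 * diff(u))
  }
  oracle <- log(0.12 * exp(0.8 * mfun(3.7)[, "gada_z"])) -
    trap_seg(0, 2, 0.25, 0.8, "gada_z") -
    trap_seg(2, 3.7, 0.12, 0.8, "gada_z") -
    trap_seg(0, 3.7, 0.05, 0.5, "hba1c")
  expect_equal(ll, unname(oracle), tolerance = 1e-5)
})

test_that("lambda = 0 fit matches the closed-form exponential MLE", {
  # one binary covariate, constant hazards: coefficient = log rate ratio
  set.seed(33)
  n <- 400
  grp <- rep(0:1, each = n / 2)
  rate <- ifelse(grp == 1, 0.5, 0.2)
  tt <- rexp(n, rate)
  cens <- pmin(tt, 8)
  d <- as.numeric(tt <= 8)
  bl <- data.frame(subject_id = sprintf("S%03d", 1:n), sex = "male",
                   age_at_gada = 5, fdr = grp, dq_group = "DQ2/8",
                   stringsAsFactors = FALSE)
  ev <- data.frame(subject_id = bl$subject_id, state = 1L, entry_time = 0,
                   exit_time = cens,
                   next_state = ifelse(d == 1, 2L, NA_integer_),
                   stringsAsFactors = FALSE)
  lng <- data.frame(subject_id = character(0), variable = character(0),
                    time = numeric(0), value = numeric(0))
  ch <- cohort(bl, lng, ev)
  paths <- lapply(seq_len(n), function(i)
    flat_path(w = c(fdr = grp[i], age = 5, dq8x = 0, dq2x = 0)))
  names(paths) <- bl$subject_id
  roster <- data.frame(transition = "1->2", covariate = "fdr",
                       type = "fixed", stringsAsFactors = FALSE)
  fit <- fit_multistate(ch, paths, lambda = 0, roster = roster,
                        cuts = list(`1->2` = numeric(0)))
  # closed form: log((d1/E1) / (d0/E0))
  E <- tapply(cens, grp, sum); D <- tapply(d, grp, sum)
  expect_equal(unname(fit$coefficients$coefficient),
               unname(log((D[2] / E[2]) / (D[1] / E[1]))),
               tolerance = 1e-6)
  # and the baseline level equals the reference-group rate at the
  # centered covariate (centering shifts it by the group mix)
  inf <- fit$inference
  expect_true(all(inf$selected))
  expect_gt(inf$std_err, 0)
  expect_lt(inf$p_value, 0.01)
})

test_that("heavy penalty shrinks every coefficient to exactly zero", {
  ch <- memo("ms_cohort", {
    cfg <- reduced_config(n = 150, seed = 71)
    simulate_cohort(cfg, observations = FALSE)
  })
  paths <- memo("ms_paths", latent_paths(ch))
  roster <- data.frame(
    transition = rep("1->2", 3),
    covariate = c("gada_z", "age", "fdr"),
    type = c("longitudinal", "fixed", "fixed"), stringsAsFactors = FALSE)
  fit_big <- fit_multistate(ch, paths, lambda = 10, roster = roster)
  expect_true(all(fit_big$coefficients$coefficient == 0))
  expect_true(all(!fit_big$inference$selected))
  # zeroed covariates still get a post-selection SE, p left missing
  expect_true(all(is.finite(fit_big$inference$std_err)))
  expect_true(all(is.na(fit_big$inference$p_value)))
  # unpenalized fit keeps the strong truth signal
  fit0 <- fit_multistate(ch, paths, lambda = 0, roster = roster)
  expect_gt(fit0$coefficients$coefficient[
    fit0$coefficients$covariate == "gada_z"], 0.4)
})

test_that("the number of selected coefficients is monotone in lambda", {
  ch <- memo("ms_cohort", {
    cfg <- reduced_config(n = 150, seed = 71)
    simulate_cohort(cfg, observations = FALSE)
  })
  paths <- memo("ms_paths", latent_paths(ch))
  roster <- data.frame(
    transition = rep("1->2", 4),
    covariate = c("gada_z", "age", "fdr", "dq2x"),
    type = c("longitudinal", "fixed", "fixed", "fixed"),
    stringsAsFactors = FALSE)
  nnz <- vapply(c(0.0005, 0.002, 0.01, 0.05, 0.5), function(l) {
    f <- fit_multistate(ch, paths, lambda = l, roster = roster)
    sum(f$coefficients$coefficient != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("cross-validation is deterministic and respects the grid", {
  ch <- memo("ms_cohort", {
    cfg <- reduced_config(n = 150, seed = 71)
    simulate_cohort(cfg, observations = FALSE)
  })
  paths <- memo("ms_paths", latent_paths(ch))
  roster <- data.frame(
    transition = rep("1->2", 3),
    covariate = c("gada_z", "age", "fdr"),
    type = c("longitudinal", "fixed", "fixed"), stringsAsFactors = FALSE)
  cv1 <- cv_select_lambda(ch, paths, grid = 0.01, folds = 3, seed = 9,
                          roster = roster)
  expect_equal(unname(cv1$lambda["1->2"]), 0.01)
  cv2 <- cv_select_lambda(ch, paths, folds = 3, seed = 9,
                          roster = roster)
  cv3 <- cv_select_lambda(ch, paths, folds = 3, seed = 9,
                          roster = roster)
  expect_identical(cv2$lambda, cv3$lambda)
  expect_identical(cv2$folds, cv3$folds)
  expect_error(cv_select_lambda(ch, paths, folds = 1, roster = roster),
               "folds")
  expect_error(cv_select_lambda(ch, paths, grid = c(-1, 1), folds = 3,
                                roster = roster), "positive")
})

test_that("transition probabilities obey identity and closed forms", {
  model <- constant_hazard_model(c("1->2" = 0.3, "1->3" = 0.1,
                                   "1->4" = 0.05))
  path <- flat_path()
  expect_equal(transition_probability_matrix(model, path, 2, 2), diag(4))
  zero <- constant_hazard_model(c("1->2" = 0, "1->3" = 0, "1->4" = 0))
  expect_equal(transition_probability_matrix(zero, path, 0, 5), diag(4))
  expect_error(transition_probability_matrix(model, path, 0, 1,
                                             step = -0.1), "positive")
  # competing-risks closed form with absorbing 2 and 3
  for (tt in c(1, 4, 9)) {
    P <- transition_probability_matrix(model, path, 0, tt, step = 1e-3)
    expect_lt(abs(P[1, 1] - exp(-0.45 * tt)), 1e-4)
    expect_lt(abs(P[1, 2] - (0.3 / 0.45) * (1 - exp(-0.45 * tt))), 1e-4)
    expect_lt(abs(P[1, 4] - (0.05 / 0.45) * (1 - exp(-0.45 * tt))), 1e-4)
  }
})

test_that("Chapman-Kolmogorov, DAG zeros and absorption monotonicity", {
  ch <- memo("ms_cohort", {
    cfg <- reduced_config(n = 150, seed = 71)
    simulate_cohort(cfg, observations = FALSE)
  })
  truth <- ch$metadata$truth
  model <- transition_model(truth$coefficients, truth$baseline,
                            centering = truth$centering)
  path <- latent_paths(ch)[[5]]
  step <- 1 / 120
  P_su <- transition_probability_matrix(model, path, 0.5, 6, step)
  P_st <- transition_probability_matrix(model, path, 0.5, 3, step)
  P_tu <- transition_probability_matrix(model, path, 3, 6, step)
  expect_lt(max(abs(P_su - P_st %*% P_tu)), 10 * step)
  # unreachable entries are exactly zero
  expect_equal(P_su[2, 1], 0)
  expect_equal(P_su[3, 1], 0)
  expect_equal(P_su[3, 2], 0)
  expect_equal(P_su[4, 1:3], rep(0, 3))
  expect_equal(P_su[4, 4], 1)
  # rows sum to one
  expect_lt(max(abs(rowSums(P_su) - 1)), 1e-8)
  # absorption probability is non-decreasing in t
  p4 <- vapply(seq(1, 9, by = 1), function(tt)
    transition_probability_matrix(model, path, 0.5, tt, 1 / 60)[1, 4],
    numeric(1))
  expect_true(all(diff(p4) >= -1e-10))
})
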