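# helpers local to the joint-model tests ------------------------------

toy_fit <- function(toy) {
  structure(list(longitudinal = toy$longfit, multistate = toy$msmodel,
                 association = "current-value"),
            class = "joint_model_fit")
}

toy_history <- function(landmark = 5, state = 1L, records = NULL) {
  structure(list(
    id = "a",
    baseline = data.frame(subject_id = "a", sex = "male",
                          age_at_gada = 5, fdr = 0, dq_group = "DQ2/8",
                          stringsAsFactors = FALSE),
    longitudinal = if (is.null(records))
      data.frame(subject_id = character(0), variable = character(0),
                 time = numeric(0), value = numeric(0)) else records,
    path = data.frame(subject_id = "a", state = state, entry_time = 0,
                      exit_time = landmark, next_state = NA_integer_,
                      stringsAsFactors = FALSE),
    landmark = landmark, current_state = state),
    class = "subject_history")
}

# last-observation-carried-forward covariate paths from observed records
locf_paths <- function(cohort, variables) {
  bd <- baseline_design(cohort$baseline)
  lng <- cohort$longitudinal
  out <- lapply(seq_len(nrow(bd)), function(i) {
    id <- bd$subject_id[i]
    rec <- lng[lng$subject_id == id, , drop = FALSE]
    funs <- lapply(variables, function(v) {
      rv <- rec[rec$variable == v, , drop = FALSE]
      rv <- rv[order(rv$time), , drop = FALSE]
      if (nrow(rv) == 0) function(times) rep(0, length(times))
      else function(times) {
        idx <- pmax(findInterval(times, rv$time), 1)
        rv$value[idx]
      }
    })
    names(funs) <- variables
    covariate_path(
      w = c(fdr = bd$fdr[i], age = bd$age[i], dq8x = bd$dq8x[i],
            dq2x = bd$dq2x[i]),
      m = function(times) {
        out <- vapply(variables, function(v) funs[[v]](times),
                      numeric(length(times)))
        if (length(times) == 1)
          out <- matrix(out, nrow = 1,
                        dimnames = list(NULL, variables))
        out
      })
  })
  stats::setNames(out, bd$subject_id)
}

# ---------------------------------------------------------------------

test_that("degenerate prior reduces the joint likelihood to a sum", {
  toy <- toy_joint_1d()
  toy$longfit$Sigma_b <- matrix(0, 1, 1,
                                dimnames = dimnames(toy$longfit$Sigma_b))
  subj <- toy_subject()
  ll <- joint_log_likelihood(toy$longfit, toy$msmodel, subj,
                             method = "laplace")
  # longitudinal density at b = 0
  mu <- 0.3 + 0.05 * subj$records$time
  ll_y <- sum(stats::dnorm(subj$records$value, mu, 0.2, log = TRUE))
  # multistate likelihood on the population-mean path
  bl <- data.frame(subject_id = "a", sex = "male", age_at_gada = 5,
                   fdr = 0, dq_group = "DQ2/8", stringsAsFactors = FALSE)
  ch <- cohort(bl, subj$records, subj$events)
  mpath <- covariate_path(subj$w, function(times)
    cbind(gada_z = 0.3 + 0.05 * times))
  ll_ms <- multistate_log_likelihood(toy$msmodel, ch, list(a = mpath),
                                     subgrid = 0.05)
  expect_equal(ll, ll_y + ll_ms, tolerance = 1e-4)
})

test_that("Laplace, Gauss-Hermite and Monte Carlo agree on a 1-D toy", {
  toy <- toy_joint_1d()
  subj <- toy_subject()
  la <- joint_log_likelihood(toy$longfit, toy$msmodel, subj, "laplace")
  gh <- joint_log_likelihood(toy$longfit, toy$msmodel, subj, "ghq",
                             nodes = 30)
  mc <- joint_log_likelihood(toy$longfit, toy$msmodel, subj, "mc",
                             n_draws = 2e5, seed = 2)
  expect_lt(abs(la - gh), 1e-2)
  expect_lt(abs(la - mc), 1e-2)
  expect_lt(abs(gh - mc), 1e-2)
})

test_that("the likelihood is maximized near the generating variance", {
  toy <- toy_joint_1d(tau2 = 0.25)
  set.seed(61)
  total <- c(truth = 0, inflated = 0, deflated = 0)
  for (i in 1:20) {
    b <- rnorm(1, 0, 0.5)
    times <- seq(0.5, 4.5, by = 1)
    recs <- data.frame(subject_id = "a", variable = "gada_z",
                       time = times,
                       value = 0.3 + 0.05 * times + b +
                         rnorm(length(times), 0, 0.2),
                       stringsAsFactors = FALSE)
    path <- covariate_path(c(fdr = 0, age = 5, dq8x = 0, dq2x = 0),
                           function(tt) cbind(gada_z = 0.3 + 0.05 * tt +
                                                b))
    set.seed(1000 + i)
    ev <- simulate_transitions(path, toy$msmodel, followup_end = 6)
    subj <- list(events = ev, w = path$w, records = recs)
    for (nm in names(total)) {
      lf <- toy$longfit
      lf$Sigma_b <- lf$Sigma_b *
        switch(nm, truth = 1, inflated = 4, deflated = 1 / 4)
      total[nm] <- total[nm] +
        joint_log_likelihood(lf, toy$msmodel, subj, "laplace")
    }
  }
  expect_gt(total["truth"], total["inflated"])
  expect_gt(total["truth"], total["deflated"])
})

test_that("zero association makes joint and two-stage fits agree", {
  cfg <- reduced_config(n = 120, seed = 301, alpha_gada = 0,
                        alpha_hba1c = 0, visit_interval = 0.5)
  ch <- simulate_cohort(cfg)
  roster <- cfg$truth_transitions$coefficients[
    c("transition", "covariate", "type")]
  jf <- fit_joint(ch, cfg$specs, roster = roster, refine_iter = 2)
  co_joint <- jf$multistate$coefficients
  co_two <- jf$two_stage$coefficients
  m <- merge(co_joint, co_two, by = c("transition", "covariate"))
  expect_lt(max(abs(m$coefficient.x - m$coefficient.y)), 0.05)
  # refit on the same data/seed gives identical estimates
  jf2 <- fit_joint(ch, cfg$specs, roster = roster, refine_iter = 2)
  expect_identical(jf$multistate$coefficients$coefficient,
                   jf2$multistate$coefficients$coefficient)
})

test_that("joint fit attenuates less than a naive LOCF fit", {
  higher <- 0
  est_joint <- c(); est_locf <- c()
  nrep <- 5
  for (r in seq_len(nrep)) {
    cfg <- reduced_config(n = 150, seed = 400 + r, visit_interval = 0.5)
    ch <- simulate_cohort(cfg)
    roster <- cfg$truth_transitions$coefficients[
      c("transition", "covariate", "type")]
    jf <- fit_joint(ch, cfg$specs, roster = roster, refine_iter = 1)
    lp <- locf_paths(ch, names(cfg$specs))
    naive <- fit_multistate(ch, lp, lambda = 0, roster = roster)
    pick <- function(fit) {
      co <- fit$coefficients
      co$coefficient[co$transition == "1->2" & co$covariate == "gada_z"]
    }
    est_joint <- c(est_joint, pick(jf$multistate))
    est_locf <- c(est_locf, pick(naive))
    if (pick(jf$multistate) > pick(naive)) higher <- higher + 1
  }
  a_true <- 0.9
  # measurement error attenuates the LOCF estimate toward zero; the
  # joint estimate sits above it in (almost) every replicate and its
  # replicate-averaged bias is smaller
  expect_gte(higher, nrep - 1)
  expect_lt(abs(mean(est_joint) - a_true), abs(mean(est_locf) - a_true))
})

test_that("posterior sampler matches the Gaussian posterior when
           hazards vanish", {
  toy <- toy_joint_1d(h0 = 0)
  recs <- data.frame(subject_id = "a", variable = "gada_z",
                     time = c(1, 2, 3), value = c(0.8, 0.9, 1.0),
                     stringsAsFactors = FALSE)
  h <- toy_history(landmark = 5, records = recs)
  fit <- toy_fit(toy)
  ps <- sample_posterior_random_effects(fit, h, n_draws = 5000, seed = 3)
  expect_equal(ps$ess, 5000, tolerance = 1e-6)
  pp <- posterior_random_effects(toy$longfit, recs)
  ks <- suppressWarnings(stats::ks.test(
    ps$draws[, 1], "pnorm", mean = pp$mean[1], sd = sqrt(pp$cov[1, 1])))
  expect_gt(ks$p.value, 0.01)
})

test_that("with no records and no hazards the sampler draws the prior", {
  toy <- toy_joint_1d(h0 = 0)
  h <- toy_history(landmark = 5)
  ps <- sample_posterior_random_effects(toy_fit(toy), h, n_draws = 5000,
                                        seed = 4)
  expect_lt(abs(mean(ps$draws[, 1])), 3 * sqrt(0.25 / 5000))
  expect_lt(abs(sd(ps$draws[, 1]) - 0.5), 0.02)
})

test_that("surviving a high hazard shifts the posterior downward", {
  # positive association: high-b subjects transition fast, so staying in
  # state 1 for 5 years argues for a lower b than the proposal mean
  toy <- toy_joint_1d(alpha = 1.5, h0 = 0.6)
  h <- toy_history(landmark = 5)
  ps <- sample_posterior_random_effects(toy_fit(toy), h, n_draws = 4000,
                                        seed = 5)
  post_mean <- sum(ps$draws[, 1] * ps$weights)
  expect_lt(post_mean, -0.05)
})

test_that("trajectory prediction collapses to data and to the prior", {
  toy <- toy_joint_1d(h0 = 0, sigma = 0.01)
  # dense nearly noiseless history: band width ~ 0 at observed times
  times <- seq(0.25, 4.75, by = 0.25)
  b_true <- 0.4
  recs <- data.frame(subject_id = "a", variable = "gada_z", time = times,
                     value = 0.3 + 0.05 * times + b_true,
                     stringsAsFactors = FALSE)
  h <- toy_history(landmark = 5, records = recs)
  pt <- predict_trajectory(toy_fit(toy), h, horizon = 3, n_draws = 400,
                           seed = 6, grid_step = 0.25)
  at_obs <- pt[pt$time %in% c(1, 3), ]
  expect_lt(max(at_obs$upper - at_obs$lower), 0.05)
  expect_true(all(pt$mean >= pt$lower & pt$mean <= pt$upper))
  expect_lt(max(abs(at_obs$mean - (0.3 + 0.05 * at_obs$time + b_true))),
            0.02)
  # no records: population mean curve with the prior band
  toy2 <- toy_joint_1d(h0 = 0)
  h0 <- toy_history(landmark = 2)
  pt0 <- predict_trajectory(toy_fit(toy2), h0, horizon = 3,
                            n_draws = 2000, seed = 7, grid_step = 1)
  expect_lt(max(abs(pt0$mean - (0.3 + 0.05 * pt0$time))), 0.05)
  # prior band approximately +/- 1.96 * tau
  expect_equal(mean(pt0$upper - pt0$lower), 2 * 1.96 * 0.5,
               tolerance = 0.1)
})

test_that("occupancy prediction reduces to known special cases", {
  toy <- toy_joint_1d(h0 = 0)
  h <- toy_history(landmark = 2)
  fit <- toy_fit(toy)
  # all hazards zero: occupancy constant and equal to the indicator
  dp <- predict_occupancy(fit, h, grid = c(2, 4, 6), n_draws = 50,
                          seed = 8)
  expect_equal(dp$occupancy$p_state1, rep(1, 3))
  expect_equal(dp$occupancy$p_state4, rep(0, 3))
  # u = s: indicator of the current state even with positive hazards
  toy2 <- toy_joint_1d(h0 = 0.2, alpha = 0)
  dp2 <- predict_occupancy(toy_fit(toy2), h, grid = 2, n_draws = 20,
                           seed = 9)
  expect_equal(as.numeric(dp2$occupancy[1, paste0("p_state", 1:4)]),
               c(1, 0, 0, 0))
  # zero association and no fixed covariates: equals the product-integral
  # row of the population path exactly (no draw dependence)
  dp3 <- predict_occupancy(toy_fit(toy2), h, grid = c(2, 5, 8),
                           n_draws = 10, seed = 10)
  mpath <- covariate_path(c(fdr = 0, age = 5, dq8x = 0, dq2x = 0),
                          function(tt) cbind(gada_z = 0.3 + 0.05 * tt))
  P <- transition_probability_matrix(toy2$msmodel, mpath, 2, 8,
                                     step = 1 / 120)
  expect_equal(dp3$occupancy$p_state2[3], P[1, 2], tolerance = 1e-6)
  expect_equal(max(dp3$occupancy$mc_se2), 0)
  # rows sum to one; absorption monotone
  expect_lt(max(abs(rowSums(
    dp3$occupancy[paste0("p_state", 1:4)]) - 1)), 1e-6)
  expect_error(predict_occupancy(fit, toy_history(state = 4L), grid = 5),
               "absorbed")
})

test_that("updating with no new data leaves the prediction unchanged", {
  toy <- toy_joint_1d(h0 = 0.15, alpha = 0.6)
  recs <- data.frame(subject_id = "a", variable = "gada_z",
                     time = c(0.5, 1.5), value = c(0.7, 0.8),
                     stringsAsFactors = FALSE)
  h <- toy_history(landmark = 3, records = recs)
  grid <- c(3, 5, 7)
  dp1 <- predict_occupancy(toy_fit(toy), h, grid, n_draws = 300,
                           seed = 11)
  dp2 <- update_prediction(toy_fit(toy), h, new_records = NULL,
                           new_state_info = NULL, grid = grid,
                           n_draws = 300, seed = 11)
  expect_equal(dp2$occupancy, dp1$occupancy, tolerance = 1e-12)
})

test_that("observed progression to a higher-risk state raises the
           predicted diabetes risk at every horizon", {
  # analogue of the worked dynamic-prediction scenario: the subject is
  # seen to move into the multiple-with-IA-2A state between landmarks
  cfg <- reduced_config(n = 100, seed = 501, visit_interval = 0.5)
  ch <- simulate_cohort(cfg)
  roster <- cfg$truth_transitions$coefficients[
    c("transition", "covariate", "type")]
  jf <- fit_joint(ch, cfg$specs, roster = roster, refine_iter = 0)
  id <- ch$baseline$subject_id[which(final_states(ch) != 4)[1]]
  h3 <- subject_history(ch, id, landmark = 3)
  # force a state-1 history at the first landmark for a clean contrast
  h3$path <- data.frame(subject_id = id, state = 1L, entry_time = 0,
                        exit_time = 3, next_state = NA_integer_,
                        stringsAsFactors = FALSE)
  h3$current_state <- 1L
  grid <- seq(6, 10, by = 1)
  dp_a <- predict_occupancy(jf, h3, grid, n_draws = 200, seed = 12)
  new_path <- data.frame(subject_id = id, state = c(1L, 3L),
                         entry_time = c(0, 3.5),
                         exit_time = c(3.5, 5),
                         next_state = c(3L, NA_integer_),
                         stringsAsFactors = FALSE)
  dp_b <- update_prediction(jf, h3, new_state_info = new_path,
                            grid = grid, landmark = 5, n_draws = 200,
                            seed = 12)
  expect_equal(dp_b$current_state, 3L)
  expect_true(all(dp_b$occupancy$p_state4 > dp_a$occupancy$p_state4))
})
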