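#' Build covariate paths from a longitudinal fit
#'
#' The current-value association: each subject's hazard covariate path is
#' the model-implied (noise-free) trajectory m_ij(t) under given random
#' effects (default: the posterior mean given that subject's records).
#'
#' @param longfit a \code{longitudinal_fit}
#' @param cohort a [cohort()]
#' @param b_list optional named list of random-effect vectors per subject
#' @return named list of [covariate_path()] objects
#' @export
fitted_paths <- function(longfit, cohort, b_list = NULL) {
  bd <- baseline_design(cohort$baseline)
  lng <- cohort$longitudinal
  vars <- names(longfit$specs)
  out <- lapply(seq_len(nrow(bd)), function(i) {
    id <- bd$subject_id[i]
    b <- if (!is.null(b_list)) b_list[[id]] else
      posterior_random_effects(
        longfit, lng[lng$subject_id == id, , drop = FALSE])$mean
    covariate_path(
      w = c(fdr = bd$fdr[i], age = bd$age[i], dq8x = bd$dq8x[i],
            dq2x = bd$dq2x[i]),
      m = local({
        b_ <- b
        function(times) {
          out <- vapply(vars, function(v)
            fitted_value(longfit, v, times, b = b_),
            numeric(length(times)))
          if (length(times) == 1)
            out <- matrix(out, nrow = 1, dimnames = list(NULL, vars))
          out
        }
      })
    )
  })
  stats::setNames(out, bd$subject_id)
}

# Precompute, for one subject, everything needed to evaluate the joint
# density terms as functions of the random-effect vector b:
# Gaussian residual part (records) and the multistate path part (pieces
# with b-free linear predictor, h0 level, exposure, and the q-vector
# mapping b into the transition's linear predictor).
build_joint_terms <- function(longfit, msmodel, events, w, records,
                              subgrid = 0.1) {
  q <- nrow(longfit$re_index)
  bi <- beta_index_of(longfit$specs)
  # Gaussian part
  if (!is.null(records) && nrow(records) > 0) {
    st <- stack_subject(records, longfit$specs, longfit$re_index, bi)
    beta_vec <- unlist(longfit$beta[names(longfit$specs)])
    r <- st$y - as.numeric(st$X %*% beta_vec)
    s2 <- longfit$sigma[st$var_of]^2
    gauss <- list(r = r, Z = st$Z, s2 = s2,
                  ZtRZ = crossprod(st$Z / sqrt(s2)),
                  ZtRr = crossprod(st$Z, r / s2),
                  const = -0.5 * (length(r) * log(2 * pi) + sum(log(s2))))
  } else {
    gauss <- list(r = numeric(0), Z = matrix(0, 0, q), s2 = numeric(0),
                  ZtRZ = matrix(0, q, q), ZtRr = matrix(0, q, 1),
                  const = 0)
  }
  # path part
  ss <- state_space()
  cen <- function(nm) {
    v <- msmodel$centering[nm]
    ifelse(is.na(v), 0, v)
  }
  gvec_at <- function(co_long, times) {
    # q x length(times): d(linear predictor)/db at each time
    G <- matrix(0, length(times), q)
    for (i in seq_len(nrow(co_long))) {
      v <- co_long$covariate[i]
      spec <- longfit$specs[[v]]
      X <- build_basis(times, spec$spline)
      cols <- which(longfit$re_index$variable == v)
      G[, cols] <- G[, cols] +
        co_long$coefficient[i] * X[, spec$random_terms, drop = FALSE]
    }
    G
  }
  lpfix_at <- function(co, times) {
    lp <- numeric(length(times))
    fx <- co[co$type == "fixed", , drop = FALSE]
    if (nrow(fx) > 0)
      lp <- lp + sum(fx$coefficient * (w[fx$covariate] - cen(fx$covariate)))
    lg <- co[co$type == "longitudinal", , drop = FALSE]
    for (i in seq_len(nrow(lg))) {
      v <- lg$covariate[i]
      mu <- fitted_value(longfit, v, times)  # population mean part
      lp <- lp + lg$coefficient[i] * (mu - cen(v))
    }
    lp
  }
  pieces <- list(); evs <- list()
  for (i in seq_len(nrow(events))) {
    qst <- events$state[i]
    ks <- transition_id(qst, ss$transitions[ss$transitions[, 1] == qst, 2])
    ks <- intersect(ks, names(msmodel$baseline))
    for (k in ks) {
      co <- msmodel$coefficients[msmodel$coefficients$transition == k, ,
                                 drop = FALSE]
      co_long <- co[co$type == "longitudinal", , drop = FALSE]
      if (events$exit_time[i] > events$entry_time[i]) {
        pc <- split_sojourn(events$entry_time[i], events$exit_time[i],
                            msmodel$baseline[[k]]$cuts, subgrid)
        pieces[[length(pieces) + 1]] <- list(
          dt = pc$end - pc$start,
          h0 = h0_eval(msmodel$baseline[[k]], pc$mid),
          lpfix = lpfix_at(co, pc$mid),
          G = gvec_at(co_long, pc$mid))
      }
      if (!is.na(events$next_state[i]) &&
          transition_id(qst, events$next_state[i]) == k) {
        tt <- events$exit_time[i]
        evs[[length(evs) + 1]] <- list(
          logh0 = log(h0_eval(msmodel$baseline[[k]], tt)),
          lpfix = lpfix_at(co, tt),
          g = as.numeric(gvec_at(co_long, tt)))
      }
    }
  }
  dt <- unlist(lapply(pieces, `[[`, "dt"))
  h0 <- unlist(lapply(pieces, `[[`, "h0"))
  lpfix <- unlist(lapply(pieces, `[[`, "lpfix"))
  G <- if (length(pieces) > 0) do.call(rbind, lapply(pieces, `[[`, "G"))
       else matrix(0, 0, q)
  list(gauss = gauss, dt = dt, h0 = h0, lpfix = lpfix, G = G, events = evs,
       q = q)
}

# Log density pieces as functions of b, with analytic gradient/Hessian.
joint_terms_eval <- function(tm, b, Sinv, logdetS) {
  q <- tm$q
  # prior
  lp_prior <- -0.5 * (q * log(2 * pi) + logdetS +
                        as.numeric(t(b) %*% Sinv %*% b))
  g_prior <- -as.numeric(Sinv %*% b)
  # Gaussian records
  rb <- tm$gauss$r - as.numeric(tm$gauss$Z %*% b)
  lp_y <- tm$gauss$const - 0.5 * sum(rb^2 / tm$gauss$s2)
  g_y <- as.numeric(tm$gauss$ZtRr) - as.numeric(tm$gauss$ZtRZ %*% b)
  # path
  if (length(tm$dt) > 0) {
    eta <- pmin(tm$lpfix + as.numeric(tm$G %*% b), 30)
    lam <- tm$dt * tm$h0 * exp(eta)
    lp_path <- -sum(lam)
    g_path <- -as.numeric(crossprod(tm$G, lam))
    H_path <- -crossprod(tm$G * sqrt(lam))
  } else {
    lam <- numeric(0)
    lp_path <- 0; g_path <- numeric(q); H_path <- matrix(0, q, q)
  }
  for (e in tm$events) {
    lp_path <- lp_path + e$logh0 + e$lpfix + sum(e$g * b)
    g_path <- g_path + e$g
  }
  H <- -(Sinv + tm$gauss$ZtRZ) + H_path
  list(logf = lp_prior + lp_y + lp_path,
       grad = g_prior + g_y + g_path, hess = H)
}

# Newton mode finding for the joint posterior of b.
joint_mode <- function(tm, Sinv, logdetS, b0 = NULL, max_iter = 50,
                       tol = 1e-8) {
  q <- tm$q
  b <- if (is.null(b0)) rep(0, q) else b0
  ev <- joint_terms_eval(tm, b, Sinv, logdetS)
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(ev$hess, -ev$grad),
                     error = function(e) -ev$grad * 0.01)
    sz <- 1
    repeat {
      bn <- b + sz * step
      evn <- joint_terms_eval(tm, bn, Sinv, logdetS)
      if (is.finite(evn$logf) && evn$logf >= ev$logf - 1e-12) break
      sz <- sz / 2
      if (sz < 1e-8) { bn <- b; evn <- ev; break }
    }
    done <- is.finite(evn$logf) && is.finite(ev$logf) &&
      abs(evn$logf - ev$logf) < tol
    b <- bn; ev <- evn
    if (done) break
  }
  list(b = b, eval = ev)
}

prior_inverse <- function(Sigma) {
  q <- nrow(Sigma)
  S <- Sigma + diag(1e-10, q)
  list(Sinv = solve(S),
       logdetS = as.numeric(determinant(S, logarithm = TRUE)$modulus))
}

#' Joint log-likelihood of one subject
#'
#' Marginal likelihood of a subject's longitudinal records and multistate
#' path, integrating the shared random effects out of
#' p(y | b) p(path | b) p(b). Three integration methods are provided:
#' Laplace approximation (default; analytic gradient/Hessian, Newton mode
#' finding), adaptive Gauss-Hermite quadrature (small random-effect
#' dimension), and plain Monte Carlo over the prior with antithetic draws
#' (reference implementation for validation).
#'
#' @param longfit a \code{longitudinal_fit} (supplies beta, sigma, Sigma_b)
#' @param msmodel a [transition_model()]
#' @param subject list with \code{events} (sojourn table), \code{w} (named
#'   fixed covariates) and \code{records} (longitudinal data.frame)
#' @param method "laplace", "ghq" or "mc"
#' @param nodes Gauss-Hermite nodes per dimension (ghq)
#' @param n_draws Monte Carlo draws (mc); antithetic pairs are used
#' @param subgrid integration sub-grid for the path part (years)
#' @param seed seed for the mc method
#' @return scalar log-likelihood
#' @export
joint_log_likelihood <- function(longfit, msmodel, subject,
                                 method = c("laplace", "ghq", "mc"),
                                 nodes = 30, n_draws = 1e5, subgrid = 0.05,
                                 seed = 1) {
  method <- match.arg(method)
  tm <- build_joint_terms(longfit, msmodel, subject$events, subject$w,
                          subject$records, subgrid = subgrid)
  pri <- prior_inverse(longfit$Sigma_b)
  q <- tm$q
  if (method == "laplace") {
    md <- joint_mode(tm, pri$Sinv, pri$logdetS)
    H <- md$eval$hess
    ld <- determinant(-H, logarithm = TRUE)$modulus
    if (!is.finite(md$eval$logf))
      stop("non-finite integrand at the posterior mode", call. = FALSE)
    return(md$eval$logf + 0.5 * q * log(2 * pi) - 0.5 * as.numeric(ld))
  }
  if (method == "ghq") {
    if (q > 3)
      stop("Gauss-Hermite quadrature supported for q <= 3 only",
           call. = FALSE)
    md <- joint_mode(tm, pri$Sinv, pri$logdetS)
    Hc <- chol(solve(-md$eval$hess))
    gh <- pracma::gaussHermite(nodes)
    grids <- replicate(q, seq_along(gh$x), simplify = FALSE)
    idx <- as.matrix(expand.grid(grids))
    vals <- apply(idx, 1, function(ix) {
      zz <- gh$x[ix]
      b <- md$b + sqrt(2) * as.numeric(t(Hc) %*% zz)
      lw <- sum(log(gh$w[ix]))
      ev <- joint_terms_eval(tm, b, pri$Sinv, pri$logdetS)
      lw + ev$logf + sum(zz^2)
    })
    mx <- max(vals)
    return(mx + log(sum(exp(vals - mx))) +
             0.5 * q * log(2) + as.numeric(
               determinant(t(Hc), logarithm = TRUE)$modulus))
  }
  # mc: average exp(log p(y|b) + log p(path|b)) over prior draws
  set.seed(seed)
  half <- ceiling(n_draws / 2)
  ev <- eigen(longfit$Sigma_b, symmetric = TRUE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), q)
  vals <- numeric(2 * half)
  chunk <- 20000L
  done <- 0L
  while (done < half) {
    nn <- min(chunk, half - done)
    Zd <- matrix(stats::rnorm(nn * q), q, nn)
    B <- cbind(rt %*% Zd, -rt %*% Zd)  # antithetic
    lps <- joint_loglik_no_prior_vec(tm, B)
    vals[2 * done + seq_len(2 * nn)] <- lps
    done <- done + nn
  }
  mx <- max(vals)
  mx + log(mean(exp(vals - mx)))
}

# Vectorized log p(y|b) + log p(path|b) over columns of B.
joint_loglik_no_prior_vec <- function(tm, B) {
  nd <- ncol(B)
  out <- numeric(nd)
  if (length(tm$gauss$r) > 0) {
    RB <- tm$gauss$Z %*% B                     # n x nd
    rb <- tm$gauss$r - RB
    out <- tm$gauss$const - 0.5 * colSums(rb^2 / tm$gauss$s2)
  }
  if (length(tm$dt) > 0) {
    eta <- pmin(tm$lpfix + tm$G %*% B, 30)     # npieces x nd
    out <- out - colSums(tm$dt * tm$h0 * exp(eta))
  }
  for (e in tm$events) {
    out <- out + e$logh0 + e$lpfix + as.numeric(crossprod(e$g, B))
  }
  out
}

#' Fit the joint longitudinal-multistate model
#'
#' Two-stage initialization followed by joint refinement:
#' \enumerate{
#'   \item ML fit of the spline mixed-effects models ([fit_mixed()]);
#'   \item multistate fit on the covariate paths implied by the
#'     longitudinal-only posterior means of the random effects;
#'   \item iterative refinement: posterior modes of each subject's random
#'     effects are recomputed under the current hazard model (so survival
#'     information feeds back into the trajectories), the multistate
#'     submodel is refitted on the updated paths, and the summed Laplace
#'     joint log-likelihood is tracked until it stabilizes.
#' }
#' Stage-wise and refined hazard estimates are both recorded.
#'
#' @param cohort a [cohort()]
#' @param specs longitudinal specifications (default package defaults)
#' @param lambda LASSO penalty for the multistate stage (default 0)
#' @param roster candidate covariate rosters (see [fit_multistate()])
#' @param structure random-effects covariance structure for [fit_mixed()]
#' @param refine_iter maximum refinement iterations (0 = pure two-stage)
#' @param subgrid risk-table sub-grid (years)
#' @param tol convergence tolerance on the joint log-likelihood
#' @return an object of class \code{joint_model_fit} with components
#'   \code{longitudinal}, \code{multistate}, \code{two_stage} (the stage-2
#'   hazard model), \code{association} ("current-value"), \code{loglik}
#'   (joint Laplace log-likelihood trace) and \code{b_modes}
#' @export
fit_joint <- function(cohort, specs = NULL, lambda = 0, roster = NULL,
                      structure = "blockdiag", refine_iter = 3,
                      subgrid = 0.1, tol = 1e-3) {
  longfit <- fit_mixed(cohort, specs, structure = structure)
  paths <- fitted_paths(longfit, cohort)
  msfit <- fit_multistate(cohort, paths, lambda = lambda, roster = roster,
                          subgrid = subgrid)
  two_stage <- msfit
  pri <- prior_inverse(longfit$Sigma_b)
  ids <- cohort$baseline$subject_id
  bd <- baseline_design(cohort$baseline)
  lng <- cohort$longitudinal
  ev <- cohort$events
  b_modes <- NULL
  trace <- numeric(0)
  iterates <- list()
  for (it in seq_len(max(refine_iter, 0) + 1)) {
    # posterior modes + joint loglik under the current hazard model
    ll <- 0
    b_modes <- stats::setNames(vector("list", length(ids)), ids)
    for (i in seq_along(ids)) {
      id <- ids[i]
      tm <- build_joint_terms(
        longfit, msfit, ev[ev$subject_id == id, , drop = FALSE],
        c(fdr = bd$fdr[i], age = bd$age[i], dq8x = bd$dq8x[i],
          dq2x = bd$dq2x[i]),
        lng[lng$subject_id == id, , drop = FALSE], subgrid = subgrid)
      md <- joint_mode(tm, pri$Sinv, pri$logdetS)
      b_modes[[id]] <- stats::setNames(md$b, rownames(longfit$Sigma_b))
      ld <- determinant(-md$eval$hess, logarithm = TRUE)$modulus
      ll <- ll + md$eval$logf + 0.5 * tm$q * log(2 * pi) -
        0.5 * as.numeric(ld)
    }
    trace <- c(trace, ll)
    iterates[[it]] <- list(msfit = msfit, b_modes = b_modes)
    if (it > max(refine_iter, 0)) break
    if (length(trace) > 1 &&
        abs(trace[length(trace)] - trace[length(trace) - 1]) < tol) break
    if (refine_iter > 0) {
      paths <- fitted_paths(longfit, cohort, b_list = b_modes)
      msfit <- fit_multistate(cohort, paths, lambda = lambda,
                              roster = roster, subgrid = subgrid)
    } else break
  }
  # keep the iterate with the highest joint log-likelihood; refinement is
  # not guaranteed monotone when a refit is unstable
  best <- which.max(trace)
  converged <- best == length(trace) ||
    abs(trace[length(trace)] - trace[best]) < tol
  out <- list(longitudinal = longfit,
              multistate = iterates[[best]]$msfit,
              two_stage = two_stage, association = "current-value",
              loglik = trace, best_iteration = best,
              converged = converged,
              b_modes = iterates[[best]]$b_modes, subgrid = subgrid)
  class(out) <- "joint_model_fit"
  out
}

#' @export
print.joint_model_fit <- function(x, ...) {
  cat(sprintf(
    "Joint longitudinal-multistate fit: %d variables, %d transitions,\n",
    length(x$longitudinal$beta), length(x$multistate$baseline)))
  cat(sprintf("  association = %s, joint logLik = %.2f (%d refinements)\n",
              x$association, x$loglik[length(x$loglik)],
              length(x$loglik) - 1))
  invisible(x)
}

history_w <- function(history) {
  bd <- baseline_design(history$baseline)
  c(fdr = bd$fdr[1], age = bd$age[1], dq8x = bd$dq8x[1], dq2x = bd$dq2x[1])
}

#' Sample the posterior of a subject's random effects given its history
#'
#' Importance sampling with the closed-form Gaussian longitudinal-only
#' posterior as proposal; weights carry the multistate history likelihood
#' (observed transitions plus survival in the current state up to the
#' landmark), so draws target p(b | records, path up to s). When all
#' hazards are zero the weights are constant and the draws follow the
#' Gaussian posterior exactly.
#'
#' @param fit a \code{joint_model_fit}
#' @param history a [subject_history()]
#' @param n_draws number of draws
#' @param seed seed
#' @param subgrid integration sub-grid (years)
#' @return list with \code{draws} (n_draws x q), \code{weights}
#'   (normalized), \code{ess} (effective sample size)
#' @export
sample_posterior_random_effects <- function(fit, history, n_draws = 500,
                                            seed = 1, subgrid = 0.05) {
  longfit <- fit$longitudinal
  post <- posterior_random_effects(longfit, history$longitudinal)
  q <- length(post$mean)
  set.seed(seed)
  ev <- eigen(post$cov, symmetric = TRUE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), q)
  Z <- matrix(stats::rnorm(n_draws * q), q, n_draws)
  draws <- t(post$mean + rt %*% Z)
  tm <- build_joint_terms(longfit, fit$multistate, history$path,
                          history_w(history), records = NULL,
                          subgrid = subgrid)
  logw <- joint_loglik_no_prior_vec(tm, t(draws))
  logw <- logw - max(logw)
  w <- exp(logw)
  w <- w / sum(w)
  ess <- 1 / sum(w^2)
  if (ess < 0.05 * n_draws)
    warning(sprintf(
      "importance-sampling ESS is %.1f (%.1f%% of draws); consider more draws",
      ess, 100 * ess / n_draws), call. = FALSE)
  colnames(draws) <- rownames(longfit$Sigma_b)
  list(draws = draws, weights = w, ess = ess)
}

weighted_quantile <- function(x, w, p) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][pmax(findInterval(p, cw) + 1, 1)]
}

#' Predict a subject's longitudinal trajectories from its history
#'
#' Pointwise posterior mean and 95\% band of the noise-free trajectories
#' m_ij(u) over posterior draws of the random effects.
#'
#' @param fit a \code{joint_model_fit}
#' @param history a [subject_history()]
#' @param horizon prediction horizon beyond the landmark (years)
#' @param n_draws posterior draws
#' @param seed seed
#' @param grid_step spacing of the output grid (years)
#' @param variables variables to predict (default all fitted)
#' @return data.frame with variable, time, mean, lower, upper
#' @export
predict_trajectory <- function(fit, history, horizon, n_draws = 500,
                               seed = 1, grid_step = 0.25,
                               variables = names(fit$longitudinal$beta)) {
  if (horizon <= 0) stop("horizon must be positive", call. = FALSE)
  ps <- sample_posterior_random_effects(fit, history, n_draws, seed)
  grid <- seq(0, history$landmark + horizon, by = grid_step)
  longfit <- fit$longitudinal
  out <- list()
  for (v in variables) {
    vals <- vapply(seq_len(nrow(ps$draws)), function(i)
      fitted_value(longfit, v, grid, b = ps$draws[i, ]),
      numeric(length(grid)))
    mean_v <- as.numeric(vals %*% ps$weights)
    lo <- apply(vals, 1, weighted_quantile, w = ps$weights, p = 0.025)
    hi <- apply(vals, 1, weighted_quantile, w = ps$weights, p = 0.975)
    out[[v]] <- data.frame(variable = v, time = grid, mean = mean_v,
                           lower = pmin(lo, mean_v),
                           upper = pmax(hi, mean_v),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Dynamic prediction of state-occupation probabilities
#'
#' For each posterior draw of the random effects the subject's covariate
#' path is reconstructed and the product-integral transition probability
#' matrix is propagated from the unit mass at the current state q(s);
#' occupancies are the importance-weighted average over draws. Conditioning
#' on the history (including survival in q(s) up to s) enters through the
#' posterior weighting of [sample_posterior_random_effects()].
#'
#' @param fit a \code{joint_model_fit}
#' @param history a [subject_history()] with current state != 4
#' @param grid output times (years post-GADA), all >= the landmark
#' @param n_draws posterior draws
#' @param seed seed
#' @param step product-integral step (years; default 1/120)
#' @return an object of class \code{dynamic_prediction}: data.frame
#'   \code{occupancy} (u, p_state1..4, mc_se1..4), plus \code{landmark},
#'   \code{current_state}, \code{n_draws}, \code{ess}, \code{seed}
#' @export
predict_occupancy <- function(fit, history, grid, n_draws = 500, seed = 1,
                              step = 1 / 120) {
  if (history$current_state == 4)
    stop("subject already absorbed in state 4 at the landmark",
         call. = FALSE)
  s <- history$landmark
  if (any(grid < s - 1e-9))
    stop("prediction grid must not precede the landmark", call. = FALSE)
  grid <- sort(unique(pmax(grid, s)))
  ps <- sample_posterior_random_effects(fit, history, n_draws, seed)
  longfit <- fit$longitudinal
  vars <- names(longfit$specs)
  w0 <- history_w(history)
  msm <- fit$multistate
  # shared discretization: step midpoints over [s, max(grid)], cut at grid
  tmax <- max(grid)
  br <- sort(unique(c(seq(s, tmax, by = step), tmax, grid)))
  if (length(br) < 2) br <- c(s, tmax)
  mids <- (br[-length(br)] + br[-1]) / 2
  du <- diff(br)
  ks <- intersect(all_transitions(), names(msm$baseline))
  from <- as.integer(sub("->.*", "", ks))
  to <- as.integer(sub(".*->", "", ks))
  cen <- function(nm) {
    v <- msm$centering[nm]
    ifelse(is.na(v), 0, v)
  }
  # b-free parts: population mean values, fixed-covariate terms, h0 levels,
  # and the per-transition q-vector mapping b into the linear predictor
  mu <- vapply(vars, function(v) fitted_value(longfit, v, mids),
               numeric(length(mids)))
  if (length(mids) == 1) mu <- matrix(mu, 1, dimnames = list(NULL, vars))
  q <- nrow(longfit$re_index)
  lp_fix <- matrix(0, length(mids), length(ks))
  Gk <- vector("list", length(ks))
  h0m <- matrix(0, length(mids), length(ks))
  for (j in seq_along(ks)) {
    co <- msm$coefficients[msm$coefficients$transition == ks[j], ,
                           drop = FALSE]
    fx <- co[co$type == "fixed", , drop = FALSE]
    base <- if (nrow(fx) > 0)
      sum(fx$coefficient * (w0[fx$covariate] - cen(fx$covariate))) else 0
    lg <- co[co$type == "longitudinal", , drop = FALSE]
    lpf <- rep(base, length(mids))
    G <- matrix(0, length(mids), q)
    for (i in seq_len(nrow(lg))) {
      v <- lg$covariate[i]
      lpf <- lpf + lg$coefficient[i] * (mu[, v] - cen(v))
      spec <- longfit$specs[[v]]
      X <- build_basis(mids, spec$spline)
      cols <- which(longfit$re_index$variable == v)
      G[, cols] <- G[, cols] +
        lg$coefficient[i] * X[, spec$random_terms, drop = FALSE]
    }
    lp_fix[, j] <- lpf
    Gk[[j]] <- G
    h0m[, j] <- h0_eval(msm$baseline[[ks[j]]], mids)
  }
  occ <- array(NA_real_, c(length(grid), 4, nrow(ps$draws)))
  for (d in seq_len(nrow(ps$draws))) {
    b <- ps$draws[d, ]
    hz <- vapply(seq_along(ks), function(j)
      h0m[, j] * exp(pmin(lp_fix[, j] + as.numeric(Gk[[j]] %*% b), 500)),
      numeric(length(mids)))
    if (length(mids) == 1) hz <- matrix(hz, nrow = 1)
    P <- diag(4)
    gi <- 1
    while (gi <= length(grid) && grid[gi] <= br[1] + 1e-12) {
      occ[gi, , d] <- P[history$current_state, ]
      gi <- gi + 1
    }
    for (i in seq_along(mids)) {
      A <- matrix(0, 4, 4)
      for (j in seq_along(ks)) A[from[j], to[j]] <- hz[i, j]
      diag(A) <- -rowSums(A)
      P <- P %*% (diag(4) + A * du[i])
      while (gi <= length(grid) && grid[gi] <= br[i + 1] + 1e-12) {
        pr <- P[history$current_state, ]
        pr[pr < 0] <- 0
        occ[gi, , d] <- pr / sum(pr)
        gi <- gi + 1
      }
    }
  }
  wts <- ps$weights
  pm <- apply(occ, c(1, 2), function(x) sum(x * wts))
  vres <- apply(occ, c(1, 2), function(x) sum(wts * (x - sum(x * wts))^2))
  mcse <- sqrt(vres / ps$ess)
  res <- data.frame(u = grid)
  for (r in 1:4) res[[paste0("p_state", r)]] <- pm[, r]
  for (r in 1:4) res[[paste0("mc_se", r)]] <- mcse[, r]
  structure(
    list(occupancy = res, landmark = s,
         current_state = history$current_state, n_draws = n_draws,
         ess = ps$ess, seed = seed),
    class = "dynamic_prediction"
  )
}

#' @export
print.dynamic_prediction <- function(x, ...) {
  cat(sprintf(
    "Dynamic prediction from landmark %.3g y (state %d), %d draws (ESS %.0f)\n",
    x$landmark, x$current_state, x$n_draws, x$ess))
  print(utils::head(round(x$occupancy, 4)))
  invisible(x)
}

#' Update a dynamic prediction with newly collected data
#'
#' Recomputation semantics: the new longitudinal records and state
#' information are appended to the history and [predict_occupancy()] is
#' rerun from the new landmark; no incremental state is kept.
#'
#' @param fit a \code{joint_model_fit}
#' @param old_history a [subject_history()]
#' @param new_records longitudinal records after the old landmark (may be
#'   empty)
#' @param new_state_info sojourn rows extending the path (may be NULL to
#'   extend survival in the current state to the new landmark)
#' @param grid output times
#' @param landmark new landmark time (default: inferred from the new data)
#' @param ... passed to [predict_occupancy()]
#' @return a \code{dynamic_prediction}
#' @export
update_prediction <- function(fit, old_history, new_records = NULL,
                              new_state_info = NULL, grid,
                              landmark = NULL, ...) {
  h <- old_history
  if (!is.null(new_records) && nrow(new_records) > 0) {
    if (any(new_records$time < h$landmark - 1e-9))
      stop("new records must postdate the old landmark", call. = FALSE)
    h$longitudinal <- rbind(
      h$longitudinal[c("subject_id", "variable", "time", "value")],
      new_records[c("subject_id", "variable", "time", "value")])
  }
  if (!is.null(new_state_info) && nrow(new_state_info) > 0) {
    # the new rows re-describe the final (previously censored) sojourn
    # onward: first row must resume the current state at its entry time
    last <- h$path[nrow(h$path), ]
    first_new <- new_state_info[1, ]
    if (first_new$state != last$state ||
        abs(first_new$entry_time - last$entry_time) > 1e-9)
      stop("new state information must resume the current sojourn",
           call. = FALSE)
    cols <- c("subject_id", "state", "entry_time", "exit_time",
              "next_state")
    new_state_info$subject_id <- h$id
    h$path <- rbind(h$path[-nrow(h$path), cols], new_state_info[cols])
  }
  new_lm <- landmark
  if (is.null(new_lm)) {
    new_lm <- max(h$landmark,
                  if (nrow(h$path) > 0) max(h$path$exit_time) else 0,
                  if (nrow(h$longitudinal) > 0) max(h$longitudinal$time)
                  else 0)
  }
  if (new_lm < h$landmark - 1e-9)
    stop("new landmark must extend the old one", call. = FALSE)
  if (h$path$exit_time[nrow(h$path)] < new_lm &&
      is.na(h$path$next_state[nrow(h$path)])) {
    h$path$exit_time[nrow(h$path)] <- new_lm
  }
  h$landmark <- new_lm
  last <- h$path[nrow(h$path), ]
  h$current_state <- if (!is.na(last$next_state)) {
    stop("path may not end in a pending transition", call. = FALSE)
  } else as.integer(last$state)
  predict_occupancy(fit, h, grid, ...)
}
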