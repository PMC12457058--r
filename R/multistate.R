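#' Covariate path for hazard evaluation
#'
#' Bundles a subject's time-invariant covariate vector \code{w} (named:
#' \code{fdr}, \code{age}, \code{dq8x}, \code{dq2x}) with a function
#' \code{m(times)} returning a matrix of current analysis-scale values of
#' the longitudinal variables (one column per registry variable).
#'
#' @param w named numeric vector of fixed covariates
#' @param m function(times) -> matrix with registry-variable columns
#' @return an object of class \code{covariate_path}
#' @export
covariate_path <- function(w, m) {
  structure(list(w = w, m = m), class = "covariate_path")
}

#' Transition-specific proportional-hazards model
#'
#' Each allowed transition k carries a piecewise-constant baseline hazard
#' and a coefficient vector over its covariate roster; the intensity is
#' \deqn{h_k(t) = h0_k(t) \exp(\sum_j \beta_{kj} (x_j(t) - c_j))}
#' where x_j is either a fixed baseline covariate or the current value of a
#' longitudinal variable and c_j an optional centering constant (centering
#' is absorbed by the baseline and does not change the coefficients).
#'
#' @param coefficients data.frame with columns \code{transition},
#'   \code{covariate}, \code{type} ("fixed"/"longitudinal"),
#'   \code{coefficient}
#' @param baseline named list (by transition id) of lists with \code{cuts}
#'   (numeric, possibly empty) and \code{levels} (length cuts + 1, >= 0)
#' @param centering named numeric vector of centering constants (missing
#'   entries treated as 0)
#' @param inference optional inference table (estimates, SEs, p-values)
#' @param lambda penalty weight used when the model was fitted
#' @return an object of class \code{transition_model}
#' @export
transition_model <- function(coefficients, baseline, centering = numeric(0),
                             inference = NULL, lambda = NA_real_) {
  for (k in names(baseline)) {
    b <- baseline[[k]]
    if (length(b$levels) != length(b$cuts) + 1)
      stop("baseline levels must have length cuts + 1 for ", k,
           call. = FALSE)
    if (any(b$levels < 0))
      stop("baseline hazard levels must be >= 0 for ", k, call. = FALSE)
  }
  if (!all(coefficients$transition %in% all_transitions()))
    stop("coefficients reference a disallowed transition", call. = FALSE)
  structure(
    list(coefficients = coefficients, baseline = baseline,
         centering = centering, inference = inference, lambda = lambda),
    class = "transition_model"
  )
}

#' @export
print.transition_model <- function(x, ...) {
  cat("Transition-specific proportional-hazards model\n")
  for (k in names(x$baseline)) {
    co <- x$coefficients[x$coefficients$transition == k, , drop = FALSE]
    nz <- sum(abs(co$coefficient) > 1e-8)
    cat(sprintf("  %s: %d covariates (%d nonzero), baseline levels %s\n",
                k, nrow(co), nz,
                paste(signif(x$baseline[[k]]$levels, 3), collapse = "/")))
  }
  invisible(x)
}

#' Convenience constructor: constant baseline hazards, no covariates
#' @param rates named numeric vector, e.g. \code{c("1->2" = 0.3)}
#' @return a [transition_model()]
#' @export
constant_hazard_model <- function(rates) {
  transition_model(
    coefficients = data.frame(transition = character(0),
                              covariate = character(0),
                              type = character(0), coefficient = numeric(0),
                              stringsAsFactors = FALSE),
    baseline = lapply(rates, function(r) list(cuts = numeric(0), levels = r))
  )
}

# Piecewise-constant baseline hazard evaluation; the last level extends
# beyond the last cut point.
h0_eval <- function(bh, t) {
  bh$levels[findInterval(t, bh$cuts) + 1]
}

# Linear predictor (centered) for one transition along a path.
linear_predictor <- function(model, path, k, times, mvals = NULL) {
  co <- model$coefficients[model$coefficients$transition == k, ,
                           drop = FALSE]
  lp <- numeric(length(times))
  if (nrow(co) == 0) return(lp)
  cen <- function(nm) {
    v <- model$centering[nm]
    ifelse(is.na(v), 0, v)
  }
  fx <- co[co$type == "fixed", , drop = FALSE]
  if (nrow(fx) > 0) {
    lp <- lp + sum(fx$coefficient * (path$w[fx$covariate] -
                                       cen(fx$covariate)))
  }
  lg <- co[co$type == "longitudinal", , drop = FALSE]
  if (nrow(lg) > 0) {
    if (is.null(mvals)) mvals <- path$m(times)
    for (i in seq_len(nrow(lg))) {
      lp <- lp + lg$coefficient[i] *
        (mvals[, lg$covariate[i]] - cen(lg$covariate[i]))
    }
  }
  as.numeric(lp)
}

#' Transition intensity along a covariate path
#'
#' @param model a [transition_model()]
#' @param path a [covariate_path()]
#' @param k transition id, e.g. \code{"1->2"}
#' @param t evaluation time(s), years since GADA positivity (>= 0)
#' @return intensity per year (vectorised over \code{t})
#' @export
hazard <- function(model, path, k, t) {
  if (!k %in% all_transitions())
    stop("not an allowed transition: ", k, call. = FALSE)
  bh <- model$baseline[[k]]
  if (is.null(bh)) return(numeric(length(t)) * 0)
  h0_eval(bh, t) * exp(linear_predictor(model, path, k, t))
}

# Split a sojourn [entry, exit] into integration pieces: sub-grid of width
# subgrid plus any baseline cut points, midpoints used for covariates.
split_sojourn <- function(entry, exit, cuts, subgrid) {
  br <- seq(entry, exit, by = subgrid)
  br <- sort(unique(c(br, exit, cuts[cuts > entry & cuts < exit])))
  if (length(br) < 2) br <- c(entry, exit)
  data.frame(start = br[-length(br)], end = br[-1],
             mid = (br[-length(br)] + br[-1]) / 2)
}

#' Full multistate log-likelihood
#'
#' Sum over subjects and transitions of the counting-process likelihood
#' \deqn{\sum_{events} \log h_k(T) - \int_{at risk} h_k(u) du,}
#' with the integral computed exactly over the piecewise-constant baseline
#' segments and the longitudinal current values evaluated on a sub-grid
#' (midpoint rule within each segment).
#'
#' @param model a [transition_model()]
#' @param cohort a [cohort()] (its events table defines sojourns and events)
#' @param paths named list of [covariate_path()] objects keyed by subject id
#' @param subgrid sub-grid width (years) for evaluating the longitudinal
#'   values inside the integral
#' @return scalar log-likelihood
#' @export
multistate_log_likelihood <- function(model, cohort, paths, subgrid = 0.05) {
  ev <- cohort$events
  if (nrow(ev) == 0) return(0)
  ss <- state_space()
  ll <- 0
  for (i in seq_len(nrow(ev))) {
    id <- as.character(ev$subject_id[i])
    path <- paths[[id]]
    if (is.null(path)) stop("no covariate path for subject ", id,
                            call. = FALSE)
    q <- ev$state[i]
    ks <- transition_id(q, ss$transitions[ss$transitions[, 1] == q, 2])
    ks <- intersect(ks, names(model$baseline))
    if (ev$exit_time[i] > ev$entry_time[i]) {
      for (k in ks) {
        pieces <- split_sojourn(ev$entry_time[i], ev$exit_time[i],
                                model$baseline[[k]]$cuts, subgrid)
        hz <- hazard(model, path, k, pieces$mid)
        ll <- ll - sum((pieces$end - pieces$start) * hz)
      }
    }
    if (!is.na(ev$next_state[i])) {
      k <- transition_id(q, ev$next_state[i])
      if (!k %in% ks)
        stop("event on unmodelled transition ", k, call. = FALSE)
      ll <- ll + log(hazard(model, path, k, ev$exit_time[i]))
    }
  }
  ll
}

#' Expand a cohort into a piecewise-exponential risk table
#'
#' For each origin state, every at-risk sojourn is split into sub-grid
#' pieces; each row carries the exposure time, the longitudinal current
#' values at the piece midpoint and the fixed covariates. This is the
#' standard Poisson representation of the piecewise-constant-hazard model:
#' the likelihood of rows with counts \code{y} (1 on a piece ending in the
#' relevant event), offset log(exposure) and log-linear intensity equals the
#' multistate likelihood up to a constant.
#'
#' @param cohort a [cohort()]
#' @param paths named list of [covariate_path()] objects
#' @param subgrid sub-grid width (years)
#' @param cuts named list (by transition) of baseline cut points to align
#'   pieces with
#' @return list of data.frames, one per origin state (1, 2, 3)
#' @export
risk_expansion <- function(cohort, paths, subgrid = 0.1, cuts = list()) {
  ev <- cohort$events
  ss <- state_space()
  out <- list()
  for (q in 1:3) {
    ks <- transition_id(q, ss$transitions[ss$transitions[, 1] == q, 2])
    allcuts <- sort(unique(unlist(cuts[ks])))
    soj <- ev[ev$state == q & ev$exit_time > ev$entry_time, , drop = FALSE]
    if (nrow(soj) == 0) { out[[as.character(q)]] <- NULL; next }
    rows <- vector("list", nrow(soj))
    for (i in seq_len(nrow(soj))) {
      id <- as.character(soj$subject_id[i])
      path <- paths[[id]]
      pieces <- split_sojourn(soj$entry_time[i], soj$exit_time[i], allcuts,
                              subgrid)
      mv <- path$m(pieces$mid)
      d <- data.frame(subject_id = id, start = pieces$start,
                      end = pieces$end, mid = pieces$mid,
                      exposure = pieces$end - pieces$start,
                      stringsAsFactors = FALSE)
      for (v in colnames(mv)) d[[v]] <- mv[, v]
      for (wn in names(path$w)) d[[wn]] <- path$w[[wn]]
      d$is_last <- seq_len(nrow(d)) == nrow(d)
      d$next_state <- soj$next_state[i]
      rows[[i]] <- d
    }
    out[[as.character(q)]] <- do.call(rbind, rows)
  }
  out
}

# Default covariate rosters per transition (the published roster layout).
default_roster <- function() {
  co <- default_truth_transitions()$coefficients
  co[c("transition", "covariate", "type")]
}

#' Fit the multistate proportional-hazards submodel
#'
#' Per-transition estimation of the piecewise-constant-baseline
#' proportional-hazards model via the Poisson risk-table representation.
#' With \code{lambda = 0} the fit is unpenalized maximum likelihood (SEs
#' and Wald p-values from the observed information). With \code{lambda > 0}
#' an L1 penalty is applied to standardized covariate coefficients (never
#' to the baseline levels); coefficients shrunk below 1e-8 are reported as
#' exact zeros, and the selected set is refitted without penalty to produce
#' SEs and p-values. Zero-flagged covariates receive a post-selection SE
#' from a one-at-a-time re-entry refit, with the p-value left missing.
#'
#' @param cohort a [cohort()]
#' @param paths named list of [covariate_path()] objects
#' @param lambda L1 penalty weight (glmnet per-observation convention), a
#'   single value or a named vector/list by transition
#' @param roster data.frame (transition, covariate, type) giving the
#'   candidate covariate set per transition; defaults to the full
#'   transition-specific rosters of the study design
#' @param subgrid sub-grid width (years) for the risk-table pieces
#' @param cuts named list of baseline cut points per transition; default:
#'   tertiles of observed event times (no cuts when a transition has < 6
#'   events)
#' @param inference compute SEs and Wald p-values (set FALSE to skip the
#'   unpenalized refits when only coefficients/selection are needed)
#' @return a [transition_model()] whose \code{inference} component is the
#'   per-transition coefficient table (estimate, SE, Wald p, selected flag)
#' @export
fit_multistate <- function(cohort, paths, lambda = 0, roster = NULL,
                           subgrid = 0.1, cuts = NULL, inference = TRUE) {
  if (is.null(roster)) roster <- default_roster()
  ev <- cohort$events
  trans <- intersect(all_transitions(), unique(roster$transition))
  if (is.null(cuts)) {
    cuts <- lapply(stats::setNames(trans, trans), function(k) {
      ft <- as.integer(sub("->.*", "", k))
      tt <- as.integer(sub(".*->", "", k))
      et <- ev$exit_time[ev$state == ft & !is.na(ev$next_state) &
                           ev$next_state == tt]
      if (length(et) >= 6)
        as.numeric(stats::quantile(et, c(1 / 3, 2 / 3), names = FALSE))
      else numeric(0)
    })
  }
  expn <- risk_expansion(cohort, paths, subgrid = subgrid, cuts = cuts)
  coef_rows <- list()
  inf_rows <- list()
  baseline <- list()
  centering <- c()
  for (k in trans) {
    q <- as.integer(sub("->.*", "", k))
    r <- as.integer(sub(".*->", "", k))
    d <- expn[[as.character(q)]]
    ros <- roster[roster$transition == k, , drop = FALSE]
    if (is.null(d)) next
    y <- as.numeric(d$is_last & !is.na(d$next_state) & d$next_state == r)
    if (sum(y) < 1) {
      warning("no events observed for transition ", k,
              "; transition left unfit", call. = FALSE)
      next
    }
    X <- as.matrix(d[ros$covariate])
    cen <- colMeans(X)
    Xc <- sweep(X, 2, cen)
    piece <- factor(findInterval(d$mid, cuts[[k]]) + 1,
                    levels = seq_len(length(cuts[[k]]) + 1))
    off <- log(d$exposure)
    lam_k <- if (length(lambda) > 1) {
      lk <- lambda[[k]]
      if (is.null(lk)) 0 else lk
    } else as.numeric(lambda)
    P <- piece_design(piece)  # intercept + piece effects
    res <- fit_one_transition(Xc, y, off, P, lam_k,
                              inference = inference)
    lev <- exp(res$base_eta)
    baseline[[k]] <- list(cuts = cuts[[k]], levels = lev)
    coef_rows[[k]] <- data.frame(
      transition = k, covariate = ros$covariate, type = ros$type,
      coefficient = res$coef, stringsAsFactors = FALSE)
    inf_rows[[k]] <- data.frame(
      transition = k, covariate = ros$covariate,
      coefficient = res$coef, std_err = res$se, p_value = res$p,
      selected = res$selected, stringsAsFactors = FALSE)
    for (j in seq_along(cen)) {
      if (!ros$covariate[j] %in% names(centering))
        centering[ros$covariate[j]] <- cen[j]
    }
  }
  inf <- do.call(rbind, inf_rows)
  rownames(inf) <- NULL
  cf <- do.call(rbind, coef_rows)
  rownames(cf) <- NULL
  transition_model(cf, baseline, centering = centering, inference = inf,
                   lambda = if (length(lambda) > 1) NA_real_ else lambda)
}

# One-transition Poisson fit: unpenalized (glm) or LASSO (glmnet) followed
# by an unpenalized refit on the selected set.
fit_one_transition <- function(Xc, y, off, P, lam, inference = TRUE) {
  p <- ncol(Xc)
  nm <- colnames(Xc)
  glm_fit <- function(cols) {
    XX <- cbind(P, Xc[, cols, drop = FALSE])
    fit <- suppressWarnings(stats::glm.fit(
      XX, y, family = stats::poisson(), offset = off,
      control = list(maxit = 100)))
    # observed information from the IRLS weights
    W <- fit$weights
    I <- crossprod(XX * sqrt(W))
    V <- tryCatch(solve(I), error = function(e) matrix(NA, ncol(XX),
                                                       ncol(XX)))
    list(coef = fit$coefficients, se = sqrt(diag(V)),
         base_idx = seq_len(ncol(P)))
  }
  if (lam <= 0) {
    f <- glm_fit(seq_len(p))
    cf <- f$coef[-(f$base_idx)]
    se <- f$se[-(f$base_idx)]
    pval <- 2 * stats::pnorm(-abs(cf / se))
    capped <- !is.finite(cf) | abs(cf) > 15
    if (any(capped)) {
      warning("divergent coefficient(s) capped: ",
              paste(nm[capped], collapse = ", "), call. = FALSE)
      cf[capped] <- sign(cf[capped]) * 15
      cf[!is.finite(cf)] <- 0
    }
    return(list(coef = stats::setNames(cf, nm), se = se, p = pval,
                selected = rep(TRUE, p), base_eta = base_eta(f$coef, P)))
  }
  XX <- cbind(P[, -1, drop = FALSE], Xc)  # glmnet supplies the intercept
  pf <- c(rep(0, ncol(P) - 1), rep(1, p))
  gfit <- glmnet::glmnet(XX, y, family = "poisson", offset = off,
                         penalty.factor = pf, lambda = lam,
                         standardize = TRUE)
  beta <- as.numeric(gfit$beta[, 1])
  cvec <- beta[(ncol(P) - 1 + 1):length(beta)]
  cvec[abs(cvec) < 1e-8] <- 0
  selected <- cvec != 0
  coef_out <- stats::setNames(rep(0, p), nm)
  se_out <- rep(NA_real_, p)
  p_out <- rep(NA_real_, p)
  if (!inference) {
    coef_out[selected] <- cvec[selected]
    eta0 <- gfit$a0[1] +
      c(0, beta[seq_len(ncol(P) - 1)])[seq_len(ncol(P))]
    if (ncol(P) == 1) eta0 <- gfit$a0[1]
    return(list(coef = coef_out, se = se_out, p = p_out,
                selected = selected, base_eta = unname(eta0)))
  }
  f_sel <- glm_fit(which(selected))
  if (any(selected)) {
    cf <- f_sel$coef[-(f_sel$base_idx)]
    se <- f_sel$se[-(f_sel$base_idx)]
    coef_out[selected] <- cf
    se_out[selected] <- se
    p_out[selected] <- 2 * stats::pnorm(-abs(cf / se))
  }
  # post-selection SE for excluded covariates: one-at-a-time re-entry
  for (j in which(!selected)) {
    fj <- glm_fit(c(which(selected), j))
    se_out[j] <- fj$se[length(fj$coef)]
  }
  list(coef = coef_out, se = se_out, p = p_out, selected = selected,
       base_eta = base_eta(f_sel$coef, P))
}

# Intercept + treatment contrasts for the baseline pieces; degenerates to
# a plain intercept column when there is a single piece.
piece_design <- function(piece) {
  if (nlevels(piece) == 1) {
    matrix(1, length(piece), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~ piece)
  }
}

# Baseline log-hazard per piece from intercept + piece contrasts.
base_eta <- function(coef, P) {
  npiece <- ncol(P)
  if (npiece == 1) return(unname(coef[1]))
  unname(coef[1] + c(0, coef[2:npiece]))
}

#' Cross-validated selection of the LASSO penalty
#'
#' Subject-level K-fold cross-validation: for each fold and candidate
#' penalty the model is fitted on the training subjects and scored by the
#' unpenalized Poisson/multistate log-likelihood of the held-out subjects;
#' the penalty maximizing the mean held-out log-likelihood is returned, per
#' transition.
#'
#' @param cohort a [cohort()]
#' @param paths named list of [covariate_path()] objects
#' @param grid positive penalty grid (log-spaced recommended); default: the
#'   glmnet path computed on the full data per transition
#' @param folds number of folds (>= 2)
#' @param seed seed for the fold assignment
#' @param rule "min" picks the penalty maximizing the mean held-out
#'   log-likelihood; "1se" picks the largest penalty whose mean held-out
#'   log-likelihood is within one fold-standard-error of the maximum (the
#'   usual parsimony rule for selection)
#' @param roster,subgrid,cuts as in [fit_multistate()]
#' @return named list: \code{lambda} (named vector of selected penalties by
#'   transition), \code{cv_loglik} (list of per-transition grids and mean
#'   held-out log-likelihoods), \code{folds} (subject fold assignment)
#' @export
cv_select_lambda <- function(cohort, paths, grid = NULL, folds = 5,
                             seed = 1, rule = c("min", "1se"),
                             roster = NULL, subgrid = 0.1,
                             cuts = NULL) {
  rule <- match.arg(rule)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  if (!is.null(grid) && any(grid <= 0))
    stop("penalty grid must be positive", call. = FALSE)
  if (is.null(roster)) roster <- default_roster()
  ev <- cohort$events
  trans <- intersect(all_transitions(), unique(roster$transition))
  if (is.null(cuts)) {
    cuts <- lapply(stats::setNames(trans, trans), function(k) {
      ft <- as.integer(sub("->.*", "", k))
      tt <- as.integer(sub(".*->", "", k))
      et <- ev$exit_time[ev$state == ft & !is.na(ev$next_state) &
                           ev$next_state == tt]
      if (length(et) >= 6)
        as.numeric(stats::quantile(et, c(1 / 3, 2 / 3), names = FALSE))
      else numeric(0)
    })
  }
  ids <- cohort$baseline$subject_id
  set.seed(seed)
  fold_of <- stats::setNames(sample(rep(seq_len(folds), length.out =
                                          length(ids))), ids)
  expn <- risk_expansion(cohort, paths, subgrid = subgrid, cuts = cuts)
  lambda_out <- c()
  cvll_out <- list()
  for (k in trans) {
    q <- as.integer(sub("->.*", "", k))
    r <- as.integer(sub(".*->", "", k))
    d <- expn[[as.character(q)]]
    if (is.null(d)) next
    ros <- roster[roster$transition == k, , drop = FALSE]
    y <- as.numeric(d$is_last & !is.na(d$next_state) & d$next_state == r)
    if (sum(y) < folds) {
      warning("too few events on ", k, " for cross-validation",
              call. = FALSE)
      next
    }
    X <- as.matrix(d[ros$covariate])
    Xc <- sweep(X, 2, colMeans(X))
    piece <- factor(findInterval(d$mid, cuts[[k]]) + 1,
                    levels = seq_len(length(cuts[[k]]) + 1))
    P <- piece_design(piece)
    XX <- cbind(P[, -1, drop = FALSE], Xc)
    pf <- c(rep(0, ncol(P) - 1), rep(1, ncol(Xc)))
    off <- log(d$exposure)
    gk <- grid
    if (is.null(gk)) {
      full <- glmnet::glmnet(XX, y, family = "poisson", offset = off,
                             penalty.factor = pf, nlambda = 30,
                             standardize = TRUE)
      gk <- full$lambda
    }
    gk <- sort(gk, decreasing = TRUE)
    fo <- fold_of[d$subject_id]
    ev_folds <- unique(fo[y == 1])
    if (length(unique(fo)) < folds || length(ev_folds) < 2)
      warning("degenerate folds for ", k, call. = FALSE)
    score <- matrix(NA_real_, folds, length(gk))
    for (f in seq_len(folds)) {
      tr <- fo != f
      if (sum(y[tr]) == 0) next
      gfit <- glmnet::glmnet(XX[tr, , drop = FALSE], y[tr],
                             family = "poisson", offset = off[tr],
                             penalty.factor = pf, lambda = gk,
                             standardize = TRUE)
      eta <- cbind(1, XX[!tr, , drop = FALSE]) %*%
        rbind(gfit$a0, as.matrix(gfit$beta)) + off[!tr]
      ll <- colSums(y[!tr] * eta - exp(eta))
      # per-event normalization so fold scores are comparable in scale
      score[f, seq_len(ncol(eta))] <- ll / max(sum(y[!tr]), 1)
    }
    mean_ll <- colMeans(score, na.rm = TRUE)
    best <- which.max(mean_ll)
    if (rule == "1se") {
      se_ll <- apply(score, 2, stats::sd, na.rm = TRUE) /
        sqrt(colSums(!is.na(score)))
      ok <- which(mean_ll >= mean_ll[best] - se_ll[best])
      best <- min(ok)  # grid is sorted decreasing: largest penalty
    }
    lambda_out[k] <- gk[best]
    cvll_out[[k]] <- data.frame(lambda = gk, mean_loglik = mean_ll)
  }
  list(lambda = lambda_out, cv_loglik = cvll_out, folds = fold_of)
}

#' Transition probability matrix by product integration
#'
#' Computes P(s, t) = prod over [s, t] of (I + A(u) du) where A(u) is the
#' intensity matrix assembled from [hazard()] along the subject's covariate
#' path (hazards evaluated at step midpoints). Rows sum to 1; entries that
#' are unreachable under the acyclic state graph are exactly 0.
#'
#' @param model a [transition_model()]
#' @param path a [covariate_path()]
#' @param s,t interval endpoints, 0 <= s <= t
#' @param step product-integral step (years); default 1/120 (about 3 days)
#' @return 4 x 4 transition probability matrix
#' @export
transition_probability_matrix <- function(model, path, s, t,
                                          step = 1 / 120) {
  if (step <= 0) stop("step must be positive", call. = FALSE)
  if (t < s) stop("t must be >= s", call. = FALSE)
  P <- diag(4)
  if (t == s) return(P)
  br <- seq(s, t, by = step)
  if (br[length(br)] < t) br <- c(br, t)
  mids <- (br[-length(br)] + br[-1]) / 2
  du <- diff(br)
  ks <- intersect(all_transitions(), names(model$baseline))
  hz <- vapply(ks, function(k) hazard(model, path, k, mids),
               numeric(length(mids)))
  if (length(mids) == 1) hz <- matrix(hz, nrow = 1, dimnames =
                                        list(NULL, ks))
  from <- as.integer(sub("->.*", "", ks))
  to <- as.integer(sub(".*->", "", ks))
  for (i in seq_along(mids)) {
    A <- matrix(0, 4, 4)
    for (j in seq_along(ks)) A[from[j], to[j]] <- hz[i, j]
    diag(A) <- -rowSums(A)
    P <- P %*% (diag(4) + A * du[i])
  }
  P[P < 0] <- 0
  P[P > 1] <- 1
  P / rowSums(P)
}
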