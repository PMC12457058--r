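#' Sample baseline covariates for a synthetic cohort
#'
#' Draws sex, first-degree-relative status and HLA DQ group at the
#' configured frequencies and age at confirmed GADA positivity from the
#' configured quantile-anchored distribution.
#'
#' @param config a [sim_config()]
#' @param n number of subjects (default \code{config$n_subjects})
#' @return baseline data.frame (see [cohort()])
#' @export
sample_baseline <- function(config, n = config$n_subjects) {
  f <- config$covariate_freqs
  if (n == 0) {
    return(data.frame(subject_id = character(0), sex = character(0),
                      age_at_gada = numeric(0), fdr = numeric(0),
                      dq_group = character(0), stringsAsFactors = FALSE))
  }
  sex <- ifelse(stats::runif(n) < f["female"], "female", "male")
  fdr <- as.numeric(stats::runif(n) < f["fdr"])
  dq <- sample(c("DQ2/8", "DQ8/X", "DQ2/X"), n, replace = TRUE,
               prob = f[c("dq2_8", "dq8_x", "dq2_x")])
  age <- sample_age_at_gada(n, config$age_anchors)
  data.frame(subject_id = sprintf("S%04d", seq_len(n)), sex = sex,
             age_at_gada = age, fdr = fdr, dq_group = dq,
             stringsAsFactors = FALSE)
}

#' Simulate latent longitudinal trajectories
#'
#' Draws per-subject random effects b_i ~ MVN(0, Sigma_b) and defines the
#' noise-free trajectory of each variable j as
#' m_ij(t) = x_j(t)' beta_j + z_j(t)' b_ij. Each subject uses its own
#' substream derived from (master seed, subject index), so trajectories are
#' reproducible subject by subject.
#'
#' @param baseline baseline data.frame (defines n and subject ids)
#' @param config a [sim_config()]
#' @param master_seed seed for the substreams (default \code{config$seed})
#' @return an object of class \code{latent_trajectories} with the random
#'   effects matrix \code{b} (subjects x effects), the truth parameters and
#'   the spline specs; evaluate with [latent_value()]
#' @export
simulate_trajectories <- function(baseline, config,
                                  master_seed = config$seed) {
  tl <- config$truth_longitudinal
  q <- nrow(tl$Sigma_b)
  n <- nrow(baseline)
  ev <- eigen(tl$Sigma_b, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop("Sigma_b is not positive semidefinite", call. = FALSE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), q)
  b <- matrix(0, n, q)
  for (i in seq_len(n)) {
    set.seed(subject_seed(master_seed, 4L * i + 1L))
    b[i, ] <- as.numeric(rt %*% stats::rnorm(q))
  }
  colnames(b) <- colnames(tl$Sigma_b)
  rownames(b) <- baseline$subject_id
  structure(
    list(b = b, beta = tl$beta, sigma = tl$sigma, re_index = tl$re_index,
         specs = config$specs),
    class = "latent_trajectories"
  )
}

#' Evaluate a latent trajectory
#'
#' @param traj a \code{latent_trajectories} object
#' @param id subject id (row name of the random-effects matrix)
#' @param variable variable name
#' @param times evaluation times (years)
#' @return numeric vector of noise-free analysis-scale values
#' @export
latent_value <- function(traj, id, variable, times) {
  spec <- traj$specs[[variable]]
  if (is.null(spec)) stop("unknown variable: ", variable, call. = FALSE)
  X <- build_basis(times, spec$spline)
  mu <- as.numeric(X %*% traj$beta[[variable]])
  rows <- which(traj$re_index$variable == variable)
  Z <- X[, spec$random_terms, drop = FALSE]
  mu + as.numeric(Z %*% traj$b[id, rows])
}

# Matrix of latent values for all registry variables at the given times.
latent_matrix <- function(traj, id, times) {
  vars <- names(traj$specs)
  out <- vapply(vars, function(v) latent_value(traj, id, v, times),
                numeric(length(times)))
  if (length(times) == 1) out <- matrix(out, nrow = 1,
                                        dimnames = list(NULL, vars))
  out
}

#' Build subject covariate paths from the simulated latent truth
#'
#' A covariate path carries the fixed covariate vector w (fdr, age, dq8x,
#' dq2x) and a function m(t) returning the current analysis-scale values of
#' all longitudinal variables; it is the object hazards are evaluated on.
#'
#' @param cohort a simulated [cohort()] whose metadata holds the latent
#'   trajectories
#' @return named list of \code{covariate_path} objects, one per subject
#' @export
latent_paths <- function(cohort) {
  traj <- cohort$metadata$trajectories
  if (is.null(traj))
    stop("cohort metadata does not contain latent trajectories",
         call. = FALSE)
  bd <- baseline_design(cohort$baseline)
  out <- lapply(seq_len(nrow(bd)), function(i) {
    id <- bd$subject_id[i]
    covariate_path(
      w = c(fdr = bd$fdr[i], age = bd$age[i], dq8x = bd$dq8x[i],
            dq2x = bd$dq2x[i]),
      m = local({
        id_ <- id
        function(times) latent_matrix(traj, id_, times)
      })
    )
  })
  stats::setNames(out, bd$subject_id)
}

#' Simulate the multistate path of one subject by thinning
#'
#' Event times are drawn from the competing time-varying intensities
#' h_k(t) = h0_k(t) exp(eta_k(t)) by Lewis-Shedler thinning: the dominating
#' rate is the maximum of the total intensity over a dense grid of the
#' remaining follow-up window times a 1.2 safety factor.
#'
#' @param path a \code{covariate_path} for the subject
#' @param model a [transition_model()] (the simulation truth)
#' @param followup_end administrative censoring time (years post-GADA)
#' @param grid_step grid spacing for the dominating rate (years)
#' @param start_state,start_time initial condition (default: state 1 at
#'   time 0); used when forward-simulating futures from a landmark
#' @return data.frame of sojourns (state, entry_time, exit_time, next_state)
#' @export
simulate_transitions <- function(path, model, followup_end,
                                 grid_step = 0.1, start_state = 1L,
                                 start_time = 0) {
  ss <- state_space()
  rec <- list()
  state <- as.integer(start_state)
  t <- start_time
  if (state == 4L || t >= followup_end) {
    return(data.frame(state = state, entry_time = t,
                      exit_time = followup_end,
                      next_state = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  while (state != 4L && t < followup_end) {
    ks <- transition_id(ss$transitions[ss$transitions[, 1] == state, 1],
                        ss$transitions[ss$transitions[, 1] == state, 2])
    ks <- intersect(ks, names(model$baseline))
    if (length(ks) == 0) {
      rec[[length(rec) + 1]] <- c(state, t, followup_end, NA)
      t <- followup_end
      break
    }
    grid <- unique(sort(c(seq(t, followup_end, by = grid_step),
                          followup_end,
                          unlist(lapply(model$baseline[ks],
                                        function(b) b$cuts)))))
    grid <- grid[grid >= t & grid <= followup_end]
    mv <- path$m(grid)
    hz <- vapply(ks, function(k)
      h0_eval(model$baseline[[k]], grid) *
        exp(linear_predictor(model, path, k, grid, mvals = mv)),
      numeric(length(grid)))
    if (length(grid) == 1) hz <- matrix(hz, nrow = 1)
    total <- rowSums(hz)
    if (any(!is.finite(total)) || max(total) > 1e6) {
      lp <- log(pmax(hz, .Machine$double.xmin))
      stop(sprintf(
        "dominating rate overflow in state %d (max log-intensity %.2f)",
        state, max(lp[is.finite(lp)])), call. = FALSE)
    }
    M <- max(total) * 1.2
    if (M <= 0) {  # no outflow possible: censored at end of follow-up
      rec[[length(rec) + 1]] <- c(state, t, followup_end, NA)
      t <- followup_end
      break
    }
    entry <- t
    event <- FALSE
    while (TRUE) {
      t <- t + stats::rexp(1, M)
      if (t >= followup_end) {
        rec[[length(rec) + 1]] <- c(state, entry, followup_end, NA)
        t <- followup_end
        break
      }
      mv1 <- path$m(t)
      hk <- vapply(ks, function(k)
        h0_eval(model$baseline[[k]], t) *
          exp(linear_predictor(model, path, k, t, mvals = mv1)),
        numeric(1))
      if (stats::runif(1) < sum(hk) / M) {
        dest <- as.integer(sub(".*->", "",
                               sample(ks, 1, prob = hk / sum(hk))))
        rec[[length(rec) + 1]] <- c(state, entry, t, dest)
        state <- dest
        event <- TRUE
        break
      }
    }
    if (!event && t >= followup_end) break
  }
  out <- as.data.frame(do.call(rbind, rec))
  names(out) <- c("state", "entry_time", "exit_time", "next_state")
  out$state <- as.integer(out$state)
  out$next_state <- as.integer(out$next_state)
  out
}

#' Apply the visit/observation scheme to one subject
#'
#' Visits are scheduled every \code{visit_interval} years from GADA
#' positivity until the end of follow-up, with optional uniform jitter.
#' Titers are measured at every visit (from t = 0); HbA1c from the first
#' post-seroconversion visit onward; OGTT variables only at visits falling
#' on the OGTT schedule while the subject is in a multiple-autoantibody
#' state (2 or 3) and at least \code{ogtt_min_age} years old. No records are
#' generated at or after entry into state 4. Observed values are the latent
#' values plus N(0, sigma_j^2) noise.
#'
#' @param id subject id
#' @param age_at_gada baseline age (years)
#' @param events the subject's sojourn table
#' @param traj latent trajectories
#' @param config a [sim_config()]
#' @return longitudinal records data.frame
#' @export
apply_observation_scheme <- function(id, age_at_gada, events, traj, config) {
  end <- max(events$exit_time)
  absorbed <- any(!is.na(events$next_state) & events$next_state == 4)
  t4 <- if (absorbed) max(events$exit_time) else Inf
  sched <- seq(0, end, by = config$visit_interval)
  jit <- config$visit_jitter_sd
  times <- sched
  if (jit > 0 && length(sched) > 1) {
    times[-1] <- sched[-1] + stats::runif(length(sched) - 1, -jit, jit)
  }
  keep <- times >= 0 & times < t4 & times <= end
  sched <- sched[keep]; times <- times[keep]
  if (length(times) == 0) {
    return(data.frame(subject_id = character(0), variable = character(0),
                      time = numeric(0), value = numeric(0),
                      stringsAsFactors = FALSE))
  }
  state_at <- function(tt) {
    s <- rep(NA_integer_, length(tt))
    for (i in seq_len(nrow(events))) {
      in_sojourn <- tt >= events$entry_time[i] & tt < events$exit_time[i]
      s[in_sojourn] <- events$state[i]
    }
    s[tt >= max(events$exit_time)] <-
      if (absorbed) 4L else events$state[nrow(events)]
    s
  }
  st <- state_at(times)
  reg <- variable_registry()
  reg <- reg[reg$variable %in% names(traj$specs), , drop = FALSE]
  recs <- list()
  for (j in seq_len(nrow(reg))) {
    v <- reg$variable[j]
    if (reg$ogtt[j]) {
      ratio <- round(config$ogtt_interval / config$visit_interval)
      on_sched <- (round(sched / config$visit_interval) %% ratio) == 0
      use <- on_sched & st %in% c(2L, 3L) &
        (age_at_gada + times) >= config$ogtt_min_age
    } else if (v == "hba1c") {
      use <- seq_along(times) > 1
    } else {
      use <- rep(TRUE, length(times))
    }
    if (!any(use)) next
    tv <- times[use]
    val <- latent_value(traj, id, v, tv) +
      stats::rnorm(length(tv), 0, traj$sigma[[v]])
    recs[[v]] <- data.frame(subject_id = id, variable = v, time = tv,
                            value = val, stringsAsFactors = FALSE)
  }
  if (length(recs) == 0) {
    return(data.frame(subject_id = character(0), variable = character(0),
                      time = numeric(0), value = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic cohort
#'
#' Composes [sample_baseline()], [simulate_trajectories()],
#' [simulate_transitions()] and [apply_observation_scheme()]. The result is
#' fully reproducible from the configuration seed; the ground-truth
#' parameters and latent trajectories are stored in the cohort metadata.
#'
#' @param config a [sim_config()]
#' @param observations logical; generate observed longitudinal records
#'   (disable for speed when only latent paths and events are needed)
#' @return a [cohort()] with \code{metadata$truth} and
#'   \code{metadata$trajectories}
#' @export
simulate_cohort <- function(config, observations = TRUE) {
  set.seed(subject_seed(config$seed, 0L))
  bl <- sample_baseline(config)
  truth_model <- transition_model(
    coefficients = config$truth_transitions$coefficients,
    baseline = config$truth_transitions$baseline,
    centering = config$truth_transitions$centering
  )
  if (config$n_subjects == 0) {
    return(cohort(
      bl,
      data.frame(subject_id = character(0), variable = character(0),
                 time = numeric(0), value = numeric(0)),
      data.frame(subject_id = character(0), state = integer(0),
                 entry_time = numeric(0), exit_time = numeric(0),
                 next_state = integer(0)),
      metadata = list(seed = config$seed, truth = config$truth_transitions)
    ))
  }
  traj <- simulate_trajectories(bl, config)
  bd <- baseline_design(bl)
  ev_list <- vector("list", nrow(bl))
  obs_list <- vector("list", nrow(bl))
  for (i in seq_len(nrow(bl))) {
    id <- bl$subject_id[i]
    pth <- covariate_path(
      w = c(fdr = bd$fdr[i], age = bd$age[i], dq8x = bd$dq8x[i],
            dq2x = bd$dq2x[i]),
      m = local({
        id_ <- id
        function(times) latent_matrix(traj, id_, times)
      })
    )
    fe <- max(config$max_followup_age - bl$age_at_gada[i],
              config$visit_interval)
    set.seed(subject_seed(config$seed, 4L * i + 2L))
    ev <- simulate_transitions(pth, truth_model, fe)
    ev$subject_id <- id
    ev_list[[i]] <- ev
    if (observations) {
      set.seed(subject_seed(config$seed, 4L * i + 3L))
      obs_list[[i]] <- apply_observation_scheme(id, bl$age_at_gada[i], ev,
                                                traj, config)
    }
  }
  events <- do.call(rbind, ev_list)
  events <- events[c("subject_id", "state", "entry_time", "exit_time",
                     "next_state")]
  rownames(events) <- NULL
  lng <- if (observations) do.call(rbind, obs_list) else
    data.frame(subject_id = character(0), variable = character(0),
               time = numeric(0), value = numeric(0),
               stringsAsFactors = FALSE)
  rownames(lng) <- NULL
  cohort(bl, lng, events,
         metadata = list(seed = config$seed, config = config,
                         truth = config$truth_transitions,
                         trajectories = traj))
}
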