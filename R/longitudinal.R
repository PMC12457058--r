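#' Longitudinal variable specification
#'
#' @param variable registry variable name
#' @param spline a [spline_spec()]
#' @param random_terms indices of basis columns carrying random effects
#'   (must be a subset of the fixed basis columns)
#' @return a list-specification as used by [fit_mixed()]
#' @export
longitudinal_spec <- function(variable, spline, random_terms = c(1L, 2L)) {
  if (any(random_terms > basis_dim(spline)))
    stop("random_terms must index fixed basis columns", call. = FALSE)
  list(variable = variable, spline = spline,
       random_terms = as.integer(random_terms))
}

# Stack one subject's records across variables into (y, X, Z, sigma index).
# X maps rows to the concatenated fixed-effect vector; Z maps rows to the
# concatenated random-effect vector described by re_index.
stack_subject <- function(records, specs, re_index, beta_index) {
  vars <- intersect(names(specs), unique(records$variable))
  nb <- max(unlist(beta_index))
  q <- nrow(re_index)
  rows <- sum(records$variable %in% names(specs))
  y <- numeric(rows); X <- matrix(0, rows, nb); Z <- matrix(0, rows, q)
  var_of <- character(rows)
  at <- 0
  for (v in vars) {
    rec <- records[records$variable == v, , drop = FALSE]
    B <- build_basis(rec$time, specs[[v]]$spline)
    idx <- at + seq_len(nrow(rec))
    y[idx] <- rec$value
    X[idx, beta_index[[v]]] <- B
    zcols <- which(re_index$variable == v)
    Z[idx, zcols] <- B[, specs[[v]]$random_terms, drop = FALSE]
    var_of[idx] <- v
    at <- at + nrow(rec)
  }
  list(y = y, X = X, Z = Z, var_of = var_of)
}

beta_index_of <- function(specs) {
  dims <- vapply(specs, function(s) basis_dim(s$spline), integer(1))
  ends <- cumsum(dims)
  starts <- c(1, utils::head(ends, -1) + 1)
  stats::setNames(Map(seq, starts, ends), names(specs))
}

#' Marginal Gaussian log-likelihood of a longitudinal parameter set
#'
#' Evaluates the multivariate linear mixed model marginal likelihood
#' y_i ~ N(X_i beta, Z_i Sigma_b Z_i' + R_i) summed over subjects, with
#' R_i diagonal (per-variable residual variances). Used both as the fit
#' objective and to compare fitted versus ground-truth parameters.
#'
#' @param params list with \code{beta} (named list), \code{sigma} (named),
#'   \code{Sigma_b}, \code{re_index}
#' @param cohort a [cohort()]
#' @param specs longitudinal specifications
#' @return scalar log-likelihood
#' @export
longitudinal_log_likelihood <- function(params, cohort, specs) {
  bi <- beta_index_of(specs)
  beta_vec <- unlist(params$beta[names(specs)])
  lng <- cohort$longitudinal
  ll <- 0
  for (id in unique(lng$subject_id)) {
    st <- stack_subject(lng[lng$subject_id == id, , drop = FALSE], specs,
                        params$re_index, bi)
    if (length(st$y) == 0) next
    r <- st$y - as.numeric(st$X %*% beta_vec)
    s2 <- params$sigma[st$var_of]^2
    ll <- ll + gaussian_marginal_ll(r, st$Z, params$Sigma_b, s2)
  }
  ll
}

# log N(r; 0, Z Sigma Z' + diag(s2)) via Woodbury/determinant lemma.
gaussian_marginal_ll <- function(r, Z, Sigma, s2) {
  n <- length(r)
  Rinv_r <- r / s2
  ZtRr <- crossprod(Z, Rinv_r)
  ZtRZ <- crossprod(Z / sqrt(s2))
  q <- ncol(Z)
  M <- diag(q) + ZtRZ %*% Sigma
  quad <- sum(r * Rinv_r) -
    sum((Sigma %*% ZtRr) * solve(M, ZtRr))
  logdet <- sum(log(s2)) + determinant(M, logarithm = TRUE)$modulus
  -0.5 * (n * log(2 * pi) + as.numeric(logdet) + quad)
}

#' Fit the spline mixed-effects models for the longitudinal variables
#'
#' Maximum-likelihood estimation of the per-variable spline fixed effects,
#' residual SDs and the random-effects covariance. Two covariance
#' structures are supported:
#' \describe{
#'   \item{blockdiag}{independent random effects across variables (full
#'     covariance within each variable's intercept/slope pair). The
#'     likelihood then factorizes and each variable is fitted by
#'     \code{lme4::lmer} with ML.}
#'   \item{full}{one unstructured covariance across all variables' random
#'     terms, estimated by direct ML with a Cholesky parameterization and
#'     profiled fixed effects. Intended for small variable subsets where
#'     cross-variable coupling is of interest.}
#' }
#'
#' @param cohort a [cohort()]
#' @param specs named list of [longitudinal_spec()]s (default: the package
#'   defaults for all nine variables present in the data)
#' @param structure "blockdiag" or "full"
#' @param control optimizer control for the "full" structure
#' @return an object of class \code{longitudinal_fit}: \code{beta},
#'   \code{beta_se}, \code{sigma}, \code{Sigma_b}, \code{re_index},
#'   \code{specs}, \code{loglik}, \code{converged}
#' @export
fit_mixed <- function(cohort, specs = NULL,
                      structure = c("blockdiag", "full"),
                      control = list(iter.max = 500, rel.tol = 1e-8)) {
  structure <- match.arg(structure)
  lng <- cohort$longitudinal
  if (is.null(specs)) {
    specs <- default_longitudinal_specs()
    specs <- specs[intersect(names(specs), unique(lng$variable))]
  }
  for (v in names(specs)) {
    tms <- unique(lng$time[lng$variable == v])
    if (length(tms) < basis_dim(specs[[v]]$spline))
      stop(sprintf(
        "variable '%s' has %d distinct observation times; need >= %d",
        v, length(tms), basis_dim(specs[[v]]$spline)), call. = FALSE)
  }
  re_index <- data.frame(
    variable = rep(names(specs),
                   vapply(specs, function(s) length(s$random_terms),
                          integer(1))),
    term = unlist(lapply(specs, function(s)
      c("intercept", "slope", "extra")[seq_along(s$random_terms)])),
    stringsAsFactors = FALSE)
  if (structure == "blockdiag") {
    fit <- fit_mixed_blockdiag(lng, specs, re_index)
  } else {
    fit <- fit_mixed_full(lng, specs, re_index, control)
  }
  fit$specs <- specs
  fit$re_index <- re_index
  rn <- paste(re_index$variable, re_index$term, sep = ".")
  dimnames(fit$Sigma_b) <- list(rn, rn)
  class(fit) <- "longitudinal_fit"
  fit
}

fit_mixed_blockdiag <- function(lng, specs, re_index) {
  beta <- list(); beta_se <- list(); sigma <- c(); ll <- 0
  q <- nrow(re_index)
  Sigma <- matrix(0, q, q)
  conv <- TRUE
  for (v in names(specs)) {
    rec <- lng[lng$variable == v, , drop = FALSE]
    B <- build_basis(rec$time, specs[[v]]$spline)
    p <- ncol(B)
    df <- data.frame(.y = rec$value, .sid = rec$subject_id)
    for (j in seq_len(p)) df[[paste0("x", j)]] <- B[, j]
    zt <- specs[[v]]$random_terms
    fixed <- paste0("x", seq_len(p), collapse = " + ")
    ran <- paste0("x", zt, collapse = " + ")
    fml <- stats::as.formula(sprintf(
      ".y ~ 0 + %s + (0 + %s | .sid)", fixed, ran))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(fml, data = df, REML = FALSE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     check.nobs.vs.nRE = "ignore")))),
      error = function(e) NULL)
    zrows <- which(re_index$variable == v)
    if (is.null(fit)) {
      # degenerate data (e.g. noiseless): plain least squares, variances 0
      lmfit <- stats::lm(.y ~ 0 + ., data = df[c(".y",
                                                 paste0("x", seq_len(p)))])
      beta[[v]] <- unname(stats::coef(lmfit))
      beta_se[[v]] <- unname(sqrt(diag(stats::vcov(lmfit))))
      sigma[v] <- sqrt(max(mean(stats::residuals(lmfit)^2), 1e-12))
      ll <- ll + as.numeric(stats::logLik(lmfit))
      next
    }
    beta[[v]] <- unname(lme4::fixef(fit))
    beta_se[[v]] <- unname(sqrt(diag(as.matrix(stats::vcov(fit)))))
    sigma[v] <- stats::sigma(fit)
    vc <- lme4::VarCorr(fit)[[".sid"]]
    Sigma[zrows, zrows] <- as.matrix(vc)[seq_along(zt), seq_along(zt)]
    ll <- ll + as.numeric(stats::logLik(fit))
    if (!is.null(fit@optinfo$conv$lme4$code)) conv <- FALSE
  }
  list(beta = beta, beta_se = beta_se, sigma = sigma, Sigma_b = Sigma,
       loglik = ll, converged = conv, method = "blockdiag")
}

fit_mixed_full <- function(lng, specs, re_index, control) {
  bi <- beta_index_of(specs)
  ids <- unique(lng$subject_id)
  stacks <- lapply(ids, function(id)
    stack_subject(lng[lng$subject_id == id, , drop = FALSE], specs,
                  re_index, bi))
  q <- nrow(re_index)
  nv <- length(specs)
  vars <- names(specs)
  ltri <- which(lower.tri(matrix(0, q, q), diag = TRUE))
  # initialize from per-variable OLS
  init_sd <- 0.2
  L0 <- diag(log(init_sd), q)
  par0 <- c(L0[ltri], rep(log(0.2), nv))
  unpack <- function(par) {
    L <- matrix(0, q, q)
    L[ltri] <- par[seq_along(ltri)]
    diag(L) <- exp(diag(L))
    sig <- exp(par[length(ltri) + seq_len(nv)])
    list(Sigma = L %*% t(L), sigma = stats::setNames(sig, vars))
  }
  profile_ll <- function(par) {
    vp <- unpack(par)
    nb <- max(unlist(bi))
    XtVX <- matrix(0, nb, nb); XtVy <- numeric(nb)
    pre <- lapply(stacks, function(st) {
      s2 <- vp$sigma[st$var_of]^2
      ZtRZ <- crossprod(st$Z / sqrt(s2))
      M <- diag(q) + ZtRZ %*% vp$Sigma
      S_Minv <- vp$Sigma %*% solve(M)  # (Sigma^-1 + Z'R^-1 Z)^-1
      Vinv <- function(x) {
        # works columnwise on vectors or matrices
        Rx <- x / s2
        Rx - (st$Z %*% (S_Minv %*% crossprod(st$Z, Rx))) / s2
      }
      list(st = st, s2 = s2, M = M, Vinv = Vinv)
    })
    for (p in pre) {
      VX <- p$Vinv(p$st$X)
      XtVX <- XtVX + crossprod(p$st$X, VX)
      XtVy <- XtVy + crossprod(VX, p$st$y)
    }
    beta_vec <- solve(XtVX, XtVy)
    ll <- 0
    for (p in pre) {
      r <- p$st$y - as.numeric(p$st$X %*% beta_vec)
      quad <- sum(r * p$Vinv(r))
      logdet <- sum(log(p$s2)) +
        as.numeric(determinant(p$M, logarithm = TRUE)$modulus)
      ll <- ll - 0.5 * (length(r) * log(2 * pi) + logdet + quad)
    }
    attr(ll, "beta") <- beta_vec
    attr(ll, "XtVX") <- XtVX
    ll
  }
  opt <- stats::nlminb(par0, function(p) -as.numeric(profile_ll(p)),
                       control = list(iter.max = control$iter.max,
                                      rel.tol = control$rel.tol))
  final <- profile_ll(opt$par)
  vp <- unpack(opt$par)
  beta_vec <- attr(final, "beta")
  Vbeta <- solve(attr(final, "XtVX"))
  beta <- lapply(bi, function(ix) unname(beta_vec[ix]))
  beta_se <- lapply(bi, function(ix) sqrt(diag(Vbeta))[ix])
  list(beta = beta, beta_se = beta_se, sigma = vp$sigma,
       Sigma_b = vp$Sigma, loglik = as.numeric(final),
       converged = opt$convergence == 0, method = "full")
}

#' @export
print.longitudinal_fit <- function(x, ...) {
  cat(sprintf(
    "Spline mixed-effects fit (%s): %d variables, logLik = %.2f\n",
    x$method, length(x$beta), x$loglik))
  invisible(x)
}

#' Population mean trajectories from a longitudinal fit
#'
#' Evaluates x(t)' beta_j (no random effects) for each requested variable.
#'
#' @param fit a \code{longitudinal_fit}
#' @param times evaluation times (years)
#' @param variables variables to evaluate (default: all fitted)
#' @return data.frame with columns variable, time, mean
#' @export
predict_mean <- function(fit, times, variables = names(fit$beta)) {
  if (length(times) == 0) {
    return(data.frame(variable = character(0), time = numeric(0),
                      mean = numeric(0), stringsAsFactors = FALSE))
  }
  out <- lapply(variables, function(v) {
    if (is.null(fit$specs[[v]])) stop("unknown variable: ", v,
                                      call. = FALSE)
    X <- build_basis(times, fit$specs[[v]]$spline)
    data.frame(variable = v, time = times,
               mean = as.numeric(X %*% fit$beta[[v]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Posterior distribution of a subject's random effects
#'
#' Exact Gaussian conditional of b given the subject's observed
#' longitudinal records under the fitted linear mixed model. With zero
#' records the prior N(0, Sigma_b) is returned. The posterior covariance is
#' never larger than the prior in the Loewner order.
#'
#' @param fit a \code{longitudinal_fit}
#' @param records data.frame with columns variable, time, value (analysis
#'   scale); may have zero rows
#' @return list with \code{mean} (length-q vector) and \code{cov}
#'   (q x q matrix), q = nrow(fit$re_index)
#' @export
posterior_random_effects <- function(fit, records) {
  q <- nrow(fit$re_index)
  if (is.null(records) || nrow(records) == 0) {
    return(list(mean = stats::setNames(rep(0, q),
                                       rownames(fit$Sigma_b)),
                cov = fit$Sigma_b))
  }
  unknown <- setdiff(unique(records$variable), names(fit$specs))
  if (length(unknown) > 0)
    stop("record(s) for unknown variable: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  bi <- beta_index_of(fit$specs)
  st <- stack_subject(records, fit$specs, fit$re_index, bi)
  beta_vec <- unlist(fit$beta[names(fit$specs)])
  r <- st$y - as.numeric(st$X %*% beta_vec)
  s2 <- fit$sigma[st$var_of]^2
  S <- fit$Sigma_b
  ZtRZ <- crossprod(st$Z / sqrt(s2))
  M <- diag(q) + ZtRZ %*% S
  mean_b <- as.numeric(S %*% solve(M, crossprod(st$Z, r / s2)))
  cov_b <- S - S %*% solve(M, ZtRZ %*% S)
  cov_b <- (cov_b + t(cov_b)) / 2
  list(mean = stats::setNames(mean_b, rownames(S)), cov = cov_b)
}

# Model-implied trajectory for given random effects b (defaults to 0).
fitted_value <- function(fit, variable, times, b = NULL) {
  spec <- fit$specs[[variable]]
  if (is.null(spec)) stop("unknown variable: ", variable, call. = FALSE)
  X <- build_basis(times, spec$spline)
  mu <- as.numeric(X %*% fit$beta[[variable]])
  if (!is.null(b)) {
    rows <- which(fit$re_index$variable == variable)
    mu <- mu + as.numeric(X[, spec$random_terms, drop = FALSE] %*% b[rows])
  }
  mu
}
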