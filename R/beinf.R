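#' Zero-one-inflated beta (BEINF) density
#'
#' Density/mass function of the beta distribution inflated at 0 and 1,
#' parameterized by the beta mean `mu`, a dispersion parameter `sigma` in
#' (0, 1), the probability of an exact zero `nu`, and the probability of an
#' exact one given the value is nonzero, `tau`.  The point masses are
#' `nu` at 0 and `(1 - nu) * tau` at 1; continuous values in (0, 1) carry
#' density `(1 - nu) * (1 - tau) * dbeta(y, a, b)` with shape parameters
#' `a = mu * (1 - sigma^2) / sigma^2` and `b = (1 - mu) * (1 - sigma^2) / sigma^2`,
#' so that the total beta precision `a + b = (1 - sigma^2) / sigma^2`
#' decreases as `sigma` grows.
#'
#' @param y Numeric vector of values in \[0, 1\].
#' @param mu Beta-component mean, in (0, 1).  Recycled against `y`.
#' @param sigma Dispersion parameter, strictly inside (0, 1).
#' @param nu Probability of an exact zero, in \[0, 1\].
#' @param tau Probability of an exact one given nonzero, in \[0, 1\].
#' @param log Return log density/mass?
#' @return Numeric vector of densities (for 0 < y < 1) or masses (at 0, 1).
#' @examples
#' dbeinf(0, mu = 0.4, sigma = 0.3, nu = 0.9, tau = 0.5)   # 0.9
#' dbeinf(0.5, mu = 0.5, sigma = 1 / sqrt(3), nu = 0, tau = 0)  # uniform: 1
#' @export
dbeinf <- function(y, mu, sigma, nu, tau, log = FALSE) {
  check_beinf_params(mu, sigma, nu, tau)
  if (any(y < 0 | y > 1)) {
    stop("'y' values must lie in [0, 1]", call. = FALSE)
  }
  n <- max(length(y), length(mu))
  y <- rep_len(y, n)
  mu <- rep_len(mu, n)
  shp <- beinf_shapes(mu, sigma)
  out <- numeric(n)
  is0 <- y == 0
  is1 <- y == 1
  mid <- !is0 & !is1
  out[is0] <- nu
  out[is1] <- (1 - nu) * tau
  out[mid] <- (1 - nu) * (1 - tau) *
    stats::dbeta(y[mid], shp$a[mid], shp$b[mid])
  if (log) log(out) else out
}

#' Draw from the BEINF distribution
#'
#' @param n Number of draws.
#' @param mu Beta-component mean(s); recycled to length `n`.
#' @inheritParams dbeinf
#' @return Numeric vector in \[0, 1\].
#' @export
rbeinf <- function(n, mu, sigma, nu, tau) {
  check_beinf_params(mu, sigma, nu, tau)
  mu <- rep_len(mu, n)
  shp <- beinf_shapes(mu, sigma)
  y <- stats::rbeta(n, shp$a, shp$b)
  # Bernoulli gates: zero with prob nu, else one with prob tau
  u0 <- stats::runif(n) < nu
  u1 <- stats::runif(n) < tau
  y[u1] <- 1
  y[u0] <- 0
  y
}

# mu/sigma -> beta shapes; a + b = (1 - sigma^2) / sigma^2
beinf_shapes <- function(mu, sigma) {
  phi <- (1 - sigma^2) / sigma^2
  list(a = mu * phi, b = (1 - mu) * phi)
}

check_beinf_params <- function(mu, sigma, nu, tau) {
  if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1)) {
    stop("'mu' must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0 || sigma >= 1) {
    stop("'sigma' must be a single value strictly inside (0, 1)", call. = FALSE)
  }
  if (nu < 0 || nu > 1 || tau < 0 || tau > 1) {
    stop("'nu' and 'tau' must lie in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' BEINF log-likelihood for a regression design
#'
#' Sums the log density/mass of `y` under a BEINF model in which the beta
#' mean follows `mu_i = plogis(X %*% beta)` while `sigma`, `nu` and `tau`
#' are shared across observations.
#'
#' @param y Numeric response in \[0, 1\].
#' @param X Design matrix (rows aligned with `y`).
#' @param beta Coefficient vector for the logit-mean linear predictor.
#' @param sigma,nu,tau Shared BEINF parameters (see [dbeinf()]).
#' @return Log-likelihood (scalar).  If any continuous observation has
#'   non-finite log density the result is `-Inf`, flagged with a warning.
#' @export
beinf_loglik <- function(y, X, beta, sigma, nu, tau) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) {
    stop("design matrix rows must align with 'y'", call. = FALSE)
  }
  if (ncol(X) != length(beta)) {
    stop("length of 'beta' must match ncol(X)", call. = FALSE)
  }
  mu <- stats::plogis(drop(X %*% beta))
  ll <- dbeinf(y, mu = mu, sigma = sigma, nu = nu, tau = tau, log = TRUE)
  if (any(!is.finite(ll))) {
    warning("non-finite log density for at least one observation; ",
            "log-likelihood is -Inf", call. = FALSE)
    return(-Inf)
  }
  sum(ll)
}

#' Fit a BEINF regression of turnover on site and time point
#'
#' Maximum-likelihood fit of the zero-one-inflated beta model with a logit
#' link on the beta mean (`~ site + time_point` fixed effects), a logit
#' link on the shared dispersion `sigma`, and intercept-only logit links
#' for the inflation probabilities `nu` and `tau`.  Because the inflation
#' intercepts carry no covariates, the likelihood factorizes: `nu` and
#' `tau` have closed-form ML estimates (the observed fractions of zeros and
#' of ones among nonzeros) and the beta block (mean coefficients plus
#' `sigma`) is maximized numerically by multi-start quasi-Newton.
#'
#' @param y Numeric response in \[0, 1\] (turnover proportions; exact 0s and
#'   1s are the inflated masses).
#' @param site Factor (or coercible) of site labels, or `NULL` for no site
#'   effect.
#' @param time_point Factor (or coercible) of transitional-period labels,
#'   or `NULL` for no time effect.
#' @param baseline_site Reference level for the site factor (default the
#'   first level alphabetically).
#' @param n_starts Number of optimizer starts (jittered after the first).
#' @param max_iter,tol Optimizer iteration cap and relative tolerance.
#' @param start_seed Seed for start-point jitter only.
#' @return An object of class `beinf_fit`: list with `coefficients`
#'   (logit-mean coefficients), `sigma`, `nu`, `tau`, `link_alpha0`
#'   (logit `nu`), `link_gamma0` (logit `tau`), `loglik`, `aic`,
#'   `standard_errors`, `wald_p`, `converged`, `n_obs`, `n_zero`, `n_one`,
#'   and the factor levels used.
#' @export
fit_beinf <- function(y, site = NULL, time_point = NULL,
                      baseline_site = NULL, n_starts = 3L,
                      max_iter = 500L, tol = 1e-12, start_seed = 101L) {
  if (any(!is.finite(y)) || any(y < 0 | y > 1)) {
    stop("'y' must be finite and in [0, 1]", call. = FALSE)
  }
  n <- length(y)
  n0 <- sum(y == 0)
  n1 <- sum(y == 1)
  ycont <- y[y > 0 & y < 1]
  if (length(ycont) == 0L) {
    stop("degenerate fit: all observations are exact 0s or 1s, ",
         "so the beta component cannot be estimated", call. = FALSE)
  }

  df <- data.frame(row = seq_len(n))
  fml <- "~ 1"
  if (!is.null(site)) {
    site <- factor(site)
    if (!is.null(baseline_site)) site <- stats::relevel(site, ref = baseline_site)
    if (any(table(site) == 0L)) stop("empty site level", call. = FALSE)
    df$site <- site
    fml <- paste(fml, "+ site")
  }
  if (!is.null(time_point)) {
    time_point <- factor(time_point)
    df$time_point <- time_point
    fml <- paste(fml, "+ time_point")
  }
  X <- stats::model.matrix(stats::as.formula(fml), df)
  Xc <- X[y > 0 & y < 1, , drop = FALSE]
  if (qr(Xc)$rank < ncol(Xc)) {
    stop("design is rank-deficient on the continuous observations", call. = FALSE)
  }
  p <- ncol(X)

  # closed-form inflation ML (intercept-only logit links)
  nu_hat <- n0 / n
  tau_hat <- if (n > n0) n1 / (n - n0) else NA_real_

  # beta block: theta = (beta_1..beta_p, logit(sigma))
  negll <- function(theta) {
    beta <- theta[seq_len(p)]
    sigma <- stats::plogis(theta[p + 1L])
    mu <- stats::plogis(drop(Xc %*% beta))
    shp <- beinf_shapes(mu, sigma)
    ll <- stats::dbeta(ycont, shp$a, shp$b, log = TRUE)
    if (any(!is.finite(ll))) return(1e10)
    -sum(ll)
  }

  # moment-based start: logit of continuous mean, sigma from its variance
  mbar <- mean(ycont)
  vbar <- stats::var(ycont)
  sig0 <- if (is.finite(vbar) && vbar > 0) {
    sqrt(min(max(vbar / (mbar * (1 - mbar)), 0.01), 0.95))
  } else 0.3
  start0 <- c(stats::qlogis(min(max(mbar, 0.02), 0.98)), rep(0, p - 1L),
              stats::qlogis(sig0))

  best <- NULL
  rng <- local({
    set.seed(start_seed)
    function(k) stats::rnorm(k, sd = 0.5)
  })
  for (s in seq_len(n_starts)) {
    st <- if (s == 1L) start0 else start0 + rng(p + 1L)
    opt <- try(stats::optim(st, negll, method = "BFGS",
                            control = list(maxit = max_iter, reltol = tol)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("optimization failed from all starts", call. = FALSE)
  converged <- best$convergence == 0L

  beta_hat <- best$par[seq_len(p)]
  names(beta_hat) <- colnames(X)
  sigma_hat <- stats::plogis(best$par[p + 1L])

  # Wald SEs: numerical Hessian for the beta block; analytic binomial
  # information for the inflation intercepts (likelihood is block diagonal)
  H <- try(stats::optimHess(best$par, negll), silent = TRUE)
  se_theta <- rep(NA_real_, p + 1L)
  if (!inherits(H, "try-error")) {
    Hi <- try(solve(H), silent = TRUE)
    if (!inherits(Hi, "try-error")) {
      v <- diag(Hi)
      se_theta[v > 0] <- sqrt(v[v > 0])
    }
  }
  alpha0 <- if (nu_hat > 0 && nu_hat < 1) stats::qlogis(nu_hat) else
    if (nu_hat == 0) -Inf else Inf
  gamma0 <- if (!is.na(tau_hat) && tau_hat > 0 && tau_hat < 1)
    stats::qlogis(tau_hat) else if (isTRUE(tau_hat == 0)) -Inf else Inf
  se_alpha0 <- if (nu_hat > 0 && nu_hat < 1)
    sqrt(1 / (n * nu_hat * (1 - nu_hat))) else NA_real_
  se_gamma0 <- if (!is.na(tau_hat) && tau_hat > 0 && tau_hat < 1)
    sqrt(1 / ((n - n0) * tau_hat * (1 - tau_hat))) else NA_real_

  est <- c(beta_hat, logit_sigma = best$par[p + 1L],
           alpha0 = alpha0, gamma0 = gamma0)
  se <- c(se_theta, se_alpha0, se_gamma0)
  names(se) <- names(est)
  wald_z <- est / se
  wald_p <- 2 * stats::pnorm(-abs(wald_z))

  ll_infl <- 0
  if (n0 > 0) ll_infl <- ll_infl + n0 * log(nu_hat)
  if (n - n0 > 0 && nu_hat < 1) ll_infl <- ll_infl + (n - n0) * log(1 - nu_hat)
  if (n1 > 0) ll_infl <- ll_infl + n1 * log(tau_hat)
  ncont <- n - n0 - n1
  if (ncont > 0 && tau_hat < 1) ll_infl <- ll_infl + ncont * log(1 - tau_hat)
  loglik <- ll_infl - best$value
  k_par <- p + 1L + (nu_hat > 0) + (!is.na(tau_hat) && tau_hat > 0)

  structure(list(
    coefficients = beta_hat,
    sigma = sigma_hat,
    nu = nu_hat,
    tau = tau_hat,
    link_alpha0 = alpha0,
    link_gamma0 = gamma0,
    loglik = loglik,
    aic = 2 * k_par - 2 * loglik,
    standard_errors = se,
    wald_p = wald_p,
    converged = converged,
    n_obs = n, n_zero = n0, n_one = n1,
    site_levels = if (!is.null(site)) levels(site) else NULL,
    time_levels = if (!is.null(time_point)) levels(time_point) else NULL,
    formula = fml
  ), class = "beinf_fit")
}

#' @export
print.beinf_fit <- function(x, ...) {
  cat("Zero-one-inflated beta (BEINF) regression fit\n")
  cat(sprintf("  n = %d (zeros: %d, ones: %d); logLik = %.3f; AIC = %.2f\n",
              x$n_obs, x$n_zero, x$n_one, x$loglik, x$aic))
  cat(sprintf("  sigma = %.4f  nu = %.4f  tau = %.4f  converged: %s\n",
              x$sigma, x$nu, x$tau, x$converged))
  cat("  logit-mean coefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predicted mean turnover proportion for a covariate combination
#'
#' Inverse-logit of the fitted linear predictor of the beta mean.
#'
#' @param fit A `beinf_fit` object.
#' @param site Site label (omit if the fit has no site effect).
#' @param time_point Time-point label (omit if the fit has no time effect).
#' @return Predicted beta-component mean in (0, 1).
#' @export
predict_mu <- function(fit, site = NULL, time_point = NULL) {
  stopifnot(inherits(fit, "beinf_fit"))
  eta <- fit$coefficients[["(Intercept)"]]
  if (!is.null(fit$site_levels)) {
    if (is.null(site)) stop("fit includes a site effect; supply 'site'", call. = FALSE)
    if (!site %in% fit$site_levels) stop("unknown site level: ", site, call. = FALSE)
    nm <- paste0("site", site)
    if (nm %in% names(fit$coefficients)) eta <- eta + fit$coefficients[[nm]]
  }
  if (!is.null(fit$time_levels)) {
    if (is.null(time_point)) stop("fit includes a time effect; supply 'time_point'", call. = FALSE)
    time_point <- as.character(time_point)
    if (!time_point %in% fit$time_levels) stop("unknown time-point level: ", time_point, call. = FALSE)
    nm <- paste0("time_point", time_point)
    if (nm %in% names(fit$coefficients)) eta <- eta + fit$coefficients[[nm]]
  }
  stats::plogis(eta)
}
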