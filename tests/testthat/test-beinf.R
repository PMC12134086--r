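test_that("BEINF density places the documented point masses", {
  expect_equal(dbeinf(0, mu = 0.4, sigma = 0.3, nu = 0.9, tau = 0.5), 0.9)
  expect_equal(dbeinf(1, mu = 0.4, sigma = 0.3, nu = 0.9, tau = 0.5), 0.05)
  # sigma = 1/sqrt(3) makes the beta component uniform
  expect_equal(dbeinf(0.5, mu = 0.5, sigma = 1 / sqrt(3), nu = 0, tau = 0), 1.0,
               tolerance = 1e-12)
  expect_error(dbeinf(1.2, 0.5, 0.3, 0, 0), "\\[0, 1\\]")
  expect_error(dbeinf(0.5, 0.5, 1.3, 0, 0), "sigma")
})

test_that("BEINF density integrates to one for random valid parameters", {
  set.seed(99)
  for (i in 1:25) {
    mu <- runif(1, 0.05, 0.95)
    sigma <- runif(1, 0.1, 0.9)
    nu <- runif(1, 0, 0.9)
    tau <- runif(1, 0, 0.9)
    total <- dbeinf(0, mu, sigma, nu, tau) + dbeinf(1, mu, sigma, nu, tau) +
      beinf_continuous_mass(mu, sigma, nu, tau)
    expect_lt(abs(total - 1), 1e-8)
  }
})

test_that("log-likelihood sums per-observation log densities", {
  X <- matrix(1, 5, 1)
  expect_equal(beinf_loglik(rep(0, 5), X, beta = 0, sigma = 0.3,
                            nu = 0.9, tau = 0.5), 5 * log(0.9))
  expect_equal(beinf_loglik(1, matrix(1, 1, 1), beta = 0, sigma = 0.3,
                            nu = 0.9, tau = 0.5), log(0.05))
  set.seed(4)
  y <- runif(20)
  X <- cbind(1, rnorm(20))
  beta <- c(0.2, -0.5)
  mu <- plogis(drop(X %*% beta))
  expect_equal(beinf_loglik(y, X, beta, 0.4, 0.1, 0.2),
               sum(dbeinf(y, mu, 0.4, 0.1, 0.2, log = TRUE)),
               tolerance = 1e-12)
  expect_error(beinf_loglik(y, X[1:5, ], beta, 0.4, 0.1, 0.2), "align")
})

test_that("parameters are recovered from a simulated sample", {
  y <- generate_beinf_sample(2000, mu = 0.4, sigma = 0.3, nu = 0.3, tau = 0.2,
                             seed = 11)
  fit <- fit_beinf(y)
  expect_true(fit$converged)
  expect_lt(abs(plogis(fit$coefficients[["(Intercept)"]]) - 0.4), 0.05)
  expect_lt(abs(fit$sigma - 0.3), 0.05)
  expect_lt(abs(fit$nu - 0.3), 0.05)
  expect_lt(abs(fit$tau - 0.2), 0.05)
})

test_that("without inflation the fit collapses to plain beta ML", {
  skip_if_not_installed("fitdistrplus")
  y <- generate_beinf_sample(800, mu = 0.35, sigma = 0.25, nu = 0, tau = 0,
                             seed = 3)
  fit <- fit_beinf(y)
  ref <- fitdistrplus::fitdist(y, "beta", method = "mle",
                               optim.method = "BFGS",
                               control = list(reltol = 1e-14))
  a <- ref$estimate[["shape1"]]; b <- ref$estimate[["shape2"]]
  expect_lt(abs(plogis(fit$coefficients[["(Intercept)"]]) - a / (a + b)), 1e-6)
  expect_lt(abs(fit$sigma - sqrt(1 / (1 + a + b))), 1e-6)
  expect_equal(fit$nu, 0)
  expect_equal(fit$tau, 0)
})

test_that("purely degenerate responses are rejected", {
  expect_error(fit_beinf(c(0, 0, 1, 1, 0)), "degenerate")
})

test_that("fitting is invariant to observation order", {
  set.seed(7)
  y <- generate_beinf_sample(400, mu = 0.45, sigma = 0.35, nu = 0.2, tau = 0.1,
                             seed = 8)
  site <- rep(c("AS", "RR"), each = 200)
  f1 <- fit_beinf(y, site = site)
  o <- sample(length(y))
  f2 <- fit_beinf(y[o], site = site[o])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
  expect_equal(f1$sigma, f2$sigma, tolerance = 1e-6)
  expect_equal(f1$nu, f2$nu)
  expect_equal(f1$tau, f2$tau)
})

test_that("adding zeros never decreases the zero-inflation estimate", {
  y <- generate_beinf_sample(300, mu = 0.5, sigma = 0.3, nu = 0.1, tau = 0.1,
                             seed = 12)
  nus <- vapply(c(0, 30, 100), function(k) fit_beinf(c(y, rep(0, k)))$nu,
                numeric(1))
  expect_true(all(diff(nus) > 0))
})

test_that("likelihood at the truth beats perturbed parameters on average", {
  set.seed(31)
  X <- matrix(1, 5000, 1)
  wins <- 0L
  for (i in 1:5) {
    y <- generate_beinf_sample(5000, mu = 0.4, sigma = 0.3, nu = 0.25,
                               tau = 0.15, seed = 310 + i)
    ll_true <- beinf_loglik(y, X, qlogis(0.4), 0.3, 0.25, 0.15)
    ll_pert <- beinf_loglik(y, X, qlogis(0.5), 0.35, 0.35, 0.1)
    wins <- wins + (ll_true > ll_pert)
  }
  expect_equal(wins, 5L)
})

test_that("predicted means respect the logit link", {
  y <- generate_beinf_sample(600, mu = 0.4, sigma = 0.3, nu = 0.1, tau = 0.05,
                             seed = 21)
  site <- rep(c("AS", "RR", "SN"), each = 200)
  fit <- fit_beinf(y, site = site, baseline_site = "AS")
  p_as <- predict_mu(fit, site = "AS")
  p_rr <- predict_mu(fit, site = "RR")
  expect_equal(qlogis(p_rr) - qlogis(p_as), fit$coefficients[["siteRR"]],
               tolerance = 1e-12)
  expect_error(predict_mu(fit, site = "XX"), "unknown site")

  # hand-built fit: all-zero effects predict 0.5; an intercept-only logit
  # inverts exactly
  f0 <- fit
  f0$coefficients[] <- 0
  expect_equal(predict_mu(f0, site = "AS"), 0.5)
  f0$coefficients[["(Intercept)"]] <- qlogis(0.25)
  expect_equal(predict_mu(f0, site = "AS"), 0.25)
})
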