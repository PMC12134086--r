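# shared fixtures built in code

small_config <- function(seed = 1L, n_sites = 2L, transects_per_site = 2L,
                         colonies_per_transect = 15L,
                         site_labels = c("AS", "RR"), ...) {
  sim_config(n_sites = n_sites, transects_per_site = transects_per_site,
             colonies_per_transect = colonies_per_transect,
             site_labels = site_labels, seed = seed, ...)
}

# quadrature of the continuous BEINF component, robust to the endpoint
# singularities of beta shapes below 1.  Each half of [0, 1] is integrated
# under the power substitution u = y^a (resp. v = (1-y)^b), whose
# transformed integrand (1 - u^(1/a))^(b-1) / (a B(a,b)) is bounded; it is
# evaluated in log space so shapes far below 1 neither overflow nor
# underflow.  The inflation weight (1 - nu)(1 - tau) is recovered from the
# density under test at an interior point, so the check exercises dbeinf
# itself, not just the closed-form beta integral.
beinf_continuous_mass <- function(mu, sigma, nu, tau) {
  phi <- (1 - sigma^2) / sigma^2
  a <- mu * phi
  b <- (1 - mu) * phi
  half <- function(a, b) {
    if (a >= 1) {
      return(stats::integrate(function(y) stats::dbeta(y, a, b), 0, 0.5,
                              rel.tol = 1e-11, subdivisions = 400L)$value)
    }
    stats::integrate(function(u) {
      # y = u^(1/a) computed in logs: log(1 - y) via log1p(-exp(.))
      log_y <- log(u) / a
      l1my <- log1p(-exp(log_y))
      exp((b - 1) * l1my - log(a) - lbeta(a, b))
    }, 0, 0.5^a, rel.tol = 1e-11, subdivisions = 400L)$value
  }
  # recover the (1 - nu)(1 - tau) weight from the density under test at an
  # interior point where the beta density cannot underflow
  weight <- dbeinf(mu, mu, sigma, nu, tau) / stats::dbeta(mu, a, b)
  weight * (half(a, b) + half(b, a))
}

# hand-built two-snapshot dwelling tables for classification tests
snap <- function(ids, colony, status, tp = 0L) {
  data.frame(dwelling_id = ids, colony_id = colony, time_point = tp,
             status = status, stringsAsFactors = FALSE)
}

colony_snap <- function(ids, mortality = "alive", tp = 1L, site = "AS",
                        transect = "AS-T1") {
  data.frame(colony_id = ids, site = site, transect = transect,
             time_point = tp, genus = "Pocillopora", max_diameter_cm = 10,
             fragment_class = "none", health_state = "healthy",
             mortality_state = mortality, stringsAsFactors = FALSE)
}

# minimal multi-time-point dataset assembled by hand:
# per-colony dwelling history encoded as list(dwelling_id = c(status at T0..))
hand_dataset <- function(colonies, histories, time_points = 0:2) {
  ct <- do.call(rbind, lapply(seq_len(nrow(colonies)), function(i) {
    tps <- colonies$tps[[i]]
    do.call(rbind, lapply(tps, function(tp) {
      colony_snap(colonies$colony_id[i],
                  mortality = colonies$state_fn[[i]](tp), tp = tp,
                  site = colonies$site[i], transect = colonies$transect[i])
    }))
  }))
  dt <- do.call(rbind, lapply(names(histories), function(d) {
    h <- histories[[d]]
    snap(rep(d, length(h$status)), rep(h$colony, length(h$status)),
         h$status, tp = h$tps)
  }))
  structure(list(colony_table = ct, dwelling_table = dt,
                 true_event_log = data.frame()),
            class = "crab_dataset")
}
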