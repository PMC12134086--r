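#' Simulation configuration for a synthetic fate-tracking survey
#'
#' Builds and validates the parameter set for the synthetic survey
#' generator.  Defaults emulate the study design the package targets:
#' 4 reef sites x 3 permanent belt transects x 43 tagged colonies
#' (516 colonies), five semiannual time points T0..T4, site-specific host
#' genus composition, a mass-bleaching disturbance at T2 that raises host
#' mortality, settlement preference for already-inhabited hosts, and
#' background dwelling overgrowth.
#'
#' @param n_sites Number of reef sites.
#' @param transects_per_site Transects per site.
#' @param colonies_per_transect Tagged colonies per transect.
#' @param time_points Number of survey time points (default 5: T0..T4).
#' @param genus_pool Character vector of host genus labels.
#' @param site_genus_weights Numeric matrix (`n_sites` x genera) of
#'   per-site composition weights; rows are normalized internally.
#' @param p_initial_occupancy Probability a colony starts inhabited at T0.
#' @param mean_initial_dwellings Mean dwellings on inhabited T0 colonies
#'   (each inhabited colony gets `1 + Poisson(mean - 1)` dwellings).
#' @param colonization_intensity Expected new dwellings per transect per
#'   transition (Poisson mean).
#' @param settlement_preference Non-negative weight multiplier psi: an
#'   inhabited colony receives settlement weight `1 + psi`, an uninhabited
#'   one weight 1.
#' @param p_background_extinction Per-dwelling per-transition probability
#'   of overgrowth by live host tissue.
#' @param p_host_full_mortality_pre,p_host_full_mortality_post Per-colony
#'   per-transition probability of full colony mortality before/after the
#'   disturbance time point.
#' @param p_host_partial_mortality_pre,p_host_partial_mortality_post
#'   Analogous probabilities of a partial-mortality event that kills a
#'   random fraction of the colony's dwellings.
#' @param disturbance_time_point Time point index at which mortality
#'   switches from the "pre" to the "post" parameter set (default 2, i.e.
#'   transitions departing from T2 onward use the post set).
#' @param site_labels Optional site label vector (length `n_sites`).
#' @param seed Integer seed; the generator is fully reproducible under it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 4L,
                       transects_per_site = 3L,
                       colonies_per_transect = 43L,
                       time_points = 5L,
                       genus_pool = c("Pocillopora", "Pavona", "Echinopora",
                                      "Goniastrea", "Dipsastraea", "Platygyra"),
                       site_genus_weights = NULL,
                       p_initial_occupancy = 0.25,
                       mean_initial_dwellings = 2.1,
                       colonization_intensity = 3,
                       settlement_preference = 5,
                       p_background_extinction = 0.10,
                       p_host_full_mortality_pre = 0.02,
                       p_host_full_mortality_post = 0.15,
                       p_host_partial_mortality_pre = 0.05,
                       p_host_partial_mortality_post = 0.20,
                       disturbance_time_point = 2L,
                       site_labels = NULL,
                       seed = 1L) {
  if (is.null(site_labels)) {
    site_labels <- c("AS", "AF", "RR", "SN", paste0("S", seq_len(max(0, n_sites - 4))))[seq_len(n_sites)]
  }
  if (is.null(site_genus_weights)) {
    # mild site-specific composition shifts around an even pool
    g <- length(genus_pool)
    site_genus_weights <- matrix(1, n_sites, g)
    for (s in seq_len(n_sites)) {
      site_genus_weights[s, 1 + (s - 1L) %% g] <- 3
      site_genus_weights[s, 1 + s %% g] <- 2
    }
  }
  site_genus_weights <- as.matrix(site_genus_weights)
  cfg <- list(
    n_sites = as.integer(n_sites),
    transects_per_site = as.integer(transects_per_site),
    colonies_per_transect = as.integer(colonies_per_transect),
    time_points = as.integer(time_points),
    genus_pool = genus_pool,
    site_genus_weights = site_genus_weights,
    p_initial_occupancy = p_initial_occupancy,
    mean_initial_dwellings = mean_initial_dwellings,
    colonization_intensity = colonization_intensity,
    settlement_preference = settlement_preference,
    p_background_extinction = p_background_extinction,
    p_host_full_mortality_pre = p_host_full_mortality_pre,
    p_host_full_mortality_post = p_host_full_mortality_post,
    p_host_partial_mortality_pre = p_host_partial_mortality_pre,
    p_host_partial_mortality_post = p_host_partial_mortality_post,
    disturbance_time_point = as.integer(disturbance_time_point),
    site_labels = site_labels,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c("p_initial_occupancy", "p_background_extinction",
             "p_host_full_mortality_pre", "p_host_full_mortality_post",
             "p_host_partial_mortality_pre", "p_host_partial_mortality_post")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      stop("configuration error: '", p, "' must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  if (cfg$colonization_intensity < 0 || cfg$settlement_preference < 0) {
    stop("configuration error: intensities and settlement preference must be >= 0",
         call. = FALSE)
  }
  if (cfg$mean_initial_dwellings <= 0) {
    stop("configuration error: 'mean_initial_dwellings' must be positive",
         call. = FALSE)
  }
  if (cfg$time_points < 2L) {
    stop("configuration error: need at least two time points", call. = FALSE)
  }
  if (nrow(cfg$site_genus_weights) != cfg$n_sites ||
      ncol(cfg$site_genus_weights) != length(cfg$genus_pool)) {
    stop("configuration error: 'site_genus_weights' must be n_sites x length(genus_pool)",
         call. = FALSE)
  }
  if (any(cfg$site_genus_weights < 0) || any(rowSums(cfg$site_genus_weights) <= 0)) {
    stop("configuration error: genus weights must be non-negative with positive row sums",
         call. = FALSE)
  }
  if (length(cfg$site_labels) != cfg$n_sites) {
    stop("configuration error: 'site_labels' must have length n_sites", call. = FALSE)
  }
  invisible(cfg)
}

#' Generate the T0 host community of a synthetic survey
#'
#' Assigns colonies to sites and transects, draws genus per the site
#' composition weights, makes each colony inhabited with
#' `p_initial_occupancy`, and gives each inhabited colony at least one
#' dwelling with the configured mean.  Deterministic under the config seed.
#'
#' @param config A [sim_config()] object.
#' @return A `crab_dataset` restricted to time point 0: list with
#'   `colony_table`, `dwelling_table` and an empty `true_event_log`.
#' @export
generate_host_community <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  init <- init_community(config)
  dataset(
    colony_table = colony_rows(init, time_point = 0L, config = config),
    dwelling_table = dwelling_rows_t0(init),
    true_event_log = empty_event_log()
  )
}

# internal: draw the T0 state used by both entry points
init_community <- function(config) {
  n_col <- config$n_sites * config$transects_per_site * config$colonies_per_transect
  site_idx <- rep(seq_len(config$n_sites),
                  each = config$transects_per_site * config$colonies_per_transect)
  transect <- rep(rep(seq_len(config$transects_per_site),
                      each = config$colonies_per_transect),
                  times = config$n_sites)
  w <- config$site_genus_weights / rowSums(config$site_genus_weights)
  genus <- vapply(site_idx, function(s) {
    sample(config$genus_pool, 1L, prob = w[s, ])
  }, character(1))
  diam <- round(stats::rlnorm(n_col, meanlog = log(18), sdlog = 0.5), 1)
  inhabited <- stats::runif(n_col) < config$p_initial_occupancy
  n_dwell <- integer(n_col)
  if (any(inhabited)) {
    extra <- max(config$mean_initial_dwellings - 1, 0)
    n_dwell[inhabited] <- 1L + stats::rpois(sum(inhabited), extra)
  }
  list(
    colony_id = sprintf("C%04d", seq_len(n_col)),
    site = config$site_labels[site_idx],
    transect = sprintf("%s-T%d", config$site_labels[site_idx], transect),
    genus = genus,
    max_diameter_cm = diam,
    n_dwell0 = n_dwell
  )
}

colony_rows <- function(init, time_point, config,
                        mortality_state = NULL, health_state = NULL,
                        fragment_class = NULL) {
  n <- length(init$colony_id)
  data.frame(
    colony_id = init$colony_id,
    site = init$site,
    transect = init$transect,
    time_point = as.integer(time_point),
    genus = init$genus,
    max_diameter_cm = init$max_diameter_cm,
    fragment_class = if (is.null(fragment_class)) rep("none", n) else fragment_class,
    health_state = if (is.null(health_state)) rep("healthy", n) else health_state,
    mortality_state = if (is.null(mortality_state)) rep("alive", n) else mortality_state,
    stringsAsFactors = FALSE
  )
}

dwelling_rows_t0 <- function(init) {
  idx <- rep(seq_along(init$colony_id), init$n_dwell0)
  n <- length(idx)
  if (n == 0L) {
    return(data.frame(dwelling_id = character(), colony_id = character(),
                      time_point = integer(), status = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    dwelling_id = sprintf("D%05d", seq_len(n)),
    colony_id = init$colony_id[idx],
    time_point = 0L,
    status = rep("occupied", n),
    stringsAsFactors = FALSE
  )
}

empty_event_log <- function() {
  data.frame(dwelling_id = character(), colony_id = character(),
             transition = integer(), event_type = character(),
             stringsAsFactors = FALSE)
}

dataset <- function(colony_table, dwelling_table, true_event_log) {
  structure(list(colony_table = colony_table,
                 dwelling_table = dwelling_table,
                 true_event_log = true_event_log),
            class = "crab_dataset")
}

#' @export
print.crab_dataset <- function(x, ...) {
  tps <- sort(unique(x$colony_table$time_point))
  cat(sprintf("Synthetic fate-tracking dataset: %d colonies, %d dwellings, T%d..T%d\n",
              length(unique(x$colony_table$colony_id)),
              length(unique(x$dwelling_table$dwelling_id)),
              min(tps), max(tps)))
  cat(sprintf("  ground-truth events: %d\n", nrow(x$true_event_log)))
  invisible(x)
}

#' Simulate a full fate-tracking survey
#'
#' Runs the T0 community forward through all transitions.  Per transition
#' departing from time point t (arriving at t + 1): (i) every live colony
#' dies fully with the era-appropriate full-mortality probability, turning
#' all its live dwellings into host-mortality extinctions and excluding the
#' colony from further dynamics (it stays in the tables as dead); (ii) each
#' surviving colony suffers a partial-mortality event with the
#' era-appropriate probability, converting a uniformly drawn fraction of
#' its dwellings (floor, minimum one) into host-mortality extinctions;
#' (iii) each remaining occupied dwelling is overgrown (background
#' extinction) with `p_background_extinction`; (iv) a Poisson number of new
#' dwellings per transect is allocated across live colonies with weight
#' `1 + psi * inhabited`.  The "post" mortality set applies to transitions
#' departing at or after `disturbance_time_point`.  Every event is appended
#' to the ground-truth event log (transition r is the interval
#' T(r-1) -> Tr).
#'
#' @param config A [sim_config()] object.
#' @return A `crab_dataset` spanning all time points, with dwelling rows at
#'   every time point (`not_yet_present` before colonization; `overgrown` /
#'   `empty_on_dead_skeleton` absorbing afterwards).
#' @export
simulate_fate_tracking <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  init <- init_community(config)
  n_col <- length(init$colony_id)
  tmax <- config$time_points - 1L

  # per-dwelling registry
  dw <- data.frame(
    dwelling_id = dwelling_rows_t0(init)$dwelling_id,
    colony_idx = rep(seq_len(n_col), init$n_dwell0),
    birth_tp = 0L,
    end_tp = NA_integer_,            # time point at which loss is visible
    end_status = NA_character_,
    stringsAsFactors = FALSE
  )
  next_dw_id <- nrow(dw) + 1L

  alive <- rep(TRUE, n_col)
  death_tp <- rep(NA_integer_, n_col)
  partial_hit_tp <- rep(NA_integer_, n_col)
  ev <- list()
  transects <- unique(init$transect)

  for (arr in seq_len(tmax)) {                  # transition TR`arr`: T(arr-1) -> T`arr`
    post <- (arr - 1L) >= config$disturbance_time_point
    p_full <- if (post) config$p_host_full_mortality_post else config$p_host_full_mortality_pre
    p_part <- if (post) config$p_host_partial_mortality_post else config$p_host_partial_mortality_pre

    live_dw <- which(is.na(dw$end_tp))          # occupied entering the transition

    # (i) full colony mortality
    dies <- alive & (stats::runif(n_col) < p_full)
    if (any(dies)) {
      hit <- live_dw[dw$colony_idx[live_dw] %in% which(dies)]
      if (length(hit)) {
        dw$end_tp[hit] <- arr
        dw$end_status[hit] <- "empty_on_dead_skeleton"
        ev[[length(ev) + 1L]] <- data.frame(
          dwelling_id = dw$dwelling_id[hit],
          colony_id = init$colony_id[dw$colony_idx[hit]],
          transition = arr, event_type = "host_mortality_extinction",
          stringsAsFactors = FALSE)
      }
      death_tp[dies] <- arr
      alive[dies] <- FALSE
    }

    # (ii) partial colony mortality
    part <- alive & (stats::runif(n_col) < p_part)
    for (ci in which(part)) {
      mine <- which(is.na(dw$end_tp) & dw$colony_idx == ci)
      if (!length(mine)) next
      k <- max(1L, min(length(mine), floor(stats::runif(1) * length(mine))))
      lost <- if (length(mine) == 1L) mine else sample(mine, k)
      dw$end_tp[lost] <- arr
      dw$end_status[lost] <- "empty_on_dead_skeleton"
      partial_hit_tp[ci] <- arr
      ev[[length(ev) + 1L]] <- data.frame(
        dwelling_id = dw$dwelling_id[lost],
        colony_id = init$colony_id[ci],
        transition = arr, event_type = "host_mortality_extinction",
        stringsAsFactors = FALSE)
    }

    # (iii) background overgrowth on remaining dwellings of live colonies
    rem <- which(is.na(dw$end_tp) & alive[dw$colony_idx])
    if (length(rem) && config$p_background_extinction > 0) {
      gone <- rem[stats::runif(length(rem)) < config$p_background_extinction]
      if (length(gone)) {
        dw$end_tp[gone] <- arr
        dw$end_status[gone] <- "overgrown"
        ev[[length(ev) + 1L]] <- data.frame(
          dwelling_id = dw$dwelling_id[gone],
          colony_id = init$colony_id[dw$colony_idx[gone]],
          transition = arr, event_type = "extinction",
          stringsAsFactors = FALSE)
      }
    }

    # (iv) colonization, transect by transect, preference for inhabited hosts
    occ_count <- tabulate(dw$colony_idx[is.na(dw$end_tp)], nbins = n_col)
    for (tr in transects) {
      cand <- which(alive & init$transect == tr)
      if (!length(cand)) next
      n_new <- stats::rpois(1L, config$colonization_intensity)
      if (n_new == 0L) next
      wts <- 1 + config$settlement_preference * (occ_count[cand] > 0)
      tgt <- if (length(cand) == 1L) rep(cand, n_new) else
        sample(cand, n_new, replace = TRUE, prob = wts)
      ids <- sprintf("D%05d", seq.int(next_dw_id, length.out = n_new))
      next_dw_id <- next_dw_id + n_new
      dw <- rbind(dw, data.frame(
        dwelling_id = ids, colony_idx = tgt, birth_tp = arr,
        end_tp = NA_integer_, end_status = NA_character_,
        stringsAsFactors = FALSE))
      ev[[length(ev) + 1L]] <- data.frame(
        dwelling_id = ids, colony_id = init$colony_id[tgt],
        transition = arr, event_type = "colonization",
        stringsAsFactors = FALSE)
    }
  }

  # expand registries into long observation tables
  tps <- 0:tmax
  ct <- do.call(rbind, lapply(tps, function(tp) {
    ms <- ifelse(is.na(death_tp) | tp < death_tp, "alive",
                 ifelse(tp == death_tp, "dead_recent", "dead_old"))
    hs <- rep("healthy", n_col)
    hs[!is.na(partial_hit_tp) & partial_hit_tp == tp & ms == "alive"] <-
      "partial_fresh_mortality"
    fc <- ifelse(!is.na(partial_hit_tp) & tp >= partial_hit_tp & ms == "alive",
                 "mixed", "none")
    colony_rows(init, tp, config, mortality_state = ms,
                health_state = hs, fragment_class = fc)
  }))

  dt <- do.call(rbind, lapply(tps, function(tp) {
    status <- ifelse(tp < dw$birth_tp, "not_yet_present",
                     ifelse(is.na(dw$end_tp) | tp < dw$end_tp, "occupied",
                            dw$end_status))
    data.frame(dwelling_id = dw$dwelling_id,
               colony_id = init$colony_id[dw$colony_idx],
               time_point = as.integer(tp), status = status,
               stringsAsFactors = FALSE)
  }))

  log <- if (length(ev)) do.call(rbind, ev) else empty_event_log()
  o <- order(log$transition, log$dwelling_id)
  dataset(colony_table = ct, dwelling_table = dt, true_event_log = log[o, , drop = FALSE])
}

#' Generate a synthetic logger temperature series
#'
#' Sinusoidal annual cycle peaking at `mmm` (so the annual range is
#' `[mmm - annual_amplitude, mmm]`), plus a triangular heatwave anomaly
#' rising linearly from `heatwave_start` to its peak at the midpoint of
#' `heatwave_days` and back, plus Gaussian reading noise.
#'
#' @param mmm Maximum Monthly Mean temperature (deg C); annual cycle peak.
#' @param annual_amplitude Peak-to-trough amplitude of the annual cycle.
#' @param heatwave_start Date the heatwave anomaly starts.
#' @param heatwave_peak_anomaly Peak anomaly (deg C) above the seasonal
#'   baseline.
#' @param heatwave_days Duration of the triangular anomaly (days).
#' @param noise_sd Gaussian noise SD per reading (deg C).
#' @param interval_minutes Logger interval: 10 or 30 minutes.
#' @param span Length-2 Date vector: first and last day of the series.
#' @param peak_yday Day of year at which the annual cycle peaks
#'   (default 244, i.e. early September).
#' @param seed Integer seed.
#' @return Object of class `temperature_series`: data frame with
#'   `timestamp` (POSIXct, UTC) and `temp_c` columns.
#' @export
generate_temperature_series <- function(mmm = 30.9, annual_amplitude = 4,
                                        heatwave_start = as.Date("2023-08-01"),
                                        heatwave_peak_anomaly = 2,
                                        heatwave_days = 90,
                                        noise_sd = 0.1,
                                        interval_minutes = 10L,
                                        span = c(as.Date("2023-01-01"),
                                                 as.Date("2023-12-31")),
                                        peak_yday = 244L,
                                        seed = 1L) {
  if (!interval_minutes %in% c(10L, 30L)) {
    stop("'interval_minutes' must be 10 or 30", call. = FALSE)
  }
  span <- as.Date(span)
  if (length(span) != 2L || span[2] < span[1]) {
    stop("'span' must be an increasing pair of dates", call. = FALSE)
  }
  set.seed(seed)
  t0 <- as.POSIXct(paste(span[1], "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(span[2], "23:59:59"), tz = "UTC")
  ts <- seq(t0, t1, by = interval_minutes * 60)
  yday <- as.POSIXlt(ts, tz = "UTC")$yday + 1
  baseline <- (mmm - annual_amplitude) +
    annual_amplitude * (1 + cos(2 * pi * (yday - peak_yday) / 365.25)) / 2
  d_from_start <- as.numeric(difftime(ts, as.POSIXct(paste(heatwave_start, "00:00:00"),
                                                     tz = "UTC"), units = "days"))
  half <- heatwave_days / 2
  anomaly <- ifelse(d_from_start >= 0 & d_from_start <= half,
                    heatwave_peak_anomaly * d_from_start / half,
                    ifelse(d_from_start > half & d_from_start <= heatwave_days,
                           heatwave_peak_anomaly * (heatwave_days - d_from_start) / half,
                           0))
  temp <- baseline + anomaly + stats::rnorm(length(ts), sd = noise_sd)
  structure(data.frame(timestamp = ts, temp_c = temp),
            class = c("temperature_series", "data.frame"))
}

#' Draw a BEINF regression sample
#'
#' Simulates responses from the zero-one-inflated beta model, optionally
#' with per-row beta means from a covariate design.
#'
#' @param n Number of draws (ignored when `design` is supplied; one draw
#'   per design row).
#' @param mu Scalar beta mean, used when no design is supplied.
#' @param sigma,nu,tau Shared BEINF parameters (see [dbeinf()]).
#' @param design Optional data frame of covariates.
#' @param beta Coefficient vector matching `model.matrix(formula, design)`.
#' @param formula Model formula for the design (default `~ .` on all
#'   columns).
#' @param seed Integer seed.
#' @return Numeric vector in \[0, 1\].
#' @export
generate_beinf_sample <- function(n, mu = 0.5, sigma = 0.3, nu = 0, tau = 0,
                                  design = NULL, beta = NULL,
                                  formula = NULL, seed = 1L) {
  set.seed(seed)
  if (!is.null(design)) {
    if (is.null(beta)) stop("supply 'beta' with 'design'", call. = FALSE)
    if (is.null(formula)) formula <- ~ .
    X <- stats::model.matrix(formula, design)
    if (ncol(X) != length(beta)) stop("'beta' does not match the design", call. = FALSE)
    mu <- stats::plogis(drop(X %*% beta))
    n <- nrow(X)
  }
  rbeinf(n, mu = mu, sigma = sigma, nu = nu, tau = tau)
}

#' Write a synthetic dataset to CSV artifacts
#'
#' Writes `colonies.csv` and `dwellings.csv` in the schemas consumed by the
#' fate-tracking functions, plus `true_events.json` with ground-truth event
#' counts per transition.
#'
#' @param x A `crab_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(x, dir) {
  stopifnot(inherits(x, "crab_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pc <- file.path(dir, "colonies.csv")
  pd <- file.path(dir, "dwellings.csv")
  pe <- file.path(dir, "true_events.json")
  utils::write.csv(x$colony_table, pc, row.names = FALSE)
  utils::write.csv(x$dwelling_table, pd, row.names = FALSE)
  counts <- as.data.frame(table(transition = x$true_event_log$transition,
                                event_type = x$true_event_log$event_type))
  jsonlite::write_json(counts, pe, auto_unbox = TRUE, digits = NA)
  invisible(c(colonies = pc, dwellings = pd, events = pe))
}

#' Read colony and dwelling observation tables
#'
#' @param colonies_csv,dwellings_csv Paths to the CSV artifacts.
#' @return A `crab_dataset` (with an empty ground-truth log).
#' @export
read_dataset <- function(colonies_csv, dwellings_csv) {
  ct <- utils::read.csv(colonies_csv, stringsAsFactors = FALSE)
  dt <- utils::read.csv(dwellings_csv, stringsAsFactors = FALSE)
  need_c <- c("colony_id", "site", "transect", "time_point", "genus",
              "fragment_class", "health_state", "mortality_state")
  need_d <- c("dwelling_id", "colony_id", "time_point", "status")
  if (!all(need_c %in% names(ct))) stop("colonies table missing columns", call. = FALSE)
  if (!all(need_d %in% names(dt))) stop("dwellings table missing columns", call. = FALSE)
  dataset(ct, dt, empty_event_log())
}
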