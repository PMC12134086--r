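#' Validate colony and dwelling observation tables
#'
#' Structural checks before analysis: referential integrity of dwelling ->
#' colony ids, legality of dwelling status sequences (absorbing states are
#' never left; a dwelling cannot revert to `not_yet_present`), time-point
#' coverage of each dwelling, one colony per dwelling across time, and the
#' contradiction of a dead colony carrying occupied dwellings.  The
#' function reports and never mutates.
#'
#' @param colony_table,dwelling_table Observation tables (see
#'   [read_dataset()] for the schemas).
#' @return Data frame with `severity` (`error`/`warning`), `rule`,
#'   `message`; zero rows for a clean dataset.
#' @export
validate_inputs <- function(colony_table, dwelling_table) {
  issues <- list()
  add <- function(severity, rule, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, rule = rule, message = message,
      stringsAsFactors = FALSE)
  }

  ckey <- paste(colony_table$colony_id, colony_table$time_point)
  dkey <- paste(dwelling_table$colony_id, dwelling_table$time_point)
  orphan <- !dwelling_table$colony_id %in% colony_table$colony_id
  if (any(orphan)) {
    for (id in unique(dwelling_table$dwelling_id[orphan])) {
      add("error", "referential_integrity",
          sprintf("dwelling %s references unknown colony", id))
    }
  }
  miss_tp <- !orphan & !dkey %in% ckey
  if (any(miss_tp)) {
    add("warning", "time_point_coverage",
        sprintf("%d dwelling row(s) at time points with no matching colony row",
                sum(miss_tp)))
  }

  # one colony per dwelling across all time points
  map <- unique(dwelling_table[, c("dwelling_id", "colony_id")])
  dup <- map$dwelling_id[duplicated(map$dwelling_id)]
  for (id in unique(dup)) {
    add("error", "dwelling_colony_map",
        sprintf("dwelling %s maps to multiple colonies", id))
  }

  # status sequence legality per dwelling
  legal_next <- list(
    occupied = c("occupied", "overgrown", "empty_on_dead_skeleton"),
    overgrown = "overgrown",
    empty_on_dead_skeleton = "empty_on_dead_skeleton",
    not_yet_present = c("not_yet_present", "occupied")
  )
  dt <- dwelling_table[order(dwelling_table$dwelling_id, dwelling_table$time_point), ]
  same <- dt$dwelling_id[-1] == dt$dwelling_id[-nrow(dt)]
  prev_st <- dt$status[-nrow(dt)][same]
  curr_st <- dt$status[-1][same]
  ids <- dt$dwelling_id[-1][same]
  bad <- !mapply(function(p, q) q %in% legal_next[[p]], prev_st, curr_st)
  for (i in which(bad)) {
    add("error", "transition_legality",
        sprintf("dwelling %s: illegal transition %s -> %s",
                ids[i], prev_st[i], curr_st[i]))
  }

  # dead colonies may not hold occupied dwellings at the same time point
  dead_keys <- ckey[colony_table$mortality_state %in% c("dead_recent", "dead_old")]
  occ_on_dead <- dwelling_table$status == "occupied" & dkey %in% dead_keys
  for (id in unique(dwelling_table$dwelling_id[occ_on_dead])) {
    add("error", "dead_colony_occupancy",
        sprintf("dwelling %s occupied on a dead colony", id))
  }

  if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(), rule = character(), message = character(),
               stringsAsFactors = FALSE)
}

#' Run the full fate-tracking analysis pipeline
#'
#' Simulate (or load) a survey, validate it, classify events, compute
#' per-colony transition rates and site summaries, fit the BEINF turnover
#' model on the analysis set, run per-site permutation tests (multi-sample
#' trend in background mortality; pre/post-disturbance difference in
#' disturbance mortality), compute baseline community statistics, and
#' compute thermal stress from per-site synthetic logger series.  All
#' intermediate artifacts are written under `out_dir`, and the run is
#' fully deterministic under the config seed.
#'
#' @param config A [sim_config()] (simulation mode), or a list with
#'   `colonies_csv` and `dwellings_csv` paths (data mode; then `seed`
#'   drives only the resampling procedures).
#' @param out_dir Output directory for artifacts.
#' @param include_hm Include host-mortality extinctions in the turnover
#'   numerator (default `TRUE`).
#' @param mmm Maximum Monthly Mean temperature for the DHW stage.
#' @param n_perm Permutations for the resampling tests.
#' @param quiet Suppress per-stage log messages.
#' @return A run report (list, also written as `report.json`).
#' @export
run_pipeline <- function(config, out_dir = tempfile("crabfate_run_"),
                         include_hm = TRUE, mmm = 30.9, n_perm = 999L,
                         quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  sim_mode <- inherits(config, "sim_config")
  if (!sim_mode && !all(c("colonies_csv", "dwellings_csv") %in% names(config))) {
    stop("config must be a sim_config or name colonies_csv/dwellings_csv inputs",
         call. = FALSE)
  }
  seed <- if (sim_mode) config$seed else (config$seed %||% 1L)

  # stage 1: data
  if (sim_mode) {
    ds <- simulate_fate_tracking(config)
    write_dataset(ds, out_dir)
    say("simulate: %d colonies, %d dwellings, %d true events",
        length(unique(ds$colony_table$colony_id)),
        length(unique(ds$dwelling_table$dwelling_id)),
        nrow(ds$true_event_log))
  } else {
    ds <- read_dataset(config$colonies_csv, config$dwellings_csv)
    say("load: %d colony rows, %d dwelling rows",
        nrow(ds$colony_table), nrow(ds$dwelling_table))
  }

  # stage 2: validation
  issues <- validate_inputs(ds$colony_table, ds$dwelling_table)
  utils::write.csv(issues, file.path(out_dir, "validation.csv"), row.names = FALSE)
  n_err <- sum(issues$severity == "error")
  say("validate: %d error(s), %d warning(s)", n_err,
      sum(issues$severity == "warning"))
  if (n_err > 0) {
    stop("input validation failed with ", n_err, " error(s); see ",
         file.path(out_dir, "validation.csv"), call. = FALSE)
  }

  # stage 3: events and rates
  events <- classify_all_events(ds)
  utils::write.csv(events, file.path(out_dir, "events.csv"), row.names = FALSE)
  rates_all <- transition_rates(ds, events = events, include_hm = include_hm)
  fas <- filter_analysis_set(ds)
  rates <- rates_all[rates_all$colony_id %in% fas$kept, ]
  utils::write.csv(rates, file.path(out_dir, "transition_rates.csv"),
                   row.names = FALSE)
  say("rates: %d colony-transition rows (%d colonies in the analysis set; %d dropped)",
      nrow(rates), length(fas$kept), nrow(fas$dropped))

  summ <- list(
    turnover = aggregate_rates(rates, "turnover_pct"),
    background = aggregate_rates(rates, "background_mortality_pct"),
    disturbance = aggregate_rates(rates, "disturbance_mortality_pct")
  )
  sp <- do.call(rbind, lapply(names(summ), function(nm) {
    cbind(rate = nm, summ[[nm]])
  }))
  utils::write.csv(sp, file.path(out_dir, "site_period_summary.csv"),
                   row.names = FALSE)

  # stage 4: BEINF turnover model
  keep <- !is.na(rates$turnover_pct)
  beinf <- tryCatch(
    fit_beinf(rates$turnover_pct[keep] / 100,
              site = rates$site[keep],
              time_point = rates$transition[keep],
              baseline_site = sort(unique(rates$site))[1]),
    error = function(e) e)
  beinf_report <- if (inherits(beinf, "error")) {
    list(error = conditionMessage(beinf))
  } else {
    say("beinf: nu=%.3f sigma=%.3f tau=%.3f logLik=%.2f converged=%s",
        beinf$nu, beinf$sigma, beinf$tau, beinf$loglik, beinf$converged)
    list(coefficients = as.list(beinf$coefficients), sigma = beinf$sigma,
         nu = beinf$nu, tau = beinf$tau, loglik = beinf$loglik,
         aic = beinf$aic, converged = beinf$converged,
         n_obs = beinf$n_obs, n_zero = beinf$n_zero, n_one = beinf$n_one)
  }

  # stage 5: permutation tests per site
  dtp <- if (sim_mode) config$disturbance_time_point else (config$disturbance_time_point %||% 2L)
  perm <- lapply(sort(unique(rates$site)), function(s) {
    rs <- rates[rates$site == s, ]
    bg <- split(rs$background_mortality_pct, rs$transition)
    bg_test <- tryCatch(
      multi_sample_perm_test(bg, n_perm = n_perm, seed = seed + 17L),
      error = function(e) NULL)
    ps <- pre_post_split(rs, disturbance_time_point = dtp)
    dist_test <- if (length(ps$pre) && length(ps$post)) {
      two_sample_perm_test(ps$pre, ps$post, n_perm = n_perm, seed = seed + 29L)
    } else NULL
    as_rep <- function(t) if (is.null(t)) NULL else
      list(observed_stat = t$observed_stat, p_value = t$p_value,
           n_perm_used = t$n_perm_used, exact = t$exact, direction = t$direction)
    list(site = s, background_trend = as_rep(bg_test),
         disturbance_pre_post = as_rep(dist_test))
  })
  say("perm-tests: %d site(s)", length(perm))

  # stage 6: community statistics (baseline time points), optional stage
  community <- tryCatch({
    cm <- community_matrix(ds$colony_table, time_points = c(1L, 3L))
    meta <- attr(cm, "meta")
    hel <- hellinger(cm)
    pca <- comm_pca(hel)
    pmv <- permanova(stats::dist(hel), site = meta$site, transect = meta$transect,
                     time_point = meta$time_point, n_perm = n_perm,
                     seed = seed + 41L)
    smp <- simper(relative_abundance(cm), groups = meta$site)
    div <- do.call(rbind, lapply(seq_len(nrow(cm)), function(i) {
      h <- hill_numbers(cm[i, ])
      data.frame(meta[i, ], N0 = h$N0, N1 = h$N1, N2 = h$N2)
    }))
    utils::write.csv(data.frame(sample = rownames(pca$scores),
                                pca$scores[, seq_len(min(3, ncol(pca$scores)))]),
                     file.path(out_dir, "ordination_scores.csv"), row.names = FALSE)
    utils::write.csv(smp$contributions, file.path(out_dir, "simper.csv"),
                     row.names = FALSE)
    utils::write.csv(div, file.path(out_dir, "diversity.csv"), row.names = FALSE)
    jsonlite::write_json(pmv$terms, file.path(out_dir, "permanova.json"),
                         auto_unbox = TRUE, digits = NA)
    say("community: %d sample units, site R2=%.3f", nrow(cm),
        pmv$terms$R2[pmv$terms$term == "site"])
    list(permanova = pmv$terms,
         site_R2 = pmv$terms$R2[pmv$terms$term == "site"],
         mean_dissimilarity = smp$mean_dissimilarity,
         top_genus = smp$contributions$genus[1],
         diversity = div,
         pc1_var = pca$variance_explained[1])
  }, error = function(e) {
    say("community stage failed: %s", conditionMessage(e))
    list(error = conditionMessage(e))
  })

  # stage 7: thermal stress, one synthetic logger series per site
  sites <- sort(unique(ds$colony_table$site))
  thermal <- lapply(seq_along(sites), function(i) {
    ser <- generate_temperature_series(
      mmm = mmm, heatwave_peak_anomaly = 2 + 0.25 * (i - 1),
      seed = seed + 1000L + i)
    res <- compute_dhw(daily_means(ser), mmm = mmm)
    write_thermal(res, file.path(out_dir, paste0("thermal_", sites[i], ".csv")))
    list(site = sites[i], max_dhw = res$max_dhw,
         first_dhw4 = format(first_exceedance(res, 4)),
         first_dhw8 = format(first_exceedance(res, 8)))
  })
  say("thermal: max DHW %.2f degC-weeks across sites",
      max(vapply(thermal, function(t) t$max_dhw, numeric(1))))

  # internal consistency audit: site summaries vs events artifact
  ev_counts <- table(events$event_type)
  rate_counts <- c(colonization = sum(rates_all$C), extinction = sum(rates_all$E),
                   host_mortality_extinction = sum(rates_all$HM))
  for (nm in names(rate_counts)) {
    n_ev <- if (nm %in% names(ev_counts)) ev_counts[[nm]] else 0L
    if (n_ev != rate_counts[[nm]]) {
      stop("internal consistency audit failed for event type ", nm, call. = FALSE)
    }
  }

  report <- list(
    provenance = list(package = "crabfate", seed = seed,
                      mode = if (sim_mode) "simulation" else "data",
                      include_hm_in_turnover = include_hm,
                      mmm = mmm, n_perm = n_perm),
    n_colonies = length(unique(ds$colony_table$colony_id)),
    n_analysis_set = length(fas$kept),
    event_counts = as.list(ev_counts),
    site_period_summary = sp,
    beinf = beinf_report,
    perm_tests = perm,
    community = community,
    thermal = thermal
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", null = "null")
  say("report written to %s", file.path(out_dir, "report.json"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
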