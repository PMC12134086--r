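test_that("event classification covers the three event types", {
  # unchanged colony: no events
  prev <- snap(c("d1", "d2", "d3"), "c1", rep("occupied", 3), tp = 0)
  curr <- snap(c("d1", "d2", "d3"), "c1", rep("occupied", 3), tp = 1)
  expect_equal(nrow(classify_events(prev, curr, transition = 1)), 0L)

  # a colony growing from 16 to 18 occupied dwellings needs >= 2 colonizations
  prev <- snap(sprintf("d%02d", 1:18), "c1",
               c(rep("occupied", 16), rep("not_yet_present", 2)), tp = 0)
  curr <- snap(sprintf("d%02d", 1:18), "c1", rep("occupied", 18), tp = 1)
  ev <- classify_events(prev, curr, transition = 1)
  expect_equal(sum(ev$event_type == "colonization"), 2L)

  # overgrowth is a background extinction
  prev <- snap("d1", "c1", "occupied", 0)
  curr <- snap("d1", "c1", "overgrown", 1)
  expect_equal(classify_events(prev, curr, transition = 1)$event_type, "extinction")

  # colony death converts all occupied dwellings to host-mortality losses
  prev <- snap(paste0("d", 1:5), "c1", rep("occupied", 5), tp = 0)
  curr <- snap(paste0("d", 1:5), "c1", rep("empty_on_dead_skeleton", 5), tp = 1)
  ev <- classify_events(prev, curr,
                        colonies_curr = colony_snap("c1", "dead_recent"),
                        transition = 1)
  expect_equal(ev$event_type, rep("host_mortality_extinction", 5))
})

test_that("illegal status transitions fail naming the dwelling", {
  prev <- snap("d7", "c1", "overgrown", 0)
  curr <- snap("d7", "c1", "occupied", 1)
  expect_error(classify_events(prev, curr), "d7")
  prev <- snap("d8", "c1", "occupied", 0)
  curr <- snap("d8", "c1", "not_yet_present", 1)
  expect_error(classify_events(prev, curr), "illegal")
})

test_that("turnover follows the (E' + C) / (D_prev + D_curr) formula", {
  expect_equal(compute_turnover(0, 0, 0, 3, 3), 0)
  expect_equal(compute_turnover(0, 1, 0, 1, 0), 100)
  expect_equal(compute_turnover(2, 1, 0, 4, 5), 100 / 3)
  # undefined, never coerced to zero
  expect_true(is.na(compute_turnover(0, 0, 0, 0, 0)))
  # the include_hm flag moves HM out of the numerator
  expect_equal(compute_turnover(1, 1, 2, 5, 3, include_hm = TRUE), 50)
  expect_equal(compute_turnover(1, 1, 2, 5, 3, include_hm = FALSE), 25)
  expect_error(compute_turnover(1, 0, 0, 4, 4), "accounting")
  expect_error(compute_turnover(-1, 0, 0, 1, 0), "non-negative")
})

test_that("mortality rates divide losses by the previous population", {
  expect_equal(compute_mortality_rates(2, 0, 10),
               data.frame(background_pct = 20, disturbance_pct = 0))
  expect_equal(compute_mortality_rates(0, 10, 10),
               data.frame(background_pct = 0, disturbance_pct = 100))
  expect_equal(compute_mortality_rates(1, 3, 8),
               data.frame(background_pct = 12.5, disturbance_pct = 37.5))
  r <- compute_mortality_rates(0, 0, 0)
  expect_true(is.na(r$background_pct) && is.na(r$disturbance_pct))
  expect_error(compute_mortality_rates(1, 0, 0), "inconsistency")
})

test_that("prevalence is the percentage of inhabited colonies", {
  expect_equal(compute_prevalence(rep(FALSE, 40)), 0)
  expect_equal(compute_prevalence(rep(TRUE, 40)), 100)
  expect_equal(compute_prevalence(c(rep(TRUE, 17), rep(FALSE, 23))), 42.5)
  expect_true(is.na(compute_prevalence(logical(0))))
})

test_that("the analysis-set filter keeps complete, ever-inhabited series", {
  alive <- function(tp) "alive"
  dead_from <- function(at) function(tp) {
    if (tp < at) "alive" else if (tp == at) "dead_recent" else "dead_old"
  }
  colonies <- data.frame(colony_id = c("keep", "dead", "never", "gap"),
                         site = "AS", transect = "AS-T1",
                         stringsAsFactors = FALSE)
  colonies$tps <- list(0:2, 0:2, 0:2, c(0L, 2L))   # "gap" misses T1 while alive
  colonies$state_fn <- list(alive, dead_from(2), alive, alive)
  histories <- list(
    k1 = list(colony = "keep", status = rep("occupied", 3), tps = 0:2),
    d1 = list(colony = "dead",
              status = c("occupied", "occupied", "empty_on_dead_skeleton"), tps = 0:2),
    g1 = list(colony = "gap", status = c("occupied", "occupied"), tps = c(0L, 2L))
  )
  ds <- hand_dataset(colonies, histories)
  out <- filter_analysis_set(ds)
  expect_setequal(out$kept, c("keep", "dead"))
  expect_equal(out$dropped$reason[out$dropped$colony_id == "never"], "never_inhabited")
  expect_equal(out$dropped$reason[out$dropped$colony_id == "gap"], "incomplete_series")
})

test_that("a colony dead mid-study is kept until mortality and counted once", {
  cfg <- small_config(seed = 11, p_host_full_mortality_pre = 0.2,
                      p_host_full_mortality_post = 0.2, p_initial_occupancy = 1)
  ds <- simulate_fate_tracking(cfg)
  tr <- transition_rates(ds)
  dead_ids <- unique(ds$colony_table$colony_id[
    ds$colony_table$mortality_state == "dead_recent"])
  expect_gt(length(dead_ids), 0)
  for (id in dead_ids) {
    rows <- tr[tr$colony_id == id, ]
    death_tr <- max(rows$transition)
    # no rate rows after death; the death transition loses everything to HM
    expect_equal(rows$transition, seq_len(death_tr))
    expect_equal(rows$D_curr[rows$transition == death_tr], 0L)
  }
})

test_that("rate aggregation reports mean, SE and n excluding undefined", {
  rates <- data.frame(site = "AS", transition = c(1, 1, 2, 2),
                      turnover_pct = c(0, 100, 40, NA))
  agg <- aggregate_rates(rates)
  r1 <- agg[agg$transition == 1, ]
  expect_equal(r1$mean, 50)
  expect_equal(r1$se, 50)
  expect_equal(r1$n, 2L)
  r2 <- agg[agg$transition == 2, ]
  expect_equal(r2$n, 1L)
  expect_equal(r2$mean, 40)
  expect_true(is.na(r2$se))
  empty <- aggregate_rates(data.frame(site = "AS", transition = 1,
                                      turnover_pct = NA_real_))
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$mean))
})

test_that("classification reproduces the simulator's ground truth", {
  for (seed in c(4, 21, 33)) {
    ds <- simulate_fate_tracking(small_config(seed = seed))
    ev <- classify_all_events(ds)
    key <- function(d) {
      d <- d[order(d$transition, d$dwelling_id),
             c("dwelling_id", "colony_id", "transition", "event_type")]
      rownames(d) <- NULL
      d
    }
    expect_identical(key(ev), key(ds$true_event_log))
  }
})

test_that("turnover and mortality invariants hold on simulated rates", {
  ds <- simulate_fate_tracking(small_config(seed = 14))
  tr <- transition_rates(ds)
  tv <- tr$turnover_pct[!is.na(tr$turnover_pct)]
  expect_true(all(tv >= 0 & tv <= 100))
  zero <- !is.na(tr$turnover_pct) & tr$turnover_pct == 0
  expect_true(all((tr$C + tr$E + tr$HM)[zero] == 0))
  both <- !is.na(tr$background_mortality_pct)
  expect_true(all(tr$background_mortality_pct[both] +
                    tr$disturbance_mortality_pct[both] <= 100 + 1e-9))
})
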