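#' Classify dwelling events between two consecutive snapshots
#'
#' Compares dwelling statuses at time point t (`prev`) and t + 1 (`curr`)
#' and classifies the three event types of the fate-tracking protocol:
#' colonization (`not_yet_present` -> `occupied`), background extinction
#' (`occupied` -> `overgrown`), and host-mortality-driven extinction
#' (`occupied` -> `empty_on_dead_skeleton`, or any occupied dwelling on a
#' colony newly recorded as dead).  Re-occupation of vacated dwellings is
#' treated as illegal: `overgrown` and `empty_on_dead_skeleton` are
#' absorbing states, and a transition out of them fails validation naming
#' the dwelling.
#'
#' @param prev Dwelling observations at t: data frame with `dwelling_id`,
#'   `colony_id`, `status`.
#' @param curr Dwelling observations at t + 1 (same schema).
#' @param colonies_curr Optional colony observations at t + 1 (with
#'   `colony_id`, `mortality_state`), used to catch occupied dwellings on
#'   newly dead colonies.
#' @param transition Transition index to stamp on the events (TR r is the
#'   interval T(r-1) -> Tr).
#' @return Data frame of events: `dwelling_id`, `colony_id`, `transition`,
#'   `event_type`.
#' @export
classify_events <- function(prev, curr, colonies_curr = NULL,
                            transition = NA_integer_) {
  statuses <- c("occupied", "overgrown", "empty_on_dead_skeleton", "not_yet_present")
  for (tb in list(prev, curr)) {
    if (!all(c("dwelling_id", "colony_id", "status") %in% names(tb))) {
      stop("dwelling snapshots need dwelling_id, colony_id, status", call. = FALSE)
    }
    bad <- setdiff(unique(tb$status), statuses)
    if (length(bad)) stop("unknown dwelling status: ", paste(bad, collapse = ", "),
                          call. = FALSE)
  }
  m <- merge(prev[, c("dwelling_id", "colony_id", "status")],
             curr[, c("dwelling_id", "colony_id", "status")],
             by = "dwelling_id", suffixes = c("_prev", "_curr"))
  if (any(m$colony_id_prev != m$colony_id_curr)) {
    stop("dwelling mapped to different colonies across snapshots: ",
         paste(m$dwelling_id[m$colony_id_prev != m$colony_id_curr], collapse = ", "),
         call. = FALSE)
  }
  # legality: absorbing states may not be left; not_yet_present may only
  # stay hidden or become occupied; occupied may not become not_yet_present
  legal <- list(
    occupied = c("occupied", "overgrown", "empty_on_dead_skeleton"),
    overgrown = "overgrown",
    empty_on_dead_skeleton = "empty_on_dead_skeleton",
    not_yet_present = c("not_yet_present", "occupied")
  )
  ok <- mapply(function(p, q) q %in% legal[[p]], m$status_prev, m$status_curr)
  if (!all(ok)) {
    b <- m[!ok, ][1L, ]
    stop(sprintf("illegal status transition %s -> %s for dwelling %s",
                 b$status_prev, b$status_curr, b$dwelling_id), call. = FALSE)
  }

  type <- rep(NA_character_, nrow(m))
  type[m$status_prev == "not_yet_present" & m$status_curr == "occupied"] <- "colonization"
  type[m$status_prev == "occupied" & m$status_curr == "overgrown"] <- "extinction"
  type[m$status_prev == "occupied" & m$status_curr == "empty_on_dead_skeleton"] <-
    "host_mortality_extinction"
  # any dwelling still marked occupied on a colony now dead counts as lost
  # to host mortality
  if (!is.null(colonies_curr)) {
    dead <- colonies_curr$colony_id[colonies_curr$mortality_state %in%
                                      c("dead_recent", "dead_old")]
    onto_dead <- m$status_prev == "occupied" & m$status_curr == "occupied" &
      m$colony_id_prev %in% dead
    type[onto_dead] <- "host_mortality_extinction"
  }
  keep <- !is.na(type)
  out <- data.frame(dwelling_id = m$dwelling_id[keep],
                    colony_id = m$colony_id_prev[keep],
                    transition = rep(as.integer(transition), sum(keep)),
                    event_type = type[keep],
                    stringsAsFactors = FALSE)
  # dwellings first recorded at t+1 (no row at t) are colonizations too
  new_rows <- curr[!(curr$dwelling_id %in% prev$dwelling_id) &
                     curr$status == "occupied", , drop = FALSE]
  if (nrow(new_rows)) {
    out <- rbind(out, data.frame(dwelling_id = new_rows$dwelling_id,
                                 colony_id = new_rows$colony_id,
                                 transition = rep(as.integer(transition), nrow(new_rows)),
                                 event_type = "colonization",
                                 stringsAsFactors = FALSE))
  }
  out[order(out$dwelling_id), , drop = FALSE]
}

#' Classify events across all transitions of a dataset
#'
#' @param x A `crab_dataset` (or list with `colony_table` and
#'   `dwelling_table`).
#' @return Event data frame across transitions TR1..TR(T-1).
#' @export
classify_all_events <- function(x) {
  tps <- sort(unique(x$dwelling_table$time_point))
  ev <- lapply(seq_len(length(tps) - 1L), function(i) {
    classify_events(
      prev = x$dwelling_table[x$dwelling_table$time_point == tps[i], ],
      curr = x$dwelling_table[x$dwelling_table$time_point == tps[i + 1L], ],
      colonies_curr = x$colony_table[x$colony_table$time_point == tps[i + 1L], ],
      transition = i
    )
  })
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

#' Turnover percentage of a colony over one transitional period
#'
#' `(E' + C) / (D_prev + D_curr) * 100`, where `E'` is extinctions alone or
#' extinctions plus host-mortality extinctions depending on `include_hm`.
#' Undefined (returned as `NA`, never coerced to 0) when both dwelling
#' counts are zero.
#'
#' @param C,E,HM Counts of colonizations, background extinctions and
#'   host-mortality extinctions over the period.  Vectorized.
#' @param D_prev,D_curr Occupied-dwelling counts at the bounding time
#'   points.
#' @param include_hm Should host-mortality extinctions enter the numerator?
#'   Default `TRUE` (all three event classes are turnover events).
#' @return Turnover percentage(s) in \[0, 100\], `NA` where undefined.
#' @export
compute_turnover <- function(C, E, HM, D_prev, D_curr, include_hm = TRUE) {
  if (any(c(C, E, HM, D_prev, D_curr) < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(D_curr != D_prev + C - E - HM, na.rm = TRUE)) {
    stop("accounting identity D_curr = D_prev + C - E - HM violated", call. = FALSE)
  }
  num <- C + E + if (include_hm) HM else 0
  den <- D_prev + D_curr
  ifelse(den == 0, NA_real_, 100 * num / den)
}

#' Background and disturbance mortality percentages
#'
#' Crab losses of each kind divided by the crabs present at the previous
#' time point: background = `E / D_prev * 100`, disturbance =
#' `HM / D_prev * 100`.  Undefined (`NA`) when `D_prev` is zero; a zero
#' denominator together with recorded losses is a data inconsistency and
#' errors.
#'
#' @param E,HM Counts of background and host-mortality extinctions.
#'   Vectorized.
#' @param D_prev Occupied dwellings at the previous time point.
#' @return Data frame with `background_pct` and `disturbance_pct`.
#' @export
compute_mortality_rates <- function(E, HM, D_prev) {
  if (any(c(E, HM, D_prev) < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  bad <- D_prev == 0 & (E + HM) > 0
  if (any(bad, na.rm = TRUE)) {
    stop("data inconsistency: losses recorded on a colony with no dwellings ",
         "at the previous time point", call. = FALSE)
  }
  data.frame(
    background_pct = ifelse(D_prev == 0, NA_real_, 100 * E / D_prev),
    disturbance_pct = ifelse(D_prev == 0, NA_real_, 100 * HM / D_prev)
  )
}

#' Gall crab prevalence in a transect
#'
#' Percentage of host colonies with at least one occupied dwelling.
#'
#' @param inhabited Logical vector: one entry per colony in the transect,
#'   `TRUE` if the colony holds >= 1 occupied dwelling at the time point.
#' @return Prevalence in \[0, 100\]; `NA` for an empty transect.
#' @export
compute_prevalence <- function(inhabited) {
  if (length(inhabited) == 0L) return(NA_real_)
  100 * mean(as.logical(inhabited))
}

#' Per-transect prevalence table
#'
#' @param x A `crab_dataset`.
#' @return Data frame: site, transect, time_point, n_colonies, prevalence_pct.
#'   Colonies recorded as dead count as uninhabited hosts no longer present
#'   and are excluded from the denominator.
#' @export
prevalence_table <- function(x) {
  occ <- x$dwelling_table[x$dwelling_table$status == "occupied", ]
  key <- paste(occ$colony_id, occ$time_point)
  ct <- x$colony_table[x$colony_table$mortality_state == "alive", ]
  ct$inhabited <- paste(ct$colony_id, ct$time_point) %in% key
  agg <- stats::aggregate(inhabited ~ site + transect + time_point, data = ct,
                          FUN = function(v) c(n = length(v), prev = 100 * mean(v)))
  data.frame(site = agg$site, transect = agg$transect,
             time_point = agg$time_point,
             n_colonies = agg$inhabited[, "n"],
             prevalence_pct = agg$inhabited[, "prev"])
}

#' Restrict a dataset to the statistical analysis set
#'
#' Keeps colonies with a complete observation series across all time
#' points — or complete until full mortality — that were inhabited by
#' crabs at least once during the study.  Returns the kept subset along
#' with the dropped colony ids and the reason for each.
#'
#' @param x A `crab_dataset`.
#' @return List: `dataset` (subset), `kept` (ids), `dropped` (data frame
#'   of `colony_id`, `reason` in `never_inhabited` / `incomplete_series`).
#' @export
filter_analysis_set <- function(x) {
  ct <- x$colony_table
  tps <- sort(unique(ct$time_point))
  occ <- x$dwelling_table[x$dwelling_table$status == "occupied", ]
  ever_inh <- unique(occ$colony_id)

  ids <- unique(ct$colony_id)
  complete <- vapply(ids, function(id) {
    rows <- ct[ct$colony_id == id, ]
    rows <- rows[order(rows$time_point), ]
    dead_at <- rows$time_point[rows$mortality_state %in% c("dead_recent", "dead_old")]
    # required coverage: every study time point up to (and including) the
    # first time point at which the colony is seen dead
    last_needed <- if (length(dead_at)) min(dead_at) else max(tps)
    needed <- tps[tps <= last_needed]
    all(needed %in% rows$time_point)
  }, logical(1))

  reason <- rep(NA_character_, length(ids))
  reason[!complete] <- "incomplete_series"
  reason[complete & !(ids %in% ever_inh)] <- "never_inhabited"
  keep <- is.na(reason)

  kept_ids <- ids[keep]
  sub <- dataset(
    colony_table = ct[ct$colony_id %in% kept_ids, ],
    dwelling_table = x$dwelling_table[x$dwelling_table$colony_id %in% kept_ids, ],
    true_event_log = x$true_event_log[x$true_event_log$colony_id %in% kept_ids, ]
  )
  list(dataset = sub, kept = kept_ids,
       dropped = data.frame(colony_id = ids[!keep], reason = reason[!keep],
                            stringsAsFactors = FALSE))
}

#' Per-colony, per-transition rate table
#'
#' Counts events and occupied dwellings per colony and transitional period
#' and derives turnover, background-mortality and disturbance-mortality
#' percentages.  Rows are emitted for every colony alive at the start of a
#' transition (a colony already dead has no dynamics left).
#'
#' @param x A `crab_dataset`.
#' @param events Optional pre-computed event table (defaults to
#'   [classify_all_events()] on `x`).
#' @param include_hm Passed to [compute_turnover()].
#' @return Data frame: colony_id, site, transect, transition, D_prev,
#'   D_curr, C, E, HM, turnover_pct, background_mortality_pct,
#'   disturbance_mortality_pct.
#' @export
transition_rates <- function(x, events = NULL, include_hm = TRUE) {
  if (is.null(events)) events <- classify_all_events(x)
  tps <- sort(unique(x$dwelling_table$time_point))
  n_tr <- length(tps) - 1L
  ct0 <- x$colony_table[x$colony_table$time_point == tps[1], ]
  meta <- ct0[, c("colony_id", "site", "transect")]

  occ <- x$dwelling_table[x$dwelling_table$status == "occupied", ]
  occ_count <- function(tp) {
    tb <- table(occ$colony_id[occ$time_point == tp])
    cnt <- as.integer(tb[meta$colony_id])
    cnt[is.na(cnt)] <- 0L
    cnt
  }
  alive_at <- function(tp) {
    a <- x$colony_table[x$colony_table$time_point == tp &
                          x$colony_table$mortality_state == "alive", "colony_id"]
    meta$colony_id %in% a
  }

  out <- lapply(seq_len(n_tr), function(r) {
    ev <- events[events$transition == r, ]
    cnt <- function(tp_type) {
      tb <- table(ev$colony_id[ev$event_type == tp_type])
      v <- as.integer(tb[meta$colony_id]); v[is.na(v)] <- 0L; v
    }
    d_prev <- occ_count(tps[r])
    d_curr <- occ_count(tps[r + 1L])
    C <- cnt("colonization"); E <- cnt("extinction"); HM <- cnt("host_mortality_extinction")
    keep <- alive_at(tps[r])
    mr <- compute_mortality_rates(E[keep], HM[keep], d_prev[keep])
    data.frame(
      colony_id = meta$colony_id[keep], site = meta$site[keep],
      transect = meta$transect[keep], transition = r,
      D_prev = d_prev[keep], D_curr = d_curr[keep],
      C = C[keep], E = E[keep], HM = HM[keep],
      turnover_pct = compute_turnover(C[keep], E[keep], HM[keep],
                                      d_prev[keep], d_curr[keep],
                                      include_hm = include_hm),
      background_mortality_pct = mr$background_pct,
      disturbance_mortality_pct = mr$disturbance_pct,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Aggregate colony rates into site x transition summaries
#'
#' Means, standard errors (sample SD / sqrt(n)) and cell sizes per
#' grouping cell, with undefined (`NA`) rates excluded.  Empty cells are
#' reported with `n = 0` and undefined mean.
#'
#' @param rates Output of [transition_rates()].
#' @param value Column to summarize (default `"turnover_pct"`).
#' @param by Grouping columns (default site and transition).
#' @return Data frame with grouping columns plus `n`, `mean`, `se`.
#' @export
aggregate_rates <- function(rates, value = "turnover_pct",
                            by = c("site", "transition")) {
  if (!value %in% names(rates)) stop("no column '", value, "' in rates", call. = FALSE)
  cells <- unique(rates[, by, drop = FALSE])
  cells <- cells[do.call(order, cells), , drop = FALSE]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- rep(TRUE, nrow(rates))
    for (b in by) sel <- sel & rates[[b]] == cells[i, b]
    v <- rates[[value]][sel]
    v <- v[!is.na(v)]
    n <- length(v)
    data.frame(cells[i, , drop = FALSE],
               n = n,
               mean = if (n > 0) mean(v) else NA_real_,
               se = if (n > 1) stats::sd(v) / sqrt(n) else NA_real_)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
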