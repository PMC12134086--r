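#' Two-sample permutation test for a difference in mean rates
#'
#' Tests whether colony-level rates differ between two pooled groups
#' (e.g. pre- vs post-disturbance mortality).  The statistic is
#' `mean(b) - mean(a)`; the null distribution comes from random relabeling
#' of the pooled values.  When the number of distinct relabelings
#' `choose(n_a + n_b, n_a)` does not exceed `exact_limit`, the full set is
#' enumerated and the p-value is exact; otherwise `n_perm` Monte-Carlo
#' relabelings are drawn and the add-one estimator
#' `(#{|stat*| >= |obs|} + 1) / (n_perm + 1)` is used.
#'
#' @param a,b Numeric vectors of colony-level rates (non-empty; `NA`s
#'   dropped).
#' @param n_perm Monte-Carlo permutations (default 9999; must be >= 99).
#' @param seed Optional seed for the Monte-Carlo draw.
#' @param alternative One of `"two_sided"`, `"less"`, `"greater"`
#'   (direction refers to `mean(b) - mean(a)`).
#' @param exact_limit Enumeration cutoff on the relabeling count
#'   (default 20000).
#' @return Object of class `perm_test_result`: list with `observed_stat`,
#'   `p_value`, `n_perm_used`, `exact`, `direction`, `alternative`.
#' @export
two_sample_perm_test <- function(a, b, n_perm = 9999L, seed = NULL,
                                 alternative = c("two_sided", "less", "greater"),
                                 exact_limit = 20000L) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (n_perm < 99L) stop("'n_perm' must be at least 99", call. = FALSE)
  pooled <- c(a, b)
  na <- length(a); nn <- length(pooled)
  obs <- mean(b) - mean(a)
  tot <- sum(pooled)

  stat_from_a_sum <- function(sa) {
    (tot - sa) / (nn - na) - sa / na
  }

  n_comb <- choose(nn, na)
  if (n_comb <= exact_limit) {
    combs <- utils::combn(nn, na)
    sa <- colSums(matrix(pooled[combs], nrow = na))
    stats_null <- stat_from_a_sum(sa)
    p <- perm_p(stats_null, obs, alternative, exact = TRUE)
    res <- list(observed_stat = obs, p_value = p, n_perm_used = n_comb,
                exact = TRUE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    stats_null <- vapply(seq_len(n_perm), function(i) {
      sa <- sum(pooled[sample.int(nn, na)])
      stat_from_a_sum(sa)
    }, numeric(1))
    p <- perm_p(stats_null, obs, alternative, exact = FALSE)
    res <- list(observed_stat = obs, p_value = p, n_perm_used = n_perm,
                exact = FALSE)
  }
  res$direction <- sign(obs)
  res$alternative <- alternative
  structure(res, class = "perm_test_result")
}

# p-value from a null sample; add-one correction in Monte-Carlo mode
perm_p <- function(stats_null, obs, alternative, exact) {
  eps <- 1e-12 * max(1, abs(obs))
  hits <- switch(alternative,
    two_sided = sum(abs(stats_null) >= abs(obs) - eps),
    greater = sum(stats_null >= obs - eps),
    less = sum(stats_null <= obs + eps)
  )
  if (exact) hits / length(stats_null) else (hits + 1) / (length(stats_null) + 1)
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s): stat = %.4f, p = %.4g [%s, %d %s]\n",
              x$alternative, x$observed_stat, x$p_value,
              if (x$exact) "exact enumeration" else "Monte-Carlo (add-one)",
              x$n_perm_used,
              if (x$exact) "relabelings" else "permutations"))
  invisible(x)
}

#' Multi-sample permutation test for a trend across transitional periods
#'
#' Tests whether mean rates differ across >= 2 ordered groups (e.g.
#' background mortality across TR1..TR4).  The statistic is the
#' between-group sum of squares of group means weighted by group size (the
#' ANOVA numerator); the null permutes group labels over the pooled
#' values.  The `direction` field reports the sign of the least-squares
#' slope of group means against the group index, supporting the
#' "declines/increases over time" reading of a significant result.  Full
#' enumeration of distinct label assignments is used when their count does
#' not exceed `exact_limit`.
#'
#' @param groups Named list of numeric vectors, ordered by period.
#' @inheritParams two_sample_perm_test
#' @return A `perm_test_result` (direction from the slope of group means).
#' @export
multi_sample_perm_test <- function(groups, n_perm = 9999L, seed = NULL,
                                   exact_limit = 20000L) {
  groups <- lapply(groups, function(v) v[!is.na(v)])
  groups <- groups[vapply(groups, length, integer(1)) > 0L]
  k <- length(groups)
  if (k < 2L) stop("need at least two non-empty groups", call. = FALSE)
  sizes <- vapply(groups, length, integer(1))
  pooled <- unlist(groups, use.names = FALSE)
  nn <- length(pooled)
  grand <- mean(pooled)
  labels <- rep(seq_len(k), sizes)

  bss <- function(values, lab) {
    mns <- vapply(split(values, factor(lab, levels = seq_len(k))), mean, numeric(1))
    sum(sizes * (mns - grand)^2)
  }
  obs <- bss(pooled, labels)
  mns <- vapply(groups, mean, numeric(1))
  slope <- stats::coef(stats::lm(mns ~ seq_len(k)))[2L]

  n_assign <- exp(lgamma(nn + 1) - sum(lgamma(sizes + 1)))
  if (n_assign <= exact_limit + 0.5) {
    assigns <- enumerate_assignments(nn, sizes)
    stats_null <- vapply(assigns, function(lab) bss(pooled, lab), numeric(1))
    p <- perm_p(stats_null, obs, "greater", exact = TRUE)
    res <- list(observed_stat = obs, p_value = p,
                n_perm_used = length(assigns), exact = TRUE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    stats_null <- vapply(seq_len(n_perm), function(i) {
      bss(pooled, labels[sample.int(nn)])
    }, numeric(1))
    p <- perm_p(stats_null, obs, "greater", exact = FALSE)
    res <- list(observed_stat = obs, p_value = p, n_perm_used = n_perm,
                exact = FALSE)
  }
  res$direction <- sign(unname(slope))
  res$alternative <- "greater"
  structure(res, class = "perm_test_result")
}

# all distinct assignments of n items into ordered groups of given sizes,
# as a list of label vectors
enumerate_assignments <- function(n, sizes) {
  recurse <- function(avail, sizes) {
    if (length(sizes) == 1L) return(list(list(avail)))
    out <- list()
    for (f in utils::combn(avail, sizes[1L], simplify = FALSE)) {
      for (r in recurse(setdiff(avail, f), sizes[-1L])) {
        out[[length(out) + 1L]] <- c(list(f), r)
      }
    }
    out
  }
  lapply(recurse(seq_len(n), sizes), function(pick) {
    lab <- integer(n)
    for (g in seq_along(pick)) lab[pick[[g]]] <- g
    lab
  })
}

#' Split transition rates into pre- and post-disturbance pools
#'
#' Pre = transitional periods up to and including the one arriving at the
#' disturbance time point (TR1..TR`d`); post = the rest.  Undefined (`NA`)
#' rates are excluded and counted.
#'
#' @param rates Output of [transition_rates()].
#' @param disturbance_time_point Disturbance time point index (default 2).
#' @param value Rate column to pool (default
#'   `"disturbance_mortality_pct"`).
#' @return List: `pre`, `post` (numeric vectors), `n_undefined`.
#' @export
pre_post_split <- function(rates, disturbance_time_point = 2L,
                           value = "disturbance_mortality_pct") {
  if (!value %in% names(rates)) stop("no column '", value, "' in rates", call. = FALSE)
  v <- rates[[value]]
  pre <- v[rates$transition <= disturbance_time_point]
  post <- v[rates$transition > disturbance_time_point]
  list(pre = pre[!is.na(pre)], post = post[!is.na(post)],
       n_undefined = sum(is.na(v)))
}
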