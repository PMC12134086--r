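#' Build a transect x genus community matrix from colony observations
#'
#' Counts live host colonies per (site, transect, time point) sample unit
#' and genus, for the baseline-survey time points.
#'
#' @param colony_table Colony observation table.
#' @param time_points Time points to include (default the baseline surveys
#'   1 and 3).
#' @return Count matrix with rownames `site|transect|T<t>` and an attached
#'   data frame of row metadata in `attr(, "meta")`.
#' @export
community_matrix <- function(colony_table, time_points = c(1L, 3L)) {
  ct <- colony_table[colony_table$time_point %in% time_points &
                       colony_table$mortality_state == "alive", ]
  if (nrow(ct) == 0L) stop("no live colonies at the requested time points", call. = FALSE)
  key <- paste(ct$site, ct$transect, paste0("T", ct$time_point), sep = "|")
  tab <- table(key, ct$genus)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  parts <- do.call(rbind, strsplit(rownames(m), "|", fixed = TRUE))
  attr(m, "meta") <- data.frame(site = parts[, 1], transect = parts[, 2],
                                time_point = parts[, 3], stringsAsFactors = FALSE)
  m
}

#' Hellinger transform of a count/abundance matrix
#'
#' `y_ij = sqrt(x_ij / rowsum_i)`: square roots of row-relative
#' abundances, giving rows of unit squared norm so Euclidean distances
#' between them behave well for community data.
#'
#' @param m Non-negative matrix with positive row sums.
#' @return Transformed matrix.
#' @export
hellinger <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  rs <- rowSums(m)
  if (any(rs == 0)) {
    bad <- rownames(m)[rs == 0]
    if (is.null(bad)) bad <- which(rs == 0)
    stop("all-zero row(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sqrt(sweep(m, 1, rs, "/"))
}

#' Relative abundances by row
#'
#' @param m Non-negative matrix with positive row sums.
#' @return Matrix with rows summing to 1.
#' @export
relative_abundance <- function(m) {
  m <- as.matrix(m)
  rs <- rowSums(m)
  if (any(rs == 0)) stop("all-zero row(s) in abundance matrix", call. = FALSE)
  sweep(m, 1, rs, "/")
}

#' Principal component analysis of a (Hellinger-transformed) matrix
#'
#' Column-centered singular value decomposition via [stats::prcomp()].
#' For cross-platform reproducibility each axis is sign-fixed so its
#' largest-magnitude loading is positive.
#'
#' @param m Numeric matrix, >= 2 rows.
#' @return List: `scores`, `loadings`, `variance_explained` (sums to 1).
#' @export
comm_pca <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least two rows", call. = FALSE)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  if (sum(pc$sdev^2) < 1e-12) {
    stop("zero total variance: all rows identical", call. = FALSE)
  }
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  list(scores = scores, loadings = loadings,
       variance_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' PERMANOVA with transect nested in site
#'
#' Partitions the total sum of squared distances sequentially into site,
#' transect-within-site, time-point and residual components
#' (McArdle-Anderson Gower-centring), with pseudo-F per term against the
#' residual mean square.  Permutation p-values respect the nesting: the
#' site term permutes transect-level units as wholes, the nested transect
#' term permutes rows within site, and the time term permutes rows within
#' transect.  Add-one Monte-Carlo p-values; with `exact = TRUE` (only for
#' a single unnested factor on small matrices) the full set of row
#' permutations is enumerated.
#'
#' @param d A `dist` object or symmetric distance matrix with zero
#'   diagonal.
#' @param site Factor of site labels per row.
#' @param transect Optional factor of transect labels (nested in site).
#' @param time_point Optional factor of time-point labels.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed.
#' @param exact Enumerate all row permutations (requires `transect` and
#'   `time_point` absent and <= 8 rows).
#' @return Object of class `permanova_result`: data frame `terms` with
#'   SS, df, R2, pseudo_F, p, plus `n_perm`.
#' @export
permanova <- function(d, site, transect = NULL, time_point = NULL,
                      n_perm = 999L, seed = NULL, exact = FALSE) {
  D <- as.matrix(d)
  if (!isTRUE(all.equal(D, t(D))) || any(abs(diag(D)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal", call. = FALSE)
  }
  n <- nrow(D)
  site <- factor(site)
  if (length(site) != n) stop("'site' length must match the matrix", call. = FALSE)
  if (any(table(site) < 2L)) {
    stop("each site level needs at least two rows (df error otherwise)", call. = FALSE)
  }
  if (!is.null(transect)) transect <- factor(transect)
  if (!is.null(time_point)) time_point <- factor(time_point)

  G <- gower_center(D)
  ss_total <- sum(diag(G))

  fit_terms <- function(site, transect, time_point) {
    df <- data.frame(site = site)
    terms <- list(site = ~ site)
    if (!is.null(transect)) {
      df$transect <- transect
      terms$transect_within_site <- ~ site + site:transect
    }
    if (!is.null(time_point)) {
      df$time_point <- time_point
      terms$time_point <- if (is.null(transect)) ~ site + time_point else
        ~ site + site:transect + time_point
    }
    ss <- numeric(length(terms)); dfree <- numeric(length(terms))
    prev_ss <- 0; prev_df <- 0
    for (i in seq_along(terms)) {
      X <- stats::model.matrix(terms[[i]], df)
      H <- hat_matrix(X)
      ss_model <- sum(H * G)               # tr(H G)
      df_model <- qr(X)$rank - 1L
      ss[i] <- ss_model - prev_ss
      dfree[i] <- df_model - prev_df
      prev_ss <- ss_model; prev_df <- df_model
    }
    list(ss = ss, df = dfree, names = names(terms),
         ss_res = ss_total - prev_ss, df_res = n - 1L - prev_df)
  }

  base <- fit_terms(site, transect, time_point)
  ms_res <- base$ss_res / base$df_res
  f_obs <- (base$ss / base$df) / ms_res

  # permutation schemes per term
  perm_idx <- function(term) {
    switch(term,
      site = {
        if (is.null(transect)) sample.int(n) else {
          # permute transect units as wholes
          unit <- interaction(site, transect, drop = TRUE)
          u_levels <- levels(unit)
          pu <- sample(u_levels)
          unlist(lapply(pu, function(u) which(unit == u)), use.names = FALSE)
        }
      },
      transect_within_site = within_perm(site),
      time_point = if (is.null(transect)) within_perm(site) else
        within_perm(interaction(site, transect, drop = TRUE))
    )
  }
  within_perm <- function(f) {
    idx <- seq_len(n)
    for (lv in levels(f)) {
      w <- which(f == lv)
      idx[w] <- w[sample.int(length(w))]
    }
    idx
  }

  k <- length(base$names)
  if (exact) {
    if (!is.null(transect) || !is.null(time_point) || n > 8L) {
      stop("'exact' enumeration supports only a single unnested factor on <= 8 rows",
           call. = FALSE)
    }
    perms <- all_permutations(n)
    f_null <- vapply(perms, function(idx) {
      ft <- fit_terms(site[idx], NULL, NULL)
      (ft$ss / ft$df) / ((ss_total - ft$ss) / (n - 1L - ft$df))
    }, numeric(1))
    p <- vapply(seq_len(k), function(i) {
      mean(f_null >= f_obs[i] - 1e-12)
    }, numeric(1))
    n_used <- length(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- numeric(k)
    for (b in seq_len(n_perm)) {
      for (i in seq_len(k)) {
        idx <- perm_idx(base$names[i])
        ft <- fit_terms(site[idx],
                        if (is.null(transect)) NULL else transect[idx],
                        if (is.null(time_point)) NULL else time_point[idx])
        f_b <- (ft$ss[i] / ft$df[i]) / (ft$ss_res / ft$df_res)
        if (f_b >= f_obs[i] - 1e-12) hits[i] <- hits[i] + 1
      }
    }
    p <- (hits + 1) / (n_perm + 1)
    n_used <- n_perm
  }

  terms_df <- data.frame(
    term = c(base$names, "residual"),
    ss = c(base$ss, base$ss_res),
    df = c(base$df, base$df_res),
    R2 = c(base$ss, base$ss_res) / ss_total,
    pseudo_F = c(f_obs, NA_real_),
    p = c(p, NA_real_),
    stringsAsFactors = FALSE
  )
  structure(list(terms = terms_df, n_perm = n_used, exact = exact,
                 ss_total = ss_total),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s, %d permutations)\n",
              if (x$exact) "exact enumeration" else "Monte-Carlo",
              x$n_perm))
  print(transform(x$terms, ss = round(ss, 4), R2 = round(R2, 4),
                  pseudo_F = round(pseudo_F, 4)), row.names = FALSE)
  invisible(x)
}

gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_permutations(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' SIMPER: per-genus contributions to between-group dissimilarity
#'
#' For every pair of rows in different groups, the per-genus Bray-Curtis
#' contribution is `|y_ij - y_ik| / sum_g (y_gj + y_gk)`; contributions
#' are averaged over all between-group pairs and ranked.  Their sum equals
#' the mean between-group Bray-Curtis dissimilarity.
#'
#' @param m Relative-abundance matrix (rows sum to 1).
#' @param groups Factor of group labels per row (>= 2 groups).
#' @return Object of class `simper_result`: data frame with `genus`,
#'   `average` (contribution to dissimilarity), `contribution_pct`,
#'   `cumulative_pct`, plus `mean_dissimilarity`.
#' @export
simper <- function(m, groups) {
  m <- as.matrix(m)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups", call. = FALSE)
  gch <- as.character(groups)
  pairs <- which(outer(gch, gch, "!=") & upper.tri(matrix(0, nrow(m), nrow(m))),
                 arr.ind = TRUE)
  contrib <- matrix(0, nrow(pairs), ncol(m))
  for (r in seq_len(nrow(pairs))) {
    j <- pairs[r, 1]; k <- pairs[r, 2]
    denom <- sum(m[j, ] + m[k, ])
    contrib[r, ] <- abs(m[j, ] - m[k, ]) / denom
  }
  avg <- colMeans(contrib)
  total <- sum(avg)
  o <- order(avg, decreasing = TRUE)
  gname <- colnames(m)
  if (is.null(gname)) gname <- paste0("g", seq_len(ncol(m)))
  out <- data.frame(
    genus = gname[o],
    average = avg[o],
    contribution_pct = 100 * avg[o] / total,
    stringsAsFactors = FALSE
  )
  out$cumulative_pct <- cumsum(out$contribution_pct)
  structure(list(contributions = out, mean_dissimilarity = total),
            class = "simper_result")
}

#' @export
print.simper_result <- function(x, ...) {
  cat(sprintf("SIMPER: mean between-group Bray-Curtis dissimilarity = %.4f\n",
              x$mean_dissimilarity))
  print(transform(x$contributions, average = round(average, 4),
                  contribution_pct = round(contribution_pct, 2),
                  cumulative_pct = round(cumulative_pct, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Hill diversity numbers of a composition
#'
#' `N0` = genus richness, `N1` = exponential of the Shannon-Wiener index,
#' `N2` = inverse Simpson index; for any composition
#' `1 <= N2 <= N1 <= N0`.
#'
#' @param counts Non-negative abundances with positive total.
#' @return List with `N0`, `N1`, `N2`.
#' @export
hill_numbers <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  tot <- sum(counts)
  if (tot == 0) stop("zero total abundance", call. = FALSE)
  p <- counts[counts > 0] / tot
  list(N0 = length(p),
       N1 = exp(-sum(p * log(p))),
       N2 = 1 / sum(p^2))
}
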