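#' Background-averaged effect estimate for one factor
#'
#' Averages a factor's effect observations over its distinct observed
#' backgrounds (each background weighted once), the estimable counterpart
#' of averaging over the full permutation set of non-target factors.  The
#' variance of the observations across backgrounds measures how much the
#' effect moves when its background moves; its inverse is the effect's
#' External Validity (EV).  Variance below \code{ev_floor} reports the
#' capped EV \code{1/ev_floor} with an \code{exact} flag, so noiseless
#' invariant effects serialize without infinities.
#'
#' @param observations data.frame of effect observations as produced by
#'   [effect_observations()] or [square_set_observations()] (columns
#'   \code{factor}, \code{background}, \code{dy}).
#' @param factor factor name to estimate.
#' @param min_obs minimum distinct backgrounds for a determinate estimate.
#' @param ev_floor variance floor for the EV cap (default 1e-12).
#' @return Object of class \code{"effect_estimate"}: list with
#'   \code{factor}, \code{effect}, \code{n_obs}, \code{variance} (mean
#'   squared deviation across backgrounds), \code{ev}, \code{exact},
#'   \code{label} (filled by [classify_factors()]),
#'   \code{from_complete_squares}.
#' @export
estimate_effect <- function(observations, factor, min_obs = 3L, ev_floor = 1e-12) {
  obs <- observations[observations$factor == factor, , drop = FALSE]
  if (nrow(obs) == 0) {
    out <- list(factor = factor, effect = NA_real_, n_obs = 0L,
                variance = NA_real_, ev = NA_real_, exact = FALSE,
                label = "undetermined", from_complete_squares = TRUE)
    class(out) <- "effect_estimate"
    return(out)
  }
  by_bg <- tapply(obs$dy, obs$background, mean)
  eff <- mean(by_bg)
  v <- mean((by_bg - eff)^2)   # population variance across backgrounds
  exact <- v < ev_floor
  ev <- if (exact) 1 / ev_floor else 1 / v
  out <- list(factor = factor, effect = eff, n_obs = length(by_bg),
              variance = v, ev = ev, exact = exact,
              label = if (length(by_bg) < min_obs) "undetermined" else NA_character_,
              from_complete_squares = TRUE)
  class(out) <- "effect_estimate"
  out
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("effect(%s) = %.4g over %d backgrounds; Var = %.4g; EV = %.4g%s\n",
              x$factor, x$effect, x$n_obs, x$variance, x$ev,
              if (x$exact) " (exact)" else ""))
  invisible(x)
}

#' Effect estimates for every factor in an observation set
#'
#' @inheritParams estimate_effect
#' @return data.frame with one row per factor: \code{factor},
#'   \code{effect}, \code{variance}, \code{ev}, \code{n_obs}, \code{exact},
#'   \code{label}.
#' @export
estimate_effects <- function(observations, min_obs = 3L, ev_floor = 1e-12) {
  facs <- sort(unique(observations$factor))
  rows <- lapply(facs, function(f) {
    e <- estimate_effect(observations, f, min_obs = min_obs, ev_floor = ev_floor)
    data.frame(factor = e$factor, effect = e$effect, variance = e$variance,
               ev = e$ev, n_obs = e$n_obs, exact = e$exact,
               label = e$label, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify factors as cause, confounder or spurious
#'
#' Under both-order observation (each factor pair seen with either member
#' in the other's background), effect-observation variances separate factor
#' roles: causes have variance near 0, confounders near
#' \eqn{0.25 \hat\rho_{ab} |\Delta y(a)|} of their root cause's effect, and
#' spurious factors near \eqn{0.5 |\Delta y(a)|}.  Each factor is assigned
#' the nearest expected value.  The root-cause candidate is the factor of
#' maximal |effect| among those rank-correlated with the target above
#' \code{rho_min} (falling back to the overall maximal-|effect| factor when
#' nothing is correlated, the spurious-candidate case).  Factors with fewer
#' than \code{min_obs} observations, or whose both-orders precondition
#' fails, are labelled undetermined.
#'
#' @param estimates data.frame from [estimate_effects()].
#' @param correlations symmetric matrix of pairwise rank correlations with
#'   factor names on both dimnames.
#' @param observations optional observation data.frame used to verify the
#'   both-orders precondition (target seen with root in background and vice
#'   versa); skipped when NULL.
#' @param rho_min correlation threshold for root-candidate eligibility.
#' @param min_obs minimum observations per factor.
#' @return The \code{estimates} data.frame with \code{label} and
#'   \code{root_candidate} columns filled.
#' @export
classify_factors <- function(estimates, correlations, observations = NULL,
                             rho_min = 0.1, min_obs = 3L) {
  if (is.null(dimnames(correlations)) ||
      !all(estimates$factor %in% rownames(correlations))) {
    stop("'correlations' must be a named matrix covering all factors")
  }
  est <- estimates
  est$root_candidate <- NA_character_
  for (i in seq_len(nrow(est))) {
    f <- est$factor[i]
    if (est$n_obs[i] < min_obs || is.na(est$variance[i])) {
      est$label[i] <- "undetermined"; next
    }
    others <- setdiff(est$factor, f)
    rho <- abs(correlations[f, others])
    corr_set <- others[!is.na(rho) & rho > rho_min]
    cand_pool <- if (length(corr_set)) corr_set else others
    eff_abs <- abs(est$effect[match(cand_pool, est$factor)])
    if (all(is.na(eff_abs))) { est$label[i] <- "undetermined"; next }
    root <- cand_pool[which.max(eff_abs)]
    est$root_candidate[i] <- root
    if (!is.null(observations) && !both_orders_seen(observations, f, root)) {
      est$label[i] <- "undetermined"; next
    }
    root_eff <- abs(est$effect[est$factor == root])
    expected <- c(cause = 0,
                  confounder = if (length(corr_set))
                    0.25 * abs(correlations[f, root]) * root_eff else NA_real_,
                  spurious = 0.5 * root_eff)
    expected <- expected[!is.na(expected)]
    est$label[i] <- names(expected)[which.min(abs(est$variance[i] - expected))]
  }
  est
}

both_orders_seen <- function(observations, f, root) {
  in_bg <- function(target, other) {
    bgs <- observations$background[observations$factor == target]
    any(vapply(strsplit(bgs, ","), function(b) other %in% b, logical(1)))
  }
  in_bg(f, root) && in_bg(root, f)
}

#' Column-wise error decomposition of square observations
#'
#' For each square column d (background size), computes the mean pairwise
#' squared difference \eqn{(\Delta_{ij} y - \Delta_{uv} y)^2} among effect
#' observations of the same factor in that column, pooled over a square
#' set.  Deeper columns expose observations to more unobserved variation,
#' so the per-column error is expected to grow roughly linearly in d; a
#' least-squares line through the per-column errors estimates that
#' gradient, and a method-of-moments one-way decomposition on the
#' factor-centered observations estimates the within-column noise
#' component.
#'
#' @param squares a \code{"square_set"}.
#' @param outcomes optional named outcome vector by unit id.
#' @return Object of class \code{"column_decomposition"}: list with
#'   \code{table} (per-column observation count, number of comparable
#'   pairs, mean pairwise squared error), \code{gradient} (intercept and
#'   slope of error vs column), \code{within} (pooled within-group noise
#'   variance), \code{monotone} (TRUE when the pairwise error is
#'   nondecreasing in d) and the underlying \code{observations}.
#' @export
column_decomposition <- function(squares, outcomes = NULL) {
  obs <- square_set_observations(squares, outcomes)
  empty <- list(table = NULL, gradient = NULL, within = NA_real_,
                monotone = NA, observations = obs)
  class(empty) <- "column_decomposition"
  if (nrow(obs) == 0) return(empty)
  tab <- column_pairwise_errors(obs)
  usable <- tab[!is.na(tab$pairwise_error), , drop = FALSE]
  if (nrow(usable) == 0) return(empty)
  grad <- NULL
  if (nrow(usable) >= 2) {
    fit <- stats::lm(pairwise_error ~ col, data = usable)
    grad <- list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]))
  }
  centered <- obs$dy - stats::ave(obs$dy, obs$col, obs$factor)
  ngrp <- nrow(unique(obs[, c("col", "factor")]))
  within <- if (nrow(obs) > ngrp) {
    sum(centered^2) / (nrow(obs) - ngrp)
  } else NA_real_
  monotone <- if (nrow(usable) >= 2) !is.unsorted(usable$pairwise_error) else NA
  out <- list(table = tab, gradient = grad, within = within,
              monotone = monotone, observations = obs)
  class(out) <- "column_decomposition"
  out
}

#' Per-column mean pairwise squared errors of effect observations
#'
#' The elementary computation behind [column_decomposition()], usable
#' directly on observations pooled over many square sets or simulation
#' replicates: within each column, observations of the same factor are
#' compared pairwise and the squared differences averaged.
#'
#' @param observations observation data.frame with \code{factor},
#'   \code{col}, \code{dy} columns.
#' @return data.frame with \code{col}, \code{n}, \code{n_pairs},
#'   \code{pairwise_error}.
#' @export
column_pairwise_errors <- function(observations) {
  cols <- sort(unique(observations$col))
  do.call(rbind, lapply(cols, function(d) {
    sub <- observations[observations$col == d, , drop = FALSE]
    err <- 0; np <- 0
    for (f in unique(sub$factor)) {
      v <- sub$dy[sub$factor == f]
      if (length(v) < 2) next
      # mean pairwise squared difference equals twice the sample variance
      err <- err + 2 * stats::var(v) * choose(length(v), 2)
      np <- np + choose(length(v), 2)
    }
    data.frame(col = d, n = nrow(sub), n_pairs = np,
               pairwise_error = if (np > 0) err / np else NA_real_)
  }))
}

#' @export
print.column_decomposition <- function(x, ...) {
  cat("column-wise pairwise error decomposition\n")
  if (!is.null(x$table)) print(x$table, row.names = FALSE)
  if (!is.null(x$gradient)) {
    cat(sprintf("  error vs column: intercept = %.4g, slope = %.4g; within-noise = %.4g\n",
                x$gradient$intercept, x$gradient$slope, x$within))
  }
  invisible(x)
}

#' Row-order adjusted effect observations
#'
#' A factor observed at column d of a square row has, as its direct
#' observation, the cumulative outcome difference from the row's reference
#' up to its cell; that difference carries the unobserved confounding of
#' every earlier gap in the row.  Conditioning on the observations prior in
#' the row order subtracts the cumulative observation at column d-1,
#' leaving the factor's own increment (exactly its effect in the noiseless
#' additive case, and never more confounded than the raw cumulative
#' observation when background variation accumulates along the row).
#' Factors first in their row have nothing earlier to condition on; their
#' raw and adjusted observations coincide.
#'
#' @param square a \code{"square"}.
#' @param outcomes optional named outcome vector by unit id.
#' @param factor factor name.
#' @return data.frame with \code{row}, \code{col}, \code{raw} (cumulative
#'   observation), \code{adjusted}.
#' @export
row_adjusted_effect <- function(square, outcomes = NULL, factor) {
  stopifnot(inherits(square, "square"))
  mp <- square$size
  cells <- square$cells
  gety <- function(row, col) {
    i <- which(cells$row == row & cells$col == col)
    u <- cells$unit_id[i]
    if (!is.null(outcomes)) as.numeric(outcomes[as.character(u)]) else cells$y[i]
  }
  pos_f <- match(factor, square$order)
  if (is.na(pos_f)) stop(sprintf("factor '%s' not in square order", factor))
  out <- lapply(seq_len(mp), function(r) {
    d <- ((pos_f - r) %% mp) + 1   # column where 'factor' is added in row r
    raw <- gety(r, d) - gety(r, 0)
    adj <- if (d >= 2) raw - (gety(r, d - 1) - gety(r, 0)) else raw
    data.frame(row = r, col = d, raw = raw, adjusted = adj)
  })
  do.call(rbind, out)
}

#' Variance-ratio F-test for equality of effect variances
#'
#' Classical two-sided variance-ratio test between two sets of effect
#' observations, with (n_a - 1, n_b - 1) degrees of freedom.  A
#' non-significant ratio (\code{p > alpha}) supports the two observation
#' sets sharing one underlying effect ("same effect").  A zero denominator
#' variance reports an infinite F with the \code{degenerate} flag.
#'
#' @param obs_a,obs_b numeric vectors of effect observations (length >= 2).
#' @param alpha significance level.
#' @return List with \code{F}, \code{df}, \code{p_value},
#'   \code{same_effect}, \code{degenerate}.
#' @export
f_test_effect_variance <- function(obs_a, obs_b, alpha = 0.05) {
  if (length(obs_a) < 2 || length(obs_b) < 2) {
    stop("both observation sets need at least 2 values")
  }
  va <- stats::var(obs_a); vb <- stats::var(obs_b)
  df <- c(length(obs_a) - 1, length(obs_b) - 1)
  if (vb == 0 && va == 0) {
    return(list(F = 1, df = df, p_value = 1, same_effect = TRUE, degenerate = TRUE))
  }
  if (vb == 0) {
    return(list(F = Inf, df = df, p_value = 0, same_effect = FALSE, degenerate = TRUE))
  }
  Fstat <- va / vb
  pv <- 2 * min(stats::pf(Fstat, df[1], df[2]),
                stats::pf(Fstat, df[1], df[2], lower.tail = FALSE))
  pv <- min(pv, 1)
  list(F = Fstat, df = df, p_value = pv, same_effect = pv > alpha,
       degenerate = FALSE)
}
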