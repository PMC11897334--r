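#' Ordinal gap profile of a sequentially observed sample
#'
#' Ranks the observed factors by first event time (a factor's event is a
#' -1 to +1 transition in time order), computes the gaps between
#' consecutive ranked first-event times, assigns every unit to the
#' recurring ordinal phase it was sampled in (the gap after the most
#' recent factor event: factor events recur as factors toggle, so gap
#' positions are revisited cyclically), and collects repeated-observation
#' outcome differences: for every distinct in-sample factor row observed
#' more than once, the outcome differences between consecutive
#' observations reflect only what changed out of sample, so they are the
#' sample's window on its unobserved backgrounds.
#'
#' @param sample sample data.frame with \code{t}, \code{f_*} and \code{y}
#'   columns.
#' @return Object of class \code{"gap_profile"}: list with
#'   \code{factor_ranks} (named rank vector, ties broken by factor name),
#'   \code{event_times}, \code{gaps} (widths between consecutive ranked
#'   event times), \code{gap_counts_observed} (units per gap interval
#'   1..m), \code{gap_distribution} (the multinomial \code{p} over gaps),
#'   \code{gap_effect_diffs} (mean repeated-observation outcome difference
#'   per gap) and \code{rep_diffs} (the underlying time-ordered
#'   data.frame with columns \code{t}, \code{gap}, \code{key}, \code{dy}).
#' @export
gap_profile <- function(sample) {
  if (!"t" %in% names(sample)) stop("gap_profile needs a time index column 't'")
  fcols <- grep("^f_", names(sample), value = TRUE)
  m <- length(fcols)
  if (m == 0) stop("sample has no factor columns (f_*)")
  ord <- order(sample$t)
  s <- sample[ord, , drop = FALSE]

  ev <- vapply(fcols, function(f) {
    i <- first_event(s[[f]])
    if (is.na(i)) Inf else s$t[i]
  }, numeric(1))
  # rank by event time, ties broken by factor name (fcols are sorted names)
  rk <- rank(ev, ties.method = "first")
  names(rk) <- fcols
  et_sorted <- sort(ev)
  gaps <- diff(et_sorted[is.finite(et_sorted)])

  # recurring gap phase of each unit: rank of the most recently fired
  # factor (a -1 -> +1 transition between consecutive units); 0 before the
  # first event
  Xs <- as.matrix(s[, fcols, drop = FALSE])
  n <- nrow(Xs)
  gap_of <- integer(n)
  phase <- 0L
  for (i in seq_len(n)) {
    fired <- if (i == 1) which(Xs[1, ] > 0) else which(Xs[i, ] > 0 & Xs[i - 1, ] < 0)
    if (length(fired)) phase <- max(rk[fired])
    gap_of[i] <- phase
  }
  counts <- tabulate(gap_of[gap_of >= 1], nbins = m)
  names(counts) <- as.character(seq_len(m))
  p <- if (sum(counts) > 0) counts / sum(counts) else rep(NA_real_, m)

  # repeated observations of identical in-sample factor rows; disjoint
  # consecutive pairs, so the differences are independent under i.i.d.
  # backgrounds (overlapping pairs would induce spurious serial dependence
  # and oversize the stationarity test)
  key <- apply(as.matrix(s[, fcols, drop = FALSE]), 1, paste, collapse = "")
  rep_t <- numeric(0); rep_gap <- integer(0); rep_key <- character(0); rep_dy <- numeric(0)
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    first <- idx[seq(1, length(idx) - 1, by = 2)]
    second <- idx[seq(2, length(idx), by = 2)]
    dy <- s$y[first] - s$y[second]   # earlier minus later
    rep_t <- c(rep_t, s$t[second])
    rep_gap <- c(rep_gap, gap_of[second])
    rep_key <- c(rep_key, rep(k, length(dy)))
    rep_dy <- c(rep_dy, dy)
  }
  rep_diffs <- data.frame(t = rep_t, gap = rep_gap, key = rep_key, dy = rep_dy,
                          stringsAsFactors = FALSE)
  rep_diffs <- rep_diffs[order(rep_diffs$t), , drop = FALSE]

  ged <- rep(NA_real_, m)
  if (nrow(rep_diffs)) {
    ag <- tapply(rep_diffs$dy, factor(rep_diffs$gap, levels = seq_len(m)), mean)
    ged[] <- as.numeric(ag)
  }

  out <- list(factor_ranks = rk, event_times = ev, gaps = gaps,
              gap_counts_observed = counts, gap_distribution = p,
              gap_effect_diffs = ged, rep_diffs = rep_diffs, m = m)
  class(out) <- "gap_profile"
  out
}

#' @export
print.gap_profile <- function(x, ...) {
  cat(sprintf("gap profile over %d factors, %d repeated-observation differences\n",
              x$m, nrow(x$rep_diffs)))
  cat("  ranks:", paste(names(sort(x$factor_ranks)), collapse = " < "), "\n")
  cat("  gap distribution p:", paste(signif(x$gap_distribution, 3), collapse = " "), "\n")
  invisible(x)
}

#' Stationarity and randomization tests on gap statistics
#'
#' Two tests certify that a (sub)sample's effect backgrounds are usable for
#' generalizable effect estimation.  Test 1 (stationarity): a Kendall-tau
#' trend test on the ranked second differences of repeated-observation
#' outcome differences; the null is a stationary gap distribution, and the
#' test passes when no trend is detected at level \code{alpha}.  Test 2
#' (randomization): the observed permutation-inversion count between the
#' first and last time-window rankings of per-gap outcome differences must
#' reach the expectation under i.i.d. multinomial gap reassignment
#' ([expected_inversions()] at the elapsed number of windows) minus two
#' Monte-Carlo standard deviations.  The literal exponential bound
#' \eqn{2 (\sum p_i^2)^{-t}} is also reported for inspection; it exceeds
#' the attainable inversion range for large \code{t}, so the calibrated
#' bound drives the pass flag.  Degenerate (all-tied) rankings are reported
#' untestable, not passed.
#'
#' @param profile a \code{"gap_profile"}.
#' @param subsample optional vector of time indices restricting the
#'   repeated-observation differences used (at least 2 required).
#' @param alpha significance level (default 0.05).
#' @param n_windows number of time windows for the randomization test
#'   (default: up to 8, at least 2, limited by the data).
#' @param mc_reps Monte-Carlo replicates for the threshold SD.
#' @return Object of class \code{"gap_test_report"} with the statistics,
#'   thresholds and \code{passed_stationarity} / \code{passed_randomization}
#'   flags (NA when untestable).
#' @export
randomization_tests <- function(profile, subsample = NULL, alpha = 0.05,
                                n_windows = NULL, mc_reps = 200L) {
  stopifnot(inherits(profile, "gap_profile"))
  rd <- profile$rep_diffs
  if (!is.null(subsample)) {
    if (length(subsample) < 2) stop("'subsample' must contain at least 2 time indices")
    rd <- rd[rd$t %in% subsample, , drop = FALSE]
  }
  m <- profile$m
  p <- profile$gap_distribution
  if (any(is.na(p))) p <- rep(1 / m, m)

  # --- test 1: stationarity (Kendall-tau on ranked second differences) ----
  stat_p <- NA_real_; stat_tau <- NA_real_
  d2_all <- numeric(0); t2_all <- numeric(0)
  for (k in unique(rd$key)) {
    i <- which(rd$key == k)
    if (length(i) < 2) next
    # disjoint pairs of first differences keep the second differences
    # independent under the stationary null
    a <- seq(1, length(i) - 1, by = 2)
    d2_all <- c(d2_all, rd$dy[i[a + 1]] - rd$dy[i[a]])
    t2_all <- c(t2_all, rd$t[i[a + 1]])
  }
  if (length(d2_all) >= 3 && stats::sd(d2_all) > 0) {
    # trend in the ranked magnitudes: background non-stationarity moves the
    # dispersion of the gap difference-of-differences
    ct <- suppressWarnings(
      stats::cor.test(t2_all, rank(abs(d2_all)), method = "kendall", exact = FALSE))
    stat_p <- ct$p.value; stat_tau <- unname(ct$estimate)
    passed_stationarity <- stat_p > alpha
  } else if (length(d2_all) >= 1 && stats::sd(d2_all) == 0) {
    passed_stationarity <- TRUE  # constant differences: trivially stationary
  } else {
    passed_stationarity <- NA
  }

  # --- test 2: randomization (inversions across window rankings) ----------
  inv_obs <- NA_integer_; threshold <- NA_real_; literal <- NA_real_
  passed_randomization <- NA
  if (nrow(rd) >= 2 * m) {
    if (is.null(n_windows)) {
      n_windows <- max(2L, min(8L, floor(nrow(rd) / m)))
    }
    wb <- stats::quantile(rd$t, probs = seq(0, 1, length.out = n_windows + 1),
                          names = FALSE, type = 1)
    win <- findInterval(rd$t, unique(wb), rightmost.closed = TRUE)
    win <- match(win, sort(unique(win)))
    rank_of_window <- function(w) {
      sub <- rd[win == w, , drop = FALSE]
      v <- vapply(seq_len(m), function(g) {
        x <- sub$dy[sub$gap == g]
        if (length(x)) mean(x) else NA_real_
      }, numeric(1))
      v
    }
    v1 <- rank_of_window(1); vT <- rank_of_window(max(win))
    tt <- max(win) - 1
    literal <- 2 * sum(p^2)^(-tt)
    e11 <- expected_inversions(p, m, tt)
    ok <- !is.na(v1) & !is.na(vT)
    if (sum(ok) >= 2 && stats::sd(v1[ok]) > 0 && stats::sd(vT[ok]) > 0) {
      r1 <- rank(v1[ok], ties.method = "first")
      rT <- rank(vT[ok], ties.method = "first")
      perm <- rT[order(r1)]
      inv_obs <- count_inversions(perm)
      sdev <- stats::sd(simulate_inversions(p, m, tt, reps = mc_reps))
      threshold <- e11 - 2 * sdev
      passed_randomization <- (e11 > 0) && (inv_obs >= threshold)
    } else {
      passed_randomization <- if (!is.na(e11) && e11 == 0) FALSE else NA
      threshold <- e11
    }
  }

  out <- list(stationarity_stat = list(tau = stat_tau, p_value = stat_p),
              inversion_count = inv_obs, threshold = threshold,
              literal_bound = literal, alpha = alpha,
              passed_stationarity = passed_stationarity,
              passed_randomization = isTRUE(passed_randomization))
  if (is.na(passed_randomization)) out$passed_randomization <- NA
  class(out) <- "gap_test_report"
  out
}

#' @export
print.gap_test_report <- function(x, ...) {
  cat("gap randomization report\n")
  cat(sprintf("  stationarity: tau = %.3g, p = %.3g -> %s\n",
              x$stationarity_stat$tau, x$stationarity_stat$p_value,
              flag_word(x$passed_stationarity)))
  cat(sprintf("  randomization: inversions = %s vs threshold %.3g (literal bound %.3g) -> %s\n",
              format(x$inversion_count), x$threshold, x$literal_bound,
              flag_word(x$passed_randomization)))
  invisible(x)
}

flag_word <- function(f) {
  if (is.na(f)) "untestable" else if (f) "pass" else "fail"
}

#' Total-variation distance of background counts to uniform
#'
#' Total-variation distance between the empirical distribution of observed
#' background states and the uniform distribution over the same support:
#' \eqn{\frac12 \sum_i |\hat p_i - 1/K|}.  Uniform counts give 0; all mass
#' on one of K states gives \eqn{1 - 1/K}.  With \code{normalize = TRUE}
#' the distance is min-max rescaled to [0, 1] against that worst case.
#'
#' @param background_counts non-negative counts over observed background
#'   states.
#' @param normalize rescale by the point-mass worst case.
#' @return Numeric scalar in [0, 1].
#' @export
variation_distance_to_uniform <- function(background_counts, normalize = FALSE) {
  if (length(background_counts) == 0 || sum(background_counts) == 0) {
    stop("'background_counts' must be non-empty with positive total")
  }
  if (any(background_counts < 0)) stop("counts must be non-negative")
  K <- length(background_counts)
  p <- background_counts / sum(background_counts)
  tv <- 0.5 * sum(abs(p - 1 / K))
  if (normalize && K > 1) tv <- tv / (1 - 1 / K)
  tv
}
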