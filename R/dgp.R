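#' Configuration for the binary-factor data-generating process
#'
#' Defines a generative model with \code{m} observed binary factors (coded
#' -1/+1), \code{q} unobserved factors, per-factor occurrence probabilities
#' and real effect sizes, an optional target correlation between each factor
#' and its lexicographic successor, and a number of time sub-periods across
#' which the unobserved part of the model is resampled (non-stationary
#' regimes).  Outcomes are drawn \eqn{y = +1} with probability
#' \eqn{\mathrm{sigmoid}(\sum_a x(a) \Delta y(a))}, the sum running over
#' observed and unobserved factors (the unobserved ones are the confounding
#' channel the estimators target), else \eqn{-1}.
#'
#' @param m number of observed factors.
#' @param q number of unobserved factors.
#' @param factor_probs length-\code{m} occurrence probabilities in [0, 1].
#' @param true_effects length-\code{m} real effects of observed factors.
#' @param hidden_probs length-\code{q} occurrence probabilities.
#' @param hidden_effects length-\code{q} real effects of unobserved factors.
#' @param rho_target length-\code{m-1} target rank correlations between each
#'   factor and its successor (0 = independent).
#' @param n_periods number of sampling sub-periods; unobserved structure is
#'   resampled at each period boundary while observed effects stay constant.
#' @param include_hidden_outcome if FALSE, the outcome sums over observed
#'   factors only (the literal outcome formula without the unobserved
#'   channel).
#' @param outcome \code{"sigmoid"} for -1/+1 Bernoulli(sigmoid) outcomes
#'   (classification regimes) or \code{"additive"} for real outcomes equal
#'   to the summed effects of the factors at +1 (exact recovery fixtures).
#' @param background_drift standard deviation, per present factor, of
#'   independent unobserved background increments added to additive
#'   outcomes: a unit with k factors at +1 accrues noise with variance
#'   \code{k * background_drift^2}.  This emulates slow sampling, where
#'   each additional exposure lets further unobserved events fall into the
#'   unit's background, and produces the linear-in-column confounding
#'   gradient across square columns.  Ignored for sigmoid outcomes.
#' @return An object of class \code{"dgp_config"}.
#' @seealso [dgp_balanced()], [dgp_unbalanced()], [dgp_correlated()],
#'   [simulate_sample()]
#' @export
dgp_config <- function(m, q, factor_probs = rep(0.5, m),
                       true_effects = rep(1, m),
                       hidden_probs = rep(0.5, q),
                       hidden_effects = rep(1, q),
                       rho_target = rep(0, max(m - 1, 0)),
                       n_periods = 1L,
                       include_hidden_outcome = TRUE,
                       outcome = c("sigmoid", "additive"),
                       background_drift = 0) {
  outcome <- match.arg(outcome)
  if (!is.numeric(background_drift) || background_drift < 0) {
    stop("'background_drift' must be a non-negative number")
  }
  check_count(m, "m"); if (m < 1) stop("'m' must be >= 1")
  check_count(q, "q")
  check_count(n_periods, "n_periods"); if (n_periods < 1) stop("'n_periods' must be >= 1")
  if (length(factor_probs) != m) stop("'factor_probs' must have length m")
  if (length(true_effects) != m) stop("'true_effects' must have length m")
  if (length(hidden_probs) != q) stop("'hidden_probs' must have length q")
  if (length(hidden_effects) != q) stop("'hidden_effects' must have length q")
  if (any(factor_probs < 0 | factor_probs > 1)) stop("'factor_probs' must lie in [0, 1]")
  if (any(hidden_probs < 0 | hidden_probs > 1)) stop("'hidden_probs' must lie in [0, 1]")
  if (length(rho_target) != max(m - 1, 0)) stop("'rho_target' must have length m - 1")
  if (any(rho_target < -1 | rho_target > 1)) stop("'rho_target' must lie in [-1, 1]")
  out <- list(m = m, q = q,
              factor_probs = as.numeric(factor_probs),
              true_effects = as.numeric(true_effects),
              hidden_probs = as.numeric(hidden_probs),
              hidden_effects = as.numeric(hidden_effects),
              rho_target = as.numeric(rho_target),
              n_periods = as.integer(n_periods),
              include_hidden_outcome = isTRUE(include_hidden_outcome),
              outcome = outcome,
              background_drift = background_drift)
  class(out) <- "dgp_config"
  out
}

#' @export
print.dgp_config <- function(x, ...) {
  cat(sprintf("DGP: m = %d observed, q = %d unobserved, %d period(s)\n",
              x$m, x$q, x$n_periods))
  cat(sprintf("  p(a) in [%.3g, %.3g]; effects in [%.3g, %.3g]; max |rho| = %.3g\n",
              min(x$factor_probs), max(x$factor_probs),
              min(x$true_effects), max(x$true_effects),
              if (length(x$rho_target)) max(abs(x$rho_target)) else 0))
  invisible(x)
}

#' Simulation presets: balanced, unbalanced, correlated
#'
#' \code{dgp_balanced()} is the stationary equiprobable regime: all
#' occurrence probabilities 0.5, all effects 1, \code{m = 10} observed and
#' \code{q = 3} unobserved factors.  \code{dgp_unbalanced()} draws
#' probabilities and effects Uniform(0, 1) and \code{q} uniform on 3..20,
#' over 10 sub-periods.  \code{dgp_correlated()} additionally draws a target
#' rank correlation Uniform(0, \code{rho_max}) between each factor and its
#' lexicographic successor.
#'
#' @param m,q factor counts (defaults are the standard study conditions).
#' @param rho_max upper bound of the uniform correlation draw, in [0, 1].
#' @param n_periods number of sub-periods for the non-stationary regimes.
#' @param seed optional integer seed set before the parameter draws.
#' @return A \code{"dgp_config"}.
#' @export
dgp_balanced <- function(m = 10L, q = 3L) {
  dgp_config(m = m, q = q)
}

#' @rdname dgp_balanced
#' @export
dgp_unbalanced <- function(m = 10L, n_periods = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- sample(3:20, 1)
  dgp_config(m = m, q = q,
             factor_probs = stats::runif(m),
             true_effects = stats::runif(m),
             hidden_probs = stats::runif(q),
             hidden_effects = stats::runif(q),
             n_periods = n_periods)
}

#' @rdname dgp_balanced
#' @export
dgp_correlated <- function(rho_max, m = 10L, n_periods = 10L, seed = NULL) {
  if (!is.numeric(rho_max) || rho_max < 0 || rho_max > 1) {
    stop("'rho_max' must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  cfg <- dgp_unbalanced(m = m, n_periods = n_periods)
  cfg$rho_target <- stats::runif(m - 1, 0, rho_max)
  cfg
}

#' Simulate a sample with known hidden truth
#'
#' Draws \code{n} units from a [dgp_config()].  Observed factors form a
#' Markov chain over the lexicographic factor order: each factor's
#' conditional occurrence probability given its predecessor is calibrated in
#' closed form so the pairwise correlation matches the configured target
#' (for -1/+1 variables Spearman and Pearson correlation coincide), clipped
#' to the Frechet-feasible range implied by the two marginals.  Unobserved
#' factors are independent.  In non-stationary regimes the hidden block
#' (count, probabilities, effects) is resampled at each period boundary;
#' observed-factor structure never changes.
#'
#' @param config a \code{"dgp_config"}.
#' @param n number of units.
#' @param seed optional integer seed set before drawing.
#' @return List with \code{sample}, a data.frame with columns
#'   \code{unit_id}, \code{t}, factor columns \code{f_a, f_b, ...} in
#'   \{-1, +1\} and outcome \code{y}; and \code{hidden}, a list with the
#'   hidden factor matrix, per-factor true effects (observed then hidden)
#'   and \code{regime_boundaries} (first time index of each period).
#' @examples
#' s <- simulate_sample(dgp_balanced(m = 4, q = 1), 50)
#' head(s$sample)
#' @export
simulate_sample <- function(config, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(config, "dgp_config"))
  check_count(n, "n"); if (n < 1) stop("'n' must be >= 1")
  m <- config$m; q <- config$q
  fnames <- factor_names(m)

  X <- matrix(NA_real_, n, m)
  p <- config$factor_probs
  X[, 1] <- ifelse(stats::runif(n) < p[1], 1, -1)
  if (m > 1) for (a in 2:m) {
    rho <- config$rho_target[a - 1]
    pa <- p[a - 1]; pb <- p[a]
    if (rho == 0 || pa %in% c(0, 1) || pb %in% c(0, 1)) {
      X[, a] <- ifelse(stats::runif(n) < pb, 1, -1)
    } else {
      s <- sqrt(pa * (1 - pa) * pb * (1 - pb))
      p11 <- clip(pa * pb + rho * s, max(0, pa + pb - 1), min(pa, pb))
      cond_plus <- p11 / pa                    # P(b=+1 | a=+1)
      cond_minus <- (pb - p11) / (1 - pa)      # P(b=+1 | a=-1)
      prev <- X[, a - 1] > 0
      pr <- ifelse(prev, cond_plus, cond_minus)
      X[, a] <- ifelse(stats::runif(n) < pr, 1, -1)
    }
  }

  # period structure: hidden block resampled per period
  bounds <- floor(seq(1, n + 1, length.out = config$n_periods + 1))
  hp <- config$hidden_probs; he <- config$hidden_effects
  qmax <- q
  U_list <- vector("list", config$n_periods)
  he_list <- vector("list", config$n_periods)
  eta_hidden <- numeric(n)
  add_hidden <- numeric(n)
  for (k in seq_len(config$n_periods)) {
    idx <- seq(bounds[k], bounds[k + 1] - 1)
    if (length(idx) == 0) { U_list[[k]] <- matrix(0, 0, 0); he_list[[k]] <- numeric(0); next }
    if (k > 1 && config$n_periods > 1 && q > 0) {
      qk <- sample(3:20, 1)
      hpk <- stats::runif(qk); hek <- stats::runif(qk)
    } else {
      qk <- q; hpk <- hp; hek <- he
    }
    qmax <- max(qmax, qk)
    Uk <- if (qk > 0) {
      matrix(ifelse(stats::runif(length(idx) * qk) < rep(hpk, each = length(idx)), 1, -1),
             length(idx), qk)
    } else matrix(0, length(idx), 0)
    U_list[[k]] <- Uk
    he_list[[k]] <- hek
    eta_hidden[idx] <- if (qk > 0) as.vector(Uk %*% hek) else 0
    add_hidden[idx] <- if (qk > 0) as.vector((Uk > 0) %*% hek) else 0
  }
  # pad hidden matrices to common width for the oracle view
  U <- matrix(NA_real_, n, qmax)
  for (k in seq_len(config$n_periods)) {
    idx <- seq(bounds[k], bounds[k + 1] - 1)
    Uk <- U_list[[k]]
    if (length(idx) && ncol(Uk) > 0) U[idx, seq_len(ncol(Uk))] <- Uk
  }

  if (config$outcome == "additive") {
    # noiseless real outcome: sum of effects of present (+1) factors
    y <- as.vector((X > 0) %*% config$true_effects)
    if (config$include_hidden_outcome) y <- y + add_hidden
    if (config$background_drift > 0) {
      k <- rowSums(X > 0)
      y <- y + stats::rnorm(n, 0, config$background_drift * sqrt(k))
    }
  } else {
    eta <- as.vector(X %*% config$true_effects)
    if (config$include_hidden_outcome) eta <- eta + eta_hidden
    y <- ifelse(stats::runif(n) < 1 / (1 + exp(-eta)), 1, -1)
  }

  samp <- data.frame(unit_id = seq_len(n), t = seq_len(n))
  for (a in seq_len(m)) samp[[fnames[a]]] <- X[, a]
  samp$y <- y

  hidden <- list(hidden_factors = U,
                 true_effects = c(stats::setNames(config$true_effects, fnames),
                                  if (q > 0) stats::setNames(config$hidden_effects,
                                                             paste0("u", seq_len(q)))),
                 hidden_effects_by_period = he_list,
                 regime_boundaries = bounds[-length(bounds)])
  list(sample = samp, hidden = hidden, config = config)
}

#' Oracle probability that a factor is confounded by unobserved events
#'
#' Given simulator output (hidden truth available), estimates
#' \eqn{P(U_{(1)} \le x)}: the fraction of observation windows in which at
#' least one unobserved factor's event precedes the event of observed factor
#' \code{x}.  A factor's event inside a window is its first -1 to +1
#' transition in time order (the first +1 position if it starts at +1 at the
#' window head is taken as an event at that position).  Windows are
#' consecutive time blocks of \code{window} units.  Windows where \code{x}
#' has no event are skipped; windows with no hidden event count as
#' unconfounded.
#'
#' @param hidden the \code{hidden} element returned by [simulate_sample()].
#' @param sample the \code{sample} data.frame returned by [simulate_sample()].
#' @param x factor name (e.g. \code{"f_a"}).
#' @param window window length in units (default 20).
#' @return Numeric scalar in [0, 1] (NaN if no window has an x event).
#' @export
confounding_probability <- function(hidden, sample, x, window = 20L) {
  if (!x %in% names(sample)) stop(sprintf("factor '%s' not in sample", x))
  n <- nrow(sample)
  U <- hidden$hidden_factors
  q <- if (is.null(U)) 0L else ncol(U)
  if (q == 0) return(0)
  ord <- order(sample$t)
  xv <- sample[[x]][ord]
  Uo <- U[ord, , drop = FALSE]
  starts <- seq(1, n, by = window)
  conf <- 0L; tot <- 0L
  for (s in starts) {
    idx <- s:min(s + window - 1, n)
    tx <- first_event(xv[idx])
    if (is.na(tx)) next
    tu <- suppressWarnings(min(vapply(seq_len(q), function(j) {
      fe <- first_event(Uo[idx, j]); if (is.na(fe)) Inf else fe
    }, numeric(1))))
    tot <- tot + 1L
    if (tu <= tx) conf <- conf + 1L
  }
  if (tot == 0) return(NaN)
  conf / tot
}

first_event <- function(v) {
  # first -1 -> +1 transition; a +1 at the head counts as an event there
  pos <- which(v > 0)
  if (length(pos) == 0) return(NA_real_)
  pos[1]
}

#' Write / read a simulated sample as CSV
#'
#' The sample CSV has columns \code{unit_id}, \code{t}, factor columns
#' \code{f_*} coded -1/+1 and outcome \code{y}.
#'
#' @param sample sample data.frame.
#' @param path file path.
#' @return \code{read_sample_csv} returns the data.frame;
#'   \code{write_sample_csv} returns \code{path} invisibly.
#' @export
write_sample_csv <- function(sample, path) {
  utils::write.csv(sample, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_csv
#' @export
read_sample_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  fcols <- grep("^f_", names(df), value = TRUE)
  if (length(fcols) == 0) stop("no factor columns (f_*) found")
  for (f in fcols) {
    if (!all(df[[f]] %in% c(-1, 1))) stop(sprintf("column '%s' must be coded -1/+1", f))
  }
  df
}

factor_names <- function(m) {
  base <- c(letters, paste0(rep(letters, each = 26), letters))
  paste0("f_", base[seq_len(m)])
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
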