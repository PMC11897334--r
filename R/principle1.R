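#' Square-row sampling construction for cause-confounder separation
#'
#' Monte-Carlo realization of the both-orders sampling conditions under
#' which effect-observation variances separate causes, confounders and
#' spurious factors.  Each replicate draws a uniform random circular order
#' of the factors; its rows are the cyclic rotations.  Walking a row, each
#' factor f is observed against the background of the factors added earlier
#' in the row: a treated and a control unit are drawn from the population
#' with f set to +1 / -1, the background factors *correlated with f* (rank
#' correlation above \code{rho_min}) pinned to +1, and all remaining
#' factors drawn at unit level from their conditional distribution given
#' the pinned values under the chain correlation structure.  The
#' observation is the treated-minus-control outcome difference.
#'
#' Pinning only the correlated background realizes the both-orders
#' requirement where it matters (order relative to a factor's correlated
#' companions) while leaving uncorrelated backgrounds free to vary, so that
#' a fully observed noiseless population yields pooled observation
#' variances near 0 for causes, near 0.25 |effect(root)| for a perfectly
#' correlated zero-effect confounder (it drags its root cause in exactly
#' the rows where the root is not yet in the background), and near
#' 0.5 |effect(root)| for an independent spurious factor (the root varies
#' freely on both sides of its observations).
#'
#' @param n_squares number of replicate squares.
#' @param effects named vector of true factor effects (outcome is the sum
#'   of effects of factors at +1; noiseless, q = 0).
#' @param rho named vector (length m-1) of chain correlations between
#'   consecutive factors (factor i with factor i+1), as in the correlated
#'   generative preset.
#' @param probs per-factor occurrence probabilities (default 0.5).
#' @param rho_min pinning threshold on |rho|.
#' @return Object of class \code{"principle1_sim"}: list with \code{obs}
#'   (data.frame square, row, factor, background, dy), \code{table}
#'   (per-factor pooled mean and population variance of observations) and
#'   the call parameters.
#' @examples
#' sim <- principle1_squares(50, effects = c(f_a = 1, f_b = 0, f_c = 0),
#'                           rho = c(1, 0))
#' sim$table
#' @export
principle1_squares <- function(n_squares, effects, rho,
                               probs = rep(0.5, length(effects)),
                               rho_min = 0.1) {
  m <- length(effects)
  if (m < 2) stop("need at least 2 factors")
  fnames <- names(effects)
  if (is.null(fnames)) { fnames <- factor_names(m); names(effects) <- fnames }
  if (length(rho) != m - 1) stop("'rho' must have length m - 1")
  if (length(probs) != m) stop("'probs' must have length m")

  # symmetric chain correlation lookup
  cor_of <- function(i, j) {
    if (abs(i - j) != 1) return(0)
    rho[min(i, j)]
  }
  correlated_with <- function(i) {
    out <- integer(0)
    if (i > 1 && abs(rho[i - 1]) > rho_min) out <- c(out, i - 1L)
    if (i < m && abs(rho[i]) > rho_min) out <- c(out, i + 1L)
    out
  }

  # draw a full +-1 unit conditional on fixed entries, walking the chain
  # outward from the fixed positions (each factor conditions on at most one
  # already-drawn neighbour)
  draw_unit <- function(fixed) {  # fixed: named numeric, +-1 or NA
    v <- fixed
    repeat {
      todo <- which(is.na(v))
      if (length(todo) == 0) return(v)
      progressed <- FALSE
      for (i in todo) {
        left <- if (i > 1 && !is.na(v[i - 1])) i - 1L else NA
        right <- if (i < m && !is.na(v[i + 1])) i + 1L else NA
        nb <- if (!is.na(left)) left else right
        if (is.na(nb)) next
        r <- cor_of(i, nb)
        pb <- probs[i]
        if (r == 0) {
          pr <- pb
        } else {
          pa <- probs[nb]
          s <- sqrt(pa * (1 - pa) * pb * (1 - pb))
          p11 <- clip(pa * pb + r * s, max(0, pa + pb - 1), min(pa, pb))
          pr <- if (v[nb] > 0) p11 / pa else (pb - p11) / (1 - pa)
        }
        v[i] <- if (stats::runif(1) < pr) 1 else -1
        progressed <- TRUE
      }
      if (!progressed) {  # isolated run with no fixed anchor: draw marginal
        i <- todo[1]
        v[i] <- if (stats::runif(1) < probs[i]) 1 else -1
      }
    }
  }

  outcome <- function(v) sum(effects[v > 0])

  sq <- integer(0); rw <- integer(0); fac <- character(0)
  bgs <- character(0); dys <- numeric(0)
  for (s in seq_len(n_squares)) {
    ord <- sample.int(m)
    for (r in seq_len(m)) {
      row_ord <- ord[((r - 1 + seq_len(m) - 1) %% m) + 1]
      for (k in seq_len(m)) {
        f <- row_ord[k]
        bg <- row_ord[seq_len(k - 1)]
        pin <- intersect(bg, correlated_with(f))
        base <- rep(NA_real_, m)
        base[pin] <- 1
        t_fix <- base; t_fix[f] <- 1
        c_fix <- base; c_fix[f] <- -1
        y1 <- outcome(draw_unit(t_fix))
        y0 <- outcome(draw_unit(c_fix))
        sq <- c(sq, s); rw <- c(rw, r); fac <- c(fac, fnames[f])
        bgs <- c(bgs, paste(sort(fnames[bg]), collapse = ","))
        dys <- c(dys, y1 - y0)
      }
    }
  }
  obs <- data.frame(square = sq, row = rw, factor = fac, background = bgs,
                    dy = dys, stringsAsFactors = FALSE)
  tab <- do.call(rbind, lapply(fnames, function(f) {
    v <- obs$dy[obs$factor == f]
    data.frame(factor = f, effect = mean(v),
               variance = mean((v - mean(v))^2),
               n_obs = length(v), stringsAsFactors = FALSE)
  }))
  out <- list(obs = obs, table = tab, effects = effects, rho = rho,
              probs = probs, rho_min = rho_min, n_squares = n_squares)
  class(out) <- "principle1_sim"
  out
}

#' @export
print.principle1_sim <- function(x, ...) {
  cat(sprintf("square-row sampling simulation: %d squares, %d factors\n",
              x$n_squares, length(x$effects)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Pooled Principle-1 variance ratio
#'
#' Ratio of a factor's pooled observation variance to the (absolute) true
#' effect of a root factor, the statistic whose expected values 0,
#' \eqn{0.25\rho}, and 0.5 separate causes, confounders and spurious
#' factors.
#'
#' @param sim a \code{"principle1_sim"}.
#' @param factor factor whose variance is measured.
#' @param root factor whose true effect scales the ratio.
#' @return Numeric scalar.
#' @export
principle1_ratio <- function(sim, factor, root) {
  stopifnot(inherits(sim, "principle1_sim"))
  v <- sim$table$variance[sim$table$factor == factor]
  e <- abs(sim$effects[[root]])
  if (e == 0) stop("root factor has zero true effect")
  v / e
}
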