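#' G-formula (standardization) effect estimate
#'
#' Stratifies the sample on all other factor columns W = X \ {a}, takes the
#' treated-minus-control outcome contrast within each stratum that contains
#' both treatment levels, and averages the contrasts weighted by stratum
#' probability.  Exact (up to sampling error) when there are no unobserved
#' factors; strata missing a treatment level are dropped and reported.
#'
#' @param sample sample data.frame with \code{f_*} columns and \code{y}.
#' @param factor treatment factor name.
#' @return List with \code{estimate}, \code{n_strata_used},
#'   \code{n_strata_dropped}, \code{coverage} (probability mass of usable
#'   strata).  \code{estimate} is NA with a diagnostic when no stratum is
#'   usable.
#' @export
g_formula <- function(sample, factor) {
  fcols <- grep("^f_", names(sample), value = TRUE)
  if (!factor %in% fcols) stop(sprintf("factor '%s' not in sample", factor))
  W <- setdiff(fcols, factor)
  a <- sample[[factor]]
  if (length(W) == 0) {
    return(list(estimate = diff_in_means(sample, factor),
                n_strata_used = 1L, n_strata_dropped = 0L, coverage = 1))
  }
  strat <- apply(as.matrix(sample[, W, drop = FALSE]), 1, paste, collapse = "")
  used <- 0L; dropped <- 0L; wsum <- 0; acc <- 0
  n <- nrow(sample)
  for (s in unique(strat)) {
    i <- strat == s
    yi <- sample$y[i]; ai <- a[i]
    if (any(ai > 0) && any(ai < 0)) {
      d <- mean(yi[ai > 0]) - mean(yi[ai < 0])
      w <- sum(i) / n
      acc <- acc + d * w; wsum <- wsum + w; used <- used + 1L
    } else {
      dropped <- dropped + 1L
    }
  }
  if (used == 0) {
    return(list(estimate = NA_real_, n_strata_used = 0L,
                n_strata_dropped = dropped, coverage = 0))
  }
  list(estimate = acc / wsum, n_strata_used = used,
       n_strata_dropped = dropped, coverage = wsum)
}

#' Unadjusted difference in means
#'
#' \eqn{mean(y | a = +1) - mean(y | a = -1)}; the no-adjustment comparator.
#'
#' @inheritParams g_formula
#' @return Numeric estimate (NA if a level is absent).
#' @export
diff_in_means <- function(sample, factor) {
  a <- sample[[factor]]
  if (is.null(a)) stop(sprintf("factor '%s' not in sample", factor))
  if (!any(a > 0) || !any(a < 0)) return(NA_real_)
  mean(sample$y[a > 0]) - mean(sample$y[a < 0])
}

#' Ridge-regularized linear predictor
#'
#' Closed-form ridge regression of the outcome on the factor columns,
#' fulfilling the pluggable predictor contract used by the sensitivity and
#' importance baselines and the experiment harness: a list with
#' \code{fit(X, y)} and \code{predict(X)} where X is the -1/+1 factor
#' matrix.  Deterministic; no access to hidden truth.
#'
#' @param lambda ridge penalty (default 1e-3).
#' @return Predictor contract (list with \code{fit} and \code{predict}).
#' @export
ridge_predictor <- function(lambda = 1e-3) {
  env <- new.env(parent = emptyenv())
  list(
    fit = function(X, y) {
      X1 <- cbind(1, as.matrix(X))
      P <- diag(ncol(X1)) * lambda
      P[1, 1] <- 0
      env$beta <- solve(crossprod(X1) + P, crossprod(X1, y))
      invisible(NULL)
    },
    predict = function(X) {
      if (is.null(env$beta)) stop("predictor not fitted")
      as.vector(cbind(1, as.matrix(X)) %*% env$beta)
    })
}

#' Sobol first-order sensitivity index of a factor
#'
#' \eqn{Var(E[\hat y | x_a]) / Var(\hat y)} with the conditional mean taken
#' over the factor's two levels, for a fitted predictor evaluated on the
#' sample.  Undefined (NA) when the predictor output has zero variance.
#'
#' @param predictor fitted predictor contract (see [ridge_predictor()]).
#' @param sample sample data.frame.
#' @param factor factor name.
#' @return Numeric index in [0, 1] (NA if undefined).
#' @export
sobol_first_order <- function(predictor, sample, factor) {
  fcols <- grep("^f_", names(sample), value = TRUE)
  if (!factor %in% fcols) stop(sprintf("factor '%s' not in sample", factor))
  X <- as.matrix(sample[, fcols, drop = FALSE])
  yhat <- predictor$predict(X)
  vt <- mean((yhat - mean(yhat))^2)
  if (vt == 0) return(NA_real_)
  lev <- X[, factor]
  mu <- tapply(yhat, lev, mean)
  pr <- tabulate(factor(lev, levels = names(mu))) / length(lev)
  vb <- sum(pr * (mu - mean(yhat))^2)
  vb / vt
}

#' Monte-Carlo permutation Shapley importance of a factor
#'
#' Shapley value of the factor for the predictor's output, with absent
#' factors mean-imputed: averaged over factor orderings, the change in
#' prediction when the factor is revealed on top of the factors preceding
#' it in the ordering, averaged over sample units.  With
#' \code{exhaustive = TRUE} all m! orderings are used (exact for small m,
#' satisfying the efficiency axiom exactly); otherwise \code{n_perms}
#' sampled orderings.
#'
#' @param predictor fitted predictor contract.
#' @param sample sample data.frame.
#' @param factor factor name.
#' @param n_perms number of sampled orderings (Monte-Carlo mode).
#' @param exhaustive use all orderings (m <= 7).
#' @return Numeric Shapley importance.
#' @export
shapley_importance <- function(predictor, sample, factor, n_perms = 100L,
                               exhaustive = FALSE) {
  fcols <- grep("^f_", names(sample), value = TRUE)
  if (!factor %in% fcols) stop(sprintf("factor '%s' not in sample", factor))
  X <- as.matrix(sample[, fcols, drop = FALSE])
  m <- ncol(X)
  mu <- colMeans(X)
  value_before_after <- function(before) {
    # mean prediction with 'before' revealed vs 'before + factor' revealed
    Xb <- matrix(mu, nrow(X), m, byrow = TRUE)
    colnames(Xb) <- fcols
    Xb[, before] <- X[, before]
    v0 <- mean(predictor$predict(Xb))
    Xb[, factor] <- X[, factor]
    v1 <- mean(predictor$predict(Xb))
    v1 - v0
  }
  if (exhaustive) {
    if (m > 7) stop("exhaustive mode limited to m <= 7")
    perms <- all_permutations(fcols)
    contribs <- vapply(perms, function(p) {
      pos <- match(factor, p)
      value_before_after(p[seq_len(pos - 1)])
    }, numeric(1))
    return(mean(contribs))
  }
  check_count(n_perms, "n_perms"); if (n_perms < 1) stop("'n_perms' must be >= 1")
  contribs <- vapply(seq_len(n_perms), function(i) {
    p <- fcols[sample.int(m)]
    pos <- match(factor, p)
    value_before_after(p[seq_len(pos - 1)])
  }, numeric(1))
  mean(contribs)
}

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in all_permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
  }
  out
}
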