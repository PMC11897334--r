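#' Fit background-averaged effects by square enumeration
#'
#' The package's central estimator.  Given an observational sample of
#' binary (-1/+1) factors and an outcome, it enumerates complete squares
#' around one or more reference units, turns across-unit differences into
#' effect observations under enumerated backgrounds, and estimates for each
#' factor its background-averaged effect, the variance of its observations
#' across backgrounds, its External Validity (inverse variance) and, when
#' requested, its Principle-1 classification as cause, confounder or
#' spurious.
#'
#' References are chosen (\code{reference = "auto"}) as the most frequent
#' distinct factor rows, which maximizes the chance of complete squares;
#' any vector of unit ids may be supplied instead.
#'
#' @param data data.frame with factor columns \code{f_*} coded -1/+1, an
#'   outcome column \code{y}, and optional \code{unit_id} and \code{t}
#'   columns (filled with row order when absent).
#' @param reference \code{"auto"} or unit id(s) to anchor squares at.
#' @param n_references number of automatic references tried.
#' @param max_size largest square size searched.
#' @param max_squares cap on squares per reference.
#' @param classify run [classify_factors()] on the estimates.
#' @param min_obs minimum backgrounds per determinate estimate.
#' @return Object of class \code{"effect_squares"}: list with
#'   \code{estimates} (per-factor table), \code{squares} (list of
#'   \code{"square_set"}, one per reference), \code{observations} (pooled
#'   effect observations), \code{correlations}, \code{data}, \code{call}.
#' @examples
#' set.seed(1)
#' s <- simulate_sample(dgp_balanced(m = 4, q = 0), 200)
#' fit <- effect_squares(s$sample)
#' coef(fit)
#' @export
effect_squares <- function(data, reference = "auto", n_references = 4L,
                           max_size = 6L, max_squares = 32L,
                           classify = TRUE, min_obs = 3L) {
  cl <- match.call()
  fcols <- grep("^f_", names(data), value = TRUE)
  if (length(fcols) == 0) stop("'data' has no factor columns (f_*)")
  if (!"y" %in% names(data)) stop("'data' has no outcome column 'y'")
  for (f in fcols) {
    if (!all(data[[f]] %in% c(-1, 1))) {
      stop(sprintf("factor column '%s' must be coded -1/+1", f))
    }
  }
  if (!"unit_id" %in% names(data)) data$unit_id <- seq_len(nrow(data))
  if (!"t" %in% names(data)) data$t <- seq_len(nrow(data))

  refs <- if (identical(reference, "auto")) {
    auto_references(data, fcols, n_references)
  } else {
    reference
  }
  square_sets <- lapply(refs, function(r) {
    enumerate_squares(data, r, max_size = max_size, max_squares = max_squares)
  })
  square_sets <- square_sets[vapply(square_sets,
                                    function(s) length(s$squares) > 0, logical(1))]
  obs <- if (length(square_sets)) {
    do.call(rbind, lapply(seq_along(square_sets), function(i) {
      o <- square_set_observations(square_sets[[i]])
      if (nrow(o)) o$reference <- square_sets[[i]]$reference
      o
    }))
  } else {
    e <- empty_observations(); e$square <- integer(0); e$reference <- numeric(0); e
  }

  est <- if (nrow(obs)) estimate_effects(obs, min_obs = min_obs) else
    data.frame(factor = fcols, effect = NA_real_, variance = NA_real_,
               ev = NA_real_, n_obs = 0L, exact = FALSE,
               label = "undetermined", stringsAsFactors = FALSE)
  missing_f <- setdiff(fcols, est$factor)
  if (length(missing_f)) {
    est <- rbind(est, data.frame(factor = missing_f, effect = NA_real_,
                                 variance = NA_real_, ev = NA_real_, n_obs = 0L,
                                 exact = FALSE, label = "undetermined",
                                 stringsAsFactors = FALSE))
    est <- est[order(est$factor), , drop = FALSE]
  }
  X <- as.matrix(data[, fcols, drop = FALSE])
  corr <- suppressWarnings(stats::cor(X, method = "spearman"))
  corr[is.na(corr)] <- 0; diag(corr) <- 1
  if (classify && nrow(obs)) {
    est <- classify_factors(est, corr, observations = obs, min_obs = min_obs)
  }
  out <- list(estimates = est, squares = square_sets, observations = obs,
              correlations = corr, data = data, factor_names = fcols,
              references = refs, call = cl)
  class(out) <- "effect_squares"
  out
}

auto_references <- function(data, fcols, n_references) {
  key <- apply(as.matrix(data[, fcols, drop = FALSE]), 1, paste, collapse = "")
  freq <- sort(table(key), decreasing = TRUE)
  keys <- names(freq)[seq_len(min(n_references, length(freq)))]
  vapply(keys, function(k) {
    i <- which(key == k)
    i <- i[order(data$t[i], data$unit_id[i])][1]
    data$unit_id[i]
  }, numeric(1), USE.NAMES = FALSE)
}

#' @export
print.effect_squares <- function(x, ...) {
  cat("Background-averaged effects from square enumeration\n\n")
  nsq <- sum(vapply(x$squares, function(s) length(s$squares), integer(1)))
  cat(sprintf("  %d square(s) over %d reference(s), %d effect observations\n\n",
              nsq, length(x$references), nrow(x$observations)))
  print(x$estimates, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.effect_squares <- function(object, ...) {
  nsq <- sum(vapply(object$squares, function(s) length(s$squares), integer(1)))
  sizes <- unlist(lapply(object$squares,
                         function(s) vapply(s$squares, `[[`, integer(1), "size")))
  out <- list(estimates = object$estimates, n_squares = nsq,
              sizes = sizes, n_obs = nrow(object$observations),
              references = object$references,
              decomposition = if (length(object$squares))
                column_decomposition(object$squares[[1]]) else NULL)
  class(out) <- "summary.effect_squares"
  out
}

#' @export
print.summary.effect_squares <- function(x, ...) {
  cat("Square-enumeration effect model\n\n")
  cat(sprintf("squares: %d (sizes %s); observations: %d; references: %s\n\n",
              x$n_squares,
              if (length(x$sizes)) paste(range(x$sizes), collapse = "-") else "none",
              x$n_obs, paste(x$references, collapse = ", ")))
  print(x$estimates, row.names = FALSE, digits = 4)
  if (!is.null(x$decomposition) && !is.null(x$decomposition$table)) {
    cat("\nper-column pairwise error (first reference):\n")
    print(x$decomposition$table, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
coef.effect_squares <- function(object, ...) {
  stats::setNames(object$estimates$effect, object$estimates$factor)
}

#' Predicted outcomes from estimated effects
#'
#' Linear prediction from the additive effect model: the sum of estimated
#' effects of the factors at +1, centered to the training outcome mean.
#' Factors without a determinate estimate contribute 0.
#'
#' @param object an \code{"effect_squares"} fit.
#' @param newdata data.frame with the factor columns (defaults to training
#'   data).
#' @param type \code{"response"} for the linear score, \code{"class"} for
#'   its sign.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.effect_squares <- function(object, newdata = NULL,
                                   type = c("response", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  fcols <- object$factor_names
  beta <- stats::setNames(object$estimates$effect, object$estimates$factor)[fcols]
  beta[is.na(beta)] <- 0
  X <- as.matrix(newdata[, fcols, drop = FALSE]) > 0
  sc <- as.vector(X %*% beta)
  # center to the training outcome mean
  sc <- sc + mean(object$data$y) -
    mean(as.vector((as.matrix(object$data[, fcols, drop = FALSE]) > 0) %*% beta))
  if (type == "class") sign(sc) else sc
}

#' @export
residuals.effect_squares <- function(object, ...) {
  object$data$y - predict.effect_squares(object)
}

#' Simulate outcomes from a fitted effect model
#'
#' Draws new -1/+1 outcomes from the sigmoid outcome model at the
#' estimated effects, on the training factor rows.
#'
#' @param object an \code{"effect_squares"} fit.
#' @param nsim number of simulated outcome vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data.frame with \code{nsim} columns of simulated outcomes.
#' @export
simulate.effect_squares <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fcols <- object$factor_names
  beta <- stats::setNames(object$estimates$effect, object$estimates$factor)[fcols]
  beta[is.na(beta)] <- 0
  eta <- as.vector(as.matrix(object$data[, fcols, drop = FALSE]) %*% beta)
  p <- 1 / (1 + exp(-eta))
  out <- as.data.frame(lapply(seq_len(nsim), function(i) {
    ifelse(stats::runif(length(p)) < p, 1, -1)
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted effect model
#'
#' Left panel: estimated effects with +-1 sd of their background
#' observations; right panel: per-column mean pairwise squared error of the
#' first reference's squares (the confounding gradient across columns).
#'
#' @param x an \code{"effect_squares"} fit.
#' @param ... passed to \code{barplot}.
#' @export
plot.effect_squares <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  est <- x$estimates
  mid <- graphics::barplot(est$effect, names.arg = est$factor, las = 2,
                           ylab = "effect", main = "background-averaged effects", ...)
  sdv <- sqrt(est$variance)
  ok <- !is.na(sdv)
  graphics::arrows(mid[ok], est$effect[ok] - sdv[ok],
                   mid[ok], est$effect[ok] + sdv[ok],
                   angle = 90, code = 3, length = 0.03)
  if (length(x$squares)) {
    dec <- column_decomposition(x$squares[[1]])
    if (!is.null(dec$table)) {
      graphics::plot(dec$table$col, dec$table$pairwise_error, type = "b",
                     xlab = "square column d", ylab = "mean pairwise sq. error",
                     main = "column error gradient")
    }
  }
  invisible(x)
}
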