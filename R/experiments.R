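#' Experiment configuration
#'
#' Bundles the knobs shared by the scaled simulation experiments: the
#' generative preset, sample size, transversal methods, replicate count and
#' seed.  Presets: \code{"balanced"} (m = 10 equiprobable factors, effects
#' 1, q = 3), \code{"unbalanced"}, \code{"correlated"} (with
#' \code{rho_max}), each optionally with a noiseless additive outcome.
#'
#' @param preset one of \code{"balanced"}, \code{"unbalanced"},
#'   \code{"correlated"}.
#' @param n sample size per replicate.
#' @param m number of observed factors.
#' @param rho_max correlation bound for the correlated preset.
#' @param methods transversal methods to compare.
#' @param replicates number of simulation replicates.
#' @param seed integer seed.
#' @param n_references references pooled when enumerating squares.
#' @param n_grid prefix sizes at which curves are evaluated (defaults to 8
#'   points up to n/2, the full internal section).
#' @param outcome outcome model passed to the preset.
#' @param out_dir optional directory for CSV results and a manifest.
#' @return List of class \code{"experiment_config"}.
#' @export
experiment_config <- function(preset = c("balanced", "unbalanced", "correlated"),
                              n = 512L, m = 10L, rho_max = 0.5,
                              methods = c("square", "random"),
                              replicates = 20L, seed = 1L,
                              n_references = 12L, n_grid = NULL,
                              outcome = c("sigmoid", "additive"),
                              out_dir = NULL) {
  preset <- match.arg(preset)
  outcome <- match.arg(outcome)
  if (replicates < 1) stop("'replicates' must be >= 1")
  ok <- c("random", "square", "square_column", "tsp")
  if (!all(methods %in% ok)) stop("unknown transversal method")
  if (is.null(n_grid)) {
    n_grid <- unique(round(seq(max(24, n / 16), n / 2, length.out = 8)))
  }
  structure(list(preset = preset, n = as.integer(n), m = as.integer(m),
                 rho_max = rho_max, methods = methods,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 n_references = as.integer(n_references),
                 n_grid = as.integer(n_grid), outcome = outcome,
                 out_dir = out_dir),
            class = "experiment_config")
}

pooled_squares <- function(data, n_references, max_size = 4L, max_squares = 16L) {
  fcols <- grep("^f_", names(data), value = TRUE)
  refs <- auto_references(data, fcols, n_references)
  sets <- lapply(refs, function(r) {
    enumerate_squares(data, r, max_size = max_size, max_squares = max_squares)
  })
  sets <- sets[vapply(sets, function(s) length(s$squares) > 0, logical(1))]
  if (length(sets) == 0) return(NULL)
  out <- list(squares = do.call(c, lapply(sets, `[[`, "squares")),
              reference = sets[[1]]$reference,
              factor_names = fcols, m = length(fcols))
  class(out) <- "square_set"
  out$member_histogram <- member_histogram(out)
  out
}

draw_preset <- function(config) {
  cfg <- switch(config$preset,
    balanced = dgp_balanced(m = config$m),
    unbalanced = dgp_unbalanced(m = config$m),
    correlated = dgp_correlated(config$rho_max, m = config$m))
  cfg$outcome <- config$outcome
  cfg
}

#' Accuracy curves by transversal order
#'
#' For each replicate, simulates a sample, splits its units 50/50 at random
#' into an internal and an external section, orders the internal section
#' under each configured transversal (squares enumerated on the internal
#' section), and trains the reference ridge classifier on growing prefixes.
#' Internal accuracy is 4-fold cross-validation inside the prefix; external
#' accuracy is measured on the held-out external section.  The
#' golden-ratio recommended size for the sample's rarest factor is attached
#' for marking on plots.
#'
#' @param config an [experiment_config()].
#' @return data.frame of class \code{"curve_result"} with columns
#'   \code{replicate}, \code{method}, \code{n}, \code{acc_internal},
#'   \code{acc_external}; attribute \code{n_recommended}.
#' @export
run_ev_curves <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  rows <- list()
  nrec <- NA_real_
  for (rep in seq_len(config$replicates)) {
    cfg <- draw_preset(config)
    sim <- simulate_sample(cfg, config$n)
    s <- sim$sample
    int_idx <- sort(sample.int(nrow(s), floor(nrow(s) / 2)))
    internal <- s[int_idx, , drop = FALSE]
    external <- s[-int_idx, , drop = FALSE]
    p_rare <- min(colMeans(internal[, grep("^f_", names(internal)), drop = FALSE] > 0))
    if (p_rare > 0) {
      nrec <- recommended_sample_size(config$m, p_rare, many_squares = TRUE)$n_many
    }
    sq <- if (any(c("square", "square_column") %in% config$methods)) {
      pooled_squares(internal, config$n_references,
                     max_size = min(4L, config$m))
    } else NULL
    for (meth in config$methods) {
      tv <- try(transversal(internal, sq, meth), silent = TRUE)
      if (inherits(tv, "try-error")) next
      ordered <- internal[match(tv$order, internal$unit_id), , drop = FALSE]
      for (k in config$n_grid) {
        if (k > nrow(ordered)) next
        train <- ordered[seq_len(k), , drop = FALSE]
        accs <- try(learn_and_score(train, external), silent = TRUE)
        if (inherits(accs, "try-error")) next
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = rep, method = meth, n = k,
          acc_internal = accs$internal, acc_external = accs$external)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_recommended") <- nrec
  class(out) <- c("curve_result", class(out))
  write_experiment(out, config, "ev_curves")
  out
}

learn_and_score <- function(train, external, folds = 4L) {
  fcols <- grep("^f_", names(train), value = TRUE)
  Xtr <- as.matrix(train[, fcols, drop = FALSE]); ytr <- train$y
  # internal: k-fold CV inside the prefix
  fold <- rep(seq_len(folds), length.out = nrow(train))
  acc_int <- mean(vapply(seq_len(folds), function(f) {
    tr <- fold != f
    if (sum(tr) < 2 || sum(!tr) < 1) return(NA_real_)
    pred <- ridge_fit_predict(Xtr[tr, , drop = FALSE], ytr[tr],
                              Xtr[!tr, , drop = FALSE])
    mean(sign(pred) == sign(ytr[!tr]))
  }, numeric(1)), na.rm = TRUE)
  Xex <- as.matrix(external[, fcols, drop = FALSE])
  pred <- ridge_fit_predict(Xtr, ytr, Xex)
  acc_ext <- mean(sign(pred) == sign(external$y))
  list(internal = acc_int, external = acc_ext)
}

ridge_fit_predict <- function(Xtr, ytr, Xte) {
  pr <- ridge_predictor(lambda = 1e-2)
  pr$fit(Xtr, ytr)
  pr$predict(Xte)
}

#' Effect-estimation error curves
#'
#' For each replicate, simulates a sample with known true effects and
#' estimates all factor effects on growing ordered prefixes under each
#' transversal, with the square estimator ([effect_squares()]) and the
#' baselines (g-formula and difference in means); reports the mean squared
#' error against the hidden true effects.  Prefixes where an estimator
#' returns no determinate estimate are recorded as missing, not
#' fabricated.
#'
#' @param config an [experiment_config()] (methods \code{"random"} /
#'   \code{"square_column"} are typical here).
#' @return data.frame of class \code{"curve_result"}: \code{replicate},
#'   \code{method}, \code{estimator}, \code{n}, \code{mse}.
#' @export
run_effect_mse <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  rows <- list()
  for (rep in seq_len(config$replicates)) {
    cfg <- draw_preset(config)
    sim <- simulate_sample(cfg, config$n)
    s <- sim$sample
    fcols <- grep("^f_", names(s), value = TRUE)
    truth <- cfg$true_effects
    sq <- pooled_squares(s, config$n_references, max_size = min(4L, config$m))
    for (meth in config$methods) {
      tv <- try(transversal(s, sq, meth), silent = TRUE)
      if (inherits(tv, "try-error")) next
      ordered <- s[match(tv$order, s$unit_id), , drop = FALSE]
      for (k in config$n_grid) {
        if (k > nrow(ordered)) next
        pre <- ordered[seq_len(k), , drop = FALSE]
        # square estimator
        fit <- try(effect_squares(pre, classify = FALSE, max_size = 4L), silent = TRUE)
        if (!inherits(fit, "try-error")) {
          est <- stats::setNames(fit$estimates$effect, fit$estimates$factor)[fcols]
          mse <- if (all(is.na(est))) NA_real_ else
            mean((est - truth)^2, na.rm = TRUE)
          rows[[length(rows) + 1L]] <- data.frame(replicate = rep, method = meth,
            estimator = "squares", n = k, mse = mse)
        }
        for (bl in c("g_formula", "diff_in_means")) {
          est <- vapply(fcols, function(f) {
            v <- if (bl == "g_formula") g_formula(pre, f)$estimate else
              diff_in_means(pre, f)
            if (is.null(v) || length(v) == 0) NA_real_ else v
          }, numeric(1))
          rows[[length(rows) + 1L]] <- data.frame(replicate = rep, method = meth,
            estimator = bl, n = k,
            mse = if (all(is.na(est))) NA_real_ else mean((est - truth)^2, na.rm = TRUE))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("curve_result", class(out))
  write_experiment(out, config, "effect_mse")
  out
}

#' Recommended-size versus optimal-split experiment
#'
#' For each replicate, simulates a sample of n' units, trains the reference
#' classifier on 100 nested random subsamples of increasing size, locates
#' the accuracy inflection (first maximum of a 5-point moving average of
#' the held-out accuracy curve; smallest size on ties), and compares it to
#' the golden-ratio recommended size for the sample's rarest factor:
#' error = (n_tilde - n_opt) / n'.
#'
#' @param config an [experiment_config()]; \code{config$n} is n'.
#' @return data.frame with \code{replicate}, \code{n_tilde}, \code{n_opt},
#'   \code{error}.
#' @export
run_split_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  if (config$n <= 100) stop("split experiment needs n > 100")
  rows <- list()
  for (rep in seq_len(config$replicates)) {
    cfg <- draw_preset(config)
    sim <- simulate_sample(cfg, config$n)
    s <- sim$sample
    fcols <- grep("^f_", names(s), value = TRUE)
    hold <- sort(sample.int(nrow(s), max(30, floor(nrow(s) / 5))))
    test <- s[hold, , drop = FALSE]
    pool <- s[-hold, , drop = FALSE]
    pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
    step <- nrow(pool) / 100
    sizes <- unique(pmax(8, round(step * seq_len(100))))
    acc <- vapply(sizes, function(k) {
      tr <- pool[seq_len(min(k, nrow(pool))), , drop = FALSE]
      pred <- ridge_fit_predict(as.matrix(tr[, fcols, drop = FALSE]), tr$y,
                                as.matrix(test[, fcols, drop = FALSE]))
      mean(sign(pred) == sign(test$y))
    }, numeric(1))
    n_opt <- sizes[inflection_index(acc)]
    p_rare <- min(colMeans(s[, fcols, drop = FALSE] > 0))
    n_tilde <- if (p_rare > 0) {
      recommended_sample_size(length(fcols), p_rare, many_squares = TRUE)$n_many
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(replicate = rep, n_tilde = n_tilde,
      n_opt = n_opt, error = (n_tilde - n_opt) / config$n)
  }
  out <- do.call(rbind, rows)
  write_experiment(out, config, "split")
  out
}

# first maximum of a 5-point moving average; smallest index on ties
inflection_index <- function(acc) {
  if (length(acc) < 5) return(which.max(acc))
  ma <- stats::filter(acc, rep(1 / 5, 5), sides = 2)
  ma[is.na(ma)] <- -Inf
  which.max(ma)  # which.max returns the first (smallest) maximizer
}

write_experiment <- function(result, config, name) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- as.data.frame(result)
  num <- vapply(res, is.numeric, logical(1))
  res[num] <- lapply(res[num], function(v) signif(v, 9))
  utils::write.csv(res, file.path(config$out_dir, paste0(name, ".csv")),
                   row.names = FALSE)
  manifest <- list(experiment = name, seed = config$seed,
                   preset = config$preset, n = config$n, m = config$m,
                   replicates = config$replicates, methods = config$methods,
                   package_version = as.character(utils::packageVersion("sqev")))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
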