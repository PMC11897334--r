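test_that("noiseless additive squares recover effects exactly with capped EV", {
  s <- make_exhaustive_sample(2, function(p) sum(c(1, 0)[p]))
  sq <- enumerate_squares(s, reference = 1)
  obs <- effect_observations(sq$squares[[1]])
  ea <- estimate_effect(obs, "f_a")
  expect_equal(ea$effect, 1)
  expect_equal(ea$variance, 0)
  expect_true(ea$exact)
  expect_equal(ea$ev, 1e12)
  # zero observations -> undetermined, no exception
  ez <- estimate_effect(obs, "f_z")
  expect_identical(ez$label, "undetermined")
  expect_identical(ez$n_obs, 0L)
})

test_that("size-3 square estimate equals the brute-force background average", {
  s <- make_exhaustive_sample(3, function(p) sum(c(2, -1, 0.5)[p]) +
                                if (all(p[1:2])) 0.25 else 0)  # interaction
  sq <- enumerate_squares(s, reference = 1, max_size = 3)
  big <- sq$squares[[which(vapply(sq$squares, `[[`, integer(1), "size") == 3)[1]]]
  obs <- effect_observations(big)
  est <- estimate_effect(obs, "f_a")
  # oracle: average of the per-background means computed by hand from obs
  by_bg <- tapply(obs$dy[obs$factor == "f_a"], obs$background[obs$factor == "f_a"], mean)
  expect_equal(est$effect, mean(by_bg))
  expect_equal(est$n_obs, length(by_bg))
})

test_that("pure-noise outcomes give effects near zero", {
  set.seed(51)
  s <- make_exhaustive_sample(3)
  s$y <- rnorm(nrow(s))
  sq <- enumerate_squares(s, reference = 1, max_size = 3)
  obs <- square_set_observations(sq)
  est <- estimate_effects(obs)
  # each effect is an average of noise differences; loose 3-sigma bound
  expect_true(all(abs(est$effect) < 3 * sqrt(2)))
})

test_that("EV is shift-invariant and scales inversely with outcome scale", {
  set.seed(52)
  s <- make_exhaustive_sample(3, function(p) sum(c(1, 0.5, 0)[p]))
  s$y <- s$y + rnorm(nrow(s), 0, 0.3)
  sqs <- enumerate_squares(s, reference = 1, max_size = 3)
  est1 <- estimate_effects(square_set_observations(sqs))
  s2 <- s; s2$y <- s$y + 7
  est2 <- estimate_effects(square_set_observations(enumerate_squares(s2, 1, max_size = 3)))
  expect_equal(est1$ev, est2$ev)
  s3 <- s; s3$y <- s$y * 2
  est3 <- estimate_effects(square_set_observations(enumerate_squares(s3, 1, max_size = 3)))
  ok <- !est1$exact
  expect_equal(est3$ev[ok], est1$ev[ok] / 4)
})

test_that("square-row construction separates cause, confounder and spurious", {
  set.seed(53)
  sim <- principle1_squares(300, effects = c(f_a = 1, f_b = 0, f_c = 0),
                            rho = c(1, 0))
  tab <- sim$table
  v <- setNames(tab$variance, tab$factor)
  expect_lt(v[["f_a"]], 1e-12)
  expect_lt(abs(v[["f_b"]] - 0.25), 0.05)
  expect_lt(abs(v[["f_c"]] - 0.5), 0.07)
  # classification by nearest expected value recovers all three labels
  est <- data.frame(factor = tab$factor, effect = tab$effect,
                    variance = tab$variance, ev = 1 / pmax(tab$variance, 1e-12),
                    n_obs = tab$n_obs, exact = FALSE, label = NA_character_,
                    stringsAsFactors = FALSE)
  corr <- diag(3); dimnames(corr) <- list(tab$factor, tab$factor)
  corr["f_a", "f_b"] <- corr["f_b", "f_a"] <- 1
  lab <- classify_factors(est, corr, observations = sim$obs)
  expect_identical(lab$label[lab$factor == "f_a"], "cause")
  expect_identical(lab$label[lab$factor == "f_b"], "confounder")
  expect_identical(lab$label[lab$factor == "f_c"], "spurious")
})

test_that("classification recovers labels in most replicates at rho 0.5 and 1", {
  set.seed(54)
  for (rho in c(0.5, 1)) {
    hits <- vapply(1:25, function(i) {
      sim <- principle1_squares(40, effects = c(f_a = 1, f_b = 0, f_c = 0),
                                rho = c(rho, 0))
      tab <- sim$table
      est <- data.frame(factor = tab$factor, effect = tab$effect,
                        variance = tab$variance, ev = 1 / pmax(tab$variance, 1e-12),
                        n_obs = tab$n_obs, exact = FALSE, label = NA_character_,
                        stringsAsFactors = FALSE)
      corr <- diag(3); dimnames(corr) <- list(tab$factor, tab$factor)
      corr["f_a", "f_b"] <- corr["f_b", "f_a"] <- rho
      lab <- classify_factors(est, corr, observations = sim$obs)
      identical(lab$label, c("cause", "confounder", "spurious"))
    }, logical(1))
    expect_gte(mean(hits), 0.9)
  }
})

test_that("undetermined labels: few observations or missing both-orders", {
  est <- data.frame(factor = c("f_a", "f_b"), effect = c(1, 0.5),
                    variance = c(0, 0.1), ev = c(1e12, 10), n_obs = c(2L, 10L),
                    exact = c(TRUE, FALSE), label = NA_character_,
                    stringsAsFactors = FALSE)
  corr <- diag(2); dimnames(corr) <- list(est$factor, est$factor)
  lab <- classify_factors(est, corr)
  expect_identical(lab$label[1], "undetermined")  # n_obs below minimum
  # both-orders precondition fails: f_b never seen with f_a in background
  obs <- data.frame(factor = c("f_a", "f_b"), background = c("f_b", ""),
                    dy = c(1, 0), stringsAsFactors = FALSE)
  lab2 <- classify_factors(est, corr, observations = obs)
  expect_identical(lab2$label[2], "undetermined")
})

test_that("column decomposition: zero noiseless error, ordered q levels", {
  # q = 0 noiseless: all column errors are 0
  s <- make_exhaustive_sample(3, function(p) sum(c(1, 0.5, 0.25)[p]))
  sqs <- enumerate_squares(s, reference = 1, max_size = 3)
  dec <- column_decomposition(sqs)
  expect_true(all(dec$table$pairwise_error < 1e-20, na.rm = TRUE))
  expect_true(dec$monotone)
  # pairwise error equals the explicit mean over same-factor pairs
  set.seed(55)
  s$y <- s$y + rnorm(nrow(s), 0, 0.5)
  dec2 <- column_decomposition(enumerate_squares(s, 1, max_size = 3))
  obs <- dec2$observations
  for (d in unique(obs$col)) {
    sub <- obs[obs$col == d, ]
    diffs <- c()
    for (f in unique(sub$factor)) {
      v <- sub$dy[sub$factor == f]
      if (length(v) < 2) next
      pairs <- combn(v, 2)
      diffs <- c(diffs, (pairs[1, ] - pairs[2, ])^2)
    }
    if (length(diffs)) {
      expect_equal(dec2$table$pairwise_error[dec2$table$col == d], mean(diffs))
    }
  }
  # fixed hidden-noise levels order the estimated within-noise components
  withins <- vapply(c(0, 0.5, 1.5), function(sig) {
    set.seed(56)
    s2 <- make_exhaustive_sample(3, function(p) sum(p))
    s2$y <- s2$y + rnorm(nrow(s2), 0, sig)
    d <- column_decomposition(enumerate_squares(s2, 1, max_size = 3))
    if (is.na(d$within)) 0 else d$within
  }, numeric(1))
  expect_true(!is.unsorted(withins))
})

test_that("empty square sets give empty decompositions and histograms", {
  s <- data.frame(unit_id = 1:2, t = 1:2, f_a = c(-1, -1), f_b = c(-1, 1),
                  y = c(0, 1))
  sqs <- enumerate_squares(s, reference = 1, max_size = 2)
  expect_true(length(sqs$squares) >= 1)  # the singleton b square exists
  # a reference with no usable neighbours
  s3 <- data.frame(unit_id = 1:2, t = 1:2, f_a = c(-1, -1), f_b = c(-1, -1),
                   y = c(0, 1))
  sqs3 <- enumerate_squares(s3, reference = 1)
  expect_length(sqs3$squares, 0)
  dec <- column_decomposition(sqs3)
  expect_null(dec$table)
})

test_that("row adjustment discounts cumulative row-shared confounding", {
  # cell outcomes accumulate background noise along each row (the additive
  # Markov-chain regime); the adjusted observation retains only the newest
  # increment, so its variance cannot exceed the raw cumulative one
  set.seed(57)
  s <- make_exhaustive_sample(3, function(p) sum(p))
  sq <- enumerate_squares(s, 1, max_size = 3)$squares[[1]]
  raw_all <- c(); adj_all <- c()
  for (rep in 1:500) {
    ra <- NULL
    eps <- rnorm(3, 0, 1)
    outc <- setNames(numeric(8), as.character(1:8))
    for (i in seq_len(nrow(sq$cells))) {
      d <- sq$cells$col[i]
      noise <- if (d >= 1) sum(eps[seq_len(d)]) else 0
      outc[as.character(sq$cells$unit_id[i])] <- d + noise
    }
    ra <- row_adjusted_effect(sq, outc, sq$order[2])
    deep <- ra$col >= 2
    raw_all <- c(raw_all, ra$raw[deep])
    adj_all <- c(adj_all, ra$adjusted[deep])
  }
  expect_lte(var(adj_all), var(raw_all))
  # noiseless additive outcomes (all effects 1): the adjusted observation
  # is the factor's own unit effect exactly
  outc0 <- setNames(s$y, as.character(s$unit_id))
  ra0 <- row_adjusted_effect(sq, outc0, sq$order[2])
  expect_true(all(abs(ra0$adjusted - 1) < 1e-12))
  # first-in-row occurrence is returned unchanged
  first <- ra0[ra0$col == 1, ]
  expect_equal(first$raw, first$adjusted)
  expect_error(row_adjusted_effect(sq, outc0, "f_z"))
})

test_that("variance-ratio F-test matches the textbook formula", {
  ft <- f_test_effect_variance(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ft$F, 1)
  expect_true(ft$same_effect)
  ft2 <- f_test_effect_variance(c(2, 4, 6), c(1, 2, 3))
  expect_equal(ft2$F, var(c(2, 4, 6)) / var(c(1, 2, 3)))
  expect_equal(ft2$F, 4)
  # p-value against the F distribution directly
  expect_equal(ft2$p_value,
               2 * min(pf(4, 2, 2), pf(4, 2, 2, lower.tail = FALSE)))
  # degenerate zero-variance denominator
  ft3 <- f_test_effect_variance(c(1, 2, 3), c(5, 5, 5))
  expect_true(is.infinite(ft3$F))
  expect_true(ft3$degenerate)
  expect_false(ft3$same_effect)
  expect_error(f_test_effect_variance(1, c(1, 2)))
})
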