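test_that("permutation, derangement and partial-permutation counts match brute force", {
  # brute-force derangement oracle over explicit permutations
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  for (m in 0:6) {
    expect_identical(count_permutations(m), factorial(m))
    if (m >= 1) {
      nd <- sum(vapply(perms(seq_len(m)), function(p) all(p != seq_len(m)), logical(1)))
      expect_equal(count_derangements(m), nd)
    }
  }
  expect_identical(count_derangements(0), 1)
  expect_identical(count_derangements(4), 9)
  # partial permutations: choose d fixed points, derange the rest
  brute_partial <- function(m, d) {
    sum(vapply(perms(seq_len(m)), function(p) sum(p == seq_len(m)) == d, logical(1)))
  }
  for (m in 2:5) for (d in 0:m) {
    expect_equal(count_partial_permutations(m, d), brute_partial(m, d))
  }
  expect_error(count_permutations(-1))
  expect_error(count_partial_permutations(3, 4))
})

test_that("enumeration ratio is the exact inverse multinomial coefficient", {
  r <- enumeration_ratio(c(4, 0, 0, 0))
  expect_identical(c(r$num, r$den), c(1, 1))
  r <- enumeration_ratio(c(1, 1, 1, 1))
  expect_identical(c(r$num, r$den), c(1, 24))
  r <- enumeration_ratio(c(2, 2))
  expect_identical(c(r$num, r$den), c(1, 6))
  # brute-force oracle: fraction of q! orders reachable when items within a
  # gap can appear in any relative order but gaps impose a block order
  brute_ratio <- function(gaps) {
    prod(factorial(gaps)) / factorial(sum(gaps))
  }
  for (g in list(c(3, 1), c(2, 1, 1), c(5), c(2, 3))) {
    expect_equal(enumeration_ratio(g)$value, brute_ratio(g))
  }
  expect_error(enumeration_ratio(integer(0)))
  expect_error(enumeration_ratio(c(1, -1)))
})

test_that("enumeration ratio limits and monotonicity under gap merging", {
  q <- 5
  expect_equal(enumeration_ratio(c(q, rep(0, 3)))$value, 1)
  expect_equal(enumeration_ratio(rep(1, q))$value, 1 / factorial(q))
  # merging two gaps can only increase the ratio
  set.seed(11)
  for (i in 1:20) {
    g <- as.vector(stats::rmultinom(1, 8, rep(1 / 4, 4)))
    merged <- c(g[1] + g[2], g[-(1:2)])
    expect_gte(enumeration_ratio(merged)$value, enumeration_ratio(g)$value)
  }
})

test_that("linear extensions enumerate chain merges with binomial counts", {
  ex <- linear_extensions(2, 3)
  expect_length(ex, 10)
  expect_identical(length(unique(vapply(ex, paste, character(1), collapse = ""))), 10L)
  expect_length(linear_extensions(0, 3), 1)
  expect_length(linear_extensions(1, 1), 2)
  for (a in 0:5) for (b in 0:5) {
    expect_length(linear_extensions(a, b), choose(a + b, a))
  }
  # each extension preserves both chain orders
  for (e in ex) {
    expect_identical(e[grepl("^x", e)], c("x1", "x2"))
    expect_identical(e[grepl("^u", e)], c("u1", "u2", "u3"))
  }
})

test_that("expected inversions formula: limits, monotonicity, saturation", {
  expect_equal(expected_inversions(c(0.3, 0.7), 4, 0), 0)
  # the p = (0.5, 0.5) case reduces to the two-gap cut-off form
  for (t in 0:10) {
    expect_equal(expected_inversions(c(0.5, 0.5), 5, t),
                 0.5 * choose(5, 2) * (1 - 2^-t))
  }
  expect_equal(expected_inversions(c(1, 0, 0), 6, 50), 0)
  vals <- vapply(0:12, function(t) expected_inversions(rep(1 / 4, 4), 5, t), numeric(1))
  expect_true(!is.unsorted(vals))
  expect_lte(max(vals), 0.5 * choose(5, 2))
  expect_error(expected_inversions(c(0.5, 0.6), 4, 1))
})

test_that("Monte-Carlo gap reassignment matches the inversion expectation", {
  set.seed(101)
  for (p in list(rep(1 / 5, 5), c(0.5, 0.5), c(0.7, 0.2, 0.1))) {
    for (t in c(1, 4, 9)) {
      mc <- simulate_inversions(p, 5, t, reps = 2500)
      se <- stats::sd(mc) / sqrt(length(mc))
      expect_lt(abs(mean(mc) - expected_inversions(p, 5, t)),
                3 * max(se, 0.02))
    }
  }
  expect_true(all(simulate_inversions(c(1, 0), 5, 8, reps = 200) == 0))
})

test_that("modular sampling sequences follow the recursion", {
  expect_identical(make_sequence(1, 1, 5, 0, 5)$values, c(0, 1, 2, 3, 4))
  expect_identical(make_sequence(2, 0, 5, 1, 5)$values, c(1, 2, 4, 3, 1))
  s <- make_sequence(0, 3, 7, 5, 4)
  expect_identical(s$values[-1], rep(3, 3))
  expect_error(make_sequence(1, 1, 0, 0, 3))
  # recursion reproduces values from constants
  s <- make_sequence(3, 2, 11, 4, 12)
  v <- s$values
  expect_true(all((3 * v[-length(v)] + 2) %% 11 == v[-1]))
})

test_that("EV-increasing, CF non-increasing and enumerating predicates", {
  expect_true(is_ev_increasing(make_sequence(1, 1, 5, 0, 5)))  # b(t) varies
  expect_true(is_ev_increasing(rep(0, 5), q = 5))              # identity residues
  expect_false(is_ev_increasing(c(0, 4, 3, 2, 1), q = 5))      # all residues 0
  expect_true(is_enumerating(5, 1, 5))
  expect_true(is_enumerating(10, 3, 5))
  expect_false(is_enumerating(3, 2, 4))
  expect_false(is_enumerating(4, 2, 4))
  expect_true(is_cf_nonincreasing(list(a = c(1, 2, 3), b = c(3, 2, 1))))
  expect_false(is_cf_nonincreasing(list(a = c(1, 2, 3), b = c(1, 2, 2))))
  # enumerating sequences are EV-increasing under a fixed background
  # (checked over small enumerated cases)
  for (q in 2:7) for (c2 in seq_len(q - 1)) {
    if (sqev:::gcd_int(c2, q) != 1) next
    expect_true(is_enumerating(q, c2, q))
    # the recursion's steady state (b0 at the fixed point c2) visits a
    # distinct background at every step
    seqs <- make_sequence(q, c2, q, c2, q)
    expect_true(is_ev_increasing(seqs))
  }
})

test_that("multiplicative order matches brute-force powers", {
  expect_identical(multiplicative_order(2, 7), 3L)
  expect_identical(multiplicative_order(2, 3), 2L)
  expect_identical(multiplicative_order(1, 9), 1L)
  brute_order <- function(c, mod) {
    x <- 1
    for (t in 1:mod) { x <- (x * c) %% mod; if (x == 1) return(t) }
    NA_integer_
  }
  for (q in 2:12) {
    mod <- 2 * q - 1
    expect_identical(multiplicative_order(2, mod), brute_order(2, mod))
  }
  expect_error(multiplicative_order(2, 4))
})

test_that("recommended sample sizes follow the golden-ratio rule", {
  r <- recommended_sample_size(10, 0.5)
  expect_identical(r$n_first, 1024)
  r2 <- recommended_sample_size(10, 0.025)
  expect_identical(r2$n_first, 20480)
  expect_identical(recommended_sample_size(1, 1)$n_first, 1)
  phi <- (1 + sqrt(5)) / 2
  for (m in c(2, 5, 10)) for (p in c(0.1, 0.33, 1)) {
    r <- recommended_sample_size(m, p, many_squares = TRUE)
    expect_equal(r$n_many / r$n_first, phi)
    expect_identical(r$n, r$n_many)
  }
  expect_error(recommended_sample_size(10, 0))
  expect_error(recommended_sample_size(0, 0.5))
})
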