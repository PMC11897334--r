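test_that("exhaustive m=2 sample yields the complete size-2 square", {
  s <- make_exhaustive_sample(2)
  sq <- enumerate_squares(s, reference = 1)
  expect_length(sq$squares, 1)
  expect_identical(sq$squares[[1]]$size, 2L)
  expect_true(sq$squares[[1]]$complete)
  expect_true(verify_square_raw(sq$squares[[1]], s))
  # removing the {a,b} unit leaves no complete size-2 square
  s2 <- s[-4, ]
  sq2 <- enumerate_squares(s2, reference = 1)
  expect_true(all(vapply(sq2$squares, `[[`, integer(1), "size") < 2))
  expect_error(enumerate_squares(s, reference = 99))
})

test_that("enumeration matches exhaustive brute-force search on small samples", {
  set.seed(31)
  for (trial in 1:25) {
    m <- sample(2:4, 1)
    n <- sample(4:16, 1)
    X <- matrix(sample(c(-1, 1), n * m, replace = TRUE), n, m)
    colnames(X) <- paste0("f_", letters[1:m])
    s <- data.frame(unit_id = 1:n, t = 1:n, X, y = rnorm(n))
    ref <- s$unit_id[sample.int(n, 1)]
    got <- enumerate_squares(s, ref, max_size = m, max_squares = 10000L)
    want <- brute_force_squares(s, ref)
    expect_identical(
      serialize_orders(lapply(got$squares, `[[`, "order")),
      serialize_orders(want))
    for (sq in got$squares) expect_true(verify_square_raw(sq, s))
  }
})

test_that("a complete size-10 square exists in the exhaustive balanced sample", {
  s <- make_exhaustive_sample(10)
  sq <- enumerate_squares(s, reference = 1, max_size = 10, max_squares = 1)
  expect_identical(sq$squares[[1]]$size, 10L)
  expect_true(verify_square_raw(sq$squares[[1]], s))
  # unit economy: beyond the reference, a complete size-m' square needs at
  # most m'(m'-1) + 1 distinct units (one per cyclic interval)
  sq10 <- sq$squares[[1]]
  others <- setdiff(unique(sq10$cells$unit_id), sq10$reference)
  expect_lte(length(others), 10 * 9 + 1)
  expect_lte(length(others) + 1, 2^10)
})

test_that("duplicate rows collapse to a representative with averaged outcomes", {
  s <- make_exhaustive_sample(2)
  dup <- s[2, ]; dup$unit_id <- 5; dup$t <- 5; dup$y <- 3  # duplicate of {a}, y 1 vs 3
  s2 <- rbind(s, dup)
  sq <- enumerate_squares(s2, reference = 1)
  cells <- sq$squares[[1]]$cells
  a_cell <- cells[cells$unit_id == 2, ]
  expect_gt(nrow(a_cell), 0)  # representative is the earlier unit
  expect_equal(unique(a_cell$y), 2)  # outcomes averaged over duplicates
})

test_that("effect observations enumerate adjacent differences with backgrounds", {
  s <- make_exhaustive_sample(2, function(p) sum(c(1, 0)[p]))  # y: a adds 1, b adds 0
  sq <- enumerate_squares(s, reference = 1)
  obs <- effect_observations(sq$squares[[1]])
  expect_identical(nrow(obs), 4L)
  get <- function(f, b) obs$dy[obs$factor == f & obs$background == b]
  expect_equal(get("f_a", ""), 1)
  expect_equal(get("f_a", "f_b"), 1)
  expect_equal(get("f_b", ""), 0)
  expect_equal(get("f_b", "f_a"), 0)
  # size-3 square equals hand-enumerated adjacent differences per cyclic row
  s3 <- make_exhaustive_sample(3, function(p) sum(c(2, -1, 0.5)[p]))
  sq3 <- enumerate_squares(s3, reference = 1, max_size = 3)
  big <- sq3$squares[[which(vapply(sq3$squares, `[[`, integer(1), "size") == 3)[1]]]
  obs3 <- effect_observations(big)
  # hand enumeration: walk each rotation of the order, difference outcomes
  ord <- big$order
  eff <- c(f_a = 2, f_b = -1, f_c = 0.5)
  for (r in 1:3) for (d in 1:3) {
    f <- ord[((r - 1 + d - 1) %% 3) + 1]
    bgset <- sort(ord[((r - 1 + seq_len(d - 1) - 1) %% 3) + 1])
    bg <- paste(bgset, collapse = ",")
    expect_equal(obs3$dy[obs3$factor == f & obs3$background == bg],
                 unname(eff[f]))
  }
  # a factor is seen under exactly m' backgrounds in a complete square
  expect_true(all(table(obs3$factor) == 3))
})

test_that("observations from a +1-bearing reference are re-oriented", {
  # reference carrying f_a at +1 observes the reverse transition; effects
  # must still come out on the canonical -1 -> +1 scale
  s <- make_exhaustive_sample(2, function(p) sum(c(1.5, 0.25)[p]))
  ref_ab <- which(s$f_a == 1 & s$f_b == 1)
  sq <- enumerate_squares(s, reference = s$unit_id[ref_ab])
  obs <- effect_observations(sq$squares[[1]])
  est <- estimate_effects(obs)
  expect_equal(est$effect[est$factor == "f_a"], 1.5)
  expect_equal(est$effect[est$factor == "f_b"], 0.25)
  # background strings are absolute +1-sets of the baseline cells
  expect_true(all(obs$background %in% c("", "f_a", "f_b", "f_a,f_b")))
})

test_that("member histogram counts distinct units by difference size", {
  s <- make_exhaustive_sample(3)
  sq <- enumerate_squares(s, reference = 1, max_size = 3, max_squares = 2)
  h <- sq$member_histogram
  big <- sq$squares[[1]]
  # complete size-3 square: 3 distinct units at sizes 1 and 2, one at size 3
  h1 <- member_histogram(structure(list(squares = list(big), reference = 1,
                                        factor_names = sq$factor_names, m = 3),
                                   class = "square_set"))
  expect_identical(unname(h1[1:3]), c(3L, 3L, 1L))
  # empty set -> all-zero histogram
  empty <- structure(list(squares = list(), reference = 1,
                          factor_names = sq$factor_names, m = 3),
                     class = "square_set")
  expect_true(all(member_histogram(empty) == 0))
})

test_that("a thin balanced sample observes no large difference structures", {
  set.seed(17)
  sim <- simulate_sample(dgp_balanced(), 200)
  s <- sim$sample
  fc <- grep("^f_", names(s), value = TRUE)
  refs <- sqev:::auto_references(s, fc, 2)
  for (r in refs) {
    sq <- enumerate_squares(s, r, max_size = 10, max_squares = 16)
    h <- sq$member_histogram
    expect_true(all(h[5:10] == 0))
  }
})

test_that("transversals are valid permutations with the stated structure", {
  s <- make_exhaustive_sample(3)
  sq <- enumerate_squares(s, reference = 1, max_size = 2, max_squares = 4)
  for (meth in c("random", "square", "square_column", "tsp")) {
    tv <- transversal(s, sq, meth, seed = 1)
    expect_setequal(tv$order, s$unit_id)
    expect_identical(anyDuplicated(tv$order), 0L)
  }
  # square method: column-1 cells of all squares precede any column-2 cell
  tv <- transversal(s, sq, "square")
  col_of <- function(uid) {
    cols <- unlist(lapply(sq$squares, function(q) q$cells$col[q$cells$unit_id == uid]))
    if (length(cols)) min(cols) else NA_integer_
  }
  cols <- vapply(tv$order, col_of, numeric(1))
  in_sq <- !is.na(cols)
  expect_true(!is.unsorted(cols[in_sq]))
  # random transversal reproducible under a seed
  expect_identical(transversal(s, sq, "random", seed = 9)$order,
                   transversal(s, sq, "random", seed = 9)$order)
  expect_error(transversal(s, NULL, "square"))
})

test_that("TSP transversal is within twice the brute-force optimum", {
  set.seed(23)
  for (trial in 1:6) {
    n <- sample(5:8, 1); m <- sample(3:5, 1)
    X <- matrix(sample(c(-1, 1), n * m, replace = TRUE), n, m)
    colnames(X) <- paste0("f_", letters[1:m])
    s <- data.frame(unit_id = 1:n, t = 1:n, X, y = 0)
    tv <- transversal(s, NULL, "tsp")
    got <- tour_length(s, tv$order)
    opt <- brute_tsp_opt(X)
    expect_lte(got, 2 * opt + 1e-9)
  }
})
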