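#' Exact permutation, derangement and partial-permutation counts
#'
#' Counting functions for the permutations of \code{m} factors: all
#' permutations \code{m!}, derangements (permutations with no fixed point)
#' \eqn{D_m = m! \sum_{d=0}^m (-1)^d / d!}, and partial permutations with
#' exactly \code{d} fixed positions, \eqn{D_m^d = C(m,d) D_{m-d}}.  These
#' counts bound the number of observable background permutations in a sample.
#'
#' Values are exact integers as long as they fit in a double (below 2^53,
#' i.e. \code{m <= 18} for factorials); larger arguments are refused.
#'
#' @param m number of factors (non-negative integer).
#' @param d number of fixed positions, \code{0 <= d <= m}.
#' @return A numeric scalar holding an exact integer count.
#' @examples
#' count_permutations(4)          # 24
#' count_derangements(4)          # 9
#' count_partial_permutations(4, 2)  # 6
#' @export
count_permutations <- function(m) {
  check_count(m, "m", max = 18L)
  if (m == 0) return(1)
  prod(seq_len(m))
}

#' @rdname count_permutations
#' @export
count_derangements <- function(m) {
  check_count(m, "m", max = 18L)
  # D_n = (n-1)(D_{n-1} + D_{n-2}); integer-exact, avoids alternating sums
  if (m == 0) return(1)
  if (m == 1) return(0)
  d2 <- 1; d1 <- 0
  for (n in 2:m) {
    d0 <- (n - 1) * (d1 + d2)
    d2 <- d1; d1 <- d0
  }
  d1
}

#' @rdname count_permutations
#' @export
count_partial_permutations <- function(m, d) {
  check_count(m, "m", max = 18L)
  check_count(d, "d", max = m)
  choose(m, d) * count_derangements(m - d)
}

#' Enumeration ratio of a gap-count configuration
#'
#' Fraction of the \code{q!} orders of \code{q} unobserved factors that a
#' sample with per-gap counts \eqn{\Delta q_{(1)}, \ldots, \Delta q_{(m)}}
#' can asymptotically enumerate:
#' \deqn{\prod_i \Delta q_{(i)}! / q!,}
#' the inverse multinomial coefficient.  All counts in one gap give ratio 1;
#' all singleton gaps give \eqn{1/q!}.
#'
#' @param gaps non-negative integer gap counts; their sum is \code{q}.
#' @return An object of class \code{"sqev_rational"}: a list with exact
#'   reduced \code{num}erator and \code{den}ominator and the numeric
#'   \code{value}.
#' @examples
#' enumeration_ratio(c(4, 0, 0, 0))  # 1
#' enumeration_ratio(c(1, 1, 1, 1))  # 1/24
#' @export
enumeration_ratio <- function(gaps) {
  if (length(gaps) == 0) stop("'gaps' must be a non-empty vector of counts")
  if (any(gaps < 0) || any(gaps != round(gaps))) {
    stop("'gaps' must be non-negative integers")
  }
  q <- sum(gaps)
  if (q > 18) stop("sum(gaps) above 18 is not exactly representable")
  num <- prod(vapply(gaps, count_permutations, numeric(1)))
  den <- count_permutations(q)
  g <- gcd_int(num, den)
  out <- list(num = num / g, den = den / g, value = num / den)
  class(out) <- "sqev_rational"
  out
}

#' @export
print.sqev_rational <- function(x, ...) {
  cat(sprintf("%d/%d (= %g)\n", x$num, x$den, x$value))
  invisible(x)
}

#' All interleavings (linear extensions) of two chains
#'
#' Enumerates every merge of two totally ordered chains that preserves both
#' internal orders: the linear extensions of the disjoint union of an
#' \code{a}-chain (elements \code{"x1" < "x2" < ...}) and a \code{b}-chain
#' (\code{"u1" < "u2" < ...}).  Their number is \code{choose(a + b, a)}.
#'
#' @param chain_a,chain_b chain lengths (0 to 8).
#' @return List of character vectors, one per extension.
#' @examples
#' length(linear_extensions(2, 3))  # choose(5, 2) = 10
#' @export
linear_extensions <- function(chain_a, chain_b) {
  check_count(chain_a, "chain_a", max = 8L)
  check_count(chain_b, "chain_b", max = 8L)
  a_lab <- if (chain_a > 0) paste0("x", seq_len(chain_a)) else character(0)
  b_lab <- if (chain_b > 0) paste0("u", seq_len(chain_b)) else character(0)
  merge_rec <- function(a, b) {
    if (length(a) == 0) return(list(b))
    if (length(b) == 0) return(list(a))
    c(lapply(merge_rec(a[-1], b), function(v) c(a[1], v)),
      lapply(merge_rec(a, b[-1]), function(v) c(b[1], v)))
  }
  merge_rec(a_lab, b_lab)
}

#' Expected permutation inversions under i.i.d. gap reassignment
#'
#' Expected number of inversions, relative to an initial background order,
#' accumulated after \code{t} steps of i.i.d. multinomial reassignment of
#' \code{m} items across gaps with probabilities \code{p}:
#' \deqn{E[I(t)] = \frac12 \binom{m}{2} \left(1 - (\sum_i p_i^2)^t\right).}
#' A uniform \code{p} saturates quickly toward the stationary expectation
#' \eqn{\binom{m}{2}/2}; a point mass generates no inversions.
#'
#' @param p probability vector of the gap distribution (sums to 1).
#' @param m number of items (factors) being permuted.
#' @param t non-negative number of elapsed steps.
#' @return Expected inversion count (numeric scalar).
#' @seealso [simulate_inversions()] for the matching Monte-Carlo process.
#' @export
expected_inversions <- function(p, m, t) {
  if (abs(sum(p) - 1) > 1e-9) stop("'p' must sum to 1")
  if (any(p < 0)) stop("'p' must be non-negative")
  check_count(m, "m")
  if (t < 0) stop("'t' must be non-negative")
  0.5 * choose(m, 2) * (1 - sum(p^2)^t)
}

#' Monte-Carlo i.i.d. multinomial gap reassignment
#'
#' Simulates the inversion-generating process behind
#' [expected_inversions()]: \code{m} items start in a reference order; at
#' each step every item independently draws a gap from \code{p} and items
#' are stably re-sorted by drawn gap (ties keep their previous relative
#' order; distinct gaps order the pair exchangeably).  Returns the inversion
#' count relative to the initial order after \code{t} steps, for each
#' replicate.
#'
#' @inheritParams expected_inversions
#' @param reps number of Monte-Carlo replicates.
#' @return Integer vector of \code{reps} inversion counts.
#' @export
simulate_inversions <- function(p, m, t, reps = 1000L) {
  if (abs(sum(p) - 1) > 1e-9) stop("'p' must sum to 1")
  check_count(m, "m")
  K <- length(p)
  vapply(seq_len(reps), function(r) {
    ord <- seq_len(m)
    if (t > 0) for (s in seq_len(t)) {
      g <- sample.int(K, m, replace = TRUE, prob = p)
      # stable sort by drawn gap; within a gap, random exchangeable order
      # between items that drew different values at this step is realized
      # by the gap draw itself (order(g) is stable on ties)
      ord <- ord[order(g[ord])]
    }
    count_inversions(ord)
  }, integer(1))
}

count_inversions <- function(perm) {
  m <- length(perm)
  if (m < 2) return(0L)
  inv <- 0L
  for (i in seq_len(m - 1)) {
    inv <- inv + sum(perm[(i + 1):m] < perm[i])
  }
  as.integer(inv)
}

#' Modular sampling sequences
#'
#' Builds the sampling sequence of the recursion
#' \eqn{b(t+1) = c_1 b(t) + c_2 \bmod q}, the modular-arithmetic description
#' of how effect backgrounds are reassigned across a sample's gaps over time.
#'
#' @param c1 multiplicative constant.
#' @param c2 additive constant.
#' @param q modulus (number of gap positions), \code{q >= 1}.
#' @param b0 starting value in \code{[0, q)}.
#' @param length number of sequence values to produce.
#' @return An object of class \code{"sampling_sequence"}: list with
#'   \code{values}, \code{c1}, \code{c2}, \code{q}, \code{b0}.
#' @examples
#' make_sequence(1, 1, 5, 0, 5)$values  # 0 1 2 3 4
#' @export
make_sequence <- function(c1, c2, q, b0 = 0, length = q) {
  check_count(q, "q"); if (q < 1) stop("'q' must be >= 1")
  check_count(length, "length")
  values <- numeric(length)
  b <- b0 %% q
  for (t in seq_len(length)) {
    values[t] <- b
    b <- (c1 * b + c2) %% q
  }
  out <- list(values = values, c1 = c1, c2 = c2, q = q, b0 = b0 %% q)
  class(out) <- "sampling_sequence"
  out
}

#' @export
print.sampling_sequence <- function(x, ...) {
  cat(sprintf("sampling sequence b(t+1) = %g b(t) + %g mod %d, b(0) = %g\n",
              x$c1, x$c2, x$q, x$b0))
  cat(" values:", paste(x$values, collapse = " "), "\n")
  invisible(x)
}

#' Sampling-sequence predicates: EV-increasing, CF non-increasing, enumerating
#'
#' \code{is_ev_increasing} checks that the residues \eqn{[t + b(t)]_q} of a
#' sampling sequence are pairwise distinct, i.e. that successive effect
#' observations land in distinct backgrounds (external-validity increasing).
#' \code{is_cf_nonincreasing} checks that the multiset of visited backgrounds
#' is identical across all in-sample factors, so no factor accrues
#' confounding the others do not.  \code{is_enumerating} checks the
#' enumeration conditions for a fixed background: \code{c1 / q} integral and
#' \code{gcd(c2, q) = 1}.
#'
#' @param seq a \code{"sampling_sequence"} from [make_sequence()] (or a bare
#'   numeric vector of \code{b(t)} values plus a \code{q} attribute-free
#'   \code{q} argument).
#' @param q modulus, required when \code{seq} is a bare vector.
#' @param assignments list with one element per factor, each the vector of
#'   background states visited by that factor.
#' @param c1,c2 recursion constants.
#' @return Logical scalar.
#' @examples
#' is_enumerating(5, 1, 5)                       # TRUE
#' is_ev_increasing(make_sequence(1, 1, 5, 0, 5))
#' @export
is_ev_increasing <- function(seq, q = NULL) {
  if (inherits(seq, "sampling_sequence")) {
    q <- seq$q; b <- seq$values
  } else {
    if (is.null(q)) stop("'q' required for a bare sequence")
    b <- seq
  }
  t <- seq_along(b) - 1
  res <- (t + b) %% q
  anyDuplicated(res) == 0
}

#' @rdname is_ev_increasing
#' @export
is_cf_nonincreasing <- function(assignments) {
  if (!is.list(assignments) || length(assignments) == 0) {
    stop("'assignments' must be a non-empty list of visited-background vectors")
  }
  ref <- sort(assignments[[1]])
  all(vapply(assignments, function(a) identical(sort(a), ref), logical(1)))
}

#' @rdname is_ev_increasing
#' @export
is_enumerating <- function(c1, c2, q) {
  check_count(q, "q"); if (q < 1) stop("'q' must be >= 1")
  (c1 %% q == 0) && (gcd_int(c2 %% q, q) == 1 || q == 1)
}

#' Multiplicative order modulo an integer
#'
#' Least \code{t >= 1} with \eqn{c^t \equiv 1 \pmod{modulus}}.  The order of
#' 2 modulo \code{2q - 1} is the enumeration period of the doubling
#' ("riffle") background recursion with \code{q} gaps: after that many
#' steps every gap assignment returns to its starting position.
#'
#' @param c base, coprime with \code{modulus}.
#' @param modulus modulus \code{>= 1}.
#' @return Integer order.
#' @examples
#' multiplicative_order(2, 7)  # 3
#' @export
multiplicative_order <- function(c, modulus) {
  check_count(modulus, "modulus"); if (modulus < 1) stop("'modulus' must be >= 1")
  c <- c %% modulus
  if (modulus == 1) return(1L)
  if (gcd_int(c, modulus) != 1) stop("'c' and 'modulus' must be coprime")
  x <- 1; t <- 0L
  repeat {
    x <- (x * c) %% modulus
    t <- t + 1L
    if (x == 1) return(t)
    if (t > modulus) stop("order not found (internal error)")  # unreachable
  }
}

#' Recommended sample sizes for square enumeration
#'
#' Asymptotic sample sizes needed to observe complete squares when the
#' rarest in-sample factor has frequency \code{p_rarest}:
#' \deqn{\tilde n_{first} = 2^{m-1} / p_{rarest}, \qquad
#'       \tilde n_{many} = \tilde n_{first} \times \phi,}
#' with \eqn{\phi = 1.6180\ldots} the golden ratio.  The first size suffices
#' for one complete square of size \code{m}; the second for the many-squares
#' regime where effect estimates stabilize.
#'
#' @param m number of observed factors.
#' @param p_rarest occurrence frequency of the rarest factor, in (0, 1].
#' @param many_squares if TRUE, \code{n} is set to the many-squares size,
#'   otherwise to the first-square size (both are always reported).
#' @return Object of class \code{"sample_size_rec"}: list with \code{m},
#'   \code{p_rarest}, \code{n_first}, \code{n_many}, \code{n}.
#' @examples
#' recommended_sample_size(10, 0.5)$n_first    # 1024
#' recommended_sample_size(10, 0.025)$n_first  # 20480
#' @export
recommended_sample_size <- function(m, p_rarest, many_squares = FALSE) {
  check_count(m, "m"); if (m < 1) stop("'m' must be >= 1")
  if (!is.numeric(p_rarest) || p_rarest <= 0 || p_rarest > 1) {
    stop("'p_rarest' must be in (0, 1]")
  }
  phi <- (1 + sqrt(5)) / 2
  n_first <- 2^(m - 1) / p_rarest
  n_many <- n_first * phi
  out <- list(m = m, p_rarest = p_rarest, n_first = n_first, n_many = n_many,
              n = if (many_squares) n_many else n_first)
  class(out) <- "sample_size_rec"
  out
}

#' @export
print.sample_size_rec <- function(x, ...) {
  cat(sprintf("recommended n (m = %d, rarest p = %g):\n", x$m, x$p_rarest))
  cat(sprintf("  first complete square: %g\n", x$n_first))
  cat(sprintf("  many squares:          %g (golden-ratio multiple)\n", x$n_many))
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

check_count <- function(x, name, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x != round(x)) {
    stop(sprintf("'%s' must be a single non-negative integer", name))
  }
  if (x > max) stop(sprintf("'%s' must be <= %d", name, as.integer(max)))
  invisible(x)
}

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { r <- a %% b; a <- b; b <- r }
  a
}
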