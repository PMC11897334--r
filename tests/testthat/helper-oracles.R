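# Independent oracles and fixture builders.  These deliberately avoid the
# package's internal code paths (bitmask DFS, stable-sort process, etc.) so
# they can serve as cross-checks.

# exhaustive sample of all 2^m factor rows with outcome from y_fun(presence
# logical vector)
make_exhaustive_sample <- function(m, y_fun = function(pres) sum(pres)) {
  G <- as.matrix(expand.grid(rep(list(c(-1, 1)), m)))
  colnames(G) <- paste0("f_", letters[seq_len(m)])
  y <- apply(G > 0, 1, y_fun)
  data.frame(unit_id = seq_len(nrow(G)), t = seq_len(nrow(G)), G, y = y)
}

# brute-force complete-square search by explicit set operations
brute_force_squares <- function(sample, reference) {
  fcols <- grep("^f_", names(sample), value = TRUE)
  X <- as.matrix(sample[, fcols, drop = FALSE])
  ref <- X[match(reference, sample$unit_id), ]
  diffsets <- apply(X, 1, function(r) paste(sort(fcols[r != ref]), collapse = ","))
  present <- unique(diffsets)
  has <- function(set) paste(sort(set), collapse = ",") %in% present
  cyc_int <- function(ord, st, len) {
    mp <- length(ord)
    ord[((st - 1 + seq_len(len) - 1) %% mp) + 1]
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  found <- list()
  m <- length(fcols)
  for (mp in seq_len(m)) {
    subs <- utils::combn(fcols, mp, simplify = FALSE)
    for (S in subs) {
      tails <- perms(S[-1])
      for (tl in tails) {
        ord <- c(S[1], tl)   # canonical rotation: smallest name first
        ok <- TRUE
        for (st in seq_len(mp)) for (len in seq_len(mp)) {
          if (!has(cyc_int(ord, st, len))) { ok <- FALSE; break }
        }
        if (ok) found[[length(found) + 1]] <- ord
      }
    }
  }
  # maximality: drop orders that are cyclic-order-preserving subsequences of
  # a larger found order
  is_sub <- function(small, big) {
    if (length(small) >= length(big) || !all(small %in% big)) return(FALSE)
    nb <- length(big)
    for (rot in seq_len(nb)) {
      b <- big[((seq_len(nb) + rot - 2) %% nb) + 1]
      if (b[1] != small[1]) next
      j <- 1
      for (x in b) if (j <= length(small) && x == small[j]) j <- j + 1
      if (j > length(small)) return(TRUE)
    }
    FALSE
  }
  keep <- vapply(seq_along(found), function(i) {
    !any(vapply(seq_along(found), function(j) {
      length(found[[j]]) > length(found[[i]]) && is_sub(found[[i]], found[[j]])
    }, logical(1)))
  }, logical(1))
  found[keep]
}

# independent verifier: recompute difference sets and the nested-interval /
# intersection conditions of a returned square from the raw factor rows
verify_square_raw <- function(square, sample) {
  fcols <- grep("^f_", names(sample), value = TRUE)
  X <- as.matrix(sample[, fcols, drop = FALSE])
  ref <- X[match(square$reference, sample$unit_id), ]
  diffset <- function(uid) {
    r <- X[match(uid, sample$unit_id), ]
    sort(fcols[r != ref])
  }
  mp <- square$size
  ord <- square$order
  for (r in seq_len(mp)) {
    prev <- character(0)
    for (d in seq_len(mp)) {
      i <- which(square$cells$row == r & square$cells$col == d)
      ds <- diffset(square$cells$unit_id[i])
      want <- sort(ord[((r - 1 + seq_len(d) - 1) %% mp) + 1])
      if (!identical(ds, want)) return(FALSE)
      # nesting and one-factor growth
      if (!all(prev %in% ds) || length(ds) != length(prev) + 1) return(FALSE)
      prev <- ds
    }
    # reference cell
    i0 <- which(square$cells$row == r & square$cells$col == 0)
    if (length(diffset(square$cells$unit_id[i0])) != 0) return(FALSE)
  }
  TRUE
}

serialize_orders <- function(orders) {
  sort(vapply(orders, paste, character(1), collapse = "|"))
}

# brute-force exact Shapley value via the coalition formula, mean imputation
brute_shapley <- function(predictor, sample, factor) {
  fcols <- grep("^f_", names(sample), value = TRUE)
  X <- as.matrix(sample[, fcols, drop = FALSE])
  mu <- colMeans(X)
  others <- setdiff(fcols, factor)
  m <- length(fcols)
  val <- function(S) {
    Xs <- matrix(mu, nrow(X), m, byrow = TRUE)
    colnames(Xs) <- fcols
    if (length(S)) Xs[, S] <- X[, S]
    mean(predictor$predict(Xs))
  }
  total <- 0
  for (k in 0:length(others)) {
    Ss <- if (k == 0) list(character(0)) else
      utils::combn(others, k, simplify = FALSE)
    w <- factorial(k) * factorial(m - k - 1) / factorial(m)
    for (S in Ss) total <- total + w * (val(c(S, factor)) - val(S))
  }
  total
}

# brute-force optimal closed tour under Hamming distance (first city fixed)
brute_tsp_opt <- function(X) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X, method = "manhattan")) / 2
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(n)[-1])) {
    tour <- c(1, p)
    len <- sum(D[cbind(tour, c(tour[-1], tour[1]))])
    best <- min(best, len)
  }
  best
}

# cyclic factor stream with recurring gap structure: rows cycle through the
# nested chain (-,-,-) (+,-,-) (+,+,-) (+,+,+); outcomes add hidden_fun(n)
make_gap_stream <- function(n_cycles, hidden_fun, m = 3) {
  stopifnot(m == 3)
  rows <- list(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(1, 1, 1))
  n <- 4 * n_cycles
  X <- do.call(rbind, rep(rows, n_cycles))
  base <- rep(c(0, 1, 2, 3), n_cycles)
  y <- base + hidden_fun(n)
  data.frame(unit_id = seq_len(n), t = seq_len(n),
             f_a = X[, 1], f_b = X[, 2], f_c = X[, 3], y = y)
}
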