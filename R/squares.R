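#' Enumerate complete squares around a reference unit
#'
#' A square of size \code{m'} for reference unit \code{x0} is a factor order
#' \code{pi} of \code{m'} factors together with sample units realizing, as
#' factor-set differences from \code{x0}, every cyclic interval of
#' \code{pi}: cell (row r, column d) is a unit whose set of disagreeing
#' factors with \code{x0} equals \code{\{pi_r, ..., pi_(r+d-1)\}} (indices
#' cyclic).  Along each row the difference sets are nested and grow by
#' exactly one factor per column, which is what turns across-unit outcome
#' differences into effect observations under enumerated backgrounds.
#'
#' The search indexes deduplicated units by difference bitmask from the
#' reference and extends factor orders depth-first, pruning on the presence
#' of every contiguous interval; wrap-around intervals are checked on
#' completion.  Only complete squares are returned (no cell is ever
#' fabricated); returned squares are maximal under extension among those
#' found.  Units with identical factor rows are collapsed to one
#' representative (lowest time index, then lowest unit id) with outcomes
#' averaged over the duplicates.
#'
#' @param sample sample data.frame with \code{f_*} factor columns in
#'   \{-1, +1\}, and \code{unit_id}, \code{t}, \code{y} columns.
#' @param reference unit id of the reference unit \code{x0}.
#' @param max_size largest square size searched (default 10).
#' @param max_squares cap on the number of squares returned per reference
#'   (default 32).
#' @return An object of class \code{"square_set"}: list with \code{squares}
#'   (each of class \code{"square"} with \code{reference}, \code{order},
#'   \code{cells}, \code{size}, \code{complete}), the \code{reference} id,
#'   and \code{member_histogram}.
#' @examples
#' s <- data.frame(unit_id = 1:4, t = 1:4,
#'                 f_a = c(-1, 1, -1, 1), f_b = c(-1, -1, 1, 1),
#'                 y = c(0, 1, 0, 1))
#' sq <- enumerate_squares(s, reference = 1)
#' sq$squares[[1]]$order
#' @export
enumerate_squares <- function(sample, reference, max_size = 10L, max_squares = 32L) {
  fcols <- grep("^f_", names(sample), value = TRUE)
  m <- length(fcols)
  if (m == 0) stop("sample has no factor columns (f_*)")
  if (!reference %in% sample$unit_id) stop("reference unit not found in sample")
  X <- as.matrix(sample[, fcols, drop = FALSE])
  ref_row <- X[match(reference, sample$unit_id), ]

  # bitmask of disagreement with the reference, per unit
  masks <- as.integer((X != matrix(ref_row, nrow(X), m, byrow = TRUE)) %*% (2^(seq_len(m) - 1)))

  # collapse duplicate factor rows: representative by lowest t then unit_id,
  # outcome averaged over duplicates
  ord <- order(masks, sample$t, sample$unit_id)
  lookup <- new.env(parent = emptyenv())
  for (i in ord) {
    key <- as.character(masks[i])
    cur <- lookup[[key]]
    if (is.null(cur)) {
      lookup[[key]] <- list(unit_id = sample$unit_id[i], y_sum = sample$y[i], n = 1L)
    } else {
      cur$y_sum <- cur$y_sum + sample$y[i]; cur$n <- cur$n + 1L
      lookup[[key]] <- cur
    }
  }
  has_mask <- function(mk) !is.null(lookup[[as.character(mk)]])
  cell_unit <- function(mk) lookup[[as.character(mk)]]$unit_id
  cell_y <- function(mk) { e <- lookup[[as.character(mk)]]; e$y_sum / e$n }

  present_singletons <- which(vapply(seq_len(m), function(j) has_mask(2^(j - 1)), logical(1)))

  squares <- list()
  ref_values <- stats::setNames(ref_row, fcols)
  interval_mask <- function(order_idx, start, len) {
    mp <- length(order_idx)
    pos <- ((start - 1 + seq_len(len) - 1) %% mp) + 1
    sum(2^(order_idx[pos] - 1))
  }

  found_orders <- list()  # per size, list of integer order vectors
  top_size <- min(max_size, m)
  n_found <- 0L
  for (mp in seq(top_size, 1)) {
    if (n_found >= max_squares) break
    res <- list()
    # DFS over orders of length mp; canonical start: smallest factor index first
    dfs <- function(chosen) {
      if (length(res) + n_found >= max_squares) return()
      k <- length(chosen)
      if (k == mp) {
        # wrap-around intervals (all non-wrapping ones, including the full
        # set, were checked during extension)
        if (mp >= 3) for (st in 3:mp) {
          lo <- mp - st + 2
          if (lo > mp - 1) next
          for (len in lo:(mp - 1)) {
            if (!has_mask(interval_mask(chosen, st, len))) return()
          }
        }
        res[[length(res) + 1L]] <<- chosen
        return()
      }
      cands <- setdiff(present_singletons, chosen)
      if (k == 0) {
        for (f in cands) dfs(f)
        return()
      }
      for (f in cands) {
        # canonical rotation: keep first element the smallest
        if (f < chosen[1]) next
        ok <- TRUE
        new <- c(chosen, f)
        for (i in seq_len(k + 1)) {  # non-wrapping intervals ending at k+1
          mk <- sum(2^(new[i:(k + 1)] - 1))
          if (!has_mask(mk)) { ok <- FALSE; break }
        }
        if (ok) dfs(new)
      }
    }
    dfs(integer(0))
    if (length(res)) {
      # maximality: drop orders that are cyclic subsequences of larger squares
      keep <- vapply(res, function(o) {
        !any(vapply(found_orders, function(big) is_cyclic_subseq(o, big), logical(1)))
      }, logical(1))
      res <- res[keep]
      for (o in res) {
        sqr <- build_square(o, reference, fcols, interval_mask, cell_unit,
                            cell_y, ref_values)
        squares[[length(squares) + 1L]] <- sqr
        found_orders[[length(found_orders) + 1L]] <- o
        n_found <- n_found + 1L
        if (n_found >= max_squares) break
      }
    }
  }

  out <- list(squares = squares, reference = reference,
              factor_names = fcols, m = m)
  class(out) <- "square_set"
  out$member_histogram <- member_histogram(out)
  out
}

build_square <- function(order_idx, reference, fcols, interval_mask, cell_unit,
                         cell_y, ref_values) {
  mp <- length(order_idx)
  rows <- integer(0); cols <- integer(0); units <- numeric(0); ys <- numeric(0)
  for (r in seq_len(mp)) {
    for (d in 0:mp) {
      if (d == 0) {
        mk <- 0
      } else {
        mk <- interval_mask(order_idx, r, d)
      }
      rows <- c(rows, r); cols <- c(cols, d)
      if (mk == 0) {
        units <- c(units, reference); ys <- c(ys, cell_y(0))
      } else {
        units <- c(units, cell_unit(mk)); ys <- c(ys, cell_y(mk))
      }
    }
  }
  sq <- list(reference = reference,
             order = fcols[order_idx],
             order_idx = order_idx,
             size = mp,
             cells = data.frame(row = rows, col = cols, unit_id = units, y = ys),
             ref_values = ref_values,
             complete = TRUE)
  class(sq) <- "square"
  sq
}

is_cyclic_subseq <- function(small, big) {
  # is 'small' obtainable from circular order 'big' by deleting elements,
  # preserving cyclic order? check all rotations of big for a (linear)
  # subsequence match of some rotation of small anchored at small[1]
  if (!all(small %in% big)) return(FALSE)
  nb <- length(big)
  for (rot in seq_len(nb)) {
    b <- big[((seq_len(nb) + rot - 2) %% nb) + 1]
    if (b[1] != small[1]) next
    j <- 1
    for (x in b) {
      if (j <= length(small) && x == small[j]) j <- j + 1
    }
    if (j > length(small)) return(TRUE)
  }
  FALSE
}

#' @export
print.square <- function(x, ...) {
  cat(sprintf("square (size %d) around reference unit %s\n", x$size, x$reference))
  cat("  order:", paste(x$order, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
print.square_set <- function(x, ...) {
  cat(sprintf("%d square(s) around reference unit %s (m = %d)\n",
              length(x$squares), x$reference, x$m))
  if (length(x$squares)) {
    cat("  sizes:", paste(vapply(x$squares, `[[`, integer(1), "size"), collapse = " "), "\n")
  }
  invisible(x)
}

#' Histogram of square member units by difference size
#'
#' Counts the distinct units participating in a square set at each
#' difference-set size from the reference (column index d = 1..m').
#'
#' @param squares a \code{"square_set"}.
#' @return Named integer vector, one entry per difference size.
#' @export
member_histogram <- function(squares) {
  stopifnot(inherits(squares, "square_set"))
  m <- squares$m
  counts <- stats::setNames(integer(m), as.character(seq_len(m)))
  if (length(squares$squares) == 0) return(counts)
  seen <- list()
  for (sq in squares$squares) {
    cl <- sq$cells[sq$cells$col > 0, ]
    for (i in seq_len(nrow(cl))) {
      key <- as.character(cl$unit_id[i])
      if (is.null(seen[[key]])) {
        seen[[key]] <- cl$col[i]
        counts[cl$col[i]] <- counts[cl$col[i]] + 1L
      }
    }
  }
  counts
}

#' Effect observations carried by a square
#'
#' Walks each row of a square across adjacent column pairs: the cell at
#' column d differs from the cell at column d-1 by exactly one factor (the
#' one added), observed against the background of the factors earlier in
#' the row.  The outcome difference between the two cells is one effect
#' observation \eqn{\Delta y(factor | background)}.  Observations are
#' oriented to the canonical -1 to +1 transition of the added factor (a
#' reference already carrying the factor at +1 observes the reverse
#' transition, so its difference is negated), and the reported background
#' is the absolute +1-set of the baseline cell, so observations pooled
#' across references with different factor rows stay comparable.  Repeated
#' (factor, background) pairs are averaged; incomplete cells (missing
#' outcome) are skipped with a warning, never fabricated.
#'
#' @param square a \code{"square"}.
#' @param outcomes optional named vector of outcomes by unit id; defaults to
#'   the outcomes stored in the square's cells (duplicate-averaged sample
#'   outcomes).
#' @return data.frame with columns \code{factor}, \code{background}
#'   (comma-separated sorted factor names at +1 in the baseline cell, ""
#'   for the empty background), \code{col}, \code{dy}, \code{n} (number of
#'   raw observations averaged).
#' @export
effect_observations <- function(square, outcomes = NULL) {
  stopifnot(inherits(square, "square"))
  mp <- square$size
  if (mp < 1) return(empty_observations())
  cells <- square$cells
  gety <- function(row, col) {
    i <- which(cells$row == row & cells$col == col)
    u <- cells$unit_id[i]
    if (!is.null(outcomes)) {
      v <- outcomes[as.character(u)]
      if (is.na(v)) return(NA_real_)
      return(as.numeric(v))
    }
    cells$y[i]
  }
  rv <- square$ref_values
  if (is.null(rv)) rv <- stats::setNames(rep(-1, mp), square$order)
  plus_ref <- names(rv)[rv > 0]
  fac <- character(0); bg <- character(0); col <- integer(0); dy <- numeric(0)
  skipped <- 0L
  for (r in seq_len(mp)) {
    for (d in seq_len(mp)) {
      pos <- ((r - 1 + d - 1) %% mp) + 1
      f <- square$order[pos]
      bpos <- if (d > 1) ((r - 1 + seq_len(d - 1) - 1) %% mp) + 1 else integer(0)
      flipped <- square$order[bpos]
      # absolute +1-set of the baseline cell: reference's +1 factors XOR the
      # factors flipped so far along the row
      b <- paste(sort(union(setdiff(plus_ref, flipped),
                            setdiff(flipped, plus_ref))), collapse = ",")
      y1 <- gety(r, d); y0 <- gety(r, d - 1)
      if (is.na(y1) || is.na(y0)) { skipped <- skipped + 1L; next }
      orient <- if (f %in% plus_ref) -1 else 1
      fac <- c(fac, f); bg <- c(bg, b); col <- c(col, d)
      dy <- c(dy, orient * (y1 - y0))
    }
  }
  if (skipped > 0) warning(sprintf("%d observation(s) skipped: missing outcomes", skipped))
  if (length(fac) == 0) return(empty_observations())
  df <- data.frame(factor = fac, background = bg, col = col, dy = dy,
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(dy ~ factor + background + col, data = df, FUN = mean)
  cnt <- stats::aggregate(dy ~ factor + background + col, data = df, FUN = length)
  agg$n <- cnt$dy
  agg[order(agg$factor, agg$col, agg$background), , drop = FALSE]
}

empty_observations <- function() {
  data.frame(factor = character(0), background = character(0),
             col = integer(0), dy = numeric(0), n = integer(0))
}

#' Observations pooled over a square set
#'
#' Convenience wrapper applying [effect_observations()] to every square and
#' row-binding the results (squares indexed by \code{square}).
#'
#' @param squares a \code{"square_set"}.
#' @param outcomes optional named outcome vector by unit id.
#' @return data.frame as in [effect_observations()] plus a \code{square}
#'   index column.
#' @export
square_set_observations <- function(squares, outcomes = NULL) {
  stopifnot(inherits(squares, "square_set"))
  out <- lapply(seq_along(squares$squares), function(i) {
    o <- effect_observations(squares$squares[[i]], outcomes)
    if (nrow(o)) o$square <- i
    o
  })
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (length(out) == 0) {
    e <- empty_observations(); e$square <- integer(0); return(e)
  }
  do.call(rbind, out)
}

#' Sample transversal orders
#'
#' Orders the units of a sample for sequential feeding to a learner or
#' estimator: \code{"square"} emits column-1 cells of all squares, then
#' column-2 cells, and so on (left-to-right across squares; references
#' first); \code{"square_column"} emits all columns of square 1, then square
#' 2, and so on (within squares); \code{"random"} is a seeded shuffle;
#' \code{"tsp"} orders units along a metric-TSP double-minimum-spanning-tree
#' 2-approximation under Hamming distance on factor vectors.  Units not in
#' any square are appended in time order.
#'
#' @param sample sample data.frame.
#' @param squares a \code{"square_set"} (required for square methods; may be
#'   NULL for \code{"random"} and \code{"tsp"}).
#' @param method one of \code{"random"}, \code{"square"},
#'   \code{"square_column"}, \code{"tsp"}.
#' @param seed optional integer seed for the random shuffle and TSP root.
#' @return Object of class \code{"transversal_order"}: list with
#'   \code{order} (unit ids, a permutation of the sample's units) and
#'   \code{method}.
#' @export
transversal <- function(sample, squares = NULL,
                        method = c("random", "square", "square_column", "tsp"),
                        seed = NULL) {
  method <- match.arg(method)
  ids <- sample$unit_id
  if (!is.null(seed)) set.seed(seed)
  ord <- switch(method,
    random = ids[sample.int(length(ids))],
    square = {
      need_squares(squares)
      sqs <- squares$squares
      maxd <- max(vapply(sqs, `[[`, integer(1), "size"))
      picked <- numeric(0)
      for (d in 0:maxd) for (sq in sqs) {
        cl <- sq$cells[sq$cells$col == d, ]
        picked <- c(picked, cl$unit_id)
      }
      unique(picked)
    },
    square_column = {
      need_squares(squares)
      picked <- numeric(0)
      for (sq in squares$squares) {
        cl <- sq$cells[order(sq$cells$col, sq$cells$row), ]
        picked <- c(picked, cl$unit_id)
      }
      unique(picked)
    },
    tsp = {
      fcols <- grep("^f_", names(sample), value = TRUE)
      X <- as.matrix(sample[, fcols, drop = FALSE])
      ids[tsp_order(X)]
    })
  rest <- setdiff(ids, ord)
  if (length(rest)) {
    rest <- rest[order(sample$t[match(rest, ids)])]
    ord <- c(ord, rest)
  }
  out <- list(order = ord, method = method)
  class(out) <- "transversal_order"
  out
}

need_squares <- function(squares) {
  if (is.null(squares) || !inherits(squares, "square_set") ||
      length(squares$squares) == 0) {
    stop("a non-empty square_set is required for square transversals")
  }
}

#' @export
print.transversal_order <- function(x, ...) {
  cat(sprintf("%s transversal of %d units\n", x$method, length(x$order)))
  invisible(x)
}

# double-MST preorder 2-approximation to the metric TSP on Hamming distance
tsp_order <- function(X) {
  n <- nrow(X)
  if (n <= 2) return(seq_len(n))
  D <- hamming_dist(X)
  # Prim MST from unit 1
  in_tree <- rep(FALSE, n); in_tree[1] <- TRUE
  parent <- rep(NA_integer_, n)
  key <- D[1, ]; key[1] <- 0
  parent[key < Inf] <- 1L
  for (it in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(key[cand])]
    in_tree[v] <- TRUE
    upd <- !in_tree & D[v, ] < key
    key[upd] <- D[v, upd]
    parent[upd] <- v
  }
  children <- split(seq_len(n)[-1], parent[-1])
  ord <- integer(0)
  stack <- 1L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ord <- c(ord, v)
    ch <- children[[as.character(v)]]
    if (!is.null(ch)) stack <- c(stack, rev(sort(ch)))
  }
  ord
}

hamming_dist <- function(X) {
  n <- nrow(X)
  G <- X %*% t(X)  # for +-1 rows: m - 2 * hamming
  (ncol(X) - G) / 2
}

#' Tour length under Hamming distance
#'
#' Length of the closed tour visiting units in the given order, with
#' Hamming distance on the \code{f_*} columns.
#'
#' @param sample sample data.frame.
#' @param order unit ids in visiting order.
#' @return Numeric tour length.
#' @export
tour_length <- function(sample, order) {
  fcols <- grep("^f_", names(sample), value = TRUE)
  X <- as.matrix(sample[match(order, sample$unit_id), fcols, drop = FALSE])
  n <- nrow(X)
  idx2 <- c(2:n, 1)
  sum(rowSums(X != X[idx2, , drop = FALSE]))
}
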