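# Assignment solvers over a raw cost matrix. These are the combinatorial
# kernels behind match_peaks(); they are exported because cost-matrix-level
# access is useful for testing and for didactic examples.

#' Solve a peak assignment problem on a cost matrix
#'
#' Finds a one-to-one matching that covers every row (or every column, if
#' there are fewer columns) of a nonnegative cost matrix.
#'
#' * `method = "optimal"`: minimum-cost bipartite assignment (Hungarian
#'   algorithm); the total matched cost is the global minimum.
#' * `method = "greedy"`: repeatedly pick the globally smallest remaining
#'   entry, delete its row and column, until the shorter side is exhausted
#'   -- the "sort the distances" strategy a spectroscopist applies by hand.
#'   Ties break by lowest row index, then lowest column index.
#' * `method = "brute"`: exhaustive enumeration of all injections of the
#'   shorter side into the longer (test oracle; requires `min(n, m) <= 8`).
#'   Cost ties resolve to the lexicographically smallest assignment vector.
#'
#' @param cost numeric matrix of nonnegative finite costs.
#' @param method `"optimal"`, `"greedy"` or `"brute"`.
#' @return A list with `assignment` (integer vector, length `nrow(cost)`;
#'   `assignment[i]` is the column matched to row i, `NA` for unmatched
#'   rows) and `total` (sum of matched costs).
#' @examples
#' d <- matrix(c(1, 2, 2, 10), 2, 2, byrow = TRUE)
#' solve_assignment(d, "greedy")$total   # 11: the greedy trap
#' solve_assignment(d, "optimal")$total  # 4
#' @export
solve_assignment <- function(cost, method = c("optimal", "greedy", "brute")) {
  method <- match.arg(method)
  cost <- as.matrix(cost)
  if (any(!is.finite(cost))) stop_input("cost matrix entries must be finite")
  switch(method,
         optimal = lsap_solve(cost),
         greedy = greedy_solve(cost),
         brute = brute_solve(cost))
}

# Hungarian solve handling the nrow > ncol case by transposition.
lsap_solve <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n <= m) {
    a <- lsap_cpp(cost)
  } else {
    ta <- lsap_cpp(t(cost))          # assigns each column to a row
    a <- rep(NA_integer_, n)
    a[ta] <- seq_len(m)
  }
  list(assignment = a, total = assignment_total(cost, a))
}

greedy_solve <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  work <- cost
  a <- rep(NA_integer_, n)
  for (step in seq_len(min(n, m))) {
    pick <- min_entry(work)
    a[pick[1L]] <- pick[2L]
    work[pick[1L], ] <- Inf
    work[, pick[2L]] <- Inf
  }
  list(assignment = a, total = assignment_total(cost, a))
}

# Smallest finite entry; ties by lowest row, then lowest column.
min_entry <- function(mat) {
  mv <- min(mat)
  cand <- which(mat == mv, arr.ind = TRUE)
  cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
  c(cand[1L, 1L], cand[1L, 2L])
}

# Exhaustive minimum over all injections; pure R, independent of the
# Hungarian kernel. Ties -> lexicographically smallest assignment vector.
brute_solve <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (min(n, m) > 8L)
    stop_input("brute-force oracle limited to min(n, m) <= 8 (got %d x %d)",
               n, m)
  transposed <- n > m
  d <- if (transposed) t(cost) else cost
  nr <- nrow(d); nc <- ncol(d)

  best <- list(total = Inf, assignment = NULL)
  used <- rep(FALSE, nc)
  cur <- integer(nr)
  recurse <- function(row, acc) {
    if (row > nr) {
      if (acc < best$total ||
          (acc == best$total && !is.null(best$assignment) &&
           lex_less(cur, best$assignment))) {
        best <<- list(total = acc, assignment = cur)
      }
      return(invisible())
    }
    for (j in seq_len(nc)) {
      if (!used[j]) {
        used[j] <<- TRUE
        cur[row] <<- j
        recurse(row + 1L, acc + d[row, j])
        used[j] <<- FALSE
      }
    }
  }
  recurse(1L, 0)

  if (transposed) {
    a <- rep(NA_integer_, n)
    a[best$assignment] <- seq_len(m)
  } else {
    a <- best$assignment
  }
  list(assignment = a, total = assignment_total(cost, a))
}

lex_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0L && a[d[1L]] < b[d[1L]]
}

assignment_total <- function(cost, a) {
  rows <- which(!is.na(a))
  sum(cost[cbind(rows, a[rows])])
}
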