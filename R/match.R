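#' Match peaks between a free-protein and a protein:ligand spectrum
#'
#' The central fitting function: pairs every peak of the shorter list with a
#' distinct peak of the longer one so that chemical shift perturbations
#' (CSPs, [csp_distance()]) can be read off per residue. Four algorithms are
#' available:
#'
#' * `"sd"` (Sorting Distances): greedy -- repeatedly match the two closest
#'   unmatched peaks. Mimics the manual approach of assigning the least
#'   shifted peaks first.
#' * `"ra"` (Resource Allocation): treats matching as a minimum-cost
#'   bipartite assignment problem and returns the matching with the smallest
#'   total CSP (Hungarian algorithm). This is the "Proximity" mode of the
#'   workflow and needs no assignments.
#' * `"sds"` (Sorting Distances Smart): greedy like SD, but a candidate pair
#'   is scored by how well its CSP agrees with the average CSP of the
#'   residue's sequence neighbours ([window_mean()], window of 7 by
#'   default), exploiting the empirical clustering of CSPs along the
#'   sequence. Neighbourhood averages start from an all-zero profile, are
#'   updated after every accepted pair, and whole passes are repeated --
#'   each seeded with the previous pass's final profile -- until the pairing
#'   stabilises.
#' * `"ras"` (Resource Allocation Smart): the "Smart" mode. Solves RA, then
#'   iteratively rescales each row i of the cost matrix by
#'   1 / max(neighbourhood average CSP of residue i, `epsilon`) and
#'   re-solves, penalising assignments whose CSP deviates from the local
#'   sequence context; stops when the pairing is stable or after
#'   `max_iter` rounds. Reported CSPs always come from the unscaled
#'   distances -- the rescaling is only a search heuristic.
#'
#' `"brute"` exhaustively enumerates all matchings (small lists only) and is
#' provided as an oracle. The two Smart algorithms require residue
#' assignments on the reference list; unassigned reference peaks are
#' neglected (dropped with a warning). Ties on any "smallest" selection
#' break by lowest reference row, then lowest target column; SDS score ties
#' additionally prefer the smaller raw distance first.
#'
#' @param ref reference [peak_list] (free protein).
#' @param tgt target [peak_list] (protein:ligand mixture), same
#'   heteronucleus.
#' @param method `"ras"`, `"ra"`, `"sds"`, `"sd"` or `"brute"`.
#' @param het_scale heteronuclear scaling divisor of [csp_distance()]
#'   (default 5).
#' @param window_k sequence window width for the Smart algorithms
#'   (default 7).
#' @param max_iter iteration cap for the Smart algorithms (default 50).
#' @param epsilon floor for neighbourhood averages used as divisors in RAS.
#' @return An object of class `peak_match` with components `pairs` (data
#'   frame: `ref_id`, `ref_residue`, `ref_label`, `tgt_id`, `csp`),
#'   `unmatched_ref`, `unmatched_tgt`, `dropped_ref` (unassigned reference
#'   peaks neglected by a Smart method), `method`, `total_cost`,
#'   `iterations`, `converged`, the `ref` and `tgt` lists used, and the
#'   matching parameters. Methods: [print()], [summary()],
#'   [coef()][csp_profile()], [plot()].
#' @examples
#' sim <- simulate_hsqc_pair(n_residues = 40, seed = 7)
#' fit <- match_peaks(sim$ref, sim$tgt, method = "ras")
#' fit
#' head(coef(fit))
#' @export
match_peaks <- function(ref, tgt,
                        method = c("ras", "ra", "sds", "sd", "brute"),
                        het_scale = 5, window_k = 7, max_iter = 50,
                        epsilon = 1e-6) {
  method <- match.arg(method)
  stopifnot(inherits(ref, "peak_list"), inherits(tgt, "peak_list"))
  if (max_iter < 1) stop_input("max_iter must be >= 1")
  if (epsilon <= 0) stop_input("epsilon must be > 0")

  dropped_ref <- character(0)
  if (method %in% c("sds", "ras")) {
    if (!any(!is.na(ref$residue_index)))
      stop_input("method '%s' requires residue assignments on the reference peak list",
                 method)
    if (anyNA(ref$residue_index)) {
      dropped_ref <- ref$peak_id[is.na(ref$residue_index)]
      warning(sprintf("%d unassigned reference peak(s) neglected by method '%s'",
                      length(dropped_ref), method))
      ref <- drop_unassigned(ref)
    }
  }

  d <- csp_matrix(ref, tgt, het_scale = het_scale)
  fit <- switch(method,
                sd = c(solve_assignment(d, "greedy"),
                       list(iterations = 1L, converged = TRUE)),
                ra = c(solve_assignment(d, "optimal"),
                       list(iterations = 1L, converged = TRUE)),
                brute = c(solve_assignment(d, "brute"),
                          list(iterations = 1L, converged = TRUE)),
                sds = sds_solve(d, ref$residue_index, window_k, max_iter),
                ras = ras_solve(d, ref$residue_index, window_k, max_iter,
                                epsilon))

  a <- fit$assignment
  matched <- which(!is.na(a))
  pairs <- data.frame(ref_id = ref$peak_id[matched],
                      ref_residue = ref$residue_index[matched],
                      ref_label = ref$residue_label[matched],
                      tgt_id = tgt$peak_id[a[matched]],
                      csp = d[cbind(matched, a[matched])],
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 unmatched_ref = ref$peak_id[is.na(a)],
                 unmatched_tgt = setdiff(tgt$peak_id, pairs$tgt_id),
                 dropped_ref = dropped_ref,
                 method = toupper(method),
                 total_cost = fit$total,
                 iterations = fit$iterations,
                 converged = fit$converged,
                 het_scale = het_scale, window_k = window_k,
                 max_iter = max_iter, epsilon = epsilon,
                 ref = ref, tgt = tgt,
                 call = match.call()),
            class = "peak_match")
}

# Sorting Distances Smart. Greedy over the score |d_ij - avg_i|, where avg_i
# is the windowed neighbourhood average of residue i's CSP profile. The
# profile starts all-zero (so the first pass reduces to SD ordering), is
# updated after each accepted pair, and passes repeat -- seeded with the
# previous pass's final profile -- until the pairing repeats.
sds_solve <- function(d, residues, window_k, max_iter) {
  n <- nrow(d); m <- ncol(d)
  res_chr <- as.character(residues)
  profile <- stats::setNames(rep(0, n), res_chr)
  prev <- NULL
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    a <- rep(NA_integer_, n)
    col_free <- rep(TRUE, m)
    row_free <- rep(TRUE, n)
    for (step in seq_len(min(n, m))) {
      avg <- window_mean(profile, residues, window_k)
      score <- abs(d - avg)            # avg recycles down columns: row-wise
      score[!row_free, ] <- Inf
      score[, !col_free] <- Inf
      pick <- sds_pick(score, d)
      i <- pick[1L]; j <- pick[2L]
      a[i] <- j
      row_free[i] <- FALSE
      col_free[j] <- FALSE
      profile[res_chr[i]] <- d[i, j]   # recalc averages after each pair
    }
    if (!is.null(prev) && identical(a, prev)) { converged <- TRUE; break }
    prev <- a
  }
  list(assignment = prev, total = assignment_total(d, prev),
       iterations = it, converged = converged)
}

# Smallest score; ties by smaller raw distance, then row, then column.
sds_pick <- function(score, d) {
  mv <- min(score)
  cand <- which(score == mv, arr.ind = TRUE)
  if (nrow(cand) > 1L) {
    dv <- d[cand]
    cand <- cand[dv == min(dv), , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
  }
  c(cand[1L, 1L], cand[1L, 2L])
}

# Resource Allocation Smart. Repeated Hungarian solves on a row-rescaled
# matrix d_ij / max(avg_i, epsilon); avg_i is recomputed from the CSP
# profile of the current solution, and the rescaling is always applied to
# the *original* distances, which are also the reported CSPs.
ras_solve <- function(d, residues, window_k, max_iter, epsilon) {
  sol <- lsap_solve(d)
  it <- 1L
  converged <- FALSE
  while (it < max_iter) {
    matched <- which(!is.na(sol$assignment))
    profile <- stats::setNames(d[cbind(matched, sol$assignment[matched])],
                               as.character(residues[matched]))
    avg <- window_mean(profile, residues, window_k)
    d2 <- d / pmax(avg, epsilon)       # row-wise rescale
    nxt <- lsap_solve(d2)
    it <- it + 1L
    same <- identical(nxt$assignment, sol$assignment)
    sol <- nxt
    if (same) { converged <- TRUE; break }
  }
  a <- sol$assignment
  list(assignment = a, total = assignment_total(d, a),
       iterations = it, converged = converged)
}
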