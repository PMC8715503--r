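#' Score a match against curated target assignments
#'
#' When the target peak list also carries residue assignments (determined
#' independently, e.g. by multidimensional NMR), the accuracy of a matching
#' is the percentage of predicted pairs whose target peak is curated to the
#' same residue as the reference peak. Pairs whose target peak carries no
#' curated assignment are not scored. The percentage is reported at full
#' precision and rounded half-up to an integer for table-style comparison.
#'
#' @param fit a [peak_match].
#' @return An object of class `accuracy_report`: `n_scored`, `n_correct`,
#'   `accuracy_pct`, `accuracy_int`, `n_unscored`, and `mismatches` (data
#'   frame: residue, predicted target peak, the peak curated to that
#'   residue or `NA` if absent).
#' @examples
#' sim <- simulate_hsqc_pair(n_residues = 30, seed = 3)
#' score_accuracy(match_peaks(sim$ref, sim$tgt, method = "ra"))
#' @export
score_accuracy <- function(fit) {
  stopifnot(inherits(fit, "peak_match"))
  tgt <- fit$tgt
  if (!any(!is.na(tgt$residue_index)))
    stop_input("accuracy scoring requires curated residue assignments on the target peak list")
  p <- fit$pairs
  pred_tgt_res <- tgt$residue_index[match(p$tgt_id, tgt$peak_id)]
  scored <- !is.na(pred_tgt_res) & !is.na(p$ref_residue)
  correct <- scored & pred_tgt_res == p$ref_residue
  n_scored <- sum(scored)
  if (n_scored == 0L)
    stop_input("no predicted pair could be scored against the curated assignments")
  n_correct <- sum(correct)

  bad <- which(scored & !correct)
  mismatches <- data.frame(
    residue_index = p$ref_residue[bad],
    predicted_tgt = p$tgt_id[bad],
    true_tgt = tgt$peak_id[match(p$ref_residue[bad], tgt$residue_index)],
    stringsAsFactors = FALSE)
  mismatches <- mismatches[order(mismatches$residue_index), ]
  rownames(mismatches) <- NULL

  pct <- 100 * n_correct / n_scored
  structure(list(n_scored = n_scored, n_correct = n_correct,
                 accuracy_pct = pct,
                 accuracy_int = round_half_up(pct),
                 n_unscored = nrow(p) - n_scored,
                 mismatches = mismatches,
                 method = fit$method),
            class = "accuracy_report")
}

round_half_up <- function(x) floor(x + 0.5)

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Assignment accuracy (%s): %.1f%% (%d of %d scored pairs; %d%% rounded)\n",
              x$method, x$accuracy_pct, x$n_correct, x$n_scored,
              x$accuracy_int))
  if (x$n_unscored > 0L)
    cat(sprintf("  %d pair(s) without curated target assignment excluded\n",
                x$n_unscored))
  if (nrow(x$mismatches) > 0L) {
    cat(sprintf("  %d mismatched residue(s):\n", nrow(x$mismatches)))
    print(x$mismatches, row.names = FALSE)
  }
  invisible(x)
}

#' Compare predicted and previously determined assignments
#'
#' The "input labeled" comparison: both peak lists must be assigned. Scores
#' exactly as [score_accuracy()] and additionally returns the full
#' per-residue comparison table (residue, predicted target peak, curated
#' target peak, agreement flag) in component `comparison`.
#'
#' @param fit a [peak_match] whose reference and target lists both carry
#'   assignments.
#' @return An `accuracy_report` with the extra `comparison` data frame.
#' @export
compare_labeled <- function(fit) {
  stopifnot(inherits(fit, "peak_match"))
  if (anyNA(fit$ref$residue_index))
    stop_input("labeled comparison requires a fully assigned reference list")
  rep <- score_accuracy(fit)
  p <- fit$pairs
  tgt <- fit$tgt
  pred_tgt_res <- tgt$residue_index[match(p$tgt_id, tgt$peak_id)]
  comparison <- data.frame(
    residue_index = p$ref_residue,
    predicted_tgt = p$tgt_id,
    curated_tgt = tgt$peak_id[match(p$ref_residue, tgt$residue_index)],
    scored = !is.na(pred_tgt_res),
    agree = !is.na(pred_tgt_res) & pred_tgt_res == p$ref_residue,
    stringsAsFactors = FALSE)
  comparison <- comparison[order(comparison$residue_index), ]
  rownames(comparison) <- NULL
  rep$comparison <- comparison
  rep
}

#' Write an accuracy report to csv
#'
#' @param report an `accuracy_report`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_accuracy <- function(report, path) {
  stopifnot(inherits(report, "accuracy_report"))
  hdr <- data.frame(key = c("method", "n_scored", "n_correct",
                            "accuracy_pct", "accuracy_int"),
                    value = c(report$method, report$n_scored,
                              report$n_correct,
                              sprintf("%.1f", report$accuracy_pct),
                              report$accuracy_int),
                    stringsAsFactors = FALSE)
  write_csv_checked(hdr, path)
}
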