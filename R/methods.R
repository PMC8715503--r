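#' Per-residue CSP profile of a match
#'
#' Extracts the chemical shift perturbation of every matched, assigned
#' reference residue, sorted by sequence position. This is the quantity
#' plotted in the per-residue CSP histogram and fed to
#' [classify_residues()].
#'
#' @param fit a [peak_match].
#' @return Named numeric vector: names are residue indices, values CSPs in
#'   ppm; attribute `labels` carries the residue labels.
#' @export
csp_profile <- function(fit) {
  stopifnot(inherits(fit, "peak_match"))
  p <- fit$pairs[!is.na(fit$pairs$ref_residue), ]
  if (nrow(p) == 0L)
    stop_input("no assigned residues among the matched pairs")
  p <- p[order(p$ref_residue), ]
  structure(stats::setNames(p$csp, as.character(p$ref_residue)),
            labels = p$ref_label)
}

#' @rdname csp_profile
#' @param object a [peak_match].
#' @param ... unused.
#' @export
coef.peak_match <- function(object, ...) csp_profile(object)

#' @export
print.peak_match <- function(x, ...) {
  cat(sprintf("Peak match (%s): %d pairs, total CSP %.4f ppm\n",
              x$method, nrow(x$pairs), x$total_cost))
  cat(sprintf("  reference '%s' (%d peaks) vs target '%s' (%d peaks), HetScale %g\n",
              attr(x$ref, "spectrum_name"), nrow(x$ref),
              attr(x$tgt, "spectrum_name"), nrow(x$tgt), x$het_scale))
  if (x$method %in% c("SDS", "RAS"))
    cat(sprintf("  %d iteration(s), %s\n", x$iterations,
                if (x$converged) "converged" else "iteration cap reached"))
  if (length(x$unmatched_ref) || length(x$unmatched_tgt))
    cat(sprintf("  unmatched: %d reference, %d target peak(s)\n",
                length(x$unmatched_ref), length(x$unmatched_tgt)))
  if (length(x$dropped_ref))
    cat(sprintf("  %d unassigned reference peak(s) neglected\n",
                length(x$dropped_ref)))
  invisible(x)
}

#' @export
summary.peak_match <- function(object, ...) {
  prof <- tryCatch(csp_profile(object), error = function(e) NULL)
  acc <- if (!anyNA(object$tgt$residue_index) &&
             !is.null(prof))
    tryCatch(score_accuracy(object), error = function(e) NULL)
  structure(list(fit = object, profile = prof, accuracy = acc),
            class = "summary.peak_match")
}

#' @export
print.summary.peak_match <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$profile)) {
    q <- stats::quantile(x$profile, c(0, .5, 1))
    cat(sprintf("  CSP per residue (n = %d): min %.4f, median %.4f, max %.4f ppm\n",
                length(x$profile), q[1], q[2], q[3]))
    top <- sort(x$profile, decreasing = TRUE)
    top <- top[seq_len(min(5L, length(top)))]
    cat("  largest CSPs:",
        paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  }
  if (!is.null(x$accuracy)) {
    cat(sprintf("  accuracy vs curated target assignments: %.1f%% (%d/%d)\n",
                x$accuracy$accuracy_pct, x$accuracy$n_correct,
                x$accuracy$n_scored))
  }
  invisible(x)
}

#' Per-residue CSP histogram
#'
#' Bar plot of the CSPs along the sequence, with the whole-protein mean and
#' the +1, +2 and +4 standard-deviation thresholds used by
#' [classify_residues()] drawn as reference lines.
#'
#' @param x a [peak_match].
#' @param thresholds draw the mean/SD threshold lines?
#' @param ... passed to [graphics::barplot()].
#' @export
plot.peak_match <- function(x, thresholds = TRUE, ...) {
  prof <- csp_profile(x)
  bp <- graphics::barplot(prof, names.arg = names(prof),
                          xlab = "residue", ylab = "CSP (ppm)",
                          main = sprintf("CSP profile (%s)", x$method),
                          las = 2, cex.names = 0.6, ...)
  if (thresholds && length(prof) >= 2L) {
    mu <- mean(prof); sd0 <- pop_sd(prof)
    graphics::abline(h = mu, lty = 1, col = "grey40")
    graphics::abline(h = mu + c(1, 2, 4) * sd0, lty = c(3, 2, 4),
                     col = c("grey40", "red3", "purple"))
    graphics::legend("topright", bty = "n", lty = c(1, 3, 2, 4),
                     col = c("grey40", "grey40", "red3", "purple"),
                     legend = c("mean", "+1 SD", "+2 SD", "+4 SD"),
                     cex = 0.8)
  }
  invisible(bp)
}
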