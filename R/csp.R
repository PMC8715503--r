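#' Chemical shift perturbation distance
#'
#' The CSP of a residue is the weighted Euclidean distance between its peak
#' positions in the two spectra,
#' \deqn{CSP = \sqrt{\Delta\delta_H^2 + (\Delta\delta_{het}/HetScale)^2}}
#' where the heteronuclear shift difference (\eqn{^{15}}N or \eqn{^{13}}C) is
#' divided by `het_scale` to compensate for the wider ppm range of the
#' heteronucleus. The default `het_scale = 5` is applied uniformly to all
#' residue types. No global normalisation constant is applied: every matching
#' algorithm in this package is invariant to a multiplicative rescaling of
#' all distances, so assignments and accuracies are unaffected by such a
#' constant, but reported CSP magnitudes from tools that include one (e.g. a
#' \eqn{1/\sqrt{2}} prefactor) differ from these by that factor.
#'
#' @param delta_h \eqn{^1}H shift difference (ppm); vectorised.
#' @param delta_het heteronuclear shift difference (ppm); vectorised.
#' @param het_scale positive scaling divisor for the heteronuclear term.
#' @return Nonnegative CSP value(s), ppm.
#' @examples
#' csp_distance(0.1, 0.5)        # sqrt(0.01 + 0.01)
#' csp_distance(0, 5, het_scale = 5)  # exactly 1
#' @export
csp_distance <- function(delta_h, delta_het, het_scale = 5) {
  if (!is.numeric(het_scale) || length(het_scale) != 1L ||
      !is.finite(het_scale) || het_scale <= 0)
    stop_input("het_scale must be a single positive number")
  if (any(!is.finite(delta_h)) || any(!is.finite(delta_het)))
    stop_input("shift differences must be finite")
  sqrt(delta_h^2 + (delta_het / het_scale)^2)
}

#' All-pairs CSP cost matrix between two peak lists
#'
#' Entry (i, j) is [csp_distance()] between reference peak i and target peak
#' j. This matrix drives all four matching algorithms.
#'
#' @param ref,tgt [peak_list] objects recorded on the same heteronucleus.
#' @param het_scale heteronuclear scaling divisor.
#' @return An n x m numeric matrix (rows = reference peaks, columns = target
#'   peaks), with the peak ids as dimnames.
#' @export
csp_matrix <- function(ref, tgt, het_scale = 5) {
  stopifnot(inherits(ref, "peak_list"), inherits(tgt, "peak_list"))
  if (!identical(attr(ref, "het_nucleus"), attr(tgt, "het_nucleus")))
    stop_input("incompatible spectra: reference is 1H-%s but target is 1H-%s",
               attr(ref, "het_nucleus"), attr(tgt, "het_nucleus"))
  dh <- outer(ref$shift_h, tgt$shift_h, "-")
  dn <- outer(ref$shift_het, tgt$shift_het, "-")
  d <- csp_distance(dh, dn, het_scale)
  dimnames(d) <- list(ref$peak_id, tgt$peak_id)
  d
}

#' Windowed neighbourhood average of a CSP profile
#'
#' Mean CSP of the sequence neighbours of `residue` within a centred window
#' of width `window_k` (default 7, i.e. three residues on either side). The
#' central residue itself is excluded so that a candidate assignment cannot
#' vote for itself; positions with no value are skipped; with no informative
#' neighbour the average is 0. This is the local-similarity term exploited by
#' the SDS and RAS algorithms.
#'
#' @param profile named numeric vector: names are residue indices, values
#'   CSPs in ppm.
#' @param residue residue index (vectorised).
#' @param window_k odd window width >= 1.
#' @return Neighbourhood mean CSP (ppm), 0 when undefined.
#' @export
window_mean <- function(profile, residue, window_k = 7) {
  if (window_k < 1) stop_input("window_k must be >= 1")
  half <- floor(window_k / 2)
  if (length(profile) == 0L || half == 0L)
    return(rep(0, length(residue)))
  pos <- as.integer(names(profile))
  vapply(as.integer(residue), function(r) {
    sel <- pos >= r - half & pos <= r + half & pos != r
    if (!any(sel)) 0 else mean(profile[sel])
  }, numeric(1))
}
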