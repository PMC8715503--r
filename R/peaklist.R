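#' Construct a peak list
#'
#' A peak list holds the picked peak positions of one 2D heteronuclear
#' spectrum (typically a \eqn{^1}H--\eqn{^{15}}N HSQC): one row per peak,
#' with the \eqn{^1}H shift and the heteronuclear shift in ppm, and an
#' optional residue assignment. Two such lists -- the free-protein
#' (reference) spectrum and the protein:ligand-mixture (target) spectrum --
#' are the input to [match_peaks()].
#'
#' @param shift_h numeric vector of \eqn{^1}H chemical shifts (ppm).
#' @param shift_het numeric vector of heteronuclear shifts (ppm),
#'   same length as `shift_h`.
#' @param residue optional integer vector of residue sequence positions
#'   (`NA` for unassigned peaks). Assigned positions must be unique and
#'   >= 1.
#' @param label optional character vector of residue labels (e.g. `"G23"`).
#'   When `residue` is missing, labels ending in digits are parsed for the
#'   sequence position.
#' @param peak_id optional character vector of unique peak identifiers;
#'   defaults to `"p1" ... "pn"`.
#' @param het_nucleus `"N15"` or `"C13"`.
#' @param name spectrum name used in printing.
#'
#' @return An object of class `peak_list`: a data frame with columns
#'   `peak_id`, `residue_index`, `residue_label`, `shift_h`, `shift_het`,
#'   plus attributes `het_nucleus` and `spectrum_name`.
#' @examples
#' pl <- peak_list(shift_h = c(8.1, 8.5), shift_het = c(118.2, 121.0),
#'                 residue = c(12, 13), label = c("A12", "G13"))
#' is_assigned(pl)
#' @export
peak_list <- function(shift_h, shift_het, residue = NULL, label = NULL,
                      peak_id = NULL, het_nucleus = c("N15", "C13"),
                      name = "peaks") {
  het_nucleus <- match.arg(het_nucleus)
  n <- length(shift_h)
  if (n == 0L) stop_input("a peak list must contain at least one peak")
  if (length(shift_het) != n)
    stop_input("shift_h and shift_het must have the same length")
  shift_h <- as.numeric(shift_h)
  shift_het <- as.numeric(shift_het)
  if (anyNA(shift_h) || anyNA(shift_het) ||
      any(!is.finite(shift_h)) || any(!is.finite(shift_het)))
    stop_input("chemical shifts must be finite numbers")

  if (is.null(peak_id)) peak_id <- paste0("p", seq_len(n))
  peak_id <- as.character(peak_id)
  if (anyDuplicated(peak_id))
    stop_input("peak ids must be unique within a peak list")

  if (is.null(label)) label <- rep(NA_character_, n) else
    label <- as.character(label)
  label[!is.na(label) & !nzchar(trimws(label))] <- NA_character_
  if (is.null(residue)) {
    residue <- parse_residue_label(label)
  } else {
    residue <- suppressWarnings(as.integer(residue))
  }
  if (length(residue) != n || length(label) != n)
    stop_input("residue/label must match the number of peaks")
  if (any(!is.na(residue) & residue < 1L))
    stop_input("residue indices must be >= 1")
  ass <- residue[!is.na(residue)]
  if (anyDuplicated(ass))
    stop_input("duplicate residue assignment: residue %s appears more than once",
               paste(unique(ass[duplicated(ass)]), collapse = ", "))
  # a bare index is still a usable label
  label[is.na(label) & !is.na(residue)] <-
    as.character(residue[is.na(label) & !is.na(residue)])

  out <- data.frame(peak_id = peak_id,
                    residue_index = residue,
                    residue_label = label,
                    shift_h = shift_h,
                    shift_het = shift_het,
                    stringsAsFactors = FALSE)
  structure(out, het_nucleus = het_nucleus, spectrum_name = name,
            class = c("peak_list", "data.frame"))
}

# "G23", "Gly23", "23" -> 23L; anything without a trailing integer -> NA
parse_residue_label <- function(label) {
  idx <- rep(NA_integer_, length(label))
  has <- !is.na(label) & grepl("[0-9]+$", label)
  idx[has] <- as.integer(sub("^.*?([0-9]+)$", "\\1", label[has]))
  idx
}

#' @rdname peak_list
#' @param x a `peak_list`.
#' @return `is_assigned()` returns `TRUE` iff every peak carries a residue
#'   index.
#' @export
is_assigned <- function(x) {
  stopifnot(inherits(x, "peak_list"))
  !anyNA(x$residue_index)
}

#' @export
print.peak_list <- function(x, ...) {
  n_ass <- sum(!is.na(x$residue_index))
  cat(sprintf("Peak list '%s': %d peaks (1H-%s), %d assigned\n",
              attr(x, "spectrum_name"),
              nrow(x),
              attr(x, "het_nucleus"),
              n_ass))
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat(sprintf("  ... %d more peaks\n", nrow(x) - 10L))
  invisible(x)
}

#' @export
`[.peak_list` <- function(x, i, ...) {
  out <- `[.data.frame`(as.data.frame(x), i, , drop = FALSE)
  structure(out, het_nucleus = attr(x, "het_nucleus"),
            spectrum_name = attr(x, "spectrum_name"),
            class = c("peak_list", "data.frame"))
}

#' Drop unassigned peaks from a peak list
#'
#' The sequence-aware (Smart) algorithms need a residue index on every
#' reference peak; peaks without one are neglected before matching. Order of
#' the retained peaks is preserved, and the operation is idempotent.
#'
#' @param x a `peak_list`.
#' @return A `peak_list` containing only the assigned peaks.
#' @export
drop_unassigned <- function(x) {
  stopifnot(inherits(x, "peak_list"))
  keep <- !is.na(x$residue_index)
  if (!any(keep))
    stop_input("no assigned peaks remain after filtering; Smart matching requires residue assignments on the reference list")
  x[keep, ]
}
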