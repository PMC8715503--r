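#' Read a peak list from a csv file
#'
#' Expects a comma-separated file with a header row. Column names are matched
#' case-insensitively against common synonyms: the \eqn{^1}H shift column may
#' be called `w_h`, `h`, `h_ppm`, `1h` or `proton`; the heteronuclear column
#' `w_het`, `n`, `n_ppm`, `15n`, `c`, `c_ppm`, `13c`, `het` or `het_ppm`;
#' the optional assignment column `assignment`, `residue`, `res`, `label` or
#' `ass`. Assignment entries of the form `"G23"`, `"Gly23"` or `"23"` all
#' yield residue index 23. Shifts are stored exactly as read; no referencing
#' correction is applied.
#'
#' @param path csv file path.
#' @param het_nucleus `"N15"` or `"C13"`.
#' @param name spectrum name; defaults to the file name.
#' @return A [peak_list].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("assignment,w_h,w_het", "G23,8.10,118.20", "A24,7.95,121.40"), f)
#' read_peaklist(f)
#' @export
read_peaklist <- function(path, het_nucleus = c("N15", "C13"), name = NULL) {
  het_nucleus <- match.arg(het_nucleus)
  if (!file.exists(path)) stop_input("peak list file not found: %s", path)
  if (is.null(name)) name <- basename(path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", strip.white = TRUE)
  if (nrow(raw) == 0L) stop_input("peak list file %s has no data rows", path)
  nm <- tolower(trimws(names(raw)))
  h_col <- match_col(nm, c("w_h", "h", "h_ppm", "hppm", "1h", "proton", "wh"))
  het_col <- match_col(nm, c("w_het", "n", "n_ppm", "nppm", "15n", "c",
                             "c_ppm", "13c", "het", "het_ppm", "whet",
                             "nitrogen", "carbon"))
  if (is.na(h_col) || is.na(het_col))
    stop_input("peak list file %s must contain 1H and heteronuclear shift columns (e.g. w_h, w_het)",
               path)
  ass_col <- match_col(nm, c("assignment", "residue", "res", "label", "ass",
                             "assign"))

  sh <- parse_shift_column(raw[[h_col]], path, names(raw)[h_col])
  shet <- parse_shift_column(raw[[het_col]], path, names(raw)[het_col])
  label <- if (!is.na(ass_col)) raw[[ass_col]] else NULL

  peak_list(shift_h = sh, shift_het = shet, label = label,
            het_nucleus = het_nucleus, name = name)
}

match_col <- function(nm, candidates) {
  hit <- which(nm %in% candidates)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

parse_shift_column <- function(x, path, colname) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | !is.finite(v))
  if (length(bad) > 0L)
    stop_input("malformed shift value '%s' in column '%s' of %s (data row %d)",
               x[bad[1L]], colname, path, bad[1L])
  v
}

#' Write a peak list to csv
#'
#' Writes columns `assignment`, `w_h`, `w_het`; shifts are printed with four
#' decimals, which round-trips through [read_peaklist()] at that precision.
#'
#' @param x a [peak_list].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_peaklist <- function(x, path) {
  stopifnot(inherits(x, "peak_list"))
  df <- data.frame(assignment = ifelse(is.na(x$residue_label), "",
                                       x$residue_label),
                   w_h = sprintf("%.4f", x$shift_h),
                   w_het = sprintf("%.4f", x$shift_het),
                   stringsAsFactors = FALSE)
  write_csv_checked(df, path)
}

write_csv_checked <- function(df, path) {
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_input("cannot write to %s", path)
  invisible(path)
}

#' Write matched peak pairs and CSPs to csv
#'
#' One row per matched pair (reference peak id and label, target peak id, CSP
#' in ppm), followed by rows flagging unmatched peaks of either list. This is
#' the downloadable assignment table of the analysis.
#'
#' @param fit a [peak_match] result.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_assignments <- function(fit, path) {
  stopifnot(inherits(fit, "peak_match"))
  p <- fit$pairs
  rows <- data.frame(ref_peak = p$ref_id,
                     assignment = ifelse(is.na(p$ref_label), "", p$ref_label),
                     tgt_peak = p$tgt_id,
                     csp_ppm = sprintf("%.4f", p$csp),
                     status = "matched",
                     stringsAsFactors = FALSE)
  if (length(fit$unmatched_ref) > 0L) {
    ur <- fit$ref[match(fit$unmatched_ref, fit$ref$peak_id), ]
    rows <- rbind(rows, data.frame(
      ref_peak = ur$peak_id,
      assignment = ifelse(is.na(ur$residue_label), "", ur$residue_label),
      tgt_peak = "", csp_ppm = "", status = "unmatched_ref",
      stringsAsFactors = FALSE))
  }
  if (length(fit$unmatched_tgt) > 0L) {
    rows <- rbind(rows, data.frame(
      ref_peak = "", assignment = "", tgt_peak = fit$unmatched_tgt,
      csp_ppm = "", status = "unmatched_tgt", stringsAsFactors = FALSE))
  }
  write_csv_checked(rows, path)
}

#' Read back an assignment table written by [write_assignments()]
#'
#' @param path csv file path.
#' @return A data frame with the matched pairs (`ref_peak`, `assignment`,
#'   `tgt_peak`, `csp_ppm` numeric) and unmatched rows flagged in `status`.
#' @export
read_assignments <- function(path) {
  if (!file.exists(path)) stop_input("assignment table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df$csp_ppm <- suppressWarnings(as.numeric(df$csp_ppm))
  df
}

#' Write the per-residue CSP profile to csv
#'
#' Exports `(residue_index, residue_label, csp_ppm)` sorted by residue index
#' -- the data behind the per-residue CSP histogram. Only matched reference
#' peaks that carry a residue assignment appear.
#'
#' @param fit a [peak_match] result with an assigned reference list.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_csp_profile <- function(fit, path) {
  stopifnot(inherits(fit, "peak_match"))
  p <- fit$pairs[!is.na(fit$pairs$ref_residue), ]
  if (nrow(p) == 0L)
    stop_input("no assigned residues in the match result; cannot export a CSP profile")
  p <- p[order(p$ref_residue), ]
  df <- data.frame(residue_index = p$ref_residue,
                   residue_label = ifelse(is.na(p$ref_label), "",
                                          p$ref_label),
                   csp_ppm = sprintf("%.6f", p$csp),
                   stringsAsFactors = FALSE)
  write_csv_checked(df, path)
}

#' Read a per-residue CSP profile from csv
#'
#' @param path csv with columns `residue_index` and `csp_ppm` (labels
#'   optional), as written by [write_csp_profile()].
#' @return A named numeric vector of CSPs (ppm), names = residue indices,
#'   with residue labels (if present) attached as attribute `labels`.
#' @export
read_csp_profile <- function(path) {
  if (!file.exists(path)) stop_input("CSP profile file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  ri <- match_col(nm, c("residue_index", "residue", "res"))
  cv <- match_col(nm, c("csp_ppm", "csp"))
  if (is.na(ri) || is.na(cv))
    stop_input("%s must contain residue_index and csp_ppm columns", path)
  prof <- as.numeric(df[[cv]])
  names(prof) <- as.character(as.integer(df[[ri]]))
  lab <- match_col(nm, c("residue_label", "label"))
  if (!is.na(lab)) attr(prof, "labels") <- as.character(df[[lab]])
  prof
}
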