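# Statistical classification of perturbed residues and its population-SD
# helper. The thresholds operate on the whole-protein CSP distribution.

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Classify residues by chemical shift perturbation
#'
#' Applies the whole-protein statistical protocol used to map CSPs onto a
#' structure:
#'
#' 1. compute the mean and standard deviation (population SD) of the CSPs
#'    over all residues present;
#' 2. residues exceeding the mean by more than 4 SD are flagged as likely
#'    `outlier`s and excluded from highlighting;
#' 3. residues exceeding the mean by more than 2 SD (up to 4 SD) are
#'    `high`ly perturbed;
#' 4. residues at least 1 SD but no more than 2 SD above the mean are
#'    `moderate`ly perturbed;
#'
#' everything else is `background`. Boundary conventions: the 2 SD and 4 SD
#' cuts are strict (`>`), the 1 SD cut is inclusive (`>=`). A degenerate
#' profile with SD = 0 (e.g. an unperturbed protein where all CSPs are
#' equal) classifies every residue as background. By default the mean and
#' SD are computed once and not revised after outlier removal; set
#' `recompute_after_outliers = TRUE` to recompute them over the non-outlier
#' residues and re-apply the 1/2 SD cuts.
#'
#' @param profile named numeric vector of per-residue CSPs (ppm), as from
#'   [csp_profile()]/[read_csp_profile()], or a [peak_match].
#' @param recompute_after_outliers recompute mean/SD after dropping >4 SD
#'   outliers before applying the high/moderate cuts?
#' @return An object of class `csp_classification`: list with `categories`
#'   (named factor with levels outlier/high/moderate/background covering
#'   exactly the profiled residues), `mean_csp`, `sd_csp`, the profile, and
#'   the flag used.
#' @examples
#' prof <- c(`1` = 0, `2` = 0, `3` = 0, `4` = 1)
#' classify_residues(prof)   # residue 4 is moderate (mean + 1.73 SD)
#' @export
classify_residues <- function(profile, recompute_after_outliers = FALSE) {
  if (inherits(profile, "peak_match")) profile <- csp_profile(profile)
  if (!is.numeric(profile) || is.null(names(profile)))
    stop_input("profile must be a named numeric vector of per-residue CSPs")
  if (anyNA(profile) || any(profile < 0))
    stop_input("CSP values must be nonnegative and non-missing")
  if (length(profile) < 2L)
    stop_input("insufficient data: at least 2 residues are needed to define the SD")

  mu <- mean(profile)
  s <- pop_sd(profile)
  cat_of <- function(x, mu, s) {
    if (s == 0) return(rep("background", length(x)))
    ifelse(x > mu + 4 * s, "outlier",
           ifelse(x > mu + 2 * s, "high",
                  ifelse(x >= mu + 1 * s, "moderate", "background")))
  }
  cats <- cat_of(profile, mu, s)
  if (recompute_after_outliers && any(cats == "outlier")) {
    keep <- cats != "outlier"
    mu2 <- mean(profile[keep])
    s2 <- pop_sd(profile[keep])
    cats2 <- cat_of(profile[keep], mu2, s2)
    cats2[cats2 == "outlier"] <- "high"   # already cleared the 4 SD screen
    cats[keep] <- cats2
  }
  categories <- factor(cats, levels = c("outlier", "high", "moderate",
                                        "background"))
  names(categories) <- names(profile)
  structure(list(categories = categories, mean_csp = mu, sd_csp = s,
                 profile = profile,
                 recompute_after_outliers = recompute_after_outliers),
            class = "csp_classification")
}

#' @export
print.csp_classification <- function(x, ...) {
  tab <- table(x$categories)
  cat(sprintf("CSP classification of %d residues (mean %.4f, SD %.4f ppm)\n",
              length(x$categories), x$mean_csp, x$sd_csp))
  for (lv in names(tab)) {
    idx <- names(x$categories)[x$categories == lv]
    cat(sprintf("  %-10s %3d%s\n", lv, tab[[lv]],
                if (lv != "background" && tab[[lv]] > 0)
                  paste0(": ", paste(idx, collapse = ", ")) else ""))
  }
  invisible(x)
}

#' Residues in a given perturbation category
#'
#' @param x a `csp_classification`.
#' @param category one of `"outlier"`, `"high"`, `"moderate"`,
#'   `"background"`.
#' @return Integer vector of residue indices.
#' @export
residues_in <- function(x, category = c("high", "moderate", "outlier",
                                        "background")) {
  stopifnot(inherits(x, "csp_classification"))
  category <- match.arg(category)
  sort(as.integer(names(x$categories)[x$categories == category]))
}
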