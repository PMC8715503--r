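#' Generate a PyMOL script mapping perturbed residues onto a structure
#'
#' Transcribes a [classify_residues()] result into molecular-viewer
#' commands: all heavy atoms of highly perturbed residues are shown as red
#' spheres at sphere scale 1.0, moderately perturbed residues as pink
#' spheres at scale 0.7, the protein backbone as a gray cartoon and the
#' ligand in green (sticks for small molecules, cartoon for oligopeptides).
#' Outliers and background residues are not highlighted. Residue numbers
#' are enumerated explicitly, never filled in as ranges, so the selections
#' reproduce the classification exactly. The structure itself is not
#' parsed; the user supplies the chain and a ligand selection expression.
#'
#' @param classification a `csp_classification`.
#' @param chain_id protein chain identifier used in the selections.
#' @param ligand_selection PyMOL selection expression for the ligand
#'   (e.g. `"organic"` or `"chain B"`).
#' @param ligand_type `"small_molecule"` (green sticks) or `"peptide"`
#'   (green cartoon).
#' @return The script text, invisibly a character vector of lines (class
#'   `pymol_script`, printed verbatim). A warning is raised when no residue
#'   is highlighted; the script is still produced.
#' @export
pymol_script <- function(classification, chain_id = "A",
                         ligand_selection = "organic",
                         ligand_type = c("small_molecule", "peptide")) {
  stopifnot(inherits(classification, "csp_classification"))
  ligand_type <- match.arg(ligand_type)
  high <- residues_in(classification, "high")
  moderate <- residues_in(classification, "moderate")
  if (length(high) == 0L && length(moderate) == 0L)
    warning("no highly or moderately perturbed residues to highlight; writing cartoon and ligand only")

  sel <- function(res) sprintf("chain %s and resi %s", chain_id,
                               paste(res, collapse = "+"))
  lines <- c("hide everything",
             "bg_color white",
             "show cartoon, polymer",
             "color gray80, polymer")
  if (length(high) > 0L) {
    lines <- c(lines,
               sprintf("select high_csp, %s", sel(high)),
               "show spheres, high_csp and not hydrogens",
               "set sphere_scale, 1.0, high_csp",
               "color red, high_csp")
  }
  if (length(moderate) > 0L) {
    lines <- c(lines,
               sprintf("select moderate_csp, %s", sel(moderate)),
               "show spheres, moderate_csp and not hydrogens",
               "set sphere_scale, 0.7, moderate_csp",
               "color pink, moderate_csp")
  }
  lines <- c(lines,
             sprintf("select ligand_sel, (%s)", ligand_selection),
             if (ligand_type == "small_molecule")
               "show sticks, ligand_sel" else "show cartoon, ligand_sel",
             "color green, ligand_sel",
             "deselect")
  structure(lines, class = "pymol_script")
}

#' @export
print.pymol_script <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}

#' Write a classification and its viewer script to disk
#'
#' @param classification a `csp_classification`.
#' @param csv_path output path for the per-residue category table.
#' @param script_path output path for the PyMOL script.
#' @param ... passed to [pymol_script()].
#' @return Invisibly, the script lines.
#' @export
write_mapping <- function(classification, csv_path, script_path, ...) {
  stopifnot(inherits(classification, "csp_classification"))
  df <- data.frame(residue_index = as.integer(names(classification$categories)),
                   csp_ppm = sprintf("%.6f", classification$profile),
                   category = as.character(classification$categories),
                   stringsAsFactors = FALSE)
  df <- df[order(df$residue_index), ]
  write_csv_checked(df, csv_path)
  scr <- pymol_script(classification, ...)
  writeLines(unclass(scr), script_path)
  invisible(scr)
}
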