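# Hand-computed classification case: profile {0, 0, 0, 1} has mean 0.25 and
# population SD sqrt(3)/4 = 0.4330...; residue 4 sits at mean + 1.73 SD,
# i.e. above 1 SD but below 2 SD -> moderate; the rest are background.

test_that("classification reproduces the hand-computed profile", {
  prof <- c(`1` = 0, `2` = 0, `3` = 0, `4` = 1)
  cls <- classify_residues(prof)
  expect_equal(cls$mean_csp, 0.25)
  expect_equal(cls$sd_csp, sqrt(3) / 4)
  expect_equal(as.character(cls$categories),
               c("background", "background", "background", "moderate"))
  expect_equal(residues_in(cls, "moderate"), 4L)
  expect_length(residues_in(cls, "high"), 0L)
  expect_length(residues_in(cls, "outlier"), 0L)
})

test_that("degenerate SD = 0 profiles flag nothing", {
  cls <- classify_residues(setNames(rep(0.2, 6), 1:6))
  expect_true(all(cls$categories == "background"))
  cls0 <- classify_residues(setNames(rep(0, 4), 1:4))
  expect_true(all(cls0$categories == "background"))
})

test_that("extreme values are outliers, excluded from the highlighted sets", {
  prof <- setNames(c(rep(0.1, 20), 2.0), 1:21)
  cls <- classify_residues(prof)
  expect_equal(residues_in(cls, "outlier"), 21L)
  expect_length(residues_in(cls, "high"), 0L)
  expect_length(residues_in(cls, "moderate"), 0L)
  # thresholds are single-pass by default: mean/SD include the outlier
  expect_equal(cls$mean_csp, mean(prof))
  # optional recomputation after outlier removal re-screens the rest
  cls2 <- classify_residues(prof, recompute_after_outliers = TRUE)
  expect_equal(residues_in(cls2, "outlier"), 21L)
})

test_that("categories are exhaustive, exclusive, and scale-invariant", {
  set.seed(7)
  prof <- setNames(abs(rnorm(40, 0.05, 0.04)), 1:40)
  cls <- classify_residues(prof)
  expect_setequal(names(cls$categories), names(prof))
  expect_false(anyNA(cls$categories))
  for (lam in c(0.2, 5, 137)) {
    cls_l <- classify_residues(prof * lam)
    expect_equal(as.character(cls_l$categories),
                 as.character(cls$categories))
  }
})

test_that("too-small profiles are rejected", {
  expect_error(classify_residues(c(`1` = 0.1)), "insufficient",
               class = "cspmatch_error")
  expect_error(classify_residues(setNames(c(0.1, NA), 1:2)),
               class = "cspmatch_error")
})

test_that("viewer script transcribes the classification exactly", {
  prof <- setNames(c(0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02, 0.02,
                     0.30, 0.31, 0.15), c(1:8, 10, 11, 12))
  cls <- classify_residues(prof)
  high <- residues_in(cls, "high")
  moderate <- residues_in(cls, "moderate")
  expect_true(length(high) > 0 && length(moderate) > 0)

  scr <- pymol_script(cls, chain_id = "A")
  txt <- paste(unclass(scr), collapse = "\n")
  expect_match(txt, sprintf("select high_csp, chain A and resi %s",
                            paste(high, collapse = "\\+")))
  expect_match(txt, "set sphere_scale, 1.0, high_csp")
  expect_match(txt, "color red, high_csp")
  expect_match(txt, sprintf("select moderate_csp, chain A and resi %s",
                            paste(moderate, collapse = "\\+")))
  expect_match(txt, "set sphere_scale, 0.7, moderate_csp")
  expect_match(txt, "color pink, moderate_csp")
  expect_match(txt, "color gray80, polymer")
  expect_match(txt, "color green, ligand_sel")
  expect_match(txt, "show sticks, ligand_sel")

  # every residue number in the script appears with the matching category
  resi <- regmatches(txt, gregexpr("resi [0-9+]+", txt))[[1]]
  in_script <- sort(as.integer(unlist(strsplit(sub("resi ", "", resi), "\\+"))))
  expect_setequal(in_script, sort(c(high, moderate)))
})

test_that("selections enumerate indices across gaps, never ranges", {
  prof <- setNames(c(rep(0.02, 16), 0.3, 0.3, 0.3), c(1:16, 20, 25, 40))
  cls <- classify_residues(prof)
  high <- residues_in(cls, "high")
  expect_equal(high, c(20L, 25L, 40L))
  txt <- paste(unclass(pymol_script(cls)), collapse = "\n")
  expect_match(txt, "resi 20\\+25\\+40")
  expect_false(grepl("resi 20-40", txt))
})

test_that("empty highlight sets warn but still emit cartoon and ligand", {
  cls <- classify_residues(setNames(rep(0.1, 5), 1:5))
  expect_warning(scr <- pymol_script(cls, ligand_type = "peptide"),
                 "no highly or moderately")
  txt <- paste(unclass(scr), collapse = "\n")
  expect_false(grepl("spheres", txt))
  expect_match(txt, "show cartoon, ligand_sel")
  expect_match(txt, "show cartoon, polymer")
})

test_that("write_mapping writes a consistent table and script", {
  prof <- setNames(c(rep(0.02, 9), 0.28), 1:10)
  cls <- classify_residues(prof)
  csv <- tempfile(fileext = ".csv"); pml <- tempfile(fileext = ".pml")
  write_mapping(cls, csv, pml)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 10L)
  expect_equal(tab$category[tab$residue_index == 10],
               as.character(cls$categories["10"]))
  expect_true(file.exists(pml))
})
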