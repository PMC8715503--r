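# Shared fixtures. All geometry is expressed in the (H, het/5) plane so that
# planar Euclidean distances equal CSP distances at the default HetScale.

# Build a peak list from coordinates given in CSP units (y = het/5).
pl_from_plane <- function(x, y, residue = NULL, peak_id = NULL,
                          name = "fixture") {
  peak_list(shift_h = x, shift_het = y * 5, residue = residue,
            peak_id = peak_id, name = name)
}

# A planted case where sequence context is needed to match correctly.
# Residues 1,3,4,5 are background (CSP 0.01); residues 7,8,9 form a
# binding-site cluster (CSP 0.30). Residues 2 and 10 sit close together in
# the spectrum and compete for two target peaks: residue 2's true partner
# (CSP 0.06) lies slightly farther from residue 10's reference peak (0.03),
# while residue 10's true partner has CSP 0.30 vs 0.32 from residue 2. The
# swapped pairing has the smaller total raw cost (1.29 vs 1.30), so SD and
# RA both take it; the neighbourhood averages (res 2: ~0.01, res 10: ~0.30)
# pull SDS and RAS onto the planted truth.
swap_fixture <- function() {
  res <- c(1L, 3L, 4L, 5L, 7L, 8L, 9L, 2L, 10L)
  rx <- c(6.5, 7.5, 8.5, 9.5, 6.5, 7.5, 8.5, 9.50, 9.55)
  ry <- c(21.0, 21.0, 21.0, 21.0, 22.5, 22.5, 22.5, 22.50, 22.54)
  # displacements: background +x 0.01; site -y 0.30; residues 2 and 10 use
  # solved intersection points giving the cross-distances quoted above
  dx <- c(0.01, 0.01, 0.01, 0.01, 0, 0, 0, 0.02401, -0.13239)
  dy <- c(0, 0, 0, 0, -0.30, -0.30, -0.30, 0.05498, 0.26923)
  ref <- pl_from_plane(rx, ry, residue = res,
                       peak_id = paste0("r", res), name = "swap-ref")
  tgt <- pl_from_plane(rx + dx, ry + dy, peak_id = paste0("t", res),
                       name = "swap-tgt")
  truth <- data.frame(ref_id = paste0("r", res), tgt_id = paste0("t", res),
                      stringsAsFactors = FALSE)
  list(ref = ref, tgt = tgt, truth = truth)
}

# Random uniform cost matrix (no ties almost surely).
rand_cost <- function(n, m = n) matrix(runif(n * m), n, m)

# Write a small peak-list csv and return its path.
write_fixture_csv <- function(lines, dir = tempdir()) {
  f <- tempfile(fileext = ".csv", tmpdir = dir)
  writeLines(lines, f)
  f
}
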