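# Enumerated-oracle values used below:
#   greedy on [[1,2],[2,10]] takes the 1 first and is forced onto 10 -> 11;
#   the two permutations cost 1+10 = 11 and 2+2 = 4, so the optimum is 4.

test_that("greedy falls into the trap the optimal solver avoids", {
  d <- matrix(c(1, 2, 2, 10), 2, 2, byrow = TRUE)
  g <- solve_assignment(d, "greedy")
  expect_equal(g$assignment, c(1L, 2L))
  expect_equal(g$total, 11)
  o <- solve_assignment(d, "optimal")
  expect_equal(o$assignment, c(2L, 1L))
  expect_equal(o$total, 4)
  b <- solve_assignment(d, "brute")
  expect_equal(b$assignment, c(2L, 1L))
  expect_equal(b$total, 4)
})

test_that("optimal solver matches the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(2:7, 1); m <- sample(2:7, 1)
    d <- rand_cost(n, m)
    expect_equal(solve_assignment(d, "optimal")$total,
                 solve_assignment(d, "brute")$total, tolerance = 1e-12)
  }
})

test_that("greedy total cost is never below the optimal total cost", {
  set.seed(202)
  for (i in 1:40) {
    d <- rand_cost(sample(2:9, 1), sample(2:9, 1))
    expect_gte(solve_assignment(d, "greedy")$total,
               solve_assignment(d, "optimal")$total - 1e-12)
  }
})

test_that("brute-force oracle handles 1x1 and refuses large instances", {
  one <- solve_assignment(matrix(0.3, 1, 1), "brute")
  expect_equal(one$assignment, 1L)
  expect_equal(one$total, 0.3)
  expect_error(solve_assignment(rand_cost(9, 9), "brute"), "oracle",
               class = "cspmatch_error")
})

test_that("greedy tie-breaking prefers the lowest row, then lowest column", {
  d <- matrix(c(0.5, 0.5,
                0.5, 0.5), 2, 2, byrow = TRUE)
  expect_equal(solve_assignment(d, "greedy")$assignment, c(1L, 2L))
})

test_that("all four algorithms recover the identity on self-matching", {
  sim <- simulate_hsqc_pair(n_residues = 25, seed = 9)
  for (m in c("sd", "ra", "sds", "ras")) {
    fit <- match_peaks(sim$ref, sim$ref, method = m)
    expect_equal(fit$pairs$ref_id, fit$pairs$tgt_id)
    expect_equal(fit$pairs$csp, rep(0, 25), tolerance = 1e-14)
    expect_equal(fit$total_cost, 0)
    expect_true(fit$converged)
  }
})

test_that("the shorter list is fully matched and results partition the inputs", {
  sim <- simulate_hsqc_pair(n_residues = 20, drop_fraction = 0.15, seed = 13)
  for (m in c("sd", "ra", "sds", "ras")) {
    fit <- match_peaks(sim$ref, sim$tgt, method = m)
    expect_equal(nrow(fit$pairs), min(nrow(sim$ref), nrow(sim$tgt)))
    # one-to-one
    expect_false(anyDuplicated(fit$pairs$ref_id) > 0)
    expect_false(anyDuplicated(fit$pairs$tgt_id) > 0)
    # exact partition of both lists
    expect_setequal(c(fit$pairs$ref_id, fit$unmatched_ref),
                    sim$ref$peak_id)
    expect_setequal(c(fit$pairs$tgt_id, fit$unmatched_tgt),
                    sim$tgt$peak_id)
  }
  # rectangular the other way round: more target than reference peaks
  fit <- match_peaks(sim$tgt, sim$ref, method = "ra")
  expect_equal(nrow(fit$pairs), nrow(sim$tgt))
  expect_equal(length(fit$unmatched_tgt), nrow(sim$ref) - nrow(sim$tgt))
})

test_that("pairings are equivariant under permutation of peak order", {
  sim <- simulate_hsqc_pair(n_residues = 18, seed = 21)
  set.seed(1)
  ref_p <- sim$ref[sample.int(18), ]
  tgt_p <- sim$tgt[sample.int(18), ]
  for (m in c("sd", "ra", "sds", "ras")) {
    a <- match_peaks(sim$ref, sim$tgt, method = m)$pairs
    b <- match_peaks(ref_p, tgt_p, method = m)$pairs
    expect_setequal(paste(a$ref_id, a$tgt_id), paste(b$ref_id, b$tgt_id))
  }
})

test_that("pairings are invariant under a global rescaling of all shifts", {
  sim <- simulate_hsqc_pair(n_residues = 16, seed = 31)
  lam <- 3.7
  scale_pl <- function(pl) peak_list(pl$shift_h * lam, pl$shift_het * lam,
                                     residue = pl$residue_index,
                                     peak_id = pl$peak_id)
  ref2 <- scale_pl(sim$ref); tgt2 <- scale_pl(sim$tgt)
  for (m in c("sd", "ra", "sds", "ras")) {
    a <- match_peaks(sim$ref, sim$tgt, method = m)$pairs
    b <- match_peaks(ref2, tgt2, method = m)$pairs
    expect_setequal(paste(a$ref_id, a$tgt_id), paste(b$ref_id, b$tgt_id))
  }
})

test_that("a single SDS pass reduces to the SD ordering (all-zero profile)", {
  sim <- simulate_hsqc_pair(n_residues = 14, seed = 17)
  sd_fit <- match_peaks(sim$ref, sim$tgt, method = "sd")
  sds_1 <- suppressWarnings(match_peaks(sim$ref, sim$tgt, method = "sds",
                                        max_iter = 1))
  expect_equal(sds_1$pairs[c("ref_id", "tgt_id")],
               sd_fit$pairs[c("ref_id", "tgt_id")])
  expect_false(sds_1$converged)   # one pass cannot demonstrate stability
})

test_that("smart algorithms need assignments and neglect unassigned reference peaks", {
  sim <- simulate_hsqc_pair(n_residues = 10, seed = 23)
  bare <- peak_list(sim$ref$shift_h, sim$ref$shift_het,
                    peak_id = sim$ref$peak_id)
  for (m in c("sds", "ras"))
    expect_error(match_peaks(bare, sim$tgt, method = m), "assignments",
                 class = "cspmatch_error")
  # proximity algorithms run fine without assignments
  expect_silent(fit <- match_peaks(bare, sim$tgt, method = "ra"))
  expect_true(all(is.na(fit$pairs$ref_residue)))

  part <- sim$ref
  part$residue_index[3] <- NA
  expect_warning(fit2 <- match_peaks(part, sim$tgt, method = "ras"),
                 "neglected")
  expect_equal(fit2$dropped_ref, sim$ref$peak_id[3])
  expect_equal(nrow(fit2$pairs), 9L)
})

test_that("sequence-aware scoring rescues the planted near-neighbour swap", {
  fx <- swap_fixture()
  rec <- sapply(c("sd", "ra", "sds", "ras"), function(m)
    recovery_rate(match_peaks(fx$ref, fx$tgt, method = m), fx$truth))
  expect_lt(rec[["sd"]], 100)
  expect_lt(rec[["ra"]], 100)
  expect_equal(rec[["sds"]], 100)
  expect_equal(rec[["ras"]], 100)
  # the raw-cost optimum really is the swapped pairing
  ra_fit <- match_peaks(fx$ref, fx$tgt, method = "ra")
  ras_fit <- match_peaks(fx$ref, fx$tgt, method = "ras")
  expect_lt(ra_fit$total_cost, ras_fit$total_cost)
  expect_true(ras_fit$converged)
})

test_that("RAS with a zero profile rescales uniformly and converges in round 2", {
  sim <- simulate_hsqc_pair(n_residues = 8, site_csp_scale = 0,
                            noise_csp_scale = 0, seed = 3)
  fit <- match_peaks(sim$ref, sim$tgt, method = "ras")
  expect_equal(fit$iterations, 2L)
  expect_true(fit$converged)
  expect_equal(recovery_rate(fit, sim$truth), 100)
  # CSPs are reported from the unscaled distances
  expect_equal(fit$total_cost, 0)
})

test_that("iteration caps are honoured and reported", {
  fx <- swap_fixture()
  fit <- match_peaks(fx$ref, fx$tgt, method = "ras", max_iter = 2)
  expect_lte(fit$iterations, 2L)
  fit50 <- match_peaks(fx$ref, fx$tgt, method = "sds")
  expect_lte(fit50$iterations, 50L)
})
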