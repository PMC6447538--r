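test_that("directionality index matches the hand-computed statistic", {
  # 5-bin chromosome, window of 2 bins; center bin has A = 2, B = 8
  n <- 5
  m <- matrix(0, n, n)
  m[3, 1] <- m[1, 3] <- 1
  m[3, 2] <- m[2, 3] <- 1     # A = 2
  m[3, 4] <- m[4, 3] <- 5
  m[3, 5] <- m[5, 3] <- 3     # B = 8
  cm <- contact_matrix("chr1", m, 25000)
  di <- directionality_index(cm, window = 50000)
  expect_equal(di$a[3], 2)
  expect_equal(di$b[3], 8)
  # E = 5, DI = +((2-5)^2/5 + (8-5)^2/5) = 3.6
  expect_equal(di$di[3], 3.6)
  # antisymmetry: swap A and B
  m2 <- m[n:1, n:1]
  di2 <- directionality_index(contact_matrix("chr1", m2, 25000),
                              window = 50000)
  expect_equal(di2$di[3], -3.6)
  # A = B gives DI = 0; so does an empty window
  ab <- matrix(1, n, n)
  di0 <- directionality_index(contact_matrix("chr1", ab, 25000),
                              window = 50000)
  expect_equal(di0$di[3], 0)
  expect_error(directionality_index(cm, window = 25000), "two bins")
  expect_error(directionality_index(cm, window = 30000), "multiple")
})

test_that("DI profile is antisymmetric under transpose-reversal", {
  g <- hic_genome(1, 1e6)
  tt <- sim_tads(g, n_boundaries = 2, seed = 2)
  cm <- simulate_hic(g, tt, depth = 50, seed = 2)$map[[1]]
  n <- n_bins(cm)
  rev_cm <- contact_matrix("chr1", cm$counts[n:1, n:1], cm$bin_size)
  di <- directionality_index(cm, 200000)
  di_rev <- directionality_index(rev_cm, 200000)
  expect_equal(di$di, -rev(di_rev$di), tolerance = 1e-10)
})

test_that("insulation score normalizes to median zero and dips at boundaries", {
  # constant matrix: normalized insulation 0, delta 0 away from edges
  const <- contact_matrix("chr1", matrix(4, 30, 30), 25000)
  ins <- insulation_score(const, square = 100000, delta_span = 50000)
  mid <- ins$norm[!is.na(ins$norm)]
  expect_true(all(abs(mid) < 1e-12))
  expect_true(all(abs(na.omit(ins$delta)) < 1e-12))
  # two clean blocks: minimum insulation at the block boundary
  bm <- block_matrix(n = 40, split = 20)
  insb <- insulation_score(bm, square = 125000, delta_span = 75000)
  expect_equal(insb$bin[which.min(insb$norm)], 21, tolerance = 1)
  # median of finite normalized values is 0 in log2 space
  g <- hic_genome(2, 1e6)
  tt <- sim_tads(g, n_boundaries = 2, seed = 5)
  map <- balance(remove_short_range(simulate_hic(g, tt, seed = 5)$map),
                 method = "ice")
  insg <- insulation_score(map)
  expect_equal(median(insg$norm, na.rm = TRUE), 0, tolerance = 1e-9)
})

test_that("boundary calling is quiet on flat profiles and finds planted ones", {
  const <- contact_matrix("chr1", matrix(4, 40, 40), 25000)
  di_flat <- directionality_index(const, 100000)
  expect_equal(nrow(call_boundaries(di_flat)$boundaries), 0)
  ins_flat <- insulation_score(const, 100000, 50000)
  expect_equal(nrow(call_boundaries(ins_flat)$boundaries), 0)
  # weak planted boundaries are recovered less often than strong ones
  g <- hic_genome(1, 1e7)
  t_strong <- sim_tads(g, n_boundaries = 8, strengths = 1, seed = 11)
  t_weak <- tad_truth(t_strong$domains,
                      rep(0.2, nrow(t_strong$boundaries)))
  r_strong <- boundary_recovery(
    sim_and_call(g, t_strong, "di", seed = 11)$boundaries,
    t_strong$boundaries)
  r_weak <- boundary_recovery(
    sim_and_call(g, t_weak, "di", seed = 11)$boundaries,
    t_weak$boundaries)
  expect_gt(r_strong, r_weak)
  expect_equal(r_strong, 1)
})

test_that("domains are the inter-boundary intervals", {
  g <- hic_genome(1, 1e7)
  tt <- sim_tads(g, n_boundaries = 5, strengths = 1, seed = 13)
  called <- sim_and_call(g, tt, "di", seed = 13)
  tads <- called$tads
  expect_true(all(tads$start < tads$end))
  # tiles the chromosome without overlap
  expect_equal(tads$start[-1], tads$end[-nrow(tads)])
  expect_equal(min(tads$start), 0)
  expect_equal(max(tads$end), 1e7)
})

test_that("boundary profiles swing across planted boundaries", {
  g <- hic_genome(1, 1e7)
  tt <- sim_tads(g, n_boundaries = 8, strengths = 1, seed = 17)
  sim <- simulate_hic(g, tt, depth = 100, seed = 17)
  m <- balance(remove_short_range(sim$map), method = "ice")
  di <- directionality_index(m)
  curve <- boundary_profile(di, tt$boundaries)
  # negative two bins before the boundary, positive two bins after
  expect_lt(curve$value[curve$offset == -50000], 0)
  expect_gt(curve$value[curve$offset == 25000], 0)
  expect_error(boundary_profile(di, tt$boundaries[0, ]), "empty")
  # flat profile gives a flat zero curve
  flat <- di
  flat$di_z <- 0
  fc <- boundary_profile(flat, tt$boundaries)
  expect_true(all(fc$value == 0))
})

test_that("profile amplitude grows with planted boundary strength", {
  g <- hic_genome(1, 1e7)
  strengths <- c(0.25, 0.5, 0.75, 1)
  amps <- vapply(strengths, function(s) {
    tt <- sim_tads(g, n_boundaries = 8, strengths = s, seed = 19)
    sim <- simulate_hic(g, tt, depth = 100, seed = 19)
    m <- balance(remove_short_range(sim$map), method = "ice")
    profile_amplitude(boundary_profile(directionality_index(m),
                                       tt$boundaries))
  }, numeric(1))
  expect_equal(cor(amps, strengths, method = "spearman"), 1)
})

test_that("compartment eigenvector separates a two-block checkerboard", {
  # two contiguous blocks: A bins correlate with A bins
  n <- 20
  lab <- rep(c(1, -1), each = n / 2)
  m <- 2 + outer(lab, lab)  # 3 within-type, 1 across
  diag(m) <- 3
  cm <- contact_matrix("chrT", m, 500000)
  cm$balanced <- m
  track <- as.numeric(lab == 1)
  cp <- compartments(cm, track)
  expect_true(all(cp$compartment[lab == 1] == "A"))
  expect_true(all(cp$compartment[lab == -1] == "B"))
  # orientation invariance: flipping the eigenvector sign does not change
  # labels because the track re-orients it
  cp2 <- compartments(cm, track)
  expect_identical(cp$compartment, cp2$compartment)
  expect_equal(compartment_agreement(cp, cp2), 1)
})

test_that("compartment agreement counts matching labels", {
  mk <- function(labels) {
    tibble::tibble(chrom = "chrT", bin = seq_along(labels),
                   start = 0, end = 1, eigen = 1, compartment = labels)
  }
  a <- mk(rep("A", 100))
  b <- mk(c(rep("A", 99), "B"))
  expect_equal(compartment_agreement(a, b), 0.99)
  set.seed(1)
  r1 <- mk(sample(c("A", "B"), 2000, replace = TRUE))
  r2 <- mk(sample(c("A", "B"), 2000, replace = TRUE))
  expect_equal(compartment_agreement(r1, r2), 0.5, tolerance = 0.1)
  expect_error(compartment_agreement(mk(NA_character_), mk(NA_character_)),
               "jointly")
})
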