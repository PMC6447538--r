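test_that("genome and TAD truth constructors validate their invariants", {
  expect_error(genome_spec("chr1", 1e6 + 1, bin_size = 25000), "multiples")
  g <- hic_genome(1, 1e6)
  dom <- tibble::tibble(chrom = "chr1", start = c(0, 4e5), end = c(4e5, 1e6))
  tt <- tad_truth(dom, 0.7)
  expect_equal(tt$boundaries$pos, 4e5)
  expect_error(tad_truth(dom, c(0.5, 0.5)), "strengths")
  gap <- tibble::tibble(chrom = "chr1", start = c(0, 5e5),
                        end = c(4e5, 1e6))
  expect_error(tad_truth(gap, 0.5), "tile")
})

test_that("hic_expected implements the planted contact model", {
  g <- hic_genome(1, 4e5)  # 16 bins
  dom <- tibble::tibble(chrom = "chr1", start = c(0, 2e5), end = c(2e5, 4e5))
  # strength 1: cross-boundary multiplier is exactly 1
  mu1 <- hic_expected(g, tad_truth(dom, 1), "chr1", depth = 10,
                      decay_exponent = 1, tad_enrichment = 3)
  expect_equal(mu1[1, 16], 10 * (1 + 15)^-1 * 1)
  # strength 0: boundary invisible, multiplier equals the enrichment
  mu0 <- hic_expected(g, tad_truth(dom, 0), "chr1", depth = 10,
                      decay_exponent = 1, tad_enrichment = 3)
  expect_equal(mu0[1, 16], 10 * (1 + 15)^-1 * 3)
  # intermediate strength interpolates
  muh <- hic_expected(g, tad_truth(dom, 0.5), "chr1", depth = 10,
                      decay_exponent = 1, tad_enrichment = 3)
  expect_equal(muh[1, 16], 10 * (1 + 15)^-1 * 2)
  # adjacent intra-TAD bins: depth 10, decay 1, enrichment 3 -> 15
  expect_equal(mu1[1, 2], 15)
})

test_that("simulated counts are Poisson draws around the closed form", {
  g <- hic_genome(1, 2e5)  # 8 bins, tiny on purpose
  dom <- tibble::tibble(chrom = "chr1", start = c(0, 1e5), end = c(1e5, 2e5))
  tt <- tad_truth(dom, 1)
  mu <- hic_expected(g, tt, "chr1", depth = 10)
  draws <- vapply(seq_len(10000), function(s) {
    simulate_hic(g, tt, depth = 10, seed = s)$map[[1]]$counts[1, 2]
  }, numeric(1))
  expect_equal(mean(draws), mu[1, 2], tolerance = 0.02)
  expect_equal(mu[1, 2], 15)
})

test_that("simulate_hic is deterministic, symmetric and grid-validating", {
  g <- hic_genome(1, 5e5)
  tt <- sim_tads(g, n_boundaries = 1, seed = 4)
  a <- simulate_hic(g, tt, seed = 11)$map[[1]]
  b <- simulate_hic(g, tt, seed = 11)$map[[1]]
  expect_identical(a$counts, b$counts)
  expect_identical(a$counts, t(a$counts))
  off <- tad_truth(tibble::tibble(chrom = "chr1", start = c(0, 260001),
                                  end = c(260001, 5e5)), 1)
  expect_error(simulate_hic(g, off), "not aligned")
})

test_that("dosage term in simulated expression matches the closed form", {
  g <- cohort_genome()
  tt <- sim_tads(g, n_boundaries = 4, seed = 1)
  co <- sim_cohort(g, n_heh = 4, n_control = 4,
                   gain_freq = c(chr1 = 1), dosage_exponent = 1,
                   coupling = c("HeH-like" = FALSE, control = FALSE),
                   tad_sd = 0, batch_sd = 0, complex_sd = 0,
                   protein_noise_sd = 0, seed = 2)
  ex <- simulate_expression(g, co, tt, n_genes = 100, noise_sd = 0, seed = 2)
  heh <- co$samples$sample[co$samples$subtype == "HeH-like"]
  ctl <- co$samples$sample[co$samples$subtype == "control"]
  on1 <- ex$genes$gene[ex$genes$chrom == "chr1"]
  shift <- rowMeans(ex$rna$values[on1, heh]) -
    rowMeans(ex$rna$values[on1, ctl])
  expect_equal(unname(shift), rep(log2(1.5), length(on1)), tolerance = 1e-12)
  # protein shift is attenuated by exactly the attenuation factor
  pshift <- rowMeans(ex$protein$values[on1, heh]) -
    rowMeans(ex$protein$values[on1, ctl])
  expect_equal(unname(pshift), rep(0.5 * log2(1.5), length(on1)),
               tolerance = 1e-12)
})

test_that("attenuation 0 makes the protein layer copy-number independent", {
  g <- cohort_genome()
  tt <- sim_tads(g, n_boundaries = 4, seed = 1)
  co <- sim_cohort(g, attenuation = 0, seed = 5)
  ex <- simulate_expression(g, co, tt, n_genes = 800, seed = 5)
  d <- cohens_d(ex$protein, genes = ex$genes)
  per_chrom <- attr(d, "per_chromosome")
  expect_true(all(abs(per_chrom$mean_d) < 0.1))
})

test_that("simulate_expression rejects a cohort chromosome missing from the genome", {
  g <- hic_genome(1, 1e6)
  tt <- sim_tads(g, n_boundaries = 2, seed = 1)
  co <- sim_cohort(g, n_heh = 3, n_control = 3, gain_freq = c(chr1 = 1),
                   seed = 1)
  co$copy$chrom[1] <- "chrZZ"
  expect_error(simulate_expression(g, co, tt, n_genes = 10), "chrZZ")
})

test_that("annotations plant peaks at boundaries and share interactions", {
  g <- hic_genome(2, 5e6)
  tt <- sim_tads(g, n_boundaries = 5, seed = 3)
  ann0 <- simulate_annotations(g, tt, peak_rate = 0, seed = 3)
  sup <- peak_support(tt$boundaries, ann0$ctcf)
  expect_equal(sup$supported_fraction, 1)
  # shared fraction 0 -> consensus empty
  none <- simulate_annotations(g, tt, shared_fraction = 0, seed = 3)
  cons0 <- consensus_interactions(none$interactions_ctcf,
                                  none$interactions_rad21)
  expect_equal(nrow(cons0), 0)
  # shared fraction 0.5 -> consensus size ~ half the domains (binomial mean)
  n_dom <- nrow(tt$domains)
  sizes <- vapply(1:10, function(s) {
    ann <- simulate_annotations(g, tt, shared_fraction = 0.5, seed = s)
    nrow(consensus_interactions(ann$interactions_ctcf,
                                ann$interactions_rad21))
  }, numeric(1))
  expect_equal(mean(sizes) / n_dom, 0.5, tolerance = 0.25)
})

test_that("CMS generator centers on the requested group means", {
  all2 <- simulate_cms(n_per_group = c(5, 5), group_means = c(2, 2),
                       case_sd = 0, spread = 0, seed = 1)
  expect_true(all(all2$score == 2))
  expect_error(simulate_cms(group_means = c(0.5, 2)), "\\[1, 3\\]")
  cms <- simulate_cms(seed = 4)
  gm <- compare_cms(cms)$groups
  expect_equal(gm$group_mean[gm$group == "HeH"], 1.8, tolerance = 0.08)
  expect_equal(gm$group_mean[gm$group == "ETV6_RUNX1"], 2.1,
               tolerance = 0.08)
})

test_that("equal-mean CMS groups are detected at roughly the nominal rate", {
  pvals <- vapply(1:300, function(s) {
    cms <- simulate_cms(n_per_group = c(12, 12), group_means = c(2, 2),
                        metaphases_per_case = 10, seed = s)
    compare_cms(cms)$p_value
  }, numeric(1))
  expect_lt(mean(pvals < 0.05), 0.10)
  expect_gt(mean(pvals < 0.5), 0.25)
})

test_that("generators give byte-identical output under a fixed seed", {
  g <- cohort_genome()
  tt <- sim_tads(g, n_boundaries = 3, seed = 7)
  co <- sim_cohort(g, n_heh = 4, n_control = 4, seed = 7)
  e1 <- simulate_expression(g, co, tt, n_genes = 50, seed = 7)
  e2 <- simulate_expression(g, co, tt, n_genes = 50, seed = 7)
  expect_identical(e1$rna$values, e2$rna$values)
  expect_identical(e1$protein$values, e2$protein$values)
  a1 <- simulate_annotations(g, tt, seed = 7)
  a2 <- simulate_annotations(g, tt, seed = 7)
  expect_identical(a1, a2)
  expect_identical(simulate_cms(seed = 7), simulate_cms(seed = 7))
})
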