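test_that("boundary matching honors the +/-100 kb tolerance", {
  ref <- tibble::tibble(chrom = "chr1", pos = 1e6)
  near <- list(s1 = tibble::tibble(chrom = "chr1", pos = 1.08e6))
  far <- list(s1 = tibble::tibble(chrom = "chr1", pos = 1.12e6))
  m_near <- match_boundaries(near, reference = ref)
  m_far <- match_boundaries(far, reference = ref)
  expect_equal(m_near$status, "present")
  expect_equal(m_near$distance, 8e4)
  expect_equal(m_far$status, "lost")
  ident <- match_boundaries(list(a = ref, b = ref), reference = ref)
  expect_true(all(ident$status == "present"))
})

test_that("two-sample matching is symmetric", {
  a <- tibble::tibble(chrom = "chr1", pos = c(1e6, 2e6, 3.5e6))
  b <- tibble::tibble(chrom = "chr1", pos = c(1.05e6, 2.3e6, 3.45e6))
  ab <- match_boundaries(list(x = b), reference = a)
  ba <- match_boundaries(list(x = a), reference = b)
  expect_equal(sum(ab$status == "present"), sum(ba$status == "present"))
  # matched pairs are the same set in both directions
  pab <- sort(ab$matched_pos[!is.na(ab$matched_pos)])
  pba <- sort(ba$pos[!is.na(ba$matched_pos)])
  expect_equal(pab, pba)
})

test_that("recurrent loss needs the required recurrence and group contrast", {
  ref <- tibble::tibble(chrom = "chr1", pos = c(1e6, 2e6))
  mk <- function(sample, status1, status2) {
    tibble::tibble(chrom = "chr1", pos = c(1e6, 2e6), sample = sample,
                   status = c(status1, status2),
                   matched_pos = NA_real_, distance = NA_real_)
  }
  matches <- dplyr::bind_rows(
    mk("A1", "lost", "present"), mk("A2", "weak", "present"),
    mk("A3", "present", "lost"), mk("A4", "present", "present"),
    mk("B1", "present", "present"), mk("B2", "present", "present"))
  labels <- c(A1 = "A", A2 = "A", A3 = "A", A4 = "A", B1 = "B", B2 = "B")
  rl <- recurrent_lost_boundaries(matches, labels)
  # boundary 1: affected in 2 A samples -> reported; boundary 2: only 1
  expect_equal(rl$pos, 1e6)
  expect_equal(rl$group, "A")
  expect_equal(rl$n_affected, 2L)
  # strict mode drops boundaries not clean in the other group
  matches2 <- dplyr::bind_rows(matches[matches$sample != "B1", ],
                               mk("B1", "lost", "present"))
  rl2 <- recurrent_lost_boundaries(matches2, labels)
  expect_equal(nrow(rl2), 0)
  rl3 <- recurrent_lost_boundaries(matches2, labels, strict = FALSE)
  expect_equal(rl3$pos, 1e6)
})

test_that("planted group-specific weakened boundaries are recovered", {
  g <- hic_genome(3, 2e7)
  t_strong <- sim_tads(g, n_boundaries = 7, strengths = 1, seed = 9)
  nb <- nrow(t_strong$boundaries)
  weak_idx <- round(seq(1, nb, length.out = 10))
  s <- rep(1, nb)
  s[weak_idx] <- 0
  t_weak <- tad_truth(t_strong$domains, s)
  sets <- list(
    A1 = sim_and_call(g, t_weak, "di", seed = 21, sample_id = "A1")$boundaries,
    A2 = sim_and_call(g, t_weak, "di", seed = 22, sample_id = "A2")$boundaries,
    B1 = sim_and_call(g, t_strong, "di", seed = 23, sample_id = "B1")$boundaries,
    B2 = sim_and_call(g, t_strong, "di", seed = 24, sample_id = "B2")$boundaries)
  mb <- match_boundaries(sets, reference = t_strong$boundaries)
  rl <- recurrent_lost_boundaries(mb, c(A1 = "A", A2 = "A",
                                        B1 = "B", B2 = "B"))
  truth <- t_strong$boundaries[weak_idx, ]
  hits <- sum(vapply(seq_len(nrow(truth)), function(i) {
    any(rl$group == "A" & rl$chrom == truth$chrom[i] &
          abs(rl$pos - truth$pos[i]) <= 25000)
  }, logical(1)))
  expect_gte(hits, 9)
  # no false reports on intact boundaries
  expect_lte(nrow(rl), length(weak_idx) + 1)
})

test_that("insulation proxy classifies planted boundary strength", {
  g <- hic_genome(1, 1e7)
  t_strong <- sim_tads(g, n_boundaries = 6, strengths = 1, seed = 31)
  t_lost <- tad_truth(t_strong$domains, rep(0, 6))
  prof <- function(tt, seed) {
    sim <- simulate_hic(g, tt, depth = 100, seed = seed)
    insulation_score(balance(remove_short_range(sim$map), method = "ice"))
  }
  p_strong <- prof(t_strong, 31)
  p_lost <- prof(t_lost, 31)
  b <- t_strong$boundaries$pos[3]
  expect_equal(classify_boundary_change(p_strong, b, "chr1"), "strong")
  expect_equal(classify_boundary_change(p_lost, b, "chr1"), "lost")
  expect_error(classify_boundary_change(p_strong, 5e8, "chr1"), "outside")
})

test_that("peak support respects the +/-50 kb window", {
  b <- tibble::tibble(chrom = "chr1", pos = 1e6)
  near <- tibble::tibble(chrom = "chr1", start = 1.03e6 - 100,
                         end = 1.03e6 + 100)
  far <- tibble::tibble(chrom = "chr1", start = 1.06e6 - 100,
                        end = 1.06e6 + 100)
  expect_equal(peak_support(b, near)$supported_fraction, 1)
  expect_equal(peak_support(b, far)$supported_fraction, 0)
  empty <- tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0))
  expect_equal(peak_support(b, empty)$supported_fraction, 0)
  unsorted <- tibble::tibble(chrom = "chr1", start = c(2e6, 1e6),
                             end = c(2e6 + 100, 1e6 + 100))
  expect_warning(peak_support(b, unsorted), "unsorted")
})

test_that("direction enrichment reproduces the printed worked example", {
  # 98 down / 36 up against a genome-wide down fraction of 2222/4645
  res <- direction_enrichment_test(98, 36, 2222 / 4645)
  expect_equal(res$statistic, 34.3676, tolerance = 1e-4)
  expect_equal(res$p_value, 4.5625e-09, tolerance = 1e-3)
  # equal split to the reference: statistic 0, p 1
  null <- direction_enrichment_test(2222, 4645 - 2222, 2222 / 4645)
  expect_equal(null$statistic, 0)
  expect_equal(null$p_value, 1)
  # invariance under swapping down/up with the complement fraction
  sw <- direction_enrichment_test(36, 98, 1 - 2222 / 4645)
  expect_equal(sw$statistic, res$statistic)
  expect_equal(sw$p_value, res$p_value)
})

test_that("proximal enrichment selects DE features within the radius", {
  genes <- tibble::tibble(gene = c("g1", "g2", "g3", "g4"),
                          chrom = "chr1",
                          tss = c(0.5e6, 1.2e6, 5e6, 1.4e6))
  de <- tibble::tibble(gene = c("g1", "g2", "g3", "g4"),
                       log2fc = c(-1, -1, 2, 1),
                       p_adj = c(0.01, 0.01, 0.01, 0.2),
                       direction = c("down", "down", "up", "up"))
  lost <- tibble::tibble(chrom = "chr1", pos = 1e6)
  res <- boundary_proximal_enrichment(lost, genes, de,
                                      genome_wide_down_fraction = 0.5)
  # g1 and g2 are proximal and significant; g3 too far, g4 not significant
  expect_equal(res$n_proximal, 2L)
  expect_equal(res$n_down, 2L)
  expect_warning(
    empty <- boundary_proximal_enrichment(
      lost, genes[3, ], de[3, ], genome_wide_down_fraction = 0.5),
    "undefined")
  expect_true(is.na(empty$p_value))
})
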