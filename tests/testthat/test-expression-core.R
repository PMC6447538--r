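test_that("expression filter applies the strict CPM and fraction rules", {
  # 10 samples in two groups; a filler gene pins every library at 1e6 so
  # the intended per-gene CPM values are exact
  counts <- rbind(
    kept = c(rep(1.2, 5), rep(0, 5)),     # 100% of group "a" above 1
    boundary = rep(1.0, 10),              # exactly 1: strict > drops it
    half = rep(c(5, 0), 5))               # 50% in both groups
  counts <- rbind(counts, filler = 1e6 - colSums(counts))
  colnames(counts) <- paste0("s", 1:10)
  groups <- rep(c("a", "b"), each = 5)
  kept <- filter_expressed(counts, groups)
  expect_true("kept" %in% kept)
  expect_false("boundary" %in% kept)
  expect_false("half" %in% kept)
  # monotone: raising the threshold never adds genes
  for (thr in c(0.5, 1, 2, 5)) {
    k1 <- filter_expressed(counts, groups, cpm_threshold = thr)
    k2 <- filter_expressed(counts, groups, cpm_threshold = thr + 1)
    expect_true(all(k2 %in% k1))
  }
  zero <- counts
  zero[, 3] <- 0
  expect_error(filter_expressed(zero, groups), "zero library")
})

test_that("Welch DE is null-calibrated, antisymmetric and sensitive", {
  set.seed(9)
  x <- matrix(rnorm(200 * 12), 200, 12,
              dimnames = list(sprintf("g%03d", 1:200), NULL))
  groups <- rep(c("a", "b"), each = 6)
  de <- differential_expression(x, groups)
  expect_lt(mean(de$significant), 0.02)
  # group swap (reference group flipped): fold changes negate, p unchanged
  de2 <- differential_expression(x[, c(7:12, 1:6)], groups)
  expect_equal(de2$log2fc, -de$log2fc)
  expect_equal(de2$p, de$p)
  # identical groups: fold changes 0, adjusted p near 1
  xx <- cbind(x[, 1:6], x[, 1:6])
  de3 <- differential_expression(xx, groups)
  expect_true(all(de3$log2fc == 0))
  expect_true(all(de3$p_adj == 1))
  # zero variance in both groups
  flat <- rbind(c(rep(1, 6), rep(1, 6)), c(rep(1, 6), rep(2, 6)))
  rownames(flat) <- c("same", "shifted")
  de4 <- differential_expression(flat, groups)
  expect_equal(de4$p[de4$gene == "same"], 1)
  expect_lt(de4$p[de4$gene == "shifted"], 0.05)
})

test_that("planted two-fold shifts are detected with controlled FDR", {
  set.seed(21)
  n_genes <- 2000
  n_shift <- 100
  x <- matrix(rnorm(n_genes * 20, sd = 0.5), n_genes, 20,
              dimnames = list(sprintf("g%04d", 1:n_genes), NULL))
  x[1:n_shift, 1:10] <- x[1:n_shift, 1:10] + 1  # 2-fold on log2 scale
  de <- differential_expression(x, rep(c("a", "b"), each = 10))
  called <- which(de$significant)
  sens <- mean(seq_len(n_shift) %in% called)
  fdr <- if (length(called)) mean(called > n_shift) else 0
  # Welch power at these settings: t non-centrality 4.47, BH cutoff near
  # p ~ 2e-3 with ~90 true calls, giving expected sensitivity ~0.8-0.85
  expect_gte(sens, 0.75)
  expect_lte(fdr, 0.1)
})

test_that("empirical-control loop: k = 0 identity and factor removal", {
  set.seed(31)
  x <- matrix(rnorm(300 * 16), 300, 16,
              dimnames = list(sprintf("g%03d", 1:300), sprintf("s%d", 1:16)))
  groups <- rep(c("a", "b"), each = 8)
  id <- iterative_empirical_controls(x, groups, k_factors = 0)
  expect_identical(id$adjusted, median_normalize(x))
  # planted batch orthogonal to groups
  batch <- rep(c(1, -1), 8)
  load <- rnorm(300)
  shift <- c(rep(1, 30), rep(0, 270))
  xb <- x + outer(load, batch) + outer(shift, as.numeric(groups == "a"))
  res <- iterative_empirical_controls(xb, groups)
  expect_true(res$ok)
  bvar <- function(m) mean((as.vector(m %*% batch) / 16)^2)
  expect_gt(1 - bvar(res$adjusted) / bvar(xb), 0.8)
  # planted group effects preserved within 10%
  de <- differential_expression(res$adjusted, groups)
  expect_equal(mean(de$log2fc[1:30]), 1, tolerance = 0.1)
  # pure noise: adjustment leaves the data highly correlated with input
  nul <- iterative_empirical_controls(x, groups)
  expect_gt(cor(as.vector(nul$adjusted), as.vector(median_normalize(x))),
            0.9)
  # degenerate: an impossible control threshold empties the control set
  expect_warning(
    bad <- iterative_empirical_controls(x, groups, control_p = 1),
    "control set")
  expect_false(bad$ok)
})

test_that("mRNA-protein correlation is rank-invariant with exact summaries", {
  set.seed(41)
  x <- matrix(rnorm(50 * 10), 50, 10,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:10)))
  same <- mrna_protein_correlation(x, x)
  expect_equal(same$genes$rho, rep(1, 50))
  expect_equal(glance(same)$mean_rho, 1)
  mono <- mrna_protein_correlation(x, exp(x) + 3)
  expect_equal(mono$genes$rho, rep(1, 50))
  # independent layers: mean near 0, few significant
  y <- matrix(rnorm(2000 * 27), 2000, 27,
              dimnames = list(sprintf("g%04d", 1:2000), NULL))
  z <- matrix(rnorm(2000 * 27), 2000, 27,
              dimnames = list(sprintf("g%04d", 1:2000), NULL))
  nul <- mrna_protein_correlation(y, z)
  expect_equal(glance(nul)$mean_rho, 0, tolerance = 0.02)
  expect_lte(glance(nul)$frac_significant, 0.05)
  # genes missing in one layer are excluded and counted
  part <- mrna_protein_correlation(x[1:30, ], x)
  expect_equal(nrow(part$genes), 30)
  expect_equal(glance(part)$n_excluded, 20)
})

test_that("complex co-regulation separates planted complexes from noise", {
  set.seed(51)
  n <- 200; ns <- 20
  x <- matrix(rnorm(n * ns), n, ns,
              dimnames = list(sprintf("g%03d", 1:n), NULL))
  cx_members <- 1:40
  fac <- matrix(rnorm(4 * ns), 4, ns)
  cmap <- tibble::tibble(gene = sprintf("g%03d", cx_members),
                         complex_id = rep(1:4, each = 10))
  x[cx_members, ] <- x[cx_members, ] + fac[rep(1:4, each = 10), ]
  res <- complex_coregulation(x, cmap, seed = 5)
  expect_gt(res$mean_within, res$mean_random)
  expect_lt(res$p_value, 0.01)
  # identical rows correlate at exactly 1
  x2 <- x
  x2[2, ] <- x2[1, ]
  one <- complex_coregulation(
    x2, tibble::tibble(gene = c("g001", "g002"), complex_id = 9), seed = 5)
  expect_equal(one$within, 1, tolerance = 1e-12)
  # random membership on pure noise: means agree
  noise <- matrix(rnorm(400 * 20), 400, 20,
                  dimnames = list(sprintf("n%03d", 1:400), NULL))
  rmap <- tibble::tibble(gene = sprintf("n%03d", 1:400),
                         complex_id = rep(1:40, each = 10))
  rnull <- complex_coregulation(noise, rmap, n_random = 4000, seed = 6)
  expect_equal(rnull$mean_within, rnull$mean_random, tolerance = 0.02)
})

test_that("partial correlation strips subtype-driven association", {
  set.seed(61)
  subtype <- rep(c("u", "v"), each = 30)
  shift <- ifelse(subtype == "u", 0, 5)
  x <- rnorm(60) + shift
  y <- rnorm(60) + shift
  raw <- suppressWarnings(cor(x, y, method = "spearman"))
  part <- partial_correlation_by_subtype(x, y, subtype)
  expect_gt(raw, 0.7)           # Simpson's-paradox construction
  expect_lt(abs(part), 0.3)
  # balanced shared signal survives residualization
  s <- rnorm(60)
  x2 <- s + rnorm(60, sd = 0.3)
  y2 <- s + rnorm(60, sd = 0.3)
  expect_gt(partial_correlation_by_subtype(x2, y2, subtype), 0.7)
  expect_warning(single <- partial_correlation_by_subtype(
    x[1:30], y[1:30], subtype[1:30]), "single subtype")
  expect_true(is.finite(single))
})

test_that("strata comparison picks the right test and handles tiny strata", {
  set.seed(71)
  a <- rnorm(200); b <- rnorm(200) + 0.2
  two <- strata_correlation_compare(c(a, b),
                                    rep(c("x", "y"), each = 200))
  expect_equal(two$test, "wilcoxon")
  expect_lt(two$p_value, 0.001)
  same <- strata_correlation_compare(c(a, a), rep(c("x", "y"), each = 200))
  expect_gt(same$p_value, 0.05)
  three <- strata_correlation_compare(rnorm(300),
                                      rep(c("x", "y", "z"), each = 100))
  expect_equal(three$test, "kruskal-wallis")
  expect_warning(
    dropped <- strata_correlation_compare(
      c(a, b, 0.5), c(rep(c("x", "y"), each = 200), "tiny")),
    "tiny")
  expect_equal(dropped$n_strata, 2L)
})

test_that("CMS comparison aggregates per case and tests one-sided", {
  flat <- tidyr::expand_grid(case_id = sprintf("c%d", 1:6),
                             metaphase = 1:5)
  flat$group <- rep(c("g1", "g2"), each = 15)
  flat$score <- 2
  res <- compare_cms(flat)
  expect_equal(res$groups$group_mean, c(2, 2))
  expect_gte(res$p_value, 0.5)
  expect_error(compare_cms(flat[flat$case_id %in% c("c1", "c4", "c5"), ]),
               "two cases")
  # pooled aggregation agrees with case means here (balanced design)
  pooled <- compare_cms(flat, pooled = TRUE)
  expect_equal(pooled$groups$group_mean, res$groups$group_mean)
})
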