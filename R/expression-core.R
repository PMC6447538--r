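#' Filter to expressed genes (CPM rule)
#'
#' A gene is expressed in a sample when its counts-per-million value
#' strictly exceeds `cpm_threshold`; it is retained when it is expressed in
#' strictly more than `fraction` of the samples of at least one group.
#'
#' @param counts Genes x samples matrix of raw read counts.
#' @param groups Group label per sample.
#' @param cpm_threshold CPM cutoff (strict `>`, default 1).
#' @param fraction Within-group sample fraction (strict `>`, default 0.8).
#' @return Character vector of retained gene ids (row names).
#' @export
filter_expressed <- function(counts, groups, cpm_threshold = 1,
                             fraction = 0.8) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  bad <- which(lib == 0)
  assert_that(length(bad) == 0,
              sprintf("sample %s has zero library size",
                      (colnames(counts) %||% as.character(bad))[bad[1]]))
  cpm <- sweep(counts, 2, lib, `/`) * 1e6
  keep <- rep(FALSE, nrow(counts))
  for (g in unique(groups)) {
    sel <- groups == g
    keep <- keep |
      rowMeans(cpm[, sel, drop = FALSE] > cpm_threshold) > fraction
  }
  (rownames(counts) %||% as.character(seq_len(nrow(counts))))[keep]
}

#' Median-normalize a log-scale matrix
#'
#' Subtracts the per-sample median (the proteomics ratio convention).
#'
#' @param x Genes x samples matrix (log scale).
#' @return Matrix with per-sample median 0.
#' @export
median_normalize <- function(x) {
  sweep(x, 2, apply(x, 2, median, na.rm = TRUE), `-`)
}

#' Two-group differential expression (Welch test, BH control)
#'
#' Per-feature Welch t-test on log-scale values with Benjamini-Hochberg
#' adjustment; the log2 fold change is group 1 mean minus group 2 mean.
#' Features with zero variance in both groups get p = 1 when the means are
#' equal and a rank-test fallback otherwise.
#'
#' @param expr An [expr_matrix()] or genes x samples matrix (log scale).
#' @param groups Two-level label per sample (first level = group 1);
#'   defaults to the `group` column of an `expr_matrix`.
#' @param alpha Significance cutoff on the adjusted p (default 0.05).
#' @return Tibble `gene log2fc p p_adj direction significant` (direction
#'   `up` means higher in group 1).
#' @export
differential_expression <- function(expr, groups = NULL, alpha = 0.05) {
  x <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  if (is.null(groups) && inherits(expr, "expr_matrix")) {
    groups <- expr$samples$group
  }
  groups <- as.character(groups)
  lv <- unique(groups)
  assert_that(length(lv) == 2, "need exactly two groups")
  g1 <- groups == lv[1]; g2 <- groups == lv[2]
  n1 <- sum(g1); n2 <- sum(g2)
  assert_that(n1 >= 3 && n2 >= 3, "need >= 3 samples per group")
  m1 <- rowMeans(x[, g1, drop = FALSE]); m2 <- rowMeans(x[, g2, drop = FALSE])
  v1 <- apply(x[, g1, drop = FALSE], 1, var)
  v2 <- apply(x[, g2, drop = FALSE], 1, var)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tt), df = df)
  dgn <- which(se2 == 0)
  for (i in dgn) {
    p[i] <- if (m1[i] == m2[i]) 1 else
      suppressWarnings(wilcox.test(x[i, g1], x[i, g2], exact = FALSE))$p.value
  }
  lfc <- unname(m1 - m2)
  p <- unname(p)
  padj <- p.adjust(p, method = "BH")
  tibble(gene = rownames(x) %||% as.character(seq_len(nrow(x))),
         log2fc = lfc, p = p, p_adj = padj,
         direction = ifelse(lfc >= 0, "up", "down"),
         significant = !is.na(padj) & padj <= alpha)
}

#' Iterative empirical-control factor normalization
#'
#' Re-implementation of the iterative empirical-control loop used for
#' proteomics batch correction: iteration 0 median-normalizes, runs DE and
#' takes features with adjusted p above `control_p` as controls; each of
#' the `n_iter` iterations estimates `k_factors` unwanted factors as the
#' leading right singular vectors of the group-mean-centered control
#' submatrix, regresses them out of the full matrix, re-runs DE and
#' redefines the controls. Controls from the last iteration are the
#' empirical controls.
#'
#' @param expr An [expr_matrix()] or matrix (log scale).
#' @param groups Two-level label per sample.
#' @param n_iter Iterations (default 10).
#' @param control_p Control threshold on the adjusted p (default 0.9).
#' @param k_factors Number of unwanted factors (default 2; 0 makes the
#'   procedure the identity after median normalization).
#' @return List with `adjusted` (matrix), `controls` (gene ids),
#'   `factors` (samples x k matrix or `NULL`), `converged_iterations` and
#'   `ok` (`FALSE` when the control set emptied early).
#' @export
iterative_empirical_controls <- function(expr, groups = NULL, n_iter = 10,
                                         control_p = 0.9, k_factors = 2) {
  x <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  if (is.null(groups) && inherits(expr, "expr_matrix")) {
    groups <- expr$samples$group
  }
  x0 <- median_normalize(x)
  de <- differential_expression(x0, groups)
  controls <- de$gene[!is.na(de$p_adj) & de$p_adj > control_p]
  adjusted <- x0
  w <- NULL
  if (k_factors == 0) {
    return(list(adjusted = x0, controls = controls, factors = NULL,
                converged_iterations = 0L, ok = TRUE))
  }
  done <- 0L
  ok <- TRUE
  for (it in seq_len(n_iter)) {
    if (length(controls) < k_factors + 1) {
      warning(sprintf("control set empty/degenerate at iteration %d", it))
      ok <- FALSE
      break
    }
    ctrl <- x0[controls, , drop = FALSE]
    # remove group means so the factors capture unwanted, not biological,
    # variation
    for (g in unique(groups)) {
      sel <- groups == g
      ctrl[, sel] <- ctrl[, sel] - rowMeans(ctrl[, sel, drop = FALSE])
    }
    sv <- svd(ctrl, nu = 0, nv = k_factors)
    w <- sv$v[, seq_len(k_factors), drop = FALSE]  # samples x k
    # project every feature onto the factor space and subtract
    beta <- x0 %*% w             # genes x k (w has orthonormal columns)
    adjusted <- x0 - beta %*% t(w)
    de <- differential_expression(adjusted, groups)
    controls <- de$gene[!is.na(de$p_adj) & de$p_adj > control_p]
    done <- it
  }
  list(adjusted = adjusted, controls = controls, factors = w,
       converged_iterations = done, ok = ok)
}

#' Per-gene mRNA-protein correlation
#'
#' Spearman correlation between matched RNA and protein rows across
#' samples, BH-adjusted over genes, with cohort summary statistics.
#'
#' @param rna,protein [expr_matrix()] objects or matrices with matched gene
#'   row names and the same sample order.
#' @param min_pairs Minimum paired finite values per gene (default 6).
#' @param alpha Significance cutoff on the adjusted p (default 0.05).
#' @return Object of class `mrna_protein_cor`: list with `genes` (tibble
#'   `gene rho p p_adj`) and `summary` (tibble `mean_rho frac_positive
#'   frac_significant n_genes n_excluded`). `tidy()` returns the per-gene
#'   table, `glance()` the summary.
#' @export
mrna_protein_correlation <- function(rna, protein, min_pairs = 6,
                                     alpha = 0.05) {
  xr <- if (inherits(rna, "expr_matrix")) rna$values else as.matrix(rna)
  xp <- if (inherits(protein, "expr_matrix")) protein$values else
    as.matrix(protein)
  assert_that(ncol(xr) == ncol(xp), "sample columns must match")
  shared <- intersect(rownames(xr), rownames(xp))
  n_excluded <- length(union(rownames(xr), rownames(xp))) - length(shared)
  xr <- xr[shared, , drop = FALSE]
  xp <- xp[shared, , drop = FALSE]
  rho <- vapply(seq_along(shared), function(i) {
    ok <- is.finite(xr[i, ]) & is.finite(xp[i, ])
    if (sum(ok) < min_pairs) return(NA_real_)
    suppressWarnings(cor(xr[i, ok], xp[i, ok], method = "spearman"))
  }, numeric(1))
  p <- spearman_p(rho, ncol(xr))
  padj <- rep(NA_real_, length(p))
  okp <- is.finite(p)
  padj[okp] <- p.adjust(p[okp], method = "BH")
  genes <- tibble(gene = shared, rho = rho, p = p, p_adj = padj)
  fin <- is.finite(rho)
  summary <- tibble(mean_rho = mean(rho[fin]),
                    frac_positive = mean(rho[fin] > 0),
                    frac_significant = mean(padj[fin] <= alpha, na.rm = TRUE),
                    n_genes = sum(fin),
                    n_excluded = n_excluded + sum(!fin))
  structure(list(genes = genes, summary = summary),
            class = "mrna_protein_cor")
}

#' @export
print.mrna_protein_cor <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<mrna_protein_cor> %d genes: mean rho %.3f, %.1f%% positive, %.1f%% significant\n",
    s$n_genes, s$mean_rho, 100 * s$frac_positive, 100 * s$frac_significant))
  invisible(x)
}

#' @export
tidy.mrna_protein_cor <- function(x, ...) x$genes

#' @export
glance.mrna_protein_cor <- function(x, ...) x$summary

#' Within-complex co-regulation of protein pairs
#'
#' Compares Spearman correlations of all pairs of measured proteins sharing
#' a complex against randomly drawn pairs, with a two-sided Mann-Whitney
#' test.
#'
#' @param expr An [expr_matrix()] or matrix.
#' @param complex_map Tibble `gene complex_id` (a gene may appear in
#'   several complexes).
#' @param n_random Number of random pairs (default 2000).
#' @param seed Integer seed for the random pairs.
#' @return List with `within` and `random` coefficient vectors,
#'   `mean_within`, `mean_random` and `p_value`.
#' @export
complex_coregulation <- function(expr, complex_map, n_random = 2000,
                                 seed = 1) {
  x <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  cmap <- filter(as_tibble(complex_map), .data$gene %in% rownames(x))
  sizes <- table(cmap$complex_id)
  keep_cx <- names(sizes)[sizes >= 2]
  assert_that(length(keep_cx) > 0,
              "no complex with at least two measured members")
  z <- standardize_rows(row_ranks(x))
  within <- unlist(lapply(keep_cx, function(cx) {
    members <- match(cmap$gene[cmap$complex_id == cx], rownames(x))
    pr <- utils::combn(members, 2)
    rowSums(z[pr[1, ], , drop = FALSE] * z[pr[2, ], , drop = FALSE])
  }))
  within <- unname(within[is.finite(within)])
  rnd <- with_seed(substream_seed(seed, "complex_pairs"), {
    i <- sample(nrow(x), n_random, replace = TRUE)
    j <- sample(nrow(x), n_random, replace = TRUE)
    ok <- i != j
    rowSums(z[i[ok], , drop = FALSE] * z[j[ok], , drop = FALSE])
  })
  rnd <- unname(rnd[is.finite(rnd)])
  pv <- suppressWarnings(wilcox.test(within, rnd))$p.value
  list(within = within, random = rnd, mean_within = mean(within),
       mean_random = mean(rnd), p_value = pv)
}

#' Partial Spearman correlation controlling for subtype
#'
#' Residualizes both vectors on the subtype indicator by least squares and
#' correlates the residuals, guarding against subtype-driven spurious
#' association (Simpson's paradox).
#'
#' @param x,y Numeric vectors.
#' @param subtype Factor/character of subtype per observation.
#' @return Spearman coefficient of the residuals (plain Spearman with a
#'   warning when only one subtype is present).
#' @export
partial_correlation_by_subtype <- function(x, y, subtype) {
  subtype <- as.factor(subtype)
  if (nlevels(droplevels(subtype)) < 2) {
    warning("single subtype; returning plain Spearman correlation")
    return(suppressWarnings(cor(x, y, method = "spearman")))
  }
  rx <- residuals(lm(x ~ subtype))
  ry <- residuals(lm(y ~ subtype))
  suppressWarnings(cor(rx, ry, method = "spearman"))
}

#' Compare per-gene correlations between strata
#'
#' Two strata: two-sided Wilcoxon rank-sum test; three or more:
#' Kruskal-Wallis. Strata with fewer than two members are dropped with a
#' warning.
#'
#' @param coefficients Numeric vector (e.g. per-gene mRNA-protein rho).
#' @param strata Stratum label per coefficient.
#' @return Tibble `test statistic p_value n_strata`.
#' @export
strata_correlation_compare <- function(coefficients, strata) {
  keep <- !is.na(coefficients) & !is.na(strata)
  coefficients <- coefficients[keep]
  strata <- as.character(strata)[keep]
  sizes <- table(strata)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning(sprintf("dropping strata with < 2 members: %s",
                    paste(small, collapse = ", ")))
    sel <- !(strata %in% small)
    coefficients <- coefficients[sel]
    strata <- strata[sel]
  }
  k <- length(unique(strata))
  assert_that(k >= 2, "need at least two usable strata")
  if (k == 2) {
    lv <- unique(strata)
    ht <- suppressWarnings(wilcox.test(coefficients[strata == lv[1]],
                                       coefficients[strata == lv[2]]))
    tibble(test = "wilcoxon", statistic = unname(ht$statistic),
           p_value = ht$p.value, n_strata = 2L)
  } else {
    ht <- kruskal.test(coefficients, factor(strata))
    tibble(test = "kruskal-wallis", statistic = unname(ht$statistic),
           p_value = ht$p.value, n_strata = as.integer(k))
  }
}

#' Compare chromosome morphology scores between groups
#'
#' Case means are the mean score across a case's metaphases; group means
#' average the case means. The one-sided Mann-Whitney test asks whether the
#' first group's case means are lower.
#'
#' @param cms CMS tibble `case_id group metaphase score` (scores in 1..3).
#' @param lower_group Group expected to score lower; defaults to the first
#'   group in order of appearance.
#' @param pooled If `TRUE`, pool all metaphases per group instead of
#'   averaging per case (alternative aggregation; the test still uses case
#'   means).
#' @return Object of class `cms_comparison`: list with `cases` (tibble
#'   `case_id group case_mean`), `groups` (tibble `group group_mean
#'   n_cases`) and `p_value`. `glance()` gives a one-row summary.
#' @export
compare_cms <- function(cms, lower_group = NULL, pooled = FALSE) {
  cms <- as_tibble(cms)
  assert_that(all(cms$score %in% 1:3), "scores must be integers in 1..3")
  grp <- unique(cms$group)
  assert_that(length(grp) == 2, "need exactly two groups")
  lower_group <- lower_group %||% grp[1]
  other <- setdiff(grp, lower_group)
  cases <- cms %>% group_by(.data$case_id, .data$group) %>%
    summarise(case_mean = mean(.data$score), .groups = "drop")
  counts <- table(cases$group)
  assert_that(all(counts >= 2), "each group needs at least two cases")
  groups <- if (pooled) {
    cms %>% group_by(.data$group) %>%
      summarise(group_mean = mean(.data$score),
                n_cases = dplyr::n_distinct(.data$case_id),
                .groups = "drop")
  } else {
    cases %>% group_by(.data$group) %>%
      summarise(group_mean = mean(.data$case_mean), n_cases = dplyr::n(),
                .groups = "drop")
  }
  ht <- suppressWarnings(wilcox.test(
    cases$case_mean[cases$group == lower_group],
    cases$case_mean[cases$group == other],
    alternative = "less"))
  structure(list(cases = cases, groups = groups, p_value = ht$p.value),
            class = "cms_comparison")
}

#' @export
print.cms_comparison <- function(x, ...) {
  g <- x$groups
  cat(sprintf("<cms_comparison> %s; one-sided Mann-Whitney p = %.4g\n",
              paste(sprintf("%s: %.2f (n=%d)", g$group, g$group_mean,
                            g$n_cases), collapse = "; "),
              x$p_value))
  invisible(x)
}

#' @export
tidy.cms_comparison <- function(x, ...) x$cases

#' @export
glance.cms_comparison <- function(x, ...) {
  g <- x$groups
  tibble(group1 = g$group[1], mean1 = g$group_mean[1],
         group2 = g$group[2], mean2 = g$group_mean[2],
         p_value = x$p_value)
}
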