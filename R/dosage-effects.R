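#' Normalized copy number per chromosome
#'
#' For every sample, the length-weighted mean copy number over the
#' chromosome (segment gaps imputed at normal ploidy with a message) is
#' divided by the normal ploidy; values are then averaged across samples.
#' Chromosomes with undefined ploidy (e.g. Y in females) give `NA` and are
#' excluded from downstream regression.
#'
#' @param segments Copy-number segments, tibble
#'   `sample chrom start end copy` (0-based half-open, integer copies).
#' @param genome A [genome_spec()] supplying chromosome lengths and normal
#'   ploidy.
#' @return Tibble `chrom norm_copy n_samples`.
#' @export
normalized_copy_number <- function(segments, genome) {
  gs <- genome$chromosomes
  seg <- as_tibble(segments)
  assert_that(all(seg$copy >= 0), "copies must be non-negative")
  assert_that(all(seg$chrom %in% gs$chrom),
              "segment chromosome missing from genome")
  per_sample <- seg %>%
    left_join(gs, by = "chrom") %>%
    group_by(.data$sample, .data$chrom) %>%
    summarise(covered = sum(.data$end - .data$start),
              wsum = sum(.data$copy * (.data$end - .data$start)),
              length = .data$length[1], ploidy = .data$ploidy[1],
              .groups = "drop")
  n_gap <- sum(per_sample$covered < per_sample$length)
  if (n_gap > 0) {
    message(sprintf(
      "%d sample-chromosome(s) with segment gaps; gaps imputed at normal ploidy",
      n_gap))
  }
  # samples absent on some chromosome count as fully normal there
  all_pairs <- tidyr::expand_grid(sample = unique(seg$sample),
                                  chrom = gs$chrom) %>%
    left_join(gs, by = "chrom")
  per_sample <- all_pairs %>%
    left_join(per_sample[, c("sample", "chrom", "covered", "wsum")],
              by = c("sample", "chrom")) %>%
    mutate(covered = dplyr::coalesce(.data$covered, 0),
           wsum = dplyr::coalesce(.data$wsum, 0),
           mean_copy = (.data$wsum +
                          (.data$length - .data$covered) * .data$ploidy) /
             .data$length,
           ratio = .data$mean_copy / .data$ploidy)
  per_sample %>%
    group_by(.data$chrom) %>%
    summarise(norm_copy = mean(.data$ratio),
              n_samples = dplyr::n(), .groups = "drop") %>%
    arrange(match(.data$chrom, gs$chrom))
}

#' Per-feature and per-chromosome Cohen's d
#'
#' `d = (mean1 - mean2) / s_pooled` with the usual pooled standard
#' deviation. Features with zero pooled sd are excluded with a flag. When a
#' gene annotation is supplied the per-chromosome value is the unweighted
#' mean of the per-feature d on that chromosome.
#'
#' @param expr An [expr_matrix()] or plain genes x samples matrix.
#' @param groups Character/factor of group labels per sample (two levels;
#'   the first level is group 1). Defaults to the `group` column of an
#'   `expr_matrix`.
#' @param genes Optional annotation tibble (`gene`, `chrom`) to aggregate
#'   per chromosome.
#' @return Tibble `feature d excluded` (plus `chrom` when annotated), with
#'   attribute `per_chromosome` (tibble `chrom mean_d n_features`) when
#'   `genes` is given.
#' @export
cohens_d <- function(expr, groups = NULL, genes = NULL) {
  x <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  if (is.null(groups) && inherits(expr, "expr_matrix")) {
    groups <- expr$samples$group
  }
  groups <- as.character(groups)
  lv <- unique(groups)
  assert_that(length(lv) == 2, "need exactly two groups")
  g1 <- groups == lv[1]
  g2 <- groups == lv[2]
  n1 <- sum(g1); n2 <- sum(g2)
  assert_that(n1 >= 2 && n2 >= 2, "need >= 2 samples per group")
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, g2, drop = FALSE])
  v1 <- apply(x[, g1, drop = FALSE], 1, var)
  v2 <- apply(x[, g2, drop = FALSE], 1, var)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  d <- unname(ifelse(sp > 0, (m1 - m2) / sp, NA_real_))
  out <- tibble(feature = rownames(x) %||% as.character(seq_len(nrow(x))),
                d = d, excluded = !is.finite(d))
  if (!is.null(genes)) {
    out <- left_join(out, genes[, c("gene", "chrom")],
                     by = c(feature = "gene"))
    attr(out, "per_chromosome") <- out %>%
      filter(!.data$excluded, !is.na(.data$chrom)) %>%
      group_by(.data$chrom) %>%
      summarise(mean_d = mean(.data$d), n_features = dplyr::n(),
                .groups = "drop")
  }
  out
}

#' Regress per-chromosome effect sizes on normalized copy number
#'
#' Ordinary least squares of per-chromosome Cohen's d on the Eq.-style
#' normalized copy number; chromosomes with `d > 0.3` are flagged as
#' significantly affected.
#'
#' @param es Tibble with `chrom`, `mean_d` (per-chromosome Cohen's d) and
#'   `norm_copy`; build it by joining the `per_chromosome` attribute of
#'   [cohens_d()] with [normalized_copy_number()].
#' @param affected_threshold Effect-size cutoff (strict `>`, default 0.3).
#' @return Object of class `dosage_fit`: list with `fit` (the `lm`),
#'   `data`, `slope`, `intercept`, `r_squared` and `affected` (chromosome
#'   vector). `tidy()` and `glance()` methods are available.
#' @export
regress_effect_size <- function(es, affected_threshold = 0.3) {
  es <- filter(as_tibble(es), is.finite(.data$mean_d),
               is.finite(.data$norm_copy))
  assert_that(nrow(es) >= 3, "need at least 3 informative chromosomes")
  fit <- lm(mean_d ~ norm_copy, data = es)
  structure(
    list(fit = fit, data = es,
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = suppressWarnings(summary(fit))$r.squared,
         affected = es$chrom[es$mean_d > affected_threshold]),
    class = "dosage_fit")
}

#' @export
print.dosage_fit <- function(x, ...) {
  cat(sprintf(
    "<dosage_fit> d = %.3f + %.3f * norm_copy (R^2 = %.3f); affected: %s\n",
    x$intercept, x$slope, x$r_squared,
    if (length(x$affected)) paste(x$affected, collapse = ", ") else "none"))
  invisible(x)
}

#' @export
tidy.dosage_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
         statistic = s[, 3], p_value = s[, 4])
}

#' @export
glance.dosage_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, n_chromosomes = nrow(x$data),
         n_affected = length(x$affected))
}

#' Project copy-number segments onto genes
#'
#' Each gene takes the copy number of the segment containing its TSS; genes
#' in gaps take the chromosome's normal ploidy.
#'
#' @param segments Tibble `sample chrom start end copy`.
#' @param genes Annotation tibble `gene chrom tss`.
#' @param genome A [genome_spec()] (for ploidy imputation).
#' @return Genes x samples numeric matrix of copy numbers.
#' @export
gene_copy_matrix <- function(segments, genes, genome) {
  samples <- unique(segments$sample)
  ploidy <- setNames(genome$chromosomes$ploidy, genome$chromosomes$chrom)
  out <- matrix(rep(ploidy[genes$chrom], length(samples)),
                nrow = nrow(genes), ncol = length(samples),
                dimnames = list(genes$gene, samples))
  for (s in samples) {
    seg <- segments[segments$sample == s, ]
    for (k in seq_len(nrow(seg))) {
      hit <- genes$chrom == seg$chrom[k] & genes$tss >= seg$start[k] &
        genes$tss < seg$end[k]
      out[hit, s] <- seg$copy[k]
    }
  }
  out
}

#' Select copy-number-variable (CNA) genes
#'
#' Keeps genes whose copy number deviates from the per-gene modal value in
#' strictly more than `min_variant_cases` samples.
#'
#' @param gene_copy Genes x samples copy-number matrix (see
#'   [gene_copy_matrix()]).
#' @param min_variant_cases Threshold (strict `>`, default 3).
#' @return Character vector of retained gene ids.
#' @export
select_cna_genes <- function(gene_copy, min_variant_cases = 3) {
  modal <- apply(gene_copy, 1, function(v) {
    tb <- table(v)
    as.numeric(names(tb)[which.max(tb)])
  })
  n_var <- rowSums(gene_copy != modal)
  rownames(gene_copy)[n_var > min_variant_cases]
}

#' cis/trans copy-number-to-expression correlation map
#'
#' Spearman rank correlation between every CNA gene's copy-number vector
#' and every expression feature across samples, BH-adjusted over all tested
#' pairs. A pair is `cis` when the CNA gene and the feature are the same
#' gene; significant trans pairs appear as vertical stripes in the map.
#'
#' @param gene_copy Genes x samples copy-number matrix.
#' @param expr An [expr_matrix()] or matrix with matching sample columns.
#' @param cna_genes Gene ids to use as CNA genes (see
#'   [select_cna_genes()]).
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return Tibble `cna_gene feature rho p p_adj cis significant`; pairs
#'   with a constant vector are reported with `NA` coefficients and are
#'   excluded from the BH family.
#' @export
cis_trans_map <- function(gene_copy, expr, cna_genes, alpha = 0.05) {
  x <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  assert_that(ncol(x) >= 6, "need at least 6 samples")
  assert_that(length(cna_genes) > 0, "cna_genes must be nonempty")
  cn <- gene_copy[cna_genes, colnames(x), drop = FALSE]
  rc <- t(apply(cn, 1, rank))
  re <- row_ranks(x)
  zc <- standardize_rows(rc)
  ze <- standardize_rows(re)
  rho <- tcrossprod(zc, ze)  # cna_genes x features
  n <- ncol(x)
  out <- as_tibble(rho, rownames = "cna_gene") %>%
    tidyr::pivot_longer(-"cna_gene", names_to = "feature",
                        values_to = "rho") %>%
    mutate(p = spearman_p(.data$rho, n))
  out$p_adj <- NA_real_
  ok <- is.finite(out$p)
  out$p_adj[ok] <- p.adjust(out$p[ok], method = "BH")
  out %>% mutate(cis = .data$cna_gene == .data$feature,
                 significant = !is.na(.data$p_adj) & .data$p_adj <= alpha)
}
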