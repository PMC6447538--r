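#' Count CTCF binding sites per gene
#'
#' Counts peaks overlapping the gene body extended by `flank` on either
#' side (`[start - flank, end + flank)`).
#'
#' @param genes Annotation tibble `gene chrom start end`.
#' @param peaks Peak tibble `chrom start end` (0-based half-open).
#' @param flank Flank in bp (default 5 kb).
#' @return Tibble `gene n_sites`.
#' @export
count_ctcf_sites <- function(genes, peaks, flank = 5000) {
  if (nrow(peaks) == 0) {
    return(tibble(gene = genes$gene, n_sites = 0L))
  }
  ggr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(0, genes$start - flank) + 1,
                     end = genes$end + flank))
  pgr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = peaks$start + 1, end = peaks$end))
  tibble(gene = genes$gene,
         n_sites = GenomicRanges::countOverlaps(ggr, pgr))
}

#' CTCF-site enrichment among differentially expressed genes
#'
#' Chi-square comparison of the site-count strata (0, 1, 2, >= 3) between
#' DE and non-DE genes; strata with expected cell counts below 1 are merged
#' upward with a warning. Additionally a Mann-Whitney test compares
#' `|log2 fold change|` between high-count (>= median) and low-count genes.
#'
#' @param counts Integer vector of per-gene site counts.
#' @param de_flags Logical vector: is the gene differentially expressed?
#' @param fold_changes Per-gene log2 fold changes.
#' @return One-row tibble `chisq_statistic chisq_p mw_p n_de n_background`;
#'   the strata table is attached as attribute `strata`.
#' @export
ctcf_de_enrichment <- function(counts, de_flags, fold_changes) {
  assert_that(all(counts >= 0), "counts must be non-negative")
  assert_that(is.logical(de_flags), "de_flags must be logical")
  strat <- cut(counts, breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
               labels = c("0", "1", "2", ">=3"))
  tab <- table(de = de_flags, stratum = strat)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  while (ncol(tab) > 2 && any(expected < 1)) {
    warning("merging sparse site-count strata")
    k <- ncol(tab)
    merged <- tab[, k - 1] + tab[, k]
    tab <- cbind(tab[, seq_len(k - 2), drop = FALSE], merged)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  }
  cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  hi <- counts >= median(counts)
  mw <- if (any(hi) && any(!hi)) {
    suppressWarnings(wilcox.test(abs(fold_changes[hi]),
                                 abs(fold_changes[!hi])))$p.value
  } else NA_real_
  out <- tibble(chisq_statistic = unname(cs$statistic),
                chisq_p = cs$p.value, mw_p = mw,
                n_de = sum(de_flags), n_background = sum(!de_flags))
  attr(out, "strata") <- tab
  out
}

#' Consensus ChIA-PET interactions between two datasets
#'
#' Interactions with PET count below `min_pet` in either set are dropped;
#' the consensus keeps interactions whose both anchors reciprocally overlap
#' (>= 1 bp each) between the sets. Anchors of a consensus record are the
#' intersections of the matched anchors and the PET count is the minimum of
#' the two, so the operation is commutative.
#'
#' @param a,b Interaction tibbles
#'   `chrom1 start1 end1 chrom2 start2 end2 pet`.
#' @param min_pet Minimum PET count (default 10).
#' @return Consensus interaction tibble in the same format.
#' @export
consensus_interactions <- function(a, b, min_pet = 10) {
  check_bedpe <- function(x, nm) {
    need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "pet")
    missing <- setdiff(need, names(x))
    assert_that(length(missing) == 0,
                sprintf("malformed interaction set %s: missing %s", nm,
                        paste(missing, collapse = ", ")))
    bad <- which(x$start1 >= x$end1 | x$start2 >= x$end2 | x$pet <= 0)
    assert_that(length(bad) == 0,
                sprintf("malformed paired record at line %d of %s",
                        if (length(bad)) bad[1] else 0L, nm))
    x
  }
  a <- filter(check_bedpe(as_tibble(a), "a"), .data$pet >= min_pet)
  b <- filter(check_bedpe(as_tibble(b), "b"), .data$pet >= min_pet)
  if (nrow(a) == 0 || nrow(b) == 0) return(a[0, ])
  ov <- function(s1, e1, s2, e2) pmax(s1, s2) < pmin(e1, e2)
  res <- list()
  for (i in seq_len(nrow(a))) {
    hit <- which(b$chrom1 == a$chrom1[i] & b$chrom2 == a$chrom2[i] &
                   ov(a$start1[i], a$end1[i], b$start1, b$end1) &
                   ov(a$start2[i], a$end2[i], b$start2, b$end2))
    for (j in hit) {
      res[[length(res) + 1]] <- tibble(
        chrom1 = a$chrom1[i],
        start1 = max(a$start1[i], b$start1[j]),
        end1 = min(a$end1[i], b$end1[j]),
        chrom2 = a$chrom2[i],
        start2 = max(a$start2[i], b$start2[j]),
        end2 = min(a$end2[i], b$end2[j]),
        pet = min(a$pet[i], b$pet[j]))
    }
  }
  if (!length(res)) return(a[0, ])
  distinct(bind_rows(res))
}

#' Classify genes as anchor or background genes
#'
#' A gene is an anchor gene when its TSS lies within `max_dist` of the
#' nearest anchor interval of the consensus interaction set (distance 0
#' inside an anchor).
#'
#' @param genes Annotation tibble `gene chrom tss`.
#' @param interactions Consensus interactions (see
#'   [consensus_interactions()]).
#' @param max_dist Distance cutoff in bp (default 5 kb).
#' @return Tibble `gene anchor distance` (`distance` is `Inf` when the
#'   chromosome has no anchors).
#' @export
classify_anchor_genes <- function(genes, interactions, max_dist = 5000) {
  assert_that(nrow(interactions) > 0, "empty interaction set")
  anchors <- bind_rows(
    tibble(chrom = interactions$chrom1, start = interactions$start1,
           end = interactions$end1),
    tibble(chrom = interactions$chrom2, start = interactions$start2,
           end = interactions$end2))
  dist <- vapply(seq_len(nrow(genes)), function(i) {
    aa <- anchors[anchors$chrom == genes$chrom[i], ]
    if (nrow(aa) == 0) return(Inf)
    inside <- genes$tss[i] >= aa$start & genes$tss[i] < aa$end
    if (any(inside)) return(0)
    min(pmin(abs(genes$tss[i] - aa$start),
             abs(genes$tss[i] - (aa$end - 1))))
  }, numeric(1))
  tibble(gene = genes$gene, anchor = dist <= max_dist, distance = dist)
}

#' Anchor-gene enrichment among differentially expressed genes
#'
#' Hypergeometric upper-tail probability of observing at least the seen
#' number of DE anchor genes, plus a two-sided Mann-Whitney comparison of
#' `|log2 fold change|` between DE anchor and DE background genes.
#'
#' @param classes Output of [classify_anchor_genes()] (or a logical vector
#'   of anchor flags).
#' @param de_flags Logical per-gene DE indicator.
#' @param fold_changes Per-gene log2 fold changes.
#' @return One-row tibble
#'   `hyper_p mw_p n_anchor n_de n_de_anchor n_genes`; degenerate class
#'   sizes give `NA` p-values with a warning.
#' @export
anchor_de_enrichment <- function(classes, de_flags, fold_changes) {
  anchor <- if (is.logical(classes)) classes else classes$anchor
  N <- length(anchor)
  K <- sum(anchor)
  n <- sum(de_flags)
  k <- sum(anchor & de_flags)
  hyper_p <- if (K == 0 || K == N || n == 0) {
    warning("degenerate class sizes; hypergeometric undefined")
    NA_real_
  } else {
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }
  fa <- abs(fold_changes[de_flags & anchor])
  fb <- abs(fold_changes[de_flags & !anchor])
  mw_p <- if (length(fa) >= 1 && length(fb) >= 1) {
    suppressWarnings(wilcox.test(fa, fb))$p.value
  } else NA_real_
  tibble(hyper_p = hyper_p, mw_p = mw_p, n_anchor = K, n_de = n,
         n_de_anchor = k, n_genes = N)
}
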