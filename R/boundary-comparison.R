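#' Match boundaries across samples
#'
#' Greedy nearest-neighbor matching of each reference boundary against every
#' sample's boundary set within `tolerance` (default +/- 100 kb). Matches
#' are assigned in order of increasing distance (ties broken leftmost); each
#' sample boundary is used at most once. A reference boundary unmatched in a
#' sample is `lost` there; a matched boundary whose strength falls below
#' `weak_threshold` is `weak`; otherwise `present`.
#'
#' @param sets Named list of boundary tibbles (`chrom`, `pos`, optional
#'   `strength`), one per sample; the `boundaries` element of
#'   [call_boundaries()] works directly.
#' @param reference Reference boundary tibble (`chrom`, `pos`); defaults to
#'   the first set.
#' @param tolerance Matching tolerance in bp (default 100 kb).
#' @param weak_threshold Strength below which a matched boundary is called
#'   `weak` (default 0.1; only used when the sets carry strengths).
#' @return Tibble with `chrom`, `pos` (reference boundary), `sample`,
#'   `status` (`present`/`weak`/`lost`), `matched_pos`, `distance`.
#' @export
match_boundaries <- function(sets, reference = NULL, tolerance = 100000,
                             weak_threshold = 0.1) {
  assert_that(tolerance > 0, "tolerance must be positive")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- sprintf("sample%d", seq_along(sets))
  }
  reference <- reference %||% sets[[1]]
  ref <- arrange(as_tibble(reference)[, c("chrom", "pos")],
                 .data$chrom, .data$pos)
  out <- purrr::imap_dfr(sets, function(bs, nm) {
    bs <- as_tibble(bs)
    has_strength <- "strength" %in% names(bs)
    res <- ref
    res$sample <- nm
    res$status <- "lost"
    res$matched_pos <- NA_real_
    res$distance <- NA_real_
    for (ch in unique(ref$chrom)) {
      ri <- which(ref$chrom == ch)
      cand <- bs[bs$chrom == ch, ]
      if (nrow(cand) == 0) next
      # all candidate pairs within tolerance, greedy by distance then leftmost
      pairs <- tidyr::expand_grid(r = ri, c = seq_len(nrow(cand))) %>%
        mutate(dist = abs(ref$pos[.data$r] - cand$pos[.data$c])) %>%
        filter(.data$dist <= tolerance) %>%
        arrange(.data$dist, ref$pos[.data$r])
      used_r <- used_c <- integer(0)
      for (k in seq_len(nrow(pairs))) {
        r <- pairs$r[k]; cc <- pairs$c[k]
        if (r %in% used_r || cc %in% used_c) next
        used_r <- c(used_r, r)
        used_c <- c(used_c, cc)
        res$matched_pos[r] <- cand$pos[cc]
        res$distance[r] <- pairs$dist[k]
        st <- "present"
        if (has_strength && is.finite(cand$strength[cc]) &&
            cand$strength[cc] < weak_threshold) {
          st <- "weak"
        }
        res$status[r] <- st
      }
    }
    res
  })
  out
}

#' Recurrently lost boundaries per group
#'
#' Boundaries whose status is `weak` or `lost` in at least `min_recurrence`
#' samples of one group and — in strict mode — `present` in every sample of
#' the other group.
#'
#' @param matches Output of [match_boundaries()].
#' @param group_labels Named character vector mapping sample to group.
#' @param min_recurrence Minimum affected samples in the reporting group
#'   (default 2).
#' @param strict If `TRUE` (default) require `present` in all samples of the
#'   other group; if `FALSE` only the recurrence condition applies.
#' @return Tibble `chrom pos group n_affected` of group-specific
#'   weakened/lost boundaries.
#' @export
recurrent_lost_boundaries <- function(matches, group_labels,
                                      min_recurrence = 2, strict = TRUE) {
  groups <- unique(group_labels)
  assert_that(length(groups) == 2, "need exactly two groups")
  counts <- table(group_labels)
  assert_that(all(counts >= min_recurrence),
              "each group needs at least min_recurrence samples")
  m <- mutate(matches, group = group_labels[.data$sample])
  assert_that(!any(is.na(m$group)), "sample missing from group_labels")
  stat <- m %>% group_by(.data$chrom, .data$pos, .data$group) %>%
    summarise(n_affected = sum(.data$status %in% c("weak", "lost")),
              n_present = sum(.data$status == "present"),
              n_total = dplyr::n(), .groups = "drop")
  out <- lapply(groups, function(g) {
    other <- setdiff(groups, g)
    this <- filter(stat, .data$group == g,
                   .data$n_affected >= min_recurrence)
    if (strict) {
      ok_other <- stat %>% filter(.data$group == other,
                                  .data$n_present == .data$n_total) %>%
        select("chrom", "pos")
      this <- dplyr::semi_join(this, ok_other, by = c("chrom", "pos"))
    }
    mutate(this, group = g)
  })
  bind_rows(out) %>% select("chrom", "pos", "group", "n_affected")
}

#' Classify a boundary as strong, weak or lost in one sample
#'
#' Quantitative proxy for visual boundary classification: `lost` if the
#' insulation delta has no upward zero-crossing within `tolerance` of the
#' position; `weak` if a crossing exists but its swing is below `b_weak`;
#' `strong` otherwise.
#'
#' @param insulation Insulation profile of the sample (from
#'   [insulation_score()]).
#' @param boundary Boundary position in bp (bin edge).
#' @param chrom Chromosome of the boundary.
#' @param tolerance Search window in bp (default 100 kb).
#' @param b_weak Weak/strong swing threshold in log2 units (default 0.1).
#' @return One of `"strong"`, `"weak"`, `"lost"`.
#' @export
classify_boundary_change <- function(insulation, boundary, chrom,
                                     tolerance = 100000, b_weak = 0.1) {
  p <- insulation[insulation$chrom == chrom, ]
  assert_that(nrow(p) > 0, "chromosome absent from insulation profile")
  assert_that(boundary >= 0 && boundary <= max(p$end),
              "boundary outside chromosome")
  bs <- attr(insulation, "bin_size") %||% (p$end[1] - p$start[1])
  span <- attr(insulation, "delta_span_bins") %||% max(1, 125000 %/% bs)
  calls <- boundaries_from_insulation(arrange(p, .data$bin),
                                      min_swing = 0, span = span, bs = bs)
  if (is.null(calls) || nrow(calls) == 0) return("lost")
  near <- calls[abs(calls$pos - boundary) <= tolerance, ]
  if (nrow(near) == 0) return("lost")
  if (max(near$strength) < b_weak) return("weak")
  "strong"
}

#' Peak support of boundaries
#'
#' A boundary is supported when at least one peak overlaps
#' `[pos - window, pos + window)`.
#'
#' @param boundaries Tibble `chrom pos`.
#' @param peaks Tibble `chrom start end` (0-based half-open). Unsorted input
#'   is sorted with a warning.
#' @param window Half-window in bp (default 50 kb).
#' @return List with `boundaries` (input plus `supported`) and
#'   `supported_fraction`.
#' @export
peak_support <- function(boundaries, peaks, window = 50000) {
  peaks <- as_tibble(peaks)
  resorted <- arrange(peaks, .data$chrom, .data$start)
  if (!identical(resorted$start, peaks$start) ||
      !identical(resorted$chrom, peaks$chrom)) {
    warning("peak set was unsorted; sorted internally")
    peaks <- resorted
  }
  if (nrow(peaks) == 0) {
    out <- mutate(as_tibble(boundaries), supported = FALSE)
    return(list(boundaries = out, supported_fraction = 0))
  }
  bgr <- GenomicRanges::GRanges(
    boundaries$chrom,
    IRanges::IRanges(start = pmax(0, boundaries$pos - window) + 1,
                     end = boundaries$pos + window))
  pgr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = peaks$start + 1, end = peaks$end))
  hit <- GenomicRanges::countOverlaps(bgr, pgr) > 0
  out <- mutate(as_tibble(boundaries), supported = hit)
  list(boundaries = out, supported_fraction = mean(hit))
}

#' Chi-square test of expression direction against a reference fraction
#'
#' One-degree-of-freedom goodness of fit (no continuity correction) of an
#' observed down/up split against a genome-wide down fraction.
#'
#' @param n_down,n_up Observed counts.
#' @param down_fraction Genome-wide fraction of downregulated features.
#' @return Tibble `n_down n_up expected_down statistic p_value`.
#' @export
direction_enrichment_test <- function(n_down, n_up, down_fraction) {
  assert_that(n_down >= 0 && n_up >= 0, "counts must be non-negative")
  assert_that(down_fraction > 0 && down_fraction < 1,
              "down_fraction must be in (0, 1)")
  n <- n_down + n_up
  e <- n * c(down_fraction, 1 - down_fraction)
  x2 <- sum((c(n_down, n_up) - e)^2 / e)
  tibble(n_down = n_down, n_up = n_up, expected_down = e[1],
         statistic = x2, p_value = pchisq(x2, df = 1, lower.tail = FALSE))
}

#' Expression-direction enrichment near lost boundaries
#'
#' Selects differentially expressed features (BH-adjusted p at most `alpha`)
#' whose TSS lies within `radius` of any lost boundary and tests the
#' observed down/up split against the genome-wide down fraction with a
#' 1-df chi-square goodness of fit.
#'
#' @param lost Tibble `chrom pos` of lost boundaries.
#' @param genes Gene annotation tibble (`gene chrom tss`).
#' @param de DE results (tibble `gene log2fc p_adj direction` as produced by
#'   [differential_expression()]).
#' @param radius TSS-to-boundary distance in bp (default 1 Mb).
#' @param genome_wide_down_fraction Null down fraction; defaults to the
#'   down fraction among all significant features in `de`.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return Tibble `n_proximal n_down n_up down_fraction statistic p_value`.
#' @export
boundary_proximal_enrichment <- function(lost, genes, de, radius = 1e6,
                                         genome_wide_down_fraction = NULL,
                                         alpha = 0.05) {
  sig <- de %>% filter(.data$p_adj <= alpha) %>%
    left_join(genes[, c("gene", "chrom", "tss")], by = "gene") %>%
    filter(!is.na(.data$chrom))
  if (is.null(genome_wide_down_fraction)) {
    genome_wide_down_fraction <- mean(sig$direction == "down")
  }
  near <- sig %>%
    dplyr::rowwise() %>%
    mutate(proximal = any(lost$chrom == .data$chrom &
                            abs(lost$pos - .data$tss) <= radius)) %>%
    ungroup() %>%
    filter(.data$proximal)
  if (nrow(near) == 0) {
    warning("no proximal differentially expressed features; test undefined")
    return(tibble(n_proximal = 0L, n_down = 0L, n_up = 0L,
                  down_fraction = genome_wide_down_fraction,
                  statistic = NA_real_, p_value = NA_real_))
  }
  nd <- sum(near$direction == "down")
  nu <- sum(near$direction == "up")
  res <- direction_enrichment_test(nd, nu, genome_wide_down_fraction)
  tibble(n_proximal = nrow(near), n_down = nd, n_up = nu,
         down_fraction = genome_wide_down_fraction,
         statistic = res$statistic, p_value = res$p_value)
}
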