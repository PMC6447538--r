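#' Directionality index profile
#'
#' For every bin, `A` is the total contact with the upstream window, `B`
#' with the downstream window, `E = (A + B) / 2`, and the raw DI is
#' `sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)`; it is 0 when `A = B` or
#' `A + B = 0`. The standardized DI is the z-score of the raw DI over
#' unmasked bins, genome-wide by default (per-chromosome via
#' `standardize`).
#'
#' @param cm A [contact_matrix()] or [hic_map()] (balanced counts are used
#'   when available).
#' @param window Window size in bp (default 500 kb); must be a multiple of
#'   the bin size and at least two bins.
#' @param standardize `"genome"` (default) or `"chromosome"`.
#' @return Tibble with `chrom`, `bin`, `start`, `end`, `a`, `b`, `di`,
#'   `di_z`, `masked`; carries attribute `profile_type = "di"`.
#' @export
directionality_index <- function(cm, window = 500000,
                                 standardize = c("genome", "chromosome")) {
  standardize <- match.arg(standardize)
  cms <- if (inherits(cm, "hic_map")) cm else hic_map(list(cm))
  bs <- cms[[1]]$bin_size
  assert_that(window %% bs == 0, "window must be a multiple of bin_size")
  assert_that(window >= 2 * bs, "window must span at least two bins")
  w <- window / bs
  prof <- bind_rows(lapply(cms, function(x) {
    m <- working_counts(x)
    n <- nrow(m)
    a <- b <- numeric(n)
    for (i in seq_len(n)) {
      cs <- cumsum(m[i, ])
      lo <- max(1L, i - w)
      a[i] <- if (i > 1) cs[i - 1] - (if (lo > 1) cs[lo - 1] else 0) else 0
      hi <- min(n, i + w)
      b[i] <- if (i < n) cs[hi] - cs[i] else 0
    }
    e <- (a + b) / 2
    di <- ifelse(e == 0 | a == b, 0,
                 sign(b - a) * ((a - e)^2 / e + (b - e)^2 / e))
    out <- bin_table(x)
    out$a <- a
    out$b <- b
    out$di <- ifelse(x$mask, NA_real_, di)
    out
  }))
  z_of <- function(v) {
    mu <- mean(v, na.rm = TRUE)
    s <- sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)) + 0 * v)
    (v - mu) / s
  }
  prof <- if (standardize == "genome") {
    mutate(prof, di_z = z_of(.data$di))
  } else {
    prof %>% group_by(.data$chrom) %>%
      mutate(di_z = z_of(.data$di)) %>% ungroup()
  }
  prof <- select(prof, "chrom", "bin", "start", "end", "a", "b", "di",
                 "di_z", "masked")
  attr(prof, "profile_type") <- "di"
  attr(prof, "bin_size") <- bs
  prof
}

#' Insulation score profile
#'
#' Per-bin mean of the square submatrix spanning `square / bin_size` bins
#' upstream by the same number downstream across the bin, computed on
#' balanced counts; the normalized score is `log2(value / genome-wide
#' median)` and `delta(i)` is the mean normalized score over
#' `(i, i + span]` minus the mean over `[i - span, i)`. Bins whose square is
#' incomplete (chromosome ends) or fully masked are missing.
#'
#' @param cm A [contact_matrix()] or [hic_map()].
#' @param square Insulation square size in bp (default 250 kb).
#' @param delta_span Delta window in bp (default 125 kb).
#' @return Tibble with `chrom`, `bin`, `start`, `end`, `insulation`,
#'   `norm`, `delta`, `masked`; attributes `profile_type = "insulation"`
#'   and `delta_span_bins`.
#' @export
insulation_score <- function(cm, square = 250000, delta_span = 125000) {
  cms <- if (inherits(cm, "hic_map")) cm else hic_map(list(cm))
  bs <- cms[[1]]$bin_size
  assert_that(square %% bs == 0, "square must be a multiple of bin_size")
  assert_that(delta_span %% bs == 0,
              "delta_span must be a multiple of bin_size")
  s <- square / bs
  span <- delta_span / bs
  prof <- bind_rows(lapply(cms, function(x) {
    m <- working_counts(x)
    keep <- !x$mask
    n <- nrow(m)
    ins <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (!keep[i] || i - s < 1 || i + s > n) next
      rows <- (i - s):(i - 1)
      cols <- (i + 1):(i + s)
      ok <- outer(keep[rows], keep[cols], `&`)
      if (!any(ok)) next
      ins[i] <- mean(m[rows, cols][ok])
    }
    out <- bin_table(x)
    out$insulation <- ins
    out
  }))
  # normalize in log space so the median of finite normalized values is
  # exactly zero
  lg <- ifelse(is.finite(prof$insulation) & prof$insulation > 0,
               log2(prof$insulation), NA_real_)
  prof$norm <- lg - median(lg, na.rm = TRUE)
  prof <- prof %>% group_by(.data$chrom) %>%
    mutate(delta = insulation_delta(.data$norm, span)) %>% ungroup()
  prof <- select(prof, "chrom", "bin", "start", "end", "insulation",
                 "norm", "delta", "masked")
  attr(prof, "profile_type") <- "insulation"
  attr(prof, "bin_size") <- bs
  attr(prof, "delta_span_bins") <- span
  prof
}

# delta(i) = mean(norm over (i, i+span]) - mean(norm over [i-span, i))
insulation_delta <- function(norm, span) {
  n <- length(norm)
  vapply(seq_len(n), function(i) {
    after <- norm[seq(min(i + 1, n + 1), min(i + span, n))]
    before <- norm[seq(max(1, i - span), max(i - 1, 0))]
    if (i + 1 > n || i - 1 < 1) return(NA_real_)
    a <- mean(after, na.rm = TRUE)
    b <- mean(before, na.rm = TRUE)
    if (!is.finite(a) || !is.finite(b)) return(NA_real_)
    a - b
  }, numeric(1))
}

#' Call TAD boundaries from a DI or insulation profile
#'
#' DI mode: a boundary is placed at the bin edge between the last bin with
#' standardized DI below `-min_di` and the first subsequent bin above
#' `+min_di`, provided the switch happens within `max_gap` bins; strength is
#' the DI jump. Insulation mode: boundaries sit at upward zero-crossings of
#' the delta vector whose local swing (max delta after minus min delta
#' before, within the delta span) is at least `min_swing`; strength is the
#' swing. Domains are the inter-boundary intervals.
#'
#' @param profile A profile from [directionality_index()] or
#'   [insulation_score()] (auto-detected).
#' @param min_di DI z-score threshold (default 0.5).
#' @param max_gap Maximum bins between the negative and positive DI bins
#'   (default 2).
#' @param min_swing Minimum delta swing in log2 units (default 0.1).
#' @param sample_id Optional sample label stored with the calls.
#' @return List with `boundaries` (tibble `sample chrom pos strength
#'   method`) and `tads` (tibble `chrom start end`).
#' @export
call_boundaries <- function(profile, min_di = 0.5, max_gap = 2,
                            min_swing = 0.1, sample_id = "sample") {
  type <- attr(profile, "profile_type") %||%
    (if ("di_z" %in% names(profile)) "di" else "insulation")
  bs <- attr(profile, "bin_size") %||%
    (profile$end[1] - profile$start[1])
  span <- attr(profile, "delta_span_bins") %||% max(1, 125000 %/% bs)
  per_chrom <- lapply(split(profile, profile$chrom), function(p) {
    p <- arrange(p, .data$bin)
    if (type == "di") {
      boundaries_from_di(p, min_di, max_gap, bs)
    } else {
      boundaries_from_insulation(p, min_swing, span, bs)
    }
  })
  bnd <- bind_rows(per_chrom)
  if (nrow(bnd) > 0) {
    bnd <- mutate(bnd, sample = sample_id, method = type, .before = 1) %>%
      arrange(.data$chrom, .data$pos)
  } else {
    bnd <- tibble(sample = character(0), method = character(0),
                  chrom = character(0), pos = numeric(0),
                  strength = numeric(0))
  }
  tads <- profile %>% group_by(.data$chrom) %>%
    summarise(len = max(.data$end), .groups = "drop") %>%
    purrr::pmap_dfr(function(chrom, len) {
      b <- sort(bnd$pos[bnd$chrom == chrom])
      edges <- c(0, b, len)
      tibble(chrom = chrom, start = edges[-length(edges)], end = edges[-1])
    }) %>% filter(.data$start < .data$end)
  list(boundaries = select(bnd, "sample", "chrom", "pos", "strength",
                           "method"),
       tads = tads)
}

boundaries_from_di <- function(p, min_di, max_gap, bs) {
  z <- p$di_z
  state <- ifelse(is.na(z), 0, ifelse(z <= -min_di, -1L,
                                      ifelse(z >= min_di, 1L, 0L)))
  idx <- which(state != 0)
  if (length(idx) < 2) return(NULL)
  res <- list()
  k <- 1
  while (k < length(idx)) {
    i <- idx[k]; j <- idx[k + 1]
    if (state[i] == -1 && state[j] == 1 && (j - i) <= max_gap) {
      edge_bin <- floor((i + 1 + j) / 2)
      res[[length(res) + 1]] <- tibble(
        chrom = p$chrom[1],
        pos = p$start[p$bin == edge_bin],
        strength = z[j] - z[i])
      k <- k + 2
    } else {
      k <- k + 1
    }
  }
  bind_rows(res)
}

boundaries_from_insulation <- function(p, min_swing, span, bs) {
  d <- p$delta
  n <- length(d)
  res <- list()
  for (i in 2:max(2, n)) {
    if (i > n) break
    if (is.na(d[i - 1]) || is.na(d[i])) next
    if (d[i - 1] < 0 && d[i] >= 0) {
      after <- d[seq(i, min(n, i + span - 1))]
      before <- d[seq(max(1, i - span), i - 1)]
      swing <- suppressWarnings(max(after, na.rm = TRUE) -
                                  min(before, na.rm = TRUE))
      if (is.finite(swing) && swing >= min_swing) {
        res[[length(res) + 1]] <- tibble(chrom = p$chrom[1],
                                         pos = p$start[i],
                                         strength = swing)
      }
    }
  }
  bind_rows(res)
}

#' Median profile around boundaries
#'
#' Aligns the signal (standardized DI or normalized insulation) in a
#' `+/- flank` window around every boundary and returns the per-offset
#' median; missing values are ignored per offset.
#'
#' @param profile A DI or insulation profile tibble.
#' @param boundaries Tibble with `chrom` and `pos` (bin-edge positions).
#' @param flank Flank size in bp (default 500 kb), multiple of the bin size.
#' @return Tibble `offset` (bp relative to the boundary edge), `value`
#'   (median signal), `n` (boundaries contributing).
#' @export
boundary_profile <- function(profile, boundaries, flank = 500000) {
  assert_that(nrow(boundaries) > 0, "empty boundary set")
  bs <- attr(profile, "bin_size") %||% (profile$end[1] - profile$start[1])
  assert_that(flank %% bs == 0, "flank must be a multiple of bin_size")
  fb <- flank / bs
  value_col <- if ("di_z" %in% names(profile)) "di_z" else "norm"
  offsets <- seq(-fb, fb)
  rows <- lapply(seq_len(nrow(boundaries)), function(r) {
    p <- profile[profile$chrom == boundaries$chrom[r], ]
    p <- p[order(p$bin), ]
    b0 <- boundaries$pos[r] / bs + 1  # bin starting at the boundary edge
    idx <- b0 + offsets
    v <- rep(NA_real_, length(offsets))
    ok <- idx >= 1 & idx <= nrow(p)
    v[ok] <- p[[value_col]][idx[ok]]
    v
  })
  vmat <- do.call(rbind, rows)
  tibble(offset = offsets * bs,
         value = apply(vmat, 2, median, na.rm = TRUE),
         n = colSums(!is.na(vmat)))
}

#' Amplitude of a boundary profile
#'
#' Max minus min of the median curve; the readout that shrinks when
#' boundaries weaken.
#'
#' @param curve Output of [boundary_profile()].
#' @return Numeric scalar.
#' @export
profile_amplitude <- function(curve) {
  max(curve$value, na.rm = TRUE) - min(curve$value, na.rm = TRUE)
}

#' A/B compartment profile
#'
#' Distance-normalized (observed/expected) balanced contacts are correlated
#' bin-by-bin; the leading eigenvector of the correlation matrix is oriented
#' so that positive values correlate with `orientation_track` (typically
#' gene density), and positive bins are labeled `A`, negative `B`.
#'
#' @param cm A balanced [contact_matrix()] (typically at 500 kb).
#' @param orientation_track Numeric per-bin track used to fix the sign.
#' @return Tibble `chrom bin start end eigen compartment` (`NA` on masked
#'   bins).
#' @export
compartments <- function(cm, orientation_track) {
  assert_that(inherits(cm, "contact_matrix"), "need a contact_matrix")
  m <- working_counts(cm)
  keep <- which(!cm$mask)
  assert_that(length(keep) >= 3, "too few unmasked bins")
  sub <- m[keep, keep, drop = FALSE]
  n <- nrow(sub)
  # observed / expected by distance
  expd <- numeric(n)
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    expd[d + 1] <- mean(sub[cbind(i, i + d)])
  }
  dist <- abs(outer(seq_len(n), seq_len(n), `-`))
  e <- expd[dist + 1]
  oe <- sub / e
  oe[!is.finite(oe)] <- 0
  if (all(oe == 0)) stop("degenerate contact matrix", call. = FALSE)
  cc <- suppressWarnings(cor(oe))
  cc[!is.finite(cc)] <- 0
  ev <- eigen(cc, symmetric = TRUE)
  v <- ev$vectors[, 1]
  tr <- orientation_track[keep]
  s <- suppressWarnings(cor(v, tr))
  if (is.finite(s) && s < 0) v <- -v
  out <- bin_table(cm)
  out$eigen <- NA_real_
  out$eigen[keep] <- v
  out$compartment <- ifelse(is.na(out$eigen), NA_character_,
                            ifelse(out$eigen >= 0, "A", "B"))
  select(out, "chrom", "bin", "start", "end", "eigen", "compartment")
}

#' Agreement between two compartment profiles
#'
#' @param a,b Compartment profiles from [compartments()] on the same
#'   binning.
#' @return Fraction of jointly labeled bins with equal A/B label.
#' @export
compartment_agreement <- function(a, b) {
  assert_that(nrow(a) == nrow(b), "profiles must share the binning")
  ok <- !is.na(a$compartment) & !is.na(b$compartment)
  assert_that(any(ok), "no jointly labeled bins")
  mean(a$compartment[ok] == b$compartment[ok])
}

#' Aggregate a contact matrix to a coarser resolution
#'
#' Sums counts into `factor`-times larger bins (e.g. 25 kb to 500 kb with
#' `factor = 20`). A coarse bin is masked only if all constituent fine bins
#' are masked.
#'
#' @param cm A [contact_matrix()].
#' @param factor Integer aggregation factor.
#' @return A [contact_matrix()] at the coarser resolution.
#' @export
coarsen <- function(cm, factor) {
  n <- n_bins(cm)
  assert_that(n %% factor == 0, "bin count not divisible by factor")
  g <- rep(seq_len(n %/% factor), each = factor)
  agg <- rowsum(t(rowsum(cm$counts, g)), g)
  mask <- tapply(cm$mask, g, all)
  contact_matrix(cm$chrom, agg, cm$bin_size * factor,
                 mask = as.logical(mask))
}
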