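#' Assign genes to TAD domains
#'
#' Each gene is assigned, per reference TAD set, to the innermost (smallest)
#' domain containing its TSS; genes outside every domain stay unassigned.
#' Two genes are consensus-same-domain only when they share a domain in
#' both sets.
#'
#' @param genes Annotation tibble `gene chrom tss`.
#' @param tads_a First TAD set (tibble `chrom start end`; may nest).
#' @param tads_b Optional second TAD set; defaults to `tads_a`, in which
#'   case consensus equals single-set assignment.
#' @return Tibble `gene chrom tss domain_a domain_b` (domain ids are
#'   `chrom:start-end` strings, `NA` when unassigned).
#' @export
assign_genes <- function(genes, tads_a, tads_b = NULL) {
  tads_b <- tads_b %||% tads_a
  inner <- function(tads) {
    tads <- as_tibble(tads)
    ids <- rep(NA_character_, nrow(genes))
    size <- rep(Inf, nrow(genes))
    for (k in seq_len(nrow(tads))) {
      hit <- genes$chrom == tads$chrom[k] & genes$tss >= tads$start[k] &
        genes$tss < tads$end[k]
      sz <- tads$end[k] - tads$start[k]
      take <- hit & sz < size
      ids[take] <- sprintf("%s:%d-%d", tads$chrom[k], tads$start[k],
                           tads$end[k])
      size[take] <- sz
    }
    ids
  }
  tibble(gene = genes$gene, chrom = genes$chrom, tss = genes$tss,
         domain_a = inner(tads_a), domain_b = inner(tads_b))
}

#' Randomly placed fixed-size domains
#'
#' @param genome A [genome_spec()].
#' @param n Number of domains (default 10000).
#' @param size Domain size in bp (default 1 Mb).
#' @param seed Integer seed.
#' @return Tibble `chrom start end` with `end - start == size` everywhere.
#' @export
random_domains <- function(genome, n = 10000, size = 1e6, seed = 1) {
  gs <- filter(genome$chromosomes, .data$length > size)
  assert_that(nrow(gs) > 0, "no chromosome longer than the domain size")
  with_seed(substream_seed(seed, "random_domains"), {
    idx <- sample(nrow(gs), n, replace = TRUE, prob = gs$length - size)
    start <- floor(runif(n, 0, gs$length[idx] - size))
    tibble(chrom = gs$chrom[idx], start = start, end = start + size)
  })
}

#' Gene-pair expression correlations by TAD membership
#'
#' For every same-chromosome gene pair within `max_distance` of TSS
#' distance, computes the Spearman correlation of expression across samples
#' and classifies the pair as `same_tad` (consensus same domain in both
#' reference sets), `different_tad` (assigned in both sets but not
#' consensus-same) — pairs involving an unassigned gene are skipped.
#' Additionally, pairs co-located in any random domain are emitted as
#' `random_domain` records.
#'
#' @param expr An [expr_matrix()] or matrix (log scale).
#' @param map Assignment from [assign_genes()].
#' @param rand Optional random domain set from [random_domains()].
#' @param max_distance Maximum TSS distance in bp (default 2 Mb).
#' @return Tibble `gene1 gene2 class distance rho`; pairs with a constant
#'   expression vector are dropped (counted in attribute
#'   `n_constant_skipped`).
#' @export
pair_correlations <- function(expr, map, rand = NULL, max_distance = 2e6) {
  x <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  assert_that(ncol(x) >= 6, "need at least 6 samples")
  map <- filter(map, .data$gene %in% rownames(x))
  z <- standardize_rows(row_ranks(x[map$gene, , drop = FALSE]))
  nsamp <- ncol(x)
  pairs_of <- function(m) {
    # same-chromosome index pairs within max_distance (two-pointer scan)
    res <- list()
    for (ch in unique(m$chrom)) {
      gi <- which(m$chrom == ch)
      gi <- gi[order(m$tss[gi])]
      ts <- m$tss[gi]
      for (a in seq_along(gi)) {
        b <- a + 1
        while (b <= length(gi) && ts[b] - ts[a] <= max_distance) b <- b + 1
        if (b - 1 > a) {
          res[[length(res) + 1]] <- tibble(i = gi[a], j = gi[(a + 1):(b - 1)])
        }
      }
    }
    bind_rows(res)
  }
  pr <- pairs_of(map)
  if (nrow(pr) == 0) {
    out <- tibble(gene1 = character(0), gene2 = character(0),
                  class = character(0), distance = numeric(0),
                  rho = numeric(0))
    attr(out, "n_constant_skipped") <- 0L
    return(out)
  }
  rho <- unname(rowSums(z[pr$i, , drop = FALSE] * z[pr$j, , drop = FALSE]))
  da_i <- map$domain_a[pr$i]; da_j <- map$domain_a[pr$j]
  db_i <- map$domain_b[pr$i]; db_j <- map$domain_b[pr$j]
  assigned <- !is.na(da_i) & !is.na(da_j) & !is.na(db_i) & !is.na(db_j)
  same <- assigned & da_i == da_j & db_i == db_j
  cls <- ifelse(same, "same_tad", ifelse(assigned, "different_tad", NA))
  base <- tibble(gene1 = map$gene[pr$i], gene2 = map$gene[pr$j],
                 class = cls,
                 distance = abs(map$tss[pr$i] - map$tss[pr$j]),
                 rho = rho) %>%
    filter(!is.na(.data$class))
  out <- base
  if (!is.null(rand) && nrow(rand) > 0) {
    # pair co-located in ANY random domain: a domain [s, s + size) covers
    # both TSS iff s in (t_hi - size, t_lo]; count via findInterval on the
    # sorted starts of that chromosome
    size <- unique(rand$end - rand$start)
    in_rand <- rep(FALSE, nrow(pr))
    t_lo <- pmin(map$tss[pr$i], map$tss[pr$j])
    t_hi <- pmax(map$tss[pr$i], map$tss[pr$j])
    pchrom <- map$chrom[pr$i]
    for (ch in unique(pchrom)) {
      s <- sort(rand$start[rand$chrom == ch])
      if (!length(s)) next
      sel <- which(pchrom == ch)
      hi <- findInterval(t_lo[sel], s)
      lo <- findInterval(t_hi[sel] - max(size), s)
      in_rand[sel] <- hi > lo
    }
    rnd <- tibble(gene1 = map$gene[pr$i], gene2 = map$gene[pr$j],
                  class = "random_domain",
                  distance = abs(map$tss[pr$i] - map$tss[pr$j]),
                  rho = rho)[in_rand, ]
    out <- bind_rows(out, rnd)
  }
  n_const <- sum(!is.finite(out$rho))
  out <- filter(out, is.finite(.data$rho))
  attr(out, "n_constant_skipped") <- n_const
  out
}

#' Class separation of TAD pair correlations
#'
#' Mean same-TAD minus mean different-TAD coefficient — positive when
#' intra-TAD co-expression exceeds the background, approximately zero when
#' TAD coupling is absent.
#'
#' @param records Output of [pair_correlations()].
#' @return Named list with `gap`, `mean_same`, `mean_different`, `n_same`,
#'   `n_different`.
#' @export
tad_class_gap <- function(records) {
  s <- records$rho[records$class == "same_tad"]
  d <- records$rho[records$class == "different_tad"]
  list(gap = mean(s) - mean(d), mean_same = mean(s),
       mean_different = mean(d), n_same = length(s), n_different = length(d))
}

#' LOESS-smoothed correlation-versus-distance curves
#'
#' Locally weighted linear least-squares fit of the pair coefficient on TSS
#' distance, per class, evaluated on a common distance grid.
#'
#' @param records Output of [pair_correlations()].
#' @param bandwidth LOESS span as a fraction of the distance range
#'   (default 0.3).
#' @param n_grid Grid points (default 50).
#' @param min_records Minimum records per class (default 20).
#' @return Tibble `class distance rho_smooth`.
#' @export
smooth_curves <- function(records, bandwidth = 0.3, n_grid = 50,
                          min_records = 20) {
  classes <- unique(records$class)
  counts <- table(records$class)
  small <- names(counts)[counts < min_records]
  assert_that(length(small) == 0,
              sprintf("class %s has fewer than %d records",
                      paste(small, collapse = ", "), min_records))
  grid <- seq(min(records$distance), max(records$distance),
              length.out = n_grid)
  bind_rows(lapply(classes, function(cl) {
    r <- records[records$class == cl, ]
    fit <- loess(rho ~ distance, data = r, span = bandwidth, degree = 1,
                 family = "gaussian")
    tibble(class = cl, distance = grid,
           rho_smooth = predict(fit, newdata = tibble(distance = grid)))
  }))
}
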