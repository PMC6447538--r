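#' Contact matrix container
#'
#' A binned, symmetric per-chromosome Hi-C contact matrix. Coordinates are
#' 0-based half-open; bin `i` (1-based index in R) covers
#' `[(i-1) * bin_size, i * bin_size)`.
#'
#' @param chrom Chromosome name.
#' @param counts Symmetric non-negative numeric matrix of raw contact counts.
#' @param bin_size Bin width in bp.
#' @param mask Logical vector, `TRUE` marks excluded bins.
#' @param mask_reason Character vector of reason codes parallel to `mask`
#'   (`"low_coverage"`, `"short_range"`, `"user"` or `NA`).
#'
#' @return An object of class `contact_matrix` with fields `chrom`,
#'   `bin_size`, `counts`, `mask`, `mask_reason`, `weights` (per-bin ICE
#'   factors, `NA` on masked bins), `balanced` (normalized matrix after
#'   [balance()]) and `converged`.
#' @export
contact_matrix <- function(chrom, counts, bin_size, mask = NULL,
                           mask_reason = NULL) {
  counts <- as.matrix(counts)
  assert_that(nrow(counts) == ncol(counts), "counts must be square")
  assert_that(all(counts >= 0), "counts must be non-negative")
  assert_that(isTRUE(all.equal(counts, t(counts), tolerance = 1e-8,
                               check.attributes = FALSE)),
              "counts must be symmetric")
  n <- nrow(counts)
  mask <- mask %||% rep(FALSE, n)
  mask_reason <- mask_reason %||% rep(NA_character_, n)
  structure(
    list(chrom = as.character(chrom), bin_size = as.integer(bin_size),
         counts = counts, mask = mask, mask_reason = mask_reason,
         weights = NULL, balanced = NULL, converged = NA),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins of %s bp, %d masked, %s\n",
              x$chrom, nrow(x$counts), format(x$bin_size, big.mark = ","),
              sum(x$mask),
              if (is.null(x$balanced)) "raw" else "balanced"))
  invisible(x)
}

#' Number of bins of a contact matrix
#' @param cm A `contact_matrix`.
#' @return Integer bin count.
#' @export
n_bins <- function(cm) nrow(cm$counts)

#' Bin table of a contact matrix
#' @param cm A `contact_matrix`.
#' @return Tibble with `chrom`, `bin` (1-based), `start`, `end` (0-based
#'   half-open bp) and `masked`.
#' @export
bin_table <- function(cm) {
  n <- n_bins(cm)
  tibble(chrom = cm$chrom, bin = seq_len(n),
         start = (seq_len(n) - 1) * as.numeric(cm$bin_size),
         end = seq_len(n) * as.numeric(cm$bin_size),
         masked = cm$mask)
}

#' Working (balanced if available) counts of a contact matrix
#' @param cm A `contact_matrix`.
#' @return Numeric matrix: balanced counts when [balance()] has been run,
#'   raw counts otherwise. Masked rows/columns are zero.
#' @export
working_counts <- function(cm) {
  m <- cm$balanced %||% cm$counts
  if (any(cm$mask)) {
    m[cm$mask, ] <- 0
    m[, cm$mask] <- 0
  }
  m
}

#' Genome-wide collection of per-chromosome contact matrices
#'
#' @param cms Named list of [contact_matrix()] objects sharing one bin size.
#' @return An object of class `hic_map` (a named list of contact matrices).
#' @export
hic_map <- function(cms) {
  assert_that(length(cms) > 0, "empty hic_map")
  bs <- unique(vapply(cms, function(x) x$bin_size, integer(1)))
  assert_that(length(bs) == 1L, "mixed bin sizes in hic_map")
  names(cms) <- vapply(cms, function(x) x$chrom, character(1))
  structure(cms, class = "hic_map")
}

#' @export
print.hic_map <- function(x, ...) {
  cat(sprintf("<hic_map> %d chromosomes (%s), bin size %d bp\n",
              length(x), paste(names(x), collapse = ", "), x[[1]]$bin_size))
  invisible(x)
}

#' @export
tidy.contact_matrix <- function(x, ...) {
  m <- working_counts(x)
  n <- nrow(m)
  idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  tibble(chrom = x$chrom, bin1 = idx[, 1], bin2 = idx[, 2],
         count = m[idx])
}

#' Load a contact matrix from a COO pixel file and a bin table
#'
#' Pixels are `bin1_id`, `bin2_id`, `count` (0-based ids, upper triangle
#' accepted); the bin table is BED3 + bin id. Duplicate pixels are summed and
#' the matrix is mirrored to full symmetry. Inter-chromosomal pixels are
#' dropped with a warning (the pipeline is cis-only).
#'
#' @param pixels_path Path to the TSV pixel file.
#' @param bins_path Path to the BED-like bin table
#'   (`chrom start end bin_id`, no header).
#' @return A [hic_map()] (single-chromosome inputs give a length-1 map).
#' @export
load_contacts <- function(pixels_path, bins_path) {
  bins <- readr::read_tsv(bins_path,
                          col_names = c("chrom", "start", "end", "bin_id"),
                          col_types = "ciii", progress = FALSE)
  assert_that(nrow(bins) > 0, "empty bin table")
  bin_size <- unique(bins$end - bins$start)
  assert_that(length(bin_size) == 1L, "bins must have uniform size")
  px <- readr::read_tsv(pixels_path,
                        col_names = c("bin1_id", "bin2_id", "count"),
                        col_types = readr::cols(
                          bin1_id = readr::col_integer(),
                          bin2_id = readr::col_integer(),
                          count = readr::col_character()),
                        progress = FALSE)
  if (nrow(px) > 0) {
    cnt <- suppressWarnings(as.numeric(px$count))
    bad <- which(!is.finite(cnt))
    if (length(bad)) {
      stop(sprintf("non-numeric count at pixel line %d", bad[1]), call. = FALSE)
    }
    px$count <- cnt
    oob <- which(!(px$bin1_id %in% bins$bin_id) | !(px$bin2_id %in% bins$bin_id))
    if (length(oob)) {
      stop(sprintf("bin id out of range at pixel line %d", oob[1]), call. = FALSE)
    }
  } else {
    px$count <- numeric(0)
  }
  chrom_of <- setNames(bins$chrom, as.character(bins$bin_id))
  cms <- lapply(split(bins, bins$chrom), function(b) {
    b <- b[order(b$start), ]
    n <- nrow(b)
    m <- matrix(0, n, n)
    local_id <- setNames(seq_len(n), as.character(b$bin_id))
    sel <- px[chrom_of[as.character(px$bin1_id)] == b$chrom[1] &
                chrom_of[as.character(px$bin2_id)] == b$chrom[1], ]
    if (nrow(sel)) {
      i <- local_id[as.character(sel$bin1_id)]
      j <- local_id[as.character(sel$bin2_id)]
      lo <- pmin(i, j); hi <- pmax(i, j)
      for (k in seq_along(lo)) m[lo[k], hi[k]] <- m[lo[k], hi[k]] + sel$count[k]
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
    }
    contact_matrix(b$chrom[1], m, bin_size)
  })
  n_trans <- if (nrow(px)) {
    sum(chrom_of[as.character(px$bin1_id)] != chrom_of[as.character(px$bin2_id)])
  } else 0L
  if (n_trans > 0) {
    warning(sprintf("dropped %d inter-chromosomal pixels", n_trans))
  }
  hic_map(cms)
}

#' Mask low-coverage bins (MAD-max filter)
#'
#' Marginal totals are computed on bins with non-zero coverage; a bin is
#' masked when `(median(log m) - log m) / MAD(log m) > madmax`, i.e. the
#' filter is one-sided and removes only low-coverage outliers. Masked
#' rows/columns are zeroed. Already-masked bins stay masked, which makes the
#' operation idempotent. Zero-coverage bins are always masked.
#'
#' @param cm A [contact_matrix()] or [hic_map()].
#' @param madmax Positive threshold in MAD units (default 2).
#' @return Object of the input class with updated `mask`/`mask_reason` and
#'   zeroed masked rows. The mask with reason codes is available via
#'   [bin_mask()].
#' @export
filter_bins <- function(cm, madmax = 2) {
  UseMethod("filter_bins")
}

#' @export
filter_bins.contact_matrix <- function(cm, madmax = 2) {
  assert_that(madmax > 0, "madmax must be positive")
  marg <- rowSums(cm$counts)
  marg[cm$mask] <- 0
  nz <- which(marg > 0)
  if (!length(nz)) {
    warning("all bins have zero coverage; matrix fully masked")
    cm$mask <- rep(TRUE, n_bins(cm))
    cm$mask_reason[is.na(cm$mask_reason)] <- "low_coverage"
    cm$counts[] <- 0
    return(cm)
  }
  lg <- log(marg[nz])
  dev <- (median(lg) - lg) / mad(lg, constant = 1)
  # NaN (zero spread) never masks; +Inf (zero MAD, bin far below median) does
  new_mask <- rep(FALSE, n_bins(cm))
  new_mask[nz[!is.nan(dev) & dev > madmax]] <- TRUE
  new_mask[marg == 0] <- TRUE
  add <- new_mask & !cm$mask
  cm$mask_reason[add] <- "low_coverage"
  cm$mask <- cm$mask | new_mask
  cm$counts[cm$mask, ] <- 0
  cm$counts[, cm$mask] <- 0
  cm
}

#' @export
filter_bins.hic_map <- function(cm, madmax = 2) {
  hic_map(lapply(cm, filter_bins, madmax = madmax))
}

#' Bin mask as a tibble
#' @param cm A `contact_matrix` or `hic_map`.
#' @return Tibble with `chrom`, `bin`, `start`, `masked`, `reason`.
#' @export
bin_mask <- function(cm) {
  if (inherits(cm, "hic_map")) {
    return(bind_rows(lapply(cm, bin_mask)))
  }
  bt <- bin_table(cm)
  bt$reason <- cm$mask_reason
  bt[, c("chrom", "bin", "start", "masked", "reason")]
}

#' Remove short-range contacts
#'
#' Zeroes the main diagonal and the +/-1 off-diagonals (reads mapping to the
#' same or adjacent bins), which are dominated by ligation artifacts.
#'
#' @param cm A [contact_matrix()] or [hic_map()].
#' @return Same class with the near-diagonal entries set to zero.
#' @export
remove_short_range <- function(cm) {
  UseMethod("remove_short_range")
}

#' @export
remove_short_range.contact_matrix <- function(cm) {
  n <- n_bins(cm)
  idx <- seq_len(n)
  cm$counts[cbind(idx, idx)] <- 0
  if (n > 1) {
    cm$counts[cbind(idx[-n], idx[-1])] <- 0
    cm$counts[cbind(idx[-1], idx[-n])] <- 0
  }
  cm
}

#' @export
remove_short_range.hic_map <- function(cm) {
  hic_map(lapply(cm, remove_short_range))
}

# One chromosome of ICE (iterative proportional fitting). Returns weights
# (NA on masked bins), the balanced matrix and a convergence flag.
ice_one <- function(counts, mask, max_iter, tol) {
  n <- nrow(counts)
  keep <- which(!mask)
  w <- rep(NA_real_, n)
  if (!length(keep)) {
    return(list(weights = w, balanced = matrix(0, n, n), converged = TRUE))
  }
  m <- counts[keep, keep, drop = FALSE]
  b <- rep(1, length(keep))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cur <- m * tcrossprod(b)
    s <- rowSums(cur)
    pos <- s > 0
    if (!any(pos)) break
    s_rel <- s / mean(s[pos])
    s_rel[!pos] <- 1
    b <- b / sqrt(s_rel)
    v <- s[pos] / mean(s[pos])
    if (max(abs(v - 1)) < tol) {
      converged <- TRUE
      break
    }
  }
  bal_sub <- m * tcrossprod(b)
  # scale so the mean unmasked marginal is 1 (cooler convention)
  ms <- mean(rowSums(bal_sub))
  if (ms > 0) {
    b <- b / sqrt(ms)
    bal_sub <- bal_sub / ms
  }
  bal <- matrix(0, n, n)
  bal[keep, keep] <- bal_sub
  w[keep] <- b
  list(weights = w, balanced = bal, converged = converged)
}

#' Balance a contact matrix (ICE / chromosome-adjusted ICE)
#'
#' `"ice"` runs iterative proportional fitting until the unmasked marginals
#' are equal within `tol`. `"caicb"` additionally removes whole-chromosome
#' multiplicative (copy-number) bias: after ICE, each chromosome's balanced
#' contacts are rescaled per genomic-distance band so that the band's mean
#' matches the cross-chromosome mean for that band. `"caicb"` therefore needs
#' a multi-chromosome [hic_map()].
#'
#' @param cm A [contact_matrix()] (`"ice"` only) or [hic_map()].
#' @param method `"ice"` or `"caicb"`.
#' @param max_iter Maximum ICE iterations (default 200).
#' @param tol Convergence tolerance on the relative marginal spread
#'   (default 1e-5).
#' @return Input object with `weights`, `balanced` and `converged` filled.
#'   For `"caicb"` the per-band scale factors are multiplied into
#'   `balanced`.
#' @export
balance <- function(cm, method = c("caicb", "ice"), max_iter = 200,
                    tol = 1e-5) {
  UseMethod("balance")
}

#' @export
balance.contact_matrix <- function(cm, method = c("caicb", "ice"),
                                   max_iter = 200, tol = 1e-5) {
  method <- match.arg(method)
  assert_that(method == "ice",
              "caicb needs a multi-chromosome hic_map; use method = 'ice'")
  res <- ice_one(cm$counts, cm$mask, max_iter, tol)
  cm$weights <- res$weights
  cm$balanced <- res$balanced
  cm$converged <- res$converged
  if (!res$converged) warning(sprintf("ICE did not converge on %s", cm$chrom))
  cm
}

#' @export
balance.hic_map <- function(cm, method = c("caicb", "ice"), max_iter = 200,
                            tol = 1e-5) {
  method <- match.arg(method)
  out <- lapply(cm, function(x) {
    res <- ice_one(x$counts, x$mask, max_iter, tol)
    x$weights <- res$weights
    x$balanced <- res$balanced
    x$converged <- res$converged
    x
  })
  if (any(!vapply(out, function(x) isTRUE(x$converged), logical(1)))) {
    warning("ICE did not converge on at least one chromosome")
  }
  if (method == "caicb") {
    n_max <- max(vapply(out, n_bins, integer(1)))
    # per-chromosome per-distance-band mean balanced contact over unmasked pairs
    band_stats <- lapply(out, function(x) {
      n <- n_bins(x)
      keep <- !x$mask
      sums <- numeric(n_max)
      cnts <- numeric(n_max)
      for (d in 0:(n - 1)) {
        i <- seq_len(n - d)
        j <- i + d
        ok <- keep[i] & keep[j]
        if (any(ok)) {
          sums[d + 1] <- sum(x$balanced[cbind(i[ok], j[ok])])
          cnts[d + 1] <- sum(ok)
        }
      }
      list(sums = sums, cnts = cnts)
    })
    tot_sums <- Reduce(`+`, lapply(band_stats, `[[`, "sums"))
    tot_cnts <- Reduce(`+`, lapply(band_stats, `[[`, "cnts"))
    global_mean <- ifelse(tot_cnts > 0, tot_sums / tot_cnts, NA_real_)
    out <- lapply(seq_along(out), function(k) {
      x <- out[[k]]
      st <- band_stats[[k]]
      n <- n_bins(x)
      chrom_mean <- ifelse(st$cnts > 0, st$sums / st$cnts, NA_real_)
      fac <- ifelse(is.finite(chrom_mean) & chrom_mean > 0 &
                      is.finite(global_mean[seq_len(n)]),
                    global_mean[seq_len(n)] / chrom_mean[seq_len(n)], 1)
      for (d in 0:(n - 1)) {
        i <- seq_len(n - d)
        j <- i + d
        x$balanced[cbind(i, j)] <- x$balanced[cbind(i, j)] * fac[d + 1]
        if (d > 0) x$balanced[cbind(j, i)] <- x$balanced[cbind(i, j)]
      }
      x
    })
  }
  hic_map(out)
}
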