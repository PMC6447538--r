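# Plain-text readers/writers for the pipeline's interchange formats.
# All genomic coordinates are 0-based half-open.

#' Write a contact matrix as COO pixels plus a bin table
#'
#' @param map A [hic_map()] or [contact_matrix()].
#' @param pixels_path,bins_path Output paths (TSV, no header). Pixels store
#'   the upper triangle only.
#' @return Invisibly, the two paths.
#' @export
write_contacts <- function(map, pixels_path, bins_path) {
  cms <- if (inherits(map, "hic_map")) map else hic_map(list(map))
  offset <- 0L
  bins <- list(); px <- list()
  for (x in cms) {
    bt <- bin_table(x)
    bins[[length(bins) + 1]] <- tibble(chrom = bt$chrom, start = bt$start,
                                       end = bt$end,
                                       bin_id = offset + bt$bin - 1L)
    idx <- which(upper.tri(x$counts, diag = TRUE) & x$counts > 0,
                 arr.ind = TRUE)
    px[[length(px) + 1]] <- tibble(bin1_id = offset + idx[, 1] - 1L,
                                   bin2_id = offset + idx[, 2] - 1L,
                                   count = x$counts[idx])
    offset <- offset + n_bins(x)
  }
  readr::write_tsv(bind_rows(bins), bins_path, col_names = FALSE)
  readr::write_tsv(bind_rows(px), pixels_path, col_names = FALSE)
  invisible(c(pixels_path, bins_path))
}

#' Write intervals as BED
#'
#' @param x Tibble with `chrom`, `start`, `end` and optional extra columns
#'   appended as BED name/score fields.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  readr::write_tsv(x[, cols], path, col_names = FALSE)
  invisible(path)
}

#' Read a BED3(+) file
#'
#' @param path Input path.
#' @param extra Names for columns beyond the first three.
#' @return Tibble with `chrom start end` (+ extras), sorted.
#' @export
read_bed <- function(path, extra = character(0)) {
  x <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                       show_col_types = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  if (length(extra)) {
    names(x)[3 + seq_along(extra)] <- extra
  }
  arrange(x, .data$chrom, .data$start)
}

#' Write boundaries as 1-bp BED features
#'
#' @param boundaries Tibble `chrom pos` (+ optional `strength`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_boundaries <- function(boundaries, path) {
  out <- tibble(chrom = boundaries$chrom, start = boundaries$pos,
                end = boundaries$pos + 1)
  if ("strength" %in% names(boundaries)) out$score <- boundaries$strength
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Write a per-bin profile as bedGraph
#'
#' @param profile Tibble with `chrom start end` and a value column.
#' @param path Output path.
#' @param value Name of the value column (default the standardized DI or
#'   normalized insulation, whichever exists).
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(profile, path, value = NULL) {
  value <- value %||% intersect(c("di_z", "norm"), names(profile))[1]
  out <- profile[, c("chrom", "start", "end", value)]
  out <- out[is.finite(out[[value]]), ]
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Write / read copy-number segments (SEG-like TSV)
#'
#' Columns `sample chrom start end copy`, with header.
#'
#' @param segments Segment tibble.
#' @param path File path.
#' @return `write_segments` invisibly returns `path`; `read_segments` the
#'   tibble.
#' @export
write_segments <- function(segments, path) {
  readr::write_tsv(segments[, c("sample", "chrom", "start", "end", "copy")],
                   path)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  readr::read_tsv(path, col_types = "ccddd", progress = FALSE)
}

#' Write / read gene annotation (TSV)
#'
#' Columns `gene chrom start end strand tss`, with header. The annotation
#' must pre-specify one (canonical) TSS per gene.
#'
#' @param genes Annotation tibble.
#' @param path File path.
#' @return `write_genes` invisibly returns `path`; `read_genes` the tibble.
#' @export
write_genes <- function(genes, path) {
  readr::write_tsv(genes[, c("gene", "chrom", "start", "end", "strand",
                             "tss")], path)
  invisible(path)
}

#' @rdname write_genes
#' @export
read_genes <- function(path) {
  readr::read_tsv(path, col_types = "ccddcd", progress = FALSE)
}

#' Write / read an expression matrix (TSV with two-line header)
#'
#' Line 1 `#layer=<rna|protein>`, line 2 `#group=<comma-separated groups>`,
#' then a header row (`gene` + sample names) and the values.
#'
#' @param expr An [expr_matrix()].
#' @param path File path.
#' @return `write_expression` invisibly returns `path`; `read_expression`
#'   an [expr_matrix()].
#' @export
write_expression <- function(expr, path) {
  df <- as_tibble(expr$values, rownames = "gene")
  writeLines(c(sprintf("#layer=%s", expr$layer),
               sprintf("#group=%s",
                       paste(expr$samples$group, collapse = ","))),
             path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  hdr <- readLines(path, n = 2)
  layer <- sub("^#layer=", "", hdr[1])
  groups <- strsplit(sub("^#group=", "", hdr[2]), ",")[[1]]
  df <- readr::read_tsv(path, skip = 2, progress = FALSE,
                        show_col_types = FALSE)
  values <- as.matrix(df[, -1])
  rownames(values) <- df$gene
  expr_matrix(values, layer,
              tibble(sample = colnames(values), group = groups))
}

#' Read / write narrowPeak intervals
#'
#' Only the first three columns are interpreted; remaining narrowPeak
#' fields are preserved on read.
#'
#' @param peaks Peak tibble `chrom start end`.
#' @param path File path.
#' @return `read_narrowpeak` returns a sorted tibble.
#' @export
read_narrowpeak <- function(path) {
  read_bed(path)
}

#' @rdname read_narrowpeak
#' @export
write_narrowpeak <- function(peaks, path) {
  out <- tibble(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
                name = ".", score = 0, strand = ".", signal = 0,
                p = -1, q = -1, peak = -1)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Write / read paired interactions (BEDPE + PET count)
#'
#' @param interactions Tibble `chrom1 start1 end1 chrom2 start2 end2 pet`.
#' @param path File path.
#' @return `read_bedpe` returns the tibble; malformed rows are rejected
#'   with their line number.
#' @export
write_bedpe <- function(interactions, path) {
  readr::write_tsv(interactions[, c("chrom1", "start1", "end1", "chrom2",
                                    "start2", "end2", "pet")],
                   path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bedpe
#' @export
read_bedpe <- function(path) {
  x <- readr::read_tsv(path,
                       col_names = c("chrom1", "start1", "end1", "chrom2",
                                     "start2", "end2", "pet"),
                       col_types = "cddcddd", progress = FALSE)
  bad <- which(!is.finite(x$pet) | x$pet <= 0 | x$start1 >= x$end1 |
                 x$start2 >= x$end2)
  if (length(bad)) {
    stop(sprintf("malformed paired record at line %d", bad[1]),
         call. = FALSE)
  }
  x
}

#' Write / read a chromosome morphology score table (TSV)
#'
#' Columns `case_id group metaphase score`, with header.
#'
#' @param cms CMS tibble.
#' @param path File path.
#' @return `write_cms` invisibly returns `path`; `read_cms` the tibble.
#' @export
write_cms <- function(cms, path) {
  readr::write_tsv(cms[, c("case_id", "group", "metaphase", "score")], path)
  invisible(path)
}

#' @rdname write_cms
#' @export
read_cms <- function(path) {
  readr::read_tsv(path, col_types = "ccdd", progress = FALSE)
}
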