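#' Genome specification for simulations
#'
#' @param chroms Character vector of chromosome names.
#' @param lengths Integer vector of chromosome lengths in bp.
#' @param ploidy Normal ploidy per chromosome (2 for autosomes; 1 or 2 for
#'   sex chromosomes, `NA` when undefined, e.g. Y in females).
#' @param bin_size Analysis bin size in bp (default 25 kb). Chromosome
#'   lengths must be multiples of it.
#' @return A `genome_spec`: list with `chromosomes` (tibble `chrom`,
#'   `length`, `ploidy`) and `bin_size`.
#' @export
genome_spec <- function(chroms, lengths, ploidy = 2, bin_size = 25000) {
  assert_that(all(lengths > 0), "chromosome lengths must be positive")
  assert_that(all(lengths %% bin_size == 0),
              "chromosome lengths must be multiples of bin_size")
  ploidy <- rep_len(ploidy, length(chroms))
  structure(
    list(chromosomes = tibble(chrom = as.character(chroms),
                              length = as.numeric(lengths),
                              ploidy = as.numeric(ploidy)),
         bin_size = as.integer(bin_size)),
    class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> %d chromosomes, %.1f Mb total, %d bp bins\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
              x$bin_size))
  invisible(x)
}

#' Planted TAD truth
#'
#' Domains tile each chromosome without overlap; each internal boundary
#' carries an insulation strength in \[0, 1\] (1 = fully insulating,
#' 0 = invisible).
#'
#' @param domains Tibble `chrom`, `start`, `end` tiling each chromosome.
#' @param strengths Numeric vector in \[0, 1\], one per internal boundary
#'   (domains within a chromosome, in order, share `nrow - 1` boundaries).
#' @return A `tad_truth`: list with `domains` and `boundaries`
#'   (tibble `chrom`, `pos`, `strength`).
#' @export
tad_truth <- function(domains, strengths) {
  domains <- arrange(as_tibble(domains), .data$chrom, .data$start)
  bnd <- domains %>%
    group_by(.data$chrom) %>%
    dplyr::slice(-1) %>%
    ungroup() %>%
    dplyr::transmute(chrom = .data$chrom, pos = .data$start)
  assert_that(length(strengths) == nrow(bnd),
              sprintf("need %d boundary strengths, got %d",
                      nrow(bnd), length(strengths)))
  assert_that(all(strengths >= 0 & strengths <= 1),
              "strengths must lie in [0, 1]")
  by_chrom <- split(domains, domains$chrom)
  for (d in by_chrom) {
    assert_that(all(d$end[-nrow(d)] == d$start[-1]),
                sprintf("domains do not tile chromosome %s", d$chrom[1]))
  }
  bnd$strength <- strengths
  structure(list(domains = domains, boundaries = bnd), class = "tad_truth")
}

#' Simulate a planted TAD segmentation
#'
#' Domain edges are drawn on the bin grid with a minimum domain size; all
#' internal boundaries receive the given strength(s).
#'
#' @param genome A [genome_spec()].
#' @param n_boundaries Internal boundaries per chromosome (recycled).
#' @param strengths Boundary strengths in \[0, 1\]; recycled across all
#'   boundaries genome-wide.
#' @param min_domain_bins Minimum domain size in bins (default 8).
#' @param seed Integer seed.
#' @return A [tad_truth()].
#' @export
sim_tads <- function(genome, n_boundaries = 7, strengths = 1,
                     min_domain_bins = 8, seed = 1) {
  nb <- rep_len(n_boundaries, nrow(genome$chromosomes))
  with_seed(substream_seed(seed, "tads"), {
    dom <- purrr::pmap_dfr(
      list(genome$chromosomes$chrom, genome$chromosomes$length, nb),
      function(chrom, len, k) {
        n <- len / genome$bin_size
        # candidate edges keeping every domain >= min_domain_bins
        edges <- sort(sample_spaced_edges(n, k, min_domain_bins))
        starts <- c(0, edges * as.numeric(genome$bin_size))
        ends <- c(edges * as.numeric(genome$bin_size), len)
        tibble(chrom = chrom, start = starts, end = ends)
      })
    tad_truth(dom, rep_len(strengths, nrow(dom) - length(unique(dom$chrom))))
  })
}

# Draw k interior edge indices in (0, n) such that consecutive gaps are all
# >= min_gap bins. Deterministic fallback to even spacing if rejection
# sampling stalls.
sample_spaced_edges <- function(n, k, min_gap) {
  assert_that((k + 1) * min_gap <= n,
              "chromosome too short for requested boundaries")
  for (try in 1:200) {
    e <- sort(sample(seq(min_gap, n - min_gap), k))
    if (k <= 1 || all(diff(e) >= min_gap)) return(e)
  }
  round(seq_len(k) * n / (k + 1))
}

#' Simulate Hi-C contact matrices with planted TADs
#'
#' Expected contact between bins i and j is
#' `depth * (1 + |i - j|)^(-decay_exponent) * m(i, j)` where `m` is
#' `tad_enrichment` for intra-domain pairs and, for pairs separated by one
#' or more boundaries, `1 + (tad_enrichment - 1) * (1 - s_min)` with `s_min`
#' the minimum planted strength among the crossed boundaries. Realized
#' counts are Poisson draws, symmetric, reproducible under a fixed seed.
#'
#' @param genome A [genome_spec()].
#' @param tads A [tad_truth()] whose domain edges lie on the bin grid.
#' @param depth Expected count at distance 0 without enrichment (> 0).
#' @param decay_exponent Distance-decay exponent (> 0).
#' @param tad_enrichment Intra-domain contact enrichment (> 1).
#' @param seed Integer seed.
#' @return A list with `map` (a [hic_map()]) and `tads` (the truth, echoed).
#' @export
simulate_hic <- function(genome, tads, depth = 100, decay_exponent = 1,
                         tad_enrichment = 3, seed = 1) {
  assert_that(depth > 0, "depth must be positive")
  assert_that(decay_exponent > 0, "decay_exponent must be positive")
  assert_that(tad_enrichment > 1, "tad_enrichment must exceed 1")
  bs <- as.numeric(genome$bin_size)
  bad <- tads$domains %>% filter(.data$start %% bs != 0 | .data$end %% bs != 0)
  if (nrow(bad) > 0) {
    stop(sprintf("domain %s:%d-%d is not aligned to the %d bp bin grid",
                 bad$chrom[1], bad$start[1], bad$end[1], genome$bin_size),
         call. = FALSE)
  }
  with_seed(substream_seed(seed, "hic"), {
    cms <- lapply(seq_len(nrow(genome$chromosomes)), function(ci) {
      chrom <- genome$chromosomes$chrom[ci]
      n <- genome$chromosomes$length[ci] / bs
      mu <- hic_expected(genome, tads, chrom, depth, decay_exponent,
                         tad_enrichment)
      draw <- matrix(0, n, n)
      ut <- upper.tri(mu, diag = TRUE)
      draw[ut] <- rpois(sum(ut), mu[ut])
      draw[lower.tri(draw)] <- t(draw)[lower.tri(draw)]
      contact_matrix(chrom, draw, genome$bin_size)
    })
    list(map = hic_map(cms), tads = tads)
  })
}

#' Expected (noise-free) Hi-C matrix for one chromosome
#'
#' The closed-form Poisson mean used by [simulate_hic()]; exposed so tests
#' can compare Monte-Carlo averages against it.
#'
#' @inheritParams simulate_hic
#' @param chrom Chromosome name.
#' @return Numeric matrix of expected counts.
#' @export
hic_expected <- function(genome, tads, chrom, depth = 100,
                         decay_exponent = 1, tad_enrichment = 3) {
  bs <- as.numeric(genome$bin_size)
  len <- genome$chromosomes$length[genome$chromosomes$chrom == chrom]
  assert_that(length(len) == 1, sprintf("unknown chromosome %s", chrom))
  n <- len / bs
  dom <- filter(tads$domains, .data$chrom == !!chrom) %>% arrange(.data$start)
  bnd <- filter(tads$boundaries, .data$chrom == !!chrom) %>% arrange(.data$pos)
  # domain index of every bin (bins are half-open so bin start decides)
  bin_start <- (seq_len(n) - 1) * bs
  dom_id <- findInterval(bin_start, dom$start)
  k <- nrow(dom)
  # multiplier between domain a and domain b (min strength of crossed bounds)
  mult <- matrix(tad_enrichment, k, k)
  if (k > 1) {
    for (a in 1:(k - 1)) {
      smin <- Inf
      for (b in (a + 1):k) {
        smin <- min(smin, bnd$strength[b - 1])
        mult[a, b] <- mult[b, a] <- 1 + (tad_enrichment - 1) * (1 - smin)
      }
    }
  }
  dist <- abs(outer(seq_len(n), seq_len(n), `-`))
  depth * (1 + dist)^(-decay_exponent) * mult[cbind(dom_id[row(dist)],
                                                    dom_id[col(dist)])]
}

#' Simulate a two-subtype cohort with whole-chromosome gains
#'
#' Emulates a high-hyperdiploid-like ("HeH-like") vs control cohort: each
#' HeH-like sample gains each listed chromosome independently with the given
#' frequency (whole-chromosome integer copies only); controls stay at normal
#' ploidy. The cohort also carries the expression-model parameters consumed
#' by [simulate_expression()].
#'
#' @param genome A [genome_spec()].
#' @param n_heh,n_control Samples per subtype (defaults 20 / 20).
#' @param gain_freq Named numeric vector of per-chromosome gain frequencies
#'   among HeH-like samples; default spreads frequencies 1 .. 0.25 over the
#'   first six chromosomes (remaining chromosomes stay disomic), emulating
#'   the nonrandom gain pattern of high hyperdiploidy.
#' @param gain_copy Copy number of a gained chromosome (default 3).
#' @param dosage_exponent Per-gene RNA dosage exponent (log2 scale).
#' @param coupling Named logical: is TAD co-expression coupling active in
#'   each subtype? Default: on in controls, off in HeH-like, the planted
#'   analogue of the TAD-border dysregulation phenotype.
#' @param attenuation Protein-layer attenuation of the RNA signal in
#'   \[0, 1\].
#' @param tad_sd,batch_sd,complex_sd,protein_noise_sd Standard deviations of
#'   the TAD, batch, complex and protein-noise components (log2 scale).
#' @param complex_fraction Fraction of genes assigned to protein complexes.
#' @param n_complexes Number of protein complexes.
#' @param trans_regulator Optional list `(chrom, n_targets, strength)`
#'   planting a trans effect: expression of `n_targets` genes elsewhere in
#'   the genome follows the copy number of the first gene on `chrom`.
#' @param seed Integer seed.
#' @return A `cohort_truth`: list with `samples` (tibble `sample`,
#'   `subtype`, `batch`), `copy` (tibble `sample`, `chrom`, `copy`) and
#'   `params`.
#' @export
sim_cohort <- function(genome, n_heh = 20, n_control = 20, gain_freq = NULL,
                       gain_copy = 3, dosage_exponent = 1,
                       coupling = c("HeH-like" = FALSE, "control" = TRUE),
                       attenuation = 0.5, tad_sd = 0.5, batch_sd = 0.2,
                       complex_sd = 0.3, protein_noise_sd = 0.6,
                       complex_fraction = 0.3, n_complexes = 40,
                       trans_regulator = NULL, seed = 1) {
  chroms <- genome$chromosomes$chrom
  if (is.null(gain_freq)) {
    k <- min(6, length(chroms))
    gain_freq <- setNames(seq(1, 0.25, length.out = k), chroms[seq_len(k)])
  }
  assert_that(all(names(gain_freq) %in% chroms),
              "gain_freq names a chromosome missing from the genome")
  samples <- tibble(
    sample = sprintf("S%02d", seq_len(n_heh + n_control)),
    subtype = rep(c("HeH-like", "control"), c(n_heh, n_control)),
    batch = rep_len(c("b1", "b2"), n_heh + n_control))
  with_seed(substream_seed(seed, "cohort"), {
    copy <- tidyr::expand_grid(sample = samples$sample, chrom = chroms) %>%
      left_join(samples[, c("sample", "subtype")], by = "sample") %>%
      left_join(genome$chromosomes[, c("chrom", "ploidy")], by = "chrom") %>%
      mutate(freq = dplyr::coalesce(gain_freq[.data$chrom], 0),
             gained = .data$subtype == "HeH-like" &
               runif(dplyr::n()) < .data$freq,
             copy = ifelse(.data$gained, gain_copy, .data$ploidy)) %>%
      select("sample", "chrom", "copy")
  })
  structure(
    list(samples = samples, copy = copy,
         params = list(dosage_exponent = dosage_exponent,
                       coupling = coupling, attenuation = attenuation,
                       tad_sd = tad_sd, batch_sd = batch_sd,
                       complex_sd = complex_sd,
                       protein_noise_sd = protein_noise_sd,
                       complex_fraction = complex_fraction,
                       n_complexes = n_complexes,
                       trans_regulator = trans_regulator)),
    class = "cohort_truth")
}

#' Expression matrix container
#'
#' @param values Numeric genes x samples matrix (log2 scale for normalized
#'   layers; raw counts allowed for the RNA counts layer).
#' @param layer `"rna"` or `"protein"`.
#' @param samples Tibble with `sample` (matching `colnames(values)`),
#'   `group` and optionally `batch`.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values, layer = c("rna", "protein"), samples) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  samples <- as_tibble(samples)
  assert_that(ncol(values) == nrow(samples),
              "samples tibble must match matrix columns")
  if (!is.null(colnames(values))) {
    assert_that(identical(colnames(values), samples$sample),
                "column names must equal samples$sample")
  } else {
    colnames(values) <- samples$sample
  }
  structure(list(values = values, layer = layer, samples = samples),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> layer %s: %d genes x %d samples (%s)\n",
              x$layer, nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$samples$group)),
                            table(x$samples$group)), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.expr_matrix <- function(x, ...) {
  as_tibble(x$values, rownames = "gene") %>%
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "value") %>%
    left_join(x$samples, by = "sample") %>%
    mutate(layer = x$layer)
}

#' Simulate RNA and protein expression with planted dosage and TAD effects
#'
#' Log2-scale RNA value = baseline + dosage_exponent * log2(copy / ploidy) +
#' TAD factor (coupled subtypes only) + batch factor + Gaussian noise.
#' Protein value = attenuation * (noise-free RNA signal) + complex factor +
#' independent noise. Genes are placed uniformly along each chromosome with
#' recorded TSS.
#'
#' @param genome A [genome_spec()].
#' @param cohort A [sim_cohort()] result.
#' @param tads A [tad_truth()].
#' @param n_genes Total gene count (at least 2 per chromosome).
#' @param noise_sd RNA noise standard deviation (log2 scale).
#' @param seed Integer seed.
#' @return List with `rna` and `protein` ([expr_matrix()]), `segments`
#'   (whole-chromosome copy-number segments, tibble `sample chrom start end
#'   copy`), `genes` (annotation tibble `gene chrom start end strand tss`)
#'   and `truth` (per-gene dosage exponent, attenuation, complex map, batch
#'   loadings, trans-regulator targets).
#' @export
simulate_expression <- function(genome, cohort, tads, n_genes = 1200,
                                noise_sd = 0.5, seed = 1) {
  gs <- genome$chromosomes
  missing_chrom <- setdiff(unique(cohort$copy$chrom), gs$chrom)
  assert_that(length(missing_chrom) == 0,
              sprintf("cohort names chromosome %s missing from genome",
                      missing_chrom[1]))
  assert_that(n_genes >= 2 * nrow(gs), "need at least 2 genes per chromosome")
  p <- cohort$params
  with_seed(substream_seed(seed, "expression"), {
    # allocate genes proportionally to length, at least 2 per chromosome
    alloc <- pmax(2, round(n_genes * gs$length / sum(gs$length)))
    genes <- purrr::pmap_dfr(list(gs$chrom, gs$length, alloc),
      function(chrom, len, k) {
        tss <- sort(round(runif(k, 0, len - 1)))
        strand <- sample(c("+", "-"), k, replace = TRUE)
        start <- ifelse(strand == "+", tss, pmax(0, tss - 20000))
        end <- ifelse(strand == "+", pmin(len, tss + 20000), tss + 1)
        tibble(chrom = chrom, start = start, end = end, strand = strand,
               tss = tss)
      })
    genes <- mutate(genes, gene = sprintf("g%04d", seq_len(nrow(genes))),
                    .before = 1)
    ns <- nrow(cohort$samples)
    ng <- nrow(genes)
    ploidy <- setNames(gs$ploidy, gs$chrom)
    copy_mat <- cohort$copy %>%
      tidyr::pivot_wider(names_from = "sample", values_from = "copy") %>%
      arrange(match(.data$chrom, gs$chrom))
    cm <- as.matrix(copy_mat[, cohort$samples$sample])
    rownames(cm) <- copy_mat$chrom
    # per-gene per-sample log2 dosage term
    dose_gene <- log2(cm[genes$chrom, , drop = FALSE] /
                        ploidy[genes$chrom])
    baseline <- rnorm(ng, mean = 5, sd = 1.5)
    dosage_exp <- rep(p$dosage_exponent, ng)
    signal <- baseline + dosage_exp * dose_gene
    # TAD factors: per (domain, sample), active only in coupled subtypes
    gdom <- assign_to_domains(genes$chrom, genes$tss, tads$domains)
    coupled <- p$coupling[cohort$samples$subtype]
    n_dom <- nrow(tads$domains)
    tad_fac <- matrix(rnorm(n_dom * ns, 0, p$tad_sd), n_dom, ns)
    tad_term <- matrix(0, ng, ns)
    ok <- !is.na(gdom)
    tad_term[ok, ] <- tad_fac[gdom[ok], , drop = FALSE]
    tad_term <- sweep(tad_term, 2, as.numeric(coupled), `*`)
    signal <- signal + tad_term
    # batch term
    batch_ind <- ifelse(cohort$samples$batch == "b1", 1, -1)
    batch_load <- rnorm(ng, 0, p$batch_sd)
    signal <- signal + outer(batch_load, batch_ind)
    # optional planted trans regulator
    trans_targets <- integer(0)
    trans_source <- NA_character_
    if (!is.null(p$trans_regulator)) {
      tr <- p$trans_regulator
      src <- which(genes$chrom == tr$chrom)[1]
      assert_that(is.finite(src), "trans_regulator chromosome has no genes")
      trans_source <- genes$gene[src]
      pool <- which(genes$chrom != tr$chrom)
      trans_targets <- sample(pool, tr$n_targets)
      src_dose <- dose_gene[src, ]
      signal[trans_targets, ] <- signal[trans_targets, ] +
        tr$strength * matrix(src_dose, length(trans_targets), ns,
                             byrow = TRUE)
    }
    rna <- signal + matrix(rnorm(ng * ns, 0, noise_sd), ng, ns)
    # protein layer: attenuated noise-free signal + complex factor + noise
    atten <- rep(p$attenuation, ng)
    complex_id <- rep(NA_integer_, ng)
    n_cx_genes <- round(p$complex_fraction * ng)
    if (n_cx_genes >= 2 && p$n_complexes >= 1) {
      members <- sample(ng, n_cx_genes)
      complex_id[members] <- sample(seq_len(p$n_complexes), n_cx_genes,
                                    replace = TRUE)
    }
    cx_fac <- matrix(rnorm(max(1, p$n_complexes) * ns, 0, p$complex_sd),
                     max(1, p$n_complexes), ns)
    cx_term <- matrix(0, ng, ns)
    okc <- !is.na(complex_id)
    cx_term[okc, ] <- cx_fac[complex_id[okc], , drop = FALSE]
    protein <- atten * signal + cx_term +
      matrix(rnorm(ng * ns, 0, p$protein_noise_sd), ng, ns)
    rownames(rna) <- rownames(protein) <- genes$gene
    colnames(rna) <- colnames(protein) <- cohort$samples$sample
    segments <- cohort$copy %>%
      left_join(gs[, c("chrom", "length")], by = "chrom") %>%
      mutate(start = 0, end = .data$length) %>%
      select("sample", "chrom", "start", "end", "copy")
    smp <- cohort$samples %>% mutate(group = .data$subtype)
    list(
      rna = expr_matrix(rna, "rna", smp),
      protein = expr_matrix(protein, "protein", smp),
      segments = segments,
      genes = genes,
      truth = list(baseline = baseline, dosage_exponent = dosage_exp,
                   attenuation = atten, complex_id = complex_id,
                   batch_loadings = batch_load, gene_domain = gdom,
                   trans_source = trans_source,
                   trans_targets = genes$gene[trans_targets]))
  })
}

# Index of the containing domain (innermost irrelevant here: truth domains
# tile, so containment is unique). NA when outside every domain.
assign_to_domains <- function(chrom, pos, domains) {
  out <- rep(NA_integer_, length(chrom))
  for (i in seq_len(nrow(domains))) {
    hit <- chrom == domains$chrom[i] & pos >= domains$start[i] &
      pos < domains$end[i]
    out[hit] <- i
  }
  out
}

#' Simulate CTCF/RAD21 peaks and ChIA-PET interactions
#'
#' Peaks are planted at every TAD boundary (jittered within +/-10 kb) plus a
#' Poisson background; loop interactions connect the two edges of each
#' domain with PET counts drawn uniformly from `pet_range`. A configurable
#' fraction of interactions is shared between the CTCF and RAD21 sets.
#'
#' @param genome A [genome_spec()].
#' @param tads A [tad_truth()].
#' @param peak_rate Background peak rate per Mb (>= 0).
#' @param pet_range Integer interval `c(lo, hi)` of PET counts.
#' @param shared_fraction Fraction of interactions present in both sets.
#' @param seed Integer seed.
#' @return List with `ctcf`, `rad21` (peak tibbles `chrom start end`),
#'   `interactions_ctcf`, `interactions_rad21` (BEDPE-style tibbles with
#'   `pet`).
#' @export
simulate_annotations <- function(genome, tads, peak_rate = 5,
                                 pet_range = c(10, 50),
                                 shared_fraction = 0.5, seed = 1) {
  assert_that(peak_rate >= 0, "peak_rate must be non-negative")
  with_seed(substream_seed(seed, "annotations"), {
    make_peaks <- function() {
      planted <- tads$boundaries %>%
        mutate(center = pmax(100, .data$pos + round(runif(dplyr::n(),
                                                          -10000, 10000))),
               start = .data$center - 100, end = .data$center + 100) %>%
        select("chrom", "start", "end")
      bg <- purrr::pmap_dfr(
        list(genome$chromosomes$chrom, genome$chromosomes$length),
        function(chrom, len) {
          k <- rpois(1, peak_rate * len / 1e6)
          if (k == 0) return(tibble(chrom = character(0), start = numeric(0),
                                    end = numeric(0)))
          ctr <- round(runif(k, 100, len - 100))
          tibble(chrom = chrom, start = ctr - 100, end = ctr + 100)
        })
      arrange(bind_rows(planted, bg), .data$chrom, .data$start)
    }
    ctcf <- make_peaks()
    rad21 <- make_peaks()
    loops <- tads$domains %>%
      mutate(a1_start = .data$start, a1_end = .data$start + 1000,
             a2_start = pmax(.data$end - 1000, .data$start + 1000),
             a2_end = .data$end) %>%
      select(chrom1 = "chrom", start1 = "a1_start", end1 = "a1_end",
             chrom2 = "chrom", start2 = "a2_start", end2 = "a2_end")
    n_int <- nrow(loops)
    shared <- runif(n_int) < shared_fraction
    only <- sample(c(TRUE, FALSE), n_int, replace = TRUE)
    pet <- function(k) {
      if (k == 0) integer(0) else
        sample(seq(pet_range[1], pet_range[2]), k, replace = TRUE)
    }
    in_a <- shared | only
    in_b <- shared | !only
    ia <- loops[in_a, ]; ia$pet <- pet(sum(in_a))
    ib <- loops[in_b, ]; ib$pet <- pet(sum(in_b))
    list(ctcf = ctcf, rad21 = rad21,
         interactions_ctcf = ia, interactions_rad21 = ib)
  })
}

#' Simulate chromosome morphology scores (CMS)
#'
#' Per-metaphase integer scores in \{1, 2, 3\} drawn from a trinomial whose
#' mean equals the case mean; case means vary around the group mean so that
#' group means center on `group_means`.
#'
#' @param n_per_group Integer vector of case counts per group.
#' @param group_means Target group mean scores, each in \[1, 3\].
#' @param metaphases_per_case Metaphases scored per case (default 20).
#' @param group_names Group labels (default `HeH`, `ETV6_RUNX1`).
#' @param case_sd Between-case standard deviation of the mean score.
#' @param spread Within-case score spread; 0 with a mean of exactly 2 makes
#'   every score 2.
#' @param seed Integer seed.
#' @return Tibble `case_id group metaphase score` (a CMS table).
#' @export
simulate_cms <- function(n_per_group = c(37, 33), group_means = c(1.8, 2.1),
                         metaphases_per_case = 20,
                         group_names = c("HeH", "ETV6_RUNX1"),
                         case_sd = 0.15, spread = 0.25, seed = 1) {
  assert_that(all(group_means >= 1 & group_means <= 3),
              "group means must lie in [1, 3]")
  assert_that(length(n_per_group) == length(group_means),
              "n_per_group and group_means must align")
  with_seed(substream_seed(seed, "cms"), {
    out <- purrr::pmap_dfr(
      list(seq_along(n_per_group), n_per_group, group_means),
      function(g, n_cases, gm) {
        purrr::map_dfr(seq_len(n_cases), function(ci) {
          m <- min(3, max(1, gm + rnorm(1, 0, case_sd)))
          d <- m - 2
          a <- min(0.5, spread + abs(d) / 2)
          probs <- c(a - d / 2, 1 - 2 * a, a + d / 2)
          tibble(case_id = sprintf("%s_%02d", group_names[g], ci),
                 group = group_names[g],
                 metaphase = seq_len(metaphases_per_case),
                 score = sample(1:3, metaphases_per_case, replace = TRUE,
                                prob = probs))
        })
      })
    out
  })
}
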