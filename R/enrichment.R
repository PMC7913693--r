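#' Generate computationally random genomic loci
#'
#' Draws point loci uniformly over the non-excluded positions of a
#' genome: a chromosome is chosen proportionally to its usable length,
#' then a usable position uniformly within it. The standard null set for
#' insertion-site enrichment comparisons is 100,000 such loci.
#'
#' @param genome Genome tibble (`name`, `sequence`) or a named integer
#'   vector of contig lengths.
#' @param n Number of loci.
#' @param seed RNG seed (required for reproducibility).
#' @param excluded Optional tibble of 0-based half-open intervals to
#'   exclude.
#' @return A tibble of 1-based point loci (`chrom`, `pos`).
#' @export
generate_random_loci <- function(genome, n, seed, excluded = NULL) {
  stopifnot(n >= 1)
  lens <- if (is.data.frame(genome)) {
    stats::setNames(nchar(genome$sequence), genome$name)
  } else {
    genome
  }
  if (length(lens) == 0 || sum(lens) == 0) stop("empty genome", call. = FALSE)
  # usable 1-based positions per contig as IRanges
  usable <- lapply(names(lens), function(chr) {
    full <- IRanges::IRanges(start = 1L, end = lens[[chr]])
    if (!is.null(excluded) && nrow(excluded) > 0) {
      ex <- excluded[excluded$chrom == chr, , drop = FALSE]
      if (nrow(ex) > 0) {
        exr <- IRanges::reduce(IRanges::IRanges(start = ex$start + 1L, end = ex$end))
        return(IRanges::setdiff(full, exr))
      }
    }
    full
  })
  names(usable) <- names(lens)
  widths <- vapply(usable, function(r) sum(IRanges::width(r)), numeric(1))
  if (sum(widths) == 0) stop("excluded intervals cover the whole genome", call. = FALSE)
  withr::with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1, n, prob = widths / sum(widths)))
    parts <- purrr::map2(names(lens), counts, function(chr, k) {
      if (k == 0) return(NULL)
      r <- usable[[chr]]
      # uniform over the union of usable ranges: index positions 1..width
      offs <- sample.int(sum(IRanges::width(r)), k, replace = TRUE)
      cum <- cumsum(IRanges::width(r))
      ridx <- findInterval(offs - 1L, c(0L, cum), rightmost.closed = FALSE)
      within <- offs - c(0L, cum)[ridx]
      tibble::tibble(chrom = chr,
                     pos = as.integer(IRanges::start(r)[ridx] + within - 1L))
    })
    dplyr::bind_rows(parts)
  })
}

#' Fraction of point loci overlapping a feature track
#'
#' A locus counts as inside the track iff its 1-based point position
#' falls in any of the track's 0-based half-open intervals. Overlap is
#' computed with [IRanges][IRanges::findOverlaps]; a brute-force linear
#' scan gives identical results (used as a test oracle).
#'
#' @param loci Tibble of point loci (`chrom`, `pos`).
#' @param track Tibble of intervals (`chrom`, `start`, `end`).
#' @return A one-row tibble: `n_in`, `n_total`, `fraction`.
#' @export
overlap_fraction <- function(loci, track) {
  if (nrow(loci) == 0) stop("zero loci", call. = FALSE)
  check_intervals(track, "track")
  pts <- GenomicRanges::GRanges(loci$chrom, IRanges::IRanges(loci$pos, width = 1L))
  tr <- intervals_to_granges(track)
  # tracks may legitimately name contigs the loci never touch
  n_in <- sum(suppressWarnings(
    IRanges::overlapsAny(pts, tr, ignore.strand = TRUE)))
  tibble::tibble(n_in = n_in, n_total = nrow(loci),
                 fraction = n_in / nrow(loci))
}

#' Fold change of a sample fraction over the random expectation
#'
#' The random-locus frequency defines the expectation, set to 1; a
#' feature with twice the random frequency has fold change 2. Undefined
#' (NA) when the random fraction is 0.
#'
#' @param sample_fraction,random_fraction Fractions in \[0, 1\]
#'   (vectorized).
#' @return Numeric fold change(s); `NA` where undefined.
#' @export
fold_change <- function(sample_fraction, random_fraction) {
  stopifnot(all(sample_fraction >= 0 & sample_fraction <= 1, na.rm = TRUE),
            all(random_fraction >= 0 & random_fraction <= 1, na.rm = TRUE))
  ifelse(random_fraction > 0, sample_fraction / random_fraction, NA_real_)
}

#' Derive gene-anatomy feature tracks from gene models
#'
#' From stranded gene intervals and their exons, builds the standard
#' gene-associated tracks used for insertion-profile comparisons: gene
#' body, exon, intron (gene minus exon), upstream and downstream windows
#' (strand-aware), TSS and TSE windows (transcription start/end +/-
#' `window_bp`), and intergenic (complement of gene bodies extended by
#' `window_bp`).
#'
#' @param genes Tibble of gene intervals (`chrom`, `start`, `end`,
#'   `strand`, optional `name`), 0-based half-open.
#' @param exons Tibble of exon intervals with a `gene` column naming the
#'   parent (or matched by containment when absent).
#' @param genome Genome tibble or named contig-length vector (bounds for
#'   windows and the intergenic complement).
#' @param window_bp Window size for upstream/downstream/TSS/TSE tracks
#'   (default 2000).
#' @return A tibble of intervals with a `feature` column (`gene_body`,
#'   `exon`, `intron`, `upstream`, `downstream`, `tss`, `tse`,
#'   `intergenic`).
#' @export
derive_gene_feature_tracks <- function(genes, exons, genome, window_bp = 2000L) {
  check_intervals(genes, "gene")
  check_intervals(exons, "exon")
  lens <- if (is.data.frame(genome)) {
    stats::setNames(nchar(genome$sequence), genome$name)
  } else genome
  # every exon must lie inside a gene on the same contig
  for (i in seq_len(nrow(exons))) {
    inside <- any(genes$chrom == exons$chrom[i] &
                    genes$start <= exons$start[i] &
                    genes$end >= exons$end[i])
    if (!inside) stop("exon outside any gene at row ", i, call. = FALSE)
  }
  clip <- function(df) {
    df$start <- pmax(df$start, 0L)
    df$end <- pmin(df$end, unname(lens[df$chrom]))
    df[df$end > df$start, c("chrom", "start", "end"), drop = FALSE]
  }
  plus <- genes$strand == "+"
  # TSS/TSE as 0-based boundary points; windows are [point - w, point + w)
  tss0 <- ifelse(plus, genes$start, genes$end)
  tse0 <- ifelse(plus, genes$end, genes$start)
  up <- tibble::tibble(chrom = genes$chrom,
                       start = ifelse(plus, genes$start - window_bp, genes$end),
                       end = ifelse(plus, genes$start, genes$end + window_bp))
  down <- tibble::tibble(chrom = genes$chrom,
                         start = ifelse(plus, genes$end, genes$start - window_bp),
                         end = ifelse(plus, genes$end + window_bp, genes$start))
  tss <- tibble::tibble(chrom = genes$chrom, start = tss0 - window_bp,
                        end = tss0 + window_bp)
  tse <- tibble::tibble(chrom = genes$chrom, start = tse0 - window_bp,
                        end = tse0 + window_bp)
  gene_body <- genes[, c("chrom", "start", "end")]
  exon_t <- exons[, c("chrom", "start", "end")]
  gr_gene <- intervals_to_granges(gene_body)
  gr_exon <- intervals_to_granges(exon_t)
  intron <- granges_to_intervals(
    GenomicRanges::setdiff(GenomicRanges::reduce(gr_gene),
                           GenomicRanges::reduce(gr_exon), ignore.strand = TRUE)
  )[, c("chrom", "start", "end")]
  extended <- clip(tibble::tibble(chrom = genes$chrom,
                                  start = genes$start - window_bp,
                                  end = genes$end + window_bp))
  full <- tibble::tibble(chrom = names(lens), start = 0L,
                         end = as.integer(unname(lens)))
  intergenic <- if (nrow(extended) > 0) {
    granges_to_intervals(
      GenomicRanges::setdiff(intervals_to_granges(full),
                             GenomicRanges::reduce(intervals_to_granges(extended)),
                             ignore.strand = TRUE)
    )[, c("chrom", "start", "end")]
  } else {
    full
  }
  dplyr::bind_rows(
    gene_body = gene_body, exon = exon_t, intron = intron,
    upstream = clip(up), downstream = clip(down),
    tss = clip(tss), tse = clip(tse), intergenic = intergenic,
    .id = "feature"
  )
}

#' Enrichment of insertion loci across feature tracks vs a random null
#'
#' For each (feature, sample) pair, computes the fraction of loci inside
#' the feature and its fold change over the random-locus fraction, with a
#' descriptive binomial confidence interval on the sample fraction.
#' Features are ordered by their row-mean fold change.
#'
#' @param site_sets Named list of point-locus tibbles (`chrom`, `pos`);
#'   e.g. `list(ZB = ..., SB = ...)`.
#' @param tracks Tibble of intervals with a `feature` column, as from
#'   [derive_gene_feature_tracks()], or a named list of track tibbles.
#' @param random_loci Tibble of random point loci defining the null.
#' @param conf_level Confidence level of the binomial interval.
#' @return A tibble of class `enrichment_result`: `feature`, `sample`,
#'   `n_in`, `n_total`, `fraction`, `random_fraction`, `fold_change`,
#'   `log2_fold`, `ci_lo`, `ci_hi`.
#' @export
enrichment_table <- function(site_sets, tracks, random_loci,
                             conf_level = 0.95) {
  if (!is.data.frame(tracks)) {
    tracks <- dplyr::bind_rows(tracks, .id = "feature")
  }
  stopifnot("feature" %in% names(tracks))
  feats <- unique(tracks$feature)
  rows <- purrr::map(feats, function(f) {
    tr <- tracks[tracks$feature == f, , drop = FALSE]
    rnd <- overlap_fraction(random_loci, tr)
    per_sample <- purrr::imap(site_sets, function(loci, nm) {
      ov <- overlap_fraction(loci, tr)
      ci <- stats::binom.test(ov$n_in, ov$n_total,
                              conf.level = conf_level)$conf.int
      tibble::tibble(feature = f, sample = nm, n_in = ov$n_in,
                     n_total = ov$n_total, fraction = ov$fraction,
                     random_fraction = rnd$fraction,
                     fold_change = fold_change(ov$fraction, rnd$fraction),
                     ci_lo = ci[1], ci_hi = ci[2])
    })
    dplyr::bind_rows(per_sample)
  })
  out <- dplyr::bind_rows(rows)
  out$log2_fold <- log2(out$fold_change)
  ord <- out |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(m = mean(.data$fold_change, na.rm = TRUE)) |>
    dplyr::arrange(dplyr::desc(.data$m))
  out$feature <- factor(out$feature, levels = ord$feature)
  out <- dplyr::arrange(out, .data$feature, .data$sample)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$sample, y = .data$feature,
                               fill = .data$log2_fold)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$fold_change), "NA",
                     sprintf("%.2f", .data$fold_change))), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 fold") +
    ggplot2::theme_minimal()
}
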