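#' Simulate a toy genome
#'
#' Contigs of i.i.d. bases with tunable AT content:
#' `P(A) = P(T) = at_fraction / 2`, `P(C) = P(G) = (1 - at_fraction) / 2`.
#' Fully determined by `seed` (the caller's RNG state is untouched).
#'
#' @param lengths Integer vector of contig lengths (one contig each).
#' @param at_fraction Target A+T fraction in (0, 1).
#' @param seed RNG seed.
#' @param prefix Contig-name prefix.
#' @return A genome tibble (`name`, `sequence`).
#' @examples
#' sim_genome(1000, seed = 1)
#' @export
sim_genome <- function(lengths, at_fraction = 0.5, seed, prefix = "contig") {
  stopifnot(all(lengths > 0), at_fraction > 0, at_fraction < 1)
  p <- c(A = at_fraction / 2, C = (1 - at_fraction) / 2,
         G = (1 - at_fraction) / 2, T = at_fraction / 2)
  withr::with_seed(seed, {
    seqs <- vapply(lengths, function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, character(1))
  })
  tibble::tibble(name = paste0(prefix, seq_along(lengths)), sequence = seqs)
}

#' Mutate a sequence under a single-hit two-parameter substitution model
#'
#' Each site is substituted independently with probability `d`; a
#' substitution is a transition with probability
#' `tstv_ratio / (tstv_ratio + 1)`, otherwise one of the two
#' transversions with equal probability. Single-hit (no site mutates
#' twice), so for small `d` the realized divergence is `d` in
#' expectation and the multiple-hit-corrected K2P estimate slightly
#' exceeds it. Uses the current RNG state (wrap in
#' [withr::with_seed()] for reproducibility).
#'
#' @param sequence Nucleotide string.
#' @param d Per-site substitution probability.
#' @param tstv_ratio Transition:transversion ratio.
#' @return The mutated sequence.
#' @export
mutate_k2p <- function(sequence, d, tstv_ratio = 2) {
  ch <- seq_chars(toupper(sequence))
  hit <- stats::runif(length(ch)) < d
  if (!any(hit)) return(sequence)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  idx <- which(hit)
  is_ts <- stats::runif(length(idx)) < tstv_ratio / (tstv_ratio + 1)
  new <- character(length(idx))
  new[is_ts] <- transition[ch[idx[is_ts]]]
  tv <- which(!is_ts)
  if (length(tv) > 0) {
    pick <- stats::runif(length(tv)) < 0.5
    new[tv] <- vapply(seq_along(tv), function(k) {
      transversions[[ch[idx[tv[k]]]]][if (pick[k]) 1L else 2L]
    }, character(1))
  }
  ch[idx] <- new
  paste(ch, collapse = "")
}

# TA positions (1-based T positions) on a contig sequence
ta_positions <- function(sequence) {
  hits <- gregexpr("TA", sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Plant diverged element copies into a genome at TA target sites
#'
#' Each copy is the consensus mutated under a single-hit two-parameter
#' substitution model to a target divergence `d` (transitions favoured by
#' `tstv_ratio`), inserted on a random strand at a TA dinucleotide with
#' the TA duplicated on both flanks (cut-and-paste target-site
#' duplication). The returned truth table fully describes every copy.
#'
#' @param genome Genome tibble.
#' @param consensus Consensus element sequence.
#' @param n Number of copies.
#' @param divergences Target divergence per copy (recycled to `n`); each
#'   must be sub-saturating.
#' @param tstv_ratio Transition:transversion ratio (default 2).
#' @param seed RNG seed.
#' @param min_gap Minimum bp between planted copies.
#' @return A list: `genome` (modified tibble) and `truth` (tibble
#'   `copy_id`, `chrom`, `start`, `end` 0-based half-open on the modified
#'   genome, `strand`, `divergence`).
#' @export
sim_plant_copies <- function(genome, consensus, n, divergences,
                             tstv_ratio = 2, seed, min_gap = 100L) {
  divergences <- rep_len(divergences, n)
  if (any(2 * divergences * tstv_ratio / (tstv_ratio + 1) >= 0.5)) {
    stop("requested divergence saturates the substitution model", call. = FALSE)
  }
  consensus <- toupper(consensus)
  withr::with_seed(seed, {
    # choose TA positions across contigs, spaced by min_gap
    cand <- dplyr::bind_rows(purrr::map2(
      genome$name, genome$sequence,
      function(nm, s) tibble::tibble(chrom = nm, pos = ta_positions(s),
                                     len = nchar(s))
    ))
    cand <- cand[cand$pos > min_gap & cand$pos < cand$len - min_gap, ]
    if (nrow(cand) < n) stop("not enough TA positions for ", n, " copies",
                             call. = FALSE)
    picked <- NULL
    cand <- cand[sample.int(nrow(cand)), ]
    for (i in seq_len(nrow(cand))) {
      row <- cand[i, ]
      if (is.null(picked) ||
          !any(picked$chrom == row$chrom & abs(picked$pos - row$pos) < min_gap)) {
        picked <- rbind(picked, row)
        if (nrow(picked) >= n) break
      }
    }
    if (is.null(picked) || nrow(picked) < n) {
      stop("not enough spaced TA positions for ", n, " copies", call. = FALSE)
    }
    picked <- picked[seq_len(n), ]
    strands <- sample(c("+", "-"), n, replace = TRUE)
    elements <- vapply(divergences, mutate_k2p, character(1),
                       sequence = consensus, tstv_ratio = tstv_ratio)
    truth <- tibble::tibble(copy_id = paste0("copy", seq_len(n)),
                            chrom = picked$chrom, ta_pos = picked$pos,
                            strand = strands, divergence = divergences,
                            element = elements)
    # insert per contig from right to left so positions stay valid
    new_genome <- genome
    starts <- integer(n); ends <- integer(n)
    for (chr in unique(truth$chrom)) {
      rows <- which(truth$chrom == chr)
      rows <- rows[order(truth$ta_pos[rows], decreasing = TRUE)]
      s <- new_genome$sequence[new_genome$name == chr]
      for (r in rows) {
        p <- truth$ta_pos[r]  # 1-based T of the target TA
        el <- if (truth$strand[r] == "+") truth$element[r] else
          revcomp(truth$element[r])
        # ...xT A y... -> ...x TA [el] TA y...  (TA duplicated)
        s <- paste0(substr(s, 1L, p + 1L), el, substr(s, p, nchar(s)))
      }
      # recompute 0-based copy intervals left to right with cumulative shift
      rows_lr <- which(truth$chrom == chr)
      rows_lr <- rows_lr[order(truth$ta_pos[rows_lr])]
      shift <- 0L
      for (r in rows_lr) {
        ins_at <- truth$ta_pos[r] + 1L + shift       # 1-based pos of last TA base before element
        starts[r] <- ins_at                          # 0-based start of element
        ends[r] <- ins_at + nchar(truth$element[r])
        shift <- shift + nchar(truth$element[r]) + 2L
      }
      new_genome$sequence[new_genome$name == chr] <- s
    }
    truth$start <- starts
    truth$end <- ends
    list(genome = new_genome,
         truth = truth[, c("copy_id", "chrom", "start", "end", "strand",
                           "divergence", "element")])
  })
}

#' Choose TA insertion sites on a genome
#'
#' Samples `n` well-separated TA dinucleotide positions (or deliberately
#' non-TA positions, for testing TA validation) with random or fixed
#' strands.
#'
#' @param genome Genome tibble.
#' @param n Number of sites.
#' @param seed RNG seed.
#' @param strand `"random"`, `"+"` or `"-"`.
#' @param min_gap Minimum bp between sites and from contig ends.
#' @param at_ta Pick TA positions (default) or non-TA positions.
#' @return A site tibble (`chrom`, `ta_pos` 1-based T position,
#'   `strand`).
#' @export
sim_ta_sites <- function(genome, n, seed, strand = "random",
                         min_gap = 600L, at_ta = TRUE) {
  withr::with_seed(seed, {
    cand <- dplyr::bind_rows(purrr::map2(
      genome$name, genome$sequence,
      function(nm, s) {
        pos <- if (at_ta) ta_positions(s) else {
          all_pos <- seq_len(nchar(s) - 1L)
          setdiff(all_pos, ta_positions(s))
        }
        tibble::tibble(chrom = nm, pos = pos, len = nchar(s))
      }
    ))
    cand <- cand[cand$pos > min_gap & cand$pos < cand$len - min_gap, ]
    if (nrow(cand) < n) stop("not enough candidate positions", call. = FALSE)
    cand <- cand[sample.int(nrow(cand)), ]
    picked <- NULL
    for (i in seq_len(nrow(cand))) {
      row <- cand[i, ]
      if (is.null(picked) ||
          !any(picked$chrom == row$chrom & abs(picked$pos - row$pos) < min_gap)) {
        picked <- rbind(picked, row)
        if (nrow(picked) >= n) break
      }
    }
    if (is.null(picked) || nrow(picked) < n) {
      stop("not enough spaced candidate positions", call. = FALSE)
    }
    strands <- if (strand == "random") sample(c("+", "-"), n, replace = TRUE)
    else rep(strand, n)
    tibble::tibble(chrom = picked$chrom[seq_len(n)],
                   ta_pos = as.integer(picked$pos[seq_len(n)]),
                   strand = strands)
  })
}

#' Plant a fixed flank context around TA sites
#'
#' Overwrites the bases to the left and right of each site's TA with the
#' given strings (e.g. `left = "ATA"`, `right = "TAT"` creates the
#' palindromic `ATATATAT` context with the central TA as the insertion
#' site). Used to give the target-site profiler a known ground truth.
#'
#' @param genome Genome tibble.
#' @param sites Site tibble (`chrom`, `ta_pos`).
#' @param left,right Context written immediately 5' and 3' of the TA.
#' @return The modified genome tibble.
#' @export
sim_plant_context <- function(genome, sites, left = "ATA", right = "TAT") {
  for (i in seq_len(nrow(sites))) {
    ci <- match(sites$chrom[i], genome$name)
    s <- genome$sequence[ci]
    p <- sites$ta_pos[i]
    substr(s, p - nchar(left), p - 1L) <- left
    substr(s, p + 2L, p + 1L + nchar(right)) <- right
    genome$sequence[ci] <- s
  }
  genome
}

#' Simulate a transposon-genome junction read library
#'
#' Each read is `[tir_tag][genomic flank][linker]`: the flank starts at
#' the site's duplicated TA and extends away from the element (rightward
#' for plus-strand insertions, leftward-reverse-complemented for minus),
#' with length uniform in `fragment_len_range` and i.i.d. per-base
#' substitution errors at `error_rate`. Sites too close to a contig end
#' for the minimum fragment are skipped with a warning and recorded.
#'
#' @param genome Genome tibble.
#' @param sites Site tibble (`chrom`, `ta_pos`, `strand`).
#' @param reads_per_site Reads emitted per site.
#' @param tir_tag,linker Library structure strings.
#' @param fragment_len_range Genomic-flank length range in bp (the
#'   200-500 bp gel-size-selection window of a sonication library).
#' @param error_rate Per-base substitution error rate.
#' @param seed RNG seed.
#' @return A list: `reads` (tibble `name`, `sequence`, `quality`),
#'   `truth` (tibble `read`, `chrom`, `ta_pos`, `strand`, `frag_len`),
#'   `skipped` (site rows skipped for lack of flank).
#' @export
sim_junction_library <- function(genome, sites, reads_per_site,
                                 tir_tag = "CAGTGGGTCAGAAGTTTACATACAC",
                                 linker = "GTCCCTTAAGCGGAGCCC",
                                 fragment_len_range = c(200L, 500L),
                                 error_rate = 0, seed) {
  genome_seq <- stats::setNames(toupper(genome$sequence), genome$name)
  tir_tag <- toupper(tir_tag); linker <- toupper(linker)
  withr::with_seed(seed, {
    reads <- list(); truth <- list(); skipped <- list()
    k <- 0L
    for (i in seq_len(nrow(sites))) {
      chrom <- sites$chrom[i]; p <- sites$ta_pos[i]; st <- sites$strand[i]
      s <- genome_seq[[chrom]]
      if (reads_per_site < 1) next
      for (j in seq_len(reads_per_site)) {
        L <- sample.int(fragment_len_range[2] - fragment_len_range[1] + 1L, 1L) +
          fragment_len_range[1] - 1L
        if (st == "+") {
          if (p + L - 1L > nchar(s)) {
            skipped[[length(skipped) + 1L]] <- sites[i, ]
            warning("site ", chrom, ":", p, " too close to contig end; skipped",
                    call. = FALSE)
            break
          }
          flank <- substr(s, p, p + L - 1L)
        } else {
          if (p + 1L - L < 1L) {
            skipped[[length(skipped) + 1L]] <- sites[i, ]
            warning("site ", chrom, ":", p, " too close to contig start; skipped",
                    call. = FALSE)
            break
          }
          flank <- revcomp(substr(s, p + 2L - L, p + 1L))
        }
        read_seq <- paste0(tir_tag, flank, linker)
        if (error_rate > 0) {
          ch <- seq_chars(read_seq)
          err <- which(stats::runif(length(ch)) < error_rate)
          if (length(err) > 0) {
            ch[err] <- vapply(ch[err], function(b) {
              sample(setdiff(c("A", "C", "G", "T"), b), 1L)
            }, character(1))
            read_seq <- paste(ch, collapse = "")
          }
        }
        k <- k + 1L
        reads[[k]] <- tibble::tibble(
          name = sprintf("read_%05d_site%03d", k, i),
          sequence = read_seq,
          quality = strrep("I", nchar(read_seq))
        )
        truth[[k]] <- tibble::tibble(read = reads[[k]]$name, chrom = chrom,
                                     ta_pos = p, strand = st, frag_len = L)
      }
    }
    list(reads = if (k > 0) dplyr::bind_rows(reads) else
      tibble::tibble(name = character(), sequence = character(),
                     quality = character()),
      truth = if (k > 0) dplyr::bind_rows(truth) else
        tibble::tibble(read = character(), chrom = character(),
                       ta_pos = integer(), strand = character(),
                       frag_len = integer()),
      skipped = if (length(skipped) > 0) dplyr::bind_rows(skipped) else
        sites[0, ])
  })
}

#' Simulate annotation tracks with known coverage
#'
#' Generates non-overlapping gene models (each with exons inside and a
#' random strand) to a target gene-body coverage, plus independent
#' enhancer-like and open-chromatin interval sets at their own target
#' coverages. Realized coverage fractions are recounted exactly and
#' recorded in the truth.
#'
#' @param genome Genome tibble.
#' @param gene_density Target fraction of the genome covered by gene
#'   bodies (0 allowed: empty gene track).
#' @param enhancer_cov,open_chromatin_cov Target coverages of the two
#'   interval tracks.
#' @param seed RNG seed.
#' @param gene_len,feature_len Interval length ranges in bp.
#' @return A list: `genes`, `exons`, `enhancers`, `open_chromatin`
#'   (interval tibbles) and `truth` (tibble of realized coverage
#'   fractions).
#' @export
sim_annotation_tracks <- function(genome, gene_density = 0.3,
                                  enhancer_cov = 0.1,
                                  open_chromatin_cov = 0.1, seed,
                                  gene_len = c(2000L, 10000L),
                                  feature_len = c(500L, 2000L)) {
  if (gene_density >= 1 || enhancer_cov >= 1 || open_chromatin_cov >= 1) {
    stop("coverages must be < 1", call. = FALSE)
  }
  lens <- stats::setNames(nchar(genome$sequence), genome$name)
  total <- sum(lens)
  withr::with_seed(seed, {
    place_intervals <- function(target_cov, len_range, non_overlapping = TRUE) {
      out <- NULL
      covered <- 0
      guard <- 0L
      while (covered < target_cov * total && guard < 10000L) {
        guard <- guard + 1L
        chr <- sample(names(lens), 1L, prob = lens / total)
        w <- sample.int(len_range[2] - len_range[1] + 1L, 1L) + len_range[1] - 1L
        if (lens[[chr]] <= w + 2L) next
        st <- sample.int(lens[[chr]] - w - 1L, 1L)
        cand <- tibble::tibble(chrom = chr, start = st, end = st + w)
        if (non_overlapping && !is.null(out) &&
            any(out$chrom == chr & out$start < cand$end & out$end > cand$start)) {
          next
        }
        out <- dplyr::bind_rows(out, cand)
        covered <- covered + w
      }
      if (is.null(out)) tibble::tibble(chrom = character(), start = integer(),
                                       end = integer()) else out
    }
    genes <- if (gene_density > 0) {
      g <- place_intervals(gene_density, gene_len)
      g$strand <- sample(c("+", "-"), nrow(g), replace = TRUE)
      g$name <- paste0("gene", seq_len(nrow(g)))
      g
    } else {
      tibble::tibble(chrom = character(), start = integer(), end = integer(),
                     strand = character(), name = character())
    }
    exons <- if (nrow(genes) > 0) {
      dplyr::bind_rows(purrr::map(seq_len(nrow(genes)), function(i) {
        g <- genes[i, ]
        n_ex <- sample(2:4, 1L)
        w <- g$end - g$start
        # n_ex exon starts on a regular grid with jittered widths
        bounds <- round(seq(g$start, g$end, length.out = 2L * n_ex + 1L))
        tibble::tibble(chrom = g$chrom,
                       start = as.integer(bounds[seq(1, 2 * n_ex, by = 2)]),
                       end = as.integer(bounds[seq(2, 2 * n_ex + 1, by = 2)]),
                       gene = g$name)
      }))
    } else {
      tibble::tibble(chrom = character(), start = integer(), end = integer(),
                     gene = character())
    }
    enhancers <- place_intervals(enhancer_cov, feature_len)
    open_chromatin <- place_intervals(open_chromatin_cov, feature_len)
    realized <- function(df) {
      if (nrow(df) == 0) return(0)
      sum(IRanges::width(IRanges::reduce(
        intervals_to_granges(df[, c("chrom", "start", "end")])
      ))) / total
    }
    list(genes = genes, exons = exons, enhancers = enhancers,
         open_chromatin = open_chromatin,
         truth = tibble::tibble(
           track = c("gene_body", "enhancer", "open_chromatin"),
           coverage = c(realized(genes), realized(enhancers),
                        realized(open_chromatin))
         ))
  })
}

#' Place insertion loci with a planted track enrichment
#'
#' Draws `n` point loci of which a fraction `frac_in` falls uniformly
#' inside the track and the rest uniformly outside; used to verify that
#' measured fold changes recover a planted enrichment.
#'
#' @param genome Genome tibble or named contig-length vector.
#' @param track Interval tibble the enrichment is planted in.
#' @param n Number of loci.
#' @param frac_in Fraction of loci placed inside the track.
#' @param seed RNG seed.
#' @return A tibble of point loci (`chrom`, `pos`).
#' @export
sim_enriched_loci <- function(genome, track, n, frac_in, seed) {
  n_in <- round(n * frac_in)
  lens <- if (is.data.frame(genome)) {
    stats::setNames(nchar(genome$sequence), genome$name)
  } else genome
  full <- tibble::tibble(chrom = names(lens), start = 0L,
                         end = as.integer(unname(lens)))
  inside <- generate_random_loci(lens, max(n_in, 1L), seed = seed,
                                 excluded = complement_intervals(track, lens))
  outside <- generate_random_loci(lens, max(n - n_in, 1L), seed = seed + 1L,
                                  excluded = track)
  dplyr::bind_rows(inside[seq_len(n_in), ],
                   outside[seq_len(n - n_in), ])
}

# complement of an interval set within contig bounds (0-based half-open)
complement_intervals <- function(track, lens) {
  full <- intervals_to_granges(tibble::tibble(
    chrom = names(lens), start = 0L, end = as.integer(unname(lens))))
  tr <- GenomicRanges::reduce(intervals_to_granges(track))
  granges_to_intervals(GenomicRanges::setdiff(full, tr, ignore.strand = TRUE)
  )[, c("chrom", "start", "end")]
}

#' Simulate excision-footprint sequence pairs
#'
#' For each requested footprint length, emits a pre-insertion donor
#' sequence (two flanks joined) and a post-excision sequence carrying
#' that many extra TIR-end-derived bases between the flanks.
#'
#' @param footprint_lengths Integer vector of footprint sizes (>= 0).
#' @param flank_len Length of each invariant flank.
#' @param seed RNG seed.
#' @return A tibble: `pair_id`, `pre`, `post`, `planted_length`.
#' @export
sim_footprint_pairs <- function(footprint_lengths, flank_len = 20L, seed) {
  stopifnot(all(footprint_lengths >= 0))
  tir_end <- "TACAGTTGAAGTCGGAAGTT"  # canonical donor of footprint bases
  withr::with_seed(seed, {
    dplyr::bind_rows(purrr::imap(footprint_lengths, function(fp, i) {
      left <- paste(sample(c("A", "C", "G", "T"), flank_len, replace = TRUE),
                    collapse = "")
      right <- paste(sample(c("A", "C", "G", "T"), flank_len, replace = TRUE),
                     collapse = "")
      extra <- if (fp > 0) substr(tir_end, 1L, fp) else ""
      tibble::tibble(pair_id = paste0("donor", i),
                     pre = paste0(left, right),
                     post = paste0(left, extra, right),
                     planted_length = as.integer(fp))
    }))
  })
}
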