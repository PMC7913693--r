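# mismatch count between two equal-length strings (scalar)
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming: unequal lengths", call. = FALSE)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Extract genomic fragments from transposon-genome junction reads
#'
#' A junction read has the structure `[TIR tag][genomic flank][linker]`.
#' The TIR tag must be present at the read start (up to `max_mismatches`
#' mismatches); the linker suffix is stripped wherever it is first found
#' (again up to `max_mismatches` mismatches over the overlapping part);
#' an optional 3' quality trim is applied before the linker search.
#' Fragments shorter than `min_fragment_len` are rejected. Rejections
#' are categorized, never silently dropped.
#'
#' @param reads Tibble with columns `name`, `sequence`, optional
#'   `quality` (Phred+33).
#' @param tir_tag Transposon TIR tag expected at the read start
#'   (>= 10 bp).
#' @param linker Linker sequence expected at the read end.
#' @param max_mismatches Mismatches tolerated in tag and linker
#'   recognition.
#' @param min_fragment_len Minimum genomic fragment length retained.
#' @param quality_trim Phred threshold for 3' quality trimming, or `NULL`
#'   (default) to disable; synthetic error-free libraries need none.
#' @return A tibble: `name`, `fragment` (NA for rejected reads), `status`
#'   (`ok`, `no_tag`, `too_short`, `all_linker`).
#' @export
extract_genomic_fragment <- function(reads, tir_tag, linker,
                                     max_mismatches = 1L,
                                     min_fragment_len = 25L,
                                     quality_trim = NULL) {
  stopifnot(all(c("name", "sequence") %in% names(reads)))
  if (nchar(tir_tag) < 10) stop("tir_tag must be >= 10 bp", call. = FALSE)
  tir_tag <- toupper(tir_tag); linker <- toupper(linker)
  nt <- nchar(tir_tag); nl <- nchar(linker)
  out <- tibble::tibble(name = reads$name,
                        fragment = NA_character_,
                        status = "no_tag")
  for (i in seq_len(nrow(reads))) {
    s <- toupper(reads$sequence[i])
    if (nchar(s) < nt) next
    if (hamming(substr(s, 1L, nt), tir_tag) > max_mismatches) next
    rem <- substr(s, nt + 1L, nchar(s))
    if (!is.null(quality_trim) && "quality" %in% names(reads) &&
        !is.na(reads$quality[i])) {
      q <- utf8ToInt(substr(reads$quality[i], nt + 1L, nchar(s))) - 33L
      low <- which(q < quality_trim)
      if (length(low) > 0) rem <- substr(rem, 1L, low[1] - 1L)
    }
    nr <- nchar(rem)
    if (nr == 0) { out$status[i] <- "all_linker"; next }
    # first position where the (possibly clipped) linker matches
    cut <- nr + 1L
    if (nl > 0) {
      for (p in seq_len(nr)) {
        cmp_len <- min(nl, nr - p + 1L)
        if (cmp_len <= 0) break
        if (hamming(substr(rem, p, p + cmp_len - 1L),
                    substr(linker, 1L, cmp_len)) <= max_mismatches) {
          cut <- p
          break
        }
      }
    }
    frag <- substr(rem, 1L, cut - 1L)
    if (nchar(frag) == 0) {
      out$status[i] <- "all_linker"
    } else if (nchar(frag) < min_fragment_len) {
      out$status[i] <- "too_short"
    } else {
      out$fragment[i] <- frag
      out$status[i] <- "ok"
    }
  }
  out
}

#' Build a k-mer index of a genome for seed-and-extend mapping
#'
#' Indexes every forward-strand k-mer position with a keyed
#' [data.table::data.table] for constant-time seed lookup.
#'
#' @param genome Genome tibble (`name`, `sequence`).
#' @param seed_len Seed k-mer length (default 16).
#' @return An object of class `genome_index`.
#' @export
build_genome_index <- function(genome, seed_len = 16L) {
  stopifnot(all(c("name", "sequence") %in% names(genome)))
  seed_len <- as.integer(seed_len)
  tabs <- purrr::map2(genome$name, toupper(genome$sequence), function(nm, s) {
    n <- nchar(s)
    if (n < seed_len) return(NULL)
    pos <- seq_len(n - seed_len + 1L)
    data.table::data.table(kmer = substring(s, pos, pos + seed_len - 1L),
                           chrom = nm, pos = pos)
  })
  idx <- data.table::rbindlist(tabs[!vapply(tabs, is.null, logical(1))])
  data.table::setkey(idx, kmer)
  structure(list(genome = dplyr::mutate(genome, sequence = toupper(sequence)),
                 seed_len = seed_len, index = idx),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("<genome_index> ", nrow(x$genome), " contig(s), ",
      sum(nchar(x$genome$sequence)), " bp, seed_len = ", x$seed_len, "\n", sep = "")
  invisible(x)
}

# candidate (chrom, start) pairs for one fragment orientation:
# look up several non-overlapping seeds and translate hits to fragment starts
seed_candidates <- function(fragment, index, max_seeds = 8L) {
  k <- index$seed_len
  nf <- nchar(fragment)
  if (nf < k) return(NULL)
  offsets <- seq(1L, nf - k + 1L, by = k)
  if (length(offsets) > max_seeds) offsets <- offsets[seq_len(max_seeds)]
  seeds <- substring(fragment, offsets, offsets + k - 1L)
  hits <- index$index[data.table::data.table(kmer = seeds), on = "kmer",
                      nomatch = NULL]
  if (nrow(hits) == 0) return(NULL)
  off_by_seed <- offsets[match(hits$kmer, seeds)]
  starts <- hits$pos - off_by_seed + 1L
  unique(data.table::data.table(chrom = hits$chrom, start = starts))
}

#' Map genomic fragments with a single-pass unique-best policy
#'
#' Seed-and-extend against a [build_genome_index()]: several
#' non-overlapping seeds per fragment nominate candidate starts on both
#' strands; each candidate is verified by full-length mismatch counting.
#' A hit is reported only when exactly one location attains the best
#' mismatch count (<= `max_mismatches`) and the second-best candidate is
#' worse by at least `margin` mismatches; otherwise the fragment is
#' `ambiguous`. Start/end are 1-based inclusive on the forward strand;
#' `strand` is the strand the fragment matched.
#'
#' @param fragments Character vector of fragments (NAs pass through as
#'   unmapped).
#' @param index A `genome_index`.
#' @param max_mismatches Maximum mismatches for a reportable hit, or
#'   `NULL` to allow 4% of the fragment length (rounded up).
#' @param margin Required separation (in mismatches) between best and
#'   second-best location.
#' @return A tibble: `fragment`, `chrom`, `start`, `end`, `strand`,
#'   `n_mismatch`, `status` (`unique`, `ambiguous`, `unmapped`).
#' @export
map_fragment <- function(fragments, index, max_mismatches = NULL, margin = 2L) {
  stopifnot(inherits(index, "genome_index"))
  genome_seq <- stats::setNames(index$genome$sequence, index$genome$name)
  n <- length(fragments)
  out <- tibble::tibble(fragment = fragments,
                        chrom = NA_character_, start = NA_integer_,
                        end = NA_integer_, strand = NA_character_,
                        n_mismatch = NA_integer_, status = "unmapped")
  for (i in seq_len(n)) {
    frag <- fragments[i]
    if (is.na(frag)) next
    frag <- toupper(frag)
    nf <- nchar(frag)
    if (nf < index$seed_len) next
    mm_cap <- if (is.null(max_mismatches)) ceiling(0.04 * nf) else max_mismatches
    cand <- list(`+` = seed_candidates(frag, index),
                 `-` = seed_candidates(revcomp(frag), index))
    hits <- NULL
    for (strand in c("+", "-")) {
      cc <- cand[[strand]]
      if (is.null(cc) || nrow(cc) == 0) next
      query <- if (strand == "+") frag else revcomp(frag)
      for (j in seq_len(nrow(cc))) {
        st <- cc$start[j]
        gseq <- genome_seq[[cc$chrom[j]]]
        if (is.null(gseq) || st < 1L || st + nf - 1L > nchar(gseq)) next
        mm <- hamming(substr(gseq, st, st + nf - 1L), query)
        hits <- rbind(hits, data.frame(chrom = cc$chrom[j], start = st,
                                       strand = strand, mm = mm))
      }
    }
    if (is.null(hits)) next
    hits <- hits[hits$mm <= mm_cap + margin, , drop = FALSE]  # keep near-misses for margin test
    best_hits <- hits[hits$mm <= mm_cap, , drop = FALSE]
    if (nrow(best_hits) == 0) next
    b <- min(best_hits$mm)
    at_best <- best_hits[best_hits$mm == b, , drop = FALSE]
    second <- sort(hits$mm[hits$mm > b])
    sep_ok <- length(second) == 0 || (second[1] - b) >= margin
    if (nrow(at_best) == 1 && sep_ok) {
      out$chrom[i] <- at_best$chrom
      out$start[i] <- at_best$start
      out$end[i] <- at_best$start + nf - 1L
      out$strand[i] <- at_best$strand
      out$n_mismatch[i] <- b
      out$status[i] <- "unique"
    } else {
      out$status[i] <- "ambiguous"
    }
  }
  out
}

#' Call transposon insertion sites from junction reads
#'
#' Full pipeline: tag/linker trimming ([extract_genomic_fragment()]),
#' unique-best mapping ([map_fragment()]), optional PCR-duplicate
#' collapsing (identical mapped start and fragment length), conversion of
#' each mapped fragment to its TA target locus, deduplication of reads to
#' sites, and TA validation against the reference.
#'
#' The genomic flank of a junction read begins with the duplicated TA, so
#' a fragment mapping forward at start `s` places the TA's T at `s`
#' (element on the plus strand); a fragment mapping in reverse with end
#' `e` places the T at `e - 1` (element on the minus strand). Sites
#' failing TA validation are retained but flagged.
#'
#' @param reads Read tibble (`name`, `sequence`, optional `quality`).
#' @param genome Genome tibble or a prebuilt `genome_index`.
#' @param tir_tag,linker Library structure strings.
#' @param max_mismatches,min_fragment_len,quality_trim Passed to
#'   [extract_genomic_fragment()].
#' @param map_max_mismatches,margin,seed_len Mapper settings.
#' @param collapse_duplicates Collapse PCR duplicates (same mapped start,
#'   strand and fragment length) before counting read support.
#' @param min_read_count Minimum deduplicated read support to keep a site
#'   (default 1, i.e. no filter).
#' @return An object of class `insertion_calls`: a list with `sites` (a
#'   tibble `chrom`, `ta_pos` 1-based, `strand`, `read_count`,
#'   `ta_validated`), `rejections` (a tibble of per-category read
#'   counts), and `params`. Use [tidy.insertion_calls()] /
#'   [glance.insertion_calls()].
#' @export
call_insertions <- function(reads, genome, tir_tag, linker,
                            max_mismatches = 1L, min_fragment_len = 25L,
                            quality_trim = NULL,
                            map_max_mismatches = NULL, margin = 2L,
                            seed_len = 16L,
                            collapse_duplicates = TRUE,
                            min_read_count = 1L) {
  index <- if (inherits(genome, "genome_index")) genome else
    build_genome_index(genome, seed_len = seed_len)
  genome_seq <- stats::setNames(index$genome$sequence, index$genome$name)
  params <- list(tir_tag = tir_tag, linker = linker,
                 max_mismatches = max_mismatches,
                 min_fragment_len = min_fragment_len,
                 map_max_mismatches = map_max_mismatches,
                 margin = margin, seed_len = index$seed_len,
                 collapse_duplicates = collapse_duplicates,
                 min_read_count = min_read_count)
  empty_sites <- tibble::tibble(chrom = character(), ta_pos = integer(),
                                strand = character(), read_count = integer(),
                                ta_validated = logical())
  if (nrow(reads) == 0) {
    res <- list(sites = empty_sites,
                rejections = tibble::tibble(reason = character(), n = integer()),
                params = params)
    class(res) <- "insertion_calls"
    return(res)
  }
  frags <- extract_genomic_fragment(reads, tir_tag, linker,
                                    max_mismatches = max_mismatches,
                                    min_fragment_len = min_fragment_len,
                                    quality_trim = quality_trim)
  mapped <- map_fragment(frags$fragment, index,
                         max_mismatches = map_max_mismatches, margin = margin)
  status <- ifelse(frags$status != "ok", frags$status,
                   ifelse(mapped$status == "unique", "mapped", mapped$status))
  rejections <- dplyr::count(tibble::tibble(reason = status), .data$reason,
                             name = "n")
  ok <- which(status == "mapped")
  if (length(ok) == 0) {
    res <- list(sites = empty_sites, rejections = rejections, params = params)
    class(res) <- "insertion_calls"
    return(res)
  }
  hits <- mapped[ok, ]
  hits$frag_len <- nchar(hits$fragment)
  if (collapse_duplicates) {
    hits <- dplyr::distinct(hits, .data$chrom, .data$start, .data$strand,
                            .data$frag_len, .keep_all = TRUE)
  }
  hits$ta_pos <- ifelse(hits$strand == "+", hits$start, hits$end - 1L)
  sites <- hits |>
    dplyr::count(.data$chrom, .data$ta_pos, .data$strand, name = "read_count") |>
    dplyr::filter(.data$read_count >= min_read_count) |>
    dplyr::arrange(.data$chrom, .data$ta_pos)
  dinuc <- substr(genome_seq[sites$chrom], sites$ta_pos, sites$ta_pos + 1L)
  sites$ta_validated <- !is.na(dinuc) & dinuc == "TA"
  res <- list(sites = tibble::as_tibble(sites), rejections = rejections,
              params = params)
  class(res) <- "insertion_calls"
  res
}

#' @export
print.insertion_calls <- function(x, ...) {
  cat("<insertion_calls> ", nrow(x$sites), " site(s), ",
      sum(x$sites$read_count), " supporting read(s); ",
      sum(x$sites$ta_validated), " TA-validated\n", sep = "")
  if (nrow(x$rejections) > 0) {
    cat("read fates: ",
        paste0(x$rejections$reason, "=", x$rejections$n, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Broom-style accessors for insertion calls
#'
#' `tidy()` returns the per-site table; `glance()` a one-row summary.
#'
#' @param x An `insertion_calls` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.insertion_calls <- function(x, ...) x$sites

#' @rdname tidy.insertion_calls
#' @export
glance.insertion_calls <- function(x, ...) {
  n_reads <- sum(x$rejections$n)
  mapped <- x$rejections$n[x$rejections$reason == "mapped"]
  tibble::tibble(
    n_reads = n_reads,
    n_mapped = if (length(mapped)) mapped else 0L,
    n_sites = nrow(x$sites),
    n_ta_validated = sum(x$sites$ta_validated),
    mean_read_count = if (nrow(x$sites)) mean(x$sites$read_count) else NA_real_
  )
}
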