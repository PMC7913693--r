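#' Germline-mobilization litter frequencies
#'
#' Pools litter records into the three headline rates of a sperm-
#' mutagenesis screen: PCR-positive frequency (transgene-positive pups /
#' pups), new-insertion (re-transposition) frequency (new insertions /
#' PCR positives), and enhancer-trap frequency (visibly GFP-positive pups
#' / pups). Totals are ratios of summed numerators and denominators,
#' never means of per-litter ratios.
#'
#' @param records Tibble with columns `n_pups`, `n_pcr_positive`,
#'   `n_new_insertion`, `n_gfp_positive`, optionally `library`.
#' @param per_library Also emit per-library rows before the total.
#' @return A tibble with columns `library` (`"total"` for the pooled
#'   row), the summed counts, and `pcr_positive_freq`,
#'   `new_insertion_freq`, `et_freq` plus `*_pct` percentage columns.
#'   Ratios with zero denominators are `NA`.
#' @examples
#' litter_frequencies(zb_mouse_litters())
#' @export
litter_frequencies <- function(records, per_library = FALSE) {
  needed <- c("n_pups", "n_pcr_positive", "n_new_insertion", "n_gfp_positive")
  stopifnot(all(needed %in% names(records)))
  bad <- records$n_new_insertion > records$n_pcr_positive |
    records$n_pcr_positive > records$n_pups |
    records$n_gfp_positive > records$n_pups
  if (any(bad, na.rm = TRUE)) {
    stop("litter record violates count invariants at row ", which(bad)[1],
         call. = FALSE)
  }
  summarise_group <- function(df, label) {
    pups <- sum(df$n_pups); pcr <- sum(df$n_pcr_positive)
    new <- sum(df$n_new_insertion); gfp <- sum(df$n_gfp_positive)
    ratio <- function(num, den) if (den > 0) num / den else NA_real_
    tibble::tibble(
      library = label, n_pups = pups, n_pcr_positive = pcr,
      n_new_insertion = new, n_gfp_positive = gfp,
      pcr_positive_freq = ratio(pcr, pups),
      new_insertion_freq = ratio(new, pcr),
      et_freq = ratio(gfp, pups)
    )
  }
  out <- summarise_group(records, "total")
  if (per_library && "library" %in% names(records)) {
    per <- records |>
      dplyr::group_by(.data$library) |>
      dplyr::group_map(~ summarise_group(.x, .y$library)) |>
      dplyr::bind_rows()
    out <- dplyr::bind_rows(per, out)
  }
  dplyr::mutate(out,
                pcr_positive_pct = 100 * .data$pcr_positive_freq,
                new_insertion_pct = 100 * .data$new_insertion_freq,
                et_pct = 100 * .data$et_freq)
}

#' Distance of mobilization events from the donor (origin) locus
#'
#' Same-chromosome events get the absolute bp distance between the two
#' 1-based points; different-chromosome events are undefined (NA,
#' rendered `"-"`). The printed rendering switches from exact bp below
#' 1 Mb to one-decimal Mb at or above it (the mixed style of published
#' mobilization tables).
#'
#' @param origin A `"chrom:pos"` string or one-row tibble (`chrom`,
#'   `pos`) for the donor locus.
#' @param events Tibble of event loci (`chrom`, `pos`; NA pos =
#'   unmapped). Other columns are carried through.
#' @return `events` with added `distance_bp` (NA when undefined) and
#'   `distance_label` columns.
#' @examples
#' distance_from_origin("Chr13:102860981",
#'                      tibble::tibble(chrom = "Chr13", pos = 102860624))
#' @export
distance_from_origin <- function(origin, events) {
  if (is.character(origin)) origin <- parse_locus(origin)
  stopifnot(all(c("chrom", "pos") %in% names(events)))
  same <- !is.na(events$pos) & events$chrom == origin$chrom[1]
  d <- ifelse(same, abs(events$pos - origin$pos[1]), NA_real_)
  dplyr::mutate(events,
                distance_bp = d,
                distance_label = format_distance(d))
}

#' @rdname distance_from_origin
#' @param distance_bp Numeric distances in bp (NA = undefined).
#' @param mb_threshold Distances at or above this switch to Mb rendering.
#' @export
format_distance <- function(distance_bp, mb_threshold = 1e6) {
  ifelse(is.na(distance_bp), "-",
         ifelse(distance_bp >= mb_threshold,
                sprintf("%.1f Mb", distance_bp / 1e6),
                paste0(format(distance_bp, scientific = FALSE, trim = TRUE),
                       " bp")))
}

#' Local-hopping fraction of mobilization events
#'
#' Cut-and-paste transposons tend to reinsert near the donor site; the
#' crudest signature is the fraction of mapped re-transposition events
#' landing on the donor chromosome.
#'
#' @inheritParams distance_from_origin
#' @return A one-row tibble: `n_same_chrom`, `n_mapped`, `fraction`
#'   (NA when nothing is mapped).
#' @export
local_hopping_fraction <- function(origin, events) {
  if (is.character(origin)) origin <- parse_locus(origin)
  mapped <- !is.na(events$pos) & !is.na(events$chrom)
  n_same <- sum(mapped & events$chrom == origin$chrom[1])
  n_mapped <- sum(mapped)
  tibble::tibble(n_same_chrom = n_same, n_mapped = n_mapped,
                 fraction = if (n_mapped > 0) n_same / n_mapped else NA_real_)
}

#' Classify an excision footprint at a donor site
#'
#' After excision of a cut-and-paste transposon, repair of the donor site
#' typically leaves a few extra bases (0-3 bp for ZB-like elements)
#' between the flanks that were invariant around the insertion. The
#' classifier anchors the longest common prefix and suffix of the
#' pre-insertion donor sequence and the recovered post-excision sequence;
#' the unmatched middle of the post sequence is the footprint.
#'
#' @param pre_seq Pre-insertion (empty) donor-site sequence.
#' @param post_seq Recovered post-excision sequence.
#' @param flank_len Minimum identical flank required on both sides.
#' @return A one-row tibble: `extra_bases` (string, possibly empty),
#'   `length` (bp).
#' @examples
#' classify_footprint("AAAACCCCGGGGTTTT", "AAAACCCCTAGGGGTTTT", flank_len = 4)
#' @export
classify_footprint <- function(pre_seq, post_seq, flank_len = 8L) {
  pre <- toupper(pre_seq); post <- toupper(post_seq)
  a <- seq_chars(pre); b <- seq_chars(post)
  # longest common prefix / suffix
  nmin <- min(length(a), length(b))
  pref_eq <- a[seq_len(nmin)] == b[seq_len(nmin)]
  lcp <- if (all(pref_eq)) nmin else which(!pref_eq)[1] - 1L
  suf_eq <- rev(a)[seq_len(nmin)] == rev(b)[seq_len(nmin)]
  lcs <- if (all(suf_eq)) nmin else which(!suf_eq)[1] - 1L
  if (lcp < flank_len || lcs < flank_len) {
    stop("unrecognized donor: flanks not found in post-excision sequence",
         call. = FALSE)
  }
  # avoid double-counting when prefix and suffix overlap in the shorter string
  overlap <- max(0L, lcp + lcs - length(a))
  lcs_adj <- lcs - overlap
  extra <- substr(post, lcp + 1L, length(b) - lcs_adj)
  pre_mid <- substr(pre, lcp + 1L, length(a) - lcs_adj)
  if (nzchar(pre_mid)) {
    stop("unrecognized donor: pre-insertion sequence not fully anchored",
         call. = FALSE)
  }
  tibble::tibble(extra_bases = extra, length = nchar(extra))
}

#' Validate the TA target-site duplication in a junction sequence
#'
#' A genuine Tc1/mariner junction reads
#' `[genomic flank][TA][start of the TIR]`: the two bases immediately 5'
#' of the TIR-start text must be `TA` (case-insensitive).
#'
#' @param junction_sequence Character vector of junction sequences.
#' @param tir_start Text with which the transposon TIR begins in the
#'   junction reads.
#' @return Logical vector; errors if the TIR-start text is absent from
#'   any junction.
#' @examples
#' validate_junction_tsd("aaaacgacagcacaTAcagcgggga", "cagcgggga")
#' @export
validate_junction_tsd <- function(junction_sequence, tir_start) {
  jx <- toupper(junction_sequence)
  tir <- toupper(tir_start)
  at <- vapply(jx, function(s) {
    p <- regexpr(tir, s, fixed = TRUE)
    as.integer(p)
  }, integer(1), USE.NAMES = FALSE)
  if (any(at < 1L)) {
    stop("TIR-start text not found in junction(s): ",
         paste(utils::head(which(at < 1L), 3), collapse = ", "), call. = FALSE)
  }
  at >= 3L & substr(jx, at - 2L, at - 1L) == "TA"
}

#' Summarize a mobilization-event table against its origin
#'
#' Adds distances from the origin and returns them together with the
#' local-hopping summary; the one-stop analysis for an annotated
#' germline mobilization table.
#'
#' @param events Event tibble as from [zb_mouse_events()] (the row with
#'   `role == "origin"` defines the donor locus when `origin` is NULL).
#' @param origin Optional `"chrom:pos"` override for the donor locus.
#' @return A list with `events` (with distance columns) and `hopping`
#'   (one-row tibble).
#' @export
mobilization_summary <- function(events, origin = NULL) {
  if (is.null(origin)) {
    stopifnot("role" %in% names(events))
    org <- events[events$role == "origin", , drop = FALSE]
    if (nrow(org) != 1) stop("expected exactly one origin row", call. = FALSE)
    origin <- tibble::tibble(chrom = org$chrom, pos = org$pos)
    events <- events[events$role != "origin", , drop = FALSE]
  } else if (is.character(origin)) {
    origin <- parse_locus(origin)
  }
  ev <- distance_from_origin(origin, events)
  list(events = ev, hopping = local_hopping_fraction(origin, events))
}
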