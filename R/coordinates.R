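#' Coordinate conventions
#'
#' All interval coordinates inside the package are 0-based half-open
#' (BED convention): an interval `[start, end)` covers `end - start` bases
#' and `start >= 0`. All human-facing point loci are 1-based, in the
#' `chrom:pos` style used by genome browsers. Conversion between the two
#' conventions goes through exactly one pair of functions so that no
#' ad-hoc off-by-one arithmetic exists elsewhere.
#'
#' @param pos 1-based point position(s).
#' @param start 0-based position(s).
#' @return An integer vector in the other convention.
#' @examples
#' locus_to_internal(1)   # 0
#' internal_to_locus(0)   # 1
#' @name coordinates
NULL

#' @rdname coordinates
#' @export
locus_to_internal <- function(pos) {
  pos <- as.integer(pos)
  if (any(pos < 1L, na.rm = TRUE)) stop("1-based positions must be >= 1", call. = FALSE)
  pos - 1L
}

#' @rdname coordinates
#' @export
internal_to_locus <- function(start) {
  start <- as.integer(start)
  if (any(start < 0L, na.rm = TRUE)) stop("0-based positions must be >= 0", call. = FALSE)
  start + 1L
}

#' Parse a browser-style locus string
#'
#' Parses `"chrom:pos"` text (as printed in genome browsers and in
#' germline-insertion tables, e.g. `"Chr13:102860981"`) into a one-row-per-
#' input tibble of 1-based point loci. Whitespace after the colon is
#' tolerated because published tables are not always consistent about it.
#'
#' @param text Character vector of `"chrom:pos"` strings.
#' @return A tibble with columns `chrom` (character) and `pos` (1-based
#'   integer position).
#' @examples
#' parse_locus("Chr13:102860981")
#' parse_locus("Chr13: 102860526")
#' @export
parse_locus <- function(text) {
  stopifnot(is.character(text))
  m <- stringr::str_match(text, "^\\s*([^:\\s]+)\\s*:\\s*(\\d+)\\s*$")
  bad <- which(is.na(m[, 1]))
  if (length(bad) > 0) {
    stop("cannot parse locus string(s): ",
         paste(utils::head(text[bad], 3), collapse = ", "),
         " (expected \"chrom:pos\")", call. = FALSE)
  }
  pos <- suppressWarnings(as.numeric(m[, 3]))
  tibble::tibble(chrom = m[, 2], pos = as.integer(round(pos)))
}

#' @rdname parse_locus
#' @param chrom,pos Chromosome names and 1-based positions to format.
#' @export
format_locus <- function(chrom, pos) {
  paste0(chrom, ":", format(as.integer(pos), scientific = FALSE, trim = TRUE))
}

# validate a tibble of 0-based half-open intervals; returns invisibly
check_intervals <- function(df, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom))) {
    stop(what, ": chrom must be non-empty", call. = FALSE)
  }
  if (any(df$start < 0)) stop(what, ": start must be >= 0", call. = FALSE)
  if (any(df$end <= df$start)) {
    i <- which(df$end <= df$start)[1]
    stop(what, ": end <= start at row ", i, call. = FALSE)
  }
  invisible(df)
}

# tibble intervals (0-based half-open) -> GRanges (1-based closed)
intervals_to_granges <- function(df, seqlengths = NULL) {
  check_intervals(df)
  strand <- if ("strand" %in% names(df)) {
    s <- df$strand
    s[is.na(s) | !(s %in% c("+", "-"))] <- "*"
    s
  } else rep("*", nrow(df))
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  if (!is.null(seqlengths)) {
    GenomicRanges::seqlengths(gr) <- seqlengths[GenomicRanges::seqlevels(gr)]
  }
  gr
}

# GRanges -> tibble intervals (0-based half-open)
granges_to_intervals <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}
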