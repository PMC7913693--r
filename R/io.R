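#' Read a FASTA file into a tibble
#'
#' Records are returned in file order, names truncated at the first
#' whitespace, sequences uppercased. Parsing is delegated to
#' [Biostrings::readDNAStringSet()] after a light structural validation
#' pass that reports the offending line number for malformed input.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `name` and `sequence`.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a desc", "ac", "gt", ">b", "TT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA: first record line ", nonblank[1],
         " does not start with '>'", call. = FALSE)
  }
  hdr <- which(startsWith(lines, ">"))
  # every header must be followed by at least one sequence line before the next
  nxt <- c(hdr[-1], length(lines) + 1L)
  for (i in seq_along(hdr)) {
    body <- lines[seq.int(hdr[i] + 1L, length.out = max(0L, nxt[i] - hdr[i] - 1L))]
    if (sum(nzchar(trimws(body))) == 0) {
      stop("malformed FASTA: empty record at line ", hdr[i], call. = FALSE)
    }
  }
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  tibble::tibble(
    name = sub("\\s.*$", "", names(seqs)),
    sequence = unname(toupper(as.character(seqs)))
  )
}

#' Write a tibble of sequences as FASTA
#'
#' @param x A tibble with columns `name` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(all(c("name", "sequence") %in% names(x)))
  set <- Biostrings::DNAStringSet(x$sequence)
  names(set) <- x$name
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' Quality strings (Sanger Phred+33) are parsed and carried alongside the
#' sequence; downstream steps use them only when quality trimming is
#' explicitly enabled.
#'
#' @param path Path to a FASTQ file.
#' @return A tibble with columns `name`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble::tibble(
    name = sub("\\s.*$", "", names(seqs)),
    sequence = unname(toupper(as.character(seqs))),
    quality = unname(as.character(S4Vectors::mcols(seqs)$qualities))
  )
}

#' Write a tibble of reads as FASTQ
#'
#' @param x A tibble with columns `name`, `sequence` and optionally
#'   `quality` (defaults to maximal quality "I").
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  stopifnot(all(c("name", "sequence") %in% names(x)))
  qual <- if ("quality" %in% names(x)) x$quality else
    strrep("I", nchar(x$sequence))
  out <- character(4L * nrow(x))
  out[seq(1, length(out), by = 4)] <- paste0("@", x$name)
  out[seq(2, length(out), by = 4)] <- x$sequence
  out[seq(3, length(out), by = 4)] <- "+"
  out[seq(4, length(out), by = 4)] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Read a BED file into a tibble of 0-based half-open intervals
#'
#' BED3 or BED6; optional columns 4-6 are mapped to `name`, `score`,
#' `strand`. Coordinate errors are reported with their line number.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end` and, when
#'   present in the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(lines) & !startsWith(lines, "#") &
                  !startsWith(lines, "track") & !startsWith(lines, "browser"))
  if (length(keep) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncol <- vapply(fields, length, integer(1))
  if (any(ncol < 3)) {
    stop("BED parse error at line ", keep[which(ncol < 3)[1]],
         ": fewer than 3 tab-separated columns", call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop("BED parse error at line ", keep[bad], ": non-integer coordinate",
         call. = FALSE)
  }
  if (any(end <= start)) {
    bad <- which(end <= start)[1]
    stop("BED parse error at line ", keep[bad], ": end <= start", call. = FALSE)
  }
  out <- tibble::tibble(chrom = chrom, start = start, end = end)
  if (all(ncol >= 4)) out$name <- vapply(fields, `[[`, character(1), 4L)
  if (all(ncol >= 5)) {
    out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 5L)))
  }
  if (all(ncol >= 6)) out$strand <- vapply(fields, `[[`, character(1), 6L)
  check_intervals(out, "BED")
  out
}

#' Write a tibble of intervals as BED
#'
#' @param x A tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open), optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x, "BED")
  cols <- c("chrom", "start", "end")
  for (extra in c("name", "score", "strand")) {
    if (extra %in% names(x)) cols <- c(cols, extra) else break
  }
  df <- as.data.frame(x[, cols])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write tab-separated result tables with a comment header
#'
#' All tabular outputs of the pipeline are TSV with `#`-prefixed header
#' lines recording the tool version, seed and parameters of the run;
#' `read_result_tsv()` skips those lines.
#'
#' @param x A data frame to write.
#' @param path File path.
#' @param params Named list recorded in the comment header.
#' @return For the writer, `path` invisibly; for the reader, a tibble.
#' @export
write_result_tsv <- function(x, path, params = list()) {
  hdr <- c(
    paste0("# tcmariner ", as.character(utils::packageVersion("tcmariner"))),
    paste0("# date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    if (length(params) > 0) {
      paste0("# ", names(params), ": ",
             vapply(params, function(p) paste(format(p), collapse = ","), character(1)))
    }
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_result_tsv
#' @export
read_result_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Built-in germline-mobilization tables
#'
#' Accessors for the small plain-text tables shipped with the package:
#' the mouse sperm-mutagenesis litter table (per-litter pup counts, PCR
#' positives, new insertions and GFP positives for four double-transgenic
#' seed males), the annotated mobilization-event table (junction
#' sequences, reinsertion loci, nearest gene, orientation and GFP status,
#' with the founder line `TnE2` as the origin), and the transgenic-founder
#' birth counts underlying the transgenesis rates.
#'
#' @return A tibble.
#' @examples
#' zb_mouse_litters()
#' @export
zb_mouse_litters <- function() {
  readr::read_tsv(
    system.file("extdata", "mouse_litters.tsv", package = "tcmariner"),
    comment = "#", show_col_types = FALSE
  )
}

#' @rdname zb_mouse_litters
#' @export
zb_mouse_events <- function() {
  readr::read_tsv(
    system.file("extdata", "mouse_mobilization_events.tsv", package = "tcmariner"),
    comment = "#", show_col_types = FALSE
  )
}

#' @rdname zb_mouse_litters
#' @export
zb_mouse_transgenesis <- function() {
  readr::read_tsv(
    system.file("extdata", "mouse_transgenesis.tsv", package = "tcmariner"),
    comment = "#", show_col_types = FALSE
  )
}
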