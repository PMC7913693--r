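# helpers ---------------------------------------------------------------

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# split a scalar sequence into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Detect terminal inverted repeats (TIRs)
#'
#' Tc1/mariner elements are delimited by terminal inverted repeats: the
#' first L bases of the element match the reverse complement of its last
#' L bases. The scan is anchored at the two termini (no interior search)
#' and returns the longest arm length in `[min_len, max_len]` whose
#' arm-vs-arm identity reaches `min_identity`.
#'
#' @param sequence Element nucleotide sequence (single string).
#' @param min_len,max_len Allowed arm lengths in bp.
#' @param min_identity Minimum fraction of matching positions between the
#'   5' arm and the reverse complement of the 3' arm (0.5-1).
#' @return A one-row tibble (`length`, `identity`, `offset5`, `offset3`)
#'   or a zero-row tibble when no qualifying arm exists. Offsets are
#'   0-based starts of the two arms within the element.
#' @examples
#' arm <- strrep("ACGT", 8)
#' el <- paste0(arm, strrep("T", 50),
#'              as.character(Biostrings::reverseComplement(Biostrings::DNAString(arm))))
#' find_tirs(el, min_len = 10, max_len = 40)
#' @export
find_tirs <- function(sequence, min_len = 20L, max_len = 250L, min_identity = 0.9) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (min_len > max_len) stop("min_len > max_len", call. = FALSE)
  if (min_identity < 0.5 || min_identity > 1) {
    stop("min_identity must be in [0.5, 1]", call. = FALSE)
  }
  n <- nchar(sequence)
  if (n < 2L * min_len) stop("element shorter than 2 * min_len", call. = FALSE)
  max_len <- min(max_len, n %/% 2L)
  ch <- seq_chars(toupper(sequence))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # m[i]: does prefix base i match the revcomp of the suffix at depth i?
  idx <- seq_len(max_len)
  m <- ch[idx] == unname(comp[ch[n + 1L - idx]])
  m[is.na(m)] <- FALSE
  ident <- cumsum(m) / idx
  # an arm must end on a matching base (trailing mismatches are trimmed,
  # otherwise a perfect arm could be "extended" by pure mismatch padding)
  ok <- which(idx >= min_len & ident >= min_identity & m)
  empty <- tibble::tibble(length = integer(), identity = numeric(),
                          offset5 = integer(), offset3 = integer())
  if (length(ok) == 0) return(empty)
  L <- max(ok)
  tibble::tibble(length = L, identity = ident[L],
                 offset5 = 0L, offset3 = n - L)
}

#' Check the target site duplication flanking a genomic copy
#'
#' Cut-and-paste integration of Tc1/mariner elements duplicates the TA
#' target dinucleotide, so a genuine copy is flanked by the same short
#' text on both sides. Returns that text when the `tsd_len` bases
#' immediately 5' of the copy equal the `tsd_len` bases immediately 3' of
#' it, `NA` otherwise. Copies at a contig edge (no room for a flank)
#' return `NA` with a warning rather than an error.
#'
#' @param genome Genome tibble (`name`, `sequence`) as from [read_fasta()].
#' @param chrom Contig name holding the copy.
#' @param start,end Copy interval, 0-based half-open.
#' @param tsd_len Duplication length to test (2 for the TA of
#'   Tc1/mariner).
#' @return The duplicated text (e.g. `"TA"`) or `NA_character_`.
#' @export
detect_tsd <- function(genome, chrom, start, end, tsd_len = 2L) {
  seq <- genome$sequence[match(chrom, genome$name)]
  if (is.na(seq)) stop("contig not found: ", chrom, call. = FALSE)
  n <- nchar(seq)
  if (start - tsd_len < 0 || end + tsd_len > n) {
    warning("copy at contig edge, no room for a ", tsd_len, "-bp flank",
            call. = FALSE)
    return(NA_character_)
  }
  left <- substr(seq, start - tsd_len + 1L, start)        # 1-based: (start-tsd+1)..start
  right <- substr(seq, end + 1L, end + tsd_len)
  if (toupper(left) == toupper(right)) toupper(left) else NA_character_
}

#' Find the longest open reading frame of an element
#'
#' Scans all six frames (or three, if `both_strands = FALSE`) for
#' ATG-initiated ORFs under the standard genetic code and returns the
#' longest one of at least `min_aa` codons. Autonomous Tc1/mariner
#' elements carry a single transposase ORF of roughly 300-400 aa.
#'
#' @param sequence Element nucleotide sequence.
#' @param both_strands Also scan the reverse complement.
#' @param min_aa Minimum protein length (amino acids, stop excluded).
#' @return A one-row tibble (`start`, `end`, `strand`, `protein`,
#'   `aa_length`) with the ORF interval 0-based half-open on the input
#'   sequence (stop codon included in the interval), or a zero-row tibble
#'   when no qualifying ORF exists.
#' @export
find_longest_orf <- function(sequence, both_strands = TRUE, min_aa = 300L) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  empty <- tibble::tibble(start = integer(), end = integer(),
                          strand = character(), protein = character(),
                          aa_length = integer())
  strands <- if (both_strands) c("+", "-") else "+"
  best <- NULL
  for (strand in strands) {
    s <- if (strand == "+") sequence else revcomp(sequence)
    for (frame in 0:2) {
      ncod <- (n - frame) %/% 3L
      if (ncod < 2) next
      codons <- substring(s, frame + 1L + 3L * (seq_len(ncod) - 1L),
                          frame + 3L * seq_len(ncod))
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      is_atg <- codons == "ATG"
      stop_idx <- which(is_stop)
      prev_stop <- 0L
      for (st in stop_idx) {
        if (st - 1L < prev_stop + 1L) { prev_stop <- st; next }
        region <- seq.int(prev_stop + 1L, st - 1L)
        atg <- region[is_atg[region]]
        if (length(atg) > 0) {
          a <- atg[1]
          aa_len <- st - a  # codons from ATG to just before stop
          if (aa_len >= min_aa && (is.null(best) || aa_len > best$aa_length)) {
            # interval on the scanned strand, 0-based, stop codon included
            s_start <- frame + 3L * (a - 1L)
            s_end <- frame + 3L * st
            if (strand == "+") {
              start <- s_start; end <- s_end
            } else {
              start <- n - s_end; end <- n - s_start
            }
            prot_dna <- substring(s, s_start + 1L, s_end - 3L)
            protein <- as.character(Biostrings::translate(
              Biostrings::DNAString(prot_dna), no.init.codon = TRUE))
            best <- list(start = start, end = end, strand = strand,
                         protein = protein, aa_length = aa_len)
          }
        }
        prev_stop <- st
      }
    }
  }
  if (is.null(best)) return(empty)
  tibble::tibble(start = as.integer(best$start), end = as.integer(best$end),
                 strand = best$strand, protein = best$protein,
                 aa_length = as.integer(best$aa_length))
}

#' Classify a transposase by its DDE/D catalytic triad spacing
#'
#' Tc1/mariner family labels encode the spacing of the three acidic
#' catalytic residues: DD34E for the Tc1 group, DD37E for TRT, DDxD for
#' pogo. The scan enumerates residue triples (D, D, X in {D, E}) whose
#' two gaps fall inside configurable windows, scores each candidate by
#' the acidic-residue content of the 11-residue context around its three
#' positions (a crude stand-in for the conservation profile a reference
#' alignment would give), and labels the element after the best-scoring
#' triad.
#'
#' @param protein Amino-acid string.
#' @param gap1_window Allowed first gap (positions between D1 and D2),
#'   default 60-120.
#' @param gap2_window Allowed second gap (D2 to the final D/E), default
#'   25-45.
#' @return A one-row tibble (`label`, `d1`, `d2`, `x`, `x_residue`,
#'   `gap1`, `gap2`, `score`) with 1-based residue positions; `label` is
#'   `"DD<gap2>E/Tc1-like"`, `"DDxD/pogo-like"`, or `"unclassified"`.
#' @export
classify_catalytic_family <- function(protein,
                                      gap1_window = c(60L, 120L),
                                      gap2_window = c(25L, 45L)) {
  stopifnot(is.character(protein), length(protein) == 1)
  if (!nzchar(protein)) stop("empty protein", call. = FALSE)
  aa <- seq_chars(toupper(protein))
  d_pos <- which(aa == "D")
  de_pos <- which(aa %in% c("D", "E"))
  unclassified <- tibble::tibble(label = "unclassified", d1 = NA_integer_,
                                 d2 = NA_integer_, x = NA_integer_,
                                 x_residue = NA_character_, gap1 = NA_integer_,
                                 gap2 = NA_integer_, score = NA_real_)
  if (length(d_pos) < 2 || length(de_pos) < 3) return(unclassified)
  acidic <- aa %in% c("D", "E")
  context_score <- function(p) {
    lo <- pmax(1L, p - 5L); hi <- pmin(length(aa), p + 5L)
    sum(acidic[lo:hi]) / (hi - lo + 1L)
  }
  best <- NULL
  for (d1 in d_pos) {
    d2s <- d_pos[d_pos - d1 >= gap1_window[1] & d_pos - d1 <= gap1_window[2]]
    for (d2 in d2s) {
      xs <- de_pos[de_pos - d2 >= gap2_window[1] & de_pos - d2 <= gap2_window[2]]
      for (x in xs) {
        sc <- context_score(d1) + context_score(d2) + context_score(x)
        if (is.null(best) || sc > best$score) {
          best <- list(d1 = d1, d2 = d2, x = x, score = sc)
        }
      }
    }
  }
  if (is.null(best)) return(unclassified)
  gap2 <- best$x - best$d2
  x_res <- aa[best$x]
  label <- if (x_res == "E") paste0("DD", gap2, "E/Tc1-like") else "DDxD/pogo-like"
  tibble::tibble(label = label, d1 = best$d1, d2 = best$d2, x = best$x,
                 x_residue = x_res, gap1 = best$d2 - best$d1,
                 gap2 = gap2, score = best$score)
}

#' Scan a transposase for simple GRPR-like and NLS-like motifs
#'
#' Lightweight surrogates for dedicated predictors: `grpr_like` is the
#' presence of a G-R-\[PK\]-R tetrapeptide within the N-terminal third of
#' the protein (the AT-hook-like GRPR motif of Tc1/mariner DNA-binding
#' domains); `nls_like` is a 6-residue window containing at least 4 basic
#' residues (K/R).
#'
#' @param protein Amino-acid string.
#' @return A one-row tibble (`grpr_like`, `grpr_pos`, `nls_like`,
#'   `nls_pos`) with 1-based match starts or `NA`.
#' @export
scan_simple_motifs <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1)
  protein <- toupper(protein)
  n <- nchar(protein)
  m <- stringr::str_locate(protein, "GR[PK]R")
  grpr_like <- !is.na(m[1, "start"]) && m[1, "start"] <= max(1L, floor(n / 3))
  grpr_pos <- if (grpr_like) as.integer(m[1, "start"]) else NA_integer_
  nls_pos <- NA_integer_
  if (n >= 6) {
    aa <- seq_chars(protein)
    basic <- as.integer(aa %in% c("K", "R"))
    win <- stats::filter(basic, rep(1, 6), sides = 1)  # sum over trailing 6
    hit <- which(!is.na(win) & win >= 4)
    if (length(hit) > 0) nls_pos <- as.integer(hit[1] - 5L)
  }
  tibble::tibble(grpr_like = grpr_like, grpr_pos = grpr_pos,
                 nls_like = !is.na(nls_pos), nls_pos = nls_pos)
}

#' Percent identity between two nucleotide sequences
#'
#' Equal-length sequences are compared position-wise; otherwise a global
#' (Needleman-Wunsch) alignment via [Biostrings::pairwiseAlignment()] is
#' used and identity is computed over the alignment.
#'
#' @param a,b Nucleotide strings.
#' @return Identity as a fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == nchar(b)) {
    ca <- seq_chars(a); cb <- seq_chars(b)
    return(sum(ca == cb) / length(ca))
  }
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global")
  Biostrings::pid(aln) / 100
}

#' Select full-length, near-identical copies of an element
#'
#' A copy counts as full length when its length is within
#' `length_tolerance` of the consensus length and its identity to the
#' consensus reaches `identity_threshold`. Optionally both TIR arms must
#' be detectable on the copy.
#'
#' @param copies Tibble with at least a `sequence` column (one genomic
#'   copy per row; other columns are carried through).
#' @param consensus Consensus element sequence.
#' @param identity_threshold Minimum identity to the consensus (default
#'   0.99, i.e. the ">99%" convention for recent expansions).
#' @param length_tolerance Allowed relative length deviation (default 0.05).
#' @param require_tirs Additionally require [find_tirs()] to succeed on
#'   the copy.
#' @param ... Passed to [find_tirs()] when `require_tirs = TRUE`.
#' @return The qualifying rows of `copies` with added `identity` and
#'   `full_length` columns; the full-length count is `nrow()` of the
#'   result.
#' @export
cluster_full_length_copies <- function(copies, consensus,
                                       identity_threshold = 0.99,
                                       length_tolerance = 0.05,
                                       require_tirs = FALSE, ...) {
  if (nrow(copies) == 0) {
    return(dplyr::mutate(copies, identity = numeric(0), full_length = logical(0)))
  }
  stopifnot("sequence" %in% names(copies))
  len_ok <- abs(nchar(copies$sequence) - nchar(consensus)) <=
    length_tolerance * nchar(consensus)
  ident <- purrr::map_dbl(copies$sequence, pairwise_identity, b = consensus)
  keep <- len_ok & ident >= identity_threshold
  if (require_tirs) {
    has_tir <- purrr::map_lgl(copies$sequence,
                              function(s) nrow(find_tirs(s, ...)) > 0)
    keep <- keep & has_tir
  }
  out <- copies[keep, , drop = FALSE]
  out$identity <- ident[keep]
  out$full_length <- TRUE
  out
}

#' Structural annotation of a consensus element
#'
#' Convenience wrapper running TIR detection, ORF finding, catalytic-
#' triad classification and simple motif scans on one consensus sequence.
#'
#' @param name Element name.
#' @param sequence Consensus nucleotide sequence.
#' @param min_orf_aa Minimum ORF length in amino acids.
#' @param ... Passed to [find_tirs()].
#' @return A one-row tibble: `name`, `length_bp`, `tir_len`,
#'   `tir_identity`, `orf_aa`, `family_label`, `grpr_like`, `nls_like`.
#' @export
annotate_element <- function(name, sequence, min_orf_aa = 300L, ...) {
  tir <- find_tirs(sequence, ...)
  orf <- find_longest_orf(sequence, min_aa = min_orf_aa)
  fam <- if (nrow(orf) > 0) classify_catalytic_family(orf$protein[1]) else NULL
  motifs <- if (nrow(orf) > 0) scan_simple_motifs(orf$protein[1]) else NULL
  tibble::tibble(
    name = name,
    length_bp = nchar(sequence),
    tir_len = if (nrow(tir) > 0) tir$length[1] else NA_integer_,
    tir_identity = if (nrow(tir) > 0) tir$identity[1] else NA_real_,
    orf_aa = if (nrow(orf) > 0) orf$aa_length[1] else NA_integer_,
    family_label = if (!is.null(fam)) fam$label[1] else NA_character_,
    grpr_like = if (!is.null(motifs)) motifs$grpr_like[1] else NA,
    nls_like = if (!is.null(motifs)) motifs$nls_like[1] else NA
  )
}

#' Extract copy sequences from a genome given a BED-style interval table
#'
#' @param genome Genome tibble (`name`, `sequence`).
#' @param intervals Tibble of 0-based half-open intervals (`chrom`,
#'   `start`, `end`, optional `strand`); minus-strand copies are
#'   reverse-complemented.
#' @return `intervals` with an added `sequence` column.
#' @export
extract_copy_sequences <- function(genome, intervals) {
  check_intervals(intervals)
  idx <- match(intervals$chrom, genome$name)
  if (anyNA(idx)) stop("contig not found: ",
                       intervals$chrom[which(is.na(idx))[1]], call. = FALSE)
  seqs <- substr(genome$sequence[idx], intervals$start + 1L, intervals$end)
  if ("strand" %in% names(intervals)) {
    minus <- which(!is.na(intervals$strand) & intervals$strand == "-")
    if (length(minus) > 0) seqs[minus] <- revcomp(seqs[minus])
  }
  dplyr::mutate(intervals, sequence = seqs)
}
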