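#' Build a position frequency matrix around TA insertion sites
#'
#' Counts bases in a `window`-bp window centred on the TA dinucleotide of
#' each called site (the TA occupies the two central columns). Windows of
#' minus-strand sites are reverse-complemented before counting when
#' `orient_by_strand` is on, so that the profile is read in element
#' orientation; with it off, strands are pooled as-is. Sites whose window
#' would overrun a contig end are dropped and counted in `n_dropped`.
#'
#' @param sites Tibble with `chrom`, `ta_pos` (1-based T position) and
#'   `strand` columns (e.g. `tidy()` of [call_insertions()]).
#' @param genome Genome tibble (`name`, `sequence`).
#' @param window Window width in bp (even; default 60).
#' @param orient_by_strand Reverse-complement minus-strand windows.
#' @return An object of class `pfm`: list with `counts` (4 x `window`
#'   matrix, rows A, C, G, T), `n_sites` (usable sites), `n_dropped`,
#'   `window`, `center` (the two TA column indices).
#' @export
build_pfm <- function(sites, genome, window = 60L, orient_by_strand = TRUE) {
  stopifnot(all(c("chrom", "ta_pos") %in% names(sites)))
  if (window %% 2 != 0) stop("window must be even", call. = FALSE)
  half <- window %/% 2L
  genome_seq <- stats::setNames(toupper(genome$sequence), genome$name)
  strand <- if ("strand" %in% names(sites)) sites$strand else
    rep("+", nrow(sites))
  # window columns 1..W, TA at columns half, half + 1
  win_start <- sites$ta_pos - half + 1L
  win_end <- sites$ta_pos + half
  contig_len <- nchar(genome_seq)[sites$chrom]
  usable <- !is.na(contig_len) & win_start >= 1L & win_end <= contig_len
  n_dropped <- sum(!usable)
  if (sum(usable) == 0) stop("zero usable sites", call. = FALSE)
  seqs <- substr(genome_seq[sites$chrom[usable]], win_start[usable], win_end[usable])
  if (orient_by_strand) {
    minus <- strand[usable] == "-"
    if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  }
  mat <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs))
  counts <- matrix(0L, nrow = 4, ncol = window,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (b in c("A", "C", "G", "T")) {
    if (b %in% rownames(mat)) counts[b, ] <- mat[b, ]
  }
  structure(list(counts = counts, n_sites = length(seqs),
                 n_dropped = n_dropped, window = as.integer(window),
                 center = c(half, half + 1L)),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("<pfm> ", x$n_sites, " site(s), window ", x$window,
      " bp, TA at columns ", x$center[1], "-", x$center[2],
      if (x$n_dropped > 0) paste0(" (", x$n_dropped, " dropped at contig edges)"),
      "\n", sep = "")
  invisible(x)
}

#' @rdname tidy.insertion_calls
#' @export
tidy.pfm <- function(x, ...) {
  tibble::tibble(
    position = rep(seq_len(x$window), each = 4L),
    base = rep(c("A", "C", "G", "T"), x$window),
    count = as.vector(x$counts),
    freq = as.vector(x$counts) / x$n_sites
  )
}

#' Per-column information content of a position frequency matrix
#'
#' `IC = 2 - H` bits per column, with `H` the Shannon entropy of the
#' base frequencies after adding `pseudocount` to each count. The
#' maximum, 2 bits (log2 of the 4-letter alphabet), is reached only by a
#' pure column at pseudocount 0.
#'
#' @param pfm A `pfm` object.
#' @param pseudocount Count added to every cell (>= 0); 0.5 is a common
#'   stabilizer, 0 gives exact values.
#' @return Numeric vector of length `window`, in bits.
#' @export
information_content <- function(pfm, pseudocount = 0) {
  stopifnot(inherits(pfm, "pfm"))
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (pfm$n_sites < 1) stop("empty PFM", call. = FALSE)
  counts <- pfm$counts + pseudocount
  freqs <- sweep(counts, 2, colSums(counts), "/")
  plogp <- ifelse(freqs > 0, freqs * log2(freqs), 0)
  2 + colSums(plogp)
}

#' Palindrome-symmetry score of a target-site profile
#'
#' Tc1/mariner target sites are palindromic (the ZB/SB consensus is an
#' ATATATAT context around the central TA). The score mirrors the window
#' about its centre: for offsets `j = 1..half_width` it takes the cosine
#' similarity between the column `j` positions left of centre and the
#' base-complement-permuted column `j` positions right of centre, and
#' averages. 1 means perfectly palindromic base composition.
#'
#' @param pfm A `pfm` object.
#' @param half_width Number of column pairs compared (default: the full
#'   half-window).
#' @return A score in \[0, 1\].
#' @export
palindrome_symmetry <- function(pfm, half_width = NULL) {
  stopifnot(inherits(pfm, "pfm"))
  if (is.null(half_width)) half_width <- pfm$window %/% 2L
  if (half_width > pfm$window %/% 2L) {
    stop("half_width exceeds the half-window", call. = FALSE)
  }
  cosine <- function(u, v) {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) return(NA_real_)
    sum(u * v) / (nu * nv)
  }
  comp_perm <- c(A = "T", C = "G", G = "C", T = "A")
  cL <- pfm$center[1]  # left TA column
  sims <- vapply(seq_len(half_width), function(j) {
    left <- pfm$counts[, cL - j + 1L]
    right <- pfm$counts[, cL + j]
    right_complemented <- right[comp_perm[rownames(pfm$counts)]]
    cosine(left, right_complemented)
  }, numeric(1))
  mean(sims, na.rm = TRUE)
}

#' @export
autoplot.pfm <- function(object, pseudocount = 0, ...) {
  ic <- information_content(object, pseudocount = pseudocount)
  df <- tidy(object)
  df$height <- df$freq * ic[df$position]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$height,
                                   fill = .data$base)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::scale_fill_manual(values = c(A = "#109648", C = "#255C99",
                                          G = "#F7B32B", T = "#D62839")) +
    ggplot2::geom_vline(xintercept = mean(object$center), linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(x = "Position in window", y = "Information (bits)",
                  fill = NULL) +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}
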