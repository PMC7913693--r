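#' Count transitions and transversions in a pairwise alignment
#'
#' Columns containing a gap (`-`) or `N` in either sequence are excluded
#' pairwise. Transitions are A<->G and C<->T; every other mismatch is a
#' transversion. `P` and `Q` are the transition and transversion
#' proportions over the included columns.
#'
#' @param aligned_copy,aligned_consensus Equal-length aligned strings
#'   over `A, C, G, T, -, N` (case-insensitive).
#' @return A one-row tibble (`P`, `Q`, `aligned_length`).
#' @examples
#' count_substitutions("A-GT", "ACGT")  # gap column dropped, n = 3
#' @export
count_substitutions <- function(aligned_copy, aligned_consensus) {
  a <- seq_chars(toupper(aligned_copy))
  b <- seq_chars(toupper(aligned_consensus))
  if (length(a) != length(b)) stop("aligned sequences differ in length", call. = FALSE)
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0) stop("no comparable sites after gap/N exclusion", call. = FALSE)
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  tibble::tibble(P = sum(transition) / n,
                 Q = sum(diff & !transition) / n,
                 aligned_length = n)
}

#' Kimura two-parameter distance
#'
#' `K = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`, correcting separately
#' for multiple transitions (`P`) and transversions (`Q`). When the
#' observed proportions violate `1 - 2P - Q > 0` or `1 - 2Q > 0` the
#' distance is saturated and `NA` is returned (callers report such copies
#' in an explicit overflow category rather than dropping them).
#'
#' @param P,Q Transition and transversion proportions (vectorized).
#' @return Numeric vector of distances; `NA` marks saturation.
#' @examples
#' kimura2p(0.04, 0.02)  # 0.06289
#' kimura2p(0.5, 0)      # saturated -> NA
#' @export
kimura2p <- function(P, Q) {
  stopifnot(length(P) == length(Q))
  if (any(P < 0 | Q < 0, na.rm = TRUE)) stop("P and Q must be >= 0", call. = FALSE)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  out <- rep(NA_real_, length(P))
  ok <- !is.na(w1) & !is.na(w2) & w1 > 0 & w2 > 0
  out[ok] <- -0.5 * log(w1[ok]) - 0.25 * log(w2[ok])
  out
}

#' @rdname kimura2p
#' @export
is_saturated <- function(P, Q) {
  (1 - 2 * P - Q) <= 0 | (1 - 2 * Q) <= 0
}

#' Convert a substitution distance to an insertion age
#'
#' `t = K / (2 r)` with the neutral substitution rate `r` in
#' substitutions per site per year. The default rate, 4.13e-9, is the
#' average rate commonly applied to zebrafish; it is expressed per
#' synonymous site but conventionally applied to all aligned sites of a
#' repeat copy, a simplification inherited from standard repeat-dating
#' practice (see the methods vignette).
#'
#' @param K K2P distance(s), substitutions per site.
#' @param r Substitution rate per site per year.
#' @return Age(s) in years.
#' @examples
#' age_from_distance(0.00826)  # 1e6 years
#' @export
age_from_distance <- function(K, r = 4.13e-9) {
  if (r <= 0) stop("substitution rate r must be > 0", call. = FALSE)
  if (any(K < 0, na.rm = TRUE)) stop("K must be >= 0", call. = FALSE)
  K / (2 * r)
}

#' Divergence and age profile of element copies against a consensus
#'
#' For each copy, counts substitutions against the consensus, computes
#' the K2P distance and converts it to years. Copies whose length equals
#' the consensus length are compared positionally; others are globally
#' aligned first with [Biostrings::pairwiseAlignment()].
#'
#' @param copies Tibble with columns `sequence` and optionally `copy_id`
#'   and `chrom`/`start`/`end` (carried through).
#' @param consensus Consensus nucleotide sequence.
#' @param r Substitution rate per site per year.
#' @return A tibble with one row per copy: `copy_id`, `aligned_length`,
#'   `P`, `Q`, `K`, `saturated`, `age_years`, `weight_bp` (copy length).
#' @export
divergence_profile <- function(copies, consensus, r = 4.13e-9) {
  stopifnot("sequence" %in% names(copies))
  if (nrow(copies) == 0) {
    return(tibble::tibble(copy_id = character(), aligned_length = integer(),
                          P = numeric(), Q = numeric(), K = numeric(),
                          saturated = logical(), age_years = numeric(),
                          weight_bp = integer()))
  }
  ids <- if ("copy_id" %in% names(copies)) as.character(copies$copy_id) else
    paste0("copy", seq_len(nrow(copies)))
  consensus <- toupper(consensus)
  rows <- purrr::map(copies$sequence, function(s) {
    s <- toupper(s)
    if (nchar(s) == nchar(consensus)) {
      count_substitutions(s, consensus)
    } else {
      aln <- Biostrings::pairwiseAlignment(s, consensus, type = "global")
      count_substitutions(as.character(Biostrings::alignedPattern(aln)),
                          as.character(Biostrings::alignedSubject(aln)))
    }
  })
  pq <- dplyr::bind_rows(rows)
  K <- kimura2p(pq$P, pq$Q)
  tibble::tibble(
    copy_id = ids,
    aligned_length = pq$aligned_length,
    P = pq$P, Q = pq$Q, K = K,
    saturated = is.na(K),
    age_years = age_from_distance(ifelse(is.na(K), NA_real_, K), r = r),
    weight_bp = nchar(copies$sequence)
  )
}

#' Bin copy ages into a divergence landscape
#'
#' Accumulates copy base pairs into fixed-width age bins (the classic
#' repeat-landscape plot: age on the x axis, genome mass on the y axis).
#' Saturated copies (no defined K2P distance) are collected in an
#' explicit overflow bin so that total mass is conserved exactly.
#'
#' @param records Tibble with `age_years` (NA = saturated) and
#'   `weight_bp` columns, as from [divergence_profile()].
#' @param bin_width Bin width in years (default 1 Myr).
#' @param genome_size Optional genome size in bp; adds a `genome_pct`
#'   column.
#' @param n_bins Number of bins; defaults to covering the oldest copy.
#' @return A tibble of class `age_landscape`: `bin_start`, `bin_end`
#'   (years; the overflow row has `NA` edges and `bin_label`
#'   `"saturated"`), `mass_bp`, and optionally `genome_pct`.
#' @export
build_landscape <- function(records, bin_width = 1e6, genome_size = NULL,
                            n_bins = NULL) {
  stopifnot(all(c("age_years", "weight_bp") %in% names(records)))
  if (any(records$weight_bp < 0)) stop("negative weights", call. = FALSE)
  ages <- records$age_years
  w <- records$weight_bp
  sat <- is.na(ages)
  if (is.null(n_bins)) {
    n_bins <- if (any(!sat)) max(1L, ceiling(max(ages[!sat]) / bin_width + 1e-9)) else 1L
  }
  edges <- bin_width * (0:n_bins)
  idx <- findInterval(ages[!sat], edges, rightmost.closed = FALSE)
  idx[idx > n_bins] <- n_bins  # clamp anything beyond the last edge
  idx[idx < 1L] <- 1L
  mass <- vapply(seq_len(n_bins),
                 function(b) sum(w[!sat][idx == b]), numeric(1))
  out <- tibble::tibble(
    bin_start = edges[-length(edges)],
    bin_end = edges[-1],
    bin_label = paste0("[", edges[-length(edges)] / 1e6, ",",
                       edges[-1] / 1e6, ") Myr"),
    mass_bp = mass
  )
  out <- dplyr::bind_rows(out, tibble::tibble(
    bin_start = NA_real_, bin_end = NA_real_,
    bin_label = "saturated", mass_bp = sum(w[sat])
  ))
  if (!is.null(genome_size)) out$genome_pct <- 100 * out$mass_bp / genome_size
  class(out) <- c("age_landscape", class(out))
  out
}

#' @export
autoplot.age_landscape <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$bin_start))
  y <- if ("genome_pct" %in% names(df)) "genome_pct" else "mass_bp"
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2e6,
                                   y = .data[[y]])) +
    ggplot2::geom_col(width = (df$bin_end[1] - df$bin_start[1]) / 1e6 * 0.9,
                      fill = "steelblue") +
    ggplot2::labs(x = "Insertion age (Myr)",
                  y = if (y == "genome_pct") "Genome (%)" else "Mass (bp)") +
    ggplot2::theme_minimal()
}
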