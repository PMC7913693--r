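# Shared fixture builders. Everything is generated in code; no binary data.

fixture_tir_tag <- "CAGTGGGTCAGAAGTTTACATACAC"
fixture_linker <- "GTCCCTTAAGCGGAGCCC"

# an element with perfect terminal inverted repeats of the given arm length;
# the all-A spacer guarantees that no arm extension position matches, so the
# planted arm length is recovered exactly
make_ir_element <- function(arm_len = 201L, spacer_len = 400L, seed = 1L) {
  withr::with_seed(seed, {
    arm <- paste(sample(c("A", "C", "G", "T"), arm_len, replace = TRUE),
                 collapse = "")
  })
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(arm)))
  paste0(arm, strrep("A", spacer_len), rc)
}

# a consensus transposon-like element: TIR arms, a planted ORF of n_aa codons
make_consensus_element <- function(n_aa = 341L, arm_len = 50L, seed = 42L) {
  withr::with_seed(seed, {
    arm <- paste(sample(c("A", "C", "G", "T"), arm_len, replace = TRUE),
                 collapse = "")
    # codons avoiding stops and ATG (start is added explicitly)
    safe <- c("GCT", "GCC", "TGT", "GAT", "GAA", "GGT", "CAT", "AAA",
              "CTT", "CCT", "AGA", "TCT", "ACT", "GTT")
    body <- paste(sample(safe, n_aa - 1L, replace = TRUE), collapse = "")
  })
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(arm)))
  paste0(arm, "CC", "ATG", body, "TAA", "CC", rc)
}

# brute-force oracles ---------------------------------------------------

# all-frames ORF scan by exhaustive substring enumeration (slow, tiny inputs)
brute_force_longest_orf <- function(sequence, min_aa = 1L) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
  best <- 0L
  for (s in c(sequence, rc)) {
    n <- nchar(s)
    for (i in seq_len(max(0L, n - 5L))) {
      if (substr(s, i, i + 2L) != "ATG") next
      j <- i + 3L
      while (j + 2L <= n) {
        cod <- substr(s, j, j + 2L)
        if (cod %in% c("TAA", "TAG", "TGA")) {
          aa <- (j - i) %/% 3L
          if (aa >= min_aa) best <- max(best, aa)
          break
        }
        j <- j + 3L
      }
    }
  }
  best
}

# brute-force TIR search over all arm lengths
brute_force_tir <- function(sequence, min_len, max_len, min_identity) {
  n <- nchar(sequence)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ch <- strsplit(sequence, "")[[1]]
  found <- integer(0)
  for (L in seq(min_len, min(max_len, n %/% 2L))) {
    i <- seq_len(L)
    m <- ch[i] == unname(comp[ch[n + 1L - i]])
    if (m[L] && mean(m) >= min_identity) found <- c(found, L)
  }
  found
}

# per-locus linear scan overlap counter
brute_force_overlap <- function(loci, track) {
  sum(vapply(seq_len(nrow(loci)), function(i) {
    any(track$chrom == loci$chrom[i] &
          track$start <= loci$pos[i] - 1L &
          track$end > loci$pos[i] - 1L)
  }, logical(1)))
}

# enumerate all (D, D, D/E) triples satisfying gap windows
brute_force_triads <- function(protein, gap1 = c(60L, 120L), gap2 = c(25L, 45L)) {
  aa <- strsplit(toupper(protein), "")[[1]]
  d <- which(aa == "D")
  de <- which(aa %in% c("D", "E"))
  out <- NULL
  for (i in d) for (j in d) for (k in de) {
    if (j - i >= gap1[1] && j - i <= gap1[2] &&
        k - j >= gap2[1] && k - j <= gap2[2]) {
      out <- rbind(out, c(i, j, k))
    }
  }
  out
}
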