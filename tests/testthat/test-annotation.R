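test_that("planted perfect TIR arms are recovered exactly", {
  el <- make_ir_element(arm_len = 201L, spacer_len = 400L, seed = 1)
  tir <- find_tirs(el, min_len = 20L, max_len = 250L, min_identity = 0.9)
  expect_equal(tir$length, 201L)
  expect_equal(tir$identity, 1.0)
  expect_equal(tir$offset3, nchar(el) - 201L)
})

test_that("random sequence without an inverted repeat yields no TIR", {
  withr::with_seed(5, {
    s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  })
  expect_equal(nrow(find_tirs(s, 20L, 250L, min_identity = 0.9)), 0L)
  # brute force confirms no qualifying arm exists
  expect_length(brute_force_tir(s, 20L, 250L, 0.9), 0L)
})

test_that("a self-reverse-complementary element returns the minimal arm", {
  half <- "ACGTACGTACGTACGTACGT"  # 20 bp
  el <- paste0(half,
               as.character(Biostrings::reverseComplement(Biostrings::DNAString(half))))
  tir <- find_tirs(el, min_len = 20L, max_len = 250L, min_identity = 0.9)
  expect_equal(tir$length, 20L)
  expect_equal(tir$identity, 1.0)
})

test_that("TIR detection is invariant under reverse complement", {
  for (seed in 1:5) {
    el <- make_ir_element(arm_len = 60L, spacer_len = 150L, seed = seed)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(el)))
    a <- find_tirs(el, 20L, 100L, 0.9)
    b <- find_tirs(rc, 20L, 100L, 0.9)
    expect_equal(a$length, b$length)
    expect_equal(a$identity, b$identity)
  }
})

test_that("TIR scan agrees with the all-arm brute force on mismatched arms", {
  withr::with_seed(9, {
    for (i in 1:5) {
      el <- make_ir_element(arm_len = 80L, spacer_len = 100L,
                            seed = sample.int(1000, 1))
      # corrupt a few arm positions
      ch <- strsplit(el, "")[[1]]
      flip <- sample(1:80, 4)
      ch[flip] <- vapply(ch[flip],
                         function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                         character(1))
      el <- paste(ch, collapse = "")
      got <- find_tirs(el, 20L, 120L, 0.9)
      want <- brute_force_tir(el, 20L, 120L, 0.9)
      if (length(want) == 0) {
        expect_equal(nrow(got), 0L)
      } else {
        expect_equal(got$length, max(want))
      }
    }
  })
})

test_that("TIR config errors are raised", {
  expect_error(find_tirs("ACGTACGT", min_len = 10L, max_len = 5L), "min_len > max_len")
  expect_error(find_tirs("ACGT", min_len = 20L, max_len = 50L), "shorter")
})

test_that("TA target-site duplications are detected from flanks", {
  # ...TA[element]TA... and a broken right flank
  g <- tibble::tibble(name = "c1",
                      sequence = paste0("CCCCTA", strrep("G", 30), "TACCCC"))
  expect_equal(detect_tsd(g, "c1", start = 6L, end = 36L), "TA")
  g2 <- tibble::tibble(name = "c1",
                       sequence = paste0("CCCCTA", strrep("G", 30), "TCCCCC"))
  expect_true(is.na(detect_tsd(g2, "c1", start = 6L, end = 36L)))
  # contig edge: warning, not error
  g3 <- tibble::tibble(name = "c1", sequence = paste0(strrep("G", 10), "TA"))
  expect_warning(res <- detect_tsd(g3, "c1", start = 0L, end = 10L), "edge")
  expect_true(is.na(res))
})

test_that("every simulator-planted copy shows the TA duplication", {
  g <- sim_genome(5e4, at_fraction = 0.6, seed = 3)
  cons <- make_consensus_element(n_aa = 100L, arm_len = 30L)
  planted <- sim_plant_copies(g, cons, n = 8, divergences = 0.02, seed = 17,
                              min_gap = 2500L)
  tsds <- purrr::pmap_chr(planted$truth[, c("chrom", "start", "end")],
                          function(chrom, start, end) {
                            detect_tsd(planted$genome, chrom, start, end)
                          })
  expect_true(all(tsds == "TA"))
})

test_that("the longest ORF is found on either strand and matches brute force", {
  el <- make_consensus_element(n_aa = 341L)
  orf <- find_longest_orf(el, min_aa = 300L)
  expect_equal(orf$aa_length, 341L)
  expect_equal(nchar(orf$protein), 341L)
  expect_equal(substr(orf$protein, 1, 1), "M")
  expect_false(grepl("\\*", orf$protein))
  expect_equal((orf$end - orf$start) %% 3, 0L)
  expect_equal(orf$aa_length, brute_force_longest_orf(el, 300L))

  expect_equal(nrow(find_longest_orf(strrep("C", 2000))), 0L)

  # minus-strand ORF found iff both strands are scanned
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(el)))
  expect_equal(find_longest_orf(rc, both_strands = TRUE, min_aa = 300L)$aa_length, 341L)
  expect_equal(nrow(find_longest_orf(rc, both_strands = FALSE, min_aa = 300L)), 0L)
})

test_that("ORF finder recovers the exact planted interval", {
  withr::with_seed(21, {
    safe <- c("GCT", "GGT", "TGC", "CAT", "AAA")
    body <- paste(sample(safe, 340, replace = TRUE), collapse = "")
  })
  orf_dna <- paste0("ATG", body, "TAA")
  el <- paste0(strrep("C", 97), orf_dna, strrep("C", 50))
  orf <- find_longest_orf(el, min_aa = 300L)
  expect_equal(orf$start, 97L)
  expect_equal(orf$end, 97L + nchar(orf_dna))
  expect_equal(orf$strand, "+")
})

test_that("catalytic-triad classification labels DD34E, DD37E and pogo-like", {
  pad <- function(n) strrep("A", n)
  p34 <- paste0(pad(20), "D", pad(89), "D", pad(33), "E", pad(40))
  expect_equal(classify_catalytic_family(p34)$label, "DD34E/Tc1-like")
  expect_equal(classify_catalytic_family(p34)$gap2, 34L)

  p37 <- paste0(pad(20), "D", pad(89), "D", pad(36), "E", pad(40))
  expect_equal(classify_catalytic_family(p37)$label, "DD37E/Tc1-like")

  pdd <- paste0(pad(20), "D", pad(89), "D", pad(33), "D", pad(40))
  expect_equal(classify_catalytic_family(pdd)$label, "DDxD/pogo-like")

  expect_equal(classify_catalytic_family(strrep("A", 300))$label, "unclassified")
  expect_error(classify_catalytic_family(""), "empty")
})

test_that("triad classification agrees with brute-force enumeration", {
  withr::with_seed(31, {
    for (i in 1:6) {
      aa <- sample(c("A", "G", "L", "S", "D", "E", "K"), 400,
                   replace = TRUE, prob = c(4, 4, 4, 4, 1.5, 1.5, 2))
      p <- paste(aa, collapse = "")
      got <- classify_catalytic_family(p)
      triads <- brute_force_triads(p)
      if (is.null(triads)) {
        expect_equal(got$label, "unclassified")
      } else {
        expect_false(got$label == "unclassified")
        # the chosen triad must be one of the enumerated ones
        expect_true(any(triads[, 1] == got$d1 & triads[, 2] == got$d2 &
                          triads[, 3] == got$x))
      }
    }
  })
})

test_that("simple motif scans locate GRPR-like and NLS-like signatures", {
  p <- paste0(strrep("A", 20), "GRPR", strrep("A", 200))
  expect_true(scan_simple_motifs(p)$grpr_like)
  # GRPR outside the N-terminal third does not count
  p2 <- paste0(strrep("A", 200), "GRPR", strrep("A", 20))
  expect_false(scan_simple_motifs(p2)$grpr_like)
  expect_true(scan_simple_motifs(paste0(strrep("G", 50), "KRKRKR"))$nls_like)
  m <- scan_simple_motifs(strrep("G", 100))
  expect_false(m$grpr_like)
  expect_false(m$nls_like)
})

test_that("full-length copy clustering counts near-identical copies", {
  # a full-size (~1.6 kb) consensus so that 0.5% divergence sits safely
  # above the 99% identity threshold for every copy
  cons <- make_consensus_element(n_aa = 500L, arm_len = 40L)
  withr::with_seed(13, {
    copies <- tibble::tibble(
      sequence = replicate(20, mutate_k2p(cons, 0.005, 2))
    )
  })
  full <- cluster_full_length_copies(copies, cons, identity_threshold = 0.99)
  expect_equal(nrow(full), 20L)

  withr::with_seed(14, {
    diverged <- mutate_k2p(cons, 0.05, 2)
  })
  copies2 <- dplyr::bind_rows(copies, tibble::tibble(sequence = diverged))
  expect_equal(nrow(cluster_full_length_copies(copies2, cons, 0.99)), 20L)

  empty <- copies[0, ]
  expect_equal(nrow(cluster_full_length_copies(empty, cons)), 0L)
})

test_that("annotate_element summarizes structure in one row", {
  el <- make_consensus_element(n_aa = 341L, arm_len = 50L)
  ann <- annotate_element("elem1", el, min_orf_aa = 300L,
                          min_len = 20L, max_len = 50L, min_identity = 0.9)
  expect_equal(ann$tir_len, 50L)
  expect_equal(ann$orf_aa, 341L)
  expect_equal(ann$length_bp, nchar(el))
})
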