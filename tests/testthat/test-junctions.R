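tag <- fixture_tir_tag
lnk <- fixture_linker

test_that("fragment extraction strips tag and linker and categorizes rejects", {
  frag30 <- strrep("ACGTA", 6)
  reads <- tibble::tibble(
    name = c("ok", "no_tag", "short"),
    sequence = c(paste0(tag, frag30, lnk),
                 paste0("TTTTTTTTTTTTTTTTTTTTTTTTT", frag30, lnk),
                 paste0(tag, "ACGTACGTAC", lnk))
  )
  got <- extract_genomic_fragment(reads, tag, lnk, max_mismatches = 0,
                                  min_fragment_len = 25L)
  expect_equal(got$status, c("ok", "no_tag", "too_short"))
  expect_equal(got$fragment[1], frag30)
  # a read that is tag + linker only
  only <- tibble::tibble(name = "x", sequence = paste0(tag, lnk))
  expect_equal(extract_genomic_fragment(only, tag, lnk)$status, "all_linker")
  expect_error(extract_genomic_fragment(only, "SHORT", lnk), ">= 10")
})

test_that("fragment extraction tolerates the configured mismatch budget", {
  frag <- strrep("GATTACA", 6)
  tag_err <- paste0("A", substr(tag, 2, nchar(tag)))  # 1 mismatch in tag
  reads <- tibble::tibble(name = "r", sequence = paste0(tag_err, frag, lnk))
  expect_equal(extract_genomic_fragment(reads, tag, lnk, max_mismatches = 1)$status, "ok")
  expect_equal(extract_genomic_fragment(reads, tag, lnk, max_mismatches = 0)$status, "no_tag")
})

test_that("mapping is unique for planted fragments, ambiguous for duplicated ones", {
  g <- sim_genome(5e4, seed = 31)
  s <- g$sequence[1]
  idx <- build_genome_index(g, seed_len = 16L)
  frag <- substr(s, 10001, 10060)
  m <- map_fragment(frag, idx)
  expect_equal(m$status, "unique")
  expect_equal(m$start, 10001L)
  expect_equal(m$strand, "+")

  # reverse-complement fragment maps on the minus strand to the same interval
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
  m2 <- map_fragment(rc, idx)
  expect_equal(m2$status, "unique")
  expect_equal(m2$start, 10001L)
  expect_equal(m2$strand, "-")

  # duplicate the fragment elsewhere -> ambiguous
  g_dup <- g
  g_dup$sequence <- paste0(s, strrep("C", 50), frag, strrep("C", 50))
  idx_dup <- build_genome_index(g_dup, seed_len = 16L)
  expect_equal(map_fragment(frag, idx_dup)$status, "ambiguous")

  # fragment absent from the genome
  absent <- strrep("ACCGGTTACCGGTTAA", 4)
  expect_equal(map_fragment(absent, idx)$status, "unmapped")
  # shorter than the seed
  expect_equal(map_fragment("ACGTACGT", idx)$status, "unmapped")
})

test_that("insertion calling recovers planted sites exactly", {
  g <- sim_genome(2e5, at_fraction = 0.5, seed = 41)
  sites <- sim_ta_sites(g, 12, seed = 42, min_gap = 700L)
  lib <- sim_junction_library(g, sites, reads_per_site = 6, tir_tag = tag,
                              linker = lnk, error_rate = 0, seed = 43)
  calls <- call_insertions(lib$reads, g, tir_tag = tag, linker = lnk)
  truth <- dplyr::distinct(lib$truth, chrom, ta_pos, strand)
  called <- calls$sites[, c("chrom", "ta_pos", "strand")]
  hits <- dplyr::inner_join(truth, called, by = c("chrom", "ta_pos", "strand"))
  expect_equal(nrow(hits), nrow(truth))     # recall 1
  expect_equal(nrow(called), nrow(truth))   # precision 1
  expect_true(all(calls$sites$ta_validated))
})

test_that("read support is counted per deduplicated read without collapsing", {
  g <- sim_genome(2e5, seed = 51)
  sites <- sim_ta_sites(g, 5, seed = 52, min_gap = 1200L)
  lib <- sim_junction_library(g, sites, reads_per_site = 20, tir_tag = tag,
                              linker = lnk, error_rate = 0, seed = 53)
  calls <- call_insertions(lib$reads, g, tir_tag = tag, linker = lnk,
                           collapse_duplicates = FALSE)
  expect_equal(sort(calls$sites$read_count), rep(20L, 5))
  # collapsing can only reduce support, never the number of sites
  calls2 <- call_insertions(lib$reads, g, tir_tag = tag, linker = lnk,
                            collapse_duplicates = TRUE)
  expect_equal(nrow(calls2$sites), 5L)
  expect_true(all(calls2$sites$read_count <= 20L))
})

test_that("zero reads yield zero sites and a non-TA site is flagged", {
  g <- sim_genome(1e5, seed = 61)
  none <- call_insertions(tibble::tibble(name = character(),
                                         sequence = character()),
                          g, tir_tag = tag, linker = lnk)
  expect_equal(nrow(none$sites), 0L)

  non_ta <- sim_ta_sites(g, 1, seed = 62, min_gap = 700L, at_ta = FALSE)
  lib <- sim_junction_library(g, non_ta, reads_per_site = 3, tir_tag = tag,
                              linker = lnk, error_rate = 0, seed = 63)
  calls <- call_insertions(lib$reads, g, tir_tag = tag, linker = lnk)
  expect_equal(nrow(calls$sites), 1L)
  expect_false(calls$sites$ta_validated[1])
})

test_that("both element orientations at a site give the same TA locus", {
  g <- sim_genome(1e5, seed = 71)
  base <- sim_ta_sites(g, 4, seed = 72, min_gap = 1200L, strand = "+")
  plus <- base
  minus <- dplyr::mutate(base, strand = "-")
  for (s in list(plus, minus)) {
    lib <- sim_junction_library(g, s, reads_per_site = 3, tir_tag = tag,
                                linker = lnk, error_rate = 0,
                                seed = 73)
    calls <- call_insertions(lib$reads, g, tir_tag = tag, linker = lnk)
    expect_equal(sort(calls$sites$ta_pos), sort(base$ta_pos))
  }
})

test_that("raising the mismatch budget never unmaps reads", {
  g <- sim_genome(1e5, seed = 81)
  sites <- sim_ta_sites(g, 6, seed = 82, min_gap = 1000L)
  lib <- sim_junction_library(g, sites, reads_per_site = 4, tir_tag = tag,
                              linker = lnk, error_rate = 0.01, seed = 83)
  frags <- extract_genomic_fragment(lib$reads, tag, lnk, max_mismatches = 2)
  idx <- build_genome_index(g)
  n_mapped <- vapply(c(0L, 2L, 5L, 10L), function(mm) {
    sum(map_fragment(frags$fragment, idx, max_mismatches = mm)$status == "unique")
  }, integer(1))
  expect_true(all(diff(n_mapped) >= 0))
})

test_that("every TA-validated site has the reference TA dinucleotide", {
  g <- sim_genome(2e5, seed = 91)
  sites <- sim_ta_sites(g, 10, seed = 92, min_gap = 700L)
  lib <- sim_junction_library(g, sites, reads_per_site = 4, tir_tag = tag,
                              linker = lnk, error_rate = 0, seed = 93)
  calls <- call_insertions(lib$reads, g, tir_tag = tag, linker = lnk)
  gs <- stats::setNames(g$sequence, g$name)
  for (i in seq_len(nrow(calls$sites))) {
    site <- calls$sites[i, ]
    if (site$ta_validated) {
      expect_equal(substr(gs[[site$chrom]], site$ta_pos, site$ta_pos + 1L), "TA")
    }
  }
  expect_s3_class(tidy(calls), "tbl_df")
  expect_equal(glance(calls)$n_sites, nrow(calls$sites))
})
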