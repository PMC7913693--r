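test_that("random loci follow contig lengths and respect exclusions", {
  lens <- c(small = 1e6, big = 3e6)
  loci <- generate_random_loci(lens, n = 100000, seed = 7)
  expect_equal(nrow(loci), 100000L)
  n_small <- sum(loci$chrom == "small")
  # binomial oracle: p = 1/4, 3 standard deviations
  expect_lt(abs(n_small - 25000), 3 * sqrt(100000 * 0.25 * 0.75))

  # determinism
  expect_identical(generate_random_loci(lens, 1000, seed = 3),
                   generate_random_loci(lens, 1000, seed = 3))

  # excluding an entire contig
  excl <- tibble::tibble(chrom = "small", start = 0L, end = 1000000L)
  loci2 <- generate_random_loci(lens, 5000, seed = 9, excluded = excl)
  expect_equal(sum(loci2$chrom == "small"), 0L)
  expect_error(generate_random_loci(c(a = 100), 10, seed = 1,
                                    excluded = tibble::tibble(chrom = "a",
                                                              start = 0L,
                                                              end = 100L)),
               "cover")
})

test_that("overlap fractions match binomial expectation and brute force", {
  lens <- c(c1 = 200000)
  track_half <- tibble::tibble(chrom = "c1", start = 0L, end = 100000L)
  loci <- generate_random_loci(lens, 1000, seed = 11)
  ov <- overlap_fraction(loci, track_half)
  expect_equal(ov$fraction, 0.5, tolerance = 0.1)  # +-0.05 absolute
  expect_equal(ov$n_in, brute_force_overlap(loci, track_half))

  # edge semantics: half-open intervals, 1-based points
  pts <- tibble::tibble(chrom = "c1", pos = c(1L, 10L, 11L))
  tr <- tibble::tibble(chrom = "c1", start = 0L, end = 10L)
  expect_equal(overlap_fraction(pts, tr)$n_in, 2L)

  expect_equal(overlap_fraction(loci,
                                tibble::tibble(chrom = "c1", start = 0L,
                                               end = 200000L))$fraction, 1.0)
  far <- tibble::tibble(chrom = "c2", start = 0L, end = 100L)
  expect_equal(overlap_fraction(loci, far)$fraction, 0.0)
  expect_error(overlap_fraction(loci[0, ], tr), "zero loci")
})

test_that("overlap agrees with the linear scan on many random tracks", {
  withr::with_seed(21, {
    lens <- c(a = 50000, b = 30000)
    loci <- generate_random_loci(lens, 500, seed = 22)
    for (i in 1:5) {
      st <- sample.int(40000, 200)
      track <- tibble::tibble(chrom = sample(c("a", "b"), 200, replace = TRUE),
                              start = st, end = st + sample.int(500, 200))
      expect_equal(overlap_fraction(loci, track)$n_in,
                   brute_force_overlap(loci, track))
    }
  })
})

test_that("fold change is the ratio to the random expectation", {
  expect_equal(fold_change(0.15, 0.15), 1.0)
  expect_equal(fold_change(0.30, 0.15), 2.0)
  expect_true(is.na(fold_change(0.3, 0)))
  expect_error(fold_change(1.3, 0.5), "sample_fraction")
})

test_that("gene feature tracks have the documented coordinate arithmetic", {
  lens <- c(c1 = 10000)
  genes <- tibble::tibble(chrom = "c1", start = 1000L, end = 2000L,
                          strand = "+", name = "g1")
  exons <- tibble::tibble(chrom = "c1", start = c(1000L, 1600L),
                          end = c(1200L, 2000L), gene = "g1")
  tracks <- derive_gene_feature_tracks(genes, exons, lens, window_bp = 500L)
  up <- tracks[tracks$feature == "upstream", ]
  expect_equal(c(up$start, up$end), c(500L, 1000L))
  tss <- tracks[tracks$feature == "tss", ]
  expect_equal(c(tss$start, tss$end), c(500L, 1500L))
  intron <- tracks[tracks$feature == "intron", ]
  expect_equal(c(intron$start, intron$end), c(1200L, 1600L))

  # minus-strand gene: upstream lies to the right
  genes_m <- dplyr::mutate(genes, strand = "-")
  tracks_m <- derive_gene_feature_tracks(genes_m, exons, lens, window_bp = 500L)
  up_m <- tracks_m[tracks_m$feature == "upstream", ]
  expect_equal(c(up_m$start, up_m$end), c(2000L, 2500L))

  # two genes: intergenic excludes both bodies and their windows
  genes2 <- tibble::tibble(chrom = "c1", start = c(1000L, 5000L),
                           end = c(2000L, 6000L), strand = c("+", "-"),
                           name = c("g1", "g2"))
  exons2 <- tibble::tibble(chrom = "c1", start = c(1000L, 5000L),
                           end = c(2000L, 6000L), gene = c("g1", "g2"))
  tr2 <- derive_gene_feature_tracks(genes2, exons2, lens, window_bp = 500L)
  ig <- tr2[tr2$feature == "intergenic", ]
  expect_equal(ig$start, c(0L, 2500L, 6500L))
  expect_equal(ig$end, c(500L, 4500L, 10000L))

  expect_error(derive_gene_feature_tracks(
    genes, dplyr::mutate(exons, end = 3000L), lens), "exon outside")
})

test_that("exon and intron point fractions partition the gene body", {
  g <- sim_genome(5e5, seed = 31)
  ann <- sim_annotation_tracks(g, gene_density = 0.3, enhancer_cov = 0.05,
                               seed = 32)
  tracks <- derive_gene_feature_tracks(ann$genes, ann$exons, g,
                                       window_bp = 1000L)
  loci <- generate_random_loci(g, 20000, seed = 33)
  n_ex <- overlap_fraction(loci, tracks[tracks$feature == "exon", ])$n_in
  n_in <- overlap_fraction(loci, tracks[tracks$feature == "intron", ])$n_in
  n_gene <- overlap_fraction(loci, tracks[tracks$feature == "gene_body", ])$n_in
  expect_equal(n_ex + n_in, n_gene)
})

test_that("an independent random set is unenriched against the null", {
  g <- sim_genome(1e6, seed = 41)
  ann <- sim_annotation_tracks(g, gene_density = 0.25, enhancer_cov = 0.08,
                               seed = 42)
  reference <- generate_random_loci(g, 100000, seed = 43)
  independent <- generate_random_loci(g, 100000, seed = 44)
  for (track in list(ann$genes[, c("chrom", "start", "end")],
                     ann$enhancers)) {
    f_ref <- overlap_fraction(reference, track)$fraction
    f_ind <- overlap_fraction(independent, track)$fraction
    expect_equal(fold_change(f_ind, f_ref), 1.0, tolerance = 0.05)
  }
})

test_that("a planted 3x enrichment is recovered", {
  g <- sim_genome(1e6, seed = 51)
  # one contiguous track covering 10% of the genome
  track <- tibble::tibble(chrom = g$name[1], start = 400000L, end = 500000L)
  loci <- sim_enriched_loci(g, track, n = 20000, frac_in = 0.30, seed = 52)
  reference <- generate_random_loci(g, 100000, seed = 53)
  fc <- fold_change(overlap_fraction(loci, track)$fraction,
                    overlap_fraction(reference, track)$fraction)
  expect_equal(fc, 3.0, tolerance = 0.1)
})

test_that("the enrichment table assembles fractions, folds and intervals", {
  g <- sim_genome(2e5, seed = 61)
  ann <- sim_annotation_tracks(g, gene_density = 0.3, enhancer_cov = 0.1,
                               seed = 62)
  rand <- generate_random_loci(g, 5000, seed = 63)
  zb <- sim_enriched_loci(g, ann$enhancers, n = 2000, frac_in = 0.3, seed = 64)
  et <- enrichment_table(
    list(ZB = zb, random2 = generate_random_loci(g, 5000, seed = 65)),
    list(enhancer = ann$enhancers,
         gene_body = ann$genes[, c("chrom", "start", "end")]),
    random_loci = rand
  )
  expect_s3_class(et, "enrichment_result")
  expect_equal(nrow(et), 4L)
  enh_zb <- et[et$feature == "enhancer" & et$sample == "ZB", ]
  expect_gt(enh_zb$fold_change, 1.5)
  expect_true(all(et$ci_lo <= et$fraction & et$fraction <= et$ci_hi))
  expect_s3_class(ggplot2::autoplot(et), "ggplot")
})
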