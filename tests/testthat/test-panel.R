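test_that("criterion flags and score follow the stated formula", {
  # nonsense in TSG, ClinVar-pathogenic, VAF 0.40, not validated
  apc <- score_variants(make_variants(make_variant(
    gene = "APC", chrom = "chr5", consequence = "nonsense",
    protein_change = "R213*", ffpe_vaf = 0.40, clinvar_pathogenic = TRUE,
    gene_role = "tumor_suppressor")))
  expect_true(apc$pathogenic_deleterious)
  expect_true(apc$stopgain_in_tsg)
  expect_false(apc$recurrent_oncogene)
  expect_false(apc$in_house_validated)
  expect_equal(apc$score, 2.40)

  # oncogene hotspot with high COSMIC recurrence, deleterious, VAF 0.30
  kras <- score_variants(make_variants(make_variant(
    cosmic_count = 10000L, predicted_deleterious = TRUE,
    gene_role = "oncogene", ffpe_vaf = 0.30)))
  expect_equal(kras$score, 2.30)
  expect_true(kras$recurrent_oncogene)
  expect_false(kras$stopgain_in_tsg)

  # COSMIC recurrence criterion is strict: more than 3 times
  borderline <- score_variants(make_variants(make_variant(
    cosmic_count = 3L, gene_role = "oncogene")))
  expect_false(borderline$recurrent_oncogene)
  expect_true(score_variants(make_variants(make_variant(
    cosmic_count = 4L, gene_role = "oncogene")))$recurrent_oncogene)

  # pathogenic OR deleterious suffices
  expect_true(score_variants(make_variants(make_variant(
    clinvar_pathogenic = TRUE)))$pathogenic_deleterious)
  expect_true(score_variants(make_variants(make_variant(
    predicted_deleterious = TRUE)))$pathogenic_deleterious)

  expect_error(score_variants(make_variants(make_variant(
    consequence = "synonymous"))), "synonymous")
})

test_that("panel selection takes the top scores with availability bounds", {
  set.seed(3)
  scored <- random_scored(12, seed = 3)
  p <- select_panel(scored, n = 5)
  expect_equal(nrow(p$members), 5L)
  expect_equal(p$members$rank, 1:5)
  # the 5 highest scores, non-increasing
  expect_equal(sort(p$members$score, decreasing = TRUE),
               sort(scored$score, decreasing = TRUE)[1:5])
  expect_true(all(diff(p$members$score) <= 0))

  small <- select_panel(random_scored(3, seed = 4), n = 5)
  expect_equal(nrow(small$members), 3L)

  # n clamped to [2, 10]
  expect_equal(nrow(select_panel(scored, n = 99)$members), 10L)
  expect_equal(nrow(select_panel(scored, n = 1)$members), 2L)

  # single eligible variant: emitted with below-minimum warning
  expect_warning(tiny <- select_panel(random_scored(1, seed = 5), n = 5),
                 "below minimum")
  expect_true(tiny$below_minimum)

  lowcx <- make_variants(make_variant(in_low_complexity = TRUE))
  expect_error(select_panel(score_variants(lowcx)), "no trackable")
})

test_that("ties break by VAF then coordinate; selection is deterministic", {
  a <- make_variant(gene = "A", chrom = "chr2", pos = 500L, ffpe_vaf = 0.30)
  b <- make_variant(gene = "B", chrom = "chr1", pos = 900L, ffpe_vaf = 0.20)
  p <- select_panel(score_variants(make_variants(a, b)), n = 2)
  expect_identical(p$members$gene, c("A", "B"))  # higher VAF first

  # identical score and VAF: coordinate ascending decides
  c1 <- make_variant(gene = "C1", chrom = "chr3", pos = 10L, ffpe_vaf = 0.2)
  c2 <- make_variant(gene = "C2", chrom = "chr3", pos = 5L, ffpe_vaf = 0.2)
  p2 <- select_panel(score_variants(make_variants(c1, c2)), n = 2)
  expect_identical(p2$members$gene, c("C2", "C1"))

  # permutation invariance of the full panel
  scored <- random_scored(10, seed = 42, tie_heavy = TRUE)
  p_fwd <- select_panel(scored, n = 5)
  set.seed(9); perm <- sample.int(nrow(scored))
  p_perm <- select_panel(scored[perm, ], n = 5)
  expect_equal(p_fwd$members$gene, p_perm$members$gene)
})

test_that("removing a non-selected variant never changes the panel", {
  scored <- random_scored(11, seed = 77)
  p <- select_panel(scored, n = 5)
  losers <- setdiff(scored$gene, p$members$gene)
  for (g in losers[1:3]) {
    p2 <- select_panel(scored[scored$gene != g, ], n = 5)
    expect_equal(p2$members$gene, p$members$gene)
  }
})

test_that("selection equals the brute-force subset oracle", {
  for (seed in 1:15) {
    n <- sample(2:12, 1)
    scored <- random_scored(n, seed = seed,
                            tie_heavy = seed %% 3 == 0)
    k <- sample(2:6, 1)
    p <- suppressWarnings(select_panel(scored, n = k))
    best <- oracle_panel(scored, k)
    expect_equal(p$members$gene, scored$gene[best],
                 info = sprintf("seed %d n %d k %d", seed, n, k))
  }
})

test_that("plasma detectability flag is inclusive at 10% FFPE VAF", {
  expect_true(plasma_detectability(0.10))
  expect_false(plasma_detectability(0.099))
  expect_true(plasma_detectability(1.0))
  # advisory only: a low-VAF variant still enters the panel
  low <- make_variants(make_variant(ffpe_vaf = 0.04),
                       make_variant(gene = "B", pos = 2L, ffpe_vaf = 0.5))
  p <- select_panel(score_variants(low), n = 2)
  expect_equal(nrow(p$members), 2L)
  expect_equal(p$members$detectable_in_plasma, c(TRUE, FALSE))
})
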