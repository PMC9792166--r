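test_that("cohort summary counts genes per patient and pools classes", {
  v <- make_variants(
    make_variant(patient_id = "P1", gene = "APC", pos = 1L),
    make_variant(patient_id = "P1", gene = "TP53", pos = 2L),
    make_variant(patient_id = "P2", gene = "APC", pos = 3L))
  s <- summarize_cohort(v)
  expect_equal(s$n_patients, 2L)
  expect_equal(s$per_gene_frequency[["APC"]], 1.0)
  expect_equal(s$per_gene_frequency[["TP53"]], 0.5)
  expect_equal(sum(s$class_distribution), 1, tolerance = 1e-9)
  expect_equal(unname(s$mutations_per_patient), c(2L, 1L))

  single <- summarize_cohort(make_variants(make_variant()))
  expect_equal(single$per_gene_frequency[["KRAS"]], 1.0)
  expect_equal(single$class_distribution[["missense"]], 1.0)
  expect_error(summarize_cohort(v[0, ]), "empty")
})

test_that("class distribution recovers binomial sampling probabilities", {
  # independent oracle: classes drawn straight from rmultinom at the
  # configured probabilities, then summarized
  probs <- c(missense = 0.723, frameshift = 0.135, nonsense = 0.123,
             other = 0.019)
  set.seed(91)
  n <- 500L
  cls <- sample(names(probs), n, replace = TRUE, prob = probs)
  v <- somatic_variants(data.frame(
    patient_id = paste0("P", rep(1:50, 10)), gene = "APC", chrom = "chr5",
    pos = seq_len(n), ref = "A", alt = "T", consequence = cls,
    ffpe_vaf = 0.2, stringsAsFactors = FALSE))
  s <- summarize_cohort(v)
  se <- sqrt(0.723 * (1 - 0.723) / n)
  expect_lt(abs(s$class_distribution[["missense"]] - 0.723), 3 * se)
  expect_lt(abs(s$class_distribution[["missense"]] - mean(cls == "missense")),
            1e-12)
})

test_that("pairwise exact test labels extreme tables correctly", {
  # 20 patients: perfect mutual exclusivity between A and B
  v1 <- somatic_variants(data.frame(
    patient_id = paste0("P", 1:20),
    gene = rep(c("A", "B"), each = 10), chrom = "chr1", pos = 1:20,
    ref = "A", alt = "T", consequence = "missense", ffpe_vaf = 0.2,
    stringsAsFactors = FALSE))
  r1 <- pairwise_interaction(v1, c("A", "B"))
  expect_identical(r1$label, "mutually_exclusive")
  expect_equal(r1$odds_ratio, 0)
  expect_equal(r1$p_value, hypergeom_p2(0, 10, 10, 0), tolerance = 1e-12)

  # perfect co-occurrence: 10 patients with both, 10 with neither
  v2 <- somatic_variants(data.frame(
    patient_id = c(paste0("P", 1:10), paste0("P", 1:10), paste0("Q", 1:10)),
    gene = c(rep("A", 10), rep("B", 10), rep("C", 10)),
    chrom = "chr1", pos = 1:30, ref = "A", alt = "T",
    consequence = "missense", ffpe_vaf = 0.2, stringsAsFactors = FALSE))
  r2 <- pairwise_interaction(v2, c("A", "B"))
  expect_identical(r2$label, "co_occurring")
  expect_equal(r2$both, 10)
  expect_equal(r2$neither, 10)

  # balanced table: no association
  t3 <- gene_pair_test(5, 5, 5, 5)
  expect_equal(t3$p_value, 1)
})

test_that("pairwise interaction is symmetric and warns on absent genes", {
  set.seed(5)
  v <- somatic_variants(data.frame(
    patient_id = sample(paste0("P", 1:15), 40, replace = TRUE),
    gene = sample(c("A", "B", "C"), 40, replace = TRUE),
    chrom = "chr1", pos = 1:40, ref = "A", alt = "T",
    consequence = "missense", ffpe_vaf = 0.2, stringsAsFactors = FALSE))
  # swapping the genes transposes the 2x2 table: identical p-value and
  # identical odds ratio
  ab <- gene_pair_test(3, 4, 5, 3)
  ba <- gene_pair_test(3, 5, 4, 3)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_equal(ab$odds_ratio, ba$odds_ratio, tolerance = 1e-6)
  expect_warning(r <- pairwise_interaction(v, c("A", "B", "ZZZ")),
                 "ZZZ")
  expect_equal(nrow(r), 1L)  # only the A-B pair remains
})

test_that("exact-test p-values match hypergeometric enumeration on a grid", {
  # spot grid here; the exhaustive n <= 30 sweep runs in the acceptance suite
  set.seed(17)
  for (i in 1:200) {
    cells <- as.integer(rmultinom(1, sample(4:30, 1), runif(4)))
    p_pkg <- gene_pair_test(cells[1], cells[2], cells[3], cells[4])$p_value
    p_ora <- hypergeom_p2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p_pkg, p_ora, tolerance = 1e-9)
  }
})

test_that("hotspot fraction counts gene-mutated patients at residues", {
  v <- make_variants(
    make_variant(patient_id = "P1", protein_change = "G12D", pos = 1L),
    make_variant(patient_id = "P2", protein_change = "G12V", pos = 2L),
    make_variant(patient_id = "P3", protein_change = "Q61H", pos = 3L),
    make_variant(patient_id = "P4", protein_change = "A146T", pos = 4L))
  expect_equal(hotspot_fraction(v, "KRAS", 12), 0.5)
  expect_equal(hotspot_fraction(v, "KRAS", c("G12")), 0.5)
  expect_equal(hotspot_fraction(v, "KRAS", integer(0)), 0)
  expect_error(hotspot_fraction(v, "EGFR", 12), "not mutated")
})

test_that("protein positions parse by letter/number/suffix convention", {
  expect_equal(parse_protein_position(c("G12D", "p.V600E", "R213*",
                                        "K117fs", NA, "?")),
               c(12L, 600L, 213L, 117L, NA, NA))
})
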