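# Shared fixture builders; all synthetic, constructed in code.

make_variant <- function(patient_id = "P1", gene = "KRAS", chrom = "chr12",
                         pos = 25245350L, ref = "C", alt = "T",
                         consequence = "missense",
                         protein_change = "G12D", ffpe_vaf = 0.30,
                         cosmic_count = 0L, clinvar_pathogenic = FALSE,
                         predicted_deleterious = FALSE,
                         gene_role = "other", in_house_validated = FALSE,
                         in_low_complexity = FALSE) {
  data.frame(patient_id = patient_id, gene = gene, chrom = chrom,
             pos = pos, ref = ref, alt = alt, consequence = consequence,
             protein_change = protein_change, ffpe_vaf = ffpe_vaf,
             cosmic_count = cosmic_count,
             clinvar_pathogenic = clinvar_pathogenic,
             predicted_deleterious = predicted_deleterious,
             gene_role = gene_role, in_house_validated = in_house_validated,
             in_low_complexity = in_low_complexity,
             stringsAsFactors = FALSE)
}

make_variants <- function(...) {
  somatic_variants(do.call(rbind, list(...)))
}

make_measurements <- function(depths, alt_reads, sample_id = "S1",
                              patient_id = "P1") {
  n <- length(depths)
  amplicon_measurements(data.frame(
    sample_id = rep(sample_id, n), patient_id = rep(patient_id, n),
    chrom = rep("chr1", n), pos = seq_len(n), ref = rep("A", n),
    alt = rep("T", n), depth = depths, alt_reads = alt_reads,
    stringsAsFactors = FALSE))
}

# Two-sided exact-test p-value by direct hypergeometric enumeration;
# independent of fisher.test. Uses the conventional relative tolerance
# when collecting tables no more probable than the observed one.
hypergeom_p2 <- function(both, a_only, b_only, neither) {
  m <- both + a_only        # margin: gene A mutated
  n <- b_only + neither
  k <- both + b_only        # margin: gene B mutated
  support <- max(0L, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  sum(d[d <= stats::dhyper(both, m, n, k) * (1 + 1e-7)])
}

# Brute-force panel-selection oracle: enumerate all size-n subsets and
# pick the best by lexicographic comparison of the sorted per-variant
# keys (score desc, VAF desc, chrom asc, pos asc). Independent of
# select_panel's sort-and-take-top implementation.
oracle_panel <- function(scored, n) {
  n <- max(2L, min(10L, n))
  k <- min(n, nrow(scored))
  idx <- utils::combn(seq_len(nrow(scored)), k, simplify = FALSE)
  key_mat <- function(rows) {
    r <- scored[rows, , drop = FALSE]
    ord <- order(-r$score, -r$ffpe_vaf, r$chrom, r$pos)
    r <- r[ord, , drop = FALSE]
    list(score = r$score, vaf = r$ffpe_vaf, chrom = r$chrom, pos = r$pos,
         rows = rows[ord])
  }
  better <- function(a, b) {
    # TRUE if subset a beats subset b
    for (i in seq_along(a$score)) {
      if (a$score[i] != b$score[i]) return(a$score[i] > b$score[i])
      if (a$vaf[i] != b$vaf[i]) return(a$vaf[i] > b$vaf[i])
      if (a$chrom[i] != b$chrom[i]) return(a$chrom[i] < b$chrom[i])
      if (a$pos[i] != b$pos[i]) return(a$pos[i] < b$pos[i])
    }
    FALSE
  }
  best <- key_mat(idx[[1L]])
  for (s in idx[-1L]) {
    cand <- key_mat(s)
    if (better(cand, best)) best <- cand
  }
  best$rows
}

# Random scored variant table for oracle comparisons.
random_scored <- function(n, seed, tie_heavy = FALSE) {
  set.seed(seed)
  v <- do.call(rbind, lapply(seq_len(n), function(i) {
    make_variant(gene = paste0("G", i), chrom = sample(c("chr1", "chr2"), 1),
                 pos = sample.int(1000L, 1L),
                 consequence = sample(c("missense", "nonsense",
                                        "frameshift"), 1),
                 ffpe_vaf = if (tie_heavy)
                   sample(c(0.1, 0.2, 0.3), 1) else round(runif(1), 3),
                 cosmic_count = sample(c(0L, 2L, 10L), 1),
                 clinvar_pathogenic = runif(1) < 0.5,
                 predicted_deleterious = runif(1) < 0.5,
                 gene_role = sample(GENE_ROLES, 1),
                 in_house_validated = runif(1) < 0.3)
  }))
  score_variants(somatic_variants(v))
}
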