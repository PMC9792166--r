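#' Cohort-level mutational-spectrum summary
#'
#' Computes, over a cohort of somatic-variant profiles: per-gene mutation
#' frequency (fraction of patients with at least one mutation in the gene),
#' the distribution of mutation consequence classes over all pooled
#' mutations, and the per-patient mutation counts.
#'
#' @param variants A somatic-variant data frame covering the whole cohort
#'   (one row per mutation, `patient_id` column identifying the patient).
#' @param patients Optional character vector of all patient identifiers,
#'   including patients with zero retained mutations; defaults to the
#'   patients present in `variants`.
#' @return An object of class `cohort_summary`: a list with `n_patients`,
#'   `per_gene_frequency` (named numeric, sorted decreasing),
#'   `class_distribution` (named numeric over [CONSEQUENCE_CLASSES],
#'   summing to 1), and `mutations_per_patient` (named integer vector).
#' @export
summarize_cohort <- function(variants, patients = NULL) {
  stopifnot(is.data.frame(variants))
  if (is.null(patients)) patients <- unique(variants$patient_id)
  patients <- as.character(patients)
  if (length(patients) == 0L) stop("empty cohort", call. = FALSE)

  counts <- table(factor(variants$patient_id, levels = patients))
  mutations_per_patient <- stats::setNames(as.integer(counts), patients)

  # gene counted once per patient
  pg <- unique(variants[, c("patient_id", "gene")])
  gene_tab <- table(pg$gene)
  per_gene <- sort(as.numeric(gene_tab) / length(patients), decreasing = TRUE)
  names(per_gene) <- names(gene_tab)[order(as.numeric(gene_tab),
                                           decreasing = TRUE)]

  cls <- table(factor(variants$consequence, levels = CONSEQUENCE_CLASSES))
  n_mut <- nrow(variants)
  class_distribution <- if (n_mut > 0L) as.numeric(cls) / n_mut else
    rep(NA_real_, length(CONSEQUENCE_CLASSES))
  names(class_distribution) <- CONSEQUENCE_CLASSES

  structure(list(n_patients = length(patients),
                 per_gene_frequency = per_gene,
                 class_distribution = class_distribution,
                 mutations_per_patient = mutations_per_patient),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: %d patients, %d mutations (mean %.1f/patient)\n",
              x$n_patients, sum(x$mutations_per_patient),
              mean(x$mutations_per_patient)))
  top <- utils::head(x$per_gene_frequency, 5L)
  cat("Top genes:",
      paste(sprintf("%s %.1f%%", names(top), 100 * top), collapse = ", "),
      "\n")
  cd <- x$class_distribution[x$class_distribution > 0]
  cat("Classes:",
      paste(sprintf("%s %.1f%%", names(cd), 100 * cd), collapse = ", "), "\n")
  invisible(x)
}

#' Exact test of association for one gene pair
#'
#' Two-sided exact (hypergeometric) test on the patient-level 2x2
#' mutated/not-mutated contingency table, with the conditional
#' maximum-likelihood odds ratio (0 and `Inf` permitted).
#'
#' @param both,a_only,b_only,neither Cell counts of the 2x2 table.
#' @return A list with `p_value` and `odds_ratio`.
#' @export
gene_pair_test <- function(both, a_only, b_only, neither) {
  tab <- matrix(c(both, a_only, b_only, neither), nrow = 2L, byrow = TRUE)
  ft <- stats::fisher.test(tab)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Pairwise co-occurrence / mutual-exclusivity analysis
#'
#' For each unordered pair of the supplied genes, builds the patient-level
#' 2x2 table (mutated / not mutated) and applies a two-sided exact test.
#' A pair is labelled `co_occurring` when `p < alpha` and the odds ratio
#' exceeds 1, `mutually_exclusive` when `p < alpha` and the odds ratio is
#' below 1, and `none` otherwise.
#'
#' @param variants Cohort somatic-variant data frame.
#' @param genes Character vector of gene symbols (>= 2). Genes absent from
#'   the cohort are dropped with a warning.
#' @param alpha Significance level for the labels, default 0.05.
#' @param p_adjust If `TRUE`, Benjamini-Hochberg-adjust the p-values before
#'   labelling (off by default).
#' @param patients Optional full patient vector (as in [summarize_cohort]).
#' @return A data frame with one row per pair: `gene_a`, `gene_b`, the four
#'   cell counts, `odds_ratio`, `p_value`, `label`. The `alpha` and
#'   `p_adjust` settings are recorded as attributes.
#' @export
pairwise_interaction <- function(variants, genes, alpha = 0.05,
                                 p_adjust = FALSE, patients = NULL) {
  stopifnot(is.data.frame(variants))
  if (is.null(patients)) patients <- unique(variants$patient_id)
  patients <- as.character(patients)
  genes <- unique(as.character(genes))
  present <- vapply(genes, function(g) any(variants$gene == g), logical(1))
  if (any(!present)) {
    warning("gene(s) absent from cohort excluded: ",
            paste(genes[!present], collapse = ", "), call. = FALSE)
    genes <- genes[present]
  }
  if (length(genes) < 2L) stop("need at least 2 genes present in the cohort",
                               call. = FALSE)

  mut <- vapply(genes, function(g) {
    patients %in% unique(variants$patient_id[variants$gene == g])
  }, logical(length(patients)))
  if (length(patients) == 1L) mut <- matrix(mut, nrow = 1L,
                                            dimnames = list(NULL, genes))

  pairs <- utils::combn(genes, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- mut[, pairs[1L, i]]
    b <- mut[, pairs[2L, i]]
    both <- sum(a & b); a_only <- sum(a & !b)
    b_only <- sum(!a & b); neither <- sum(!a & !b)
    tst <- gene_pair_test(both, a_only, b_only, neither)
    data.frame(gene_a = pairs[1L, i], gene_b = pairs[2L, i],
               both = both, a_only = a_only, b_only = b_only,
               neither = neither, odds_ratio = tst$odds_ratio,
               p_value = tst$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  p_lab <- if (p_adjust) stats::p.adjust(out$p_value, method = "BH") else
    out$p_value
  out$label <- ifelse(p_lab < alpha & out$odds_ratio > 1, "co_occurring",
               ifelse(p_lab < alpha & out$odds_ratio < 1,
                      "mutually_exclusive", "none"))
  attr(out, "alpha") <- alpha
  attr(out, "p_adjust") <- if (p_adjust) "BH" else "none"
  out
}

#' Parse the residue position from a protein change
#'
#' `"G12D"` (or `"p.G12D"`) parses to position 12 with reference residue
#' `"G"`; nonsense notation such as `"R213*"` is handled.
#'
#' @param protein_change Character vector of protein changes.
#' @return Integer vector of residue positions (`NA` where unparseable).
#' @export
parse_protein_position <- function(protein_change) {
  x <- sub("^p\\.", "", as.character(protein_change))
  m <- regexpr("^[A-Za-z*]{1,3}[0-9]+", x)
  out <- rep(NA_integer_, length(x))
  hit <- !is.na(x) & m > 0L
  tok <- substr(x[hit], 1L, attr(m, "match.length")[hit])
  out[hit] <- as.integer(sub("^[A-Za-z*]{1,3}", "", tok))
  out
}

parse_protein_ref <- function(protein_change) {
  x <- sub("^p\\.", "", as.character(protein_change))
  m <- regexpr("^[A-Za-z*]{1,3}(?=[0-9])", x, perl = TRUE)
  out <- rep(NA_character_, length(x))
  hit <- !is.na(x) & m > 0L
  out[hit] <- substr(x[hit], 1L, attr(m, "match.length")[hit])
  out
}

#' Fraction of gene-mutated patients hit at hotspot residues
#'
#' @param variants Cohort somatic-variant data frame.
#' @param gene Gene symbol; must be mutated in at least one patient.
#' @param residues Residue positions defining the hotspot, either integers
#'   (e.g. `12`) or residue labels (e.g. `"G12"`, matched on position).
#' @return Fraction of patients with a mutation in `gene` that carry at
#'   least one mutation whose protein position is in `residues`.
#' @export
hotspot_fraction <- function(variants, gene, residues) {
  stopifnot(is.data.frame(variants))
  gv <- variants[variants$gene == gene, , drop = FALSE]
  if (nrow(gv) == 0L) stop("gene not mutated in cohort: ", gene,
                           call. = FALSE)
  if (length(residues) == 0L) return(0)
  if (is.character(residues)) residues <- parse_protein_position(residues)
  residues <- as.integer(residues)
  pos <- parse_protein_position(gv$protein_change)
  hit <- tapply(pos %in% residues, gv$patient_id, any)
  mean(hit)
}

#' Write landscape summary tables
#'
#' Writes the gene-frequency, class-distribution, and per-patient burden
#' tables of a [summarize_cohort] result as TSV files.
#'
#' @param summary A `cohort_summary` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "cohort_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "gene_frequency.tsv")
  utils::write.table(data.frame(gene = names(summary$per_gene_frequency),
                                frequency = summary$per_gene_frequency),
                     p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "class_distribution.tsv")
  utils::write.table(data.frame(consequence = names(summary$class_distribution),
                                fraction = summary$class_distribution),
                     p2, sep = "\t", quote = FALSE, row.names = FALSE)
  p3 <- file.path(dir, "mutation_burden.tsv")
  utils::write.table(data.frame(patient_id = names(summary$mutations_per_patient),
                                n_mutations = summary$mutations_per_patient),
                     p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
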