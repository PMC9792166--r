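#' Score somatic variants for plasma tracking
#'
#' Ranks a patient's non-synonymous somatic variants by a criterion-count
#' score. Four boolean criteria are evaluated per variant:
#'
#' * `pathogenic_deleterious` — annotated pathogenic in ClinVar **or**
#'   predicted deleterious (SIFT/PolyPhen-style flag);
#' * `stopgain_in_tsg` — a nonsense (stop-gained) mutation in a tumor
#'   suppressor gene;
#' * `recurrent_oncogene` — a mutation in an oncogene reported strictly
#'   more than 3 times in COSMIC;
#' * `in_house_validated` — previously validated as tumor-derived.
#'
#' The score is the number of satisfied criteria plus the FFPE VAF (a
#' fraction in `[0, 1]`), so the criterion count dominates and the VAF
#' orders variants within a criterion tier.
#'
#' @param variants Somatic-variant data frame. Synonymous variants are
#'   ineligible and raise an error; drop them first (see
#'   [eligible_variants]).
#' @return The input with added columns `pathogenic_deleterious`,
#'   `stopgain_in_tsg`, `recurrent_oncogene` (criterion flags) and `score`.
#' @export
score_variants <- function(variants) {
  stopifnot(is.data.frame(variants))
  if (any(variants$consequence == "synonymous")) {
    stop("synonymous variants are ineligible for tracking at row(s) ",
         paste(utils::head(which(variants$consequence == "synonymous"), 5L),
               collapse = ", "), call. = FALSE)
  }
  variants$pathogenic_deleterious <-
    variants$clinvar_pathogenic | variants$predicted_deleterious
  variants$stopgain_in_tsg <-
    variants$consequence == "nonsense" &
    variants$gene_role == "tumor_suppressor"
  variants$recurrent_oncogene <-
    variants$gene_role == "oncogene" & variants$cosmic_count > 3L
  n_flags <- variants$pathogenic_deleterious + variants$stopgain_in_tsg +
    variants$recurrent_oncogene + variants$in_house_validated
  variants$score <- n_flags + variants$ffpe_vaf
  variants
}

#' Variants eligible for panel selection
#'
#' Removes synonymous variants and variants in low-complexity regions
#' (exclusion criterion).
#'
#' @param variants Somatic-variant data frame.
#' @return The eligible subset.
#' @export
eligible_variants <- function(variants) {
  variants[variants$consequence != "synonymous" &
             !variants$in_low_complexity, , drop = FALSE]
}

panel_order <- function(scored) {
  order(-scored$score, -scored$ffpe_vaf, scored$chrom, scored$pos)
}

#' Select a personalized tracking panel
#'
#' Picks the top-scoring variants for plasma tracking: sort by score
#' descending, ties broken by FFPE VAF descending and then by genomic
#' coordinate (chrom, pos) ascending, giving a total, input-order-invariant
#' ordering. The requested panel size is clamped to `[2, 10]`; the default
#' of 5 matches routine practice for this assay class.
#'
#' @param scored Output of [score_variants] for a single patient (already
#'   restricted to eligible variants, see [eligible_variants]).
#' @param n Requested panel size, default 5; clamped to `[2, 10]`.
#' @return A `tracking_panel`: list with `patient_id`, `members` (the
#'   selected rows with `rank` and advisory `detectable_in_plasma` flag),
#'   `n_requested`, and `below_minimum` (`TRUE` when fewer than 2 eligible
#'   variants were available).
#' @export
select_panel <- function(scored, n = 5L) {
  stopifnot(is.data.frame(scored))
  if (!"score" %in% names(scored)) scored <- score_variants(scored)
  scored <- eligible_variants(scored)
  if (nrow(scored) == 0L) stop("no trackable mutations", call. = FALSE)
  n <- as.integer(max(2L, min(10L, n)))
  below_minimum <- nrow(scored) < 2L
  if (below_minimum) {
    warning("fewer than 2 eligible variants; panel emitted below minimum",
            call. = FALSE)
  }
  ord <- panel_order(scored)
  members <- scored[ord[seq_len(min(n, nrow(scored)))], , drop = FALSE]
  members$rank <- seq_len(nrow(members))
  members$detectable_in_plasma <- plasma_detectability(members$ffpe_vaf)
  rownames(members) <- NULL
  structure(list(patient_id = members$patient_id[1L], members = members,
                 n_requested = n, below_minimum = below_minimum),
            class = "tracking_panel")
}

#' @export
print.tracking_panel <- function(x, ...) {
  cat(sprintf("Tracking panel for %s: %d variant(s)%s\n", x$patient_id,
              nrow(x$members),
              if (x$below_minimum) " [below minimum of 2]" else ""))
  print(x$members[, c("rank", "gene", "protein_change", "ffpe_vaf", "score",
                      "detectable_in_plasma")])
  invisible(x)
}

#' Advisory plasma-detectability flag
#'
#' Variants with FFPE VAF below 10% have a markedly lower plasma detection
#' rate; this flag (inclusive at the threshold) is attached to panel
#' members as advisory metadata and never used for exclusion.
#'
#' @param ffpe_vaf Numeric vector of FFPE VAFs.
#' @param threshold Detectability threshold, default `0.10`.
#' @return Logical vector, `TRUE` where `ffpe_vaf >= threshold`.
#' @export
plasma_detectability <- function(ffpe_vaf, threshold = 0.10) {
  ffpe_vaf >= threshold
}

#' Write a tracking panel as TSV
#' @param panel A `tracking_panel`.
#' @param path Output path.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "tracking_panel"))
  utils::write.table(panel$members, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
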