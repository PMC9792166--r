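#' Read a drug-actionability rule table
#'
#' Rules map gene/protein-change patterns to drugs with a direction
#' (sensitivity or resistance) and an evidence level: `L1` (approved drug,
#' clinical evidence), `L3` (compelling clinical evidence for an
#' investigational drug), `L4` (laboratory evidence), `R1` (approved-drug
#' resistance). Three match modes are supported: `exact_protein_change`
#' (e.g. `V600E`), `codon_set` (reference residue + position, so `G12D`
#' and `G12V` both match codon `G12`), and `any_nonsynonymous`.
#'
#' The bundled default table (`system.file("extdata",
#' "actionability_rules.tsv", package = "mrdtrack")`) encodes the standard
#' colorectal-cancer biomarkers (KRAS/NRAS anti-EGFR resistance, BRAF
#' V600E, KRAS G12C) plus laboratory-evidence placeholder rows; it is a
#' synthetic, editable starting point, not a clinical knowledge base.
#'
#' @param path Path to a rule TSV with columns `gene`, `match_mode`,
#'   `targets` (comma-separated; empty for `any_nonsynonymous`), `drug`,
#'   `direction`, `level`, and optionally `note`. Defaults to the bundled
#'   table.
#' @return A validated rule data frame.
#' @export
read_actionability_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "actionability_rules.tsv",
                        package = "mrdtrack")
  }
  rules <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             quote = "")
  validate_rules(rules)
}

validate_rules <- function(rules) {
  req <- c("gene", "match_mode", "targets", "drug", "direction", "level")
  missing_cols <- setdiff(req, names(rules))
  if (length(missing_cols) > 0L) {
    stop("rule table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(rules$match_mode %in%
                  c("exact_protein_change", "codon_set", "any_nonsynonymous")),
            all(rules$direction %in% c("sensitivity", "resistance")),
            all(rules$level %in% c("L1", "L3", "L4", "R1")))
  rules$targets[is.na(rules$targets)] <- ""
  needs_targets <- rules$match_mode != "any_nonsynonymous"
  if (any(needs_targets & !nzchar(rules$targets))) {
    stop("codon_set/exact rules require non-empty targets", call. = FALSE)
  }
  if (!"note" %in% names(rules)) rules$note <- ""
  rules
}

rule_matches <- function(rule, variants) {
  hit <- variants$gene == rule$gene
  if (!any(hit)) return(hit)
  targets <- trimws(strsplit(rule$targets, ",")[[1L]])
  pc <- sub("^p\\.", "", variants$protein_change)
  if (rule$match_mode == "exact_protein_change") {
    hit & !is.na(pc) & pc %in% targets
  } else if (rule$match_mode == "codon_set") {
    codon <- paste0(parse_protein_ref(pc), parse_protein_position(pc))
    hit & !is.na(pc) & codon %in% targets
  } else {
    hit & variants$consequence != "synonymous"
  }
}

#' Classify one patient's variants against an actionability rule table
#'
#' @param variants Somatic-variant data frame for a single patient.
#' @param rules Rule table from [read_actionability_rules].
#' @return An `actionability_report`: list with `patient_id`, `hits`
#'   (one row per matching variant x rule pair), and `summary` — named
#'   logical flags, one per evidence level and per direction, each the OR
#'   over the patient's hits.
#' @export
classify_patient <- function(variants, rules) {
  rules <- validate_rules(rules)
  stopifnot(is.data.frame(variants))
  pid <- if (nrow(variants) > 0L) variants$patient_id[1L] else NA_character_
  if (nrow(variants) > 0L && length(unique(variants$patient_id)) > 1L) {
    stop("classify_patient expects variants from a single patient",
         call. = FALSE)
  }
  hits <- list()
  for (i in seq_len(nrow(rules))) {
    m <- rule_matches(rules[i, ], variants)
    if (any(m)) {
      hits[[length(hits) + 1L]] <-
        data.frame(variants[m, c("gene", "chrom", "pos", "ref", "alt",
                                 "protein_change")],
                   drug = rules$drug[i], direction = rules$direction[i],
                   level = rules$level[i], match_mode = rules$match_mode[i],
                   stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hits) > 0L) do.call(rbind, hits) else
    data.frame(gene = character(0), chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               protein_change = character(0), drug = character(0),
               direction = character(0), level = character(0),
               match_mode = character(0), stringsAsFactors = FALSE)
  levels_all <- c("L1", "L3", "L4", "R1")
  dirs_all <- c("sensitivity", "resistance")
  summary <- c(stats::setNames(levels_all %in% hits$level, levels_all),
               stats::setNames(dirs_all %in% hits$direction, dirs_all))
  structure(list(patient_id = pid, hits = hits, summary = summary),
            class = "actionability_report")
}

#' @export
print.actionability_report <- function(x, ...) {
  cat(sprintf("Actionability report for %s: %d hit(s)\n", x$patient_id,
              nrow(x$hits)))
  if (nrow(x$hits) > 0L) {
    print(x$hits[, c("gene", "protein_change", "drug", "direction", "level")])
  }
  invisible(x)
}

#' Cohort actionability fractions
#'
#' Fraction of patients with at least one actionability hit, per evidence
#' level and per direction; each patient counts once per category
#' regardless of hit count.
#'
#' @param variants Cohort somatic-variant data frame.
#' @param rules Rule table.
#' @param patients Optional full patient vector.
#' @return Named numeric vector of fractions (`L1`, `L3`, `L4`, `R1`,
#'   `sensitivity`, `resistance`).
#' @export
cohort_actionability <- function(variants, rules, patients = NULL) {
  if (is.null(patients)) patients <- unique(variants$patient_id)
  patients <- as.character(patients)
  if (length(patients) == 0L) stop("empty cohort", call. = FALSE)
  flags <- vapply(patients, function(p) {
    classify_patient(variants[variants$patient_id == p, , drop = FALSE],
                     rules)$summary
  }, logical(6L))
  rowMeans(flags)
}
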