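write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_manifest <- function(dir, command, params) {
  manifest <- list(command = command,
                   package = "mrdtrack",
                   version = as.character(utils::packageVersion("mrdtrack")),
                   parameters = params)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.json"))
}

#' Generate and write a full synthetic dataset
#'
#' Runs every synthetic-data generator under one configuration and writes
#' the TSV dialects the pipeline consumes: tumor variants, patient table,
#' tracking panels, plasma measurements, longitudinal event timelines,
#' titration series and healthy-donor panel, plus a machine-readable
#' `manifest.json` recording the seed and parameters. Byte-identical
#' under a repeated seed.
#'
#' @param out_dir Output directory, created if needed.
#' @param config A [sim_config].
#' @return Invisibly, the output directory.
#' @export
run_simulate <- function(out_dir, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_tumor_cohort(config)
  tit <- generate_titration_panel(config)
  sim <- generate_timelines(cohort, config)

  write_tsv(cohort$patients, file.path(out_dir, "patients.tsv"))
  write_variants(cohort$variants, file.path(out_dir, "variants.tsv"))
  panels <- do.call(rbind, lapply(sim$panels, function(p) p$members))
  write_tsv(panels, file.path(out_dir, "panels.tsv"))
  write_tsv(sim$measurements, file.path(out_dir, "plasma_measurements.tsv"))
  write_tsv(sim$calls, file.path(out_dir, "calls.tsv"))
  write_timelines(sim$timelines, file.path(out_dir, "timelines.tsv"))
  write_tsv(tit$titration, file.path(out_dir, "titration.tsv"))
  write_tsv(tit$healthy, file.path(out_dir, "healthy.tsv"))
  cfg <- unclass(config)
  cfg$gene_table <- NULL
  write_manifest(out_dir, "simulate", cfg)
  invisible(out_dir)
}

#' Cohort profiling: landscape and actionability outputs
#'
#' Reads a cohort variant table and writes the mutational-landscape
#' summary tables (gene frequency, class distribution, per-patient
#' burden), the pairwise co-occurrence/mutual-exclusivity table for the
#' most frequently mutated genes, and the per-level/direction cohort
#' actionability fractions.
#'
#' @param variants_path Path to a cohort somatic-variant TSV.
#' @param out_dir Output directory.
#' @param rules_path Optional actionability rule table; bundled default
#'   when `NULL`.
#' @param top_genes Number of top genes entering the pairwise analysis,
#'   default 10.
#' @param alpha Significance level for interaction labels, default 0.05.
#' @return Invisibly, the output directory.
#' @export
run_profile <- function(variants_path, out_dir, rules_path = NULL,
                        top_genes = 10L, alpha = 0.05) {
  variants <- read_variants(variants_path)
  variants <- filter_spectrum(variants)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- summarize_cohort(variants)
  write_cohort_summary(summary, out_dir)
  genes <- utils::head(names(summary$per_gene_frequency), top_genes)
  if (length(genes) >= 2L) {
    inter <- pairwise_interaction(variants, genes, alpha = alpha)
    write_tsv(inter, file.path(out_dir, "interactions.tsv"))
  }
  rules <- read_actionability_rules(rules_path)
  act <- cohort_actionability(variants, rules)
  write_tsv(data.frame(category = names(act), fraction = act),
            file.path(out_dir, "actionability.tsv"))
  write_manifest(out_dir, "profile",
                 list(variants = variants_path, top_genes = top_genes,
                      alpha = alpha, min_vaf = 0.05))
  invisible(out_dir)
}

#' Panel selection, plasma calling and longitudinal monitoring
#'
#' Ties the tracking stages together: selects a tracking panel per
#' patient from the tumor variant table, calls ctDNA positivity for every
#' plasma sample in the measurement table at the given limit of
#' detection, and — when a timeline table is supplied — summarizes
#' molecular relapse and lead time per patient. Measurements for patients
#' without a panel are recorded as per-patient errors and the run
#' continues; measurements whose variant key is not in the patient's
#' panel are skipped with a warning.
#'
#' @param variants_path Path to the tumor variant TSV.
#' @param plasma_path Path to the plasma measurement TSV (`sample_id`,
#'   `patient_id`, `chrom`, `pos`, `ref`, `alt`, `depth`, `alt_reads`).
#' @param out_dir Output directory.
#' @param timeline_path Optional longitudinal event TSV (see
#'   [read_timelines]).
#' @param lod Positivity threshold, default `5e-4` (0.05% VAF).
#' @param panel_size Panel size, default 5.
#' @param min_depth Amplicon QC floor, default 10000.
#' @return Invisibly, a list with `panels`, `calls` (data frame),
#'   `monitoring` (data frame or `NULL`), and `errors`.
#' @export
run_track <- function(variants_path, plasma_path, out_dir,
                      timeline_path = NULL, lod = 5e-4, panel_size = 5L,
                      min_depth = 10000L) {
  variants <- read_variants(variants_path)
  plasma <- amplicon_measurements(
    utils::read.delim(plasma_path, sep = "\t", stringsAsFactors = FALSE),
    min_depth = min_depth)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  panels <- build_panels(variants, n = panel_size)
  write_tsv(do.call(rbind, lapply(panels, function(p) p$members)),
            file.path(out_dir, "panels.tsv"))

  errors <- character(0)
  calls <- list()
  for (sid in unique(plasma$sample_id)) {
    meas <- plasma[plasma$sample_id == sid, , drop = FALSE]
    pid <- meas$patient_id[1L]
    panel <- panels[[pid]]
    if (is.null(panel)) {
      errors <- c(errors, sprintf("%s: no tracking panel for patient %s",
                                  sid, pid))
      next
    }
    key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)
    known <- key(meas) %in% key(panel$members)
    if (any(!known)) {
      warning(sprintf("%s: %d measurement(s) with unknown variant key skipped",
                      sid, sum(!known)), call. = FALSE)
      meas <- meas[known, , drop = FALSE]
    }
    if (nrow(meas) == 0L) {
      errors <- c(errors, sprintf("%s: no tracked measurements", sid))
      next
    }
    calls[[sid]] <- as.data.frame(call_sample(meas, lod,
                                              min_depth = min_depth))
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  write_tsv(calls, file.path(out_dir, "calls.tsv"))

  monitoring <- NULL
  if (!is.null(timeline_path)) {
    timelines <- read_timelines(timeline_path)
    monitoring <- do.call(rbind, lapply(timelines, function(tl) {
      v <- monitor_patient(tl)
      data.frame(patient_id = v$patient_id,
                 molecular_relapse_date = v$molecular_relapse_date,
                 clinical_relapse_date = v$clinical_relapse_date,
                 lead_time_months = v$lead_time_months,
                 cea_elevated_at_molecular_relapse =
                   v$cea_elevated_at_molecular_relapse,
                 stringsAsFactors = FALSE)
    }))
    rownames(monitoring) <- NULL
    write_tsv(monitoring, file.path(out_dir, "monitoring.tsv"))
    write_tsv(swimmer_export(timelines),
              file.path(out_dir, "swimmer.tsv"))
  }
  if (length(errors) > 0L) {
    writeLines(errors, file.path(out_dir, "errors.log"))
  }
  write_manifest(out_dir, "track",
                 list(variants = variants_path, plasma = plasma_path,
                      timelines = timeline_path, lod = lod,
                      panel_size = panel_size, min_depth = min_depth))
  invisible(list(panels = panels, calls = calls, monitoring = monitoring,
                 errors = errors))
}
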