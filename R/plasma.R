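#' Build and validate a plasma amplicon-measurement table
#'
#' One row per tracked mutation per plasma sample, from ultra-deep amplicon
#' sequencing (average depth around 100,000X per amplicon). Computes the
#' VAF (`alt_reads / depth`, 0 where depth is 0) and the per-amplicon QC
#' flag (`depth >= 10000`).
#'
#' @param df Data frame with columns `sample_id`, `patient_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `depth`, `alt_reads`.
#' @param min_depth QC depth threshold, default 10000.
#' @return The validated data frame with `vaf` and `qc_pass` columns.
#' @export
amplicon_measurements <- function(df, min_depth = 10000L) {
  req <- c("sample_id", "patient_id", "chrom", "pos", "ref", "alt",
           "depth", "alt_reads")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("measurement table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$depth <- as.integer(df$depth)
  df$alt_reads <- as.integer(df$alt_reads)
  if (any(df$depth < 0L) || any(df$alt_reads < 0L)) {
    stop("depth and alt_reads must be non-negative", call. = FALSE)
  }
  if (any(df$alt_reads > df$depth)) {
    stop("alt_reads exceeds depth at row(s) ",
         paste(utils::head(which(df$alt_reads > df$depth), 5L),
               collapse = ", "), call. = FALSE)
  }
  df$vaf <- ifelse(df$depth > 0L, df$alt_reads / df$depth, 0)
  df$qc_pass <- df$depth >= min_depth
  df
}

#' Per-amplicon depth QC
#'
#' Amplicons with coverage below `min_depth` (default 10,000X) are
#' considered failed and removed from positivity and mean-VAF computation;
#' exactly 10,000X passes.
#'
#' @param measurements Amplicon-measurement data frame.
#' @param min_depth Minimum retained depth (inclusive), default 10000.
#' @return List with `retained` and `failed` data frames.
#' @export
qc_amplicons <- function(measurements, min_depth = 10000L) {
  stopifnot(is.data.frame(measurements))
  if (nrow(measurements) == 0L) {
    return(list(retained = measurements, failed = measurements))
  }
  keep <- measurements$depth >= min_depth
  list(retained = measurements[keep, , drop = FALSE],
       failed = measurements[!keep, , drop = FALSE])
}

#' Variant allele fraction
#'
#' @param alt_reads Alternate-allele read count(s).
#' @param depth Total depth(s); must be positive.
#' @return `alt_reads / depth`.
#' @export
compute_vaf <- function(alt_reads, depth) {
  if (any(depth == 0)) stop("VAF undefined at zero depth", call. = FALSE)
  stopifnot(all(alt_reads >= 0), all(alt_reads <= depth))
  alt_reads / depth
}

#' Calibrate the assay limit of detection
#'
#' Given titration-series observations (reference-standard mixtures at
#' known average VAFs) and a healthy-donor background panel, chooses the
#' smallest candidate threshold whose empirical false-positive rate over
#' the healthy measurements is strictly below `fp_max`. The false-positive
#' rate of a threshold `t` is the fraction of healthy measurements with
#' VAF at or above `t` (per-measurement definition; a per-sample rate —
#' any tracked site at or above `t` — is also reported when sample
#' identifiers are supplied).
#'
#' @param titration Data frame with columns `level` (expected mixture VAF)
#'   and `vaf` (observed), or a named list mapping level to observed-VAF
#'   vectors.
#' @param healthy_vafs Numeric vector of healthy-panel observed VAFs, or a
#'   data frame with columns `vaf` and optionally `sample_id`.
#' @param candidates Candidate thresholds, ascending; default
#'   `c(1e-4, 2e-4, 5e-4, 1e-3)` (0.01%-0.1%).
#' @param fp_max Maximum tolerated false-positive rate, default 0.01.
#' @return An `lod_calibration`: list with `candidates`, `fp_table`
#'   (candidate, per-measurement and, when available, per-sample FP rate),
#'   `chosen_lod`, `fp_rate_at_lod`, and `per_level_detection` (fraction
#'   of titration observations at each level detected at the chosen
#'   threshold).
#' @export
calibrate_lod <- function(titration, healthy_vafs,
                          candidates = c(1e-4, 2e-4, 5e-4, 1e-3),
                          fp_max = 0.01) {
  if (is.list(titration) && !is.data.frame(titration)) {
    titration <- data.frame(
      level = rep(as.numeric(names(titration)),
                  vapply(titration, length, integer(1))),
      vaf = unlist(titration, use.names = FALSE))
  }
  stopifnot(is.data.frame(titration), all(c("level", "vaf") %in%
                                            names(titration)))
  sample_id <- NULL
  if (is.data.frame(healthy_vafs)) {
    if ("sample_id" %in% names(healthy_vafs)) {
      sample_id <- healthy_vafs$sample_id
    }
    healthy_vafs <- healthy_vafs$vaf
  }
  if (length(healthy_vafs) == 0L) stop("healthy panel is empty",
                                       call. = FALSE)
  if (is.unsorted(candidates)) stop("candidates must be sorted ascending",
                                    call. = FALSE)

  fp_meas <- vapply(candidates,
                    function(t) mean(healthy_vafs >= t), numeric(1))
  fp_table <- data.frame(candidate = candidates, fp_rate = fp_meas)
  if (!is.null(sample_id)) {
    fp_table$fp_rate_per_sample <- vapply(candidates, function(t) {
      mean(tapply(healthy_vafs >= t, sample_id, any))
    }, numeric(1))
  }
  ok <- fp_meas < fp_max
  if (!any(ok)) {
    stop("no candidate threshold achieves false-positive rate below ",
         fp_max, "; fp table:\n",
         paste(sprintf("  %.5f -> %.4f", candidates, fp_meas),
               collapse = "\n"), call. = FALSE)
  }
  chosen <- candidates[which(ok)[1L]]
  per_level <- tapply(titration$vaf >= chosen, titration$level, mean)
  structure(list(candidates = candidates, fp_table = fp_table,
                 chosen_lod = chosen,
                 fp_rate_at_lod = fp_meas[which(ok)[1L]],
                 per_level_detection =
                   stats::setNames(as.numeric(per_level),
                                   names(per_level))),
            class = "lod_calibration")
}

#' @export
print.lod_calibration <- function(x, ...) {
  cat(sprintf("LOD calibration: chosen threshold %.4f%% VAF (FP rate %.3f%%)\n",
              100 * x$chosen_lod, 100 * x$fp_rate_at_lod))
  print(x$fp_table)
  cat("Detection at chosen LOD by titration level:\n")
  print(round(x$per_level_detection, 3))
  invisible(x)
}

#' Call ctDNA positivity for one plasma sample
#'
#' A sample is ctDNA-positive when at least one tracked mutation on a
#' QC-passing amplicon has VAF at or above the limit of detection. The
#' sample mean VAF follows a two-branch rule: the mean over positive
#' mutations when any exist, otherwise the mean over all retained tracked
#' mutations. When every amplicon fails depth QC the call is
#' `indeterminate` (`positive = NA`), never silently negative.
#'
#' @param measurements Amplicon-measurement data frame for one sample.
#' @param lod Limit of detection (VAF fraction), e.g. `5e-4` for 0.05%.
#' @param min_depth Amplicon QC depth threshold, default 10000.
#' @return A `ctdna_call`: list with `sample_id`, `patient_id`, `status`
#'   (`"positive"`, `"negative"`, `"indeterminate"`), `positive` (logical,
#'   `NA` when indeterminate), `positive_mutations`, `mean_vaf`,
#'   `n_failed_amplicons`, `lod`, and the retained measurements.
#' @export
call_sample <- function(measurements, lod, min_depth = 10000L) {
  stopifnot(is.data.frame(measurements), nrow(measurements) >= 1L,
            lod >= 0)
  if (!"vaf" %in% names(measurements)) {
    measurements <- amplicon_measurements(measurements,
                                          min_depth = min_depth)
  }
  qc <- qc_amplicons(measurements, min_depth = min_depth)
  retained <- qc$retained
  sample_id <- measurements$sample_id[1L]
  patient_id <- measurements$patient_id[1L]
  if (nrow(retained) == 0L) {
    return(structure(list(sample_id = sample_id, patient_id = patient_id,
                          status = "indeterminate", positive = NA,
                          positive_mutations = retained,
                          mean_vaf = NA_real_,
                          n_failed_amplicons = nrow(qc$failed), lod = lod,
                          tracked = retained),
                     class = "ctdna_call"))
  }
  pos <- retained$vaf >= lod
  mean_vaf <- if (any(pos)) mean(retained$vaf[pos]) else mean(retained$vaf)
  structure(list(sample_id = sample_id, patient_id = patient_id,
                 status = if (any(pos)) "positive" else "negative",
                 positive = any(pos),
                 positive_mutations = retained[pos, , drop = FALSE],
                 mean_vaf = mean_vaf,
                 n_failed_amplicons = nrow(qc$failed), lod = lod,
                 tracked = retained),
            class = "ctdna_call")
}

#' @export
print.ctdna_call <- function(x, ...) {
  cat(sprintf("ctDNA call %s [%s]: %s; mean VAF %s; %d failed amplicon(s)\n",
              x$sample_id, x$patient_id, x$status,
              ifelse(is.na(x$mean_vaf), "NA",
                     sprintf("%.4f%%", 100 * x$mean_vaf)),
              x$n_failed_amplicons))
  invisible(x)
}

#' One-row data-frame view of a ctDNA call
#' @param x A `ctdna_call`.
#' @param ... Unused.
#' @return Data frame with sample/patient ids, status, positivity, mean
#'   VAF, counts of positive and failed amplicons.
#' @export
as.data.frame.ctdna_call <- function(x, ...) {
  data.frame(sample_id = x$sample_id, patient_id = x$patient_id,
             status = x$status, positive = x$positive,
             mean_vaf = x$mean_vaf,
             n_positive = nrow(x$positive_mutations),
             n_tracked = nrow(x$tracked),
             n_failed_amplicons = x$n_failed_amplicons,
             stringsAsFactors = FALSE)
}

#' Plasma cfDNA input QC
#'
#' cfDNA input passes when the concentration is at least 0.1 ng/uL **or**
#' the total mass is at least 3 ng.
#'
#' @param concentration_ng_per_ul cfDNA concentration in ng/uL.
#' @param total_ng Total cfDNA mass in ng.
#' @return Logical pass/fail.
#' @export
cfdna_input_check <- function(concentration_ng_per_ul, total_ng) {
  stopifnot(all(concentration_ng_per_ul >= 0), all(total_ng >= 0))
  concentration_ng_per_ul >= 0.1 | total_ng >= 3
}
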