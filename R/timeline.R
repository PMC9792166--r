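DAYS_PER_MONTH <- 30.4375  # calendar-neutral month for lead-time reporting

#' Classify a serum CEA value
#'
#' Carcinoembryonic antigen below 5 ng/mL is considered normal; 5 ng/mL
#' and above is elevated.
#'
#' @param value_ng_per_ml CEA value(s) in ng/mL, non-negative.
#' @return Character vector, `"normal"` or `"elevated"`.
#' @export
classify_cea <- function(value_ng_per_ml) {
  stopifnot(all(value_ng_per_ml >= 0, na.rm = TRUE))
  ifelse(value_ng_per_ml < 5, "normal", "elevated")
}

#' Construct a patient monitoring timeline
#'
#' @param patient_id Patient identifier.
#' @param surgery_date Surgery date (`Date` or ISO-8601 string).
#' @param samples Data frame of serial plasma samples with columns `date`,
#'   `positive` (logical ctDNA call; `NA` for indeterminate), and
#'   optionally `sample_id`, `mean_vaf`, `cea` (ng/mL, `NA` if not
#'   measured). Must be strictly ordered by date.
#' @param clinical_relapse_date Date of clinically confirmed relapse
#'   (imaging/biopsy), or `NULL`.
#' @param adjuvant_windows Optional data frame of treatment windows with
#'   columns `start`, `end`, `label`.
#' @return A `patient_timeline` object.
#' @details Samples drawn on the surgery date count as pre-operative
#'   (pre-operative draws precede surgery by design; the surgery-day tie
#'   is resolved to the pre-operative side). A clinical relapse date, when
#'   present, must fall after surgery.
#' @export
patient_timeline <- function(patient_id, surgery_date, samples,
                             clinical_relapse_date = NULL,
                             adjuvant_windows = NULL) {
  surgery_date <- as.Date(surgery_date)
  stopifnot(is.data.frame(samples),
            all(c("date", "positive") %in% names(samples)))
  samples$date <- as.Date(samples$date)
  if (!"mean_vaf" %in% names(samples)) samples$mean_vaf <- NA_real_
  if (!"cea" %in% names(samples)) samples$cea <- NA_real_
  if (!"sample_id" %in% names(samples)) {
    samples$sample_id <- paste0(patient_id, "_S", seq_len(nrow(samples)))
  }
  if (is.unsorted(samples$date, strictly = TRUE)) {
    stop("samples must be strictly ordered by date", call. = FALSE)
  }
  if (!is.null(clinical_relapse_date)) {
    clinical_relapse_date <- as.Date(clinical_relapse_date)
    if (!is.na(clinical_relapse_date) &&
        clinical_relapse_date <= surgery_date) {
      stop("clinical relapse date must fall after surgery", call. = FALSE)
    }
    if (is.na(clinical_relapse_date)) clinical_relapse_date <- NULL
  }
  samples$postoperative <- samples$date > surgery_date
  structure(list(patient_id = patient_id, surgery_date = surgery_date,
                 samples = samples,
                 clinical_relapse_date = clinical_relapse_date,
                 adjuvant_windows = adjuvant_windows),
            class = "patient_timeline")
}

#' @export
print.patient_timeline <- function(x, ...) {
  cat(sprintf("Timeline %s: surgery %s, %d sample(s)%s\n", x$patient_id,
              format(x$surgery_date), nrow(x$samples),
              if (!is.null(x$clinical_relapse_date))
                paste0(", clinical relapse ",
                       format(x$clinical_relapse_date)) else ""))
  invisible(x)
}

#' Detect molecular relapse on a timeline
#'
#' Molecular relapse is the earliest post-operative plasma sample with a
#' positive ctDNA call. Pre-operative samples never qualify and
#' indeterminate calls are skipped (not treated as negative).
#'
#' @param timeline A `patient_timeline`.
#' @return The molecular relapse `Date`, or `NA` (class `Date`) when all
#'   post-operative calls are negative or indeterminate.
#' @export
detect_molecular_relapse <- function(timeline) {
  stopifnot(inherits(timeline, "patient_timeline"))
  post <- timeline$samples[timeline$samples$postoperative, , drop = FALSE]
  if (nrow(post) == 0L) stop("no post-operative samples", call. = FALSE)
  pos <- which(!is.na(post$positive) & post$positive)
  if (length(pos) == 0L) return(as.Date(NA))
  post$date[pos[1L]]
}

#' Lead time of molecular over clinical relapse
#'
#' Months (30.4375 days) between molecular relapse detection and clinical
#' relapse diagnosis. Positive values mean the molecular call preceded the
#' clinical diagnosis; negative values (molecular call after clinical
#' diagnosis) are permitted and flagged with a warning.
#'
#' @param timeline A `patient_timeline`.
#' @return Lead time in months, or `NA` when either date is missing.
#' @export
lead_time <- function(timeline) {
  stopifnot(inherits(timeline, "patient_timeline"))
  if (is.null(timeline$clinical_relapse_date)) return(NA_real_)
  mol <- detect_molecular_relapse(timeline)
  if (is.na(mol)) return(NA_real_)
  lt <- as.numeric(timeline$clinical_relapse_date - mol) / DAYS_PER_MONTH
  if (lt < 0) {
    warning("molecular relapse called after clinical diagnosis (negative ",
            "lead time)", call. = FALSE)
  }
  lt
}

#' Summarize monitoring for one patient
#'
#' @param timeline A `patient_timeline`.
#' @return A `monitoring_verdict`: list with `patient_id`,
#'   `molecular_relapse_date`, `clinical_relapse_date`,
#'   `lead_time_months`, and `cea_elevated_at_molecular_relapse`
#'   (`NA` when no molecular relapse or no CEA measurement at that draw).
#' @export
monitor_patient <- function(timeline) {
  mol <- detect_molecular_relapse(timeline)
  lt <- if (!is.na(mol) && !is.null(timeline$clinical_relapse_date)) {
    lead_time(timeline)
  } else NA_real_
  cea_flag <- NA
  if (!is.na(mol)) {
    cea <- timeline$samples$cea[timeline$samples$date == mol]
    if (length(cea) == 1L && !is.na(cea)) {
      cea_flag <- classify_cea(cea) == "elevated"
    }
  }
  structure(list(patient_id = timeline$patient_id,
                 molecular_relapse_date = mol,
                 clinical_relapse_date =
                   if (is.null(timeline$clinical_relapse_date)) as.Date(NA)
                 else timeline$clinical_relapse_date,
                 lead_time_months = lt,
                 cea_elevated_at_molecular_relapse = cea_flag),
            class = "monitoring_verdict")
}

months_post_op <- function(dates, surgery_date) {
  as.numeric(as.Date(dates) - as.Date(surgery_date)) / DAYS_PER_MONTH
}

#' Long-format export for swimmer plots
#'
#' Flattens timelines to one row per event (sample call, clinical relapse,
#' treatment window) with dates expressed in months after surgery, sorted
#' by patient then date, ready for any plotting layer.
#'
#' @param timelines A list of `patient_timeline` objects (or a single one).
#' @return A data frame with columns `patient_id`, `event`,
#'   `months_post_op`, `months_end` (treatment windows only), `result`,
#'   `mean_vaf`, `cea`, `label`.
#' @export
swimmer_export <- function(timelines) {
  if (inherits(timelines, "patient_timeline")) timelines <- list(timelines)
  stopifnot(length(timelines) >= 1L)
  rows <- lapply(timelines, function(tl) {
    s <- tl$samples
    out <- data.frame(patient_id = tl$patient_id, event = "sample",
                      months_post_op = months_post_op(s$date,
                                                      tl$surgery_date),
                      months_end = NA_real_,
                      result = ifelse(is.na(s$positive), "indeterminate",
                                      ifelse(s$positive, "positive",
                                             "negative")),
                      mean_vaf = s$mean_vaf, cea = s$cea,
                      label = NA_character_, stringsAsFactors = FALSE)
    if (!is.null(tl$clinical_relapse_date)) {
      out <- rbind(out, data.frame(
        patient_id = tl$patient_id, event = "clinical_relapse",
        months_post_op = months_post_op(tl$clinical_relapse_date,
                                        tl$surgery_date),
        months_end = NA_real_, result = NA_character_,
        mean_vaf = NA_real_, cea = NA_real_, label = NA_character_,
        stringsAsFactors = FALSE))
    }
    if (!is.null(tl$adjuvant_windows) && nrow(tl$adjuvant_windows) > 0L) {
      aw <- tl$adjuvant_windows
      out <- rbind(out, data.frame(
        patient_id = tl$patient_id, event = "treatment",
        months_post_op = months_post_op(aw$start, tl$surgery_date),
        months_end = months_post_op(aw$end, tl$surgery_date),
        result = NA_character_, mean_vaf = NA_real_, cea = NA_real_,
        label = aw$label, stringsAsFactors = FALSE))
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_id, out$months_post_op), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read patient timelines from the long event TSV dialect
#'
#' The event table has one row per clinical/molecular event with columns
#' `patient_id`, `event_type` (`surgery`, `sample`, `relapse`,
#' `treatment`), `date` (ISO-8601), and payload columns `sample_id`,
#' `positive`, `mean_vaf`, `cea`, `end_date`, `label` as applicable.
#'
#' @param path Path to the TSV.
#' @return Named list of `patient_timeline` objects.
#' @export
read_timelines <- function(path) {
  ev <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          quote = "")
  req <- c("patient_id", "event_type", "date")
  if (!all(req %in% names(ev))) {
    stop("timeline table requires columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  ev$date <- as.Date(ev$date)
  tls <- lapply(split(ev, ev$patient_id), function(e) {
    surg <- e$date[e$event_type == "surgery"]
    if (length(surg) != 1L) {
      stop("patient ", e$patient_id[1L],
           ": exactly one surgery event required", call. = FALSE)
    }
    s <- e[e$event_type == "sample", , drop = FALSE]
    s <- s[order(s$date), , drop = FALSE]
    samples <- data.frame(date = s$date,
                          positive = if ("positive" %in% names(s))
                            as.logical(s$positive) else NA,
                          stringsAsFactors = FALSE)
    for (col in c("sample_id", "mean_vaf", "cea")) {
      if (col %in% names(s)) samples[[col]] <- s[[col]]
    }
    relapse <- e$date[e$event_type == "relapse"]
    aw <- NULL
    tr <- e[e$event_type == "treatment", , drop = FALSE]
    if (nrow(tr) > 0L) {
      aw <- data.frame(start = tr$date, end = as.Date(tr$end_date),
                       label = if ("label" %in% names(tr)) tr$label else
                         "treatment", stringsAsFactors = FALSE)
    }
    patient_timeline(e$patient_id[1L], surg, samples,
                     clinical_relapse_date =
                       if (length(relapse) > 0L) relapse[1L] else NULL,
                     adjuvant_windows = aw)
  })
  tls
}

#' Write patient timelines in the long event TSV dialect
#' @param timelines List of `patient_timeline` objects.
#' @param path Output path.
#' @export
write_timelines <- function(timelines, path) {
  if (inherits(timelines, "patient_timeline")) timelines <- list(timelines)
  rows <- lapply(timelines, function(tl) {
    s <- tl$samples
    out <- data.frame(patient_id = tl$patient_id, event_type = "surgery",
                      date = tl$surgery_date, sample_id = NA_character_,
                      positive = NA, mean_vaf = NA_real_, cea = NA_real_,
                      end_date = as.Date(NA), label = NA_character_,
                      stringsAsFactors = FALSE)
    out <- rbind(out, data.frame(
      patient_id = tl$patient_id, event_type = "sample", date = s$date,
      sample_id = s$sample_id, positive = s$positive,
      mean_vaf = s$mean_vaf, cea = s$cea, end_date = as.Date(NA),
      label = NA_character_, stringsAsFactors = FALSE))
    if (!is.null(tl$clinical_relapse_date)) {
      out <- rbind(out, data.frame(
        patient_id = tl$patient_id, event_type = "relapse",
        date = tl$clinical_relapse_date, sample_id = NA_character_,
        positive = NA, mean_vaf = NA_real_, cea = NA_real_,
        end_date = as.Date(NA), label = NA_character_,
        stringsAsFactors = FALSE))
    }
    if (!is.null(tl$adjuvant_windows) && nrow(tl$adjuvant_windows) > 0L) {
      aw <- tl$adjuvant_windows
      out <- rbind(out, data.frame(
        patient_id = tl$patient_id, event_type = "treatment",
        date = aw$start, sample_id = NA_character_, positive = NA,
        mean_vaf = NA_real_, cea = NA_real_, end_date = aw$end,
        label = aw$label, stringsAsFactors = FALSE))
    }
    out
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
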