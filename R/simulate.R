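#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the previous RNG
#' state, so seeded generators do not disturb the caller's stream. A
#' `NULL` seed evaluates the expression on the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default cohort gene model
#'
#' Per-patient mutation probabilities and roles for the headline genes of
#' a colorectal-cancer panel. Frequencies follow the cohort structure the
#' simulator emulates (APC 69.9%, TP53 63.1%, KRAS 39.8%, FAT4 27.2%, ...).
#'
#' @return Data frame with columns `gene`, `freq`, `role`.
#' @export
default_gene_table <- function() {
  data.frame(
    gene = c("APC", "TP53", "KRAS", "FAT4", "PIK3CA", "SMAD4", "FBXW7",
             "TRRAP", "RNF213", "TCF7L2", "ATM", "ARID1A", "ATR", "AMER1",
             "RNF43", "NF1", "BRAF", "NRAS"),
    freq = c(0.699, 0.631, 0.398, 0.272, 0.150, 0.120, 0.110,
             0.100, 0.100, 0.100, 0.090, 0.080, 0.080, 0.060,
             0.060, 0.050, 0.050, 0.019),
    role = c("tumor_suppressor", "tumor_suppressor", "oncogene",
             "tumor_suppressor", "oncogene", "tumor_suppressor",
             "tumor_suppressor", "other", "other", "other",
             "tumor_suppressor", "tumor_suppressor", "tumor_suppressor",
             "tumor_suppressor", "tumor_suppressor", "tumor_suppressor",
             "oncogene", "oncogene"),
    stringsAsFactors = FALSE)
}

filler_gene_pool <- function() {
  c("ACVR2A", "AXIN2", "B2M", "BMPR2", "BRCA1", "BRCA2", "CDKN2A",
    "CTNNB1", "EGFR", "ERBB2", "ERBB3", "GNAS", "HRAS", "JAK1", "KIT",
    "MAP2K1", "MET", "MLH1", "MSH2", "MSH3", "MSH6", "MTOR", "NOTCH1",
    "PDGFRA", "PMS2", "POLE", "PTEN", "RET", "SMAD2", "SMAD3", "SOX9",
    "STK11", "TGFBR2", "TSC1", "TSC2", "UBR5", "ZFHX3")
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators. Defaults
#' emulate the study conditions of a stage I-IV colorectal-cancer MRD
#' cohort profiled on a 95-gene panel with 5-plex ultra-deep plasma
#' amplicon sequencing; see the methods vignette for the rationale behind
#' each value.
#'
#' @param seed Integer master seed; fully determines all generator output.
#' @param n_patients Cohort size, default 103.
#' @param stage_distribution Probabilities over TNM stages I-IV
#'   (renormalized over patients with known stage).
#' @param gene_table Data frame (`gene`, `freq`, `role`): per-patient
#'   mutation probability and role of each headline gene; see
#'   [default_gene_table].
#' @param class_probabilities Mutation-class probabilities (missense
#'   0.723, frameshift 0.135, nonsense 0.123, remainder split over splice,
#'   in-frame indel and other).
#' @param mutations_per_patient_mean Mean somatic mutations per patient,
#'   default 7.
#' @param p_no_mutation Probability a patient has no detectable mutation,
#'   default 0.01.
#' @param mutation_count_size Negative-binomial size for the heavy-tailed
#'   extra-mutation count, default 0.5.
#' @param ffpe_vaf_shape Beta shape parameters of the FFPE VAF
#'   distribution, default `c(2, 4)` (mean 1/3).
#' @param kras_codon_probs Distribution over resistance codons for the
#'   primary KRAS mutation; G12 at 0.568 reproduces the codon-12 hotspot
#'   share of KRAS-mutated patients.
#' @param braf_v600e_fraction Fraction of BRAF-mutated patients carrying
#'   V600E, default 0.38.
#' @param amplicon_depth_mean Mean amplicon depth, default 100000.
#' @param depth_dispersion Negative-binomial size of the depth
#'   distribution, default 50.
#' @param amplicon_fail_rate Fraction of amplicons drawn with sub-10,000X
#'   depth, default 0.038.
#' @param background_error_mean Mean per-site background error rate,
#'   default 1.5e-4.
#' @param background_error_shape1 First Beta shape of the per-site error
#'   distribution (overdispersion knob), default 3.
#' @param heterozygosity Expected mutant-allele fraction per shed diploid
#'   genome, default 0.5.
#' @param detection_target Marginal pre-operative ctDNA detection
#'   probability the stage-dependent shedding model is calibrated to,
#'   default 0.905.
#' @param stage1_relative_detection Stage-I detection relative to stages
#'   II-IV, default 0.75.
#' @param shedding_meanlog,shedding_sdlog Log-normal parameters of the
#'   tumor fraction in shedding patients, defaults `log(0.01)` and 1.
#' @param relapse_probability Probability of clinical relapse within
#'   follow-up, default `2/19`.
#' @param relapse_ramp_months Months before clinical relapse over which
#'   tumor shedding ramps up, default 8.
#' @param relapse_peak_tf Tumor fraction reached at clinical relapse,
#'   default 0.1.
#' @param relapse_doubling_months ctDNA doubling time during the ramp,
#'   default 1.
#' @param cea_preop_elevated_rate Marginal pre-operative CEA elevation
#'   rate, default 0.413.
#' @param cea_relapse_sensitivity Probability CEA is elevated at draws in
#'   the relapse ramp window, default 0.3.
#' @param followup_months Post-operative follow-up horizon, default 16.
#' @param panel_size Tracking-panel size, default 5.
#' @param lod Positivity threshold used when simulating calls, default
#'   5e-4 (0.05% VAF).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 103L,
                       stage_distribution = c(I = 0.134, II = 0.423,
                                              III = 0.412, IV = 0.031),
                       gene_table = default_gene_table(),
                       class_probabilities = c(missense = 0.723,
                                               frameshift = 0.135,
                                               nonsense = 0.123,
                                               splice = 0.010,
                                               inframe_indel = 0.006,
                                               synonymous = 0,
                                               other = 0.003),
                       mutations_per_patient_mean = 7,
                       p_no_mutation = 0.01,
                       mutation_count_size = 0.5,
                       ffpe_vaf_shape = c(2, 4),
                       kras_codon_probs = c(G12 = 0.568, G13 = 0.261,
                                            Q61 = 0.080, A146 = 0.060,
                                            K117 = 0.031),
                       braf_v600e_fraction = 0.38,
                       amplicon_depth_mean = 100000L,
                       depth_dispersion = 50,
                       amplicon_fail_rate = 0.038,
                       background_error_mean = 1.5e-4,
                       background_error_shape1 = 4,
                       heterozygosity = 0.5,
                       detection_target = 0.905,
                       stage1_relative_detection = 0.75,
                       shedding_meanlog = log(0.01),
                       shedding_sdlog = 1,
                       relapse_probability = 2 / 19,
                       relapse_ramp_months = 8,
                       relapse_peak_tf = 0.1,
                       relapse_doubling_months = 1,
                       cea_preop_elevated_rate = 0.413,
                       cea_relapse_sensitivity = 0.3,
                       followup_months = 16,
                       panel_size = 5L,
                       lod = 5e-4) {
  cfg <- as.list(environment())
  .check_probs <- function(p, name, sum_to_one = TRUE) {
    if (any(p < 0) || any(p > 1)) {
      stop("invalid probabilities in ", name, call. = FALSE)
    }
    if (sum_to_one && abs(sum(p) - 1) > 1e-6) {
      stop(name, " must sum to 1", call. = FALSE)
    }
  }
  .check_probs(cfg$stage_distribution, "stage_distribution")
  .check_probs(cfg$class_probabilities, "class_probabilities")
  .check_probs(cfg$gene_table$freq, "gene_table$freq", sum_to_one = FALSE)
  .check_probs(cfg$kras_codon_probs, "kras_codon_probs")
  stopifnot(cfg$n_patients >= 1L, cfg$mutations_per_patient_mean > 0,
            cfg$background_error_mean > 0, cfg$background_error_mean < 1,
            cfg$detection_target > 0, cfg$detection_target < 1,
            cfg$heterozygosity > 0, cfg$heterozygosity <= 1,
            cfg$lod > 0)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

background_error_shape2 <- function(config) {
  config$background_error_shape1 *
    (1 - config$background_error_mean) / config$background_error_mean
}

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")

random_protein_change <- function(n, consequence) {
  pos <- sample(5:1500, n, replace = TRUE)
  ref <- sample(AA1, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(AA1, r), 1L), character(1))
  out <- paste0(ref, pos, alt)
  out[consequence == "nonsense"] <- paste0(ref, pos, "*")[consequence ==
                                                            "nonsense"]
  out[consequence == "frameshift"] <- paste0(ref, pos, "fs")[consequence ==
                                                               "frameshift"]
  out[consequence %in% c("splice", "other")] <- NA_character_
  out
}

random_alleles <- function(n, consequence) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                character(1))
  ins <- consequence == "frameshift"
  ref[ins] <- paste0(ref[ins], "A")
  alt[ins] <- substr(ref[ins], 1L, 1L)
  del3 <- consequence == "inframe_indel"
  ref[del3] <- paste0(ref[del3], "AAA")
  alt[del3] <- substr(ref[del3], 1L, 1L)
  list(ref = ref, alt = unname(alt))
}

#' Generate a synthetic tumor cohort
#'
#' Draws per-patient somatic-variant profiles with the statistical
#' structure of the emulated cohort: stage-distributed patients, headline
#' genes present by independent per-patient Bernoulli draws at their
#' configured frequencies, a heavy-tailed total mutation count (mean 7),
#' configured mutation-class probabilities, Beta-distributed FFPE VAFs,
#' KRAS codon-12 hotspots in 56.8% of KRAS-mutated patients, and
#' annotation evidence (COSMIC recurrence, pathogenicity flags, gene
#' roles) drawn from documented conditional rules.
#'
#' @param config A [sim_config].
#' @return A list with `patients` (data frame `patient_id`, `stage`) and
#'   `variants` (a validated somatic-variant data frame). Fully
#'   deterministic under `config$seed`.
#' @export
generate_tumor_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    pid <- sprintf("SIM%03d", seq_len(n))
    stage <- sample(names(config$stage_distribution), n, replace = TRUE,
                    prob = config$stage_distribution)
    patients <- data.frame(patient_id = pid, stage = stage,
                           stringsAsFactors = FALSE)

    gt <- config$gene_table
    fillers <- setdiff(filler_gene_pool(), gt$gene)
    extra_mu <- max(0.1, config$mutations_per_patient_mean /
                      (1 - config$p_no_mutation) - sum(gt$freq))
    role_of <- stats::setNames(gt$role, gt$gene)

    # pass 1: gene lists and hotspot-primary decisions per patient
    genes_by_patient <- vector("list", n)
    forced_by_patient <- vector("list", n)
    for (i in seq_len(n)) {
      if (stats::runif(1) < config$p_no_mutation) next
      present <- gt$gene[stats::runif(nrow(gt)) < gt$freq]
      n_extra <- stats::rnbinom(1L, size = config$mutation_count_size,
                                mu = extra_mu)
      if (length(present) == 0L && n_extra == 0L) n_extra <- 1L
      genes_i <- c(present, sample(fillers, n_extra, replace = TRUE))
      forced <- integer(0)
      if ("KRAS" %in% genes_i) forced <- c(forced,
                                           which(genes_i == "KRAS")[1L])
      if ("NRAS" %in% genes_i) forced <- c(forced,
                                           which(genes_i == "NRAS")[1L])
      if ("BRAF" %in% genes_i &&
          stats::runif(1) < config$braf_v600e_fraction) {
        forced <- c(forced, which(genes_i == "BRAF")[1L])
      }
      genes_by_patient[[i]] <- genes_i
      forced_by_patient[[i]] <- forced
    }

    # hotspot primaries are missense by construction; compensate the
    # remaining class draws so the pooled class distribution stays at
    # the configured probabilities
    m_total <- sum(lengths(genes_by_patient))
    f_total <- sum(lengths(forced_by_patient))
    cls <- config$class_probabilities
    p_mis <- cls[["missense"]]
    p_adj <- cls
    if (m_total > f_total && f_total > 0L && p_mis < 1) {
      p_mis_adj <- min(1, max(0, (p_mis * m_total - f_total) /
                                (m_total - f_total)))
      p_adj["missense"] <- p_mis_adj
      rest <- setdiff(names(cls), "missense")
      p_adj[rest] <- cls[rest] * (1 - p_mis_adj) / (1 - p_mis)
    }

    # pass 2: draw mutations
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      genes_i <- genes_by_patient[[i]]
      if (is.null(genes_i)) next
      forced <- forced_by_patient[[i]]
      m <- length(genes_i)
      consequence <- sample(names(p_adj), m, replace = TRUE, prob = p_adj)
      consequence[forced] <- "missense"
      vaf <- stats::rbeta(m, config$ffpe_vaf_shape[1L],
                          config$ffpe_vaf_shape[2L])
      alleles <- random_alleles(m, consequence)
      role <- ifelse(genes_i %in% names(role_of), role_of[genes_i], "other")
      pchange <- random_protein_change(m, consequence)
      for (k in forced) {
        if (genes_i[k] == "KRAS") {
          codon <- sample(names(config$kras_codon_probs), 1L,
                          prob = config$kras_codon_probs)
          alt_aa <- sample(setdiff(AA1, substr(codon, 1L, 1L)), 1L)
          pchange[k] <- paste0(codon, alt_aa)
        } else if (genes_i[k] == "NRAS") {
          pchange[k] <- paste0("Q61", sample(c("K", "R", "L"), 1L))
        } else {
          pchange[k] <- "V600E"
        }
      }
      hotspot <- seq_len(m) %in% forced
      # annotation evidence: truncating variants are mostly flagged
      # pathogenic; hotspots carry large COSMIC recurrence
      truncating <- consequence %in% c("nonsense", "frameshift")
      clinvar <- stats::runif(m) < ifelse(hotspot, 0.9,
                                          ifelse(truncating, 0.5, 0.25))
      delet <- stats::runif(m) < ifelse(hotspot | truncating, 0.85, 0.55)
      cosmic <- ifelse(hotspot,
                       stats::rnbinom(m, size = 2, mu = 5000),
                       ifelse(role == "oncogene",
                              stats::rnbinom(m, size = 1, mu = 6),
                              stats::rpois(m, 0.6)))
      rows[[i]] <- data.frame(
        patient_id = pid[i], gene = genes_i,
        chrom = paste0("chr", (abs(vapply(genes_i, function(g)
          sum(utf8ToInt(g)), numeric(1))) %% 22L) + 1L),
        pos = sample.int(199000000L, m) + 1000000L,
        ref = alleles$ref, alt = alleles$alt,
        consequence = consequence, protein_change = pchange,
        ffpe_vaf = vaf, cosmic_count = as.integer(cosmic),
        clinvar_pathogenic = clinvar, predicted_deleterious = delet,
        gene_role = role,
        in_house_validated = stats::runif(m) < 0.3,
        in_low_complexity = stats::runif(m) < 0.02,
        stringsAsFactors = FALSE)
    }
    variants <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    rownames(variants) <- NULL
    list(patients = patients, variants = somatic_variants(variants))
  })
}

#' Simulate one plasma sample for a tracking panel
#'
#' Draws per-amplicon depths around the configured mean (a configurable
#' fraction deliberately below the 10,000X QC floor), per-site background
#' error rates from the Beta error model, and alternate read counts from a
#' binomial whose success probability is
#' `tumor_fraction * heterozygosity + site_error` (an overdispersed
#' beta-binomial counting model).
#'
#' @param panel A `tracking_panel` (or its `members` data frame).
#' @param tumor_fraction Tumor fraction of the sample in `[0, 1]`.
#' @param config A [sim_config].
#' @param sample_id Sample identifier.
#' @param seed Optional seed; `NULL` (default) draws from the current RNG
#'   stream so callers can orchestrate determinism.
#' @param fail_rate Fraction of amplicons drawn with sub-10,000X depth;
#'   defaults to `config$amplicon_fail_rate`.
#' @return An amplicon-measurement data frame (one row per tracked site).
#' @export
generate_plasma_sample <- function(panel, tumor_fraction, config,
                                   sample_id = "S1", seed = NULL,
                                   fail_rate = config$amplicon_fail_rate) {
  stopifnot(inherits(config, "sim_config"),
            tumor_fraction >= 0, tumor_fraction <= 1)
  members <- if (inherits(panel, "tracking_panel")) panel$members else panel
  stopifnot(is.data.frame(members), nrow(members) >= 1L)
  with_seed(seed, {
    m <- nrow(members)
    failed <- stats::runif(m) < fail_rate
    depth <- stats::rnbinom(m, size = config$depth_dispersion,
                            mu = config$amplicon_depth_mean) + 1L
    depth[failed] <- sample(2000:9999, sum(failed), replace = TRUE)
    e <- stats::rbeta(m, config$background_error_shape1,
                      background_error_shape2(config))
    p <- pmin(1, tumor_fraction * config$heterozygosity + e)
    alt <- stats::rbinom(m, depth, p)
    amplicon_measurements(data.frame(
      sample_id = sample_id, patient_id = members$patient_id,
      chrom = members$chrom, pos = members$pos, ref = members$ref,
      alt = members$alt, depth = depth, alt_reads = alt,
      stringsAsFactors = FALSE))
  })
}

#' Simulate an LOD titration series and healthy-donor panel
#'
#' Titration observations mimic reference-standard mixtures at known
#' average VAFs processed through the amplicon workflow; healthy samples
#' carry background error only. Reference-standard input is plentiful, so
#' no depth failures are simulated here.
#'
#' @param config A [sim_config].
#' @param levels Expected mixture VAFs; must include 0. Default
#'   `c(0.03, 0.005, 0.001, 0.0005, 0)` (3%-0%).
#' @param replicates Measurements per titration level, default 50.
#' @param n_healthy Number of healthy-donor samples, default 150.
#' @param n_sites Tracked sites per healthy sample, default 5.
#' @param seed Seed; defaults to `config$seed + 1`.
#' @return List with `titration` (`level`, `replicate`, `depth`,
#'   `alt_reads`, `vaf`) and `healthy` (`sample_id`, `site`, `depth`,
#'   `alt_reads`, `vaf`).
#' @export
generate_titration_panel <- function(config,
                                     levels = c(0.03, 0.005, 0.001,
                                                5e-4, 0),
                                     replicates = 50L, n_healthy = 150L,
                                     n_sites = 5L,
                                     seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"), 0 %in% levels)
  with_seed(seed, {
    draw <- function(expected_vaf, n) {
      depth <- stats::rnbinom(n, size = config$depth_dispersion,
                              mu = config$amplicon_depth_mean) + 1L
      e <- stats::rbeta(n, config$background_error_shape1,
                        background_error_shape2(config))
      p <- pmin(1, expected_vaf + e)
      alt <- stats::rbinom(n, depth, p)
      data.frame(depth = depth, alt_reads = alt, vaf = alt / depth)
    }
    titration <- do.call(rbind, lapply(levels, function(lv) {
      cbind(data.frame(level = lv, replicate = seq_len(replicates)),
            draw(lv, replicates))
    }))
    healthy <- do.call(rbind, lapply(seq_len(n_healthy), function(i) {
      cbind(data.frame(sample_id = sprintf("HD%03d", i),
                       site = seq_len(n_sites)),
            draw(0, n_sites))
    }))
    list(titration = titration, healthy = healthy)
  })
}

# Deterministic quadrature over the Beta error model: probability a null
# (background-only) measurement reaches `threshold`, at the mean depth.
null_positive_rate <- function(config, threshold,
                               depth = config$amplicon_depth_mean,
                               k_grid = 400L) {
  q <- (seq_len(k_grid) - 0.5) / k_grid
  e <- stats::qbeta(q, config$background_error_shape1,
                    background_error_shape2(config))
  mean(stats::pbinom(ceiling(threshold * depth) - 1L, depth, e,
                     lower.tail = FALSE))
}

# Per-site detection probability at tumor fraction tf, by the same
# quadrature; then per-sample detection for a k-site panel.
site_detection_rate <- function(config, tf, threshold,
                                depth = config$amplicon_depth_mean,
                                k_grid = 200L) {
  q <- (seq_len(k_grid) - 0.5) / k_grid
  e <- stats::qbeta(q, config$background_error_shape1,
                    background_error_shape2(config))
  p <- pmin(1, tf * config$heterozygosity + e)
  mean(stats::pbinom(ceiling(threshold * depth) - 1L, depth, p,
                     lower.tail = FALSE))
}

#' Stage-dependent shedding calibration
#'
#' Pre-operative shedding is a two-component mixture: a patient either
#' sheds (tumor fraction log-normal) or does not (tumor fraction 0). The
#' per-stage shedder probability is solved so that the marginal
#' probability of a positive pre-operative call equals
#' `config$detection_target` (default 0.905), with stage-I detection at
#' `stage1_relative_detection` times the stage II-IV level, accounting for
#' the null false-positive rate and the imperfect detection of shedders
#' (both computed by deterministic quadrature over the error model).
#'
#' @param config A [sim_config].
#' @param lod Positivity threshold; defaults to `config$lod`.
#' @return Named numeric vector of per-stage shedder probabilities.
#' @export
stage_shedder_probs <- function(config, lod = config$lod) {
  w <- config$stage_distribution
  r <- config$stage1_relative_detection
  base <- config$detection_target / (w[["I"]] * r + sum(w) - w[["I"]])
  d_target <- c(I = r * base, II = base, III = base, IV = base)
  d_target <- pmin(d_target, 1)

  # effective sites per sample: depth-failed amplicons drop out of calling
  n_eff <- config$panel_size * (1 - config$amplicon_fail_rate)
  p_site_null <- null_positive_rate(config, lod)
  p0 <- 1 - (1 - p_site_null)^n_eff
  # detection among shedders, integrating over the log-normal tumor
  # fraction on a quantile grid
  qs <- (seq_len(100L) - 0.5) / 100
  tfs <- stats::qlnorm(qs, config$shedding_meanlog, config$shedding_sdlog)
  p_shed <- mean(vapply(tfs, function(tf) {
    1 - (1 - site_detection_rate(config, tf, lod))^n_eff
  }, numeric(1)))
  d <- (d_target - p0) / (p_shed - p0)
  pmin(pmax(d, 0), 1)
}

#' Simulate longitudinal monitoring timelines
#'
#' For each patient with a trackable panel: one pre-operative plasma
#' sample (7 days before surgery) with stage-dependent shedding, then
#' post-operative samples at 1 month and every 6 months thereafter within
#' the follow-up horizon. Relapsing patients (probability
#' `relapse_probability`) receive a clinical relapse date 9-15 months
#' after surgery and exponentially ramping tumor shedding over the
#' preceding `relapse_ramp_months`, so molecular detection precedes the
#' clinical diagnosis; monitoring stops at clinical relapse. CEA values
#' are drawn with the configured marginal pre-operative elevation rate and
#' relapse sensitivity. Stage-III patients carry an adjuvant-chemotherapy
#' window.
#'
#' @param cohort Output of [generate_tumor_cohort].
#' @param config A [sim_config].
#' @param panels Optional named list of `tracking_panel` objects; built
#'   with [score_variants]/[select_panel] when `NULL`.
#' @param lod Positivity threshold for the simulated calls; defaults to
#'   `config$lod`.
#' @param seed Seed; defaults to `config$seed + 2`.
#' @return A `sim_timelines` list: `timelines` (named list of
#'   `patient_timeline`), `measurements` (all simulated amplicon rows),
#'   `calls` (one row per sample with `phase` `"preop"`/`"postop"`), and
#'   `panels`.
#' @export
generate_timelines <- function(cohort, config, panels = NULL,
                               lod = config$lod,
                               seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(panels)) panels <- build_panels(cohort$variants, config)
  d_stage <- stage_shedder_probs(config, lod)
  with_seed(seed, {
    timelines <- list()
    meas_all <- list()
    calls_all <- list()
    for (i in seq_len(nrow(cohort$patients))) {
      pid <- cohort$patients$patient_id[i]
      stage <- cohort$patients$stage[i]
      panel <- panels[[pid]]
      if (is.null(panel)) next
      surgery <- as.Date("2021-06-01") + (i - 1L)

      relapse <- stats::runif(1) < config$relapse_probability
      relapse_month <- if (relapse) stats::runif(1, 9, 15) else Inf
      clinical_relapse <- if (relapse) {
        surgery + round(relapse_month * DAYS_PER_MONTH)
      } else NULL

      visit_months <- c(-7 / DAYS_PER_MONTH, 1,
                        seq(7, config$followup_months, by = 6))
      visit_months <- visit_months[visit_months < relapse_month]

      shedder <- stats::runif(1) < d_stage[[stage]]
      tf_pre <- if (shedder) {
        stats::rlnorm(1, config$shedding_meanlog, config$shedding_sdlog)
      } else 0

      samples <- list()
      for (m in visit_months) {
        preop <- m <= 0
        tf <- if (preop) {
          tf_pre
        } else if (relapse && m >= relapse_month -
                     config$relapse_ramp_months) {
          config$relapse_peak_tf *
            2^(-(relapse_month - m) / config$relapse_doubling_months)
        } else 0
        sid <- sprintf("%s_%s", pid,
                       if (preop) "PRE" else sprintf("M%02d", round(m)))
        meas <- generate_plasma_sample(panel, min(tf, 1), config,
                                       sample_id = sid)
        call <- call_sample(meas, lod)
        elev <- if (preop) {
          stats::runif(1) < config$cea_preop_elevated_rate
        } else if (relapse && m >= relapse_month -
                     config$relapse_ramp_months) {
          stats::runif(1) < config$cea_relapse_sensitivity
        } else FALSE
        cea <- if (elev) 5 * exp(abs(stats::rnorm(1, 0, 0.8))) else
          stats::runif(1, 0.5, 4.9)
        meas_all[[length(meas_all) + 1L]] <- meas
        calls_all[[length(calls_all) + 1L]] <-
          cbind(as.data.frame(call),
                data.frame(phase = if (preop) "preop" else "postop",
                           months_post_op = m, stage = stage,
                           cea = cea, stringsAsFactors = FALSE))
        samples[[length(samples) + 1L]] <- data.frame(
          date = surgery + round(m * DAYS_PER_MONTH), sample_id = sid,
          positive = call$positive, mean_vaf = call$mean_vaf, cea = cea,
          stringsAsFactors = FALSE)
      }
      samples <- do.call(rbind, samples)
      aw <- if (stage == "III") {
        data.frame(start = surgery + 30, end = surgery + 120,
                   label = "adjuvant chemotherapy",
                   stringsAsFactors = FALSE)
      } else NULL
      timelines[[pid]] <- patient_timeline(pid, surgery, samples,
                                           clinical_relapse_date =
                                             clinical_relapse,
                                           adjuvant_windows = aw)
    }
    structure(list(timelines = timelines,
                   measurements = do.call(rbind, meas_all),
                   calls = do.call(rbind, calls_all),
                   panels = panels),
              class = "sim_timelines")
  })
}

#' Build tracking panels for every patient in a cohort
#'
#' @param variants Cohort somatic-variant data frame.
#' @param config A [sim_config] (or `NULL` for the default panel size).
#' @param n Panel size; defaults to `config$panel_size`.
#' @return Named list of `tracking_panel` objects; patients with no
#'   trackable mutation are omitted with a warning.
#' @export
build_panels <- function(variants, config = NULL,
                         n = if (is.null(config)) 5L else
                           config$panel_size) {
  out <- list()
  skipped <- character(0)
  for (pid in unique(variants$patient_id)) {
    pv <- eligible_variants(variants[variants$patient_id == pid, ,
                                     drop = FALSE])
    if (nrow(pv) == 0L) {
      skipped <- c(skipped, pid)
      next
    }
    out[[pid]] <- suppressWarnings(select_panel(score_variants(pv), n = n))
  }
  if (length(skipped) > 0L) {
    warning("no trackable mutations for patient(s): ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  out
}
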