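test_that("generators are fully deterministic under the seed", {
  cfg <- sim_config(seed = 33, n_patients = 20)
  a <- generate_tumor_cohort(cfg)
  b <- generate_tumor_cohort(cfg)
  expect_identical(a, b)
  ta <- generate_titration_panel(cfg, replicates = 5L, n_healthy = 10L)
  tb <- generate_titration_panel(cfg, replicates = 5L, n_healthy = 10L)
  expect_identical(ta, tb)
  sa <- suppressWarnings(generate_timelines(a, cfg))
  sb <- suppressWarnings(generate_timelines(b, cfg))
  expect_identical(sa$calls, sb$calls)
  # seeded generation does not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_tumor_cohort(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("single-patient and invalid configs behave per contract", {
  cfg1 <- sim_config(seed = 2, n_patients = 1, p_no_mutation = 0)
  co1 <- generate_tumor_cohort(cfg1)
  expect_equal(nrow(co1$patients), 1L)
  expect_gt(nrow(co1$variants), 0L)
  expect_error(sim_config(stage_distribution = c(I = 0.5, II = 0.6,
                                                 III = 0, IV = 0)),
               "sum to 1")
  expect_error(sim_config(class_probabilities = c(missense = 2)),
               "probabilities")
})

test_that("cohort generator recovers configured gene frequencies", {
  cfg <- sim_config(seed = 11, n_patients = 200)
  co <- generate_tumor_cohort(cfg)
  s <- summarize_cohort(co$variants, patients = co$patients$patient_id)
  for (g in c("APC", "TP53", "KRAS")) {
    target <- cfg$gene_table$freq[cfg$gene_table$gene == g]
    se <- sqrt(target * (1 - target) / cfg$n_patients)
    expect_lt(abs(s$per_gene_frequency[[g]] - target), 3 * se,
              label = sprintf("%s freq dev", g))
  }
  # mutation burden centered on the configured mean
  expect_lt(abs(mean(s$mutations_per_patient) -
                  cfg$mutations_per_patient_mean), 1.5)
  # KRAS codon-12 hotspot share among KRAS-mutated patients
  frac <- hotspot_fraction(co$variants, "KRAS", 12)
  n_kras <- sum(tapply(co$variants$gene == "KRAS",
                       co$variants$patient_id, any))
  se12 <- sqrt(0.568 * (1 - 0.568) / n_kras)
  expect_lt(abs(frac - 0.568), 3 * se12)
})

test_that("plasma counting model respects bounds and expectations", {
  cfg <- sim_config(seed = 5)
  panel <- select_panel(random_scored(8, seed = 6), n = 5)
  m0 <- generate_plasma_sample(panel, 0, cfg, seed = 1, fail_rate = 0)
  expect_true(all(m0$alt_reads <= m0$depth))
  # null sample: VAFs at background scale, far below 1%
  expect_lt(mean(m0$vaf), 0.01)

  # tumor fraction 0.005 at depth ~100k: ~250 alt reads before ploidy,
  # ~125 with the default heterozygosity factor of 0.5
  set.seed(2)
  reps <- do.call(rbind, lapply(1:60, function(i)
    generate_plasma_sample(panel, 0.005, cfg, fail_rate = 0)))
  expected <- 0.005 * cfg$heterozygosity + cfg$background_error_mean
  expect_equal(mean(reps$vaf), expected, tolerance = 0.1)

  # depth failures drawn at the configured rate
  set.seed(3)
  many <- do.call(rbind, lapply(1:400, function(i)
    generate_plasma_sample(panel, 0, cfg)))
  expect_equal(mean(many$depth < 10000), 0.038, tolerance = 0.3)
})

test_that("titration observations center on their expected level", {
  cfg <- sim_config(seed = 13)
  tit <- generate_titration_panel(cfg, replicates = 50L)
  for (lv in c(0.03, 0.005)) {
    obs <- tit$titration$vaf[tit$titration$level == lv]
    se <- stats::sd(obs) / sqrt(length(obs))
    expect_lt(abs(mean(obs) - (lv + cfg$background_error_mean)), 3 * se)
  }
  null_obs <- tit$titration$vaf[tit$titration$level == 0]
  expect_equal(mean(null_obs), cfg$background_error_mean, tolerance = 0.5)
  expect_equal(nrow(tit$healthy), 150L * 5L)
})

test_that("simulated healthy panel keeps the false-positive rate under 1%", {
  cfg <- sim_config(seed = 29)
  panel <- select_panel(random_scored(8, seed = 6), n = 5)
  set.seed(101)
  null_meas <- do.call(rbind, lapply(1:220, function(i)
    generate_plasma_sample(panel, 0, cfg,
                           sample_id = sprintf("N%04d", i))))
  retained <- qc_amplicons(null_meas)$retained
  expect_gt(nrow(retained), 1000L)
  expect_lt(mean(retained$vaf >= 5e-4), 0.01)
})

test_that("timelines follow the visit schedule and relapse construction", {
  cfg <- sim_config(seed = 3, n_patients = 60)
  co <- generate_tumor_cohort(cfg)
  sim <- suppressWarnings(generate_timelines(co, cfg))

  tl <- sim$timelines[[1L]]
  mo <- round(as.numeric(tl$samples$date - tl$surgery_date) / 30.4375, 1)
  expect_equal(mo[1], -0.2, tolerance = 0.1)        # pre-op draw
  expect_true(all(abs(mo[-1] - c(1, 7, 13)[seq_along(mo[-1])]) < 0.1))

  relapsers <- Filter(function(t) !is.null(t$clinical_relapse_date),
                      sim$timelines)
  expect_gt(length(relapsers), 0L)
  for (tl in relapsers) {
    mol <- detect_molecular_relapse(tl)
    expect_false(is.na(mol))
    expect_lt(as.numeric(mol), as.numeric(tl$clinical_relapse_date))
    expect_gt(lead_time(tl), 0)
  }

  # no relapses when the relapse probability is zero
  cfg0 <- sim_config(seed = 3, n_patients = 15, relapse_probability = 0)
  sim0 <- suppressWarnings(generate_timelines(generate_tumor_cohort(cfg0),
                                              cfg0))
  expect_true(all(vapply(sim0$timelines,
                         function(t) is.null(t$clinical_relapse_date),
                         logical(1))))
})

test_that("end-to-end pre-operative detection matches the calibrated target", {
  cfg <- sim_config(seed = 47, n_patients = 200)
  co <- generate_tumor_cohort(cfg)
  sim <- suppressWarnings(generate_timelines(co, cfg))
  pre <- sim$calls[sim$calls$phase == "preop", ]
  se <- sqrt(cfg$detection_target * (1 - cfg$detection_target) / nrow(pre))
  expect_lt(abs(mean(pre$positive, na.rm = TRUE) - cfg$detection_target),
            3 * se)
  # stage I detection sits below stages II-III
  by_stage <- tapply(pre$positive, pre$stage, mean, na.rm = TRUE)
  expect_lt(by_stage[["I"]], by_stage[["II"]])
})
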