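mk_timeline <- function(months, positive, relapse_month = NULL,
                        cea = NULL, surgery = as.Date("2021-06-01")) {
  samples <- data.frame(date = surgery + round(months * 30.4375),
                        positive = positive)
  if (!is.null(cea)) samples$cea <- cea
  patient_timeline("P1", surgery, samples,
                   clinical_relapse_date = if (is.null(relapse_month))
                     NULL else surgery + round(relapse_month * 30.4375))
}

test_that("CEA classification uses the 5 ng/mL boundary", {
  expect_identical(classify_cea(4.9), "normal")
  expect_identical(classify_cea(5.0), "elevated")
  expect_identical(classify_cea(0), "normal")
  expect_identical(classify_cea(c(1, 10)), c("normal", "elevated"))
})

test_that("molecular relapse is the earliest positive post-operative sample", {
  tl <- mk_timeline(c(1, 6, 8), c(FALSE, TRUE, TRUE))
  expect_equal(detect_molecular_relapse(tl),
               tl$samples$date[2])

  none <- mk_timeline(c(1, 6), c(FALSE, FALSE))
  expect_true(is.na(detect_molecular_relapse(none)))

  skipped <- mk_timeline(c(1, 6), c(NA, TRUE))
  expect_equal(detect_molecular_relapse(skipped), skipped$samples$date[2])

  # pre-operative positives never qualify (surgery-day sample is pre-op)
  pre <- mk_timeline(c(0, 2), c(TRUE, FALSE))
  expect_true(is.na(detect_molecular_relapse(pre)))
  expect_error(detect_molecular_relapse(mk_timeline(-0.2, TRUE)),
               "no post-operative")
})

test_that("relapse detection ignores inserted negative samples", {
  tl1 <- mk_timeline(c(1, 6), c(FALSE, TRUE))
  tl2 <- mk_timeline(c(1, 3, 5, 6), c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(detect_molecular_relapse(tl1), detect_molecular_relapse(tl2))
})

test_that("lead time in 30.4375-day months with sign semantics", {
  # molecular at 6 months, clinical at 10 months -> 4.0 months lead
  tl <- mk_timeline(c(1, 6), c(FALSE, TRUE), relapse_month = 10)
  expect_equal(lead_time(tl), 4.0, tolerance = 0.02)

  # molecular on the clinical date: zero lead
  tl0 <- patient_timeline("P1", as.Date("2021-06-01"),
                          data.frame(date = as.Date("2021-12-01"),
                                     positive = TRUE),
                          clinical_relapse_date = as.Date("2021-12-01"))
  expect_equal(lead_time(tl0), 0)

  # no molecular relapse: no lead time
  expect_true(is.na(lead_time(mk_timeline(c(1, 6), c(FALSE, FALSE),
                                          relapse_month = 10))))

  # molecular after clinical: negative, flagged
  late <- mk_timeline(c(1, 12), c(FALSE, TRUE), relapse_month = 10)
  expect_warning(lt <- lead_time(late), "negative")
  expect_lt(lt, 0)

  # antisymmetry under swapping the two dates
  d1 <- as.Date("2022-01-01"); d2 <- as.Date("2022-05-01")
  expect_equal(as.numeric(d2 - d1) / 30.4375,
               -as.numeric(d1 - d2) / 30.4375)
})

test_that("monitoring verdict links molecular relapse, lead time and CEA", {
  tl <- mk_timeline(c(1, 6), c(FALSE, TRUE), relapse_month = 10,
                    cea = c(2.0, 3.1))
  v <- monitor_patient(tl)
  expect_equal(v$lead_time_months, 4.0, tolerance = 0.02)
  expect_false(v$cea_elevated_at_molecular_relapse)  # CEA stayed normal
  v2 <- monitor_patient(mk_timeline(c(1, 6), c(FALSE, TRUE),
                                    relapse_month = 10, cea = c(2, 8)))
  expect_true(v2$cea_elevated_at_molecular_relapse)
})

test_that("timeline invariants: ordering, relapse after surgery, partition", {
  surgery <- as.Date("2021-06-01")
  expect_error(patient_timeline("P1", surgery,
                                data.frame(date = surgery + c(10, 10),
                                           positive = c(TRUE, FALSE))),
               "strictly ordered")
  expect_error(patient_timeline("P1", surgery,
                                data.frame(date = surgery + 10,
                                           positive = TRUE),
                                clinical_relapse_date = surgery - 1),
               "after surgery")
  tl <- mk_timeline(c(-0.25, 0, 1), c(TRUE, TRUE, FALSE))
  expect_equal(tl$samples$postoperative, c(FALSE, FALSE, TRUE))
})

test_that("swimmer export flattens events sorted by patient and time", {
  tl1 <- mk_timeline(c(-0.25, 1, 7), c(TRUE, FALSE, FALSE))
  ex1 <- swimmer_export(tl1)
  expect_equal(sum(ex1$event == "sample"), 3L)
  expect_equal(sum(ex1$event == "clinical_relapse"), 0L)

  tl2 <- mk_timeline(c(1, 6), c(FALSE, TRUE), relapse_month = 10)
  ex2 <- swimmer_export(list(tl1, tl2))
  expect_equal(sum(ex2$event == "clinical_relapse"), 1L)
  expect_true(!is.unsorted(ex2$months_post_op[ex2$patient_id == "P1"][1:3]))

  # generator round-trip: relapse markers equal simulated relapse count
  cfg <- sim_config(seed = 19, n_patients = 19)
  sim <- suppressWarnings(generate_timelines(generate_tumor_cohort(cfg), cfg))
  n_rel <- sum(vapply(sim$timelines,
                      function(tl) !is.null(tl$clinical_relapse_date),
                      logical(1)))
  ex <- swimmer_export(sim$timelines)
  expect_equal(sum(ex$event == "clinical_relapse"), n_rel)
})

test_that("timeline TSV dialect round-trips", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "timelines.tsv")
  tl <- mk_timeline(c(-0.25, 1, 6), c(TRUE, FALSE, TRUE),
                    relapse_month = 10, cea = c(6.2, 1.0, 2.0))
  write_timelines(tl, path)
  back <- read_timelines(path)[["P1"]]
  expect_equal(back$surgery_date, tl$surgery_date)
  expect_equal(back$samples$date, tl$samples$date)
  expect_equal(back$samples$positive, tl$samples$positive)
  expect_equal(back$clinical_relapse_date, tl$clinical_relapse_date)
  expect_equal(lead_time(back), lead_time(tl))
})
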