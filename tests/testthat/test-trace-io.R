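test_that("balance logs parse, deduplicate and drop bad rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,w", "0,100.000", "3,99.998", "6,99.996"), f)
  tr <- read_balance_log(f, time_col = "t", weight_col = "w")
  expect_s3_class(tr, "flow_trace")
  expect_equal(n_samples(tr), 3L)
  expect_equal(tr$sampling_interval_s, 3)
  expect_equal(tr$weight_g, c(100.000, 99.998, 99.996))

  writeLines(c("t,w", "0,100.000", "3,99.998", "3,99.996", "6,99.994"), f)
  expect_warning(tr2 <- read_balance_log(f, time_col = "t", weight_col = "w"),
                 "duplicated")
  expect_equal(n_samples(tr2), 3L)
  expect_equal(tr2$weight_g[2], mean(c(99.998, 99.996)))

  writeLines(c("t,w", "0,100.000", "3,oops", "6,99.996", "9,99.994"), f)
  expect_warning(tr3 <- read_balance_log(f, time_col = "t", weight_col = "w"),
                 "dropped 1")
  expect_equal(n_samples(tr3), 3L)
})

test_that("wall-clock time columns convert to elapsed seconds", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,weight_g",
               "2024-06-01 09:00:00,100.0",
               "2024-06-01 09:00:03,99.998",
               "2024-06-01 09:00:06,99.996"), f)
  tr <- read_balance_log(f, time_col = "time")
  expect_equal(tr$time_s, c(0, 3, 6))
})

test_that("malformed logs raise format and empty-trace errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), f)
  expect_error(read_balance_log(f, time_col = "t", weight_col = "w"),
               "format error")
  writeLines(c("t,w", "0,100.0"), f)
  expect_error(read_balance_log(f, time_col = "t", weight_col = "w"),
               "fewer than 2")
})

test_that("raw flow tables round-trip through read_balance_log", {
  sim <- simulate_flow(trace_spec(duration_s = 300, seed = 5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_raw_flow_table(sim$trace, "leaf-01", f)
  expect_equal(length(readLines(f)), n_samples(sim$trace) + 1L)
  back <- read_balance_log(f, time_col = "time_s", weight_col = "weight_g",
                           flow_col = "flow_mmol_m2_s")
  expect_false(!is.null(back$weight_g))
  expect_equal(back$time_s, sim$trace$time_s, tolerance = 1e-9)
  expect_equal(back$flow, sim$trace$flow, tolerance = 1e-9)
  expect_identical(back$flow_units, "mmol m-2 s-1")

  expect_error(write_raw_flow_table(sim$trace, "", f), "leaf_id")
  wonly <- flow_trace(0:9, weight_g = 100 - (0:9) * 1e-4)
  expect_error(write_raw_flow_table(wonly, "x", f), "no computed flow")
})

test_that("leaf records validate their fields by name", {
  expect_error(leaf_record("rice", leaf_area_m2 = 0, psi_final_MPa = -0.3),
               "leaf_area_m2")
  expect_error(leaf_record("rice", leaf_area_m2 = 1e-3, psi_final_MPa = 0.3),
               "psi_final_MPa")
  rec <- leaf_record("rice", leaf_area_m2 = 2.5e-3, psi_final_MPa = -0.31,
                     T_leaf_C = 27)
  expect_s3_class(rec, "leaf_record")
})

test_that("reports carry units in headers and NA for non-steady leaves", {
  leaf <- leaf_record("Oryza sativa", leaf_area_m2 = 2.5e-3,
                      psi_final_MPa = -0.31, PARa_umol_m2_s = 1000)
  steady_sim <- simulate_flow(trace_spec(seed = 3))
  st_D <- classify_trace(steady_sim$trace)
  kl <- compute_kleaf(extract_E(steady_sim$trace, st_D), leaf$psi_final_MPa)
  rec_D <- report_record(leaf, st_D, kl, leaf_id = "L1")

  short_sim <- simulate_flow(trace_spec(duration_s = 840, rise_tau_s = 90,
                                        seed = 4))
  st_C <- classify_trace(short_sim$trace)
  expect_identical(st_C$curve_class, "C")
  rec_C <- report_record(leaf, st_C, leaf_id = "L2")

  f <- withr::local_tempfile(fileext = ".csv")
  write_report(list(rec_D, rec_C), f,
               thresholds = list(slope_alpha = 0.001))
  tab <- read_report(f)
  required <- c("species", "leaf_area_m2", "psi_initial_MPa", "psi_final_MPa",
                "T_leaf_C", "PARa_umol_m2_s", "T_air_C", "airflow_m_s",
                "E_mmol_m2_s", "K_leaf_mmol_m2_s_MPa",
                "K_leaf25_mmol_m2_s_MPa", "steadiness_class")
  expect_true(all(required %in% names(tab)))
  expect_equal(nrow(tab), 2L)
  expect_false(is.na(tab$K_leaf_mmol_m2_s_MPa[1]))
  expect_identical(tab$steadiness_class[2], "C")
  expect_true(is.na(tab$K_leaf_mmol_m2_s_MPa[2]))
  expect_true(is.na(tab$E_mmol_m2_s[2]))
  # literal NA token in the serialized file
  expect_match(readLines(f)[3], ",NA,")
  expect_true(validate_report(f))

  # a non-steady record must not carry K_leaf
  expect_error(report_record(leaf, st_C, kl, leaf_id = "L3"),
               "non-steady")
  # zero records -> header-only file
  write_report(list(), f)
  expect_equal(length(readLines(f)), 1L)
  expect_equal(nrow(read_report(f)), 0L)
})

test_that("validate_report catches a K_leaf inconsistent with its own row", {
  leaf <- leaf_record("rice", leaf_area_m2 = 2.5e-3, psi_final_MPa = -0.31)
  sim <- simulate_flow(trace_spec(seed = 6))
  st <- classify_trace(sim$trace)
  kl <- compute_kleaf(extract_E(sim$trace, st), -0.31)
  f <- withr::local_tempfile(fileext = ".csv")
  write_report(report_record(leaf, st, kl, "L1"), f)
  tab <- utils::read.csv(f, check.names = FALSE)
  tab$K_leaf_mmol_m2_s_MPa <- tab$K_leaf_mmol_m2_s_MPa * 2
  utils::write.csv(tab, f, row.names = FALSE, na = "NA")
  expect_error(validate_report(f), "not re-derivable")
})
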