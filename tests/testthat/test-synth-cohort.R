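test_that("the same scenario and seed reproduce the cohort exactly", {
  a <- simulate_cohort(sim_scenario(n_patients = 20, seed = 9))
  b <- simulate_cohort(sim_scenario(n_patients = 20, seed = 9))
  expect_identical(a$metastases, b$metastases)
  expect_identical(a$patients, b$patients)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(sim_scenario(n_patients = 20, seed = 10))
  expect_false(identical(a$metastases, c$metastases))

  # written files are byte-identical across runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_cohort(sim_scenario(n_patients = 10, seed = 3), dir = d1)
  simulate_cohort(sim_scenario(n_patients = 10, seed = 3), dir = d2)
  for (f in c("metastases.csv", "patients.csv", "truth.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("every simulated metastasis carries exactly one truth label", {
  co <- simulate_cohort(sim_scenario(n_patients = 25, trajectory = "mixed",
                                     seed = 6))
  expect_equal(nrow(co$truth), nrow(co$metastases))
  expect_equal(co$truth$diameter_mm, co$metastases$diameter_mm)
  expect_true(all(!is.na(co$truth$wave_id)))
  # wave members share their generating mean; isolated rows have none
  in_wave <- co$truth$wave_id > 0
  expect_true(all(!is.na(co$truth$true_wave_mean[in_wave])))
  expect_true(all(is.na(co$truth$true_wave_mean[!in_wave])))
})

test_that("scenario validation rejects impossible configurations", {
  expect_error(sim_scenario(organ_mix = c(0.5, 0.2, 0.2)), "organ_mix")
  expect_error(sim_scenario(p_metachronous = 1.4), "p_metachronous")
  expect_error(sim_scenario(noise_sd = c(lung = -1, liver = 1)), "noise_sd")
  # six waves cannot be resolved below the size ceiling at a huge tolerance
  expect_error(sim_scenario(tolerances = c(lung = 12, liver = 30)),
               "infeasible scenario")
  expect_error(sim_scenario(first_wave_median = c(lung = 0.5, liver = 10)),
               "detectability")
})

test_that("fixed-composition cohorts match the designed category counts", {
  co <- simulate_cohort(reference_scenario(seed = 2))
  tab <- composition_table(co$patients, co$metastases)
  cnt <- function(cat, lvl) tab$count[tab$category == cat & tab$level == lvl]
  expect_equal(cnt("timing", "synchronous"), 97)
  expect_equal(cnt("timing", "metachronous"), 36)
  expect_equal(cnt("organ_pattern", "liver_only"), 80)
  expect_equal(cnt("organ_pattern", "lung_only"), 27)
  expect_equal(cnt("organ_pattern", "both"), 26)
  # synchronous patients have zero lead by construction
  sync <- co$patients$timing == "synchronous"
  expect_true(all(co$patients$months_primary_to_mets[sync] == 0))
  expect_true(all(co$patients$months_primary_to_mets[!sync] > 0))
})

test_that("random timing assignment converges to the configured fraction", {
  co <- simulate_cohort(sim_scenario(n_patients = 2000, seed = 14))
  frac <- mean(co$patients$timing == "metachronous")
  # binomial sd at n = 2000 is ~0.010; a 3-sigma band
  expect_lt(abs(frac - 0.271), 0.03)
})

test_that("zero measurement noise gives exactly equal within-wave diameters", {
  sc <- sim_scenario(n_patients = 10, noise_sd = c(lung = 0, liver = 0),
                     seed = 21)
  co <- simulate_cohort(sc)
  by_wave <- split(co$truth$diameter_mm,
                   paste(co$truth$patient_id, co$truth$organ, co$truth$wave_id))
  expect_true(all(vapply(by_wave, function(d) all(d == d[1]), TRUE)))
})

test_that("single-wave lung patients are recovered as LPR +1", {
  sc <- sim_scenario(
    n_patients = 30, organ_mix = c(liver_only = 0, lung_only = 1, both = 0),
    wave_count_probs = list(lung = c(1, 0, 0, 0, 0, 0),
                            liver = c(0, 0, 1, 0, 0, 0)),
    mets_per_wave_lambda = c(lung = 9, liver = 2.7),
    noise_sd = c(lung = 0.2, liver = 1), seed = 30
  )
  co <- simulate_cohort(sc)
  s <- summarize_cohort(co$metastases)
  # noise sd 0.2 with ~10 mets per wave keeps the band within 1 mm with
  # overwhelming probability
  expect_equal(median(s$lpr), 1)
  expect_gte(mean(s$lpr == 1), 0.9)
  expect_true(all(s$n_waves[s$lpr == 1] == 1))
})

test_that("wave counts are recovered when waves are separated and noise is small", {
  for (k in 1:4) {
    probs <- rep(0, 6); probs[k] <- 1
    sc <- sim_scenario(
      n_patients = 15, organ_mix = c(liver_only = 0.5, lung_only = 0.5, both = 0),
      wave_count_probs = list(lung = probs, liver = probs),
      noise_sd = c(lung = 0.01, liver = 0.01), seed = 100 + k
    )
    co <- simulate_cohort(sc)
    s <- summarize_cohort(co$metastases)
    expect_true(all(s$n_waves == k), info = paste("K =", k))
    expect_true(all(s$lpr == 1), info = paste("K =", k))
  }
})

test_that("linear cohorts score far higher LPR than parallel cohorts", {
  lin <- simulate_cohort(sim_scenario(n_patients = 100, seed = 77))
  par <- simulate_cohort(sim_scenario(n_patients = 100,
                                      trajectory = "parallel", seed = 77))
  s_lin <- summarize_cohort(lin$metastases)
  s_par <- summarize_cohort(par$metastases)
  expect_equal(median(s_lin$lpr), 1)
  # chance clustering in an organ-typical size range keeps the parallel
  # medians well above the idealised -1: near 0 for lung (1 mm tolerance,
  # ~26 mm dispersion) and higher for liver (3 mm tolerance)
  expect_lt(median(s_par$lpr[s_par$organ == "lung"]), 0.5)
  expect_lt(median(s_par$lpr), median(s_lin$lpr))
  expect_gt(median(s_lin$lpr[s_lin$organ == "lung"]) -
              median(s_par$lpr[s_par$organ == "lung"]), 0.5)
})

test_that("the recovery experiment reports per-condition LPR and survival medians", {
  rep <- recovery_experiment(list(
    linear = sim_scenario(n_patients = 40, seed = 5),
    parallel = sim_scenario(n_patients = 40, trajectory = "parallel", seed = 5)
  ))
  expect_true(all(c("scenario", "organ", "median_lpr", "primary_p", "mets_p")
                  %in% names(rep)))
  expect_equal(sort(unique(rep$scenario)), c("linear", "parallel"))
  lin_lpr <- rep$median_lpr[rep$scenario == "linear"]
  expect_true(all(lin_lpr == 1))
})
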