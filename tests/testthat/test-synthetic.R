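test_that("transition calibration solves the switch target in closed form", {
  # two equiprobable types at switch 0.5 -> the i.i.d. uniform matrix
  P <- calibrate_transitions(c(a = 0.5, b = 0.5), 0.5)
  expect_equal(P, matrix(0.5, 2, 2, dimnames = dimnames(P)), ignore_attr = TRUE)

  # switch target near 0 -> near-identity matrix
  P0 <- calibrate_transitions(c(a = 0.5, b = 0.5), 0.001)
  expect_gt(min(diag(P0)), 0.99)

  # stationary distribution equals the requested proportions (eigen oracle)
  p <- c(a = 0.6, b = 0.25, c = 0.15)
  P2 <- calibrate_transitions(p, 0.55)
  ev <- eigen(t(P2))
  stat <- Re(ev$vectors[, which.max(Re(ev$values))]); stat <- stat / sum(stat)
  expect_equal(unname(stat), unname(p), tolerance = 1e-9)
  # expected repetition probability matches 1 - switch
  expect_equal(sum(p * diag(P2)), 0.45, tolerance = 1e-12)

  # an overwhelming dominant type cannot reach a high switch target
  expect_error(calibrate_transitions(c(a = 0.97, b = 0.03), 0.9),
               class = "usvrep_calibration")
})

test_that("power-law calibration matches its closed forms and the Zipf fit", {
  expect_equal(calibrate_zipf(4, -1), c(12, 6, 4, 3) / 25)
  expect_equal(calibrate_zipf(5, 0), rep(0.2, 5))
  # fitting the Zipf regression to exact expected counts recovers the exponent
  p <- calibrate_zipf(8, -1.97)
  counts <- setNames(p * 1e6, paste0("t", 1:8))
  expect_equal(zipf_slope(counts)$slope, -1.97, tolerance = 1e-10)
})

test_that("packaged age specifications carry the documented calibration", {
  specs <- age_specs()
  expect_identical(names(specs), c("p5", "p7", "p9", "p11", "p13", "adult"))
  expect_identical(specs$p5$n_syllables, 3145)
  expect_identical(specs$p13$n_syllables, 3082)
  expect_identical(specs$adult$n_syllables, 6963)
  expect_equal(specs$adult$interval_median, 69.4)
  expect_equal(specs$p5$bout_mean, 24)
  for (s in specs) {
    expect_equal(sum(s$type_probs), 1)
    expect_equal(sum(s$initial_probs), 1)
    expect_true(all(names(s$provenance) != ""))
    # flat is always the modal bout-initial type
    expect_identical(names(which.max(s$initial_probs)), "flat")
  }
})

test_that("generated datasets are reproducible and classifier-consistent", {
  spec <- age_specs("p11")
  d1 <- generate_dataset(spec, 17, n_syllables = 800)
  d2 <- generate_dataset(spec, 17, n_syllables = 800)
  expect_identical(d1$annotations, d2$annotations)
  expect_identical(d1$truth$types, d2$truth$types)

  # every generated syllable re-classifies to its generating type
  cl <- classify_table(d1$annotations)
  expect_identical(cl$syll_type, d1$truth$types)

  # bout skeleton: lengths >= 3 and consistent with the row count
  expect_true(all(d1$truth$bout_lengths >= 3))
  expect_identical(sum(d1$truth$bout_lengths), nrow(d1$annotations))

  # segmentation at the packaged threshold recovers the bouts exactly
  seg <- segment_bouts(cl, spec$bout_threshold)
  expect_identical(length(seg$bouts), length(d1$truth$bout_lengths))
  expect_identical(vapply(seg$bouts, function(b) nrow(b$syllables), 0L),
                   d1$truth$bout_lengths)
})

test_that("calibration closes the loop on the headline statistics", {
  # switch probability at the packaged p13 target
  ds <- generate_dataset(age_specs("p13"), 1)
  sw <- switching_probability(pair_table(truth_sequences(ds)))
  expect_equal(sw, 0.63, tolerance = 0.035)

  # above-100 kHz audibility at the packaged p5 target
  ds5 <- generate_dataset(age_specs("p5"), 1)
  cl5 <- classify_table(ds5$annotations)
  cens <- audibility_census(cl5)
  expect_equal(cens$frac_dominant_above, 0.301, tolerance = 0.1)
  # some pup syllables have all energy above 100 kHz
  expect_gt(cens$frac_all_energy_above, 0)

  # median within-bout interval near the packaged p5 value
  seg <- segment_bouts(cl5, 1569.8)
  bs <- bout_stats(seg)
  expect_equal(bs$median_interval_ms, 190.2, tolerance = 0.12)
  expect_equal(bs$mean_syllables_per_bout, 24, tolerance = 0.2)

  # purity census near the packaged p13 nonlinear fraction
  cl13 <- classify_table(ds$annotations)
  pc <- purity_census(cl13)
  expect_equal(pc$frac_nonlinear, 0.235, tolerance = 0.15)
})

test_that("the full pipeline runs end to end at every age", {
  set.seed(61)
  outdir <- withr::local_tempdir()
  for (ag in age_groups()) {
    ds <- generate_dataset(age_specs(ag), 23, n_syllables = 600)
    rep <- run_pipeline(list(annotations = ds$annotations,
                             outdir = file.path(outdir, ag),
                             threshold = 1569.8))
    expect_s3_class(rep, "usv_report")
    expect_gt(rep$segmentation$n_bouts, 0)
    expect_true(is.finite(rep$per_age[[ag]]$zipf$slope))
    expect_true(all(file.exists(file.path(outdir, ag,
                                          c("classified.csv", "bouts.csv",
                                            "stats.json", "entropy.json",
                                            "summary.txt")))))
  }
})

test_that("pipeline reports are deterministic and fail cleanly on empty input", {
  ds <- generate_dataset(age_specs("p7"), 29, n_syllables = 400)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_pipeline(list(annotations = ds$annotations, outdir = d1, seed = 1))
  run_pipeline(list(annotations = ds$annotations, outdir = d2, seed = 1))
  drop_path <- function(p) {
    x <- jsonlite::read_json(p)
    x$provenance$config$outdir <- NULL
    x
  }
  expect_identical(drop_path(file.path(d1, "stats.json")),
                   drop_path(file.path(d2, "stats.json")))
  expect_identical(drop_path(file.path(d1, "entropy.json")),
                   drop_path(file.path(d2, "entropy.json")))
  expect_error(run_pipeline(list(annotations = ds$annotations[0, ], outdir = d1)),
               class = "usvrep_io")
})

test_that("an all-age synthetic stream reproduces the pooled interval profile", {
  # pooled interval mean/SD targets 337.8 / 616.0; sampled recovery is
  # checked at a reduced per-age size for speed, with tolerances set by
  # the generator's calibration error plus sampling noise
  set.seed(62)
  all_ages <- do.call(rbind, lapply(age_groups(), function(ag) {
    spec <- age_specs(ag)
    generate_dataset(spec, 71 + match(ag, age_groups()),
                     n_syllables = round(spec$n_syllables / 4))$annotations
  }))
  st <- interval_stats(all_ages, window = 5000)
  expect_equal(st$mean, 337.8, tolerance = 0.12)
  expect_equal(st$sd, 616.0, tolerance = 0.15)
  thr <- bout_threshold(st)
  expect_equal(thr, 1569.8, tolerance = 0.12)
})
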