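test_that("full pipeline conserves wall area and reports coherent thresholds", {
  cf <- phantom_config(n_frames = 3, seed = 17)
  ph <- phantom_pullback(cf)
  fit <- suppressWarnings(
    analyze_pullback(ph$frames, ph$contours, cf$pixel_spacing_mm,
                     cf$frame_spacing_mm))
  for (i in seq_along(fit$labels)) {
    expect_identical(sum(fit$labels[[i]] != ECHO_CLASSES["outside"]),
                     sum(fit$masks[[i]]$total_wall))
  }
  expect_gte(fit$thresholds$high_threshold, fit$thresholds$median_threshold)
  v <- fit$volumes
  for (cp in unique(v$compartment))
    expect_equal(sum(v$percent[v$compartment == cp]), 100, tolerance = 0.1)
  g <- attr(v, "geometry")
  expect_identical(g[["neointima"]], g[["vessel"]] - g[["lumen"]])
  # print/summary/plot methods run
  expect_output(print(fit), "reference median")
  expect_output(print(summary(fit)), "Per-frame")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit, frame = 1))
  expect_s3_class(as.data.frame(fit), "data.frame")
})

test_that("guidewire intervals propagate into the reference selection", {
  cf <- phantom_config(n_frames = 1, n_struts = 0, seed = 23)
  ph <- phantom_pullback(cf)
  fit_all <- suppressWarnings(
    analyze_pullback(ph$frames, ph$contours, cf$pixel_spacing_mm,
                     cf$frame_spacing_mm))
  fit_gw <- suppressWarnings(
    analyze_pullback(ph$frames, ph$contours, cf$pixel_spacing_mm,
                     cf$frame_spacing_mm, guidewire = list(c(0, 40))))
  # [0, 40) covers 20 sectors; some may already be excluded by speckle
  expect_lt(fit_gw$per_frame$n_included_sectors,
            fit_all$per_frame$n_included_sectors)
  expect_lte(fit_gw$per_frame$n_included_sectors, 160)
})

test_that("pullback roundtrips through disk in both frame formats", {
  cf <- phantom_config(n_frames = 2, seed = 31)
  ph <- phantom_pullback(cf)
  for (fmt in c("png", "tiff")) {
    dir <- file.path(tempdir(), paste0("pb_", fmt))
    write_pullback(ph, dir, format = fmt)
    back <- read_pullback(dir)
    expect_identical(back$frames, ph$frames)
    expect_equal(back$meta$pixel_spacing_mm, cf$pixel_spacing_mm)
    expect_equal(back$meta$center, ph$meta$center)
    for (ty in c("lumen", "scaffold", "vessel"))
      expect_equal(unname(back$contours[[1]][[ty]]),
                   unname(ph$contours[[1]][[ty]]), tolerance = 1e-6)
    unlink(dir, recursive = TRUE)
  }
})

test_that("cmd_analyze writes the full bundle and is byte-deterministic", {
  cf <- phantom_config(n_frames = 2, seed = 41)
  src <- file.path(tempdir(), "pb_src")
  cmd_phantom(src, config = cf)
  out1 <- file.path(tempdir(), "out1")
  out2 <- file.path(tempdir(), "out2")
  suppressWarnings(cmd_analyze(src, out1, scaffold_id = "s1"))
  suppressWarnings(cmd_analyze(src, out2, scaffold_id = "s1"))
  need <- c("volumes.csv", "volumes_long.csv", "reference.csv",
            "thresholds.json", "run_config.json", "labels_0000.png")
  for (f in need) expect_true(file.exists(file.path(out1, f)))
  for (f in c("volumes.csv", "reference.csv", "thresholds.json"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  # conservation holds in the written long CSV
  v <- read.csv(file.path(out1, "volumes_long.csv"))
  for (cp in unique(v$compartment))
    expect_equal(sum(v$percent[v$compartment == cp]), 100, tolerance = 0.1)
  unlink(c(src, out1, out2), recursive = TRUE)
})

test_that("contours referencing an absent frame abort with the frame named", {
  cf <- phantom_config(n_frames = 2, seed = 43)
  src <- file.path(tempdir(), "pb_bad")
  cmd_phantom(src, config = cf)
  ct <- read.csv(file.path(src, "contours.csv"))
  ct$frame_index[ct$frame_index == 1] <- 7
  write.csv(ct, file.path(src, "contours.csv"), row.names = FALSE)
  expect_error(cmd_analyze(src, file.path(tempdir(), "out_bad")), "7")
  unlink(src, recursive = TRUE)
})

test_that("cmd_stats joins volumes with molecular weights and reports finite statistics", {
  coh <- degradation_cohort(n_per_timepoint = 1, seed = 6, n_frames = 1,
                            mw_schedule = c(92.9, 76, 47.1, 26.2, 7.9, 0),
                            timepoint_months = c(1, 6, 12, 18, 24, 42))
  df <- analyze_cohort(coh)
  vdir <- file.path(tempdir(), "statin")
  dir.create(vdir, showWarnings = FALSE)
  vols_csv <- file.path(vdir, "volumes.csv")
  mw_csv <- file.path(vdir, "mw.csv")
  write.csv(df[setdiff(names(df), c("mw_kDa", "timepoint_months", "seed"))],
            vols_csv, row.names = FALSE)
  write.csv(coh$table[c("scaffold_id", "mw_kDa")], mw_csv, row.names = FALSE)
  out <- file.path(vdir, "report")
  rep <- cmd_stats(vols_csv, mw_csv, out, k = 3)
  expect_true(is.finite(rep$pearson$scaffold_vessel_hyperupper$r))
  expect_true(is.finite(rep$regression_mw_on_hyperupper$r_squared))
  expect_true(file.exists(file.path(out, "report.json")))
  cl <- read.csv(file.path(out, "clusters.csv"))
  expect_equal(sort(unique(cl$cluster)), 1:3)
  # empty join errors
  mw2 <- coh$table[c("scaffold_id", "mw_kDa")]
  mw2$scaffold_id <- paste0("x_", mw2$scaffold_id)
  write.csv(mw2, mw_csv, row.names = FALSE)
  expect_error(cmd_stats(vols_csv, mw_csv, out), "empty join")
  unlink(vdir, recursive = TRUE)
})

test_that("cmd_reproducibility reports ICC = 1 for duplicated readings", {
  vdir <- file.path(tempdir(), "repro")
  dir.create(vdir, showWarnings = FALSE)
  set.seed(3)
  y <- rnorm(12, 20, 4)
  csv <- file.path(vdir, "readings.csv")
  write.csv(data.frame(reader1 = y, reader2 = y), csv, row.names = FALSE)
  res <- cmd_reproducibility(csv, vdir)
  expect_equal(res$icc, 1)
  expect_true(file.exists(file.path(vdir, "icc.json")))
  unlink(vdir, recursive = TRUE)
})
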