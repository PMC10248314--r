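test_that("component spec validation enforces ordering, range, granularity", {
  expect_s3_class(component_spec("CD", "low_fails", c(6, 5, 4), c(1, 19)),
                  "component_spec")
  expect_s3_class(component_spec("FMS", "high_fails", c(3, 4, 5), c(0, 30)),
                  "component_spec")
  expect_error(component_spec("bad", "low_fails", c(5, 5, 4), c(0, 20)),
               "strictly decreasing")
  expect_error(component_spec("bad", "high_fails", c(5, 4, 3), c(0, 20)),
               "strictly increasing")
  expect_error(component_spec("bad", "low_fails", c(6, 5, 4), c(5, 20)),
               "outside valid_range")
  expect_error(component_spec("bad", "low_fails", c(6, 5, 4), c(0, 20),
                              granularity = -1),
               "granularity")
})

test_that("recode_score reproduces the published level columns", {
  bat <- ei5_battery()
  expect_identical(recode_score(5, bat$components$CD), 2L)
  expect_identical(recode_score(8, bat$components$RDS), 0L)
  expect_identical(recode_score(0, bat$components$FMS_WCST), 0L)
  # level-3 thresholds, inclusive
  expect_identical(recode_score(4, bat$components$CD), 3L)
  expect_identical(recode_score(22.0, bat$components$RCFT_Copy), 3L)
  expect_identical(recode_score(5, bat$components$FMS_WCST), 3L)
  # figure-copy bands on the half-point grid
  expect_identical(recode_score(c(30.5, 29.0, 25.5, 25.0, 22.5),
                                bat$components$RCFT_Copy),
                   c(0L, 1L, 1L, 2L, 2L))
})

test_that("off-grid scores snap toward the failure direction at midpoints", {
  rcft <- ei5_battery()$components$RCFT_Copy
  expect_identical(recode_score(25.25, rcft), 2L)  # midpoint -> severe side
  expect_identical(recode_score(25.3, rcft), 1L)   # nearer 25.5
  expect_identical(recode_score(22.25, rcft), 3L)
  fms <- ei5_battery()$components$FMS_WCST
  expect_identical(recode_score(2.5, fms), 1L)     # high_fails midpoint -> up
  expect_identical(recode_score(2.4, fms), 0L)
})

test_that("recode errors on out-of-range and non-finite input", {
  cd <- ei5_battery()$components$CD
  expect_error(recode_score(0, cd), "outside valid_range")
  expect_error(recode_score(20, cd), "outside valid_range")
  expect_error(recode_score(NA_real_, cd), "finite")
  expect_error(recode_score(Inf, cd), "finite")
})

test_that("recoding is monotone and partitions the score grid", {
  set.seed(11)
  for (i in 1:20) {
    sp <- random_spec()
    grid <- seq(sp$valid_range[1], sp$valid_range[2], by = sp$granularity)
    lv <- recode_score(grid, sp)
    expect_true(all(lv %in% 0:3))
    dlv <- diff(lv)
    if (sp$direction == "low_fails") expect_true(all(dlv <= 0))
    else expect_true(all(dlv >= 0))
    expect_setequal(unique(lv), 0:3)  # cuts inside range => all levels occur
  }
})

test_that("recode_profile follows battery order and flags unknown/missing", {
  bat <- ei5_battery()
  lv <- recode_profile(c(CD = 5, RCFT_Copy = 30.5, FMS_WCST = 0, RDS = 8,
                         RH_CVLT = 13), bat)
  expect_identical(unname(lv), c(2L, 0L, 0L, 0L, 0L))
  expect_identical(names(lv), names(bat$components))
  all3 <- recode_profile(c(CD = 4, RCFT_Copy = 22.0, FMS_WCST = 5, RDS = 5,
                           RH_CVLT = 10), bat)
  expect_identical(unname(all3), rep(3L, 5))
  expect_error(recode_profile(c(CD = 5), bat), "missing component")
  expect_error(recode_profile(c(CD = 5, RCFT_Copy = 30, FMS_WCST = 0, RDS = 8,
                                RH_CVLT = 13, XX = 1), bat),
               "unknown component")
})

test_that("battery invariants: unique names, attainable Fail, sane bands", {
  cs <- list(component_spec("A", "low_fails", c(6, 5, 4), c(0, 20)))
  expect_error(battery_config(list(cs[[1]], cs[[1]])), "unique")
  expect_error(battery_config(cs, pass_max = 1, borderline_max = 3),
               "Fail unattainable")
  expect_error(battery_config(cs, pass_max = 2, borderline_max = 1),
               "borderline_max")
  bat <- battery_config(cs, pass_max = 0, borderline_max = 2)
  expect_identical(length(bat$components), 1L)
})

test_that("config round-trip reproduces identical recoding on a dense grid", {
  bat <- ei5_battery()
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_battery_config(bat, path)
    bat2 <- read_battery_config(path)
    expect_identical(bat2$pass_max, bat$pass_max)
    expect_identical(bat2$borderline_max, bat$borderline_max)
    for (nm in names(bat$components)) {
      sp <- bat$components[[nm]]
      grid <- seq(sp$valid_range[1], sp$valid_range[2], by = sp$granularity / 2)
      expect_identical(recode_score(grid, bat2$components[[nm]]),
                       recode_score(grid, sp), info = paste(ext, nm))
    }
  }
})
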