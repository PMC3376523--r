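test_that("generation is deterministic and schema-stable", {
  a <- generate_cohort(seed = 11)
  b <- generate_cohort(seed = 11)
  expect_identical(a, b)
  expect_named(a, c("id", "arm", "completed", "grade",
                    paste0("wtp_c", 1:4), "satisfaction"))
  expect_equal(nrow(a), 68 + 67)
  expect_false(identical(a, generate_cohort(seed = 12)))
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- runif(5)
  set.seed(99); invisible(generate_cohort(seed = 3)); after <- runif(5)
  expect_identical(before, after)
})

test_that("non-completers carry no survey or grade fields", {
  cohort <- generate_cohort(seed = 21)
  nc <- cohort[!cohort$completed, ]
  expect_true(all(is.na(nc$grade)))
  expect_true(all(is.na(nc$satisfaction)))
  for (ctx in 1:4) expect_true(all(is.na(nc[[paste0("wtp_c", ctx)]])))
  # completers' grades live on the percent scale
  g <- cohort$grade[!is.na(cohort$grade)]
  expect_true(all(g >= 0 & g <= 100))
  w <- unlist(cohort[paste0("wtp_c", 1:4)])
  expect_true(all(w[!is.na(w)] >= 0))
  expect_true(all(cohort$satisfaction[!is.na(cohort$satisfaction)] %in% 1:5))
})

test_that("degenerate specifications collapse as specified", {
  spec <- list(web = cohort_arm_spec(
    n_enrolled = 30, completion_probability = 1,
    grade_mean = 80, grade_sd = 0,
    wtp_mean = c(100, 100, 100, 100), wtp_sd = c(10, 10, 10, 10),
    rho = rep(0.5, 4)
  ))
  cohort <- generate_cohort(spec, seed = 5)
  expect_true(all(cohort$completed))
  expect_equal(cohort$grade, rep(80, 30))
  # sd = 0 with a positive mean cannot be matched by a right-skewed model
  expect_error(
    cohort_arm_spec(10, 0.5, 80, 5, wtp_mean = c(100, 1, 1, 1),
                    wtp_sd = c(0, 1, 1, 1), rho = rep(0, 4)),
    "moment-match"
  )
  expect_error(cohort_arm_spec(10, 1.5, 80, 5, rep(1, 4), rep(1, 4),
                               rep(0, 4)), "completion_probability")
  expect_error(cohort_arm_spec(10, 0.5, 80, 5, rep(1, 4), rep(1, 4),
                               rep(2, 4)), "rho")
})

test_that("large cohorts recover the specified parameters", {
  spec <- default_cohort_spec()
  spec$face_to_face$n_enrolled <- 5000L
  spec$web$n_enrolled <- 5000L
  cohort <- generate_cohort(spec, seed = 31)
  s <- summarize_cohort(cohort)
  for (a in c("face_to_face", "web")) {
    row <- s$arms[s$arms$arm == a, ]
    expect_lt(abs(row$completers / row$n -
                    spec[[a]]$completion_probability), 0.03)
    expect_lt(abs(row$grade_mean - spec[[a]]$grade_mean), 0.5)
    expect_lt(abs(row$grade_sd - spec[[a]]$grade_sd), 0.5)
    for (ctx in 1:4) {
      w <- s$wtp[s$wtp$arm == a & s$wtp$context == ctx, ]
      expect_lt(abs(w$mean / spec[[a]]$wtp_mean[ctx] - 1), 0.05)
    }
  }
})

test_that("realized WTP-satisfaction rank correlation hits the target", {
  spec <- default_cohort_spec()
  spec$face_to_face$n_enrolled <- 2000L
  spec$web$n_enrolled <- 2000L
  cohort <- generate_cohort(spec, seed = 41)
  v <- wtp_construct_validity(wtp_long(cohort))
  target <- spec$web$rho
  for (ctx in 1:4) {
    expect_lt(abs(v$rho[ctx] - target[ctx]), 0.05)
  }
})

test_that("grade truncation introduces no material bias", {
  spec <- list(web = cohort_arm_spec(
    n_enrolled = 200000L, completion_probability = 1,
    grade_mean = 82, grade_sd = 10,
    wtp_mean = rep(100, 4), wtp_sd = rep(50, 4), rho = rep(0, 4)
  ))
  truncated <- generate_cohort(spec, seed = 51)$grade
  # untruncated control at the same nominal moments
  set.seed(51)
  control <- rnorm(length(truncated), 82, 10)
  expect_lt(abs(mean(truncated) - mean(control)), 0.2)
  expect_lt(abs(mean(truncated) - 82), 0.2)
})

test_that("summaries use the analysis estimators and handle edge tables", {
  cohort <- generate_cohort(seed = 61)
  s <- summarize_cohort(cohort)
  long <- wtp_long(cohort)
  m <- mean_wtp(long, "web", 2)
  w <- s$wtp[s$wtp$arm == "web" & s$wtp$context == 2, ]
  expect_equal(w$n, m$n)
  expect_equal(w$mean, m$mean)
  expect_equal(w$sd, m$sd)

  empty <- cohort[0, ]
  se <- summarize_cohort(empty)
  expect_equal(nrow(se$arms), 0)

  one <- cohort[which(cohort$completed)[1], ]
  so <- summarize_cohort(one)
  expect_equal(so$arms$grade_mean, one$grade)
  expect_true(is.na(so$arms$grade_sd))

  expect_error(summarize_cohort(cohort[, 1:3]), "lacks columns")
})
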