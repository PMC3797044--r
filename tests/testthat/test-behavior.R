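test_that("open-field scoring handles degenerate and scripted paths", {
  never <- score_open_field(data.frame(time = 0, x = 1, y = 1))
  expect_equal(never$latency, 600)
  expect_equal(never$total_squares, 0)
  # scripted path visiting all four internal squares once
  log <- data.frame(time = c(0, 10, 20, 30, 40, 50),
                    x = c(1, 3, 4, 3, 4, 1), y = c(1, 3, 3, 4, 4, 1))
  r <- score_open_field(log)
  expect_equal(r$latency, 10)
  expect_equal(r$internal_squares, 4)
  expect_equal(r$external_squares, 1)
  expect_equal(r$total_squares, 5)
  expect_error(score_open_field(data.frame(time = 0, x = 7, y = 1)),
               "off-grid")
  expect_error(score_open_field(data.frame(time = 700, x = 1, y = 1)),
               "within the session")
})

test_that("zone dwell times account for the full session", {
  set.seed(12)
  times <- sort(runif(200, 0, 600))
  log <- data.frame(time = c(0, times),
                    x = sample(1:6, 201, replace = TRUE),
                    y = sample(1:6, 201, replace = TRUE))
  r <- score_open_field(log)
  expect_equal(r$time_internal + r$time_external, 600, tolerance = 1e-9)
})

test_that("scoring is stable under timestamp refinement", {
  # continuous path sampled at two resolutions
  path <- function(t) cbind(x = 1 + floor(5 * t / 600 + 1e-12),
                            y = 1 + floor(3 * t / 600 + 1e-12))
  mk <- function(dt) {
    t <- seq(0, 599.9, by = dt)
    p <- path(t)
    data.frame(time = t, x = pmin(p[, "x"], 6), y = pmin(p[, "y"], 6))
  }
  r1 <- score_open_field(mk(1))
  r2 <- score_open_field(mk(0.5))
  expect_equal(r1$total_squares, r2$total_squares)
  expect_lt(abs(r1$time_internal - r2$time_internal) / 600, 0.01)
})

test_that("discrimination index follows its closed form and exclusion rules", {
  fam <- data.frame(object = "left", duration = 5)
  extreme <- score_recognition(fam, data.frame(object = "novel", duration = 10))
  expect_equal(extreme$di, 1)
  expect_true(extreme$learned)
  expect_true(extreme$excluded) # familiar object never explored in testing
  tie <- score_recognition(fam, data.frame(object = c("novel", "familiar"),
                                           duration = c(5, 5)))
  expect_equal(tie$di, 0)
  expect_false(tie$learned) # criterion is strictly above zero
  expect_false(tie$excluded)
  none_fam <- score_recognition(data.frame(object = character(),
                                           duration = numeric()),
                                data.frame(object = "novel", duration = 3))
  expect_true(none_fam$excluded)
  expect_match(none_fam$exclusion_reason, "familiarization")
  no_test <- score_recognition(fam, data.frame(object = character(),
                                               duration = numeric()))
  expect_true(no_test$excluded)
  expect_true(is.na(no_test$di))
})

test_that("DI is antisymmetric under swapping novel and familiar", {
  set.seed(9)
  for (i in 1:20) {
    nv <- runif(1, 0.5, 20); fm <- runif(1, 0.5, 20)
    fam <- data.frame(object = "left", duration = 5)
    a <- score_recognition(fam, data.frame(object = c("novel", "familiar"),
                                           duration = c(nv, fm)))
    b <- score_recognition(fam, data.frame(object = c("novel", "familiar"),
                                           duration = c(fm, nv)))
    expect_equal(a$di, -b$di)
  }
})

test_that("group comparison routes by normality and controls type I error", {
  set.seed(31)
  n <- 20
  rejections <- vapply(1:200, function(i) {
    tbl <- data.frame(group = rep(c("control", "case"), each = n / 2),
                      gender = sample(rep(c("male", "female"), n / 2)),
                      y = rnorm(n))
    compare_groups(tbl, "y")$p < 0.05
  }, logical(1))
  expect_equal(mean(rejections), 0.05, tolerance = 0.5)
  # presentation contract: exactly one of mean(SD) / median(IQR) per route
  tbl <- data.frame(group = rep(c("control", "case"), each = 10),
                    gender = rep(c("male", "female"), 10),
                    normal_var = rnorm(20, 10),
                    skewed_var = rlnorm(20, 0, 1.5))
  cg_n <- compare_groups(tbl, "normal_var")
  expect_true(cg_n$normal)
  expect_match(cg_n$method, "linear model")
  cg_s <- compare_groups(tbl, "skewed_var")
  expect_match(cg_s$method, "log-transformed")
  rep_tab <- report_group_table(tbl, c("normal_var", "skewed_var"))
  expect_equal(grepl("†", rep_tab$variable), !rep_tab$normal)
})

test_that("a pure gender effect is absorbed by the adjustment", {
  set.seed(17)
  hits <- vapply(1:100, function(i) {
    gender <- sample(rep(c("male", "female"), 10))
    tbl <- data.frame(group = rep(c("control", "case"), each = 10),
                      gender = gender,
                      y = rnorm(20) + 2 * (gender == "male"))
    compare_groups(tbl, "y")$p < 0.05
  }, logical(1))
  expect_gte(mean(!hits), 0.9)
})

test_that("categorical comparison reproduces the textbook chi-squared", {
  tbl <- data.frame(group = rep(c("control", "case"), c(19, 30)),
                    gender = "female",
                    died = c(rep(c("yes", "no"), c(5, 14)),
                             rep(c("yes", "no"), c(17, 13))))
  cg <- compare_groups(tbl, "died", "categorical")
  # hand evaluation of sum((O-E)^2/E) on the 2x2 table
  O <- rbind(c(14, 5), c(13, 17))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(cg$statistic, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_equal(cg$p, 1 - pchisq(sum((O - E)^2 / E), 1), tolerance = 1e-12)
})

test_that("cohort accounting reproduces the printed flow rates", {
  flow <- data.frame(group = c("control", "case"),
                     included = c(23, 47), alive = c(19, 30),
                     survived = c(14, 13), evaluated = c(14, 13),
                     excluded = c(3, 3))
  acc <- cohort_accounting(flow)
  expect_equal(acc$stillbirth_pct, c(17.4, 36.2))
  expect_equal(acc$neonatal_mortality_pct, c(26.3, 56.7))
  expect_equal(acc$final_n, c(11, 10))
  expect_equal(attr(acc, "final_total"), 21)
  bad <- flow; bad$alive[1] <- 25
  expect_error(cohort_accounting(bad), "monotone")
})

test_that("inter-rater ICC behaves across agreement regimes", {
  set.seed(23)
  x <- rnorm(50)
  expect_equal(interrater_icc(x, x), 1)
  # independent scores: ICC near zero
  expect_lt(abs(interrater_icc(x, rnorm(50))), 0.3)
  # constant shift: absolute agreement < consistency
  expect_lt(interrater_icc(x, x + 1), interrater_icc(x, x + 1, "consistency"))
  expect_equal(interrater_icc(x, x + 1, "consistency"), 1)
  expect_error(interrater_icc(rep(1, 5), rep(1, 5)), "zero total variance")
})
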