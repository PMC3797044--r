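test_that("b=0 volumes carry exactly S0 in a noiseless phantom", {
  ph <- make_phantom(single_bundle_spec(), scheme_lite)
  b0 <- ph$dwi$signal[, , , which(scheme_lite$bvalues == 0)]
  expect_equal(max(abs(b0 - 100)), 0)
})

test_that("seeded phantom generation is bit-reproducible", {
  spec <- single_bundle_spec(sigma = 3, seed = 99)
  ph1 <- make_phantom(spec, scheme_lite)
  ph2 <- make_phantom(spec, scheme_lite)
  expect_identical(ph1$dwi$signal, ph2$dwi$signal)
})

test_that("Rician corruption converges to the clean signal as sigma -> 0", {
  clean <- make_phantom(single_bundle_spec(sigma = 0), scheme_lite)
  tiny <- make_phantom(single_bundle_spec(sigma = 1e-8), scheme_lite)
  expect_lt(max(abs(tiny$dwi$signal - clean$dwi$signal)), 1e-6)
})

test_that("overlapping bundles with fractions above one are rejected", {
  vs <- 0.7
  mk <- function(nm) list(name = nm,
                          centerline = rbind(c(0, vs, 1.4), c(0, 4 * vs, 1.4)),
                          radius = 100, evals = c(1.7, 0.3, 0.3) * 1e-3,
                          frac = 0.6)
  spec <- phantom_spec(shape = c(6, 6, 4), bundles = list(mk("a"), mk("b")),
                       regions = list(), sigma = 0)
  expect_error(make_phantom(spec, scheme_lite), "fractions exceed 1")
})

test_that("gradient scheme invariants are enforced", {
  expect_error(gradient_scheme(c(0, 1000), rbind(c(0, 0, 0))), "counts differ")
  expect_error(gradient_scheme(c(1000, 2000), rbind(c(1, 0, 0), c(0, 1, 0))),
               "b=0")
  expect_error(gradient_scheme(c(0, 1000), rbind(c(0, 0, 0), c(2, 0, 0))),
               "unit vectors")
  sch <- default_scheme(126, 3000)
  expect_equal(sch$n, 127)
  nrm <- sqrt(rowSums(sch$directions[sch$bvalues > 0, ]^2))
  expect_lt(max(abs(nrm - 1)), 1e-6)
})

test_that("default atlas places every paired region with valid labels", {
  ph <- make_phantom(phantom_spec(shape = c(24, 24, 12), sigma = 0),
                     scheme_lite)
  at <- ph$atlas
  expect_setequal(unique(at$table$region),
                  c("prefrontal cortex", "cingulate cortex", "temporal cortex",
                    "caudate", "putamen", "thalamus", "amygdala",
                    "hippocampus", "hippocampal formation"))
  expect_setequal(unique(at$table$hemisphere), c("left", "right"))
  ids <- unique(as.vector(at$labels))
  expect_true(all(setdiff(ids, 0) %in% at$table$id))
  # bundle traversals carry the network-defining regions
  expect_setequal(ph$truth$traversals$anxiety_left$region,
                  c("amygdala", "hippocampal formation", "cingulate cortex"))
  expect_setequal(ph$truth$traversals$memory_right$region,
                  c("hippocampal formation", "hippocampus", "temporal cortex",
                    "prefrontal cortex"))
})

test_that("study table matches the cohort design (11 controls + 10 cases)", {
  coh <- simulate_cohort(cohort_spec(n_controls = 11, n_cases = 10, seed = 5),
                         phantom_spec(shape = c(20, 20, 10), sigma = 0),
                         scheme_lite, materialize = FALSE)
  expect_equal(nrow(coh$table), 21)
  expect_equal(sum(coh$table$group == "control"), 11)
  expect_equal(sum(coh$table$group == "case"), 10)
  expect_false(any(is.na(coh$table$group)))
  expect_false(any(is.na(coh$table$gender)))
  expect_equal(anyDuplicated(coh$table$id), 0)
})

test_that("null cohort (zero effect) leaves the groups identical in law", {
  csp <- cohort_spec(n_controls = 10, n_cases = 10, fa_effect = 0,
                     thinning = 0, seed = 11)
  coh <- simulate_cohort(csp, phantom_spec(shape = c(20, 20, 10), sigma = 1),
                         scheme_lite)
  m <- vapply(coh$subjects, function(ph) mean(ph$dwi$signal), numeric(1))
  grp <- coh$table$group
  d <- mean(m[grp == "control"]) - mean(m[grp == "case"])
  se <- sqrt(var(m[grp == "control"]) / 10 + var(m[grp == "case"]) / 10)
  expect_lt(abs(d), 3 * se + 1e-12)
})

test_that("behavioral coupling gives negative severity-DI rank correlation", {
  coh <- simulate_cohort(cohort_spec(n_controls = 25, n_cases = 25, seed = 3),
                         phantom_spec(shape = c(20, 20, 10), sigma = 0),
                         scheme_lite, materialize = FALSE)
  rho <- cor(coh$table$severity, coh$table$di, method = "spearman")
  expect_lt(rho, 0)
  # latency increases with severity
  expect_gt(cor(coh$table$severity, coh$table$latency, method = "spearman"), 0)
})

test_that("cases receive the planted eigenvalue reduction and thinning", {
  csp <- cohort_spec(n_controls = 2, n_cases = 2, fa_effect = 0.3,
                     thinning = 0.4, seed = 8)
  coh <- simulate_cohort(csp, phantom_spec(shape = c(24, 24, 12), sigma = 0),
                         scheme_lite, materialize = FALSE)
  ctrl <- make_phantom(coh$specs[[which(coh$table$group == "control")[1]]],
                       scheme_lite)
  case <- make_phantom(coh$specs[[which(coh$table$group == "case")[1]]],
                       scheme_lite)
  n_ctrl <- length(ctrl$truth$bundles$anxiety_left$voxels)
  n_case <- length(case$truth$bundles$anxiety_left$voxels)
  expect_equal(n_case / n_ctrl, 0.6, tolerance = 0.05)
  expect_gt(length(case$truth$bundles$anxiety_left$effect_voxels), 0)
  expect_equal(length(ctrl$truth$bundles$anxiety_left$effect_voxels), 0)
})
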