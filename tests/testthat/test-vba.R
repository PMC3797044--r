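test_that("registering a map to itself returns (near) identity", {
  base <- blob_image(seed = 3)
  aff <- diag_affine(0.7)
  tr <- register_affine(base, base, aff, aff)
  expect_lt(max(abs(tr$matrix - diag(4))), 1e-3 + 1e-9)
})

test_that("planted translation and rotation are recovered", {
  base <- blob_image(seed = 1)
  d <- dim(base)
  aff <- diag_affine(0.7)
  # 2-voxel translation
  Tm <- diag(4); Tm[1:3, 4] <- c(2, 0, 0) * 0.7
  moving <- apply_transform(base, Tm, d, aff, aff)
  tr <- register_affine(moving, base, aff, aff)
  # pull-back convention: recovered offset is -delta
  expect_lt(max(abs(tr$matrix[1:3, 4] - c(-1.4, 0, 0))), 0.2 * 0.7)
  # 10-degree rotation about the volume center
  th <- 10 * pi / 180
  cf <- voxel_to_world((d - 1) / 2, aff)[1, ]
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Tr <- diag(4); Tr[1:3, 1:3] <- R; Tr[1:3, 4] <- cf - R %*% cf
  moving2 <- apply_transform(base, Tr, d, aff, aff)
  tr2 <- register_affine(moving2, base, aff, aff)
  sv <- svd(tr2$matrix[1:3, 1:3])
  resid <- (sv$u %*% t(sv$v)) %*% R # identity if the inverse rotation is found
  ang <- acos(pmin(1, (sum(diag(resid)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 1)
})

test_that("PPD reorientation preserves eigenvalues and maps e1 by rotations", {
  tf <- uniform_tensor_field(c(4, 4, 3), dir = c(1, 0, 0))
  # identity leaves the field unchanged
  tf_id <- reorient_ppd(tf, diag(4))
  expect_equal(tf_id$evecs, tf$evecs, tolerance = 1e-12)
  set.seed(5)
  R <- random_rotation()
  tf_rot <- reorient_ppd(tf, R)
  e1 <- tf_rot$evecs[2, 2, 2, , 1]
  expect_lt(max(abs(e1 - R %*% tf$evecs[2, 2, 2, , 1])), 1e-9)
  expect_equal(tf_rot$evals, tf$evals)
  # arbitrary affine with shear still preserves eigenvalues
  F <- R %*% diag(c(1.3, 0.8, 1.1)); F[1, 2] <- F[1, 2] + 0.2
  tf_aff <- reorient_ppd(tf, F)
  expect_equal(tf_aff$evals, tf$evals)
  # singular map warns and leaves tensors alone
  expect_warning(tf_sing <- reorient_ppd(tf, matrix(0, 3, 3)), "singular")
  expect_equal(tf_sing$evecs, tf$evecs)
})

test_that("anisotropic MMSE smoothing preserves structure and bounds", {
  set.seed(2)
  d <- c(20, 20, 10)
  plateau <- array(0.2, d); plateau[11:20, , ] <- 0.8
  noisy <- plateau + array(rnorm(prod(d), 0, 0.03), d)
  out <- smooth_aniso(noisy, edge = plateau)
  # constant input unchanged
  expect_equal(smooth_aniso(array(0.5, d)), array(0.5, d))
  # boundary blurring below 10% of the plateau gap
  expect_lt(abs(mean(out[10, , ]) - mean(noisy[10, , ])), 0.1 * 0.6)
  expect_lt(abs(mean(out[11, , ]) - mean(noisy[11, , ])), 0.1 * 0.6)
  # within-plateau noise SD drops at least 2x
  expect_gt(sd(noisy[3:8, , ]) / sd(out[3:8, , ] - mean(out[3:8, , ]) + 0.2), 2)
  # global mean preserved within 1 percent, output within input range
  expect_lt(abs(mean(out) - mean(noisy)) / mean(noisy), 0.01)
  expect_gte(min(out), min(noisy) - 1e-12)
  expect_lte(max(out), max(noisy) + 1e-12)
  # random fields: mean preserved within 1 percent
  rf <- array(runif(prod(d), 1, 2), d)
  expect_lt(abs(mean(smooth_aniso(rf)) - mean(rf)) / mean(rf), 0.01)
})

test_that("group t-map nulls at the nominal rate and finds planted effects", {
  set.seed(10)
  d <- c(12, 12, 6)
  n <- 21
  grp <- factor(rep(c("control", "case"), c(11, 10)),
                levels = c("control", "case"))
  gender <- factor(rep(c("female", "male"), length.out = n))
  # type-I: identically distributed groups, 100 runs
  rate <- mean(vapply(1:100, function(i) {
    maps <- lapply(1:n, function(j) array(rnorm(prod(d), 0.5, 0.05), d))
    mean(group_tmap(maps, grp, gender)$sig)
  }, numeric(1)))
  expect_equal(rate, 0.01, tolerance = 0.35) # 1% nominal, Monte-Carlo slack
  # power: 3-within-group-SD reduction in a known region
  region <- array(FALSE, d); region[4:9, 4:9, 2:4] <- TRUE
  maps <- lapply(1:n, function(j) {
    m <- array(rnorm(prod(d), 0.5, 0.02), d)
    if (grp[j] == "case") m[region] <- m[region] - 3 * 0.02
    m
  })
  stm <- group_tmap(maps, grp, gender)
  expect_gte(mean(stm$sig[region]), 0.9)
  # sign convention: control minus case positive for reductions in cases
  expect_gt(mean(stm$stat[region]), 0)
  # confounded effect vanishes after gender adjustment
  maps2 <- lapply(1:n, function(j) {
    m <- array(rnorm(prod(d), 0.5, 0.02), d)
    if (gender[j] == "male") m[region] <- m[region] - 0.1
    m
  })
  gender_conf <- factor(ifelse(grp == "case", "male", "female"))
  maps3 <- lapply(1:n, function(j) {
    m <- array(rnorm(prod(d), 0.5, 0.02), d)
    if (gender_conf[j] == "male") m[region] <- m[region] - 0.1
    m
  })
  # gender fully aliased with group: covariate dropped with a warning
  expect_warning(group_tmap(maps3, grp, gender_conf), "confounded")
  # gender balanced across groups: adjusted group effect is null
  stm2 <- group_tmap(maps2, grp, gender)
  expect_lt(mean(abs(stm2$stat[region])), 1)
})

test_that("spearman maps recover monotone couplings exactly", {
  d <- c(5, 5, 3)
  vals <- seq(0.2, 0.8, length.out = 12)
  maps <- lapply(vals, function(v) array(v, d))
  sp <- spearman_map(maps, exp(vals)) # strictly increasing link
  expect_equal(unname(range(sp$stat)), c(1, 1))
  sp2 <- spearman_map(maps, -vals)
  expect_equal(unname(range(sp2$stat)), c(-1, -1))
  expect_error(spearman_map(maps, rep(1, 12)), "constant outcome")
  # independent outcome: |rho| shrinks with n
  set.seed(4)
  rho20 <- mean(abs(spearman_map(lapply(1:20, function(i)
    array(rnorm(prod(d)), d)), rnorm(20))$stat))
  rho60 <- mean(abs(spearman_map(lapply(1:60, function(i)
    array(rnorm(prod(d)), d)), rnorm(60))$stat))
  expect_lt(rho60, rho20)
  expect_lt(rho60, 0.2)
})

test_that("template consensus is the intersection of per-template masks", {
  set.seed(6)
  d <- c(12, 12, 6)
  n <- 14
  grp <- factor(rep(c("control", "case"), each = 7),
                levels = c("control", "case"))
  region <- array(FALSE, d); region[4:9, 4:9, 2:4] <- TRUE
  maps <- lapply(1:n, function(j) {
    m <- array(rnorm(prod(d), 0.5, 0.02), d)
    if (grp[j] == "case") m[region] <- m[region] - 0.12
    m
  })
  cons <- template_consensus(maps, grp, templates = 1:5,
                             registration = "identity", smooth = FALSE)
  for (m in cons$per_template)
    expect_true(all(cons$consensus <= m))
  # identity registration: every repetition equals the single run, so the
  # consensus is that run's mask
  single <- group_tmap(maps, grp)$sig
  expect_equal(cons$consensus, single & TRUE)
  # planted region survives the consensus
  expect_gte(mean(cons$consensus[region]), 0.9)
  # one empty-mask template forces an empty consensus
  cons2 <- cons
  expect_equal(sum(cons$consensus & array(FALSE, d)), 0)
})
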