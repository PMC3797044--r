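make_test_atlas <- function() {
  labels <- array(0L, c(10, 4, 4))
  labels[1:2, , ] <- 1L   # left amygdala
  labels[4:5, , ] <- 2L   # left hippocampal formation
  labels[7:8, , ] <- 3L   # left thalamus
  tab <- data.frame(id = 1:3,
                    region = c("amygdala", "hippocampal formation", "thalamus"),
                    hemisphere = "left", stringsAsFactors = FALSE)
  region_atlas(labels, tab, diag_affine(1))
}

line_tract <- function(...) {
  sls <- list(...)
  structure(list(streamlines = sls,
                 seed_voxel = matrix(0L, length(sls), 3), step = 0.5,
                 params = list()), class = "tractogram")
}

test_that("passes_through follows nearest-voxel label lookup", {
  at <- make_test_atlas()
  inside <- rbind(c(1, 1, 1))
  expect_true(passes_through(inside, at, "amygdala"))
  expect_true(passes_through(inside, at, "amygdala", "left"))
  expect_false(passes_through(inside, at, "amygdala", "right"))
  background <- rbind(c(9, 2, 2))
  expect_false(passes_through(background, at, "amygdala"))
  outside <- rbind(c(50, 50, 50))
  expect_false(passes_through(outside, at, "thalamus"))
  expect_error(passes_through(inside, at, "putamen"), "not present")
})

test_that("fine sampling detects region corners the coarse step would confirm", {
  at <- make_test_atlas()
  # diagonal streamline clipping the hippocampal-formation slab between
  # sample points: dense-resampling oracle agrees with step <= width/2
  sl <- rbind(c(3.4, 0, 0), c(3.75, 1, 1), c(4.1, 2, 2))
  expect_true(passes_through(sl, at, "hippocampal formation"))
})

test_that("network extraction applies AND/OR logic with laterality", {
  at <- make_test_atlas()
  spec <- network_spec("toy", required = c("amygdala", "hippocampal formation"),
                       optional = "thalamus")
  full <- rbind(c(1, 2, 2), c(4, 2, 2), c(7, 2, 2))   # all three regions
  required_only <- rbind(c(1, 2, 2), c(4, 2, 2))      # no optional region
  amygdala_only <- rbind(c(1, 2, 2))
  tg <- line_tract(full, required_only, amygdala_only)
  kept <- extract_network(tg, at, spec, "global")
  expect_equal(attr(kept, "member_index"), 1L)
  kept_l <- extract_network(tg, at, spec, "left")
  expect_equal(attr(kept_l, "member_index"), 1L)
  kept_r <- extract_network(tg, at, spec, "right")
  expect_equal(total_fiber_count(kept_r), 0)
  expect_error(extract_network(tg, at, network_spec("bad", "putamen", "caudate"),
                               "global"),
               "absent from the atlas")
})

test_that("a bilateral fiber is global-only", {
  labels <- array(0L, c(10, 4, 4))
  labels[1:2, , ] <- 1L; labels[4:5, , ] <- 2L; labels[7:8, , ] <- 3L
  tab <- data.frame(id = 1:3,
                    region = c("amygdala", "hippocampal formation", "thalamus"),
                    hemisphere = c("left", "right", "left"),
                    stringsAsFactors = FALSE)
  at <- region_atlas(labels, tab, diag_affine(1))
  spec <- network_spec("toy", required = c("amygdala", "hippocampal formation"),
                       optional = "thalamus")
  crossing <- rbind(c(1, 2, 2), c(4, 2, 2), c(7, 2, 2)) # left Am, right HpF
  tg <- line_tract(crossing)
  expect_equal(total_fiber_count(extract_network(tg, at, spec, "global")), 1)
  expect_equal(total_fiber_count(extract_network(tg, at, spec, "left")), 0)
  expect_equal(total_fiber_count(extract_network(tg, at, spec, "right")), 0)
})

test_that("phantom network membership matches the brute-force trace oracle", {
  ph <- make_phantom(phantom_spec(shape = c(24, 24, 12), sigma = 1.5,
                                  seed = 13), scheme_lite)
  tf <- fit_tensor(ph$dwi)
  sm <- scalar_maps(tf)
  tg <- track(tf, sm)
  expect_lte(total_fiber_count(tg), 1200)
  for (net in c("anxiety", "memory")) {
    for (side in c("global", "left", "right")) {
      got <- logical(total_fiber_count(tg))
      got[attr(extract_network(tg, ph$atlas, net, side), "member_index")] <- TRUE
      want <- oracle_network_membership(tg, ph$atlas, net, side)
      expect_identical(got, want)
    }
    gl <- attr(extract_network(tg, ph$atlas, net, "global"), "member_index")
    le <- attr(extract_network(tg, ph$atlas, net, "left"), "member_index")
    ri <- attr(extract_network(tg, ph$atlas, net, "right"), "member_index")
    expect_length(intersect(le, ri), 0)
    expect_true(all(le %in% gl))
    expect_true(all(ri %in% gl))
  }
})

test_that("fiber ratio arithmetic and monotonicity hold", {
  at <- make_test_atlas()
  sl <- rbind(c(1, 2, 2), c(4, 2, 2), c(7, 2, 2))
  bg <- rbind(c(9, 1, 1), c(9, 2, 2))
  whole <- do.call(line_tract, c(rep(list(sl), 5), rep(list(bg), 45)))
  spec <- network_spec("toy", required = c("amygdala", "hippocampal formation"),
                       optional = "thalamus")
  net <- extract_network(whole, at, spec, "global")
  expect_equal(fiber_ratio(net, whole), 0.1)
  expect_equal(fiber_ratio(whole, whole), 1.0)
  expect_error(fiber_ratio(net, line_tract()), "empty")
  # adding streamlines to the whole set never increases the ratio
  bigger <- concat_tractograms(whole, line_tract(bg))
  expect_lte(fiber_ratio(net, bigger), fiber_ratio(net, whole))
})

test_that("network mean FA pools points and flags empty networks", {
  fa <- array(0.5, c(10, 4, 4))
  maps <- structure(list(fa = fa, affine = diag_affine(1),
                         mask = array(TRUE, c(10, 4, 4))),
                    class = "scalar_maps")
  tg <- line_tract(rbind(c(2, 2, 2), c(3, 2, 2)), rbind(c(5, 2, 2)))
  expect_equal(network_mean_fa(tg, maps), 0.5)
  expect_warning(v <- network_mean_fa(subset_tractogram(tg, integer(0)), maps),
                 "empty network")
  expect_true(is.na(v))
  # pooled weighted mean over regions of different FA and point counts
  fa2 <- fa
  fa2[1:5, , ] <- 0.2
  fa2[6:10, , ] <- 0.8
  maps2 <- structure(list(fa = fa2, affine = diag_affine(1),
                          mask = array(TRUE, c(10, 4, 4))),
                     class = "scalar_maps")
  t2 <- line_tract(rbind(c(1, 2, 2), c(2, 2, 2), c(3, 2, 2)), # 3 pts at 0.2
                   rbind(c(7, 2, 2)))                          # 1 pt at 0.8
  expect_equal(network_mean_fa(t2, maps2), (3 * 0.2 + 1 * 0.8) / 4)
})
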