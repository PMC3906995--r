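test_that("segmentation finds disjoint nuclei and returns none on blank images", {
  cfg <- sim_config(seed = 1)
  set.seed(1)
  st <- layout_nuclei(5, cfg, image_size = 256)
  st$n_foci <- 0L; st$p53_level <- 100
  stk <- render_image_stack(st, cfg, image_size = 256)
  seg <- segment_nuclei(max_project(stk$channels$h2b))
  expect_identical(nrow(seg$nuclei), 5L)
  # centroids match the layout
  d <- vapply(seq_len(5), function(i)
    min(sqrt((seg$nuclei$cy - st$cy[i])^2 + (seg$nuclei$cx - st$cx[i])^2)),
    numeric(1))
  expect_true(all(d < 4))
  # blank: zero labels, not an error
  set.seed(2)
  blank <- matrix(abs(rnorm(96 * 96, 100, 10)), 96, 96)
  expect_identical(nrow(segment_nuclei(blank)$nuclei), 0L)
  expect_error(segment_nuclei(matrix(0, 10, 10)), "64 x 64")
})

test_that("touching nuclei are split by the watershed", {
  cfg <- sim_config(seed = 1)
  set.seed(3)
  # two ellipses overlapping by < 30% of the minor axis
  st <- data.frame(cell_id = 1:2, cy = c(64, 64), cx = c(50, 128 - 44),
                   ry = c(40, 40), rx = c(42, 42), n_foci = 0L,
                   p53_level = 100)
  stk <- render_image_stack(st, cfg, image_size = 176)
  seg <- segment_nuclei(max_project(stk$channels$h2b),
                        seed_min_distance = 25L)
  expect_identical(nrow(seg$nuclei), 2L)
})

test_that("foci detection: empty, well-separated and boundary cases", {
  set.seed(4)
  stk0 <- render_test_nucleus(0)
  seg0 <- segment_nuclei(max_project(stk0$channels$h2b))
  det0 <- detect_foci(max_project(stk0$channels$foci), seg0)
  expect_identical(sum(det0$counts$count), 0L)

  stk12 <- render_test_nucleus(12, snr = 5)
  seg12 <- segment_nuclei(max_project(stk12$channels$h2b))
  det12 <- detect_foci(max_project(stk12$channels$foci), seg12)
  expect_identical(sum(det12$counts$count), 12L)
  # each centroid within 1 px of ground truth
  tr <- stk12$truth$foci
  err <- vapply(seq_len(nrow(det12$foci)), function(j)
    min(sqrt((tr$y - det12$foci$y[j])^2 + (tr$x - det12$foci$x[j])^2)),
    numeric(1))
  expect_true(all(err <= 1.0))

  # nucleus smaller than the structuring element: count 0 with warning
  lab <- matrix(0L, 96, 96); lab[40:44, 40:44] <- 1L
  expect_warning(
    d <- detect_foci(matrix(100, 96, 96), lab),
    "structuring element")
  expect_identical(d$counts$count, 0L)
})

test_that("touching foci are separated by the marker-directed watershed", {
  # two spots at ~3.3 sigma centre distance: a single merged candidate
  # region, split into two by the seeded watershed (closer pairs merge
  # into one true maximum and are not resolvable by any method)
  cfg <- sim_config(seed = 1)
  cfg$read_noise_sd <- 0.5; cfg$background <- 200; cfg$spot_peak <- 200
  set.seed(5)
  hits <- vapply(1:10, function(i) {
    st <- data.frame(cell_id = 1, cy = 64, cx = 64, ry = 43, rx = 46,
                     n_foci = 0L, p53_level = 100)
    stk <- render_image_stack(st, cfg, image_size = 128)
    vol <- array(cfg$background, dim = dim(stk$channels$foci))
    vol <- fociPulse:::add_gaussian_spot(vol, 64, 61.5, 4, cfg$spot_peak, 1.5, 1)
    vol <- fociPulse:::add_gaussian_spot(vol, 64, 66.5, 4, cfg$spot_peak, 1.5, 1)
    stk$channels$foci <- fociPulse:::apply_camera_noise(vol, cfg)
    seg <- segment_nuclei(max_project(stk$channels$h2b))
    sum(detect_foci(max_project(stk$channels$foci), seg)$counts$count)
  }, integer(1))
  expect_true(all(hits == 2L))
})

test_that("threshold sweep: identity at 1.0, monotone, dead above the maximum", {
  set.seed(6)
  stk <- render_test_nucleus(10, snr = 6)
  seg <- segment_nuclei(max_project(stk$channels$h2b))
  proj <- max_project(stk$channels$foci)
  sw1 <- threshold_sweep(proj, seg, factors = 1.0)
  expect_identical(sw1$counts$count, detect_foci(proj, seg)$counts$count)
  sw <- threshold_sweep(proj, seg, factors = c(0.6, 0.8, 1.0, 1.15, 1.3, 50))
  per <- sw$counts$count[order(sw$counts$threshold_factor)]
  expect_true(all(diff(per) <= 0))
  expect_identical(per[length(per)], 0L)   # factor far above the maximum
  expect_error(threshold_sweep(proj, seg, factors = c(-1, 1)), "factors")
})

test_that("counts are invariant to additive offset and whole-pixel translation", {
  set.seed(7)
  stk <- render_test_nucleus(8, snr = 6)
  seg <- segment_nuclei(max_project(stk$channels$h2b))
  proj <- max_project(stk$channels$foci)
  base <- sum(detect_foci(proj, seg)$counts$count)
  # +500 intensity offset everywhere: the top-hat removes it
  off <- sum(detect_foci(proj + 500, seg)$counts$count)
  expect_identical(off, base)
  # translate image and mask by 5 px
  sh <- function(m) rbind(m[-(1:5), ], m[1:5, ])
  lab <- sh(seg$labels)
  shifted <- sum(detect_foci(sh(proj), lab)$counts$count)
  expect_identical(shifted, base)
})
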