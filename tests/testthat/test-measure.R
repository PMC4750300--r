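test_that("polyline length: 3-4-5 triangle, additivity, reversal symmetry", {
  expect_equal(polyline_length_2d(rbind(c(0, 0), c(3, 4)), dxy = 1), 5)
  expect_equal(
    polyline_length_2d(rbind(c(0, 0), c(1, 0), c(2, 0)), dxy = 0.5), 1
  )
  pts <- rbind(c(0.2, 1.3), c(4.5, 2.2), c(7.1, 9.9))
  expect_equal(
    polyline_length_2d(pts, 0.13),
    polyline_length_2d(pts[3:1, ], 0.13)
  )
  expect_error(polyline_length_2d(rbind(c(0, 0)), 1), "2 points")
})

test_that("z_extent counts slice intervals, not slices", {
  expect_equal(z_extent(make_annotation("c", c(0, 1), c(0, 1), 5, 5), 0.25), 0)
  expect_equal(z_extent(make_annotation("c", c(0, 1), c(0, 1), 2, 10), 0.25), 2)
})

test_that("PyT combines projection and depth; reduces to MIP at zero depth", {
  # a = 3 um (30 px at 0.1 um), b = 4 um (16 intervals at 0.25) -> c = 5
  ann <- make_annotation("c", c(0, 30), c(0, 0), 0, 16)
  expect_equal(measure_pyt(ann, dxy = 0.1, dz = 0.25), 5)
  flat <- make_annotation("c", c(2, 17.3), c(1, 8.6), 7, 7)
  expect_identical(
    measure_pyt(flat, dxy = 0.1, dz = 0.25),
    measure_mip(flat, dxy = 0.1)
  )
})

test_that("PyT >= MIP always, equality only for single-slice annotations", {
  set.seed(21)
  for (i in 1:50) {
    zf <- sample(0:10, 1)
    zl <- zf + sample(0:8, 1)
    ann <- make_annotation("c", runif(3, 0, 40), runif(3, 0, 40), zf, zl)
    mip <- measure_mip(ann, 0.1)
    pyt <- measure_pyt(ann, 0.1, 0.25)
    expect_gte(pyt, mip)
    if (zf == zl) expect_identical(pyt, mip) else expect_gt(pyt, mip)
  }
})

test_that("PyT error on synthetic cilia is bounded by the span quantization", {
  # analytic bound: |c - L| <= |b - E| <= dz for nearest-plane spans
  set.seed(8)
  for (i in 1:20) {
    L <- runif(1, 2, 5)
    el <- runif(1, 0, 70)
    dz <- 0.25
    bz <- runif(1, 0.9, 1.6)
    gt <- ground_truth_cilia("c", 1, 1, bz, L, el, 0)
    ann <- analytic_annotations(gt, dxy = 0.1, dz = dz)
    pyt <- measure_pyt(ann, 0.1, dz)
    expect_lt(abs(pyt - L), dz + 1e-9)
  }
})

test_that("MIP underestimates angled cilia by the elevation cosine", {
  r <- render_clean(3, 60)
  m <- measure_cilia(r$stack, r$annotations, methods = c("MIP", "PYT"),
    replicates = 1)
  mip <- m$length_um[m$method == "MIP"]
  expect_equal(mip, 3 * cos(60 * pi / 180), tolerance = 0.05)
  expect_lt(mip, m$length_um[m$method == "PYT"])
})

test_that("max projection takes the per-pixel maximum over z", {
  vox <- array(0L, c(7, 5, 6))
  vox[5, 3, 2] <- 200L
  st <- zstack(vox, dxy = 0.1, dz = 0.25)
  pr <- max_projection(st)
  expect_equal(sum(pr > 0), 1L)
  expect_equal(pr[3, 2], 200L)
  one <- zstack(array(3L, c(1, 2, 2)), dxy = 1, dz = 1)
  expect_true(all(max_projection(one) == 3L))
})

test_that("classification is a pure function of the slice span", {
  spans <- list(c(0, 3), c(0, 4), c(2, 2), c(5, 12))
  expected <- c("FLAT", "ANGLED", "FLAT", "ANGLED")
  for (i in seq_along(spans)) {
    ann <- make_annotation("c", c(0, 5, 9), c(0, 2, 7),
      spans[[i]][1], spans[[i]][2])
    expect_equal(classify_cilia(ann)$classification, expected[i])
    # permuting polyline points never changes the call
    perm <- ann[sample(nrow(ann)), ]
    perm$point_index <- seq_len(nrow(perm)) - 1L
    expect_equal(classify_cilia(perm)$classification, expected[i])
  }
  # configurable boundary
  ann5 <- make_annotation("c", c(0, 1), c(0, 1), 0, 4)
  expect_equal(
    classify_cilia(ann5, measure_config(flat_max_slices = 5))$classification,
    "FLAT"
  )
})

test_that("replicate averaging reports mean and QC range, order-invariantly", {
  m <- tibble::tibble(
    cilium_id = "c1", method = "PYT", replicate = 1:3,
    length_um = c(3.0, 3.1, 3.2), classification = "FLAT"
  )
  avg <- average_replicates(m)
  expect_equal(avg$length_um, 3.1)
  expect_equal(avg$length_range_um, 0.2, tolerance = 1e-12)
  expect_equal(average_replicates(m[c(3, 1, 2), ]), avg)
  single <- average_replicates(m[1, ])
  expect_equal(single$length_um, 3.0)
  expect_equal(single$length_range_um, 0)
  expect_error(average_replicates(m[, c("cilium_id", "replicate")]),
    "lack columns")
})

test_that("measure_cilia emits one row per cilium x method x replicate", {
  r <- render_clean(3, 30)
  ann2 <- dplyr::bind_rows(
    r$annotations,
    dplyr::mutate(r$annotations, cilium_id = "c2")
  )
  m <- measure_cilia(r$stack, ann2, replicates = 3)
  expect_equal(nrow(m), 2 * 3 * 3)
  # deterministic mode: replicates identical
  rng <- average_replicates(m)
  expect_true(all(rng$length_range_um == 0))
  m1 <- measure_cilia(r$stack, ann2, methods = "PYT", replicates = 3)
  expect_equal(nrow(m1), 6)
})
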