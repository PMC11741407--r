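make_series <- function(dims = c(6, 6, 4), n_vol = 5, fd = NULL,
                        seed = 1) {
  set.seed(seed)
  if (is.null(fd)) fd <- runif(n_vol, 0, 0.25)
  base <- array(rnorm(prod(dims), 100, 10), dims)
  vols <- array(0, c(dims, n_vol))
  for (t in seq_len(n_vol)) vols[, , , t] <- base + rnorm(prod(dims), 0, 1)
  volume_series(vols, fd)
}

test_that("FD censoring applies the strict threshold rule", {
  expect_equal(censor_volumes(c(0.1, 0.4, 0.2)), c(TRUE, FALSE, TRUE))
  expect_equal(censor_volumes(rep(0, 5)), rep(TRUE, 5))
  expect_equal(censor_volumes(c(0.3, 0.30000001)), c(TRUE, FALSE))
  expect_error(censor_volumes(rep(0.31, 4)), "4 volumes exceed")
})

test_that("nT2*w maps are invariant to per-volume affine intensity changes", {
  s <- make_series()
  m1 <- compute_nt2w_map(s)
  v2 <- s$intensities
  set.seed(2)
  for (t in seq_len(dim(v2)[4])) {
    v2[, , , t] <- runif(1, 0.2, 3) * v2[, , , t] + runif(1, -50, 50)
  }
  s2 <- volume_series(v2, s$fd, coverage_mask = s$coverage_mask)
  m2 <- compute_nt2w_map(s2)
  expect_lt(max(abs(m1 - m2), na.rm = TRUE), 1e-10)
})

test_that("single-volume and constant-volume edge cases behave as specified", {
  s <- make_series(n_vol = 3, fd = c(0.1, 0.5, 0.5))
  keep <- censor_volumes(s)
  m <- compute_nt2w_map(s, keep)
  v <- s$intensities[, , , 1]
  z <- (v - mean(v)) / sd(v)
  expect_equal(m, z, tolerance = 1e-12, ignore_attr = TRUE)

  flat <- s
  flat$intensities[, , , 1] <- 7
  expect_error(compute_nt2w_map(flat, keep), "volume 1")
})

test_that("median aggregation uses the lower median and honors planted levels", {
  # region sitting exactly 2 SD below the mask mean in every volume is -2
  dims <- c(8, 8, 2)
  n_bg <- prod(dims) - 4
  set.seed(3)
  bg <- rnorm(n_bg)
  vols <- array(0, c(dims, 3))
  for (t in 1:3) {
    # iterate the plant so that mask mean/sd include the ROI voxels
    m <- 0; s <- 1
    for (i in 1:100) {
      full <- c(bg, rep(m - 2 * s, 4))
      m_new <- mean(full); s_new <- sd(full)
      if (abs(m_new - m) < 1e-15 && abs(s_new - s) < 1e-15) break
      m <- m_new; s <- s_new
    }
    vols[, , , t] <- array(c(bg, rep(m - 2 * s, 4)) + 100, dims)
  }
  fd <- rep(0.1, 3)
  sr <- volume_series(vols, fd)
  map <- compute_nt2w_map(sr)
  roi_vals <- array(map, dims)[seq(prod(dims) - 3, prod(dims))]
  expect_equal(unname(roi_vals), rep(-2, 4), tolerance = 1e-10)

  # lower median for even counts
  vals <- c(1, 2, 10, 11)
  expect_equal(quantile(vals, 0.5, type = 1, names = FALSE), 2)
})

test_that("ROI extraction pools hemispheres by voxel-weighted union", {
  map <- array(NA_real_, c(4, 1, 1))
  map[] <- c(-1, -3, 5, 5)
  atlas <- array(c(1L, 1L, 2L, 0L), c(4, 1, 1))
  got <- extract_roi(map, atlas, list(roi_a = 1L, roi_b = 2L))
  expect_equal(got$nT2w[got$region == "roi_a"], -2)
  expect_equal(got$n_voxels, c(2L, 1L))

  # two hemispheric labels pooled as one region
  atlas2 <- array(c(1L, 1L, 2L, 2L), c(4, 1, 1))
  pooled <- extract_roi(map, atlas2, list(roi = c(1L, 2L)))
  expect_equal(pooled$nT2w, mean(c(-1, -3, 5, 5)))
  expect_error(extract_roi(map, atlas, list(gone = 9L)), "no atlas voxels")
})

test_that("batch harmonization removes planted offsets and preserves slopes", {
  set.seed(4)
  n <- 80
  base <- tidyr::expand_grid(
    id = seq_len(n),
    region = c("putamen", "caudate", "globus_pallidus")) |>
    dplyr::mutate(age = rep(runif(n, 10, 33), each = 3),
                  sex = rep(rbinom(n, 1, 0.5), each = 3),
                  nT2w = -0.3 - 0.02 * age + rnorm(3 * n, 0, 0.1))
  # batch B is an exact +0.05 offset copy of batch A
  ab <- dplyr::bind_rows(
    dplyr::mutate(base, batch = "A", session = paste0("a", id)),
    dplyr::mutate(base, batch = "B", session = paste0("b", id),
                  nT2w = nT2w + 0.05))
  harm <- harmonize_batches(ab)
  by_batch <- harm |>
    dplyr::group_by(.data$region, .data$batch) |>
    dplyr::summarise(m = mean(.data$nT2w), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "batch", values_from = "m")
  expect_true(all(abs(by_batch$A - by_batch$B) < 1e-6))
  expect_true("nT2w_raw" %in% names(harm))

  # no batch effect: harmonized values nearly identical to originals
  null_batch <- dplyr::mutate(base, batch = rep(c("A", "B"), length.out = dplyr::n()),
                              session = paste0("s", id))
  harm0 <- harmonize_batches(null_batch)
  expect_gte(cor(harm0$nT2w, harm0$nT2w_raw), 0.99)

  # identical age slope across batches survives harmonization within 5%
  sl <- function(d) coef(lm(nT2w ~ age, data = d))[["age"]]
  expect_lt(abs(sl(harm) - sl(ab)) / abs(sl(ab)), 0.05)

  expect_error(harmonize_batches(dplyr::mutate(base, batch = "A",
                                               session = paste0("s", id))),
               "2 batches")
  tiny <- dplyr::bind_rows(
    dplyr::mutate(base, batch = "A", session = paste0("a", id)),
    dplyr::mutate(base[base$id <= 2, ], batch = "B",
                  session = paste0("b", id)))
  expect_warning(harmonize_batches(tiny), "without shrinkage")
})

test_that("phantom round-trip recovers planted ROI values through the pipeline", {
  cfg <- cohort_config(n_subjects = 3)
  ch <- generate_cohort(cfg, seed = 5, simulate_trials = FALSE)
  ph <- make_volume_phantoms(ch, n_sessions = 2, seed = 6)
  for (s in ph$series) {
    keep <- censor_volumes(s)
    expect_identical(keep, s$fd <= 0.3)
    map <- compute_nt2w_map(s, keep)
    got <- extract_roi(map, ph$atlas, ph$regions, session = s$session)
    want <- ph$truth[ph$truth$session == s$session, ]
    m <- dplyr::inner_join(got, want, by = c("session", "region"))
    expect_equal(m$nT2w.x, m$nT2w.y, tolerance = 1e-6)
  }
})
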