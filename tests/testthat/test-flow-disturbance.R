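test_that("Fourier-truncation trend absorbs low harmonics exactly", {
  w <- uniform_window(1, 257)
  ts <- w$sample_times
  # content only at harmonics 0..3, cutoff 10 -> perturbation ~ 0
  u <- 0.6 + 0.2 * sin(2 * pi * ts) + 0.05 * cos(2 * pi * 3 * ts + 0.4)
  uf <- field_series(array(u, dim = c(257, 1, 1)), "scalar", "node", w, "m s-1")
  dec <- reynolds_decompose(uf, w, trend_spec(10))
  expect_lt(max(abs(dec$perturbation$values)) / max(abs(u)), 1e-10)
})

test_that("an injected high-frequency sinusoid is recovered exactly", {
  w <- uniform_window(0.8, 257)
  ts <- w$sample_times
  inj <- 0.04 * sin(2 * pi * 40 * (ts / 0.8) + 0.3)
  u <- 0.5 + 0.3 * sin(2 * pi * ts / 0.8) + inj
  uf <- field_series(array(u, dim = c(257, 1, 1)), "scalar", "node", w, "m s-1")
  dec <- reynolds_decompose(uf, w, trend_spec(10))
  expect_lt(max(abs(dec$perturbation$values[, 1, 1] - inj)), 1e-8)
  # RMS of the recovered sinusoid
  rms <- perturbation_rms(dec$perturbation)$values
  expect_equal(rms, 0.04 / sqrt(2), tolerance = 0.01)
})

test_that("decomposition additivity is exact and inputs are validated", {
  set.seed(21)
  w <- uniform_window(1, 64)
  u <- matrix(rnorm(64 * 5), 64, 5)
  uf <- field_series(array(u, dim = c(64, 5, 1)), "scalar", "node", w, "m s-1")
  dec <- reynolds_decompose(uf, w, trend_spec(10))
  expect_equal(dec$trend$values + dec$perturbation$values, uf$values,
               tolerance = 1e-13)
  expect_error(reynolds_decompose(uf, w, trend_spec(40)), "at least")
})

test_that("perturbation RMS is homogeneous and cutoff-insensitive below it", {
  w <- uniform_window(1, 257)
  ts <- w$sample_times
  pert <- 0.03 * sin(2 * pi * 30 * ts + 0.1)
  pf <- field_series(array(pert, dim = c(257, 1, 1)), "scalar", "node", w,
                     "m s-1")
  r1 <- perturbation_rms(pf)$values
  pf3 <- pf; pf3$values <- 3 * pf$values
  expect_equal(perturbation_rms(pf3)$values, 3 * r1, tolerance = 1e-12)
  # adding content below the cutoff to the raw signal leaves the RMS intact
  base <- 0.5 + 0.3 * sin(2 * pi * ts)
  for (extra in list(0, 0.2 * cos(2 * pi * 5 * ts + 1))) {
    u <- base + extra + pert
    uf <- field_series(array(u, dim = c(257, 1, 1)), "scalar", "node", w,
                       "m s-1")
    dec <- reynolds_decompose(uf, w, trend_spec(10))
    expect_equal(perturbation_rms(dec$perturbation)$values, r1,
                 tolerance = 1e-9)
  }
})

test_that("seeded perturbation realisations recover eps/sqrt(2) in the median", {
  w <- uniform_window(1, 129)
  base <- field_series(array(0.4, dim = c(129, 6, 1)), "scalar", "node", w,
                       "m s-1")
  eps <- 0.05
  rms_all <- sapply(1:20, function(s) {
    d <- disturbed_velocity_series(base, eps, 32, seed = s)
    dec <- reynolds_decompose(d, w, trend_spec(10))
    stats::median(perturbation_rms(dec$perturbation)$values)
  })
  expect_equal(stats::median(rms_all), eps / sqrt(2), tolerance = 0.02)
})

test_that("cross-section medians select symmetric slabs along the tangent", {
  tv <- make_tube_volume(3e-3, 0.03, n_circ = 10L, n_rad = 2L, n_axial = 20L)
  # constant field -> the constant at every station
  cm_const <- cross_section_median(rep(4.2, nrow(tv$mesh$points)), tv$mesh,
                                   tv$centreline, c(0.01, 0.02), 1e-3)
  expect_equal(cm_const$median, c(4.2, 4.2))
  # field equal to the axial coordinate -> medians near the station positions
  z <- tv$mesh$points[, 3]
  cm <- cross_section_median(z, tv$mesh, tv$centreline, c(0.01, 0.02), 1e-3)
  expect_equal(cm$median, c(0.01, 0.02), tolerance = 0.08)
  expect_true(all(cm$n_members > 0))
  # a slab that misses the mesh entirely is reported missing
  expect_warning(
    cm_out <- cross_section_median(z, tv$mesh,
                                   centreline(rbind(c(0, 0, 0), c(0, 0, 0.2))),
                                   0.15, 1e-3),
    "empty")
  expect_true(is.na(cm_out$median))
})

test_that("centreline pressure profiles interpolate the time-averaged field", {
  tv <- make_tube_volume(3e-3, 0.03, n_circ = 10L, n_rad = 2L, n_axial = 10L)
  w <- uniform_window(1, 5)
  np <- nrow(tv$mesh$points)
  # uniform constant pressure -> zero drop
  pc <- field_series(array(2000, dim = c(5, np, 1)), "scalar", "node", w, "Pa")
  prof_c <- centreline_pressure_profile(pc, tv$mesh, tv$centreline, w)
  expect_equal(prof_c$drop_Pa, 0)
  # linear axial pressure with slope -g -> drop = g * L (exact for P1 fields)
  g <- 1500
  pv <- outer(rep(1, 5), 5000 - g * tv$mesh$points[, 3])
  pl <- field_series(array(pv, dim = c(5, np, 1)), "scalar", "node", w, "Pa")
  prof_l <- centreline_pressure_profile(pl, tv$mesh, tv$centreline, w)
  expect_equal(prof_l$drop_Pa, g * 0.03, tolerance = 1e-10)
  # time-varying spatially uniform pressure -> flat profile at the trapezoid
  # time average
  ts <- w$sample_times
  p_t <- 4000 + 800 * sin(2 * pi * ts)
  pt <- field_series(array(rep(p_t, np), dim = c(5, np, 1)), "scalar", "node",
                     w, "Pa")
  prof_t <- centreline_pressure_profile(pt, tv$mesh, tv$centreline, w)
  expect_equal(unique(round(prof_t$profile$mean_pressure_Pa, 9)),
               round(trapz_ref(ts, p_t), 9))
  # a centreline escaping the mesh warns and falls back to the nearest node
  cl_out <- centreline(rbind(c(0, 0, 0.01), c(0, 0, 0.05)))
  expect_warning(centreline_pressure_profile(pc, tv$mesh, cl_out, w),
                 "outside")
})
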