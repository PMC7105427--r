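test_that("tube surface area converges to 2*pi*r*L from below", {
  r <- 3e-3; L <- 0.03
  analytic <- 2 * pi * r * L
  fine <- make_tube_surface(tube_spec(r, L, 1e-3, n_circ = 48L, n_axial = 20L))
  expect_equal(sum(fine$mesh$element_area), analytic, tolerance = 5e-3)
  # doubling n_circ monotonically reduces the area error
  errs <- sapply(c(8L, 16L, 32L, 64L), function(nc) {
    m <- make_tube_surface(tube_spec(r, L, 1e-3, n_circ = nc,
                                     n_axial = 4L))$mesh
    abs(sum(m$element_area) - analytic)
  })
  expect_true(all(diff(errs) < 0))
  # centreline spans exactly the tube length
  cl <- fine$centreline
  expect_equal(cl$arclength[length(cl$arclength)], L)
})

test_that("waveform reconstruction stays positive and evaluates its mean", {
  wf <- default_waveform()
  ts <- seq(0, wf$period_T, length.out = 513)
  q <- waveform_eval(wf, ts)
  expect_true(all(q > 0))
  expect_equal(mean(q[-1]), wf$mean_flow, tolerance = 1e-10)
  expect_error(waveform_spec(1e-5, 1, harmonics = list(c(1.5, 0))),
               "non-positive")
})

test_that("quasi-steady Poiseuille WSS matches the closed form", {
  spec <- tube_spec(3e-3, 0.03, 0.63e-3, n_circ = 12L, n_axial = 4L)
  fl <- fluid_spec() # mu = 4.5e-3
  steady <- waveform_spec(1e-5, 1) # 600 ml/min
  ps <- poiseuille_wss_series(spec, steady, fl, 16L)
  expected <- 4 * 4.5e-3 * 1e-5 / (pi * (3e-3)^3) # = 2.122 Pa
  mag <- sqrt(rowSums(ps$field$values[1, , ]^2))
  expect_equal(unname(mag), rep(expected, length(mag)), tolerance = 1e-12)
  expect_equal(expected, 2.122, tolerance = 1e-4)
  # steady flow is unidirectional: OSI = 0 everywhere
  expect_equal(max(compute_osi(ps$field)$values), 0)
  # linearity in Q
  ps2 <- poiseuille_wss_series(spec, waveform_spec(2e-5, 1), fl, 16L)
  expect_equal(ps2$field$values, 2 * ps$field$values, tolerance = 1e-12)
})

test_that("prescribed-OSI series reproduce their target through Eq.-3 metrics", {
  w <- uniform_window(1, 64)
  s25 <- prescribed_osi_wss_series(0.25, 2, w)
  expect_equal(attr(s25, "f_nominal"), 0.75)
  expect_equal(compute_osi(s25)$values, 0.25, tolerance = 1e-9)
  # target 0: steady forward signal
  s0 <- prescribed_osi_wss_series(0, 2, w)
  expect_equal(unique(as.numeric(s0$values[, , 1])), 2)
  expect_equal(compute_osi(s0)$values, 0)
  # target 0.5: zero time-integral
  s5 <- prescribed_osi_wss_series(0.5, 2, w)
  expect_equal(trapz_ref(w$sample_times, s5$values[, 1, 1]), 0,
               tolerance = 1e-15)
  expect_equal(compute_osi(s5)$values, 0.5, tolerance = 1e-9)
  expect_error(prescribed_osi_wss_series(0.6, 2, w), "0, 0.5")
  # round trip within 1e-6 across random targets and sample counts
  set.seed(5)
  for (i in 1:25) {
    n <- sample(c(64L, 101L, 128L, 257L), 1)
    tg <- runif(1, 0.01, 0.5)
    wn <- uniform_window(1, n)
    s <- prescribed_osi_wss_series(tg, runif(1, 0.5, 5), wn)
    expect_equal(compute_osi(s)$values, tg, tolerance = 1e-6)
  }
})

test_that("pressurised tube stresses follow the Laplace law", {
  w <- uniform_window(1, 8)
  p50 <- mmhg_to_pa(50) # 6666.1 Pa
  vspec <- tube_spec(3.57e-3, 0.02, 0.357e-3, n_circ = 12L, n_axial = 3L)
  res <- pressurised_tube_stress_series(vspec, rep(p50, 8), w,
                                        youngs_modulus = 0.445e6)
  s_th <- p50 * 3.57e-3 / 0.357e-3
  expect_equal(s_th, 66661, tolerance = 1e-4)
  # principal stresses of the generated tensor are {s_th, s_z, 0}
  S6 <- res$stress$values[1, 1, ]
  S <- matrix(c(S6[1], S6[4], S6[5], S6[4], S6[2], S6[6], S6[5], S6[6], S6[3]),
              3, 3)
  ev <- sort(eigen(S, symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(ev, c(s_th, s_th / 2, 0), tolerance = 1e-10)
  expect_true(all(ev >= -1e-9)) # positive semidefinite for p >= 0
  # von Mises equals the plane-stress closed form at every element/time
  vm <- von_mises(res$stress)
  closed <- sqrt(s_th^2 + (s_th / 2)^2 - s_th * s_th / 2)
  expect_equal(max(abs(vm$values - closed)) / closed, 0, tolerance = 1e-12)
  # zero pressure -> zero stress and zero strain
  res0 <- pressurised_tube_stress_series(vspec, rep(0, 8), w,
                                         youngs_modulus = 0.445e6)
  expect_equal(max(abs(res0$stress$values)), 0)
  eps0 <- engineering_strain(res0$area0, res0$areas, w)
  expect_equal(max(abs(eps0$values)), 0)
  # thick wall warns but computes
  thick <- tube_spec(1e-3, 0.01, 0.5e-3, n_circ = 8L, n_axial = 2L)
  expect_warning(pressurised_tube_stress_series(thick, rep(p50, 8), w),
                 "thin-wall")
})

test_that("disturbed velocity series are seeded and recover epsilon/sqrt(2)", {
  w <- uniform_window(1, 257)
  base_mag <- matrix(0.5, 257, 8)
  base <- field_series(array(base_mag, dim = c(257, 8, 1)), "scalar", "node",
                       w, "m s-1")
  d1 <- disturbed_velocity_series(base, 0.05, 40, seed = 3L)
  d2 <- disturbed_velocity_series(base, 0.05, 40, seed = 3L)
  expect_identical(d1$values, d2$values)
  d3 <- disturbed_velocity_series(base, 0.05, 40, seed = 4L)
  expect_false(identical(d1$values, d3$values))
  # an integer number of perturbation periods recovers RMS = eps/sqrt(2)
  dec <- reynolds_decompose(d1, w, trend_spec(10))
  rms <- perturbation_rms(dec$perturbation)$values
  expect_equal(rms, rep(0.05 / sqrt(2), 8), tolerance = 0.01)
  # zero amplitude -> zero RMS
  d0 <- disturbed_velocity_series(base, 0, 40, seed = 3L)
  dec0 <- reynolds_decompose(d0, w, trend_spec(10))
  expect_equal(max(perturbation_rms(dec0$perturbation)$values), 0,
               tolerance = 1e-12)
  # frequency at/below the trend cutoff is rejected
  expect_error(disturbed_velocity_series(base, 0.05, 8, seed = 1L),
               "cutoff")
})

test_that("anastomosis surface partitions cleanly and matches the sphere ROI", {
  g <- tube_spec(3e-3, 0.03, 0.63e-3, n_circ = 12L, n_axial = 8L)
  v <- tube_spec(3.57e-3, 0.075, 0.357e-3, n_circ = 12L, n_axial = 16L)
  an <- make_anastomosis_surface(g, v, angle = pi / 4)
  # labels partition the surface
  areas <- vapply(an$regions, function(r) r$total_area, numeric(1))
  expect_equal(sum(areas), sum(an$mesh$element_area), tolerance = 1e-12)
  ids <- sort(unlist(lapply(an$regions, function(r) r$element_ids)))
  expect_equal(ids, seq_len(n_elements_for_test(an$mesh)) - 1L,
               ignore_attr = TRUE)
  # the anastomosis mask equals an independently built sphere ROI
  sr <- sphere_region(an$mesh, sphere_roi(an$junction, 0.012))
  expect_setequal(sr$element_ids, an$regions$anastomosis$element_ids)
  expect_error(make_anastomosis_surface(g, v, angle = 0), "angle")
})
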