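test_that("TAWSS matches closed forms and converges at second order", {
  w <- uniform_window(1, 1000)
  ts <- w$sample_times
  # constant (3,0,0) Pa -> 3 Pa
  f_const <- axial_series(matrix(3, 1000, 1), w)
  expect_equal(compute_tawss(f_const)$values, 3)
  # |sin| has cycle mean 2/pi
  f_sin <- axial_series(matrix(sin(2 * pi * ts), ncol = 1), w)
  expect_equal(compute_tawss(f_sin)$values, 2 / pi, tolerance = 1e-4)
  # zero field
  expect_equal(compute_tawss(axial_series(matrix(0, 1000, 1), w))$values, 0)
  # second-order convergence of the trapezoid on a smooth non-periodic
  # magnitude (exp has a known integral and no endpoint cancellation)
  errs <- sapply(c(32, 64, 128, 256), function(n) {
    wn <- uniform_window(1, n + 1)
    sig <- matrix(exp(wn$sample_times), ncol = 1)
    abs(compute_tawss(axial_series(sig, wn))$values - (exp(1) - 1))
  })
  rate <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(rate > 1.9 & rate < 2.1))
})

test_that("WSS_max is the sampled maximum and dominates TAWSS", {
  w <- uniform_window(1, 5) # includes t = 0.25 where sin peaks
  sig <- matrix(sin(2 * pi * w$sample_times), ncol = 1)
  expect_equal(compute_wss_max(axial_series(sig, w))$values, 1)
  expect_equal(compute_wss_max(axial_series(matrix(4.2, 5, 1), w))$values, 4.2)
  set.seed(11)
  for (i in 1:20) {
    f <- random_wss_series(5)
    expect_true(all(compute_wss_max(f)$values >= compute_tawss(f)$values))
  }
})

test_that("OSI spans its definitional range and handles degeneracy", {
  w <- uniform_window(1, 1000)
  ts <- w$sample_times
  # steady unidirectional -> 0
  expect_equal(compute_osi(axial_series(matrix(2, 1000, 1), w))$values, 0,
               tolerance = 1e-9)
  # antisymmetric sinusoid -> 0.5
  f_sin <- axial_series(matrix(sin(2 * pi * ts), ncol = 1), w)
  expect_equal(compute_osi(f_sin)$values, 0.5, tolerance = 1e-6)
  # forward 3/4 cycle, reverse 1/4, equal magnitude: brute-force quadrature
  sig <- ifelse(ts < 0.75, 1, -1)
  num <- abs(trapz_ref(ts, sig))
  den <- trapz_ref(ts, abs(sig))
  expect_equal(compute_osi(axial_series(matrix(sig, ncol = 1), w))$values,
               0.5 * (1 - num / den))
  expect_equal(0.5 * (1 - num / den), 0.25, tolerance = 2e-3)
  # identically zero signal is flagged, not fatal
  expect_warning(z <- compute_osi(axial_series(matrix(0, 1000, 1), w)),
                 "zero WSS")
  expect_equal(z$values, 0)
  expect_true(z$flags[1])
})

test_that("OSI stays in [0, 0.5] for arbitrary random series", {
  set.seed(42)
  for (i in 1:30) {
    f <- random_wss_series(20, n_t = 16L)
    osi <- compute_osi(f)$values
    expect_true(all(osi >= 0 & osi <= 0.5))
  }
})

test_that("TAWSS, WSS_max and OSI are invariant under rigid rotation", {
  set.seed(7)
  f <- random_wss_series(10)
  R <- random_rotation()
  fr <- f
  for (s in seq_len(dim(f$values)[1]))
    fr$values[s, , ] <- f$values[s, , ] %*% t(R)
  expect_equal(compute_tawss(fr)$values, compute_tawss(f)$values,
               tolerance = 1e-12)
  expect_equal(compute_wss_max(fr)$values, compute_wss_max(f)$values,
               tolerance = 1e-12)
  expect_equal(compute_osi(fr)$values, compute_osi(f)$values,
               tolerance = 1e-10)
})

test_that("area fractions are area-weighted with strict bounds", {
  m10 <- strip_mesh(rep(2, 10))
  w <- uniform_window(1, 3)
  reg <- whole_surface_region(m10)
  map <- metric_map(c(rep(10, 3), rep(1, 7)), "WSS_max", "Pa")
  th <- threshold_spec("WSS_max", 7, "above")
  expect_equal(area_fraction(map, th, reg, m10), 30)
  # areas 1 and 3: only the larger exceeds -> 75%
  m2 <- strip_mesh(c(2, 6))
  map2 <- metric_map(c(1, 10), "WSS_max", "Pa")
  expect_equal(area_fraction(map2, th, whole_surface_region(m2), m2), 75)
  # all below -> 0; value equal to the bound does not count (strict)
  map3 <- metric_map(c(7, 5), "WSS_max", "Pa")
  expect_equal(area_fraction(map3, th, whole_surface_region(m2), m2), 0)
  expect_error(area_fraction(map, th, region_mask(integer(0), m10), m10),
               "empty")
})

test_that("area fractions match a brute-force oracle; thresholds nest", {
  set.seed(3)
  th7 <- threshold_spec("WSS_max", 7, "above")
  th40 <- threshold_spec("WSS_max", 40, "above")
  for (i in 1:25) {
    n <- sample(5:40, 1)
    m <- strip_mesh(runif(n, 0.5, 4))
    reg <- whole_surface_region(m)
    vals <- runif(n, 0, 60)
    map <- metric_map(vals, "WSS_max", "Pa")
    expect_equal(area_fraction(map, th7, reg, m),
                 brute_area_fraction(vals, m$element_area, 7, "above"))
    expect_true(area_fraction(map, th40, reg, m) <=
                  area_fraction(map, th7, reg, m))
  }
})

test_that("robust maximum follows the cumulative-area omission rule", {
  m <- strip_mesh(rep(2, 100))
  reg <- whole_surface_region(m)
  map <- metric_map(1:100, "WSS_max", "Pa")
  # equal areas, omit 1% -> the single top element is dropped
  expect_equal(robust_max(map, reg, m, 0.01), 99)
  expect_equal(robust_max(map, reg, m, 0), 100)
  # top element holding ~2% of area, omit 1% -> it is removed
  m2 <- strip_mesh(c(rep(1, 98), 4)) # last element ~3.9% of area
  map2 <- metric_map(1:99, "x", "")
  expect_equal(robust_max(map2, whole_surface_region(m2), m2, 0.01), 98)
  expect_error(robust_max(map, reg, m, 1), "< 1")
})

test_that("robust maximum matches brute force on random unequal areas", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    h <- runif(n, 0.2, 5)
    m <- strip_mesh(h)
    vals <- runif(n, 0, 100)
    omit <- runif(1, 0.005, 0.2)
    got <- robust_max(metric_map(vals, "x", ""), whole_surface_region(m), m,
                      omit)
    expect_equal(got, brute_robust_max(vals, m$element_area, omit))
    # robust max never exceeds the plain max and is monotone in omission
    expect_true(got <= max(vals))
    expect_true(robust_max(metric_map(vals, "x", ""),
                           whole_surface_region(m), m, min(0.5, omit * 2))
                <= got + 1e-12)
  }
})

test_that("region median is area-weighted by cumulative area", {
  m3 <- strip_mesh(rep(2, 3))
  expect_equal(region_median(metric_map(c(1, 2, 3), "x", ""),
                             whole_surface_region(m3), m3), 2)
  # values {1, 10} with areas {3, 1}: half the area is reached inside 1
  m2 <- strip_mesh(c(6, 2))
  expect_equal(region_median(metric_map(c(1, 10), "x", ""),
                             whole_surface_region(m2), m2), 1)
  expect_equal(region_median(metric_map(c(5, 5), "x", ""),
                             whole_surface_region(m2), m2), 5)
  # count-based alternative
  expect_equal(region_median(metric_map(c(1, 10), "x", ""),
                             whole_surface_region(m2), m2, weighted = FALSE),
               5.5)
})
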