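nd <- nondimensionalize(default_parameters())

test_that("grid construction places both boundaries and validates input", {
  g <- build_grid(1 / 12, 12)
  expect_equal(g$n_nodes, 12L)
  expect_equal(g$r[1], 1 / 12)
  expect_equal(g$r[12], 1)
  expect_true(all(diff(g$r) > 0))
  expect_error(build_grid(1 / 12, 2), "n_nodes")
  expect_error(build_grid(1.2, 12), "between 0 and 1")
  g2 <- build_grid(1 / 12, 24)
  expect_equal(c(g2$r[1], g2$r[24]), c(g$r[1], g$r[12]))
})

test_that("radial Laplacian is exact on constants and second-order accurate", {
  g <- build_grid(1 / 12, 101)
  expect_equal(radial_laplacian(rep(3.7, 101), g), rep(0, 101))
  ## ln(r) is harmonic in radial coordinates; r^2 has Laplacian 4.
  ## The truncation constant of the ln(r) test scales like 1/r^4, so the
  ## error is measured away from the inner radius.
  away <- which(g$r > 0.3 & g$r < 1)
  err_log <- max(abs(radial_laplacian(log(g$r), g)[away]))
  expect_lt(err_log, 5e-3)
  err_r2 <- max(abs(radial_laplacian(g$r^2, g)[2:100] - 4))
  expect_lt(err_r2, 1e-9)
  ## halving the spacing cuts the ln(r) error by about 4 (order 2)
  g2 <- build_grid(1 / 12, 201)
  away2 <- which(g2$r > 0.3 & g2$r < 1)
  err_log2 <- max(abs(radial_laplacian(log(g2$r), g2)[away2]))
  expect_equal(err_log / err_log2, 4, tolerance = 0.15)
  expect_error(radial_laplacian(rep(1, 5), g), "length")
})

test_that("wall flux and pump rate laws evaluate as written", {
  expect_equal(capillary_flux(2, 2, K = 5), 0)
  expect_equal(capillary_flux(4, 0, K = 5), 20)
  expect_equal(capillary_flux(3, 3, K = 5, K1 = 0.7), 0.7)
  expect_error(capillary_flux(-1, 0, K = 5), "non-negative")

  expect_equal(intracellular_rate(0, 0, nd), 0)
  ## equal pump capacities balance when saturations match
  E <- 0.4
  I_bal <- nd$k2 * E / nd$k1
  expect_equal(intracellular_rate(E, I_bal, nd), 0, tolerance = 1e-14)
  ## half-saturation on the uptake side, dimensional check
  dim_p <- list(v1 = 0.28, v2 = 0.28, k1 = 0.219, k2 = 1.37)
  expect_equal(intracellular_rate(0.219, 0, dim_p), 0.14)
})

test_that("extracellular rates vanish at constructed equilibria", {
  g <- build_grid(nd$rc, 31)
  z <- rep(0, 31)
  r0 <- extracellular_rates(z, z, z, rep(1, 31), S = 0, g, nd)
  expect_equal(r0$dE, z)
  expect_equal(r0$dB, z)
  ## uniform state with binding, pumping and wall exchange all balanced
  E <- rep(0.5, 31)
  B <- nd$k3 / nd$k4 * E
  I <- nd$k2 * E[1] / nd$k1 * rep(1, 31)
  rs <- extracellular_rates(E, B, I, rep(1, 31), S = 0.5, g, nd)
  expect_equal(rs$dE, z, tolerance = 1e-10)
  expect_equal(rs$dB, z, tolerance = 1e-10)
  expect_error(extracellular_rates(E, B, I, rep(-1, 31), 0.5, g, nd),
               "non-negative")
})

test_that("discrete transport conserves mass up to the wall flux", {
  ## no cells, no binding: total drug changes only through the capillary wall
  nd0 <- nd
  nd0$k3 <- nd0$k4 <- 0
  g <- build_grid(nd$rc, 41)
  set.seed(7)
  E <- stats::runif(41, 0, 2)
  z <- rep(0, 41)
  rates <- extracellular_rates(E, z, z, z, S = 3, g, nd0)
  ## finite-volume weights: interior cells r*dr, half cells at both ends
  w <- c(g$r[1] * g$dr / 2 + g$dr^2 / 8,
         g$r[2:40] * g$dr,
         g$r[41] * g$dr / 2 - g$dr^2 / 8)
  total_rate <- sum(w * rates$dE)
  wall_influx <- g$r[1] * capillary_flux(3, E[1], nd0$Kw, nd0$K1)
  expect_equal(total_rate, wall_influx, tolerance = 1e-12)
})

test_that("dose protocols are piecewise constant with left-closed segments", {
  pc <- protocol_constant(4)
  expect_equal(dose_concentration(pc, c(0, 10, 1e5)), c(4, 4, 4))
  pp <- protocol_pulse(4, 1.75)
  expect_equal(dose_concentration(pp, c(0, 1, 1.75, 2)), c(4, 4, 0, 0))
  db <- protocol_pulses(4, 1.5, gap_h = 24, n_pulses = 2)
  expect_equal(db$start_h, c(0, 24))
  expect_equal(dose_concentration(db, c(1, 12, 24.5, 26)), c(4, 0, 4, 0))
  expect_error(dose_protocol(c(0, 1), c(2, 3), c(1, 1)), "overlap")
  expect_error(dose_protocol(0, 0, 1), "start_h < end_h")
  expect_error(protocol_pulses(4, 2, gap_h = 1), "overlap")
})
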