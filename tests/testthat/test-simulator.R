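test_that("unperturbed cord stays exactly at its initial equilibrium", {
  res <- cached_run(protocol_constant(0, 100), "monostable",
                    t_end_h = 100, n_nodes = 31, n_out = 41)
  expect_true(all(res$fields$E == 0))
  expect_true(all(res$fields$B == 0))
  expect_true(all(res$fields$I == 0))
  expect_true(all(abs(res$fields$c_norm - 1) < 1e-9))
  expect_equal(sum(!is.na(res$time_fired_h)), 0)
})

test_that("result object is shape-consistent and starts from the basal state", {
  res <- cached_run(ref_bolus(), "bistable", t_end_h = 12, n_nodes = 31)
  nt <- length(res$times_h)
  expect_true(all(diff(res$times_h) > 0))
  for (f in names(res$fields))
    expect_equal(dim(res$fields[[f]]), c(nt, 31))
  expect_equal(dim(res$fired), c(nt, 31))
  b <- basal_switch_state("bistable", res$nd$signalling)
  expect_equal(res$fields$R[1, ], rep(b$R, 31))
  expect_equal(res$fields$R1[1, ], rep(b$R1, 31))
  df <- as.data.frame(res)
  expect_equal(nrow(df), nt * 31)
  expect_named(df, c("time_h", "node", "r", "E", "B", "I", "R", "R1",
                     "c", "c_norm", "fired"))
})

test_that("fields remain non-negative and bounded through a bolus", {
  for (m in c("bistable", "monostable")) {
    res <- cached_run(ref_bolus(), m, t_end_h = 12, n_nodes = 31)
    for (f in c("E", "B", "I", "c"))
      expect_gt(min(res$fields[[f]]), -1e-9)
    expect_true(all(res$fields$R >= -1e-9 & res$fields$R <= 1 + 1e-9))
    expect_true(all(res$fields$R1 >= -1e-9 & res$fields$R1 <= 1 + 1e-9))
  }
})

test_that("identical configurations reproduce bitwise-identical trajectories", {
  a <- simulate_cord(ref_bolus(), "bistable", t_end_h = 6, n_nodes = 31)
  b <- simulate_cord(ref_bolus(), "bistable", t_end_h = 6, n_nodes = 31)
  expect_identical(a$fields, b$fields)
  expect_identical(a$times_h, b$times_h)
  expect_identical(a$time_fired_h, b$time_fired_h)
})

test_that("monostable latch fires once, at the dense-solve crossing time", {
  res <- cached_run(protocol_pulse(3.2, 2), "monostable", t_end_h = 12)
  fired_any <- !is.na(res$time_fired_h)
  expect_gt(sum(fired_any), 0)
  ## latch is monotone per node
  for (j in which(fired_any))
    expect_true(all(diff(as.integer(res$fired[, j])) >= 0))
  ## event times agree with a 10x denser output reference
  dense <- cached_run(protocol_pulse(3.2, 2), "monostable", t_end_h = 12,
                      n_out = 2001)
  expect_equal(res$time_fired_h, dense$time_fired_h, tolerance = 1e-4)
  ## and the latch outlives the drug: nodes stay fired at the end
  expect_true(all(res$fired[nrow(res$fired), fired_any]))
})

test_that("solver rejects nonsense tolerances and unknown scenarios fail loudly", {
  expect_error(simulate_cord(ref_bolus(), "bistable", rtol = -1),
               "tolerance")
  expect_error(simulate_cord(ref_bolus(), "bistable", rtol = 0.5),
               "tolerance")
  expect_error(scenario("fig99"), "unknown scenario")
})

test_that("cell density varies slowly relative to drug transport", {
  ## freezing the population dynamics for the first 30 min changes the
  ## extracellular field negligibly
  res <- simulate_cord(ref_bolus(), "bistable", t_end_h = 0.5, n_nodes = 31)
  ## scale net growth and saturation down 1000x: same carrying capacity,
  ## population dynamics effectively frozen on the transport time scale
  frozen <- default_parameters()
  frozen$a1 <- 0.24 + 0.26e-3
  frozen$a2 <- 0.24
  frozen$b <- 0.02592e-3
  frozen$a1_triggered <- 0
  res_f <- simulate_cord(ref_bolus(), "bistable", params = frozen,
                         t_end_h = 0.5, n_nodes = 31)
  it <- nrow(res$fields$E)
  if_ <- nrow(res_f$fields$E)
  expect_equal(res$times_h[it], res_f$times_h[if_])
  E1 <- res$fields$E[it, ]
  E2 <- res_f$fields$E[if_, ]
  expect_lt(max(abs(E1 - E2)) / max(E1), 0.01)
})

test_that("steady-state diagnostics detect unfinished runs", {
  short <- cached_run(ref_bolus(), "bistable", t_end_h = 12, n_nodes = 31)
  expect_error(steady_state_diagnostics(short), "not at steady state")
})
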