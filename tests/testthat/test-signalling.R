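sg <- default_parameters()$signalling

test_that("switch rate laws evaluate to their closed-form values", {
  expect_equal(monostable_rate(0, 0, sg$monostable), 0)
  expect_equal(monostable_rate(0.5, sg$monostable$k_h, sg$monostable), 0)
  expect_equal(monostable_rate(0, sg$monostable$k_h, sg$monostable),
               0.432 * 0.5)
  expect_error(monostable_rate(0, -1, sg$monostable), "negative")

  expect_equal(effector_rate(0, 0, sg$effector), 0)
  R <- 0.6
  expect_equal(effector_rate(R / (R + sg$effector$k_r / sg$effector$k_f), R,
                             sg$effector), 0)
  expect_equal(effector_rate(0, 1, sg$effector), 3.6)
  expect_error(effector_rate(1.2, 0, sg$effector), "outside")

  b <- sg$bistable
  expect_equal(bistable_rate(1, 5, b), -b$V_r / (b$K_m2 + 1))
  expect_equal(bistable_rate(0, 0, b), 27 / 101)
  expect_error(bistable_rate(0.5, -0.1, b), "negative")
})

test_that("monostable steady states follow the Hill and effector formulas", {
  ss0 <- monostable_steady_state(0, sg)
  expect_equal(ss0$R, 0)
  expect_equal(ss0$R1, 0)
  ssh <- monostable_steady_state(sg$monostable$k_h, sg)
  expect_equal(ssh$R, 0.5)
  expect_equal(ssh$R1, 0.5 / 0.54)     # k_r/k_f = 0.04
  ssb <- monostable_steady_state(1e9, sg)
  expect_equal(ssb$R, 1, tolerance = 1e-8)
  expect_equal(ssb$R1, 1 / 1.04, tolerance = 1e-8)
})

test_that("closed-form monostable transient matches decay law and stiff ODE", {
  m <- sg$monostable
  ## zero input: pure exponential decay
  tt <- c(0.5, 2, 10)
  expect_equal(monostable_transient(function(t) 0, tt, m, R0 = 0.3),
               0.3 * exp(-m$k * tt), tolerance = 1e-9)
  ## constant input converges to the steady state
  expect_equal(monostable_transient(function(t) 2, 60, m, R0 = 0),
               monostable_steady_state(2, sg)$R, tolerance = 1e-6)
  ## rectangular pulse against numerical integration of the same ODE
  I_pulse <- function(t) ifelse(t >= 1 & t < 4, 1.5, 0)
  rhs <- function(t, y, parms) list(monostable_rate(min(max(y, 0), 1),
                                                    I_pulse(t), m))
  ts <- c(0, 0.5, 1, 2, 3, 4, 5, 8, 12)
  ode <- deSolve::ode(c(R = 0.1), ts, rhs, NULL, method = "lsoda",
                      rtol = 1e-11, atol = 1e-13)
  quad <- monostable_transient(I_pulse, ts, m, R0 = 0.1)
  expect_equal(quad, unname(ode[, "R"]), tolerance = 1e-6)
})

## brute-force root oracle: dense sign-change scan of the rate function
scan_roots <- function(I, p, step = 1e-5) {
  g <- seq(0, 1, by = step)
  v <- bistable_rate(g, I, p)
  idx <- which(v[-1] * v[-length(v)] < 0)
  (g[idx] + g[idx + 1]) / 2
}

test_that("bistable steady states agree with a dense sign-scan oracle", {
  b <- sg$bistable
  for (I in c(0, 0.5, 0.9, 1.005, 1.2, 2)) {
    ss <- bistable_steady_states(I, b)
    oracle <- scan_roots(I, b)
    expect_equal(nrow(ss), length(oracle), label = paste("branch count at I =", I))
    expect_lt(max(abs(ss$R_star - oracle)), 1e-5)
    expect_true(all(ss$R_star >= 0 & ss$R_star <= 1))
  }
  ## basal input: bistable with the classic stable/unstable/stable pattern
  ss0 <- bistable_steady_states(0, b)
  expect_equal(ss0$stability, c("stable", "unstable", "stable"))
  ## far above threshold: single high stable state
  ss2 <- bistable_steady_states(2, b)
  expect_equal(ss2$stability, "stable")
  expect_gt(ss2$R_star, 0.8)
})

test_that("fold location matches a brute-force input scan and input decoupling removes it", {
  b <- sg$bistable
  folds <- bistable_fold_inputs(b)
  expect_true(folds$bistable)
  expect_true(is.na(folds$lower))      # bistable all the way down to I = 0
  ## oracle: branch-count change on a fine input grid
  Is <- seq(0.95, 1.05, by = 1e-4)
  counts <- vapply(Is, function(I) length(scan_roots(I, b, step = 1e-4)),
                   integer(1))
  i_change <- which(diff(counts) != 0)
  expect_equal(folds$upper, Is[i_change[1]], tolerance = 2e-4)
  ## q = 0: input no longer moves the branch structure
  b0 <- b
  b0$q <- 0
  f0 <- bistable_fold_inputs(b0)
  expect_false(f0$bistable)
  expect_equal(attr(f0, "message"), "monostable for all I")
})

test_that("bifurcation diagram tabulates branches with fold metadata", {
  tab <- bifurcation_diagram(sg$bistable, I_values = seq(0, 1.5, by = 0.1))
  expect_true(all(c("I", "R_star", "stability") %in% names(tab)))
  expect_true(all(tab$R_star >= 0 & tab$R_star <= 1))
  counts <- table(tab$I)
  expect_true(all(counts %in% c(1, 3)))
  expect_equal(attr(tab, "folds")$upper, 1, tolerance = 0.02)
})

test_that("trigger semantics: monostable latches, bistable tracks instantaneously", {
  e <- sg$effector
  st <- trigger_status("monostable_latch")
  st <- apoptosis_trigger(0.5, st, e, time = 1)
  expect_false(st$fired)
  st <- apoptosis_trigger(0.95, st, e, time = 2)
  expect_true(st$fired)
  expect_equal(st$time_fired, 2)
  st <- apoptosis_trigger(0.1, st, e, time = 3)
  expect_true(st$fired)                # latched
  expect_equal(st$time_fired, 2)

  rv <- trigger_status("bistable_reversible")
  rv <- apoptosis_trigger(0.95, rv, e, time = 1)
  expect_true(rv$fired)
  rv <- apoptosis_trigger(0.1, rv, e, time = 2)
  expect_false(rv$fired)               # reversible
})

test_that("both switches keep (R, R1) inside the unit square", {
  for (module in c("monostable", "bistable")) {
    for (I_const in c(0, 0.5, 2)) {
      for (start in list(c(1e-6, 1e-6), c(0.999, 0.999), c(1e-6, 0.999))) {
        out <- cordsim:::integrate_module(
          module, sg, function(t) I_const, seq(0, 40, by = 0.5),
          R0 = start[1], R1_0 = start[2])
        expect_true(all(out[, "R"] >= -1e-9 & out[, "R"] <= 1 + 1e-9))
        expect_true(all(out[, "R1"] >= -1e-9 & out[, "R1"] <= 1 + 1e-9))
      }
    }
  }
})

test_that("bistable switch shows hysteresis under an input excursion", {
  ## step the input 0 -> 2 -> 0; the module must stay on the upper branch
  I_fun <- function(t) ifelse(t >= 5 & t < 25, 2, 0)
  R0 <- basal_switch_state("bistable", sg)$R
  out <- cordsim:::integrate_module("bistable", sg, I_fun,
                                    seq(0, 120, by = 1))
  R_end <- unname(out[nrow(out), "R"])
  expect_gt(R_end - R0, 0.5)
  ss0 <- bistable_steady_states(0, sg$bistable)
  upper <- max(ss0$R_star[ss0$stability == "stable"])
  expect_equal(R_end, upper, tolerance = 1e-4)
})

test_that("module calibration report: matched thresholds, mismatch flagged", {
  cal <- calibrate_module_match(sg)
  expect_equal(cal$threshold$monostable, 0.5625^0.1, tolerance = 1e-10)
  expect_equal(cal$threshold$bistable, 1, tolerance = 0.02)
  expect_equal(cal$threshold$ratio, 1, tolerance = 0.1)
  expect_true(cal$threshold_matched)
  ## doubling the Hill constant doubles the monostable threshold
  sg2 <- sg
  sg2$monostable$k_h <- 2 * sg$monostable$k_h
  cal2 <- calibrate_module_match(sg2)
  expect_equal(cal2$threshold$ratio / cal$threshold$ratio, 2,
               tolerance = 1e-6)
  expect_false(cal2$threshold_matched)
})
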