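test_that("default parameter set carries the reference doxorubicin values", {
  p <- default_parameters()
  expect_equal(p$k_d, 0.568)
  expect_equal(p$k_db, 0.032)
  expect_equal(p$V1, 0.28)
  expect_equal(p$V2, 0.28)
  expect_equal(p$k1, 0.219)
  expect_equal(p$k2, 1.37)
  expect_equal(p$k3, 3000)
  expect_equal(p$k4, 1000)
  expect_equal(p$a1, 0.5)
  expect_equal(p$a2, 0.24)
  expect_equal(p$b, 0.02592)
  expect_equal(p$R_C / p$R_T, 1 / 12)
  b <- p$signalling$bistable
  expect_equal(unlist(b[c("V_f", "V_r", "K_m1", "K_m2", "k_fb", "p", "q")]),
               c(V_f = 27, V_r = 0.459, K_m1 = 100, K_m2 = 0.01,
                 k_fb = 2.927, p = 0.7, q = 0.3))
  m <- p$signalling$monostable
  expect_equal(unlist(m), c(k = 0.432, k_h = 1, n = 10))
  e <- p$signalling$effector
  expect_equal(unlist(e), c(k_f = 3.6, k_r = 0.144, R1_th = 0.9))
  expect_silent(validate_parameters(p))
})

test_that("validation names each violated invariant", {
  p <- default_parameters()
  p$a1 <- 0.1
  expect_error(validate_parameters(p), "growth does not dominate decay")
  p <- default_parameters()
  p$signalling$effector$R1_th <- 1.5
  expect_error(validate_parameters(p), "threshold outside \\(0,1\\)")
  p <- default_parameters()
  p$R_C <- 150
  expect_error(validate_parameters(p), "R_C < R_T")
  p <- default_parameters()
  p$k_d <- -1
  expect_error(validate_parameters(p), "'k_d' must be a single positive")
  p <- default_parameters()
  p$a1_triggered <- 0.3   # above a2: triggered cells would not die out
  expect_error(validate_parameters(p), "a1_triggered < a2")
})

test_that("nondimensionalization uses the diffusion time scale and unit bridges", {
  p <- default_parameters()
  nd <- nondimensionalize(p)
  expect_equal(nd$t_scale, (p$R_T / 1000)^2 / p$k_d)
  expect_equal(nd$rc, 1 / 12)
  expect_equal(nd$D_E, 1)              # by construction of t_scale
  expect_equal(nd$D_B, 0.032 / 0.568)
  ## per-minute to per-hour conversion for the membrane pumps
  expect_equal(nd$v1, 0.28 * 60 * nd$t_scale)
  ## k1 in ug/ml equals its value in E_ref units (1 ug/ml = E_ref)
  expect_equal(nd$k1, 0.219)
  expect_equal(nd$chi, 10)             # c_ref in 1e5 cells/mm^3
  ## untreated logistic steady state close to the density reference
  expect_equal(nd$c_star, (0.5 - 0.24) / (0.02592 * 10))
  expect_equal(nd$c_star, 1, tolerance = 0.005)
})

test_that("nondimensionalization round-trips on perturbed parameter sets", {
  set.seed(42)
  leaves <- function(x) unlist(x, use.names = TRUE)
  for (i in 1:5) {
    p <- default_parameters()
    scl <- function(x) x * exp(stats::runif(1, -0.3, 0.3))
    for (nm in c("k_d", "k_db", "V1", "V2", "k1", "k2", "k3", "k4",
                 "b", "R_T", "K"))
      p[[nm]] <- scl(p[[nm]])
    p$R_C <- min(scl(p$R_C), 0.5 * p$R_T)
    back <- redimensionalize(nondimensionalize(p))
    expect_equal(leaves(unclass(back)), leaves(unclass(p)),
                 tolerance = 1e-12)
  }
})

test_that("parameter files merge over defaults and reject unknown fields", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("K: 2.5", "signalling:", "  bistable:", "    q: 0.4"), yml)
  p <- read_parameters(yml)
  expect_equal(p$K, 2.5)
  expect_equal(p$signalling$bistable$q, 0.4)
  expect_equal(p$k_d, 0.568)           # untouched default
  jsn <- tempfile(fileext = ".json")
  writeLines('{"a1": 0.6}', jsn)
  expect_equal(read_parameters(jsn)$a1, 0.6)
  bad <- tempfile(fileext = ".yaml")
  writeLines("nonsense_field: 1", bad)
  expect_error(read_parameters(bad), "unknown parameter field")
})
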