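## Shared run cache: several tests interrogate the same simulations, so each
## distinct configuration is integrated once per test session.
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(...) {
  key <- paste(deparse(list(...)), collapse = "")
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- simulate_cord(...)
  .run_cache[[key]]
}

## reference bolus of the study: capillary concentration 4 for 1.75 h
ref_bolus <- function() protocol_pulse(4, 1.75)

expect_nondecreasing <- function(x, tol = 1e-9) {
  expect_true(all(diff(x) >= -tol),
              label = paste0("non-decreasing sequence (", paste(signif(x, 4),
                             collapse = ", "), ")"))
}
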