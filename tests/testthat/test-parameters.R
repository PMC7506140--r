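test_that("default parameters validate and parameter files round-trip", {
  p <- coupled_pars
  expect_silent(validate_parameters(p))
  f <- tempfile(fileext = ".tsv")
  write_parameters(p, f)
  q <- read_parameters(f)
  expect_equal(q[names(p)], p[names(p)], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("invalid parameters are rejected", {
  p <- coupled_pars
  p$ku <- -1
  expect_error(validate_parameters(p), "ku")
  p <- coupled_pars
  p$l_i[1] <- 0.9
  expect_error(validate_parameters(p), "l_i")
  p <- coupled_pars
  p$gamma_m <- rev(p$gamma_m)
  expect_error(validate_parameters(p), "gamma_m")
})

test_that("setting the coupling fold-changes to 1 recovers core dynamics", {
  pC <- coupled_pars
  p0 <- core_reduction(pC)
  # (mu, mz, Z) derivatives agree at arbitrary states for any SNAIL input
  for (seed in 1:10) {
    st <- random_state(pC, seed)
    S <- runif(1, 0, 5e5)
    dC <- mech_rhs(st, p0, S)
    d0 <- mech_rhs(st, core_pars, S)
    expect_equal(dC[c("mu", "mz", "Z")], d0[c("mu", "mz", "Z")],
                 tolerance = 1e-12)
  }
})
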