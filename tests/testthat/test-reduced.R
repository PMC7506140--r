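test_that("lifted fixed points of the reduced drift satisfy the full model", {
  for (S in c(330e3, 380e3)) {
    fp <- reduced_fixed_points(coupled_pars, S)
    red <- qss_reduce(coupled_pars, S)
    for (i in seq_len(nrow(fp))) {
      d <- red$drift(fp$Z[i], fp$mu[i])
      # drift vanishes at the lifted point (relative to state scale)
      expect_lt(abs(d[["dZ"]]) / max(fp$Z[i], 1), 1e-6)
      expect_lt(abs(d[["dmu"]]) / max(fp$mu[i], 1), 1e-6)
      # closures lift back to a full-model fixed point
      st <- c(mu = fp$mu[i], mz = red$mz_star(fp$Z[i], fp$mu[i]),
              Z = fp$Z[i], E = red$E_star(fp$Z[i]), N = red$N_star)
      expect_lt(max(abs(mech_rhs(st, coupled_pars, S)) / pmax(st, 1)), 1e-6)
    }
  }
})

test_that("with coupling fold-changes at 1 the reduced drift is the core drift", {
  pr <- core_reduction(coupled_pars)
  rC <- qss_reduce(pr, 250e3)
  r0 <- qss_reduce(core_pars, 250e3)
  for (seed in 1:6) {
    set.seed(seed)
    Z <- exp(runif(1, log(100), log(2e6)))
    mu <- exp(runif(1, log(100), log(1e5)))
    expect_equal(rC$drift(Z, mu), r0$drift(Z, mu), tolerance = 1e-12)
  }
})

test_that("microRNA degradation makes the mRNA closure decrease with miR-200", {
  red <- qss_reduce(coupled_pars, 330e3)
  Z <- 5e4
  expect_lt(red$mz_star(Z, 1e6), red$mz_star(Z, 0))
})
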