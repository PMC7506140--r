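test_that("compiled and reference right-hand sides agree", {
  for (seed in 1:12) {
    st <- random_state(coupled_pars, seed)
    S <- runif(1, 0, 5e5)
    expect_equal(unname(emtnfatc:::cpp_mech_rhs(st, coupled_pars, S)),
                 unname(mech_rhs(st, coupled_pars, S)),
                 tolerance = 1e-10)
  }
})

test_that("the non-negative orthant is forward-invariant", {
  # any state with one component at zero has a non-negative derivative there
  set.seed(4)
  for (rep in 1:20) {
    st <- random_state(coupled_pars, rep + 100)
    i <- sample(4, 1)            # N is handled analytically below
    st[i] <- 0
    d <- mech_rhs(st, coupled_pars, runif(1, 0, 5e5))
    expect_gte(d[[i]], 0)
  }
  st <- random_state(coupled_pars, 1)
  st["N"] <- 0
  expect_gte(mech_rhs(st, coupled_pars, 0)[["N"]], 0)
})

test_that("steady states are fixed points and stable ones attract", {
  for (S in c(0, 330e3, 450e3)) {
    ss <- find_steady_states(coupled_pars, S, n_starts = 60, seed = 2)
    expect_gt(nrow(ss), 0)
    for (i in seq_len(nrow(ss))) {
      d <- mech_rhs(unlist(ss[i, c("mu", "mz", "Z", "E", "N")]),
                    coupled_pars, S)
      expect_lt(max(abs(d)), 1e-5)
    }
    # integration oracle: a stable state perturbed by +1% returns
    st <- ss[ss$stable, , drop = FALSE]
    for (i in seq_len(nrow(st))) {
      x0 <- unlist(st[i, c("mu", "mz", "Z", "E", "N")])
      tr <- simulate_model(x0 * 1.01, coupled_pars, S, t_max = 500,
                           dt_out = 100)
      xT <- unlist(tr[nrow(tr), c("mu", "mz", "Z", "E", "N")])
      expect_equal(log(pmax(xT, 1)), log(pmax(x0, 1)), tolerance = 0.02)
    }
  }
})

test_that("NFATc relaxes to its analytic fixed point from any start", {
  st <- random_state(coupled_pars, 3)
  st["N"] <- 1
  tr <- simulate_model(st, coupled_pars, 1e5, t_max = 200, dt_out = 50)
  expect_equal(tr$N[nrow(tr)], coupled_pars$gN / coupled_pars$kN,
               tolerance = 1e-4)
})

test_that("a trajectory started at a stable state stays there", {
  ss <- find_steady_states(coupled_pars, 330e3, n_starts = 60, seed = 2)
  x0 <- unlist(ss[ss$stable, ][1, c("mu", "mz", "Z", "E", "N")])
  tr <- simulate_model(x0, coupled_pars, 330e3, t_max = 300, dt_out = 50)
  for (v in c("mu", "mz", "Z", "E", "N"))
    expect_equal(tr[[v]], rep(x0[[v]], nrow(tr)), tolerance = 1e-3)
})

test_that("root finding and long integration find the same stable states", {
  # oracle equivalence on perturbed parameter sets
  set.seed(9)
  n_agree <- 0
  for (rep in 1:8) {
    p <- coupled_pars
    for (nm in c("gu", "gm", "ku", "km", "lZm", "lNu"))
      p[[nm]] <- p[[nm]] * runif(1, 0.8, 1.25)
    S <- runif(1, 1e5, 4.5e5)
    ss <- find_steady_states(p, S, n_starts = 80, seed = rep)
    stable <- ss[ss$stable, , drop = FALSE]
    # brute force: terminal states of integrations from random starts
    ends <- list()
    inits <- random_initial_states(p, 30, seed = rep + 50)
    for (i in seq_len(nrow(inits))) {
      xT <- emtnfatc:::cpp_mech_relax(inits[i, ], p, S, 4000, 0.05)
      dup <- FALSE
      for (q in ends)
        if (max(abs(log(pmax(xT, 1)) - log(pmax(q, 1)))) < 0.1) dup <- TRUE
      if (!dup) ends[[length(ends) + 1]] <- xT
    }
    matched <- vapply(ends, function(e) {
      any(vapply(seq_len(nrow(stable)), function(i) {
        max(abs(log(pmax(e, 1)) -
                log(pmax(unlist(stable[i, c("mu", "mz", "Z", "E", "N")]), 1)))) < 0.1
      }, logical(1)))
    }, logical(1))
    expect_true(all(matched))
    if (length(ends) == nrow(stable)) n_agree <- n_agree + 1
  }
  # the two routes give identical state COUNTS in nearly every case
  expect_gte(n_agree, 6)
})

test_that("band entry times are detected on trajectories", {
  tr <- data.frame(time = 0:10, mz = c(0:5, 7, 9, 30, 40, 50))
  expect_equal(time_to_band(tr, lower = 9), 7)
  expect_equal(time_to_band(tr, lower = 100), Inf)
})
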