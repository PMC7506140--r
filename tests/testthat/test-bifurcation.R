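test_that("the calibrated coupled diagram has the expected phase structure", {
  sw <- cached_sweep("coupled")
  r <- rle(sw$phases)
  # monostable epithelial regime at low SNAIL
  expect_equal(r$values[1], "E")
  # no monostable hybrid regime anywhere
  expect_false(any(sw$phases == "H"))
  # hybrid coexists with M ({E,H,M} then {H,M}) at intermediate SNAIL,
  # fully mesenchymal at high SNAIL
  expect_true("EHM" %in% r$values)
  expect_true("HM" %in% r$values)
  expect_equal(tail(r$values, 1), "M")
  # the printed landscape SNAIL levels lie in multistable H/M regions
  for (S in c(323e3, 330e3)) {
    ph <- sw$phases[which.min(abs(sw$S_grid - S))]
    expect_true(grepl("H", ph) && grepl("M", ph))
  }
})

test_that("the core diagram is epithelial at low and mesenchymal at high SNAIL", {
  sw <- cached_sweep("core")
  r <- rle(sw$phases)
  expect_equal(r$values[1], "E")
  expect_equal(tail(r$values, 1), "M")
  expect_true("EHM" %in% r$values)
  expect_true("HM" %in% r$values)   # needed by the residence-time analysis
})

test_that("NFATc widens the hybrid SNAIL window", {
  hC <- hybrid_interval(cached_sweep("coupled"))
  h0 <- hybrid_interval(cached_sweep("core"))
  expect_gt(attr(hC, "length"), attr(h0, "length"))
  # the coupled window also sits at higher SNAIL (a stronger stimulus is
  # needed to leave the epithelial state)
  expect_gt(hC[["S_lo"]], h0[["S_lo"]])
})

test_that("interval endpoints bracket stable-count changes found independently", {
  sw <- cached_sweep("coupled")
  h <- hybrid_interval(sw)
  for (end in c(h[["S_lo"]], h[["S_hi"]])) {
    lo <- sum(find_steady_states(sw$params, end - 3e3, n_starts = 60,
                                 seed = 3)$stable)
    hi <- sum(find_steady_states(sw$params, end + 3e3, n_starts = 60,
                                 seed = 3)$stable)
    expect_true(lo != hi)
  }
})

test_that("phases agree with brute-force terminal states of integrations", {
  sw <- cached_sweep("coupled")
  for (S in c(150e3, 330e3, 420e3)) {
    i <- which.min(abs(sw$S_grid - S))
    n_expect <- sw$stable_counts[i]
    inits <- random_initial_states(sw$params, 60, seed = 8)
    ends <- list()
    for (k in seq_len(nrow(inits))) {
      xT <- emtnfatc:::cpp_mech_relax(inits[k, ], sw$params, sw$S_grid[i], 4000, 0.05)
      dup <- FALSE
      for (q in ends)
        if (max(abs(log(pmax(xT, 1)) - log(pmax(q, 1)))) < 0.1) dup <- TRUE
      if (!dup) ends[[length(ends) + 1]] <- xT
    }
    expect_equal(length(ends), n_expect)
  }
})

test_that("an empty hybrid interval is reported as empty, not an error", {
  # a sweep restricted to the monostable epithelial region has no H state
  p <- coupled_pars
  sw <- sweep_bifurcation(p, seq(0, 1e5, length.out = 51), seed = 1)
  h <- hybrid_interval(sw, refine = FALSE)
  expect_equal(attr(h, "length"), 0)
  expect_true(all(is.na(h)))
})

test_that("zero perturbation reports exactly zero sensitivity", {
  sa <- sensitivity_analysis(coupled_pars, delta = 0,
                             S_grid = seq(0, 5e5, length.out = 81),
                             parameters = c("gu", "lNu", "Z0m"))
  expect_true(all(sa$percent_change == 0))
})
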