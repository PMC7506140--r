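# a small helper: attractors + basin grid at one SNAIL level, cached
.sde_cache <- new.env()
sde_setup <- function(S = 330e3) {
  key <- as.character(S)
  if (is.null(.sde_cache[[key]])) {
    att <- reduced_fixed_points(coupled_pars, S)
    bg <- basin_grid(coupled_pars, S, att, grid_n = 80)
    .sde_cache[[key]] <- list(att = att, bg = bg)
  }
  .sde_cache[[key]]
}

test_that("identical seeds reproduce stochastic runs bit for bit", {
  s <- sde_setup()
  r1 <- euler_maruyama(coupled_pars, 330e3, hours = 100, seed = 11,
                       attractors = s$att, basin_cache = s$bg)
  r2 <- euler_maruyama(coupled_pars, 330e3, hours = 100, seed = 11,
                       attractors = s$att, basin_cache = s$bg)
  expect_identical(r1$itinerary, r2$itinerary)
  expect_identical(r1$traj, r2$traj)
  r3 <- euler_maruyama(coupled_pars, 330e3, hours = 100, seed = 12,
                       attractors = s$att, basin_cache = s$bg)
  expect_false(identical(r1$traj, r3$traj))
})

test_that("zero noise reduces Euler-Maruyama to the deterministic flow", {
  s <- sde_setup()
  # started at a stable fixed point: stays there
  r <- euler_maruyama(coupled_pars, 330e3, sigma = 0, hours = 200, seed = 1,
                      attractors = s$att, basin_cache = s$bg)
  expect_lt(max(abs(log(r$final[1] / s$att$Z[1])),
                abs(log(r$final[2] / s$att$mu[1]))), 1e-3)
  # started elsewhere: terminal point matches RK4 integration of the drift
  r2 <- euler_maruyama(coupled_pars, 330e3, sigma = 0, hours = 500, seed = 1,
                       init = c(2e5, 2e3),
                       attractors = s$att, basin_cache = s$bg)
  det <- emtnfatc:::cpp_red_relax(2e5, 2e3, coupled_pars, 330e3, 500, 0.01)
  expect_equal(log(r2$final), log(unname(det)), tolerance = 0.02)
  expect_error(euler_maruyama(coupled_pars, 330e3, dt = -1), "dt")
})

test_that("residence-time bookkeeping is exact on synthetic itineraries", {
  # single label: one visit of the whole duration, occupancy 1
  it <- factor(rep("M", 1000), levels = c("H", "M"))
  m <- mean_residence_time(it, dt = 0.01)
  expect_equal(m$mrt[m$state == "M"], 10)
  expect_equal(m$fraction[m$state == "M"], 1)
  expect_true(is.na(m$mrt[m$state == "H"]))
  # strictly alternating runs of k steps: both MRTs equal k dt
  it2 <- factor(rep(rep(c("A", "B"), 50), each = 7), levels = c("A", "B"))
  m2 <- mean_residence_time(it2, dt = 0.5)
  expect_equal(m2$mrt, c(3.5, 3.5))
  expect_equal(sum(m2$fraction), 1)
})

test_that("occupancy fractions sum to one on real runs", {
  s <- sde_setup()
  r <- euler_maruyama(coupled_pars, 330e3, hours = 500, seed = 3,
                      attractors = s$att, basin_cache = s$bg)
  m <- mean_residence_time(coarse_grain(r))
  expect_equal(sum(m$fraction), 1)
})

test_that("a symmetric double well yields symmetric barriers", {
  # synthetic two-basin histogram built from a known symmetric density;
  # the landscape machinery must recover equal barrier heights
  n <- 80
  x <- seq(-3, 3, length.out = n)
  U_true <- outer((x^2 - 1)^2, x^2 / 2, `+`)
  P <- exp(-U_true / 0.35)
  run <- structure(list(
    hist = P / sum(P) * 1e6,
    Zgrid = exp(seq(log(10), log(1000), length.out = n)),
    MuGrid = exp(seq(log(10), log(1000), length.out = n)),
    attractors = data.frame(
      Z = exp(seq(log(10), log(1000), length.out = n))[c(which.min(abs(x + 1)),
                                                          which.min(abs(x - 1)))],
      mu = exp(seq(log(10), log(1000), length.out = n))[which.min(abs(x))][c(1, 1)],
      label = c("L", "R"))), class = "emt_sde_run")
  qp <- quasi_potential(run, bw = 1)
  expect_equal(unname(qp$barriers["L"]), unname(qp$barriers["R"]),
               tolerance = 0.05)
  expect_true(all(qp$barriers > 0))
})

test_that("with vanishing noise the trajectory stays in its starting basin", {
  s <- sde_setup()
  # start at the mesenchymal attractor: noise amplitudes scale with the
  # attractor span, so the deepest/widest basin is the right probe
  k <- which.max(s$att$Z)
  r <- euler_maruyama(coupled_pars, 330e3, sigma = 0.005, hours = 2000,
                      seed = 5, init = c(s$att$Z[k], s$att$mu[k]),
                      attractors = s$att, basin_cache = s$bg)
  m <- mean_residence_time(coarse_grain(r))
  expect_gt(m$fraction[m$state == s$att$label[k]], 0.99)
})
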