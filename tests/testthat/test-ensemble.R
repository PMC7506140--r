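test_that("kinetic sampling respects the published ranges and sign conventions", {
  topo <- wildtype_topology()
  med <- emtnfatc:::.median_levels(topo)
  set.seed(1)
  g <- k <- lam_act <- lam_inh <- n_hill <- c()
  act <- topo$edges$sign == "activation"
  for (i in 1:400) {
    p <- sample_model_parameters(topo, med)
    g <- c(g, p$g); k <- c(k, p$k); n_hill <- c(n_hill, p$n)
    lam_act <- c(lam_act, p$lambda[act])
    lam_inh <- c(lam_inh, p$lambda[!act])
  }
  expect_true(all(g >= 1 & g <= 100))
  expect_true(all(k >= 0.1 & k <= 1))
  expect_true(all(n_hill %in% 1:6))
  expect_true(all(lam_act >= 1 & lam_act <= 100))
  expect_true(all(lam_inh > 0 & lam_inh <= 1))
})

test_that("edge thresholds track the source's median operating level", {
  # oracle: direct simulation of the sampling rule itself
  topo <- core_topology()
  med <- emtnfatc:::.median_levels(topo)
  set.seed(2)
  thr <- replicate(5000, sample_model_parameters(topo, med)$threshold[1])
  src <- topo$edges$source[1]
  expect_equal(median(thr), med[[src]], tolerance = 0.1)
})

test_that("a single unregulated node settles at g/k from every start", {
  single <- network_topology("A", data.frame(source = "A", target = "A",
                                             sign = "activation",
                                             mechanism = "transcriptional"))
  pars <- list(g = c(A = 40), k = c(A = 0.5), lambda = 1, n = 2,
               threshold = 50)
  set.seed(3)
  sol <- solve_ensemble_model(single, pars, 25)
  expect_equal(nrow(sol$states), 1)
  expect_equal(unname(sol$states[1, "A"]), 80, tolerance = 1e-3)
  expect_true(all(sol$arrivals == 1))
})

test_that("a strong toggle switch matches a brute-force grid relaxation", {
  toggle <- network_topology(c("A", "B"), rbind(
    regulatory_edge("A", "B", "inhibition"),
    regulatory_edge("B", "A", "inhibition")))
  pars <- list(g = c(A = 50, B = 50), k = c(A = 0.5, B = 0.5),
               lambda = c(0.02, 0.02), n = c(4, 4), threshold = c(50, 50))
  set.seed(4)
  sol <- solve_ensemble_model(toggle, pars, 60)
  expect_equal(nrow(sol$states), 2)
  # brute-force oracle: relax a 9x9 grid of starts with an independent
  # R-side Euler integration
  rhs <- function(x) c(50 * (1 + 0.02 * (x[2] / 50)^4) / (1 + (x[2] / 50)^4) - 0.5 * x[1],
                       50 * (1 + 0.02 * (x[1] / 50)^4) / (1 + (x[1] / 50)^4) - 0.5 * x[2])
  ends <- list()
  for (a in exp(seq(log(0.1), log(500), length.out = 9)))
    for (b in exp(seq(log(0.1), log(500), length.out = 9))) {
      x <- c(a, b * 1.013)   # off-diagonal start: the symmetric saddle is
                             # an attractor within the diagonal subspace
      for (s in 1:4000) x <- pmax(x + 0.05 * rhs(x), 0)
      dup <- FALSE
      for (q in ends) if (max(abs(log(pmax(x, 1e-3)) - log(pmax(q, 1e-3)))) < 0.2)
        dup <- TRUE
      if (!dup) ends[[length(ends) + 1]] <- x
    }
  expect_equal(length(ends), 2)
  for (e in ends)
    expect_true(any(vapply(seq_len(2), function(i)
      max(abs(log(pmax(e, 1e-3)) - log(pmax(sol$states[i, ], 1e-3)))) < 0.2,
      logical(1))))
})

test_that("pooled z-scores are standardized and labels follow the sign rule", {
  en <- classify_ensemble(run_ensemble(core_topology(), n_models = 150,
                                       n_inits = 50, seed = 6))
  expect_equal(unname(colMeans(en$z)), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(apply(en$z, 2, sd)), rep(1, 3), tolerance = 1e-10)
  zz <- en$z[, "ZEB"]; zm <- en$z[, "miR200"]
  expect_true(all(en$label[zz > 0 & zm < 0] == "M"))
  expect_true(all(en$label[zz > 0 & zm > 0] == "H"))
  expect_true(all(en$label[zz < 0 & zm > 0] == "E"))
})

test_that("phase counts partition the ensemble and are seed-reproducible", {
  pf <- phase_frequencies(list(core = core_topology()), n_models = 120,
                          n_inits = 40, replicates = 2, seed = 9)
  for (r in 1:2)
    expect_equal(sum(pf$counts["core", , r]), 120)
  pf2 <- phase_frequencies(list(core = core_topology()), n_models = 120,
                           n_inits = 40, replicates = 2, seed = 9)
  expect_identical(pf$counts, pf2$counts)
})

test_that("relative-stability arrival counts sum to the number of starts", {
  rs <- relative_stability(core_topology(), phase = "EM", n_models = 150,
                           n = 200, repeats = 2, n_inits = 50, seed = 10)
  expect_false(is.null(rs))
  sums <- tapply(rs$count, list(rs$model, rs$rep), sum)
  expect_true(all(sums == 200, na.rm = TRUE))
})
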