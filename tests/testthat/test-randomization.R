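test_that("sign randomization of the wild-type yields 461 networks", {
  rnd <- enumerate_randomized(wildtype_topology())
  expect_equal(rnd$n, 461)          # C(11, 6) - 1
  # every member preserves endpoints (hence all degrees) and the 6/5 split
  set.seed(1)
  for (i in sample(rnd$n, 12)) {
    t2 <- rnd$topologies(i)
    expect_equal(t2$edges[c("source", "target")],
                 rnd$base$edges[c("source", "target")])
    expect_equal(sum(t2$edges$sign == "activation"), 6)
  }
  # the wild-type assignment itself is excluded
  wt <- rnd$base$edges$sign == "activation"
  expect_false(any(apply(rnd$assignments, 1, function(v) all(v == wt))))
})

test_that("toy enumerations match the closed-form count", {
  toy <- network_topology(c("A", "B", "C", "D"), rbind(
    regulatory_edge("A", "B", "activation"),
    regulatory_edge("B", "C", "activation"),
    regulatory_edge("C", "D", "inhibition"),
    regulatory_edge("D", "A", "inhibition")))
  rnd <- enumerate_randomized(toy)
  expect_equal(rnd$n, choose(4, 2) - 1)
  # brute force: all distinct sign vectors with two activations, minus WT
  all_v <- unique(t(apply(combn(4, 2), 2, function(ix) {
    v <- c(FALSE, FALSE, FALSE, FALSE); v[ix] <- TRUE; v
  })))
  expect_equal(nrow(all_v) - 1, rnd$n)

  # an all-activating topology has no sign randomizations
  allact <- network_topology(c("A", "B"), rbind(
    regulatory_edge("A", "B", "activation"),
    regulatory_edge("B", "A", "activation")))
  expect_equal(enumerate_randomized(allact)$n, 0)
})

test_that("subsampled comparisons are reproducible and self-consistent", {
  # phenotype calls need the ZEB and miR200 nodes; one activation and one
  # inhibition give exactly one sign randomization to compare against
  toy <- network_topology(c("ZEB", "miR200"), rbind(
    regulatory_edge("miR200", "ZEB", "inhibition"),
    regulatory_edge("ZEB", "ZEB", "activation")))
  r1 <- compare_phase_fractions(toy, phase = "EM", n_models = 60,
                                n_inits = 30, subsample = 1, seed = 3)
  r2 <- compare_phase_fractions(toy, phase = "EM", n_models = 60,
                                n_inits = 30, subsample = 1, seed = 3)
  expect_identical(r1$fractions, r2$fractions)
  expect_identical(r1$indices, r2$indices)
  expect_true(r1$percentile >= 0 && r1$percentile <= 100)
})
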