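test_that("fixture bundles regenerate byte-identically from the master seed", {
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- generate_fixtures(d1, seed = 1729)
  m2 <- generate_fixtures(d2, seed = 1729)
  expect_identical(m1$checksums, m2$checksums)
  # refusal to overwrite without force
  expect_error(generate_fixtures(d1, seed = 1729), "force")
  expect_silent(generate_fixtures(d1, seed = 1729, force = TRUE))
})

test_that("fixture files round-trip through their readers", {
  d <- tempfile()
  generate_fixtures(d, seed = 1)
  wt <- read_topo(file.path(d, "wildtype_coupled.topo"))
  expect_length(wt$nodes, 5)
  expect_equal(nrow(wt$edges), 11)
  p <- read_parameters(file.path(d, "params_coupled.tsv"))
  expect_equal(p$gu, coupled_pars$gu)
  tr <- read.csv(file.path(d, "example_trajectory.csv"))
  expect_true(all(c("time", "mu", "mz", "Z", "E", "N") %in% names(tr)))
  expect_true(nrow(tr) > 10)
})
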