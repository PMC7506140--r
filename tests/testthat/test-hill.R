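test_that("shifted Hill hits its exact landmark values", {
  # zero regulator: factor is 1 regardless of the block
  expect_equal(shifted_hill(0, 1e4, 2, 7.5), 1)
  expect_equal(shifted_hill(0, 3, 6, 0.01), 1)
  # at threshold: (1 + lambda)/2
  expect_equal(shifted_hill(1e4, 1e4, 4, 3), 2)
  expect_equal(shifted_hill(50, 50, 1, 0.1), 0.55)
  # saturation: approaches lambda
  expect_equal(shifted_hill(1e6 * 20, 20, 2, 0.1), 0.1, tolerance = 1e-6)
})

test_that("shifted Hill is monotone and bounded between 1 and lambda", {
  x <- seq(0, 1e6, length.out = 200)
  for (lam in c(0.05, 0.6, 1, 4, 90)) {
    h <- shifted_hill(x, 1.7e4, 3, lam)
    expect_true(all(h >= min(1, lam) - 1e-12 & h <= max(1, lam) + 1e-12))
    d <- diff(h)
    if (lam > 1) expect_true(all(d >= -1e-12))
    if (lam < 1) expect_true(all(d <= 1e-12))
  }
  expect_error(shifted_hill(1, -2, 2, 2), "A0")
  expect_error(shifted_hill(1, 2, 0.5, 2), "n")
})

test_that("binding-site occupancies are a probability distribution", {
  # no occupancy at zero microRNA
  expect_equal(mirna_site_occupancy(0, 1e4, 6, 0), 1)
  # mu = mu0, two sites, one occupied: 2 * 1 * 1 / 4
  expect_equal(mirna_site_occupancy(1e4, 1e4, 2, 1), 0.5)
  # binomial normalization at arbitrary levels
  for (mu in c(0, 17, 1e3, 1e4, 2e5)) {
    expect_equal(sum(mirna_site_occupancy(mu, 1e4, 6, 0:6)), 1)
  }
  expect_error(mirna_site_occupancy(1, 1e4, 6, 7), "range")
})

test_that("occupancy sums: translation falls and degradation rises with microRNA", {
  p <- default_parameters("coupled")
  mus <- c(0, 1e3, 5e3, 2e4, 1e5)
  s <- t(vapply(mus, mirna_sums, numeric(3), params = p))
  expect_true(all(diff(s[, "L"]) < 0))
  expect_true(all(diff(s[, "Ym"]) > 0))
  expect_equal(unname(s[1, "L"]), 1)   # l_i[0] = 1 at zero occupancy
  expect_equal(unname(s[1, "Ym"]), 0)
  expect_equal(unname(s[1, "Ymu"]), 0)
})
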