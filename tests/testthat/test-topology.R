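test_that("shipped topologies match the circuit they model", {
  wt <- wildtype_topology()
  expect_length(wt$nodes, 5)
  expect_equal(nrow(wt$edges), 11)
  expect_equal(sum(wt$edges$sign == "activation"), 6)
  expect_equal(sum(wt$edges$sign == "inhibition"), 5)
  # the microRNA edge and the indirect E-cadherin arm are mechanism-tagged
  expect_equal(wt$edges$mechanism[wt$edges$source == "miR200"], "mirna")
  expect_equal(wt$edges$mechanism[wt$edges$source == "Ecad"], "indirect")

  core <- core_topology()
  expect_setequal(core$nodes, c("SNAIL", "miR200", "ZEB"))
  expect_equal(nrow(core$edges), 5)
  # the core is the coupled topology restricted to its nodes
  wt_core <- wt$edges[wt$edges$source %in% core$nodes &
                      wt$edges$target %in% core$nodes, ]
  expect_equal(nrow(wt_core), 5)
})

test_that("topology files round-trip losslessly", {
  f <- tempfile(fileext = ".topo")
  for (topo in list(wildtype_topology(), core_topology())) {
    write_topo(topo, f)
    back <- read_topo(f)
    expect_equal(back$edges, topo$edges)
    expect_setequal(back$nodes, topo$nodes)
  }
})

test_that("malformed topology files are rejected with line information", {
  f <- tempfile(fileext = ".topo")
  writeLines(c("Source Target Type", "A B 3"), f)
  expect_error(read_topo(f), "line 2")
  writeLines(c("Bad Header Row2"), f)
  expect_error(read_topo(f), "header")
  writeLines("Source Target Type", f)
  expect_warning(t0 <- read_topo(f), "no edges")
  expect_equal(nrow(t0$edges), 0)
})

test_that("validation catches duplicate and dangling edges", {
  e <- rbind(regulatory_edge("A", "B", "activation"),
             regulatory_edge("A", "B", "inhibition"))
  expect_error(network_topology(c("A", "B"), e), "duplicate")
  expect_error(network_topology("A", regulatory_edge("A", "C", "activation")),
               "unknown node")
  expect_error(regulatory_edge("A", "B", "sometimes"))
})
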