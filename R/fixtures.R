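#' Generate the synthetic input bundle
#'
#' Writes every input the analyses consume: the wild-type coupled and core
#' topologies, the calibrated mechanistic parameter files, toy oracle
#' circuits (single node; toggle switch), a seeded example trajectory of
#' the coupled model under EMT-inducing SNAIL, and a manifest with the
#' sub-seeds and md5 checksums.  All sub-seeds are derived from the master
#' seed by fixed offsets, so each fixture is independently reproducible
#' and two runs with the same master seed produce byte-identical files.
#'
#' @param dir output directory.
#' @param seed master seed.
#' @param force overwrite an existing non-empty directory.
#' @return the manifest, invisibly.
#' @export
generate_fixtures <- function(dir, seed = 1729, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) && !force)
    stop("output directory is not empty (use force = TRUE): ", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sub <- list(trajectory = seed + 1L)
  write_topo(wildtype_topology(), file.path(dir, "wildtype_coupled.topo"))
  write_topo(core_topology(), file.path(dir, "core.topo"))
  write_parameters(default_parameters("coupled"),
                   file.path(dir, "params_coupled.tsv"))
  write_parameters(default_parameters("core"),
                   file.path(dir, "params_core.tsv"))
  # toy oracle circuits
  single <- network_topology("A", regulatory_edge("A", "A", "activation"))
  # self-edge only used as a carrier; the solver treats lambda = 1 as inert
  write_topo(single, file.path(dir, "toy_single_node.topo"))
  toggle <- network_topology(c("A", "B"), rbind(
    regulatory_edge("A", "B", "inhibition"),
    regulatory_edge("B", "A", "inhibition")))
  write_topo(toggle, file.path(dir, "toy_toggle.topo"))
  # symmetric double-well drift used as a landscape oracle: dx = -dU/dx
  # with U = (x^2-1)^2 + y^2/2; minima at x = +/-1, separatrix x = 0
  write_json(list(potential = "(x^2-1)^2 + y^2/2",
                  minima = list(c(-1, 0), c(1, 0)),
                  saddle = c(0, 0), separatrix = "x = 0",
                  barrier = 1),
             file.path(dir, "toy_double_well.json"),
             auto_unbox = TRUE, pretty = TRUE)
  # seeded example trajectory: epithelial start, EMT-inducing SNAIL
  p <- default_parameters("coupled")
  set.seed(sub$trajectory)
  tr <- simulate_model(epithelial_state(p), p, S = 330000, t_max = 200,
                       dt_out = 5)
  write.csv(format(tr, digits = 10, trim = TRUE, scientific = FALSE),
            file.path(dir, "example_trajectory.csv"), row.names = FALSE,
            quote = FALSE)
  files <- setdiff(dir(dir), "manifest.json")
  manifest <- list(master_seed = seed, sub_seeds = sub,
                   checksums = as.list(md5sum(file.path(dir, sort(files)))))
  names(manifest$checksums) <- sort(files)
  write_json(manifest, file.path(dir, "manifest.json"),
             auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
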