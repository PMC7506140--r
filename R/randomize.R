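#' Enumerate degree-preserving sign randomizations of a topology
#'
#' Every edge keeps its source and target (so all in/out degrees are
#' preserved exactly); only the assignment of which edges are activating
#' changes, under the global constraint that the numbers of activation and
#' inhibition edges equal the wild-type's.  All `C(E, A)` assignments are
#' enumerated in lexicographic edge order and the wild-type assignment is
#' excluded, giving `C(E, A) - 1` networks.
#'
#' @param topology an `emt_topology`.
#' @return list with `base` (the input), `assignments` (logical matrix,
#'   one row per randomized network, TRUE = activation) and `topologies()`
#'   accessor returning the i-th randomized `emt_topology`.
#' @export
enumerate_randomized <- function(topology) {
  stopifnot(inherits(topology, "emt_topology"), nrow(topology$edges) >= 1)
  ne <- nrow(topology$edges)
  wt <- topology$edges$sign == "activation"
  na <- sum(wt)
  combos <- combn(ne, na)
  asg <- t(apply(combos, 2, function(ix) {
    v <- logical(ne); v[ix] <- TRUE; v
  }))
  keep <- !apply(asg, 1, function(v) all(v == wt))
  asg <- asg[keep, , drop = FALSE]
  make <- function(i) {
    e <- topology$edges
    e$sign <- ifelse(asg[i, ], "activation", "inhibition")
    network_topology(topology$nodes, e)
  }
  list(base = topology, assignments = asg, n = nrow(asg), topologies = make)
}

#' Compare the wild-type phase fraction against sign-randomized networks
#'
#' Runs a RACIPE-style ensemble on the wild-type and on (a seeded random
#' subsample of) its sign randomizations, and reports the fraction of
#' models realizing the queried phase for each network, together with the
#' wild-type's percentile within the randomized distribution.
#'
#' @param topology wild-type `emt_topology`.
#' @param phase phase string, e.g. `"EHM"`.
#' @param n_models,n_inits ensemble size per network.
#' @param subsample number of randomized networks to run (`Inf` = all).
#' @param seed integer seed (controls the subsample and the ensembles).
#' @param wt_n_models ensemble size for the wild-type itself (defaults to
#'   `n_models`; a larger value stabilises the fraction estimate of rare
#'   phases, which is compared against the randomized distribution).
#' @return list: `fractions` (randomized networks), `wildtype` fraction,
#'   `percentile` (0-100), `indices` of the sampled networks.
#' @export
compare_phase_fractions <- function(topology, phase = "EHM",
                                    n_models = 1000, n_inits = 100,
                                    subsample = 50, seed = 1,
                                    wt_n_models = n_models) {
  set.seed(seed)
  rnd <- enumerate_randomized(topology)
  idx <- if (is.finite(subsample) && subsample < rnd$n)
    sort(sample.int(rnd$n, subsample)) else seq_len(rnd$n)
  frac_of <- function(topo, s, nm = n_models) {
    en <- classify_ensemble(run_ensemble(topo, nm, n_inits, seed = s))
    mean(en$phase_per_model == phase)
  }
  fr <- vapply(seq_along(idx), function(i)
    frac_of(rnd$topologies(idx[i]), seed + i), numeric(1))
  wt <- frac_of(topology, seed, wt_n_models)
  list(fractions = fr, wildtype = wt,
       percentile = 100 * mean(fr < wt) + 50 * mean(fr == wt),
       indices = idx, phase = phase)
}
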