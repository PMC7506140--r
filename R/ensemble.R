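# Random-circuit-perturbation (RACIPE-style) ensemble analysis: sample
# kinetic parameters for a fixed topology, find each model's stable states
# by relaxation from many initial conditions, classify phenotypes by
# z-scores of pooled log2 levels, and tabulate multistable phase
# frequencies.

.topo_matrices <- function(topology) {
  idx <- setNames(seq_along(topology$nodes) - 1L, topology$nodes)
  e <- topology$edges
  list(src = unname(idx[e$source]), tgt = unname(idx[e$target]),
       act = e$sign == "activation")
}

# Monte-Carlo estimate of each node's median operating level under the
# sampling ranges: g/k draws modulated by every regulatory input of the
# node at half activation (factor (1 + lambda)/2 with lambda drawn from
# the edge's sampling range).  Uses a private RNG stream (fixed sub-seed)
# so the estimate is a per-topology constant.
.median_levels <- function(topology, n = 1000, subseed = 20200908) {
  tm <- .topo_matrices(topology)
  n_in <- function(i, act) sum(tm$tgt == i & tm$act == act)
  withr_seed <- .Random.seed_exists()
  old <- if (withr_seed) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(subseed)
  med <- vapply(seq_along(topology$nodes), function(j) {
    lv <- runif(n, 1, 100) / runif(n, 0.1, 1)
    for (r in seq_len(n_in(j - 1L, FALSE)))
      lv <- lv * (1 + 1 / runif(n, 1, 100)) / 2
    for (r in seq_len(n_in(j - 1L, TRUE)))
      lv <- lv * (1 + runif(n, 1, 100)) / 2
    median(lv)
  }, numeric(1))
  if (withr_seed) assign(".Random.seed", old, envir = globalenv())
  setNames(med, topology$nodes)
}

.Random.seed_exists <- function() exists(".Random.seed", envir = globalenv())

#' Sample one RACIPE-style kinetic parameter set
#'
#' Per node: production `g ~ U[1, 100]`, degradation `k ~ U[0.1, 1]`.
#' Per edge: integer cooperativity `n ~ U{1..6}`; fold change
#' `lambda ~ U[1, 100]` for activations and the reciprocal for
#' inhibitions; threshold sampled uniformly over `[0.02, 1.98] x` the
#' source node's median operating level (half-functional rule).  Draws
#' come from the current RNG stream, so runs are reproducible from
#' `set.seed`.
#'
#' @param topology an `emt_topology`.
#' @param medians optional precomputed median levels (see Details in
#'   [run_ensemble()]); computed on the fly if missing.
#' @return list with `g`, `k` (named by node) and per-edge `lambda`, `n`,
#'   `threshold`.
#' @export
sample_model_parameters <- function(topology, medians = NULL) {
  if (is.null(medians)) medians <- .median_levels(topology)
  nn <- length(topology$nodes)
  ne <- nrow(topology$edges)
  act <- topology$edges$sign == "activation"
  lam <- runif(ne, 1, 100)
  lam[!act] <- 1 / lam[!act]
  list(g = setNames(runif(nn, 1, 100), topology$nodes),
       k = setNames(runif(nn, 0.1, 1), topology$nodes),
       lambda = lam,
       n = sample.int(6, ne, replace = TRUE),
       threshold = runif(ne, 0.02, 1.98) * medians[topology$edges$source])
}

#' Stable states of one sampled ensemble model
#'
#' Shifted-Hill dynamics (no microRNA binding-site formalism in ensemble
#' mode) relaxed from log-uniform initial conditions (sampled within each
#' node's estimated operating range when `medians` is given) until the relative
#' sup-norm of the right-hand side falls below `tol`; endpoints are
#' deduplicated at `dedup` in log levels and kept only if the Jacobian is
#' stable.
#'
#' @param topology an `emt_topology`.
#' @param pars output of [sample_model_parameters()].
#' @param n_inits number of initial conditions.
#' @param tol convergence tolerance.
#' @param dedup log-level deduplication tolerance.
#' @return list: `states` (matrix, one stable state per row, columns =
#'   nodes), `arrivals` (initial condition -> state index, 0 =
#'   unresolved), `n_unresolved`.
#' @export
solve_ensemble_model <- function(topology, pars, n_inits = 100,
                                 tol = 1e-6, dedup = 1e-2, medians = NULL) {
  tm <- .topo_matrices(topology)
  nn <- length(topology$nodes)
  inits <- if (is.null(medians)) {
    matrix(exp(runif(n_inits * nn, log(1e-2), log(1e5))), nrow = n_inits)
  } else {
    # log-uniform within each node's estimated operating range
    m <- vapply(seq_len(nn), function(j)
      exp(runif(n_inits, log(medians[[j]] / 100), log(medians[[j]] * 100))),
      numeric(n_inits))
    matrix(m, nrow = n_inits)
  }
  r <- cpp_solve_model(tm$src, tm$tgt, pars$lambda, pars$n, pars$threshold,
                       unname(pars$g), unname(pars$k), inits,
                       tol, log(1 + dedup) * 5, 1e4)
  colnames(r$states) <- topology$nodes
  r
}

#' Run a RACIPE-style ensemble
#'
#' @param topology an `emt_topology`.
#' @param n_models number of random models.
#' @param n_inits initial conditions per model.
#' @param seed integer seed.
#' @return list: `states` (pooled stable states, one per row with model
#'   id), `n_states_per_model`, `topology`.
#' @export
run_ensemble <- function(topology, n_models = 1000, n_inits = 100,
                         seed = 1) {
  set.seed(seed)
  med <- .median_levels(topology)
  states <- vector("list", n_models)
  pars_all <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    pars <- sample_model_parameters(topology, med)
    pars_all[[m]] <- pars
    sol <- solve_ensemble_model(topology, pars, n_inits)
    if (nrow(sol$states))
      states[[m]] <- cbind(model = m, sol$states)
  }
  pooled <- do.call(rbind, states[!vapply(states, is.null, logical(1))])
  nsm <- tabulate(pooled[, "model"], nbins = n_models)
  list(states = pooled, n_states_per_model = nsm, topology = topology,
       n_models = n_models, seed = seed, pars = pars_all, medians = med)
}

#' Phenotype calls from pooled ensemble z-scores
#'
#' log2 levels of every node are z-scored over the pooled stable states of
#' the whole ensemble; a state is mesenchymal (M) if `z_ZEB > 0` and
#' `z_miR200 < 0`, hybrid (H) if both are positive, epithelial (E) if
#' `z_ZEB < 0` and `z_miR200 > 0`, otherwise it falls into an explicit
#' unlabeled bin.
#'
#' @param ensemble output of [run_ensemble()].
#' @return the ensemble with added `z` matrix, `label` vector and
#'   `phase_per_model` (each model's sorted set of state labels, e.g.
#'   `"EHM"`; `"none"` for models with no stable state; unlabeled states
#'   are ignored for the phase unless a model has only unlabeled states,
#'   which yields `"unlabeled"`).
#' @export
classify_ensemble <- function(ensemble) {
  st <- ensemble$states
  nodes <- ensemble$topology$nodes
  lv <- log2(pmax(st[, nodes, drop = FALSE], 1e-6))
  sds <- apply(lv, 2, sd)
  if (any(sds == 0)) stop("degenerate ensemble: zero variance in node(s) ",
                          paste(nodes[sds == 0], collapse = ", "))
  z <- scale(lv)
  zz <- z[, "ZEB"]; zm <- z[, "miR200"]
  label <- ifelse(zz > 0 & zm < 0, "M",
           ifelse(zz > 0 & zm > 0, "H",
           ifelse(zz < 0 & zm > 0, "E", "unlabeled")))
  phase <- vapply(seq_len(ensemble$n_models), function(m) {
    l <- label[st[, "model"] == m]
    if (!length(l)) return("none")
    l2 <- sort(unique(l[l != "unlabeled"]))
    if (!length(l2)) return("unlabeled")
    paste(l2, collapse = "")
  }, character(1))
  ensemble$z <- z
  ensemble$label <- label
  ensemble$phase_per_model <- phase
  ensemble
}

.phase_levels <- c("E", "H", "M", "EH", "EM", "HM", "EHM", "unlabeled", "none")

#' Multistable phase frequencies with replicates
#'
#' Runs `replicates` independent ensembles per topology (fresh seed each)
#' and tabulates how many of the `n_models` random models fall into each
#' phase.  When two or more topologies are supplied, each is compared to
#' the first by an unpaired two-tailed equal-variance t-test on the
#' replicate frequencies.
#'
#' @param topologies named list of `emt_topology` objects.
#' @param n_models,n_inits,replicates,seed ensemble settings.
#' @return list: `counts` (topology x phase x replicate array), `summary`
#'   data frame (topology, phase, mean, sd), `tests` (phase-wise p-values
#'   vs the first topology; NULL if one topology or replicates < 2).
#' @export
phase_frequencies <- function(topologies, n_models = 1000, n_inits = 100,
                              replicates = 3, seed = 1) {
  stopifnot(length(topologies) >= 1)
  if (is.null(names(topologies)))
    names(topologies) <- paste0("topology", seq_along(topologies))
  counts <- array(0L, dim = c(length(topologies), length(.phase_levels),
                              replicates),
                  dimnames = list(names(topologies), .phase_levels, NULL))
  for (r in seq_len(replicates)) {
    for (t in seq_along(topologies)) {
      en <- run_ensemble(topologies[[t]], n_models, n_inits,
                         seed = seed + 1000L * (r - 1L) + t)
      en <- classify_ensemble(en)
      tb <- table(factor(en$phase_per_model, levels = .phase_levels))
      counts[t, , r] <- as.integer(tb)
    }
  }
  summ <- do.call(rbind, lapply(names(topologies), function(tn) {
    data.frame(topology = tn, phase = .phase_levels,
               mean = apply(counts[tn, , , drop = FALSE], 2, mean),
               sd = apply(counts[tn, , , drop = FALSE], 2, sd))
  }))
  tests <- NULL
  if (length(topologies) > 1 && replicates >= 2) {
    ref <- names(topologies)[1]
    tests <- do.call(rbind, lapply(names(topologies)[-1], function(tn) {
      data.frame(topology = tn, phase = .phase_levels,
                 p_value = vapply(.phase_levels, function(ph) {
                   a <- counts[ref, ph, ]; b <- counts[tn, ph, ]
                   if (sd(a) == 0 && sd(b) == 0) return(NA_real_)
                   t.test(b, a, var.equal = TRUE)$p.value
                 }, numeric(1)))
    }))
  } else if (replicates < 2 && length(topologies) > 1) {
    warning("replicates < 2: topology comparison tests skipped")
  }
  list(counts = counts, summary = summ, tests = tests,
       n_models = n_models, replicates = replicates, seed = seed)
}

#' Relative stability of coexisting states by basin sampling
#'
#' For sampled models whose phase is multistable, `n` random initial
#' conditions are relaxed to steady state and arrivals at each labelled
#' state are counted, with `repeats` independent sets of initial
#' conditions.  Initial conditions that fail to resolve are counted in an
#' explicit overflow bin so counts always sum to `n`.
#'
#' @param topology an `emt_topology`.
#' @param phase phase to select, e.g. `"HM"` or `"EHM"`.
#' @param n_models models to sample (the selection keeps those whose phase
#'   matches).
#' @param n initial conditions per model and repeat.
#' @param repeats independent repeats.
#' @param n_inits initial conditions used to discover each model's states.
#' @param seed integer seed.
#' @return data frame: model, repeat, state label, count; each
#'   (model, repeat) block sums to `n` including the `overflow` label.
#' @export
relative_stability <- function(topology, phase = "HM", n_models = 1000,
                               n = 1000, repeats = 3, n_inits = 100,
                               seed = 1) {
  en <- classify_ensemble(run_ensemble(topology, n_models, n_inits, seed))
  sel <- which(en$phase_per_model == phase)
  if (!length(sel)) return(NULL)
  rows <- list()
  set.seed(seed + 13L)
  for (m in sel) {
    st <- en$states[en$states[, "model"] == m, , drop = FALSE]
    labs <- en$label[en$states[, "model"] == m]
    for (r in seq_len(repeats)) {
      sol <- solve_ensemble_model(topology, en$pars[[m]], n)
      # match solved states to the recorded labelled states; counts are
      # accumulated per recorded state, then reported by label
      cnt <- integer(length(labs) + 1)   # last bin = overflow
      for (i in seq_len(nrow(sol$states))) {
        d <- apply(abs(log(pmax(st[, topology$nodes, drop = FALSE], 1e-6)) -
                       matrix(log(pmax(sol$states[i, ], 1e-6)),
                              nrow(st), length(topology$nodes),
                              byrow = TRUE)), 1, max)
        j <- which.min(d)
        k <- if (d[j] < 0.7) j else length(cnt)
        cnt[k] <- cnt[k] + sum(sol$arrivals == i)
      }
      cnt[length(cnt)] <- cnt[length(cnt)] + sum(sol$arrivals == 0)
      rows[[length(rows) + 1]] <-
        data.frame(model = m, rep = r, state = c(labs, "overflow"),
                   count = cnt)
    }
  }
  do.call(rbind, rows)
}
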