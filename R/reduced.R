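#' Quasi-steady-state reduction to the (ZEB protein, miR-200) plane
#'
#' ZEB mRNA, E-cadherin and NFATc relax much faster than ZEB protein and
#' miR-200, so their time derivatives are set to zero and solved in closed
#' form: `N* = gN/kN`, `E*(Z) = gE H(Z) H(N*) / kE`, and
#' `mz*(Z, mu) = gm H(Z) H(S) H(N*) H(E*(Z)) / (Ym(mu) + km)`.
#' Substituting the closures into the miR-200 and ZEB-protein equations
#' leaves two coupled ODEs whose fixed points coincide with those of the
#' full model.
#'
#' @param params an `emt_params` list.
#' @param S SNAIL level (molecules).
#' @return list with `drift(Z, mu)` returning `c(dZ, dmu)`, and closures
#'   `mz_star(Z, mu)`, `E_star(Z)`, `N_star`.
#' @export
qss_reduce <- function(params, S) {
  p <- params
  force(S)
  N_star <- p$gN / p$kN
  E_star <- function(Z) {
    p$gE * shifted_hill(Z, p$Z0E, p$nZE, p$lZE) *
      shifted_hill(N_star, p$N0E, p$nNE, p$lNE) / p$kE
  }
  mz_star <- function(Z, mu) {
    s3 <- mirna_sums(mu, p)
    hm <- shifted_hill(Z, p$Z0m, p$nZm, p$lZm) *
          shifted_hill(S, p$S0m, p$nSm, p$lSm) *
          shifted_hill(N_star, p$N0m, p$nNm, p$lNm) *
          shifted_hill(E_star(Z), p$E0m, p$nEm, p$lEm)
    p$gm * hm / (s3[["Ym"]] + p$km)
  }
  drift <- function(Z, mu) {
    d <- cpp_red_drift(Z, mu, p, S)
    c(dZ = d[["dZ"]], dmu = d[["dmu"]])
  }
  list(drift = drift, mz_star = mz_star, E_star = E_star, N_star = N_star,
       params = p, S = S)
}

#' Fixed points of the reduced system
#'
#' Computed from the full model's steady states (the closures make the two
#' fixed-point sets identical); returns their (Z, mu) coordinates with
#' stability and phenotype labels from a reference sweep labelling, or by
#' ZEB-mRNA ordering when no sweep is supplied (lowest stable = E when it
#' is miR-200-dominant, highest = M, middle = H).
#'
#' @param params an `emt_params` list.
#' @param S SNAIL level.
#' @param n_starts,seed multi-start settings.
#' @param labels optional character vector of labels to assign to the
#'   stable states in ascending ZEB-mRNA order.
#' @return data frame: Z, mu, mz, stable, label.
#' @export
reduced_fixed_points <- function(params, S, n_starts = 120, seed = 1,
                                 labels = NULL) {
  ss <- find_steady_states(params, S, n_starts = n_starts, seed = seed)
  st <- ss[ss$stable, , drop = FALSE]
  st <- st[order(st$mz), ]
  lab <- if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(st))
    labels
  } else {
    # heuristic for the calibrated parameter family: epithelial states have
    # low ZEB mRNA, mesenchymal states have collapsed miR-200
    vapply(seq_len(nrow(st)), function(i) {
      if (st$mz[i] < 150) "E" else if (st$mu[i] < 4000) "M" else "H"
    }, character(1))
  }
  data.frame(Z = st$Z, mu = st$mu, mz = st$mz, stable = TRUE, label = lab)
}
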