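#' Shifted Hill function
#'
#' `H(x) = (1 + lambda (x/A0)^n) / (1 + (x/A0)^n)`: equals 1 at zero
#' regulator and saturates at `lambda` (activation if lambda > 1,
#' inhibition if lambda < 1, inert if lambda == 1).
#'
#' @param level regulator level (molecules, >= 0); vectorized.
#' @param A0 threshold (molecules, > 0).
#' @param n Hill cooperativity (>= 1).
#' @param lambda fold change (> 0).
#' @return dimensionless regulation factor.
#' @export
shifted_hill <- function(level, A0, n, lambda) {
  if (!is.numeric(A0) || A0 <= 0) stop("A0 must be positive")
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be positive")
  r <- (level / A0)^n
  (1 + lambda * r) / (1 + r)
}

#' MicroRNA binding-site occupancy
#'
#' Probability that exactly `i` of `n_sites` microRNA binding sites on a
#' target mRNA are occupied, under independent binding with per-site
#' threshold `mu0`:
#' `M_i(mu) = C(n_sites, i) (mu/mu0)^i / (1 + mu/mu0)^n_sites`.
#'
#' @param mu microRNA level (molecules).
#' @param mu0 per-site threshold (molecules).
#' @param n_sites number of binding sites.
#' @param i occupancy (0..n_sites).
#' @return occupancy probability.
#' @export
mirna_site_occupancy <- function(mu, mu0, n_sites, i) {
  if (any(i < 0) || any(i > n_sites)) stop("i out of range 0..n_sites")
  r <- mu / mu0
  choose(n_sites, i) * r^i / (1 + r)^n_sites
}

#' Occupancy-weighted microRNA coupling sums
#'
#' Evaluates the three occupancy-weighted sums of the binding-site
#' formalism at microRNA level `mu`:
#' translation factor `L = sum_i l_i M_i`, active mRNA degradation
#' `Ym = sum_i gamma_m_i M_i`, and microRNA co-degradation
#' `Ymu = sum_i i gamma_mu_i M_i`.
#'
#' @param mu microRNA level (molecules, scalar).
#' @param params an `emt_params` list (uses `mu0`, `l_i`, `gamma_m`,
#'   `gamma_mu`).
#' @return named vector `c(L, Ym, Ymu)`.
#' @export
mirna_sums <- function(mu, params) {
  ns <- length(params$l_i) - 1
  Mi <- mirna_site_occupancy(mu, params$mu0, ns, 0:ns)
  c(L   = sum(params$l_i * Mi),
    Ym  = sum(params$gamma_m * Mi),
    Ymu = sum((0:ns) * params$gamma_mu * Mi))
}
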