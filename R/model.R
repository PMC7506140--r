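.state_names <- c("mu", "mz", "Z", "E", "N")

#' Right-hand side of the mechanistic ODE model
#'
#' Reference R implementation (the compiled solver uses an identical C++
#' routine; the two are cross-checked in the test suite).  Production of
#' each species is its basal rate times the product of shifted-Hill factors
#' over incoming transcriptional/indirect edges; the miR-200 -> ZEB-mRNA
#' edge uses the binding-site formalism: translation `gz * mz * L(mu)`,
#' microRNA-dependent mRNA loss `mz * Ym(mu)` and duplex-mediated microRNA
#' loss `mz * Ymu(mu)`.  NFATc production is constitutive and SNAIL enters
#' only as the clamped input `S`.
#'
#' @param state named numeric (mu, mz, Z, E, N), molecules.
#' @param params an `emt_params` list.
#' @param S SNAIL level (molecules).
#' @return named vector of time derivatives (molecules/h).
#' @export
mech_rhs <- function(state, params, S) {
  if (any(state < 0)) stop("state components must be non-negative")
  mu <- state[["mu"]]; mz <- state[["mz"]]; Z <- state[["Z"]]
  E <- state[["E"]]; N <- state[["N"]]
  p <- params
  s3 <- mirna_sums(mu, p)
  hu <- shifted_hill(Z, p$Z0u, p$nZu, p$lZu) *
        shifted_hill(S, p$S0u, p$nSu, p$lSu) *
        shifted_hill(N, p$N0u, p$nNu, p$lNu)
  hm <- shifted_hill(Z, p$Z0m, p$nZm, p$lZm) *
        shifted_hill(S, p$S0m, p$nSm, p$lSm) *
        shifted_hill(N, p$N0m, p$nNm, p$lNm) *
        shifted_hill(E, p$E0m, p$nEm, p$lEm)
  hE <- shifted_hill(Z, p$Z0E, p$nZE, p$lZE) *
        shifted_hill(N, p$N0E, p$nNE, p$lNE)
  c(mu = p$gu * hu - mz * s3[["Ymu"]] - p$ku * mu,
    mz = p$gm * hm - mz * s3[["Ym"]] - p$km * mz,
    Z  = p$gz * mz * s3[["L"]] - p$kz * Z,
    E  = p$gE * hE - p$kE * E,
    N  = p$gN - p$kN * N)
}

#' Log-uniform random initial states
#'
#' Samples each species log-uniformly over `[1e-2, 1.2] x` its maximal
#' unregulated level `g_X max(1, lambda_max)/k_X`; NFATc is started at its
#' (unique) fixed point `gN/kN`.
#'
#' @param params an `emt_params` list.
#' @param n number of states.
#' @param seed optional integer seed.
#' @return an `n x 5` matrix.
#' @export
random_initial_states <- function(params, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- params
  lmax <- max(1, p$lZm * p$lSm * p$lNm)
  hi <- 1.2 * c(p$gu * max(1, p$lNu) / p$ku,
                p$gm * lmax / p$km,
                p$gz * p$gm * lmax / (p$km * p$kz),
                p$gE * max(1, p$lNE) / p$kE,
                p$gN / p$kN)
  lo <- 0.01 * hi
  m <- vapply(1:5, function(j) exp(runif(n, log(lo[j]), log(hi[j]))),
              numeric(n))
  m <- matrix(m, nrow = n)
  m[, 5] <- p$gN / p$kN
  colnames(m) <- .state_names
  m
}

#' Find steady states by multi-start Newton iteration
#'
#' Damped Newton root finding on the mechanistic right-hand side from
#' log-uniformly sampled starting points (plus any supplied warm starts),
#' deduplicated at relative tolerance `dedup_tol` (levels floored at one
#' molecule), each root classified stable/unstable by the real part of the
#' Jacobian's leading eigenvalue against `eps_eig`.
#'
#' @param params an `emt_params` list.
#' @param S SNAIL level (molecules).
#' @param n_starts number of random starting points.
#' @param seed integer seed for the starts.
#' @param warm_starts optional matrix of additional starting points.
#' @param eps_eig stability tolerance (1/h).
#' @param dedup_tol relative deduplication tolerance.
#' @return data frame with columns mu, mz, Z, E, N, eig, stable, sorted by
#'   ascending ZEB mRNA.  Zero rows (with a warning) if no root converged.
#' @export
find_steady_states <- function(params, S, n_starts = 60, seed = 1,
                               warm_starts = NULL, eps_eig = 1e-6,
                               dedup_tol = 1e-2) {
  stopifnot(n_starts >= 1, S >= 0)
  starts <- random_initial_states(params, n_starts, seed)
  if (!is.null(warm_starts)) {
    warm_starts <- matrix(as.numeric(warm_starts), ncol = 5)
    starts <- rbind(warm_starts, starts)
  }
  m <- cpp_mech_steady_states(params, S, starts, 1e-8, dedup_tol, 200L)
  if (nrow(m) == 0) {
    warning("no steady state found from any start at S = ", S)
    return(data.frame(mu = numeric(0), mz = numeric(0), Z = numeric(0),
                      E = numeric(0), N = numeric(0), eig = numeric(0),
                      stable = logical(0)))
  }
  df <- as.data.frame(m)
  df$stable <- df$eig < -eps_eig
  df
}

#' Deterministic trajectory of the mechanistic model
#'
#' Integrates the ODEs with a stiff-capable adaptive solver
#' (`deSolve::lsoda`) under a constant (or piecewise-constant) SNAIL input.
#'
#' @param init named initial state (mu, mz, Z, E, N).
#' @param params an `emt_params` list.
#' @param S SNAIL level; either a single value or a data frame with
#'   columns `time`, `S` giving a piecewise-constant signal.
#' @param t_max simulation horizon (h).
#' @param dt_out output time step (h).
#' @return data frame: time, mu, mz, Z, E, N, S.
#' @export
simulate_model <- function(init, params, S, t_max, dt_out = 1) {
  stopifnot(t_max > 0)
  times <- seq(0, t_max, by = dt_out)
  s_fun <- if (is.data.frame(S)) {
    stopifnot(all(c("time", "S") %in% names(S)))
    function(t) S$S[findInterval(t, S$time, rightmost.closed = FALSE)]
  } else {
    force(S); function(t) S
  }
  dfun <- function(t, y, parms) {
    names(y) <- .state_names
    list(mech_rhs(pmax(y, 0), params, s_fun(t)))
  }
  out <- deSolve::lsoda(y = setNames(as.numeric(init[.state_names]), .state_names),
                        times = times, func = dfun, parms = NULL,
                        rtol = 1e-8, atol = 1e-6)
  if (attr(out, "istate")[1] < 0)
    stop("integrator failure after t = ", max(out[, "time"]))
  df <- as.data.frame(out)
  df$S <- vapply(df$time, s_fun, numeric(1))
  df
}

#' Epithelial resting state
#'
#' The unique stable steady state of the model at `S = 0` (high miR-200,
#' low ZEB).
#'
#' @param params an `emt_params` list.
#' @param seed seed for the multi-start search.
#' @return named state vector.
#' @export
epithelial_state <- function(params, seed = 1) {
  ss <- find_steady_states(params, 0, n_starts = 80, seed = seed)
  st <- ss[ss$stable, , drop = FALSE]
  if (nrow(st) != 1)
    warning("expected a unique stable state at S = 0, found ", nrow(st))
  unlist(st[1, .state_names])
}

#' First time a trajectory variable enters a band
#'
#' @param traj data frame from [simulate_model()].
#' @param var variable name (default ZEB mRNA).
#' @param lower,upper band bounds; `Inf`/` -Inf` allowed.
#' @return entry time (h), or `Inf` if the band is never entered.
#' @export
time_to_band <- function(traj, var = "mz", lower = -Inf, upper = Inf) {
  inside <- traj[[var]] >= lower & traj[[var]] <= upper
  if (!any(inside)) return(Inf)
  traj$time[which(inside)[1]]
}
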