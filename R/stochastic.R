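#' Euler-Maruyama simulation of the reduced (Z, mu) system
#'
#' Additive Gaussian white noise with per-variable amplitude proportional
#' to the variable's deterministic range (the span of its stable
#' fixed-point values at this SNAIL level; for a monostable system, the
#' fixed-point value itself), reflecting boundary at zero.  A
#' `"multiplicative"` noise mode (amplitude proportional to the current
#' level) is also available.  The itinerary of basins visited is computed
#' on the fly against a log-spaced basin-assignment grid built by
#' deterministic relaxation, and a visit histogram on the same grid is
#' accumulated for landscape estimation.
#'
#' @param params an `emt_params` list.
#' @param S SNAIL level (molecules).
#' @param sigma fractional noise amplitude (default 0.05).
#' @param dt time step (h).
#' @param hours simulated duration (h).
#' @param seed integer seed (full run is reproducible from it).
#' @param init `c(Z, mu)` start; defaults to the first attractor.
#' @param attractors optional data frame from [reduced_fixed_points()].
#' @param noise `"additive"` or `"multiplicative"`.
#' @param grid_n basin/landscape grid resolution per axis.
#' @param grid_span multiplicative padding of the attractor bounding box.
#' @return an `emt_sde_run` list: `itinerary` (integer basin index per
#'   step, 0 = unresolved), `labels` (basin index -> phenotype),
#'   `hist`, `Zgrid`, `MuGrid`, `traj` (thinned), `dt`, `seed`.
#' @export
euler_maruyama <- function(params, S, sigma = 0.05, dt = 0.01, hours = 2e4,
                           seed = 1, init = NULL, attractors = NULL,
                           noise = c("additive", "multiplicative"),
                           grid_n = 100, grid_span = 30, basin_cache = NULL) {
  noise <- match.arg(noise)
  if (dt <= 0) stop("dt must be positive")
  if (sigma < 0) stop("sigma must be non-negative")
  if (is.null(attractors)) attractors <- reduced_fixed_points(params, S)
  if (!nrow(attractors)) stop("no stable attractor at S = ", S)
  a <- as.matrix(attractors[, c("Z", "mu")])
  if (is.null(basin_cache)) basin_cache <- basin_grid(params, S, attractors,
                                                      grid_n, grid_span)
  Zg <- basin_cache$Zgrid
  Ug <- basin_cache$MuGrid
  basin <- basin_cache$basin
  rng <- function(v) if (nrow(a) > 1) diff(range(v)) else v[1]
  sig <- switch(noise,
                additive = c(sigma * rng(a[, 1]), sigma * rng(a[, 2])),
                multiplicative = c(sigma, sigma))
  if (is.null(init)) init <- a[1, ]
  # deterministic-step size check (logged, not fatal)
  d0 <- cpp_red_drift(init[1], init[2], params, S)
  if (any(abs(d0[1:2]) * dt > 0.1 * pmax(init, 1)))
    warning("dt may be too coarse: deterministic step exceeds 10% of state")
  set.seed(seed)
  r <- cpp_red_em(params, S, init[1], init[2], sig[1], sig[2], dt,
                  round(hours / dt), Zg, Ug, basin, 100L,
                  noise == "multiplicative")
  structure(list(itinerary = r$itinerary,
                 labels = attractors$label,
                 hist = r$hist, Zgrid = Zg, MuGrid = Ug,
                 traj = r$traj, final = r$final, dt = dt, seed = seed,
                 sigma = sig, S = S, attractors = attractors),
            class = "emt_sde_run")
}

#' Basin-assignment grid of the reduced system
#'
#' Log-spaced grid over (Z, mu) covering the attractor bounding box with
#' multiplicative padding; each cell is assigned to the basin of the
#' attractor a deterministic relaxation from it converges to (0 where the
#' relaxation does not resolve within the horizon).  Build once per
#' (parameters, SNAIL) and pass to [euler_maruyama()] via `basin_cache`
#' when running many seeds.
#'
#' @param params an `emt_params` list.
#' @param S SNAIL level.
#' @param attractors data frame from [reduced_fixed_points()].
#' @param grid_n cells per axis.
#' @param grid_span multiplicative padding.
#' @param horizon relaxation horizon (h).
#' @return list: `basin` (integer matrix), `Zgrid`, `MuGrid`,
#'   `unresolved` count.
#' @export
basin_grid <- function(params, S, attractors, grid_n = 100, grid_span = 30,
                       horizon = 800) {
  a <- as.matrix(attractors[, c("Z", "mu")])
  Zg <- exp(seq(log(max(min(a[, 1]) / grid_span, 1)),
                log(max(a[, 1]) * grid_span), length.out = grid_n))
  Ug <- exp(seq(log(max(min(a[, 2]) / grid_span, 1)),
                log(max(a[, 2]) * grid_span), length.out = grid_n))
  b <- cpp_red_basin_grid(params, S, a, Zg, Ug, horizon, 0.05, 0.35)
  list(basin = b, Zgrid = Zg, MuGrid = Ug, unresolved = sum(b == 0))
}

#' Coarse-grained basin itinerary of a stochastic run
#'
#' @param run an `emt_sde_run`.
#' @return factor vector of phenotype labels per time step (`NA` where the
#'   relaxation grid could not resolve a basin).
#' @export
coarse_grain <- function(run) {
  lv <- run$labels
  f <- factor(ifelse(run$itinerary == 0, NA, lv[pmax(run$itinerary, 1)]),
              levels = unique(lv))
  attr(f, "dt") <- run$dt
  f
}

#' Mean residence times and occupancy fractions of an itinerary
#'
#' Contiguous runs of each basin label are collected; the mean residence
#' time of a state is its mean run length times the step size, the
#' occupancy fraction its total step share.  States never visited are
#' reported as `NA` (absent), not zero.
#'
#' @param itinerary factor from [coarse_grain()] (or any label vector).
#' @param dt step size in hours (taken from the itinerary attribute if
#'   present).
#' @return data frame: state, mrt (h), fraction, n_visits.
#' @export
mean_residence_time <- function(itinerary, dt = NULL) {
  if (is.null(dt)) dt <- attr(itinerary, "dt")
  if (is.null(dt)) stop("dt must be supplied")
  if (!length(itinerary)) stop("empty itinerary")
  lev <- if (is.factor(itinerary)) levels(itinerary) else unique(itinerary)
  x <- as.character(itinerary)
  r <- rle(x)
  keep <- !is.na(r$values)
  out <- lapply(lev, function(s) {
    sel <- keep & r$values == s
    if (!any(sel))
      return(data.frame(state = s, mrt = NA_real_, fraction = 0,
                        n_visits = 0L))
    data.frame(state = s, mrt = mean(r$lengths[sel]) * dt,
               fraction = sum(r$lengths[sel]) / length(x),
               n_visits = sum(sel))
  })
  out <- do.call(rbind, out)
  # unresolved steps are excluded from the labelled fractions; renormalise
  tot <- sum(out$fraction)
  if (tot > 0) out$fraction <- out$fraction / tot
  out
}

# gaussian smoothing of a matrix in index space (reflecting edges)
.smooth2d <- function(m, bw = 1.5) {
  r <- ceiling(3 * bw)
  k <- dnorm(seq(-r, r), sd = bw)
  k <- k / sum(k)
  pad <- function(v, n) c(rev(v[seq_len(n)]), v, rev(v[seq(length(v) - n + 1, length(v))]))
  conv1 <- function(v) {
    vp <- pad(v, r)
    vapply(seq_along(v), function(i) sum(vp[i:(i + 2 * r)] * k), numeric(1))
  }
  m <- apply(m, 2, conv1)
  t(apply(m, 1, conv1))
}

#' Quasi-potential landscape and barrier heights
#'
#' `U = -ln P` from the kernel-smoothed visit histogram of one or more
#' runs (shifted so min U = 0).  Minima are local minima of U matched to
#' the deterministic attractors on the grid; the saddle between two minima
#' is found by flooding: cells are added in order of increasing U and the
#' level at which two minima's components merge is the saddle level.  The
#' barrier of a state is the lowest such saddle level minus its minimum.
#'
#' @param runs an `emt_sde_run` or list of runs on the same grid.
#' @param bw Gaussian smoothing bandwidth in cells.
#' @return list: `U` matrix (Inf where unvisited), `Zgrid`, `MuGrid`,
#'   `minima` (data frame: label, iZ, iMu, U), `barriers` (named vector).
#' @export
quasi_potential <- function(runs, bw = 1.5) {
  if (inherits(runs, "emt_sde_run")) runs <- list(runs)
  h <- Reduce(`+`, lapply(runs, `[[`, "hist"))
  run1 <- runs[[1]]
  visited <- h > 0
  hs <- .smooth2d(h, bw)
  P <- hs / sum(hs)
  U <- -log(P)
  U[!visited & !(.smooth2d(visited + 0, bw) > 1e-3)] <- Inf
  U <- U - min(U[is.finite(U)])
  # match attractors to local minima: nearest grid cell, then steepest
  # descent to the local minimum
  att <- run1$attractors
  lZ <- log(run1$Zgrid); lU <- log(run1$MuGrid)
  n1 <- nrow(U); n2 <- ncol(U)
  descend <- function(i, j) {
    repeat {
      ni <- pmin(pmax(i + c(-1, 1, 0, 0), 1), n1)
      nj <- pmin(pmax(j + c(0, 0, -1, 1), 1), n2)
      v <- U[cbind(ni, nj)]
      b <- which.min(v)
      # move only strictly downhill so plateaus terminate
      if (!is.finite(v[b]) || v[b] >= U[i, j]) return(c(i, j))
      i <- ni[b]; j <- nj[b]
    }
  }
  minima <- do.call(rbind, lapply(seq_len(nrow(att)), function(k) {
    i <- which.min(abs(lZ - log(max(att$Z[k], 1))))
    j <- which.min(abs(lU - log(max(att$mu[k], 1))))
    ij <- descend(i, j)
    data.frame(label = att$label[k], iZ = ij[1], iMu = ij[2],
               U = U[ij[1], ij[2]])
  }))
  barriers <- setNames(rep(NA_real_, nrow(minima)), minima$label)
  if (nrow(minima) > 1) {
    # flood cells in order of increasing U; union-find over grid cells
    ord <- order(U)
    finite <- is.finite(U[ord])
    ord <- ord[finite]
    parent <- integer(n1 * n2)
    findp <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    added <- logical(n1 * n2)
    mincell <- (minima$iMu - 1) * n1 + minima$iZ
    saddle <- matrix(NA_real_, nrow(minima), nrow(minima))
    pending <- sum(upper.tri(saddle))
    for (cell in ord) {
      parent[cell] <- cell
      added[cell] <- TRUE
      i <- (cell - 1) %% n1 + 1
      j <- (cell - 1) %/% n1 + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        i2 <- i + d[1]; j2 <- j + d[2]
        if (i2 < 1 || i2 > n1 || j2 < 1 || j2 > n2) next
        c2 <- (j2 - 1) * n1 + i2
        if (!added[c2]) next
        r1 <- findp(cell); r2 <- findp(c2)
        if (r1 != r2) {
          # before merging, check whether this connects two minima
          for (a in seq_len(nrow(minima) - 1)) for (b in seq((a + 1), nrow(minima))) {
            if (!is.na(saddle[a, b])) next
            if (!added[mincell[a]] || !added[mincell[b]]) next
            ra <- findp(mincell[a]); rb <- findp(mincell[b])
            if ((ra == r1 && rb == r2) || (ra == r2 && rb == r1)) {
              saddle[a, b] <- saddle[b, a] <- U[cell]
              pending <- pending - 1
            }
          }
          parent[r2] <- r1
        }
      }
      if (pending == 0) break
    }
    for (k in seq_len(nrow(minima))) {
      s <- min(saddle[k, -k], na.rm = TRUE)
      barriers[k] <- s - minima$U[k]
    }
  }
  list(U = U, Zgrid = run1$Zgrid, MuGrid = run1$MuGrid,
       minima = minima, barriers = barriers)
}

#' Mean-residence-time and landscape analysis at one SNAIL level
#'
#' Runs seeded Euler-Maruyama simulations started at each attractor,
#' pools the itineraries for residence-time statistics, and estimates the
#' quasi-potential barriers from the pooled histograms.
#'
#' @param params an `emt_params` list.
#' @param S SNAIL level.
#' @param sigma fractional noise amplitude.
#' @param hours duration per run (h).
#' @param dt step (h).
#' @param seeds integer vector of seeds (averaged).
#' @param noise noise mode, see [euler_maruyama()].
#' @param labels optional attractor labels (ascending ZEB mRNA).
#' @return list: `mrt` data frame (pooled over seeds and starts),
#'   `barriers`, `attractors`, `potential`.
#' @export
mrt_analysis <- function(params, S, sigma = 0.05, hours = 2e4, dt = 0.01,
                         seeds = 1:5, noise = "additive", labels = NULL,
                         grid_n = 100) {
  att <- reduced_fixed_points(params, S, labels = labels)
  bg <- basin_grid(params, S, att, grid_n = grid_n)
  runs <- list()
  its <- list()
  for (sd in seeds) {
    for (k in seq_len(nrow(att))) {
      r <- euler_maruyama(params, S, sigma = sigma, dt = dt, hours = hours,
                          seed = sd * 1000L + k,
                          init = c(att$Z[k], att$mu[k]),
                          attractors = att, noise = noise, basin_cache = bg)
      runs[[length(runs) + 1]] <- r
      its[[length(its) + 1]] <- as.character(coarse_grain(r))
    }
  }
  mrt <- mean_residence_time(factor(unlist(its), levels = att$label), dt = dt)
  pot <- quasi_potential(runs)
  list(mrt = mrt, barriers = pot$barriers, attractors = att, potential = pot)
}
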