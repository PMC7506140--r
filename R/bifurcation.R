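#' Sweep the SNAIL control parameter and assemble solution branches
#'
#' At each grid value, steady states are found by multi-start Newton
#' iteration warm-started from the neighbouring grid point (the sweep runs
#' once upward and once downward so branches are picked up on whichever
#' side they are easiest to reach from).  Stable states are linked into
#' branches by nearest-neighbour continuation in log ZEB-mRNA; ties are
#' broken towards the smaller jump.  Branches are labelled by identity:
#' the branch reaching the lowest SNAIL values with the lowest ZEB mRNA is
#' epithelial (E), the branch present at the high-SNAIL end with the
#' highest ZEB mRNA is mesenchymal (M), every other stable branch is
#' hybrid (H).
#'
#' @param params an `emt_params` list.
#' @param S_grid increasing vector of SNAIL values (>= 50 points
#'   recommended).
#' @param n_starts random starts per grid point and direction.
#' @param seed seed for the random starts.
#' @param link_tol maximal |log mz| jump linked into one branch.
#' @return an `emt_sweep` object: `states` (one row per steady state:
#'   S, mu, mz, Z, E, N, eig, stable, branch, label), `S_grid`, `phases`
#'   (per-S character of coexisting stable phenotypes), `fold_points`.
#' @export
sweep_bifurcation <- function(params, S_grid, n_starts = 40, seed = 1,
                              link_tol = 0.8) {
  stopifnot(!is.unsorted(S_grid, strictly = TRUE))
  starts <- random_initial_states(params, n_starts, seed)
  scan <- function(Sseq) {
    carry <- NULL
    out <- vector("list", length(Sseq))
    for (i in seq_along(Sseq)) {
      st <- if (is.null(carry)) starts else rbind(carry, starts)
      m <- cpp_mech_steady_states(params, Sseq[i], st, 1e-8, 1e-2, 200L)
      out[[i]] <- m
      if (nrow(m)) carry <- m[, 1:5, drop = FALSE]
    }
    names(out) <- as.character(Sseq)
    out
  }
  up <- scan(S_grid)
  dn <- scan(rev(S_grid))
  rows <- lapply(as.character(S_grid), function(k) {
    m <- rbind(up[[k]], dn[[k]])
    if (!nrow(m)) return(NULL)
    # merge the two directions
    keep <- rep(TRUE, nrow(m))
    lg <- log(pmax(m[, 1:5, drop = FALSE], 1))
    for (i in seq_len(nrow(m))[-1])
      for (j in seq_len(i - 1))
        if (keep[j] && max(abs(lg[i, ] - lg[j, ])) < 0.05) { keep[i] <- FALSE; break }
    df <- as.data.frame(m[keep, , drop = FALSE])
    df$S <- as.numeric(k)
    df[order(df$mz), ]
  })
  states <- do.call(rbind, rows)
  states$stable <- states$eig < -1e-6
  states$branch <- NA_integer_
  # continuation linking of stable states
  active <- list()   # branch id -> last log mz
  next_id <- 1L
  for (S in S_grid) {
    idx <- which(states$S == S & states$stable)
    if (!length(idx)) { active <- list(); next }
    lmz <- log(pmax(states$mz[idx], 1))
    used <- character(0)
    ord <- order(lmz)
    for (i in idx[ord]) {
      l <- log(max(states$mz[i], 1))
      best <- NULL; bestd <- link_tol
      for (b in setdiff(names(active), used)) {
        d <- abs(l - active[[b]])
        if (d < bestd) { bestd <- d; best <- b }
      }
      if (is.null(best)) {
        best <- as.character(next_id)
        next_id <- next_id + 1L
      }
      states$branch[i] <- as.integer(best)
      used <- c(used, best)
      active[[best]] <- l
    }
    active <- active[as.character(states$branch[idx])]
  }
  # label branches
  st <- states[states$stable, ]
  lab <- setNames(rep("H", length(unique(st$branch))),
                  as.character(sort(unique(st$branch))))
  lowS <- st[st$S == min(st$S), ]
  if (nrow(lowS)) lab[as.character(lowS$branch[which.min(lowS$mz)])] <- "E"
  hiS <- st[st$S == max(st$S), ]
  if (nrow(hiS)) lab[as.character(hiS$branch[which.max(hiS$mz)])] <- "M"
  states$label <- NA_character_
  sel <- states$stable
  states$label[sel] <- lab[as.character(states$branch[sel])]
  phases <- vapply(S_grid, function(S) {
    l <- sort(unique(states$label[states$S == S & states$stable]))
    if (!length(l)) "-" else paste(l, collapse = "")
  }, character(1))
  counts <- vapply(S_grid, function(S) sum(states$S == S & states$stable),
                   integer(1))
  folds <- S_grid[which(diff(counts) != 0)] +
    diff(S_grid)[pmin(which(diff(counts) != 0), length(S_grid) - 1)] / 2
  structure(list(states = states, S_grid = S_grid, phases = phases,
                 stable_counts = counts, fold_points = folds,
                 params = params),
            class = "emt_sweep")
}

#' @export
print.emt_sweep <- function(x, ...) {
  r <- rle(x$phases)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  cat("SNAIL sweep,", length(x$S_grid), "grid points; phase regions:\n")
  for (i in seq_along(r$values))
    cat(sprintf("  {%s}: S in [%g, %g]\n", r$values[i],
                x$S_grid[starts[i]], x$S_grid[ends[i]]))
  invisible(x)
}

#' Phase diagram of a sweep
#'
#' @param sweep an `emt_sweep`.
#' @return data frame: S, phase, n_stable; `fold_points` attribute.
#' @export
phase_diagram <- function(sweep) {
  structure(data.frame(S = sweep$S_grid, phase = sweep$phases,
                       n_stable = sweep$stable_counts),
            fold_points = sweep$fold_points)
}

#' ZEB-mRNA bands of the three phenotypes
#'
#' Bands are derived from the model's own bifurcation diagram: epithelial
#' below the lowest hybrid-branch ZEB-mRNA value, mesenchymal above the
#' highest, hybrid between.
#'
#' @param sweep an `emt_sweep` with a hybrid branch.
#' @return named vector `c(lower, upper)` of the hybrid band.
#' @export
phenotype_bands <- function(sweep) {
  h <- sweep$states[sweep$states$stable & sweep$states$label == "H", "mz"]
  if (!length(h)) stop("sweep has no hybrid branch")
  c(lower = min(h), upper = max(h))
}

#' SNAIL interval supporting a stable hybrid state
#'
#' The union of grid regions whose phase contains H, with both endpoints
#' refined by bisection on the stable-state count between the bracketing
#' grid points (to 0.1 percent of the grid span by default).
#'
#' @param sweep an `emt_sweep`.
#' @param refine logical; bisect the endpoints.
#' @param rel_tol endpoint resolution as a fraction of the grid span.
#' @param n_starts,seed multi-start settings for the bisection probes.
#' @return numeric `c(S_lo, S_hi)` with attribute `length`; an empty
#'   interval (length 0, NA bounds) if no hybrid state exists.
#' @export
hybrid_interval <- function(sweep, refine = TRUE, rel_tol = 1e-3,
                            n_starts = 40, seed = 1) {
  hasH <- grepl("H", sweep$phases)
  if (!any(hasH)) {
    out <- c(S_lo = NA_real_, S_hi = NA_real_)
    attr(out, "length") <- 0
    return(out)
  }
  S <- sweep$S_grid
  lo <- S[which(hasH)[1]]
  hi <- S[tail(which(hasH), 1)]
  tol <- rel_tol * diff(range(S))
  bisect <- function(S_out, S_in) {
    # invariant: hybrid present at S_in, absent at S_out
    n_in <- sum(sweep$states$S == S_in & sweep$states$stable)
    while (abs(S_in - S_out) > tol) {
      mid <- (S_in + S_out) / 2
      ss <- find_steady_states(sweep$params, mid, n_starts = n_starts,
                               seed = seed)
      if (sum(ss$stable) >= n_in) S_in <- mid else S_out <- mid
    }
    (S_in + S_out) / 2
  }
  if (refine) {
    i <- which(hasH)[1]
    if (i > 1) lo <- bisect(S[i - 1], S[i])
    j <- tail(which(hasH), 1)
    if (j < length(S)) hi <- bisect(S[j + 1], S[j])
  }
  out <- c(S_lo = lo, S_hi = hi)
  attr(out, "length") <- hi - lo
  out
}

#' Single-parameter sensitivity of the hybrid SNAIL window
#'
#' Every continuous scalar parameter is varied one at a time by
#' `+/- delta` (integer Hill cooperativities are excluded), the bifurcation
#' sweep is recomputed, and the percent change of the hybrid-interval
#' length is reported.  The attribute `reference` carries the
#' core-vs-coupled comparison `100 (len_core - len_coupled)/len_coupled`
#' computed at the same settings.
#'
#' @param params coupled-circuit `emt_params`.
#' @param delta relative perturbation (default 0.10).
#' @param S_grid sweep grid.
#' @param parameters which scalars to perturb (default: all continuous).
#' @param refine refine interval endpoints by bisection.
#' @param n_starts,seed multi-start settings.
#' @return data frame (parameter, direction, percent_change) with
#'   attributes `baseline_length` and `reference`.
#' @export
sensitivity_analysis <- function(params, delta = 0.10,
                                 S_grid = seq(0, 5e5, length.out = 101),
                                 parameters = .scalar_par_names(),
                                 refine = TRUE, n_starts = 30, seed = 1) {
  ivl <- function(p) {
    sw <- sweep_bifurcation(p, S_grid, n_starts = n_starts, seed = seed)
    as.numeric(attr(hybrid_interval(sw, refine = refine,
                                    n_starts = n_starts, seed = seed),
                    "length"))
  }
  base_len <- ivl(params)
  if (base_len <= 0) stop("baseline hybrid interval is empty")
  core_len <- ivl(core_reduction(params))
  rows <- list()
  for (nm in parameters) {
    for (dir in c(1, -1)) {
      p2 <- params
      p2[[nm]] <- p2[[nm]] * (1 + dir * delta)
      len <- if (delta == 0) base_len else tryCatch(ivl(p2), error = function(e) NA_real_)
      if (is.na(len)) {
        warning("perturbed model lost all steady states: ", nm)
        len <- 0
      }
      rows[[length(rows) + 1]] <-
        data.frame(parameter = nm,
                   direction = sprintf("%+g%%", 100 * dir * delta),
                   percent_change = 100 * (len - base_len) / base_len)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "baseline_length") <- base_len
  attr(out, "reference") <- 100 * (core_len - base_len) / base_len
  out
}
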