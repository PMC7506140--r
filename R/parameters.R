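#' Default calibrated parameters of the mechanistic EMT-NFATc model
#'
#' State variables are miR-200 (`mu`), ZEB mRNA (`mz`), ZEB protein (`Z`),
#' E-cadherin (`E`) and NFATc (`N`); SNAIL (`S`) is a clamped external
#' input.  Units are molecules and hours.
#'
#' The miR-200/ZEB/SNAIL core uses the published binding-site model values
#' for the microRNA arm (six sites, translation factors `l_i`, active mRNA
#' degradation `gamma_m`, duplex co-degradation `gamma_mu`) and shifted-Hill
#' blocks for transcriptional edges.  Two core values are calibrated
#' (SNAIL Hill cooperativities set to 1) and all NFATc/E-cadherin coupling
#' fold-changes are calibrated, so that the coupled circuit is multistable
#' around SNAIL = 323-380 thousand molecules and maintains a wider hybrid
#' window than the core; none of these numbers is an experimentally
#' measured constant.
#'
#' Hill blocks are named by regulator and target: e.g. `Z0u/nZu/lZu` is the
#' ZEB -| miR-200 block (threshold/cooperativity/fold-change), `S0m/nSm/lSm`
#' SNAIL -> ZEB mRNA, `N0E/nNE/lNE` NFATc -> E-cadherin, `E0m/nEm/lEm`
#' E-cadherin -| ZEB mRNA.
#'
#' @param circuit `"coupled"` (with NFATc and E-cadherin arms) or `"core"`
#'   (all coupling fold-changes set to 1).
#' @return a named list of class `emt_params`.
#' @export
default_parameters <- function(circuit = c("coupled", "core")) {
  circuit <- match.arg(circuit)
  p <- list(
    # production (molecules/h; gz is a per-mRNA translation rate 1/h)
    gu = 2100, gm = 11, gz = 100, gE = 4000, gN = 5000,
    # first-order degradation (1/h)
    ku = 0.05, km = 0.5, kz = 0.1, kE = 0.1, kN = 0.1,
    # ZEB -| miR-200
    Z0u = 220000, nZu = 3, lZu = 0.1,
    # SNAIL -| miR-200
    S0u = 180000, nSu = 1, lSu = 0.1,
    # NFATc -> miR-200
    N0u = 50000, nNu = 2, lNu = 1.6,
    # ZEB -> ZEB mRNA (self-activation)
    Z0m = 25000, nZm = 2, lZm = 7.5,
    # SNAIL -> ZEB mRNA
    S0m = 180000, nSm = 1, lSm = 10,
    # NFATc -> ZEB mRNA
    N0m = 50000, nNm = 2, lNm = 1.15,
    # E-cadherin -| ZEB mRNA (indirect)
    E0m = 50000, nEm = 2, lEm = 0.85,
    # ZEB -| E-cadherin
    Z0E = 150000, nZE = 2, lZE = 0.05,
    # NFATc -> E-cadherin
    N0E = 50000, nNE = 2, lNE = 4,
    # microRNA binding-site coupling (miR-200 on ZEB mRNA, 6 sites)
    mu0 = 10000,
    l_i      = c(1, 0.6, 0.3, 0.1, 0.05, 0.05, 0.05),
    gamma_m  = c(0, 0.04, 0.2, 1, 1, 1, 1),
    gamma_mu = c(0, 0.005, 0.05, 0.5, 0.5, 0.5, 0.5))
  class(p) <- c("emt_params", "list")
  attr(p, "circuit") <- circuit
  if (circuit == "core") p <- core_reduction(p)
  validate_parameters(p)
  p
}

#' Reduce coupled parameters to the core circuit
#'
#' Sets every coupling fold-change of the NFATc/E-cadherin extension
#' (NFATc -> miR-200/ZEB/E-cadherin and E-cadherin -| ZEB) to 1, making the
#' (miR-200, ZEB mRNA, ZEB protein) dynamics identical to the 3-node core
#' model.
#'
#' @param params an `emt_params` list.
#' @return the reduced parameter list, tagged `circuit = "core"`.
#' @export
core_reduction <- function(params) {
  params$lNu <- 1
  params$lNm <- 1
  params$lNE <- 1
  params$lEm <- 1
  attr(params, "circuit") <- "core"
  params
}

.scalar_par_names <- function() {
  c("gu", "gm", "gz", "gE", "gN", "ku", "km", "kz", "kE", "kN",
    "Z0u", "lZu", "S0u", "lSu", "N0u", "lNu",
    "Z0m", "lZm", "S0m", "lSm", "N0m", "lNm",
    "E0m", "lEm", "Z0E", "lZE", "N0E", "lNE", "mu0")
}

#' Validate a mechanistic parameter list
#'
#' Checks positivity of rates and thresholds, Hill cooperativities >= 1,
#' and the shape constraints of the microRNA coupling vectors
#' (length n_sites+1, `l_i[1] == 1` and non-increasing, `gamma_m[1] == 0`
#' and non-decreasing, `gamma_mu[1] == 0`, all non-negative).
#'
#' @param params an `emt_params` list.
#' @return `params`, invisibly; stops on violation.
#' @export
validate_parameters <- function(params) {
  rates <- c("gu", "gm", "gz", "gE", "gN", "ku", "km", "kz", "kE", "kN")
  for (nm in rates)
    if (!is.numeric(params[[nm]]) || params[[nm]] <= 0)
      stop("parameter ", nm, " must be positive")
  for (nm in grep("^[A-Z]0|^mu0", .scalar_par_names(), value = TRUE))
    if (params[[nm]] <= 0) stop("threshold ", nm, " must be positive")
  for (nm in c("nZu", "nSu", "nNu", "nZm", "nSm", "nNm", "nEm", "nZE", "nNE"))
    if (params[[nm]] < 1) stop("cooperativity ", nm, " must be >= 1")
  for (nm in c("lZu", "lSu", "lNu", "lZm", "lSm", "lNm", "lEm", "lZE", "lNE"))
    if (params[[nm]] <= 0) stop("fold change ", nm, " must be positive")
  nsite <- length(params$l_i) - 1
  if (nsite < 1) stop("l_i must have length n_sites + 1 >= 2")
  for (nm in c("l_i", "gamma_m", "gamma_mu")) {
    v <- params[[nm]]
    if (length(v) != nsite + 1) stop(nm, " must have length ", nsite + 1)
    if (any(v < 0)) stop(nm, " must be non-negative")
  }
  if (params$l_i[1] != 1) stop("l_i[1] (zero occupancy) must equal 1")
  if (is.unsorted(rev(params$l_i))) stop("l_i must be non-increasing")
  if (params$gamma_m[1] != 0 || params$gamma_mu[1] != 0)
    stop("gamma_m[1] and gamma_mu[1] must be 0")
  if (is.unsorted(params$gamma_m)) stop("gamma_m must be non-decreasing")
  invisible(params)
}

#' Write parameters as tab-separated name/value pairs
#'
#' Vector-valued entries (the microRNA coupling vectors) are written one
#' element per row as `name.index`.
#'
#' @param params an `emt_params` list.
#' @param path output path.
#' @export
write_parameters <- function(params, path) {
  rows <- list()
  for (nm in names(params)) {
    v <- params[[nm]]
    if (length(v) == 1) {
      rows[[nm]] <- data.frame(name = nm, value = v)
    } else {
      rows[[nm]] <- data.frame(name = sprintf("%s.%d", nm, seq_along(v) - 1),
                               value = v)
    }
  }
  df <- do.call(rbind, rows)
  df$value <- format(df$value, digits = 15, scientific = FALSE, trim = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read parameters written by [write_parameters()]
#'
#' @param path file path.
#' @param circuit circuit tag to attach.
#' @return an `emt_params` list.
#' @export
read_parameters <- function(path, circuit = "coupled") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  p <- list()
  plain <- !grepl("\\.", df$name)
  for (i in which(plain)) p[[df$name[i]]] <- as.numeric(df$value[i])
  vec <- df[!plain, , drop = FALSE]
  if (nrow(vec)) {
    base <- sub("\\.[0-9]+$", "", vec$name)
    idx <- as.integer(sub("^.*\\.", "", vec$name))
    for (nm in unique(base)) {
      sel <- base == nm
      v <- numeric(max(idx[sel]) + 1)
      v[idx[sel] + 1] <- as.numeric(vec$value[sel])
      p[[nm]] <- v
    }
  }
  class(p) <- c("emt_params", "list")
  attr(p, "circuit") <- circuit
  validate_parameters(p)
  p
}
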