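#' Regulatory edge of a gene-circuit topology
#'
#' An edge carries a sign (activation or inhibition) and a mechanism tag:
#' transcriptional, indirect (e.g. via beta-catenin sequestration) or
#' microRNA-mediated (binding-site) regulation.
#'
#' @param source,target node names.
#' @param sign `"activation"` or `"inhibition"`.
#' @param mechanism `"transcriptional"`, `"indirect"` or `"mirna"`.
#' @return a one-row data frame.
#' @export
regulatory_edge <- function(source, target, sign,
                            mechanism = "transcriptional") {
  sign <- match.arg(sign, c("activation", "inhibition"))
  mechanism <- match.arg(mechanism, c("transcriptional", "indirect", "mirna"))
  data.frame(source = source, target = target, sign = sign,
             mechanism = mechanism, stringsAsFactors = FALSE)
}

#' Construct and validate a network topology
#'
#' @param nodes ordered character vector of node names.
#' @param edges data frame with columns source, target, sign, mechanism.
#' @return an `emt_topology` object.
#' @export
network_topology <- function(nodes, edges) {
  stopifnot(is.character(nodes), length(nodes) >= 1, !anyDuplicated(nodes))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  req <- c("source", "target", "sign")
  if (!all(req %in% names(edges)))
    stop("edges must have columns source, target, sign")
  if (is.null(edges$mechanism)) edges$mechanism <- "transcriptional"
  bad <- setdiff(unique(c(edges$source, edges$target)), nodes)
  if (length(bad))
    stop("edge references unknown node(s): ", paste(bad, collapse = ", "))
  if (!all(edges$sign %in% c("activation", "inhibition")))
    stop("edge sign must be activation or inhibition")
  if (!all(edges$mechanism %in% c("transcriptional", "indirect", "mirna")))
    stop("edge mechanism must be transcriptional, indirect or mirna")
  key <- paste(edges$source, edges$target)
  if (anyDuplicated(key))
    stop("duplicate edge(s): ", paste(unique(key[duplicated(key)]), collapse = "; "))
  structure(list(nodes = nodes, edges = edges), class = "emt_topology")
}

#' @export
print.emt_topology <- function(x, ...) {
  cat(sprintf("network topology: %d nodes, %d edges (%d activation, %d inhibition)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "activation"),
              sum(x$edges$sign == "inhibition")))
  cat("nodes:", paste(x$nodes, collapse = ", "), "\n")
  invisible(x)
}

#' Wild-type coupled EMT-NFATc topology
#'
#' Five nodes, eleven edges (six activating, five inhibiting).  NFATc
#' activates ZEB, miR-200, E-cadherin and SNAIL; SNAIL activates ZEB and
#' represses miR-200; ZEB self-activates, represses miR-200 and E-cadherin;
#' miR-200 silences ZEB (microRNA mechanism); E-cadherin restrains ZEB
#' indirectly.
#'
#' @return an `emt_topology`.
#' @export
wildtype_topology <- function() {
  e <- rbind(
    regulatory_edge("SNAIL",  "ZEB",    "activation"),
    regulatory_edge("SNAIL",  "miR200", "inhibition"),
    regulatory_edge("ZEB",    "miR200", "inhibition"),
    regulatory_edge("miR200", "ZEB",    "inhibition", "mirna"),
    regulatory_edge("ZEB",    "ZEB",    "activation"),
    regulatory_edge("ZEB",    "Ecad",   "inhibition"),
    regulatory_edge("Ecad",   "ZEB",    "inhibition", "indirect"),
    regulatory_edge("NFATc",  "ZEB",    "activation"),
    regulatory_edge("NFATc",  "miR200", "activation"),
    regulatory_edge("NFATc",  "Ecad",   "activation"),
    regulatory_edge("NFATc",  "SNAIL",  "activation"))
  network_topology(c("SNAIL", "miR200", "ZEB", "Ecad", "NFATc"), e)
}

#' Core EMT topology (miR-200/ZEB/SNAIL)
#' @return an `emt_topology`.
#' @export
core_topology <- function() {
  e <- rbind(
    regulatory_edge("SNAIL",  "ZEB",    "activation"),
    regulatory_edge("SNAIL",  "miR200", "inhibition"),
    regulatory_edge("ZEB",    "miR200", "inhibition"),
    regulatory_edge("miR200", "ZEB",    "inhibition", "mirna"),
    regulatory_edge("ZEB",    "ZEB",    "activation"))
  network_topology(c("SNAIL", "miR200", "ZEB"), e)
}

.mech_codes <- c(transcriptional = "T", indirect = "I", mirna = "R")

#' Read a topology file
#'
#' Whitespace-delimited text with header `Source Target Type`, where Type is
#' 1 (activation) or 2 (inhibition).  An optional fourth column `Mechanism`
#' in {T, I, R} is accepted and defaults to T.
#'
#' @param path file path.
#' @return an `emt_topology`.
#' @export
read_topo <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty topology file: ", path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 3 || !identical(tolower(hdr[1:3]), c("source", "target", "type")))
    stop("malformed header (line 1): expected 'Source Target Type'")
  has_mech <- length(hdr) >= 4 && tolower(hdr[4]) == "mechanism"
  if (length(lines) == 1) {
    warning("topology file has no edges: ", path)
    nodes <- character(0)
    return(structure(list(nodes = nodes,
                          edges = data.frame(source = character(0),
                                             target = character(0),
                                             sign = character(0),
                                             mechanism = character(0))),
                     class = "emt_topology"))
  }
  rows <- lapply(seq(2, length(lines)), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 3) stop("malformed row at line ", i, ": ", lines[i])
    if (!f[3] %in% c("1", "2"))
      stop("unknown Type code '", f[3], "' at line ", i, " (expected 1 or 2)")
    mech <- "T"
    if (has_mech && length(f) >= 4) mech <- f[4]
    if (!mech %in% c("T", "I", "R"))
      stop("unknown Mechanism code '", mech, "' at line ", i)
    data.frame(source = f[1], target = f[2],
               sign = c("activation", "inhibition")[as.integer(f[3])],
               mechanism = names(.mech_codes)[match(mech, .mech_codes)],
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, rows)
  nodes <- unique(c(edges$source, edges$target))
  network_topology(nodes, edges)
}

#' Write a topology file
#'
#' Inverse of [read_topo()]; always writes the Mechanism column so the
#' round-trip is lossless.
#'
#' @param topology an `emt_topology`.
#' @param path output path.
#' @export
write_topo <- function(topology, path) {
  stopifnot(inherits(topology, "emt_topology"))
  e <- topology$edges
  lines <- c("Source Target Type Mechanism",
             sprintf("%s %s %d %s", e$source, e$target,
                     ifelse(e$sign == "activation", 1L, 2L),
                     .mech_codes[e$mechanism]))
  writeLines(lines, path)
  invisible(path)
}
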