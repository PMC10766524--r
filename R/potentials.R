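# Atom-pairwise statistical potential and the attention bias it induces.
#
# The bias added to every attention logit is:
#   1                          for covalent edges,
#   2 * ln P(type_k, type_u, dist)   for virtual edges with covered types,
#   0.8                        when either type is uncovered.
# P is a distance-binned inverse-Boltzmann (frequency-ratio) potential
# fitted on ligand-pocket contacts; the original literature potential is
# pluggable through the same table interface.

#' Construct a PotentialTable
#' @param types atom-type alphabet (element symbols)
#' @param breaks distance-bin edges over (0, cutoff]
#' @param values positive array [type, type, bin], symmetric in types
#' @return a \linkS4class{PotentialTable}
#' @export
potentialTable <- function(types, breaks, values) {
  new("PotentialTable", types = types, breaks = breaks, values = values)
}

#' Look up P(type_k, type_u, dist)
#' @param table PotentialTable
#' @param typeK,typeU atom types (element symbols)
#' @param dist distance in Angstrom
#' @return the potential value, or NA when a type is uncovered or the
#'   distance falls outside the binned range
#' @export
lookupPotential <- function(table, typeK, typeU, dist) {
  i <- match(typeK, table@types)
  j <- match(typeU, table@types)
  b <- findInterval(dist, table@breaks, left.open = TRUE,
                    rightmost.closed = FALSE)
  nb <- length(table@breaks) - 1L
  bad <- is.na(i) | is.na(j) | b < 1L | b > nb
  out <- rep(NA_real_, length(dist))
  if (any(!bad)) {
    out[!bad] <- table@values[cbind(i[!bad], j[!bad], b[!bad])]
  }
  out
}

#' Attention bias term for an edge
#'
#' @param table PotentialTable
#' @param typeK,typeU atom types of the edge endpoints
#' @param dist edge length in Angstrom (must be > 0 for virtual edges)
#' @param edgeKind "covalent", "virtual_distance" or "virtual_aromatic"
#' @return scalar bias (vectorized over the inputs)
#' @export
pairwiseBias <- function(table, typeK, typeU, dist, edgeKind) {
  n <- max(length(typeK), length(typeU), length(dist), length(edgeKind))
  typeK <- rep_len(typeK, n); typeU <- rep_len(typeU, n)
  dist <- rep_len(dist, n); edgeKind <- rep_len(edgeKind, n)
  out <- numeric(n)
  cov <- edgeKind == "covalent"
  out[cov] <- table@covalentBias
  if (any(!cov)) {
    if (any(dist[!cov] <= 0)) stop("virtual edges require dist > 0")
    p <- lookupPotential(table, typeK[!cov], typeU[!cov], dist[!cov])
    val <- ifelse(is.na(p), table@fallbackBias, 2 * log(p))
    out[!cov] <- val
  }
  out
}

#' Fit a reference potential from observed complexes
#'
#' Inverse-Boltzmann estimator on the virtual-distance contacts of a set
#' of complex graphs: for each unordered type pair the observed contact
#' count per distance bin is divided by the count expected if that pair's
#' contacts were spread uniformly over the bins, with an additive
#' pseudocount; values are clipped to [1e-3, 1e3] and the table is
#' symmetrized by construction.
#'
#' @param complexes list of ComplexGraph objects with virtual_distance edges
#' @param binWidth distance-bin width in Angstrom (0.25)
#' @param cutoff upper distance limit (5.0)
#' @param pseudocount additive regularizer (1)
#' @return a \linkS4class{PotentialTable}
#' @export
fitReferencePotential <- function(complexes, binWidth = 0.25, cutoff = 5.0,
                                  pseudocount = 1) {
  contacts <- do.call(rbind, lapply(complexes, function(g) {
    e <- g@edges
    vd <- e$kind == "virtual_distance" & e$src < e$dst
    if (!any(vd)) return(NULL)
    data.frame(a = g@nodes$element[e$src[vd]],
               b = g@nodes$element[e$dst[vd]],
               d = e$dist[vd], stringsAsFactors = FALSE)
  }))
  if (is.null(contacts) || !nrow(contacts)) {
    stop("no virtual_distance edges observed")
  }
  breaks <- seq(0, cutoff, by = binWidth)
  types <- sort(unique(c(contacts$a, contacts$b)))
  nt <- length(types); nb <- length(breaks) - 1L
  bin <- findInterval(contacts$d, breaks, left.open = TRUE)
  keep <- bin >= 1L & bin <= nb
  contacts <- contacts[keep, , drop = FALSE]; bin <- bin[keep]
  counts <- array(0, c(nt, nt, nb))
  ia <- match(contacts$a, types); ib <- match(contacts$b, types)
  for (r in seq_along(bin)) {
    counts[ia[r], ib[r], bin[r]] <- counts[ia[r], ib[r], bin[r]] + 1
    if (ia[r] != ib[r]) {
      counts[ib[r], ia[r], bin[r]] <- counts[ib[r], ia[r], bin[r]] + 1
    }
  }
  # reference state: the type pair's contacts spread uniformly over the
  # distance bins, so P > 1 flags bins enriched above chance for that pair
  pairTotal <- apply(counts, c(1, 2), sum)
  vals <- array(1, c(nt, nt, nb))
  for (b in seq_len(nb)) {
    expected <- pairTotal / nb
    vals[, , b] <- (counts[, , b] + pseudocount) / (expected + pseudocount)
  }
  vals <- pmin(pmax(vals, 1e-3), 1e3)
  potentialTable(types, breaks, vals)
}

#' Serialize a potential table to JSON
#' @param table PotentialTable
#' @param file output path
#' @export
writePotentialTable <- function(table, file) {
  # 17 significant digits guarantee a bit-exact double round trip
  obj <- list(types = table@types,
              breaks = sprintf("%.17g", table@breaks),
              values = sprintf("%.17g", as.numeric(table@values)),
              covalentBias = table@covalentBias,
              fallbackBias = table@fallbackBias)
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' Read a potential table from JSON
#' @param file path written by \code{\link{writePotentialTable}}
#' @return a \linkS4class{PotentialTable}
#' @export
readPotentialTable <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  nt <- length(obj$types); nb <- length(obj$breaks) - 1L
  tab <- potentialTable(obj$types, as.numeric(obj$breaks),
                        array(as.numeric(obj$values), c(nt, nt, nb)))
  tab@covalentBias <- obj$covalentBias
  tab@fallbackBias <- obj$fallbackBias
  tab
}

#' Default bundled potential
#'
#' A small table fitted on synthetic congeneric fixtures (shipped as JSON
#' in \code{inst/extdata}) so the network runs with no external download.
#' @return a \linkS4class{PotentialTable}
#' @export
defaultPotential <- function() {
  f <- system.file("extdata", "default_potential.json",
                   package = "PocketPairNet")
  if (!nzchar(f)) stop("bundled potential not found")
  readPotentialTable(f)
}
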