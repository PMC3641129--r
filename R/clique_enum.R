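#' Enumerate maximal cliques of the PPI network
#'
#' All maximal cliques with at least `min_size` members, enumerated on the
#' original PPI network only (GO-slim dummy vertices never take part in
#' cliques). Output is deterministic: members of each clique sorted
#' lexicographically, cliques sorted by their member tuple, so downstream
#' density tie-breaking is reproducible.
#'
#' @param ppi a [ppi_network]
#' @param min_size smallest clique size to report (default 3)
#' @return list of character vectors, each a maximal clique
#' @export
maximal_cliques <- function(ppi, min_size = 3L) {
  stopifnot(inherits(ppi, "ppi_network"))
  if (min_size < 1L) stop("'min_size' must be at least 1")
  if (length(ppi$proteins) == 0L) return(list())
  g <- ppi_igraph(ppi)
  cl <- igraph::max_cliques(g, min = min_size)
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  keys <- vapply(cl, paste, "", collapse = "\r")
  cl[order(keys, method = "radix")]
}
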