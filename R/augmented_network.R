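#' Build an ontology augmented graph
#'
#' Augments a PPI network with one "dummy" vertex per GO-slim term,
#' connected by an annotation edge to every network protein it annotates.
#' Annotations of proteins absent from the network are dropped (and
#' reported via `message()`), as are terms left annotating no network
#' protein. The vertex order is the network's protein order followed by the
#' surviving terms in the annotation map's term order; dummy vertices are
#' never adjacent to each other.
#'
#' @param ppi a [ppi_network]
#' @param ann an [annotation_map] (may be empty)
#' @return an object of class `augmented_graph` with elements `network`,
#'   `annotations` (restricted map), `vertex_order`, `n_proteins`, `n_terms`
#' @export
build_augmented_graph <- function(ppi, ann = annotation_map()) {
  stopifnot(inherits(ppi, "ppi_network"), inherits(ann, "annotation_map"))
  known <- names(ann$by_protein) %in% ppi$proteins
  if (any(!known)) {
    message(sprintf(
      "build_augmented_graph: dropped annotations for %d protein(s) absent from the network",
      sum(!known)))
  }
  by_protein <- ann$by_protein[known]
  terms <- ann$terms[ann$terms %in% unlist(by_protein, use.names = FALSE)]
  restricted <- annotation_map(by_protein)
  restricted$terms <- terms  # preserve original term order
  structure(list(network = ppi,
                 annotations = restricted,
                 vertex_order = c(ppi$proteins, terms),
                 n_proteins = length(ppi$proteins),
                 n_terms = length(terms)),
            class = "augmented_graph")
}

#' @export
print.augmented_graph <- function(x, ...) {
  n_ann_edges <- sum(vapply(x$annotations$by_protein, length, 1L))
  cat(sprintf(
    "augmented_graph: %d proteins + %d GO-slim dummy vertices, %d PPI edges, %d annotation edges\n",
    x$n_proteins, x$n_terms, nrow(x$network$edges), n_ann_edges))
  invisible(x)
}

#' Transition matrix of an ontology augmented graph
#'
#' Row-stochastic single-step random-walk matrix over proteins followed by
#' GO-slim dummy vertices. From a protein v with PPI neighbours N(v) and
#' annotation terms A(v), each incident augmented edge (to a neighbour
#' protein or to an owned term) gets probability 1/(|N(v)|+|A(v)|). From a
#' dummy vertex a annotating the protein set N(a), each annotated protein
#' gets 1/|N(a)|. Dummy-dummy entries are identically zero; a vertex with no
#' incident edges has an all-zero row.
#'
#' @param ag an [augmented_graph]
#' @param sparse logical; store as a `Matrix::dgCMatrix` instead of a dense
#'   base matrix. Defaults to dense below `sparse_threshold` vertices.
#' @param sparse_threshold vertex count above which the sparse
#'   representation is chosen when `sparse` is unset (default 2000)
#' @return an object of class `transition_matrix` with elements `matrix`
#'   (square, rows/cols in `vertex_order`), `vertex_order`, `n_proteins`,
#'   `n_terms`
#' @export
transition_matrix <- function(ag, sparse = NULL, sparse_threshold = 2000L) {
  stopifnot(inherits(ag, "augmented_graph"))
  n <- length(ag$vertex_order)
  if (is.null(sparse)) sparse <- n > sparse_threshold
  vi <- stats::setNames(seq_len(n), ag$vertex_order)

  adj <- ppi_adjacency(ag$network)
  byp <- ag$annotations$by_protein

  from <- integer(0); to <- integer(0); p <- numeric(0)
  for (v in ag$network$proteins) {
    nb <- adj[[v]]
    tm <- if (v %in% names(byp)) byp[[v]] else character(0)
    deg <- length(nb) + length(tm)
    if (deg == 0L) next
    tgt <- c(vi[nb], vi[tm])
    from <- c(from, rep(vi[[v]], deg))
    to <- c(to, tgt)
    p <- c(p, rep(1 / deg, deg))
  }
  # term rows: uniform over annotated proteins
  if (ag$n_terms > 0L) {
    owners <- split(
      rep(names(byp), vapply(byp, length, 1L)),
      factor(unlist(byp, use.names = FALSE), levels = ag$annotations$terms))
    for (a in ag$annotations$terms) {
      pr <- owners[[a]]
      from <- c(from, rep(vi[[a]], length(pr)))
      to <- c(to, vi[pr])
      p <- c(p, rep(1 / length(pr), length(pr)))
    }
  }
  m <- Matrix::sparseMatrix(i = from, j = to, x = p, dims = c(n, n),
                            dimnames = list(ag$vertex_order, ag$vertex_order))
  if (!sparse) m <- as.matrix(m)
  structure(list(matrix = m, vertex_order = ag$vertex_order,
                 n_proteins = ag$n_proteins, n_terms = ag$n_terms),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("transition_matrix: %d x %d (%d proteins + %d terms), %s storage\n",
              length(x$vertex_order), length(x$vertex_order),
              x$n_proteins, x$n_terms,
              if (is.matrix(x$matrix)) "dense" else "sparse"))
  invisible(x)
}

#' Dump a transition matrix as labelled TSV
#'
#' @param P a [transition_matrix]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_transition_matrix <- function(P, path) {
  m <- as.matrix(P$matrix)
  utils::write.table(format(m, digits = 10, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = TRUE, col.names = NA)
  invisible(path)
}
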