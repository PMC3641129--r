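#' Unified distance matrix (closed form)
#'
#' The unified distance between two proteins on the ontology augmented
#' graph is the delay-damped sum over all walk lengths of the summed
#' transition probability:
#' \deqn{R = \sum_{l \ge 1} c (1-c)^l P^l = c(1-c) P (I - (1-c)P)^{-1}}
#' where `P` is the augmented transition matrix and `c` in (0,1) the delay
#' parameter (shorter walks weigh more as `c` grows). Walks may pass
#' through GO-slim dummy vertices — that is the mechanism by which shared
#' annotations increase closeness — but the returned matrix is restricted
#' to the protein-by-protein block. Larger values mean closer. Since row
#' sums of `P` are at most 1, the spectral radius of `(1-c)P` is at most
#' `1-c < 1` and the series always converges; entries lie in
#' `[0, 1-c]`.
#'
#' The linear system is solved directly (no explicit inversion).
#'
#' @param P a [transition_matrix]
#' @param c delay parameter, strictly between 0 and 1 (default 0.1)
#' @return an object of class `distance_matrix` with elements `values`
#'   (dense protein-by-protein matrix, dimnames = protein identifiers),
#'   `c`, `protein_order`. Asymmetric in general; see [symmetrized_distance].
#' @seealso [unified_distance_series] for the truncated-series form
#' @export
unified_distance <- function(P, c = 0.1) {
  stopifnot(inherits(P, "transition_matrix"))
  if (!is.numeric(c) || length(c) != 1L || c <= 0 || c >= 1) {
    stop("delay parameter 'c' must lie strictly between 0 and 1")
  }
  n <- length(P$vertex_order)
  prots <- P$vertex_order[seq_len(P$n_proteins)]
  if (n == 0L) {
    return(new_distance_matrix(matrix(0, 0, 0), c, character(0)))
  }
  M <- (1 - c) * P$matrix
  # R = cM (I - M)^{-1}  <=>  (I - M)^T R^T = (cM)^T
  if (is.matrix(M)) {
    A <- diag(n) - M
    Rt <- solve(t(A), t(c * M))
  } else {
    A <- Matrix::Diagonal(n) - M
    Rt <- as.matrix(Matrix::solve(Matrix::t(A), Matrix::t(c * M)))
  }
  R <- t(Rt)[seq_len(P$n_proteins), seq_len(P$n_proteins), drop = FALSE]
  dimnames(R) <- list(prots, prots)
  new_distance_matrix(R, c, prots)
}

#' Unified distance matrix (truncated series)
#'
#' Direct evaluation of \eqn{\sum_{l=1}^{L} c(1-c)^l P^l} restricted to the
#' protein block. Converges to [unified_distance] as `L` grows; intended as
#' a brute-force cross-check of the closed form.
#'
#' @inheritParams unified_distance
#' @param L number of walk lengths to sum, at least 1
#' @return a `distance_matrix`
#' @export
unified_distance_series <- function(P, c = 0.1, L = 200L) {
  stopifnot(inherits(P, "transition_matrix"))
  if (!is.numeric(c) || length(c) != 1L || c <= 0 || c >= 1) {
    stop("delay parameter 'c' must lie strictly between 0 and 1")
  }
  if (L < 1L) stop("'L' must be at least 1")
  n <- length(P$vertex_order)
  prots <- P$vertex_order[seq_len(P$n_proteins)]
  Pm <- as.matrix(P$matrix)
  acc <- matrix(0, n, n)
  Pl <- diag(n)
  for (l in seq_len(L)) {
    Pl <- Pl %*% Pm
    acc <- acc + c * (1 - c)^l * Pl
  }
  R <- acc[seq_len(P$n_proteins), seq_len(P$n_proteins), drop = FALSE]
  dimnames(R) <- list(prots, prots)
  new_distance_matrix(R, c, prots)
}

new_distance_matrix <- function(values, c, protein_order) {
  structure(list(values = values, c = c, protein_order = protein_order),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix: %d x %d proteins, c = %g\n",
              nrow(x$values), ncol(x$values), x$c))
  invisible(x)
}

#' Symmetrized pairwise closeness
#'
#' `R` is asymmetric in general (rows of the transition matrix are
#' normalized by unequal degrees); wherever a closeness of an unordered
#' protein pair is needed (clique density, connectivity score) the
#' symmetrized value `(R[u,v] + R[v,u]) / 2` is used.
#'
#' @param R a `distance_matrix`
#' @return a symmetric numeric matrix with the same dimnames
#' @export
symmetrized_distance <- function(R) {
  stopifnot(inherits(R, "distance_matrix"))
  (R$values + t(R$values)) / 2
}

#' Dump the protein-block unified distance matrix as labelled TSV
#'
#' @param R a `distance_matrix`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_distance_matrix <- function(R, path) {
  utils::write.table(format(R$values, digits = 10, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = TRUE,
                     col.names = NA)
  invisible(path)
}
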