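#' Construct a PPI network
#'
#' An undirected simple graph over protein identifiers. Self-loops are
#' dropped and duplicate undirected edges collapsed. Protein order is the
#' order of first appearance (edge endpoints scanned left-to-right, row by
#' row, then any extra `proteins`), so matrix indices downstream are
#' reproducible.
#'
#' @param edges character matrix (or data.frame) with two columns of protein
#'   identifiers, one interaction per row. May have zero rows.
#' @param proteins optional character vector of additional protein
#'   identifiers (e.g. isolated proteins with no interactions).
#' @return an object of class `ppi_network` with elements `proteins`
#'   (character vector) and `edges` (two-column character matrix, deduplicated,
#'   no self-loops).
#' @export
ppi_network <- function(edges = NULL, proteins = NULL) {
  if (is.null(edges)) {
    edges <- matrix(character(0), ncol = 2L)
  }
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (!is.matrix(edges) || ncol(edges) < 2L) {
    stop("'edges' must be a two-column matrix of protein identifiers")
  }
  edges <- matrix(as.character(edges[, 1:2]), ncol = 2L)
  storage.mode(edges) <- "character"

  # first-appearance vertex order: interleave endpoints row-wise
  seen <- as.vector(t(edges))
  if (!is.null(proteins)) seen <- c(seen, as.character(proteins))
  prots <- unique(seen)

  keep <- edges[, 1L] != edges[, 2L]
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) > 0L) {
    key <- paste(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]), sep = "\r")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  structure(list(proteins = prots, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d proteins, %d interactions\n",
              length(x$proteins), nrow(x$edges)))
  invisible(x)
}

#' Number of proteins / interactions
#' @param ppi a [ppi_network]
#' @return integer count
#' @export
n_proteins <- function(ppi) length(ppi$proteins)

#' @rdname n_proteins
#' @export
n_interactions <- function(ppi) nrow(ppi$edges)

# adjacency list: named list protein -> character vector of neighbours,
# one entry per protein in network order (isolated proteins get length 0)
ppi_adjacency <- function(ppi) {
  e <- ppi$edges
  split(c(e[, 2L], e[, 1L]),
        factor(c(e[, 1L], e[, 2L]), levels = ppi$proteins))
}

# igraph view of the network (vertices in network order, isolated kept)
ppi_igraph <- function(ppi) {
  igraph::graph_from_data_frame(
    d = as.data.frame(ppi$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ppi$proteins, stringsAsFactors = FALSE))
}

#' Read a PPI network from a tab-separated edge list
#'
#' Each non-comment line carries at least two whitespace/tab-separated
#' fields: the two interacting protein identifiers. Extra columns (e.g.
#' confidence scores) are ignored; with `sif = TRUE` the file is read as SIF
#' (`A relation B`), taking fields 1 and 3. Self-loops and duplicate
#' undirected edges are dropped, with counts reported via `message()`.
#'
#' @param path path to the edge-list file. Lines starting with `#` and blank
#'   lines are skipped.
#' @param sif logical; interpret lines as SIF three-column records.
#' @return a [ppi_network]. An empty file yields an empty network.
#' @export
read_ppi_edgelist <- function(path, sif = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(ppi_network())
  fields <- strsplit(lines[idx], "[ \t]+")
  need <- if (sif) 3L else 2L
  bad <- which(vapply(fields, length, 1L) < need)
  if (length(bad) > 0L) {
    stop(sprintf("parse error at line %d: expected at least %d fields",
                 idx[bad[1L]], need))
  }
  a <- vapply(fields, `[`, "", 1L)
  b <- vapply(fields, `[`, "", if (sif) 3L else 2L)
  net <- ppi_network(cbind(a, b))
  n_dropped <- length(a) - nrow(net$edges)
  if (n_dropped > 0L) {
    message(sprintf("read_ppi_edgelist: dropped %d self-loop/duplicate edge line(s)",
                    n_dropped))
  }
  net
}

#' Write a PPI network as a two-column tab-separated edge list
#'
#' @param ppi a [ppi_network]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_ppi_edgelist <- function(ppi, path) {
  utils::write.table(ppi$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
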