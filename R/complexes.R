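#' Construct a set of protein complexes
#'
#' @param complexes list of character vectors, each the member set of one
#'   complex. Members are deduplicated; empty complexes are rejected.
#' @param labels optional character vector of complex identifiers, one per
#'   complex.
#' @return an object of class `complex_set`
#' @export
complex_set <- function(complexes = list(), labels = NULL) {
  complexes <- lapply(complexes, function(x) unique(as.character(x)))
  if (any(vapply(complexes, length, 1L) == 0L)) {
    stop("complexes must be nonempty")
  }
  if (!is.null(labels) && length(labels) != length(complexes)) {
    stop("'labels' must match the number of complexes")
  }
  structure(list(complexes = complexes, labels = labels),
            class = "complex_set")
}

#' @export
print.complex_set <- function(x, ...) {
  sizes <- vapply(x$complexes, length, 1L)
  cat(sprintf("complex_set: %d complexes", length(x$complexes)))
  if (length(sizes) > 0L) {
    cat(sprintf(" (sizes %d-%d)", min(sizes), max(sizes)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.complex_set <- function(x) length(x$complexes)

# collapse complexes with identical member sets (order-insensitive),
# keeping first occurrence
dedupe_complexes <- function(cs) {
  if (length(cs$complexes) == 0L) return(cs)
  key <- vapply(cs$complexes, function(m) paste(sort(m), collapse = "\r"), "")
  keep <- !duplicated(key)
  complex_set(cs$complexes[keep],
              if (is.null(cs$labels)) NULL else cs$labels[keep])
}

#' Read a complex catalogue
#'
#' One complex per line, members tab-separated (CYC2008-style). With
#' `labelled = TRUE` the first field of each line is a complex identifier.
#'
#' @param path input path
#' @param labelled logical; first column is a label, not a member
#' @return a [complex_set]; an empty file yields an empty set
#' @export
read_complexes <- function(path, labelled = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  idx <- which(!grepl("^\\s*(#|$)", lines))
  if (length(idx) == 0L) return(complex_set())
  fields <- strsplit(lines[idx], "\t")
  need <- if (labelled) 2L else 1L
  bad <- which(vapply(fields, length, 1L) < need)
  if (length(bad) > 0L) {
    stop(sprintf("parse error at line %d: complex with no members", idx[bad[1L]]))
  }
  if (labelled) {
    labels <- vapply(fields, `[`, "", 1L)
    members <- lapply(fields, `[`, -1L)
    complex_set(members, labels)
  } else {
    complex_set(fields)
  }
}

#' Write a complex catalogue
#'
#' One complex per line, members tab-separated; duplicate member lists are
#' collapsed before writing.
#'
#' @param cs a [complex_set]
#' @param path output path
#' @param labelled logical; prepend the label column (requires labels)
#' @return invisibly, `path`
#' @export
write_complexes <- function(cs, path, labelled = FALSE) {
  cs <- dedupe_complexes(cs)
  if (labelled && is.null(cs$labels)) stop("complex set has no labels")
  lines <- vapply(seq_along(cs$complexes), function(i) {
    m <- paste(cs$complexes[[i]], collapse = "\t")
    if (labelled) paste(cs$labels[i], m, sep = "\t") else m
  }, "")
  writeLines(lines, path)
  invisible(path)
}
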