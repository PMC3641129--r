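#' Construct a protein-to-GO-slim annotation map
#'
#' Maps each protein identifier to its set of GO-slim term identifiers.
#' Term order is deterministic: order of first appearance across proteins
#' (in the order given).
#'
#' @param by_protein named list; names are protein identifiers, elements are
#'   character vectors of GO-slim identifiers. Duplicates within a protein
#'   are collapsed.
#' @return an object of class `annotation_map` with elements `terms`
#'   (character vector) and `by_protein` (named list of character vectors).
#' @export
annotation_map <- function(by_protein = list()) {
  if (length(by_protein) > 0L && is.null(names(by_protein))) {
    stop("'by_protein' must be a named list (protein -> terms)")
  }
  by_protein <- lapply(by_protein, function(x) unique(as.character(x)))
  by_protein <- by_protein[vapply(by_protein, length, 1L) > 0L]
  terms <- unique(unlist(by_protein, use.names = FALSE))
  if (is.null(terms)) terms <- character(0)
  structure(list(terms = terms, by_protein = by_protein),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation_map: %d proteins annotated with %d GO-slim terms\n",
              length(x$by_protein), length(x$terms)))
  invisible(x)
}

#' Read protein annotations
#'
#' Two dialects: `tsv`, a two-column table `protein-id<TAB>term-id`; and
#' `gaf`, GAF 2.x, using the DB-object-symbol (column 3) and GO-ID
#' (column 5) fields, with `!`-prefixed comment lines skipped. Multiple rows
#' for one protein are unioned into its term set. The GAF aspect column is
#' not filtered unless `aspects` is given.
#'
#' @param path input file path
#' @param format `"tsv"` or `"gaf"`
#' @param aspects optional character vector of GAF aspect codes
#'   (`"P"`, `"F"`, `"C"`) to keep; `NULL` keeps all three.
#' @return an [annotation_map]
#' @export
read_annotations <- function(path, format = c("tsv", "gaf"), aspects = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "tsv") {
    idx <- which(!grepl("^\\s*(#|$)", lines))
    if (length(idx) == 0L) return(annotation_map())
    fields <- strsplit(lines[idx], "\t")
    bad <- which(vapply(fields, length, 1L) < 2L)
    if (length(bad) > 0L) {
      stop(sprintf("parse error at line %d: expected 2 tab-separated fields",
                   idx[bad[1L]]))
    }
    prot <- vapply(fields, `[`, "", 1L)
    term <- vapply(fields, `[`, "", 2L)
  } else {
    idx <- which(!grepl("^\\s*(!|$)", lines))
    if (length(idx) == 0L) return(annotation_map())
    fields <- strsplit(lines[idx], "\t")
    bad <- which(vapply(fields, length, 1L) < 9L)
    if (length(bad) > 0L) {
      stop(sprintf("parse error at line %d: GAF record has fewer than 9 columns",
                   idx[bad[1L]]))
    }
    prot <- vapply(fields, `[`, "", 3L)
    term <- vapply(fields, `[`, "", 5L)
    if (!is.null(aspects)) {
      asp <- vapply(fields, `[`, "", 9L)
      keep <- asp %in% aspects
      prot <- prot[keep]; term <- term[keep]
    }
  }
  annotation_map(split(term, factor(prot, levels = unique(prot))))
}

#' Write annotations as a two-column TSV
#'
#' @param ann an [annotation_map]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_annotations <- function(ann, path) {
  prot <- rep(names(ann$by_protein),
              vapply(ann$by_protein, length, 1L))
  term <- unlist(ann$by_protein, use.names = FALSE)
  utils::write.table(cbind(prot, term), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
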