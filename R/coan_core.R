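#' COAN parameters
#'
#' @param c delay parameter of the random walk, in (0,1); default 0.1
#' @param extend_thres minimum connectivity score for a neighbouring
#'   protein to be absorbed into a seed's complex; default 0.6
#' @param min_clique smallest admissible clique/complex kernel size;
#'   default 3, must be at least 3
#' @return an object of class `coan_params`
#' @export
coan_params <- function(c = 0.1, extend_thres = 0.6, min_clique = 3L) {
  if (!is.numeric(c) || c <= 0 || c >= 1) {
    stop("'c' must lie strictly between 0 and 1")
  }
  if (!is.numeric(extend_thres) || extend_thres <= 0) {
    stop("'extend_thres' must be positive")
  }
  if (min_clique < 3L) stop("'min_clique' must be at least 3")
  structure(list(c = c, extend_thres = extend_thres,
                 min_clique = as.integer(min_clique)),
            class = "coan_params")
}

#' Unified-distance density of a clique
#'
#' Mean symmetrized unified distance over all unordered member pairs. A
#' high density marks a clique whose members are both tightly
#' interconnected and rich in shared GO-slim annotations. The mean (rather
#' than a sum) keeps the score size-independent, so cliques of different
#' sizes rank on one scale.
#'
#' @param q character vector of clique members, at least 2
#' @param R a `distance_matrix` from [unified_distance], or the symmetric
#'   matrix from [symmetrized_distance]
#' @return non-negative scalar
#' @export
clique_density <- function(q, R) {
  S <- as_sym_matrix(R)
  if (length(q) < 2L) stop("clique must have at least 2 members")
  missing <- setdiff(q, rownames(S))
  if (length(missing) > 0L) {
    stop("protein(s) absent from the distance matrix: ",
         paste(missing, collapse = ", "))
  }
  sub <- S[q, q, drop = FALSE]
  sum(sub[upper.tri(sub)]) / (length(q) * (length(q) - 1) / 2)
}

as_sym_matrix <- function(R) {
  if (inherits(R, "distance_matrix")) symmetrized_distance(R) else R
}

#' Select disjoint seed cliques by density ranking and overlap pruning
#'
#' Candidate cliques are kept ranked in descending density. Repeatedly: the
#' top-ranked clique becomes a seed; every remaining clique that overlaps
#' it has the seed's members subtracted — if the remainder still has at
#' least `min_clique` members it replaces the original (density recomputed,
#' ranking refreshed), otherwise it is removed. The loop ends when the
#' candidate set is empty, leaving pairwise-disjoint seeds. Ties in density
#' break toward the larger clique, then the lexicographically smaller
#' member tuple.
#'
#' @param cands list of cliques (character vectors), e.g. from
#'   [maximal_cliques]
#' @param R distance matrix (see [clique_density])
#' @param min_clique smallest seed size retained after pruning (default 3)
#' @return an object of class `seed_set`: list with `seeds` (list of
#'   character vectors, selection order) and `densities` (numeric, density
#'   of each seed at the moment of selection)
#' @export
select_seed_cliques <- function(cands, R, min_clique = 3L) {
  S <- as_sym_matrix(R)
  cands <- lapply(cands, sort)
  dens <- vapply(cands, clique_density, 0, R = S)
  seeds <- list()
  seed_dens <- numeric(0)
  while (length(cands) > 0L) {
    sizes <- vapply(cands, length, 1L)
    keys <- vapply(cands, paste, "", collapse = "\r")
    top <- order(-dens, -sizes, keys, method = "radix")[1L]
    s <- cands[[top]]
    seeds[[length(seeds) + 1L]] <- s
    seed_dens <- c(seed_dens, dens[top])
    cands <- cands[-top]
    dens <- dens[-top]
    if (length(cands) == 0L) break
    overlaps <- vapply(cands, function(q) any(q %in% s), TRUE)
    keep <- !overlaps
    pruned <- lapply(cands[overlaps], setdiff, y = s)
    ok <- vapply(pruned, length, 1L) >= min_clique
    pruned <- pruned[ok]
    cands <- c(cands[keep], pruned)
    dens <- c(dens[keep], vapply(pruned, clique_density, 0, R = S))
  }
  structure(list(seeds = seeds, densities = seed_dens), class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("seed_set: %d disjoint seed cliques\n", length(x$seeds)))
  invisible(x)
}

#' Connectivity score of a protein with respect to a seed clique
#'
#' The mean symmetrized unified distance from `p` to the seed members,
#' normalized by the seed's own density — a unit-scaled measure of how
#' strongly `p` is tied to the seed relative to the seed's internal
#' cohesion. Returns 0 when the seed density is 0.
#'
#' @param p a protein identifier, not a member of `s`
#' @param s seed clique (character vector, at least 2 members)
#' @param R distance matrix (see [clique_density])
#' @return non-negative scalar; values near or above 1 mark proteins about
#'   as close to the seed as its members are to each other
#' @export
connectivity_score <- function(p, s, R) {
  S <- as_sym_matrix(R)
  if (p %in% s) stop("'p' must not be a member of the seed clique")
  if (!(p %in% rownames(S))) {
    stop("protein absent from the distance matrix: ", p)
  }
  d <- clique_density(s, S)
  if (d == 0) return(0)
  mean(S[p, s]) / d
}

#' Expand a seed clique into a predicted complex
#'
#' Candidates are the PPI neighbours of any seed member that are not
#' themselves members. Each candidate whose [connectivity_score] against
#' the fixed seed reaches `extend_thres` is absorbed, in a single pass
#' (accepted proteins do not recruit further candidates), so raising the
#' threshold can only shrink the result.
#'
#' @param s seed clique (character vector)
#' @param ppi the [ppi_network]
#' @param R distance matrix
#' @param extend_thres acceptance threshold (default 0.6)
#' @return character vector, sorted: seed plus accepted neighbours
#' @export
expand_seed <- function(s, ppi, R, extend_thres = 0.6) {
  S <- as_sym_matrix(R)
  adj <- ppi_adjacency(ppi)
  cand <- setdiff(unique(unlist(adj[s], use.names = FALSE)), s)
  if (length(cand) == 0L) return(sort(s))
  scores <- vapply(cand, connectivity_score, 0, s = s, R = S)
  sort(c(s, cand[scores >= extend_thres]))
}

#' Predict protein complexes (the full COAN pipeline)
#'
#' Builds the ontology augmented graph, its transition matrix and the
#' unified distance matrix; enumerates maximal cliques of the PPI network
#' (size >= `min_clique`); selects disjoint seed cliques by density ranking
#' with overlap pruning; expands each seed by connectivity score; collapses
#' duplicate complexes. Deterministic given inputs and parameters. Seeds
#' are disjoint but expanded complexes may overlap.
#'
#' @param ppi a [ppi_network]
#' @param ann an [annotation_map] (may be empty: prediction then uses
#'   topology alone)
#' @param params a [coan_params]
#' @return a [complex_set] of predicted complexes, each of size >=
#'   `min_clique`
#' @export
predict_complexes <- function(ppi, ann = annotation_map(),
                              params = coan_params()) {
  stopifnot(inherits(params, "coan_params"))
  cands <- maximal_cliques(ppi, min_size = params$min_clique)
  if (length(cands) == 0L) return(complex_set())
  ag <- build_augmented_graph(ppi, ann)
  P <- transition_matrix(ag)
  R <- unified_distance(P, c = params$c)
  S <- symmetrized_distance(R)
  seeds <- select_seed_cliques(cands, S, min_clique = params$min_clique)
  complexes <- lapply(seeds$seeds, expand_seed, ppi = ppi, R = S,
                      extend_thres = params$extend_thres)
  dedupe_complexes(complex_set(complexes))
}
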