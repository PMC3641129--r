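#' Specification of a synthetic planted-complex benchmark
#'
#' Describes a benchmark instance: dense planted complexes (near-clique
#' subgraphs) whose members share dedicated GO-slim annotations, embedded
#' in a background of sparsely wired proteins, with missing intra-complex
#' edges and spurious annotations as noise.
#'
#' @param n_complexes number of planted complexes (default 10)
#' @param size_range integer pair, min/max complex size; min >= 3
#'   (default c(4, 10))
#' @param p_in probability an intra-complex protein pair is wired
#'   (default 0.9)
#' @param p_fn probability an intra-complex edge, once wired, is deleted —
#'   the false-negative rate of interaction detection (default 0.1)
#' @param n_background background proteins outside any complex (default 60)
#' @param p_out probability any non-intra-complex pair is wired — noise and
#'   inter-complex edges (default 0.02)
#' @param n_terms GO-slim vocabulary size; the first
#'   `n_complexes * terms_per_complex` terms are dedicated complex slims,
#'   the remainder are noise slims (default 30)
#' @param terms_per_complex dedicated slims per complex (default 2)
#' @param p_share probability a complex member carries each of its
#'   complex's dedicated slims (default 0.9)
#' @param p_noise_ann probability a protein carries each noise slim
#'   (default 0.05)
#' @param seed RNG seed; the generator is deterministic given the spec
#'   (default 42)
#' @return an object of class `benchmark_spec`
#' @export
benchmark_spec <- function(n_complexes = 10L, size_range = c(4L, 10L),
                           p_in = 0.9, p_fn = 0.1,
                           n_background = 60L, p_out = 0.02,
                           n_terms = 30L, terms_per_complex = 2L,
                           p_share = 0.9, p_noise_ann = 0.05,
                           seed = 42L) {
  probs <- c(p_in = p_in, p_fn = p_fn, p_out = p_out, p_share = p_share,
             p_noise_ann = p_noise_ann)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  if (length(size_range) != 2L || size_range[1L] < 3L ||
      size_range[2L] < size_range[1L]) {
    stop("'size_range' must be c(min, max) with min >= 3 and max >= min")
  }
  if (n_complexes < 0L || n_background < 0L) stop("counts must be non-negative")
  if (n_terms < n_complexes * terms_per_complex) {
    stop("'n_terms' must cover the dedicated complex slims (",
         n_complexes * terms_per_complex, " needed)")
  }
  structure(list(n_complexes = as.integer(n_complexes),
                 size_range = as.integer(size_range),
                 p_in = p_in, p_fn = p_fn,
                 n_background = as.integer(n_background), p_out = p_out,
                 n_terms = as.integer(n_terms),
                 terms_per_complex = as.integer(terms_per_complex),
                 p_share = p_share, p_noise_ann = p_noise_ann,
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' Generate a planted-complex benchmark instance
#'
#' Draws complex sizes, assigns disjoint member sets, wires intra-complex
#' pairs with probability `p_in` then deletes each realized edge with
#' probability `p_fn`, wires every other pair with probability `p_out`,
#' gives each member each of its complex's dedicated GO slims with
#' probability `p_share`, and sprinkles each noise slim on every protein
#' with probability `p_noise_ann`. A single RNG stream seeded from
#' `spec$seed` is consumed in that fixed order (sizes, memberships implied
#' by sequential naming, intra edges, deletions, background edges,
#' shared annotations, noise annotations), so output is reproducible.
#'
#' @param spec a [benchmark_spec]
#' @return list with elements `network` ([ppi_network]), `annotations`
#'   ([annotation_map]), `truth` ([complex_set] of the planted complexes,
#'   labelled `C1`, `C2`, ...)
#' @export
generate_benchmark <- function(spec = benchmark_spec()) {
  stopifnot(inherits(spec, "benchmark_spec"))
  set.seed(spec$seed)

  sizes <- if (spec$n_complexes > 0L) {
    sample(seq(spec$size_range[1L], spec$size_range[2L]),
           spec$n_complexes, replace = TRUE)
  } else integer(0)
  n_total <- sum(sizes) + spec$n_background
  if (n_total > 99999L) stop("requested protein count exceeds the P##### namespace")
  prots <- sprintf("P%05d", seq_len(n_total))
  membership <- rep(0L, n_total)  # 0 = background
  membership[seq_len(sum(sizes))] <- rep(seq_along(sizes), sizes)

  complexes <- split(prots[membership > 0L], membership[membership > 0L])
  names(complexes) <- NULL

  # candidate pairs, in fixed (i < j) order
  edges <- character(0)
  e_from <- character(0); e_to <- character(0)
  if (n_total >= 2L) {
    pr <- utils::combn(n_total, 2L)
    intra <- membership[pr[1L, ]] == membership[pr[2L, ]] &
      membership[pr[1L, ]] > 0L
    # intra wiring then thinning
    n_in <- sum(intra)
    wired_in <- stats::runif(n_in) < spec$p_in
    kept_in <- wired_in & (stats::runif(n_in) >= spec$p_fn)
    # all other pairs
    wired_out <- stats::runif(sum(!intra)) < spec$p_out
    keep <- logical(ncol(pr))
    keep[intra] <- kept_in
    keep[!intra] <- wired_out
    e_from <- prots[pr[1L, keep]]
    e_to <- prots[pr[2L, keep]]
  }
  net <- ppi_network(cbind(e_from, e_to), proteins = prots)

  terms <- sprintf("GO:%04d", seq_len(spec$n_terms))
  n_dedicated <- spec$n_complexes * spec$terms_per_complex
  by_protein <- stats::setNames(
    replicate(n_total, character(0), simplify = FALSE), prots)
  # dedicated slims, complex by complex
  for (k in seq_along(complexes)) {
    slims <- terms[((k - 1L) * spec$terms_per_complex + 1L):
                     (k * spec$terms_per_complex)]
    for (m in complexes[[k]]) {
      carry <- stats::runif(length(slims)) < spec$p_share
      by_protein[[m]] <- c(by_protein[[m]], slims[carry])
    }
  }
  # noise slims on every protein
  noise_terms <- if (n_dedicated < spec$n_terms) {
    terms[(n_dedicated + 1L):spec$n_terms]
  } else character(0)
  if (length(noise_terms) > 0L) {
    for (m in prots) {
      carry <- stats::runif(length(noise_terms)) < spec$p_noise_ann
      by_protein[[m]] <- c(by_protein[[m]], noise_terms[carry])
    }
  }
  ann <- annotation_map(by_protein)

  truth <- if (length(complexes) > 0L) {
    complex_set(complexes, labels = paste0("C", seq_along(complexes)))
  } else complex_set()
  list(network = net, annotations = ann, truth = truth)
}
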