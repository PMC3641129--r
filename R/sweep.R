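#' Sweep the expansion threshold
#'
#' Computes the unified distance matrix and the seed clique set once, then
#' re-runs seed expansion and evaluation for each threshold, emitting one
#' row per threshold: the largest predicted complex shrinks (weakly) as
#' the threshold rises, trading sensitivity for PPV.
#'
#' @param ppi a [ppi_network]
#' @param ann an [annotation_map]
#' @param thresholds numeric vector of expansion thresholds, each in (0, 1)
#' @param ref reference [complex_set] to score against
#' @param omega match threshold for neighborhood affinity (default 0.2)
#' @param params base [coan_params]; its `extend_thres` is ignored in
#'   favour of `thresholds`
#' @return data.frame with columns `extend_thres`, `n_complexes`, `size`
#'   (largest predicted complex), `precision`, `recall`, `f1`,
#'   `sensitivity`, `ppv`, `accuracy`; zero rows for an empty threshold
#'   list
#' @export
sweep_extend_thres <- function(ppi, ann, thresholds, ref, omega = 0.2,
                               params = coan_params()) {
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie strictly between 0 and 1")
  }
  empty <- data.frame(extend_thres = numeric(0), n_complexes = integer(0),
                      size = integer(0), precision = numeric(0),
                      recall = numeric(0), f1 = numeric(0),
                      sensitivity = numeric(0), ppv = numeric(0),
                      accuracy = numeric(0))
  if (length(thresholds) == 0L) return(empty)
  cands <- maximal_cliques(ppi, min_size = params$min_clique)
  if (length(cands) == 0L) {
    res <- do.call(rbind, lapply(thresholds, function(th) {
      rep_row(th, evaluate_complexes(complex_set(), ref, omega))
    }))
    rownames(res) <- NULL
    return(res)
  }
  ag <- build_augmented_graph(ppi, ann)
  P <- transition_matrix(ag)
  S <- symmetrized_distance(unified_distance(P, c = params$c))
  seeds <- select_seed_cliques(cands, S, min_clique = params$min_clique)
  res <- do.call(rbind, lapply(thresholds, function(th) {
    complexes <- lapply(seeds$seeds, expand_seed, ppi = ppi, R = S,
                        extend_thres = th)
    pred <- dedupe_complexes(complex_set(complexes))
    rep_row(th, evaluate_complexes(pred, ref, omega))
  }))
  rownames(res) <- NULL
  res
}

rep_row <- function(th, rpt) {
  data.frame(extend_thres = th,
             n_complexes = rpt$n_predicted,
             size = rpt$largest_predicted_size,
             precision = rpt$precision, recall = rpt$recall, f1 = rpt$f1,
             sensitivity = rpt$sensitivity, ppv = rpt$ppv,
             accuracy = rpt$accuracy)
}
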