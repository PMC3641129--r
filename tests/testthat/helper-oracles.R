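# Independent oracles and instance generators used across the suite.
# These deliberately avoid the package's internal code paths: the clique
# oracle enumerates subsets exhaustively, and the pipeline oracle is a
# straight-line re-implementation with dense matrices and explicit loops.

# --- exhaustive maximal-clique enumeration (n <= ~14) -----------------------

brute_force_cliques <- function(ppi, min_size = 3L) {
  prots <- ppi$proteins
  n <- length(prots)
  if (n == 0L) return(list())
  adjm <- matrix(FALSE, n, n, dimnames = list(prots, prots))
  for (i in seq_len(nrow(ppi$edges))) {
    a <- ppi$edges[i, 1L]; b <- ppi$edges[i, 2L]
    adjm[a, b] <- TRUE; adjm[b, a] <- TRUE
  }
  masks <- bitwShiftL(1L, 0:(n - 1L))
  res <- list()
  for (m in seq_len(2L^n - 1L)) {
    v <- which(bitwAnd(m, masks) != 0L)
    k <- length(v)
    if (k < min_size) next
    sub <- adjm[v, v, drop = FALSE]
    if (any(!sub[upper.tri(sub)])) next
    out <- setdiff(seq_len(n), v)
    if (length(out) > 0L &&
        any(colSums(adjm[v, out, drop = FALSE]) == k)) next
    res[[length(res) + 1L]] <- sort(prots[v])
  }
  keys <- vapply(res, paste, "", collapse = "\r")
  res[order(keys, method = "radix")]
}

# --- straight-line pipeline oracle ------------------------------------------

naive_predict <- function(ppi, ann, c = 0.1, extend_thres = 0.6,
                          min_clique = 3L) {
  prots <- ppi$proteins
  byp <- ann$by_protein[names(ann$by_protein) %in% prots]
  terms <- ann$terms[ann$terms %in% unlist(byp, use.names = FALSE)]
  verts <- c(prots, terms)
  n <- length(verts)
  if (n == 0L) return(list())

  A <- matrix(0, n, n, dimnames = list(verts, verts))
  for (i in seq_len(nrow(ppi$edges))) {
    a <- ppi$edges[i, 1L]; b <- ppi$edges[i, 2L]
    A[a, b] <- 1; A[b, a] <- 1
  }
  for (p in names(byp)) {
    for (t in intersect(byp[[p]], terms)) {
      A[p, t] <- 1; A[t, p] <- 1
    }
  }
  P <- matrix(0, n, n, dimnames = list(verts, verts))
  for (v in verts) {
    if (v %in% terms) {
      deg <- sum(A[v, prots])
      if (deg > 0) P[v, prots] <- A[v, prots] / deg
    } else {
      deg <- sum(A[v, ])
      if (deg > 0) P[v, ] <- A[v, ] / deg
    }
  }
  M <- (1 - c) * P
  Rfull <- (c * M) %*% solve(diag(n) - M)
  S <- (Rfull[prots, prots, drop = FALSE] +
          t(Rfull[prots, prots, drop = FALSE])) / 2

  dens <- function(q) {
    tot <- 0; np <- 0L
    for (i in seq_len(length(q) - 1L)) {
      for (j in seq(i + 1L, length(q))) {
        tot <- tot + S[q[i], q[j]]; np <- np + 1L
      }
    }
    tot / np
  }

  cands <- brute_force_cliques(ppi, min_clique)
  seeds <- list()
  while (length(cands) > 0L) {
    d <- vapply(cands, dens, 0)
    sz <- vapply(cands, length, 1L)
    keys <- vapply(cands, paste, "", collapse = "\r")
    top <- order(-d, -sz, keys, method = "radix")[1L]
    s <- cands[[top]]
    seeds[[length(seeds) + 1L]] <- s
    cands <- cands[-top]
    nxt <- list()
    for (q in cands) {
      if (any(q %in% s)) {
        rem <- setdiff(q, s)
        if (length(rem) >= min_clique) nxt[[length(nxt) + 1L]] <- rem
      } else {
        nxt[[length(nxt) + 1L]] <- q
      }
    }
    cands <- nxt
  }

  adj <- list()
  for (v in prots) adj[[v]] <- character(0)
  for (i in seq_len(nrow(ppi$edges))) {
    a <- ppi$edges[i, 1L]; b <- ppi$edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  out <- list()
  for (s in seeds) {
    cand <- setdiff(unique(unlist(adj[s])), s)
    acc <- character(0)
    d_s <- dens(s)
    for (p in cand) {
      score <- if (d_s == 0) 0 else mean(S[p, s]) / d_s
      if (score >= extend_thres) acc <- c(acc, p)
    }
    out[[length(out) + 1L]] <- sort(c(s, acc))
  }
  keys <- vapply(out, paste, "", collapse = "\r")
  out[!duplicated(keys)]
}

# sorted canonical form of a complex_set, for set-wise comparison
complex_keys <- function(cs) {
  sort(vapply(cs$complexes, function(m) paste(sort(m), collapse = "\r"), ""))
}

# --- random instance generators ---------------------------------------------

random_ppi <- function(n, p_edge, seed) {
  set.seed(seed)
  prots <- sprintf("v%03d", seq_len(n))
  if (n < 2L) return(ppi_network(proteins = prots))
  pr <- utils::combn(n, 2L)
  sel <- stats::runif(ncol(pr)) < p_edge
  ppi_network(cbind(prots[pr[1L, sel]], prots[pr[2L, sel]]),
              proteins = prots)
}

random_augmented_instance <- function(n, p_edge, n_terms, p_ann, seed) {
  net <- random_ppi(n, p_edge, seed)
  terms <- sprintf("t%03d", seq_len(n_terms))
  byp <- lapply(net$proteins, function(p) terms[stats::runif(n_terms) < p_ann])
  names(byp) <- net$proteins
  list(net = net, ann = annotation_map(byp))
}

# small toy instances shared by the pipeline-oracle tests (<= 10 proteins)
toy_instances <- function() {
  list(
    # two 4-cliques joined by one bridge, each sharing a distinct slim
    two_cliques_bridge = {
      q <- sprintf("q%d", 1:4); p <- sprintf("p%d", 1:4)
      e <- rbind(t(utils::combn(q, 2L)), t(utils::combn(p, 2L)),
                 c("q4", "p1"))
      ann <- annotation_map(c(
        stats::setNames(rep(list("t1"), 4L), q),
        stats::setNames(rep(list("t2"), 4L), p)))
      list(net = ppi_network(e), ann = ann)
    },
    # triangle plus pendant, one slim on the triangle
    triangle_pendant = {
      e <- rbind(c("a", "b"), c("b", "c"), c("a", "c"), c("c", "d"))
      list(net = ppi_network(e),
           ann = annotation_map(list(a = "t1", b = "t1", c = "t1")))
    },
    # overlapping cliques {a,b,c,d} and {c,d,e,f}, no annotations
    overlapping_cliques = {
      e <- rbind(t(utils::combn(c("a", "b", "c", "d"), 2L)),
                 t(utils::combn(c("c", "d", "e", "f"), 2L)))
      list(net = ppi_network(e), ann = annotation_map())
    },
    # dense random graph with annotations, 8 proteins
    random8 = random_augmented_instance(8L, 0.5, 3L, 0.4, seed = 7L),
    # sparse random graph, 10 proteins, no annotations
    random10 = list(net = random_ppi(10L, 0.35, seed = 11L),
                    ann = annotation_map())
  )
}
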