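#' Neighborhood affinity between two complexes
#'
#' `NA(p, b) = |p n b|^2 / (|p| * |b|)`, a symmetric overlap score in
#' `[0, 1]`; 1 iff the member sets are identical, 0 iff disjoint.
#'
#' @param p,b nonempty character vectors (member sets)
#' @return scalar in `[0, 1]`
#' @export
neighborhood_affinity <- function(p, b) {
  p <- unique(p); b <- unique(b)
  if (length(p) == 0L || length(b) == 0L) {
    stop("neighborhood affinity is undefined for empty complexes")
  }
  length(intersect(p, b))^2 / (length(p) * length(b))
}

# |ref_i intersect pred_j| contingency table (rows = reference)
overlap_table <- function(pred, ref) {
  t_ij <- matrix(0L, nrow = length(ref$complexes), ncol = length(pred$complexes))
  for (i in seq_along(ref$complexes)) {
    for (j in seq_along(pred$complexes)) {
      t_ij[i, j] <- length(intersect(ref$complexes[[i]], pred$complexes[[j]]))
    }
  }
  t_ij
}

#' Count matched predicted and reference complexes
#'
#' A predicted complex matches a reference complex when their neighborhood
#' affinity is at least `omega` (matching the convention that scores below
#' omega mark non-matches).
#'
#' @param pred,ref [complex_set]s of predicted and reference complexes
#' @param omega match threshold in (0, 1], default 0.2
#' @return named numeric vector `c(n_cp = ..., n_cb = ...)`: predicted
#'   complexes matching at least one reference, and reference complexes
#'   matched by at least one prediction
#' @export
match_counts <- function(pred, ref, omega = 0.2) {
  if (!is.numeric(omega) || omega <= 0 || omega > 1) {
    stop("'omega' must lie in (0, 1]")
  }
  np <- length(pred$complexes); nr <- length(ref$complexes)
  if (np == 0L || nr == 0L) return(c(n_cp = 0, n_cb = 0))
  na_ij <- matrix(0, nr, np)
  for (i in seq_len(nr)) {
    for (j in seq_len(np)) {
      na_ij[i, j] <- neighborhood_affinity(pred$complexes[[j]],
                                           ref$complexes[[i]])
    }
  }
  hit <- na_ij >= omega
  c(n_cp = sum(colSums(hit) > 0L), n_cb = sum(rowSums(hit) > 0L))
}

#' Precision, recall and F1 of a predicted complex set
#'
#' `precision = n_cp / #predicted`, `recall = n_cb / #reference`,
#' `f1 = 2 P R / (P + R)`; any metric with a zero denominator is 0.
#'
#' @inheritParams match_counts
#' @return named numeric vector `c(precision, recall, f1)`
#' @export
precision_recall_f1 <- function(pred, ref, omega = 0.2) {
  mc <- match_counts(pred, ref, omega)
  precision <- if (length(pred$complexes) > 0L) {
    mc[["n_cp"]] / length(pred$complexes)
  } else 0
  recall <- if (length(ref$complexes) > 0L) {
    mc[["n_cb"]] / length(ref$complexes)
  } else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Sensitivity, positive predictive value and accuracy
#'
#' Complex-wise contingency metrics over the overlap table
#' `t_ij = |ref_i n pred_j|`: `Sn = sum_i max_j t_ij / sum_i |ref_i|`;
#' `PPV = sum_j max_i t_ij / sum_j sum_i t_ij`, where predictions with zero
#' total overlap are excluded from the PPV denominator (they contribute
#' nothing to either sum, avoiding division artifacts);
#' `Acc = sqrt(Sn * PPV)`.
#'
#' @inheritParams match_counts
#' @return named numeric vector `c(sensitivity, ppv, accuracy)`; all zeros
#'   (with a warning) when either set is empty
#' @export
sn_ppv_acc <- function(pred, ref) {
  if (length(pred$complexes) == 0L || length(ref$complexes) == 0L) {
    warning("empty predicted or reference complex set; Sn/PPV/Acc reported as 0")
    return(c(sensitivity = 0, ppv = 0, accuracy = 0))
  }
  t_ij <- overlap_table(pred, ref)
  n_i <- vapply(ref$complexes, function(x) length(unique(x)), 1L)
  sn <- sum(apply(t_ij, 1L, max)) / sum(n_i)
  col_tot <- colSums(t_ij)
  nz <- col_tot > 0L
  ppv <- if (any(nz)) {
    sum(apply(t_ij[, nz, drop = FALSE], 2L, max)) / sum(col_tot[nz])
  } else 0
  c(sensitivity = sn, ppv = ppv, accuracy = sqrt(sn * ppv))
}

#' Score a predicted complex set against a reference catalogue
#'
#' Bundles the match counts, precision/recall/F1 and Sn/PPV/accuracy into
#' one report, alongside the complex counts and the size of the largest
#' predicted complex.
#'
#' @inheritParams match_counts
#' @return an object of class `eval_report` (a named list) with fields
#'   `n_predicted`, `n_reference`, `n_cp`, `n_cb`, `precision`, `recall`,
#'   `f1`, `sensitivity`, `ppv`, `accuracy`, `omega`,
#'   `largest_predicted_size`
#' @export
evaluate_complexes <- function(pred, ref, omega = 0.2) {
  stopifnot(inherits(pred, "complex_set"), inherits(ref, "complex_set"))
  mc <- match_counts(pred, ref, omega)
  prf <- precision_recall_f1(pred, ref, omega)
  spa <- if (length(pred$complexes) > 0L && length(ref$complexes) > 0L) {
    sn_ppv_acc(pred, ref)
  } else c(sensitivity = 0, ppv = 0, accuracy = 0)
  sizes <- vapply(pred$complexes, length, 1L)
  structure(list(
    n_predicted = length(pred$complexes),
    n_reference = length(ref$complexes),
    n_cp = unname(mc[["n_cp"]]),
    n_cb = unname(mc[["n_cb"]]),
    precision = unname(prf[["precision"]]),
    recall = unname(prf[["recall"]]),
    f1 = unname(prf[["f1"]]),
    sensitivity = unname(spa[["sensitivity"]]),
    ppv = unname(spa[["ppv"]]),
    accuracy = unname(spa[["accuracy"]]),
    omega = omega,
    largest_predicted_size = if (length(sizes) > 0L) max(sizes) else 0L
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    paste0("eval_report: %d predicted vs %d reference (omega = %g)\n",
           "  precision %.3f  recall %.3f  F1 %.3f\n",
           "  Sn %.3f  PPV %.3f  accuracy %.3f  largest size %d\n"),
    x$n_predicted, x$n_reference, x$omega,
    x$precision, x$recall, x$f1,
    x$sensitivity, x$ppv, x$accuracy, x$largest_predicted_size))
  invisible(x)
}

#' Write an evaluation report as a one-row TSV
#'
#' Column order mirrors the usual comparison tables: complex count, largest
#' size, then precision/recall/F1 and Sn/PPV/accuracy.
#'
#' @param report an `eval_report`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_eval_report <- function(report, path) {
  df <- data.frame(
    n_complexes = report$n_predicted,
    size = report$largest_predicted_size,
    precision = report$precision,
    recall = report$recall,
    f1 = report$f1,
    sensitivity = report$sensitivity,
    ppv = report$ppv,
    accuracy = report$accuracy)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
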