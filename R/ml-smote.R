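#' Synthetic minority over-sampling (SMOTE)
#'
#' Balances a training set by generating synthetic minority-class rows:
#' each synthetic point is `x + u * (x' - x)` where `x` is a minority
#' sample, `x'` one of its `k` nearest minority neighbors (Euclidean
#' distance), and `u ~ U(0, 1)`. Applied to training partitions only; the
#' output has equal class counts. A singleton minority class falls back
#' to duplication with a warning.
#'
#' @param features Numeric feature matrix or data frame (training rows).
#' @param labels 0/1 labels of the training rows.
#' @param k Number of nearest neighbors (default 5).
#' @param seed RNG seed.
#' @return List with the balanced `features` tibble and `labels` vector;
#'   synthetic rows are appended after the originals.
#' @export
#' @examples
#' out <- smote(data.frame(x = c(1:9, 0, 1)), c(rep(0, 9), 1, 1), seed = 1)
#' table(out$labels)
smote <- function(features, labels, k = 5L, seed = 1L) {
  x <- as.matrix(features)
  stopifnot(nrow(x) == length(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  minority <- if (n1 <= n0) 1 else 0
  n_min <- min(n1, n0)
  n_need <- abs(n0 - n1)
  if (n_need == 0L) {
    return(list(features = as_tibble(as.data.frame(x)), labels = labels))
  }
  min_idx <- which(labels == minority)
  with_seed(seed, {
    if (n_min == 1L) {
      warning("minority class is a singleton; duplicating instead of interpolating")
      synth <- x[rep(min_idx, n_need), , drop = FALSE]
    } else {
      xm <- x[min_idx, , drop = FALSE]
      d <- as.matrix(stats::dist(xm))
      diag(d) <- Inf
      k_eff <- min(k, n_min - 1L)
      nn <- apply(d, 1L, function(r) order(r)[seq_len(k_eff)], simplify = FALSE)
      base <- sample(rep_len(seq_len(n_min), n_need))
      pick <- vapply(base, function(b) nn[[b]][sample.int(k_eff, 1L)], integer(1))
      u <- runif(n_need)
      synth <- xm[base, , drop = FALSE] +
        u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
    }
    out_x <- rbind(x, synth)
    rownames(out_x) <- NULL
    list(
      features = as_tibble(as.data.frame(out_x)),
      labels = c(labels, rep(minority, n_need))
    )
  })
}
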