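#' Stratified fold assignment
#'
#' Assigns rows to `k` disjoint folds so that each fold's class
#' proportion is within one item of the global proportion: within each
#' class, rows are shuffled and dealt round-robin over the folds.
#'
#' @param labels 0/1 label vector.
#' @param k Number of folds (>= 2).
#' @param seed RNG seed.
#' @return Integer vector of fold ids (1..k) per row.
#' @export
#' @examples
#' table(stratified_folds(rep(c(0, 1), c(80, 20)), k = 10, seed = 1),
#'   rep(c(0, 1), c(80, 20))
#' )
stratified_folds <- function(labels, k, seed = 1L) {
  if (k < 2L) stop_config("`k` must be at least 2")
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts < k)) {
    stop_config("each class needs at least k = %d members (have %s)", k,
      paste(counts, collapse = "/")
    )
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in c(0, 1)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Participant-grouped stratified folds
#'
#' Assigns whole participants to folds (every row of a participant lands
#' in the same fold), stratifying participants by whether they have any
#' depressed response. Used by the grouped cross-validation mode that
#' keeps repeated measures of one participant out of both partitions.
#'
#' @param labels 0/1 label vector.
#' @param groups Participant id per row.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer fold ids per row.
#' @export
grouped_folds <- function(labels, groups, k, seed = 1L) {
  if (k < 2L) stop_config("`k` must be at least 2")
  part <- tapply(labels, groups, max)
  ids <- names(part)
  fold_of <- setNames(integer(length(ids)), ids)
  with_seed(seed, {
    for (cl in c(0, 1)) {
      idx <- sample(ids[part == cl])
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  unname(fold_of[as.character(groups)])
}
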