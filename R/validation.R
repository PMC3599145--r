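# External validation of a clustering against ground-truth labels via
# normalized mutual information.

#' Normalized mutual information between two labelings
#'
#' Views the predicted clustering and the ground truth as two discrete
#' distributions over the same items, builds their contingency table, and
#' returns `2 I(X;Y) / (H(X) + H(Y))` with natural logarithms — a symmetric
#' score in `[0, 1]` that is invariant to relabeling on either side; 1 means
#' the two partitions coincide. Degenerate cases: if both sides are a single
#' cluster the partitions coincide trivially and the score is 1; if exactly
#' one side has zero entropy the score is 0.
#'
#' @param pred,truth Two-column data frames (id, label) or named vectors.
#'   The two id sets must be identical.
#' @return A single number in `[0, 1]`.
#' @examples
#' nmi(c(a = 1, b = 1, c = 2, d = 2), c(a = "x", b = "x", c = "y", d = "y"))
#' @export
nmi <- function(pred, truth) {
  p <- as_membership(pred, "pred")
  t <- as_membership(truth, "truth")
  if (length(p) == 0L) {
    abort("At least one item is required.", class = "mpick_error_usage")
  }
  miss_p <- setdiff(names(t), names(p))
  miss_t <- setdiff(names(p), names(t))
  if (length(miss_p) > 0L || length(miss_t) > 0L) {
    msg <- c("Id sets differ between `pred` and `truth`.")
    if (length(miss_p) > 0L)
      msg <- c(msg, sprintf("Missing from pred: %s%s",
                            paste(head(miss_p, 5L), collapse = ", "),
                            if (length(miss_p) > 5L) ", ..." else ""))
    if (length(miss_t) > 0L)
      msg <- c(msg, sprintf("Missing from truth: %s%s",
                            paste(head(miss_t, 5L), collapse = ", "),
                            if (length(miss_t) > 5L) ", ..." else ""))
    abort(paste(msg, collapse = " "), class = "mpick_error_data")
  }
  t <- t[names(p)]
  n <- length(p)
  tab <- table(p, t)
  pk <- rowSums(tab) / n
  pl <- colSums(tab) / n
  hx <- -sum(pk[pk > 0] * log(pk[pk > 0]))
  hy <- -sum(pl[pl > 0] * log(pl[pl > 0]))
  if (hx == 0 && hy == 0) return(1)
  if (hx == 0 || hy == 0) return(0)
  pkl <- tab / n
  nz <- pkl > 0
  expected <- outer(pk, pl)
  mi <- sum(pkl[nz] * log(pkl[nz] / expected[nz]))
  max(0, min(1, 2 * mi / (hx + hy)))
}

#' Mean and spread of OTU counts over replicate runs
#'
#' @param x A numeric vector of OTU counts, or a list of fits/partitions
#'   (anything accepted by [nmi()]'s label arguments or `mpick_fit`
#'   objects), one per replicate.
#' @return A one-row tibble: `n_replicates`, `mean_otus`, `sd_otus`
#'   (sample standard deviation; 0 with a warning for a single replicate).
#' @export
otu_count_summary <- function(x) {
  counts <- if (is.numeric(x)) {
    x
  } else if (is.list(x)) {
    vapply(x, function(el) {
      if (inherits(el, "mpick_fit")) el$n_otus
      else length(unique(as_membership(el)))
    }, 1)
  } else {
    abort("`x` must be a numeric vector or a list of results.",
          class = "mpick_error_usage")
  }
  if (length(counts) == 0L) {
    abort("At least one replicate is required.", class = "mpick_error_usage")
  }
  s <- if (length(counts) == 1L) {
    warn("Single replicate: standard deviation reported as 0.")
    0
  } else {
    sd(counts)
  }
  tibble(n_replicates = length(counts), mean_otus = mean(counts),
         sd_otus = s)
}
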