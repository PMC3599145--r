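# Weighted modularity and its bottom-up (Louvain-style) maximization.
#
# Modularity of a partition C on a weighted graph:
#   Q = (1/2m) * sum_ij [ w_ij - k_i k_j / (2m) ] delta(C_i, C_j)
# where m is the total edge weight, k_i the weighted degree, and the sum
# runs over ordered vertex pairs (w_ii = 0). Computed here through the
# equivalent per-community form
#   Q = sum_c [ w_in(c)/m - (tot(c)/(2m))^2 ]
# with w_in(c) the total intra-community edge weight (each edge once) and
# tot(c) the summed degrees; equality with the literal double loop is
# asserted in the unit tests.

membership_for_graph <- function(g, partition) {
  membership <- as_membership(partition)
  missing <- setdiff(g$vertices, names(membership))
  if (length(missing) > 0L) {
    abort(sprintf("Partition misses %d vertices (first: '%s').",
                  length(missing), missing[1L]),
          class = "mpick_error_data")
  }
  extra <- setdiff(names(membership), g$vertices)
  if (length(extra) > 0L) {
    abort(sprintf("Partition contains unknown vertex '%s'.", extra[1L]),
          class = "mpick_error_data")
  }
  labels <- membership[g$vertices]
  match(labels, unique(labels))
}

q_from_membership <- function(comm, ei, ej, ew, k, m) {
  w_in <- sum(ew[comm[ei] == comm[ej]])
  tot <- rowsum(k, comm)
  w_in / m - sum((tot / (2 * m))^2)
}

#' Weighted modularity of a partition
#'
#' @param g An `mpick_graph` with positive total edge weight.
#' @param partition Two-column data frame (id, cluster) or named vector
#'   covering exactly the graph's vertices; cluster labels are arbitrary.
#' @return The modularity Q, a dimensionless real `<= 1`.
#' @examples
#' dm <- all_pairs(tibble::tibble(id = c("a", "b", "c", "d"),
#'                                x = c(0, 0.01, 1, 1.01)))
#' g <- build_graph(dm, epsilon = 0.1, weight_mode = "binary")
#' modularity_q(g, tibble::tibble(id = c("a", "b", "c", "d"),
#'                                cluster = c(1, 1, 2, 2)))
#' @export
modularity_q <- function(g, partition) {
  if (g$m <= 0) {
    abort("Modularity is undefined on an edgeless graph.",
          class = "mpick_error_data")
  }
  comm <- membership_for_graph(g, partition)
  q_from_membership(comm, g$edges$i, g$edges$j, g$edges$weight,
                    unname(g$degree), g$m)
}

# One local-moving sweep phase. Vertices (possibly super-vertices carrying
# self-loop weight) are visited in a freshly shuffled order each pass; each
# vertex moves to the neighboring community with the largest positive
# modularity gain (ties to the smallest community id) until a full pass
# makes no move. Caller provides the RNG state.
louvain_one_level <- function(nn, ei, ej, ew, m) {
  sl <- ei == ej
  self_w <- numeric(nn)
  if (any(sl)) {
    agg <- rowsum(ew[sl], ei[sl])
    self_w[as.integer(rownames(agg))] <- agg
  }
  src <- c(ei[!sl], ej[!sl])
  dst <- c(ej[!sl], ei[!sl])
  w2 <- c(ew[!sl], ew[!sl])
  ord <- order(src)
  src <- src[ord]; dst <- dst[ord]; w2 <- w2[ord]
  deg_count <- tabulate(src, nn)
  ptr_end <- cumsum(deg_count)
  ptr_start <- ptr_end - deg_count + 1L
  k <- numeric(nn)
  if (length(src) > 0L) {
    agg <- rowsum(w2, src)
    k[as.integer(rownames(agg))] <- agg
  }
  k <- k + 2 * self_w
  comm <- seq_len(nn)
  tot <- k
  moved_any <- FALSE
  repeat {
    moved <- FALSE
    for (v in sample.int(nn)) {
      cv <- comm[v]
      if (deg_count[v] == 0L) next
      sel <- ptr_start[v]:ptr_end[v]
      wc <- rowsum(w2[sel], comm[dst[sel]])
      cand <- as.integer(rownames(wc))
      if (!(cv %in% cand)) {
        cand <- c(cand, cv)
        wc <- c(wc, 0)
      }
      tot[cv] <- tot[cv] - k[v]
      gain <- wc / m - tot[cand] * k[v] / (2 * m^2)
      best <- which(gain == max(gain))
      target <- cand[best][which.min(cand[best])]
      cur_gain <- gain[match(cv, cand)]
      if (target != cv && gain[match(target, cand)] > cur_gain + 1e-12) {
        comm[v] <- target
        tot[target] <- tot[target] + k[v]
        moved <- TRUE
        moved_any <- TRUE
      } else {
        tot[cv] <- tot[cv] + k[v]
      }
    }
    if (!moved) break
  }
  list(comm = match(comm, sort(unique(comm))), moved = moved_any)
}

#' Maximize modularity with the bottom-up two-phase optimizer
#'
#' Starts from the all-singletons partition; phase one sweeps vertices in a
#' seed-shuffled order, greedily moving each to the neighboring community
#' with the largest positive modularity gain; phase two aggregates
#' communities into super-vertices (intra-community weight becomes a
#' self-loop) and repeats, until a full cycle yields no move. The returned
#' partition is a local maximum: no single-vertex move to a neighboring
#' community increases Q. Deterministic given `(g, seed)`.
#'
#' @param g An `mpick_graph` with positive total edge weight.
#' @param seed Integer seed controlling the vertex sweep order.
#' @return A partition tibble (`member_id`, `cluster`) with the achieved
#'   modularity in attribute `"q_value"`.
#' @export
louvain_maximize <- function(g, seed = 42L) {
  if (g$m <= 0) {
    abort("Modularity is undefined on an edgeless graph.",
          class = "mpick_error_data")
  }
  n <- length(g$vertices)
  ei <- g$edges$i; ej <- g$edges$j; ew <- g$edges$weight
  node_of <- seq_len(n)
  m <- g$m
  with_seed(seed, {
    repeat {
      nn <- max(node_of)
      res <- louvain_one_level(nn, ei, ej, ew, m)
      comm <- res$comm
      K <- max(comm)
      node_of <- comm[node_of]
      if (!res$moved || K == nn) break
      ci <- pmin(comm[ei], comm[ej])
      cj <- pmax(comm[ei], comm[ej])
      key <- (ci - 1) * K + cj
      agg <- rowsum(ew, key)
      keys <- as.numeric(rownames(agg))
      ei <- as.integer((keys - 1) %/% K) + 1L
      ej <- as.integer((keys - 1) %% K) + 1L
      ew <- as.numeric(agg[, 1L])
    }
  })
  out <- tibble(member_id = g$vertices, cluster = node_of)
  attr(out, "q_value") <- q_from_membership(node_of, g$edges$i, g$edges$j,
                                            g$edges$weight,
                                            unname(g$degree), g$m)
  class(out) <- c("mpick_partition", class(tibble()))
  out
}

# Enumerate restricted growth strings (canonical set-partition encodings)
# in lexicographic order, calling `fun` on each membership vector.
rgs_enumerate <- function(n, fun) {
  a <- rep(1L, n)
  repeat {
    fun(a)
    # successor: rightmost position (past the first) that can be raised
    mx <- cummax(c(0L, a[-n]))
    i <- n
    while (i > 1L && a[i] > mx[i]) i <- i - 1L
    if (i == 1L) break
    a[i] <- a[i] + 1L
    if (i < n) a[(i + 1L):n] <- 1L
  }
  invisible(NULL)
}

#' Exhaustive modularity maximization (test oracle)
#'
#' Enumerates every set partition of the vertices and returns the one with
#' maximal modularity. Exponential in the vertex count; intended as an
#' independent oracle for [louvain_maximize()] on tiny graphs. Ties are
#' broken by fewer clusters, then by the lexicographically smallest
#' canonical encoding.
#'
#' @param g An `mpick_graph` with at most 12 vertices and positive total
#'   edge weight.
#' @return A partition tibble (`member_id`, `cluster`) with attribute
#'   `"q_value"`.
#' @export
best_partition_bruteforce <- function(g) {
  n <- length(g$vertices)
  if (n > 12L) {
    abort("Exhaustive enumeration is limited to 12 vertices.",
          class = "mpick_error_usage")
  }
  if (g$m <= 0) {
    abort("Modularity is undefined on an edgeless graph.",
          class = "mpick_error_data")
  }
  ei <- g$edges$i; ej <- g$edges$j; ew <- g$edges$weight
  k <- unname(g$degree); m <- g$m
  best_q <- -Inf; best_a <- NULL; best_k <- Inf
  rgs_enumerate(n, function(a) {
    q <- q_from_membership(a, ei, ej, ew, k, m)
    nk <- max(a)
    better <- q > best_q + 1e-12 ||
      (abs(q - best_q) <= 1e-12 && nk < best_k)
    if (better) {
      best_q <<- q; best_a <<- a; best_k <<- nk
    }
  })
  out <- tibble(member_id = g$vertices, cluster = best_a)
  attr(out, "q_value") <- best_q
  class(out) <- c("mpick_partition", class(tibble()))
  out
}

#' Modularity achieved by a partition object
#'
#' @param partition A partition returned by [louvain_maximize()] or
#'   [best_partition_bruteforce()].
#' @return The stored modularity value.
#' @export
q_value <- function(partition) {
  attr(partition, "q_value")
}
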