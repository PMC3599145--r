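# Independent oracles and fixture builders. Each oracle recomputes a
# quantity by a route the implementation does not share: literal formula
# expansion, exhaustive enumeration, or brute-force reachability.

# Literal double-loop modularity: Q = (1/2m) sum_ij (w_ij - k_i k_j / 2m)
# over ordered vertex pairs (w_ii = 0), delta on shared cluster.
oracle_modularity <- function(g, partition) {
  membership <- partition
  if (is.data.frame(membership)) {
    membership <- setNames(as.character(membership[[2]]),
                           as.character(membership[[1]]))
  }
  n <- length(g$vertices)
  W <- matrix(0, n, n)
  for (r in seq_len(nrow(g$edges))) {
    i <- g$edges$i[r]; j <- g$edges$j[r]
    W[i, j] <- W[i, j] + g$edges$weight[r]
    W[j, i] <- W[j, i] + g$edges$weight[r]
  }
  k <- rowSums(W)
  m <- sum(W) / 2
  comm <- membership[g$vertices]
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (comm[i] == comm[j]) q <- q + W[i, j] - k[i] * k[j] / (2 * m)
    }
  }
  q / (2 * m)
}

# Exhaustive alignment enumeration for tiny sequences under the package's
# scoring (match +1, mismatch -1, gap -2, terminal gaps free). Walks every
# monotone path through the alignment lattice; gap moves on the boundary
# rows/columns are free and unscored. Returns the optimal score and the
# set of distances realised by optimal alignments.
oracle_align <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  best <- list(score = -Inf, distances = numeric(0))
  recurse <- function(i, j, score, mis, gaps, cols) {
    if (i == n && j == m) {
      if (score > best$score + 1e-12) {
        best <<- list(score = score,
                      distances = if (cols > 0) (mis + gaps) / cols else 1)
      } else if (abs(score - best$score) <= 1e-12) {
        d <- if (cols > 0) (mis + gaps) / cols else 1
        best$distances <<- unique(c(best$distances, d))
      }
      return(invisible(NULL))
    }
    if (i < n && j < m) {
      eq <- a[i + 1] == b[j + 1] && a[i + 1] %in% c("A", "C", "G", "T")
      recurse(i + 1, j + 1, score + if (eq) 1 else -1,
              mis + !eq, gaps, cols + 1)
    }
    if (i < n) { # gap in b; free on the boundary columns j == 0 or j == m
      free <- j == 0 || j == m
      recurse(i + 1, j, score + if (free) 0 else -2,
              mis, gaps + !free, cols + !free)
    }
    if (j < m) { # gap in a; free on the boundary rows i == 0 or i == n
      free <- i == 0 || i == n
      recurse(i, j + 1, score + if (free) 0 else -2,
              mis, gaps + !free, cols + !free)
    }
    invisible(NULL)
  }
  recurse(0, 0, 0, 0, 0, 0)
  best
}

# Brute-force reachability components via boolean matrix powers.
oracle_components <- function(g) {
  n <- length(g$vertices)
  R <- diag(TRUE, n)
  for (r in seq_len(nrow(g$edges))) {
    R[g$edges$i[r], g$edges$j[r]] <- TRUE
    R[g$edges$j[r], g$edges$i[r]] <- TRUE
  }
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R > 0)) break
    R <- R2
  }
  groups <- unique(lapply(seq_len(n), function(i) which(R[i, ])))
  lapply(groups, function(idx) g$vertices[idx])
}

# Independent NMI from first principles, using base-2 logarithms (the
# score is base-invariant, so this cross-checks the natural-log route).
oracle_nmi <- function(pred, truth) {
  tab <- table(pred, truth)
  n <- sum(tab)
  h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hx <- h(rowSums(tab) / n)
  hy <- h(colSums(tab) / n)
  if (hx == 0 && hy == 0) return(1)
  if (hx == 0 || hy == 0) return(0)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      if (tab[i, j] > 0) {
        mi <- mi + tab[i, j] / n *
          log2(tab[i, j] * n / (sum(tab[i, ]) * sum(tab[, j])))
      }
    }
  }
  2 * mi / (hx + hy)
}

# Distance-object fixture with full control over stored pairs and labels.
make_dist <- function(pairs, labels = NULL, mode = "sequence") {
  pairs <- tibble::as_tibble(pairs)
  names(pairs) <- c("id1", "id2", "distance")
  if (is.null(labels)) labels <- unique(c(rbind(pairs$id1, pairs$id2)))
  mpick:::new_mpick_dist(pairs, labels, mode)
}

# Random weighted graph on n vertices: edges kept with probability p,
# weights in (0.05, 1]; optionally forced connected via a random spanning
# tree. Returned as an mpick_graph built through the public API.
random_graph <- function(n, seed, p = 0.5, connected = FALSE) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n))
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  if (connected && n > 1) {
    perm <- sample(n)
    tree <- cbind(perm[-1], perm[vapply(2:n, function(i) sample(i - 1, 1), 1)])
    tree <- t(apply(tree, 1, sort))
    keep <- keep | (paste(pairs[, 1], pairs[, 2]) %in% paste(tree[, 1], tree[, 2]))
  }
  pairs <- pairs[keep, , drop = FALSE]
  w <- runif(nrow(pairs), 0.05, 1)
  dm <- make_dist(
    tibble::tibble(id1 = ids[pairs[, 1]], id2 = ids[pairs[, 2]],
                   distance = 1 - w),
    labels = ids)
  build_graph(dm, epsilon = 1, weight_mode = "similarity")
}

# Clique-union fixture: disjoint unit-weight cliques, optionally joined in
# a chain by single unit edges.
clique_graph <- function(sizes, join = TRUE) {
  ids <- unlist(lapply(seq_along(sizes), function(k)
    sprintf("c%d_%02d", k, seq_len(sizes[k]))))
  blocks <- split(ids, rep(seq_along(sizes), sizes))
  pairs <- do.call(rbind, lapply(blocks, function(b) {
    if (length(b) < 2) return(NULL)
    t(combn(b, 2))
  }))
  if (join && length(blocks) > 1) {
    for (k in seq_len(length(blocks) - 1)) {
      pairs <- rbind(pairs, c(blocks[[k]][1], blocks[[k + 1]][1]))
    }
  }
  dm <- make_dist(tibble::tibble(id1 = pairs[, 1], id2 = pairs[, 2],
                                 distance = 0),
                  labels = ids)
  build_graph(dm, epsilon = 1, weight_mode = "similarity")
}

membership_of <- function(fit) {
  setNames(fit$otus$otu_id, fit$otus$member_id)
}
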