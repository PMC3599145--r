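# The epsilon-neighborhood similarity graph and the sub-graph services used
# by the recursive clustering driver.

new_mpick_graph <- function(vertices, edges, epsilon, weight_mode) {
  vertices <- as.character(vertices)
  degree <- rep(0, length(vertices))
  names(degree) <- vertices
  if (nrow(edges) > 0L) {
    agg <- tapply(c(edges$weight, edges$weight), c(edges$i, edges$j), sum)
    degree[as.integer(names(agg))] <- agg
  }
  structure(list(vertices = vertices,
                 edges = edges,
                 epsilon = epsilon,
                 weight_mode = weight_mode,
                 m = sum(edges$weight),
                 degree = degree),
            class = "mpick_graph")
}

#' Build the epsilon-neighborhood graph
#'
#' Retains an edge for every stored pair with distance strictly below
#' `epsilon` (equivalently, similarity above `1 - epsilon`). In
#' `"similarity"` mode edge weights are `1 - distance`; in `"binary"` mode
#' every retained edge has weight 1 (useful for generic metrics whose
#' distances exceed 1, where `1 - d` would go negative). Items without any
#' retained edge remain in the graph as isolated vertices.
#'
#' @param dm Sparse distance object from [all_pairs()] or
#'   [read_distances()].
#' @param epsilon Positive neighborhood threshold; must be `<= 1` in
#'   similarity mode.
#' @param weight_mode `"similarity"` or `"binary"`.
#' @return An `mpick_graph`: vertices, weighted edge list, total edge weight
#'   `m` and weighted vertex degrees.
#' @export
build_graph <- function(dm, epsilon, weight_mode = c("similarity", "binary")) {
  weight_mode <- match.arg(weight_mode)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    abort("`epsilon` must be a single positive number.",
          class = "mpick_error_usage")
  }
  if (weight_mode == "similarity" && epsilon > 1) {
    abort("Similarity weights 1 - d require `epsilon` <= 1; use weight_mode = \"binary\" for larger thresholds.",
          class = "mpick_error_usage")
  }
  cutoff <- attr(dm, "cutoff")
  if (!is.null(cutoff) && !is.na(cutoff) && epsilon > cutoff) {
    abort(sprintf("`epsilon` (%g) exceeds the storage cutoff (%g) of the distance matrix.",
                  epsilon, cutoff),
          class = "mpick_error_usage")
  }
  vertices <- dist_labels(dm)
  keep <- dm$distance < epsilon
  i <- match(dm$id1[keep], vertices)
  j <- match(dm$id2[keep], vertices)
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  w <- if (weight_mode == "similarity") 1 - dm$distance[keep]
       else rep(1, sum(keep))
  edges <- tibble(i = i, j = j,
                  from = vertices[i], to = vertices[j],
                  weight = w)[order(i, j), ]
  new_mpick_graph(vertices, edges, epsilon, weight_mode)
}

#' @export
print.mpick_graph <- function(x, ...) {
  cat(sprintf("<mpick_graph> %d vertices, %d edges (epsilon = %g, %s weights), m = %.6g\n",
              length(x$vertices), nrow(x$edges), x$epsilon, x$weight_mode,
              x$m))
  invisible(x)
}

#' Connected components of a graph
#'
#' Because merging disconnected parts of a graph never increases
#' modularity, each component can be clustered independently; the driver
#' relies on this decomposition.
#'
#' @param g An `mpick_graph`.
#' @return A list of character vectors of vertex ids, each sorted by
#'   position in `g$vertices`; components ordered by their smallest vertex.
#'   Isolated vertices are singleton components.
#' @export
graph_components <- function(g) {
  n <- length(g$vertices)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(g$edges) > 0L) {
    for (k in seq_len(nrow(g$edges))) {
      ri <- find(g$edges$i[k]); rj <- find(g$edges$j[k])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  comps <- split(seq_len(n), root)
  comps <- comps[order(as.integer(names(comps)))]
  lapply(unname(comps), function(idx) g$vertices[sort(idx)])
}

#' Induced sub-graph
#'
#' Retains exactly the edges with both endpoints in `vertex_subset`;
#' total weight and degrees are recomputed on the sub-graph.
#'
#' @param g An `mpick_graph`.
#' @param vertex_subset Non-empty character vector of vertex ids.
#' @return An `mpick_graph` over `vertex_subset`.
#' @export
induced_subgraph <- function(g, vertex_subset) {
  vertex_subset <- as.character(vertex_subset)
  if (length(vertex_subset) == 0L) {
    abort("`vertex_subset` must be non-empty.", class = "mpick_error_usage")
  }
  unknown <- setdiff(vertex_subset, g$vertices)
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown vertex '%s' in subset.", unknown[1L]),
          class = "mpick_error_usage")
  }
  vertices <- g$vertices[g$vertices %in% vertex_subset]
  pos <- match(g$vertices, vertices)
  ni <- pos[g$edges$i]
  nj <- pos[g$edges$j]
  keep <- !is.na(ni) & !is.na(nj)
  edges <- tibble(i = ni[keep], j = nj[keep],
                  from = vertices[ni[keep]], to = vertices[nj[keep]],
                  weight = g$edges$weight[keep])
  new_mpick_graph(vertices, edges, g$epsilon, g$weight_mode)
}

#' Write the edge list of a graph
#'
#' Debug writer: emits `id1<TAB>id2<TAB>weight` rows.
#'
#' @param g An `mpick_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(g, path) {
  write_atomically(path, function(tmp) {
    writeLines(sprintf("%s\t%s\t%.17g", g$edges$from, g$edges$to,
                       g$edges$weight), tmp)
  })
  invisible(path)
}
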