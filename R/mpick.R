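# The M-pick driver: build the epsilon-neighborhood graph, cluster each
# connected component by recursive modularity maximization, stop splitting
# a sub-graph when its maximum attainable modularity falls below delta, and
# report the leaves as OTUs.

leaf_node <- function(vertices, max_q = NA_real_) {
  list(vertices = vertices, max_q = max_q, is_otu = TRUE, children = list())
}

#' Recursively cluster one connected sub-graph
#'
#' Runs the modularity maximizer on the sub-graph. If the achieved
#' modularity is below `delta` (strictly), or the optimizer returns a
#' single cluster, the sub-graph is accepted as one OTU. Otherwise the
#' split is accepted and each sub-cluster — re-split into connected
#' components first, since a locally optimal cluster may be internally
#' disconnected — is processed recursively.
#'
#' @param g_sub A connected `mpick_graph` with at least one vertex.
#' @param delta Stopping threshold on sub-graph modularity, in `[0, 1)`.
#' @param seed Integer seed passed to [louvain_maximize()].
#' @param depth Current recursion depth (used internally).
#' @param max_depth Safety cap on recursion depth.
#' @return A list with `leaves` (list of vertex-id vectors, one per OTU),
#'   `tree` (the recursion node) and `splits` (a tibble of the modularity
#'   values examined at each node).
#' @export
recurse_component <- function(g_sub, delta = 0.1, seed = 42L, depth = 0L,
                              max_depth = 50L) {
  nv <- length(g_sub$vertices)
  if (nv == 1L || g_sub$m <= 0) {
    leaves <- as.list(g_sub$vertices)
    node <- if (nv == 1L) leaf_node(g_sub$vertices)
            else list(vertices = g_sub$vertices, max_q = NA_real_,
                      is_otu = FALSE,
                      children = lapply(g_sub$vertices, leaf_node))
    return(list(leaves = leaves, tree = node,
                splits = tibble(depth = integer(), n_vertices = integer(),
                                q = double(), accepted = logical())))
  }
  if (depth >= max_depth) {
    warn(sprintf("Recursion depth cap (%d) reached on a sub-graph of %d vertices; accepting it as one OTU.",
                 max_depth, nv))
    return(list(leaves = list(g_sub$vertices),
                tree = leaf_node(g_sub$vertices),
                splits = tibble(depth = depth, n_vertices = nv,
                                q = NA_real_, accepted = FALSE)))
  }
  part <- louvain_maximize(g_sub, seed)
  q <- q_value(part)
  clusters <- split(part$member_id, part$cluster)
  record <- tibble(depth = depth, n_vertices = nv, q = q,
                   accepted = !(q < delta || length(clusters) == 1L))
  if (q < delta || length(clusters) == 1L) {
    return(list(leaves = list(g_sub$vertices),
                tree = leaf_node(g_sub$vertices, max_q = q),
                splits = record))
  }
  leaves <- list()
  children <- list()
  splits <- list(record)
  for (cl in clusters) {
    sub2 <- induced_subgraph(g_sub, cl)
    for (comp in graph_components(sub2)) {
      res <- recurse_component(induced_subgraph(sub2, comp), delta = delta,
                               seed = seed, depth = depth + 1L,
                               max_depth = max_depth)
      leaves <- c(leaves, res$leaves)
      children <- c(children, list(res$tree))
      splits <- c(splits, list(res$splits))
    }
  }
  list(leaves = leaves,
       tree = list(vertices = g_sub$vertices, max_q = q, is_otu = FALSE,
                   children = children),
       splits = dplyr::bind_rows(splits))
}

#' Cluster a distance matrix into OTUs
#'
#' The core M-pick procedure on precomputed distances: (1) build the
#' epsilon-neighborhood graph; (2) isolated vertices become singleton OTUs;
#' (3) every connected component is clustered by recursive modularity
#' maximization with stopping threshold `delta`. The final partition is
#' complete over all input ids and deterministic given `(dm, parameters,
#' seed)`.
#'
#' @param dm Sparse distance object from [all_pairs()] or
#'   [read_distances()].
#' @param epsilon Distance threshold for the neighborhood graph (default
#'   0.04, the recommended species-level setting for 16S data).
#' @param delta Stopping threshold on sub-graph modularity (default 0.1).
#' @param seed Integer seed for the optimizer's sweep order.
#' @param weight_mode `"similarity"` (edge weight `1 - d`) or `"binary"`.
#' @param max_depth Safety cap on recursion depth.
#' @return An object of class `mpick_fit`; see [tidy.mpick_fit()],
#'   [glance.mpick_fit()] and [autoplot.mpick_fit()].
#' @examples
#' pts <- tibble::tibble(id = paste0("p", 1:6),
#'                       x = c(0, 0.1, 0.2, 5, 5.1, 5.2))
#' fit <- mpick_cluster(all_pairs(pts), epsilon = 0.5)
#' tidy(fit)
#' @export
mpick_cluster <- function(dm, epsilon = 0.04, delta = 0.1, seed = 42L,
                          weight_mode = c("similarity", "binary"),
                          max_depth = 50L) {
  weight_mode <- match.arg(weight_mode)
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 || delta >= 1) {
    abort("`delta` must lie in [0, 1).", class = "mpick_error_usage")
  }
  if (nrow(dm) == 0L && length(dist_labels(dm)) == 0L) {
    abort("The distance matrix is empty.", class = "mpick_error_usage")
  }
  g <- build_graph(dm, epsilon, weight_mode)
  comps <- graph_components(g)
  leaves <- list()
  forest <- list()
  splits <- list()
  for (comp in comps) {
    if (length(comp) == 1L) {
      leaves <- c(leaves, list(comp))
      forest <- c(forest, list(leaf_node(comp)))
    } else {
      res <- recurse_component(induced_subgraph(g, comp), delta = delta,
                               seed = seed, max_depth = max_depth)
      leaves <- c(leaves, res$leaves)
      forest <- c(forest, list(res$tree))
      splits <- c(splits, list(res$splits))
    }
  }
  member_id <- unlist(leaves, use.names = FALSE)
  cluster <- rep(seq_along(leaves), lengths(leaves))
  otus <- canonical_otus(member_id, cluster)
  structure(list(otus = otus,
                 params = list(epsilon = epsilon, delta = delta, seed = seed,
                               weight_mode = weight_mode,
                               max_depth = max_depth),
                 n_otus = length(leaves),
                 n_items = length(member_id),
                 n_components = length(comps),
                 n_edges = nrow(g$edges),
                 total_weight = g$m,
                 splits = dplyr::bind_rows(splits),
                 tree = forest),
            class = "mpick_fit")
}

#' Run the full OTU-picking pipeline
#'
#' Accepts exactly one input kind — sequence records (`id`, `sequence`),
#' point coordinates (`id` plus numeric columns), or a precomputed sparse
#' distance object — computes pairwise distances where needed, optionally
#' preclusters sequences first, clusters with [mpick_cluster()], and (for a
#' preclustered run) expands the representative-level OTUs back to all
#' members.
#'
#' @param input Sequence tibble, point tibble, or sparse distance object.
#' @inheritParams mpick_cluster
#' @param precluster_level Optional greedy preclustering distance level
#'   (e.g. 0.01); sequence input only.
#' @param out Optional path: write the OTU table there.
#' @param log Optional path: append timestamped run records there.
#' @return An `mpick_fit` (with OTUs over all input members).
#' @export
run_mpick <- function(input, epsilon = 0.04, delta = 0.1, seed = 42L,
                      weight_mode = c("similarity", "binary"),
                      precluster_level = NULL, out = NULL, log = NULL,
                      max_depth = 50L) {
  weight_mode <- match.arg(weight_mode)
  logf <- function(fmt, ...) {
    if (!is.null(log)) {
      line <- sprintf("%s\tINFO\t%s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                      sprintf(fmt, ...))
      cat(line, "\n", sep = "", file = log, append = TRUE)
    }
  }
  logf("run_mpick epsilon=%g delta=%g seed=%d weight_mode=%s", epsilon,
       delta, as.integer(seed), weight_mode)
  is_dist <- inherits(input, "mpick_dist")
  is_seq <- !is_dist && is.data.frame(input) && "sequence" %in% names(input)
  is_pts <- !is_dist && !is_seq && is.data.frame(input) &&
    "id" %in% names(input)
  if (!is_dist && !is_seq && !is_pts) {
    abort("`input` must be sequences (id, sequence), points (id + numeric columns), or a sparse distance object.",
          class = "mpick_error_usage")
  }
  preclusters <- NULL
  if (!is.null(precluster_level)) {
    if (!is_seq) {
      abort("`precluster_level` applies to sequence input only.",
            class = "mpick_error_usage")
    }
    preclusters <- precluster_greedy(input, precluster_level)
    reps <- unique(preclusters$representative)
    logf("preclustered %d sequences into %d representatives at level %g",
         nrow(input), length(reps), precluster_level)
    input <- input[match(reps, input$id), ]
  }
  dm <- if (is_dist) input else all_pairs(input)
  logf("distance matrix: %d items, %d stored pairs", length(dist_labels(dm)),
       nrow(dm))
  fit <- mpick_cluster(dm, epsilon = epsilon, delta = delta, seed = seed,
                       weight_mode = weight_mode, max_depth = max_depth)
  if (!is.null(preclusters)) {
    expanded <- expand_partition(
      stats::setNames(fit$otus$otu_id, fit$otus$member_id), preclusters)
    fit$otus <- canonical_otus(expanded$member_id, expanded$cluster)
    fit$n_items <- nrow(fit$otus)
    fit$n_otus <- length(unique(fit$otus$otu_id))
    fit$preclusters <- preclusters
  }
  logf("picked %d OTUs from %d items (%d graph components)", fit$n_otus,
       fit$n_items, fit$n_components)
  if (!is.null(out)) {
    write_otu_table(stats::setNames(fit$otus$otu_id, fit$otus$member_id), out)
    logf("wrote OTU table to %s", out)
  }
  fit
}

#' @export
print.mpick_fit <- function(x, ...) {
  cat(sprintf("<mpick_fit> %d OTUs from %d items\n", x$n_otus, x$n_items))
  cat(sprintf("  epsilon = %g, delta = %g, seed = %d, %s weights\n",
              x$params$epsilon, x$params$delta, as.integer(x$params$seed),
              x$params$weight_mode))
  cat(sprintf("  graph: %d components, %d edges, total weight %.4g\n",
              x$n_components, x$n_edges, x$total_weight))
  sizes <- table(x$otus$otu_id)
  cat(sprintf("  OTU sizes: largest %d, median %g, singletons %d\n",
              max(sizes), stats::median(as.integer(sizes)),
              sum(sizes == 1L)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an OTU clustering result
#'
#' @param x An `mpick_fit`.
#' @param ... Unused.
#' @return The OTU membership tibble (`member_id`, `otu_id`), rows ordered
#'   by OTU then member.
#' @export
tidy.mpick_fit <- function(x, ...) {
  x$otus
}

#' One-row summary of an OTU clustering result
#'
#' @param x An `mpick_fit`.
#' @param ... Unused.
#' @return A one-row tibble: item and OTU counts, graph statistics, the
#'   parameters used, and the recursion depth reached.
#' @export
glance.mpick_fit <- function(x, ...) {
  tibble(n_items = x$n_items,
         n_otus = x$n_otus,
         n_components = x$n_components,
         n_edges = x$n_edges,
         total_weight = x$total_weight,
         epsilon = x$params$epsilon,
         delta = x$params$delta,
         seed = as.integer(x$params$seed),
         weight_mode = x$params$weight_mode,
         max_depth_used = if (nrow(x$splits) > 0L) max(x$splits$depth) + 1L
                          else 0L)
}
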