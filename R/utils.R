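# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, leaving the caller's RNG state
# untouched. All stochastic package code funnels through this so results are
# pure functions of (input, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.", class = "mpick_error_usage")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Canonical OTU naming: clusters ordered by decreasing size, ties broken by
# the lexicographically smallest member id; names OTU_000001, OTU_000002, ...
# Rows come back sorted by otu_id then member_id so the table is
# byte-deterministic for a fixed partition.
canonical_otus <- function(member_id, cluster) {
  stopifnot(length(member_id) == length(cluster))
  member_id <- as.character(member_id)
  cluster <- as.character(cluster)
  size <- table(cluster)
  first_member <- tapply(member_id, cluster, function(x) min(x))
  ord <- order(-as.integer(size[names(first_member)]),
               as.character(first_member))
  ranks <- seq_along(ord)
  names(ranks) <- names(first_member)[ord]
  otu <- sprintf("OTU_%06d", ranks[cluster])
  out <- tibble(member_id = member_id, otu_id = unname(otu))
  out[order(out$otu_id, out$member_id), ]
}

# Coerce a partition-like input (two-column data frame id/cluster, or a
# named vector) to a named character vector of cluster labels keyed by id.
as_membership <- function(x, arg = "partition") {
  if (length(x) == 0L && !is.data.frame(x)) {
    return(stats::setNames(character(0), character(0)))
  }
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) {
      abort(sprintf("`%s` must have an id column and a cluster column.", arg),
            class = "mpick_error_usage")
    }
    out <- as.character(x[[2L]])
    names(out) <- as.character(x[[1L]])
  } else if (!is.null(names(x))) {
    out <- as.character(x)
    names(out) <- names(x)
  } else {
    abort(sprintf("`%s` must be a two-column data frame or a named vector.", arg),
          class = "mpick_error_usage")
  }
  if (anyDuplicated(names(out))) {
    abort(sprintf("`%s` assigns some ids more than once.", arg),
          class = "mpick_error_data")
  }
  out
}

# Atomic file write: write to a temp file in the destination directory and
# rename into place, so failures never leave partial output behind.
write_atomically <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(sprintf("Directory does not exist: %s", dir),
          class = "mpick_error_usage")
  }
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    abort(sprintf("Could not write to %s", path), class = "mpick_error_data")
  }
  invisible(path)
}
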