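# Pairwise distances: global-alignment distances for sequences, Euclidean
# distances for point mode, plus the optional greedy preclustering step used
# to shrink large datasets before all-pairs alignment.

check_sequences <- function(sequence, arg = "sequence") {
  if (any(nchar(sequence) == 0L)) {
    abort("Sequences must be non-empty.", class = "mpick_error_data")
  }
  bad <- grepl(sprintf("[^%s]", IUPAC_DNA), sequence)
  if (any(bad)) {
    abort(sprintf("Sequence contains characters outside the IUPAC DNA alphabet: %s",
                  substr(sequence[bad][1L], 1L, 40L)),
          class = "mpick_error_data")
  }
  invisible(sequence)
}

normalize_residues <- function(sequence) {
  gsub("U", "T", toupper(sequence), fixed = TRUE)
}

#' Global-alignment distance between two sequences
#'
#' Needleman-Wunsch alignment with match +1, mismatch -1, gap -2 and free
#' terminal gaps. The distance is (mismatch columns + internal gap columns)
#' divided by the number of aligned columns excluding terminal-gap columns,
#' a fraction in `[0, 1]`. Ambiguity codes (`N` etc.) count as mismatches
#' against every residue, including themselves. The function is symmetric in
#' its arguments.
#'
#' @param a,b DNA sequences (character scalars; lower case and `U` accepted).
#' @return A single distance in `[0, 1]`.
#' @examples
#' seq_distance("ACGT", "ACGA") # one mismatch over four columns: 0.25
#' @export
seq_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  a <- normalize_residues(a); b <- normalize_residues(b)
  check_sequences(c(a, b))
  # fixed evaluation order makes ties in the optimal alignment symmetric
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  .nw_align_stats(a, b)$distance
}

#' Alignment details for two sequences
#'
#' Same convention as [seq_distance()], returning the optimal score and the
#' column counts behind the distance.
#'
#' @inheritParams seq_distance
#' @return A one-row tibble: `score`, `distance`, `mismatches`,
#'   `internal_gaps`, `scored_columns`.
#' @export
align_stats <- function(a, b) {
  a <- normalize_residues(a); b <- normalize_residues(b)
  check_sequences(c(a, b))
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  as_tibble(.nw_align_stats(a, b))
}

#' All pairwise distances
#'
#' Evaluates every unordered pair of items. For sequence input (a tibble
#' with `id` and `sequence` columns, as from [read_fasta()]) distances are
#' global-alignment fractions; for point input (a tibble with `id` and
#' numeric coordinate columns) they are Euclidean. If `cutoff` is given only
#' pairs with distance strictly below it are stored; the sparse result is
#' sufficient for any neighborhood graph with `epsilon <= cutoff`.
#'
#' @param x Sequence or point tibble.
#' @param cutoff Optional positive storage cutoff.
#' @return A sparse distance object (see [read_distances()]).
#' @export
all_pairs <- function(x, cutoff = NULL) {
  stopifnot(is.data.frame(x), "id" %in% names(x))
  if (!is.null(cutoff)) {
    if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
      abort("`cutoff` must be a single positive number.",
            class = "mpick_error_usage")
    }
  }
  ids <- as.character(x$id)
  if (anyDuplicated(ids)) {
    abort("Item ids must be unique.", class = "mpick_error_data")
  }
  if (nrow(x) < 2L) {
    abort("At least two items are required.", class = "mpick_error_usage")
  }
  lim <- if (is.null(cutoff)) Inf else cutoff
  if ("sequence" %in% names(x)) {
    seqs <- normalize_residues(x$sequence)
    check_sequences(seqs)
    res <- .nw_all_pairs(seqs, lim)
    mode <- "sequence"
  } else {
    coords <- as.matrix(x[setdiff(names(x), "id")])
    if (!is.numeric(coords) || ncol(coords) < 1L) {
      abort("Point input needs at least one numeric coordinate column.",
            class = "mpick_error_data")
    }
    D <- as.matrix(dist(coords))
    idx <- which(upper.tri(D), arr.ind = TRUE)
    keep <- D[idx] < lim
    res <- list(i = idx[keep, 1L], j = idx[keep, 2L], d = D[idx][keep])
    mode <- "point"
  }
  ord <- order(res$i, res$j)
  pairs <- tibble(id1 = ids[res$i][ord], id2 = ids[res$j][ord],
                  distance = res$d[ord])
  new_mpick_dist(pairs, ids, mode,
                 cutoff = if (is.null(cutoff)) NA_real_ else cutoff)
}

#' Greedy preclustering of sequences
#'
#' Incremental single-pass preclustering at a small distance level, used to
#' reduce large datasets before all-pairs alignment: a representative from
#' each precluster stands in for its members. Records are processed in
#' decreasing length order (ties broken by id); each record joins the first
#' existing representative at alignment distance below `level`, otherwise it
#' founds a new precluster.
#'
#' @param records Sequence tibble (`id`, `sequence`).
#' @param level Distance level in (0, 1); 0.01 is the conventional choice.
#' @return A tibble with columns `representative` and `id` (one row per
#'   member; representatives are members of their own preclusters), in
#'   founding order.
#' @export
precluster_greedy <- function(records, level = 0.01) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence") %in% names(records)))
  if (nrow(records) == 0L) {
    abort("No sequences to precluster.", class = "mpick_error_usage")
  }
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    abort("`level` must lie in (0, 1).", class = "mpick_error_usage")
  }
  seqs <- normalize_residues(records$sequence)
  check_sequences(seqs)
  ids <- as.character(records$id)
  ord <- order(-nchar(seqs), ids)
  rep_seq <- character(0)
  rep_id <- character(0)
  assign_to <- character(length(ids))
  names(assign_to) <- ids
  for (k in ord) {
    hit <- 0L
    for (r in seq_along(rep_seq)) {
      if (.nw_align_stats(rep_seq[r], seqs[k])$distance < level) {
        hit <- r; break
      }
    }
    if (hit == 0L) {
      rep_seq <- c(rep_seq, seqs[k])
      rep_id <- c(rep_id, ids[k])
      hit <- length(rep_id)
    }
    assign_to[ids[k]] <- rep_id[hit]
  }
  out <- tibble(representative = unname(assign_to), id = names(assign_to))
  out[order(match(out$representative, rep_id), match(out$id, ids)), ]
}

#' Expand a representative-level partition to all members
#'
#' After clustering precluster representatives, every member inherits the
#' cluster of its representative.
#'
#' @param partition Partition over representatives (two-column data frame or
#'   named vector).
#' @param preclusters Tibble from [precluster_greedy()].
#' @return A tibble `member_id`, `cluster` covering every member.
#' @export
expand_partition <- function(partition, preclusters) {
  membership <- as_membership(partition)
  stopifnot(is.data.frame(preclusters),
            all(c("representative", "id") %in% names(preclusters)))
  missing <- setdiff(unique(preclusters$representative), names(membership))
  if (length(missing) > 0L) {
    abort(sprintf("Representative '%s' is missing from the partition.",
                  missing[1L]),
          class = "mpick_error_data")
  }
  tibble(member_id = preclusters$id,
         cluster = unname(membership[preclusters$representative]))
}
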