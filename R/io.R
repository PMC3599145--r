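# Readers and writers for every external representation the tool touches:
# FASTA sequences, distance matrices (sparse-column and square dialects),
# point tables, OTU membership tables, and ground-truth label maps.

IUPAC_DNA <- "ACGTRYSWKMBDHVN"

#' Read amplicon sequences from a FASTA file
#'
#' Reads plain or gzip-compressed FASTA. Sequence ids are the first
#' whitespace-delimited token of each header; multi-line bodies are
#' concatenated. Residues are stored upper-case with `U` converted to `T`,
#' and must belong to the IUPAC DNA alphabet (`ACGT`, `N` and ambiguity
#' codes).
#'
#' @param path Path to a FASTA file, optionally `.gz`-compressed.
#' @return A tibble with columns `id` and `sequence`, one row per record,
#'   in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGT", ">s2", "AC", "GU"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "mpick_error_usage")
  }
  first <- readLines(con <- gzfile(path, "rt"), n = 50L, warn = FALSE)
  close(con)
  nonblank <- which(nzchar(trimws(first)))
  if (length(nonblank) == 0L) {
    abort(sprintf("%s: empty file, expected FASTA.", path),
          class = "mpick_error_data")
  }
  if (!startsWith(trimws(first[nonblank[1L]]), ">")) {
    abort(sprintf("%s: line %d: expected a FASTA header starting with '>'.",
                  path, nonblank[1L]),
          class = "mpick_error_data")
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, "", 1L)
  if (any(!nzchar(ids))) {
    abort(sprintf("%s: record %d has an empty id.", path,
                  which(!nzchar(ids))[1L]),
          class = "mpick_error_data")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    abort(sprintf("%s: duplicate sequence id '%s'.", path, dup[1L]),
          class = "mpick_error_data")
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    abort(sprintf("%s: sequence '%s' has an empty body.", path,
                  ids[nchar(seqs) == 0L][1L]),
          class = "mpick_error_data")
  }
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- grepl(sprintf("[^%s]", IUPAC_DNA), seqs)
  if (any(bad)) {
    abort(sprintf("%s: sequence '%s' contains characters outside the IUPAC DNA alphabet.",
                  path, ids[bad][1L]),
          class = "mpick_error_data")
  }
  tibble(id = unname(ids), sequence = unname(seqs))
}

# Constructor for the sparse pairwise distance container. `pairs` holds each
# unordered pair once (id1 appearing before id2 in `labels`); ids absent from
# `pairs` are "beyond any cutoff", not distance zero.
new_mpick_dist <- function(pairs, labels, mode, cutoff = NA_real_) {
  out <- as_tibble(pairs)
  attr(out, "labels") <- as.character(labels)
  attr(out, "mode") <- mode
  attr(out, "cutoff") <- cutoff
  class(out) <- c("mpick_dist", class(tibble()))
  out
}

#' Labels carried by a sparse distance matrix
#'
#' @param dm An object created by [all_pairs()] or [read_distances()].
#' @return Character vector of all item ids, including ids that have no
#'   stored pair.
#' @export
dist_labels <- function(dm) {
  lab <- attr(dm, "labels")
  if (is.null(lab)) unique(c(dm$id1, dm$id2)) else lab
}

validate_pairs <- function(id1, id2, d, mode, origin) {
  if (mode == "sequence" && any(d < 0 | d > 1)) {
    abort(sprintf("%s: sequence-mode distances must lie in [0, 1].", origin),
          class = "mpick_error_data")
  }
  if (any(d < 0)) {
    abort(sprintf("%s: negative distances are not allowed.", origin),
          class = "mpick_error_data")
  }
  self <- id1 == id2
  if (any(self & d != 0)) {
    abort(sprintf("%s: self-pair '%s' with non-zero distance.", origin,
                  id1[self & d != 0][1L]),
          class = "mpick_error_data")
  }
  keep <- !self
  id1 <- id1[keep]; id2 <- id2[keep]; d <- d[keep]
  # order each unordered pair canonically, then check duplicates agree
  a <- pmin(id1, id2); b <- pmax(id1, id2)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    rng <- tapply(d, key, function(x) diff(range(x)))
    if (any(rng > 1e-9)) {
      bad <- strsplit(names(rng)[rng > 1e-9][1L], "\r", fixed = TRUE)[[1L]]
      abort(sprintf("%s: conflicting duplicate entries for pair (%s, %s).",
                    origin, bad[1L], bad[2L]),
            class = "mpick_error_data")
    }
    first <- !duplicated(key)
    a <- a[first]; b <- b[first]; d <- d[first]
  }
  tibble(id1 = a, id2 = b, distance = unname(d))
}

#' Read a pairwise distance matrix
#'
#' Two dialects are supported. `"sparse"` is the widespread three-column
#' whitespace-delimited convention `id1 id2 distance` (lines starting with
#' `#` are ignored); pairs absent from a sparse file are treated as farther
#' than any neighborhood threshold, not as distance zero. `"square"` is a
#' PHYLIP-style square matrix: a first line giving the number of items, then
#' one row per item, `label d1 ... dn`.
#'
#' @param path Path to the distance file.
#' @param dialect `"sparse"` or `"square"`.
#' @param mode `"sequence"` (distances must lie in `[0, 1]`) or `"point"`
#'   (any nonnegative metric value).
#' @return A sparse distance object: a tibble with columns `id1`, `id2`,
#'   `distance` plus a `labels` attribute (see [dist_labels()]).
#' @export
read_distances <- function(path, dialect = c("sparse", "square"),
                           mode = c("sequence", "point")) {
  dialect <- match.arg(dialect)
  mode <- match.arg(mode)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "mpick_error_usage")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (dialect == "sparse") {
    if (length(lines) == 0L) {
      return(new_mpick_dist(tibble(id1 = character(), id2 = character(),
                                   distance = double()),
                            character(), mode))
    }
    tok <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(tok)
    if (any(nf != 3L)) {
      abort(sprintf("%s: line %d does not have 3 whitespace-delimited fields.",
                    path, which(nf != 3L)[1L]),
            class = "mpick_error_data")
    }
    id1 <- vapply(tok, `[`, "", 1L)
    id2 <- vapply(tok, `[`, "", 2L)
    d <- suppressWarnings(as.numeric(vapply(tok, `[`, "", 3L)))
    if (anyNA(d)) {
      abort(sprintf("%s: line %d: non-numeric distance.", path,
                    which(is.na(d))[1L]),
            class = "mpick_error_data")
    }
    labels <- unique(c(rbind(id1, id2)))
    pairs <- validate_pairs(id1, id2, d, mode, path)
    new_mpick_dist(pairs, labels, mode)
  } else {
    n <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]), "[ \t]+")[[1L]][1L]))
    if (is.na(n) || n < 1L) {
      abort(sprintf("%s: first line of a square matrix must give the item count.",
                    path),
            class = "mpick_error_data")
    }
    if (length(lines) < n + 1L) {
      abort(sprintf("%s: expected %d matrix rows, found %d.", path, n,
                    length(lines) - 1L),
            class = "mpick_error_data")
    }
    tok <- strsplit(trimws(lines[2:(n + 1L)]), "[ \t]+")
    nf <- lengths(tok)
    if (any(nf != n + 1L)) {
      abort(sprintf("%s: matrix row %d does not have a label plus %d values.",
                    path, which(nf != n + 1L)[1L], n),
            class = "mpick_error_data")
    }
    labels <- vapply(tok, `[`, "", 1L)
    M <- t(vapply(tok, function(x) as.numeric(x[-1L]), numeric(n)))
    if (anyNA(M)) {
      abort(sprintf("%s: non-numeric entry in the matrix body.", path),
            class = "mpick_error_data")
    }
    if (any(abs(M - t(M)) > 1e-9)) {
      abort(sprintf("%s: square matrix is not symmetric.", path),
            class = "mpick_error_data")
    }
    if (any(abs(diag(M)) > 0)) {
      abort(sprintf("%s: non-zero diagonal entry.", path),
            class = "mpick_error_data")
    }
    idx <- which(upper.tri(M), arr.ind = TRUE)
    pairs <- validate_pairs(labels[idx[, 1L]], labels[idx[, 2L]],
                            M[idx], mode, path)
    new_mpick_dist(pairs, labels, mode)
  }
}

#' Write a pairwise distance matrix
#'
#' Inverse of [read_distances()]. The square dialect requires a complete
#' matrix (every unordered pair stored); the sparse dialect writes exactly
#' the stored pairs.
#'
#' @param dm A sparse distance object.
#' @param path Output path.
#' @inheritParams read_distances
#' @return `path`, invisibly.
#' @export
write_distances <- function(dm, path, dialect = c("sparse", "square")) {
  dialect <- match.arg(dialect)
  labels <- dist_labels(dm)
  if (dialect == "sparse") {
    write_atomically(path, function(tmp) {
      writeLines(sprintf("%s\t%s\t%.17g", dm$id1, dm$id2, dm$distance), tmp)
    })
  } else {
    n <- length(labels)
    if (nrow(dm) != n * (n - 1L) / 2L) {
      abort("Square dialect requires a complete distance matrix.",
            class = "mpick_error_usage")
    }
    M <- matrix(0, n, n, dimnames = list(labels, labels))
    i <- match(dm$id1, labels); j <- match(dm$id2, labels)
    M[cbind(i, j)] <- dm$distance
    M[cbind(j, i)] <- dm$distance
    write_atomically(path, function(tmp) {
      con <- file(tmp, "wt"); on.exit(close(con))
      writeLines(as.character(n), con)
      writeLines(paste(labels,
                       apply(M, 1L, function(r) paste(sprintf("%.17g", r),
                                                      collapse = "\t")),
                       sep = "\t"),
                 con)
    })
  }
  invisible(path)
}

#' Write an OTU membership table
#'
#' Writes a two-column TSV `member_id<TAB>otu_id` with a single header line.
#' OTU ids are `OTU_000001`, `OTU_000002`, ... assigned in decreasing
#' cluster-size order, ties broken by the lexicographically smallest member
#' id; rows are sorted by OTU then member, so the byte content is a pure
#' function of the partition.
#'
#' @param partition A two-column data frame (id, cluster) or named vector of
#'   cluster labels; cluster labels may be arbitrary.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(partition, path) {
  membership <- as_membership(partition)
  write_atomically(path, function(tmp) {
    con <- file(tmp, "wt"); on.exit(close(con))
    writeLines("member_id\totu_id", con)
    if (length(membership) > 0L) {
      tab <- canonical_otus(names(membership), membership)
      writeLines(paste(tab$member_id, tab$otu_id, sep = "\t"), con)
    }
  })
  invisible(path)
}

#' Read a label map (OTU table or ground truth)
#'
#' Reads a two-column whitespace-delimited table `id label`. A first line
#' equal to the [write_otu_table()] header (`member_id otu_id`) is skipped,
#' so OTU tables round-trip. Order-insensitive.
#'
#' @param path Path to the table.
#' @return A tibble with columns `id` and `label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "mpick_error_usage")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 0L) {
    first <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
    if (identical(first, c("member_id", "otu_id"))) lines <- lines[-1L]
  }
  if (length(lines) == 0L) {
    return(tibble(id = character(), label = character()))
  }
  tok <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(tok)
  if (any(nf != 2L)) {
    abort(sprintf("%s: line %d does not have 2 whitespace-delimited fields.",
                  path, which(nf != 2L)[1L]),
          class = "mpick_error_data")
  }
  id <- vapply(tok, `[`, "", 1L)
  label <- vapply(tok, `[`, "", 2L)
  conflict <- tapply(label, id, function(x) length(unique(x)))
  if (any(conflict > 1L)) {
    abort(sprintf("%s: id '%s' maps to more than one label.", path,
                  names(conflict)[conflict > 1L][1L]),
          class = "mpick_error_data")
  }
  keep <- !duplicated(id)
  tibble(id = id[keep], label = label[keep])
}

#' Read a point-coordinate table
#'
#' Reads a whitespace-delimited table whose header line starts with `id`
#' followed by coordinate column names (as written by
#' [write_points()]).
#'
#' @param path Path to the table.
#' @return A tibble with an `id` column and one numeric column per dimension.
#' @export
read_points <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "mpick_error_usage")
  }
  df <- utils::read.table(path, header = TRUE, colClasses = NA,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "id") {
    abort(sprintf("%s: expected a header line starting with 'id'.", path),
          class = "mpick_error_data")
  }
  df$id <- as.character(df$id)
  if (ncol(df) < 2L || !all(vapply(df[-1L], is.numeric, TRUE))) {
    abort(sprintf("%s: coordinate columns must be numeric.", path),
          class = "mpick_error_data")
  }
  if (anyDuplicated(df$id)) {
    abort(sprintf("%s: duplicate point id '%s'.", path,
                  df$id[duplicated(df$id)][1L]),
          class = "mpick_error_data")
  }
  as_tibble(df)
}

#' Write a point-coordinate table
#'
#' @param points A data frame with an `id` column and numeric coordinate
#'   columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path) {
  stopifnot(is.data.frame(points), names(points)[1L] == "id")
  write_atomically(path, function(tmp) {
    con <- file(tmp, "wt"); on.exit(close(con))
    writeLines(paste(names(points), collapse = "\t"), con)
    body <- do.call(paste, c(lapply(points, function(x)
      if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)),
      sep = "\t"))
    writeLines(body, con)
  })
  invisible(path)
}

#' Write sequences to FASTA
#'
#' @param records A tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence") %in% names(records)))
  write_atomically(path, function(tmp) {
    writeLines(paste0(">", records$id, "\n", records$sequence), tmp)
  })
  invisible(path)
}
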