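# Seeded generators for test inputs: a three-component Gaussian-mixture
# point cloud, and a multi-taxon amplicon dataset with small within-taxon
# and large between-taxon divergence.

#' Specification of a Gaussian-mixture point cloud
#'
#' Defaults describe a three-component mixture with x-means -0.5, 1 and 3,
#' standard deviations 0.2, 0.4 and 0.6, and deliberately unequal component
#' sizes — a toy where no single distance cut-off separates all clusters.
#' Every non-x coordinate is drawn as `Normal(0, sd)` with the component's
#' standard deviation.
#'
#' @param means Per-component x-means.
#' @param sds Per-component standard deviations (all positive).
#' @param sizes Per-component point counts (all at least 1).
#' @param dim Dimension of the points (at least 1).
#' @return A `mixture_spec` list.
#' @export
mixture_spec <- function(means = c(-0.5, 1, 3), sds = c(0.2, 0.4, 0.6),
                         sizes = c(150L, 100L, 250L), dim = 2L) {
  if (length(means) != length(sds) || length(means) != length(sizes)) {
    abort("`means`, `sds` and `sizes` must have equal length.",
          class = "mpick_error_usage")
  }
  if (any(sds <= 0) || any(sizes < 1L) || dim < 1L) {
    abort("Mixture spec requires sds > 0, sizes >= 1 and dim >= 1.",
          class = "mpick_error_usage")
  }
  structure(list(means = means, sds = sds, sizes = as.integer(sizes),
                 dim = as.integer(dim)),
            class = "mixture_spec")
}

#' Sample points from a Gaussian mixture
#'
#' Draws `spec$sizes[k]` points from each component; the `component` column
#' records the ground-truth component of origin. A pure function of
#' `(spec, seed)`.
#'
#' @param spec A [mixture_spec()].
#' @param seed Integer seed.
#' @return A tibble with `id`, coordinate columns `x1..x<dim>` (the first
#'   carrying the component means) and `component`.
#' @export
sim_gaussian_points <- function(spec = mixture_spec(), seed = 42L) {
  stopifnot(inherits(spec, "mixture_spec"))
  with_seed(seed, {
    k <- length(spec$sizes)
    n <- sum(spec$sizes)
    comp <- rep(seq_len(k), spec$sizes)
    coords <- matrix(0, n, spec$dim)
    coords[, 1L] <- rnorm(n, mean = spec$means[comp], sd = spec$sds[comp])
    if (spec$dim > 1L) {
      for (d in 2:spec$dim) {
        coords[, d] <- rnorm(n, mean = 0, sd = spec$sds[comp])
      }
    }
    colnames(coords) <- paste0("x", seq_len(spec$dim))
    out <- as_tibble(coords)
    out <- dplyr::bind_cols(
      tibble(id = sprintf("p%04d", seq_len(n))), out)
    out$component <- sprintf("C%d", comp)
    out
  })
}

#' Specification of a synthetic multi-taxon amplicon dataset
#'
#' Defaults emulate a well-separated multi-species community: 11 taxa of
#' 100 reads each, read length 250, within-taxon substitution rate 0.01 per
#' site (so within-taxon distances concentrate near 0.02, safely below an
#' epsilon of 0.04) and between-taxon ancestor divergence of at least 0.10
#' (safely above it).
#'
#' @param n_taxa Number of taxa.
#' @param sizes Reads per taxon; a scalar is recycled. Down-sample one entry
#'   (e.g. `sizes[8] <- 20`) to probe the rare-taxon regime.
#' @param seq_length Read length in bases.
#' @param within_rate Expected substitutions per site per read relative to
#'   the taxon ancestor; a scalar is recycled, a vector gives per-taxon
#'   rates.
#' @param min_between Minimum pairwise divergence between taxon ancestors,
#'   as a fraction of sites.
#' @return A `taxa_spec` list.
#' @export
taxa_spec <- function(n_taxa = 11L, sizes = 100L, seq_length = 250L,
                      within_rate = 0.01, min_between = 0.10) {
  sizes <- rep_len(as.integer(sizes), n_taxa)
  within_rate <- rep_len(within_rate, n_taxa)
  if (n_taxa < 1L || any(sizes < 1L) || seq_length < 1L) {
    abort("Taxa spec requires n_taxa >= 1, sizes >= 1, seq_length >= 1.",
          class = "mpick_error_usage")
  }
  if (any(within_rate < 0) || min_between <= max(within_rate) ||
      min_between > 1) {
    abort("Rates must satisfy 0 <= within_rate < min_between <= 1.",
          class = "mpick_error_usage")
  }
  structure(list(n_taxa = as.integer(n_taxa), sizes = sizes,
                 seq_length = as.integer(seq_length),
                 within_rate = within_rate, min_between = min_between),
            class = "taxa_spec")
}

mutate_sites <- function(seq_codes, sites) {
  # substitute uniformly among the three alternative bases
  shift <- sample.int(3L, length(sites), replace = TRUE)
  seq_codes[sites] <- ((seq_codes[sites] - 1L + shift) %% 4L) + 1L
  seq_codes
}

#' Simulate a multi-taxon amplicon dataset
#'
#' Taxon ancestors are derived from one random root by mutating a fixed
#' fraction of sites, redrawn until every ancestor pair differs at no fewer
#' than `min_between * seq_length` sites. Each read carries
#' `floor(within_rate * seq_length)` substitutions plus one more with
#' probability equal to the fractional remainder, at uniformly chosen
#' sites — the expected per-site rate is exactly `within_rate`, while the
#' low-variance count keeps within-taxon divergence concentrated at the
#' nominal level, so the planted separability is realized in every draw.
#' No indels are introduced, so alignment distances track per-site
#' divergence directly. A pure function of `(spec, seed)`.
#'
#' @param spec A [taxa_spec()].
#' @param seed Integer seed.
#' @param max_attempts Attempts allowed per ancestor before the spec is
#'   declared infeasible.
#' @return A tibble with `id`, `sequence` and ground-truth `taxon`.
#' @export
sim_taxa_sequences <- function(spec = taxa_spec(), seed = 42L,
                               max_attempts = 1000L) {
  stopifnot(inherits(spec, "taxa_spec"))
  bases <- c("A", "C", "G", "T")
  L <- spec$seq_length
  need <- ceiling(spec$min_between * L)
  with_seed(seed, {
    root <- sample.int(4L, L, replace = TRUE)
    # ancestors: mutate 25% of sites (or more if the divergence floor
    # demands it), reject until pairwise divergence clears the floor
    frac <- max(0.25, min(0.6, spec$min_between * 1.5))
    n_mut <- max(need, ceiling(frac * L))
    if (n_mut > L) {
      abort("Requested between-taxon divergence is unreachable at this sequence length.",
            class = "mpick_error_usage")
    }
    ancestors <- vector("list", spec$n_taxa)
    for (t in seq_len(spec$n_taxa)) {
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        cand <- mutate_sites(root, sample.int(L, n_mut))
        div <- vapply(ancestors[seq_len(t - 1L)],
                      function(a) sum(a != cand), 1)
        if (t == 1L || all(div >= need)) { ok <- TRUE; break }
      }
      if (!ok) {
        abort(sprintf("Could not place ancestor %d at the requested divergence after %d attempts.",
                      t, max_attempts),
              class = "mpick_error_data")
      }
      ancestors[[t]] <- cand
    }
    ids <- character(0); seqs <- character(0); taxa <- character(0)
    for (t in seq_len(spec$n_taxa)) {
      mu <- spec$within_rate[t] * L
      for (r in seq_len(spec$sizes[t])) {
        codes <- ancestors[[t]]
        n_sub <- floor(mu) + (runif(1) < mu - floor(mu))
        if (n_sub > 0L) codes <- mutate_sites(codes, sample.int(L, n_sub))
        ids <- c(ids, sprintf("t%02d_r%04d", t, r))
        seqs <- c(seqs, paste(bases[codes], collapse = ""))
        taxa <- c(taxa, sprintf("Taxon%02d", t))
      }
    }
    tibble(id = ids, sequence = seqs, taxon = taxa)
  })
}
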