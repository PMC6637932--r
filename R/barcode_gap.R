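# Intra- vs inter-specific distance partitioning, per-species
# closest-neighbour summaries, distance histograms, and the global
# barcoding-gap verdict.

#' Partition pairwise distances by species relationship
#'
#' Splits every defined unordered pairwise distance into the intra-specific
#' class (both samples from the same species) or the inter-specific class.
#' Undefined (NA) entries are excluded from both classes and counted.
#'
#' @param m Distance matrix from [pairwise_matrix()].
#' @param sp Species map (named character vector, see [species_map()])
#'   covering every matrix label.
#' @return An object of class `distance_partition`: list with data frames
#'   `intra` (`species`, `distance`) and `inter` (`species_a`, `species_b`,
#'   `distance`; pair sorted alphabetically), plus `n_undefined`.
#' @export
partition_distances <- function(m, sp) {
  labels <- rownames(m)
  missing <- setdiff(labels, names(sp))
  if (length(missing) > 0L)
    stop("samples missing from species map: ", paste(missing, collapse = ", "))
  idx <- which(upper.tri(m), arr.ind = TRUE)
  d <- m[idx]
  sa <- unname(sp[labels[idx[, 1L]]])
  sb <- unname(sp[labels[idx[, 2L]]])
  defined <- !is.na(d)
  intra_sel <- defined & sa == sb
  inter_sel <- defined & sa != sb
  lo <- pmin(sa, sb)
  hi <- pmax(sa, sb)
  structure(list(
    intra = data.frame(species = sa[intra_sel], distance = d[intra_sel],
                       stringsAsFactors = FALSE),
    inter = data.frame(species_a = lo[inter_sel], species_b = hi[inter_sel],
                       distance = d[inter_sel], stringsAsFactors = FALSE),
    n_undefined = sum(!defined)), class = "distance_partition")
}

#' @export
print.distance_partition <- function(x, ...) {
  cat(sprintf("distance partition: %d intra-specific, %d inter-specific, %d undefined\n",
              nrow(x$intra), nrow(x$inter), x$n_undefined))
  invisible(x)
}

#' Per-species divergence summary (closest-neighbour analysis)
#'
#' For every species, reports the maximum intra-specific distance (undefined
#' for singleton species), the minimum inter-specific distance, the species
#' achieving that minimum (ties broken alphabetically), and whether the
#' species shows a local barcoding gap. A multi-sample species has a gap when
#' its smallest inter-specific distance exceeds its largest intra-specific
#' one; a singleton species is scored on `min_inter > 0`.
#'
#' @inheritParams partition_distances
#' @return Data frame with one row per species: `species`, `n_samples`,
#'   `max_intra`, `min_inter`, `nearest_species`, `gap_present`.
#' @export
species_gap_summary <- function(m, sp) {
  part <- partition_distances(m, sp)
  species <- sort(unique(unname(sp[rownames(m)])))
  if (length(species) < 2L) stop("need at least two species for a gap summary")
  n_samples <- vapply(species, function(s)
    sum(unname(sp[rownames(m)]) == s), integer(1L))
  rows <- lapply(seq_along(species), function(i) {
    s <- species[i]
    d_intra <- part$intra$distance[part$intra$species == s]
    inter_sel <- part$inter$species_a == s | part$inter$species_b == s
    d_inter <- part$inter$distance[inter_sel]
    if (length(d_inter) == 0L)
      stop("species '", s, "' has no defined inter-specific distances")
    other <- ifelse(part$inter$species_a[inter_sel] == s,
                    part$inter$species_b[inter_sel],
                    part$inter$species_a[inter_sel])
    min_inter <- min(d_inter)
    cand <- sort(unique(other[d_inter == min_inter]))
    max_intra <- if (length(d_intra) > 0L) max(d_intra) else NA_real_
    gap <- if (is.na(max_intra)) min_inter > 0 else min_inter > max_intra
    data.frame(species = s, n_samples = n_samples[i], max_intra = max_intra,
               min_inter = min_inter, nearest_species = cand[1L],
               gap_present = gap, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Histogram of intra- and inter-specific distances
#'
#' Bins both distance classes on a common grid of half-open intervals
#' `[k*w, (k+1)*w)`. Bin counts conserve the class totals.
#'
#' @param partition A `distance_partition` from [partition_distances()].
#' @param bin_width Positive bin width `w` (substitutions/site). Bin widths
#'   of 0.004 and 0.008 are typical for barcoding-gap displays; see
#'   [default_bin_width()].
#' @return Data frame with columns `bin_start`, `bin_end`, `intra_count`,
#'   `inter_count`.
#' @export
build_histogram <- function(partition, bin_width) {
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("bin_width must be a single positive number")
  d_intra <- partition$intra$distance
  d_inter <- partition$inter$distance
  all_d <- c(d_intra, d_inter)
  if (length(all_d) == 0L) stop("no defined distances to bin")
  n_bins <- max(floor(all_d / bin_width)) + 1L
  bin_of <- function(d) floor(d / bin_width) + 1L
  tab <- function(d) tabulate(bin_of(d), nbins = n_bins)
  k <- seq_len(n_bins) - 1L
  data.frame(bin_start = k * bin_width, bin_end = (k + 1L) * bin_width,
             intra_count = tab(d_intra), inter_count = tab(d_inter))
}

#' Global barcoding-gap verdict
#'
#' A marker shows a clear barcoding gap when the smallest inter-specific
#' distance exceeds the largest intra-specific distance (strictly; a tie is
#' scored as overlap). The margin `min(inter) - max(intra)` is reported
#' either way (negative under overlap).
#'
#' @param partition A `distance_partition` with both classes non-empty.
#' @return An object of class `gap_verdict`: list with `verdict` (`"clear
#'   gap"` or `"overlap"`), `margin`, `max_intra`, `min_inter`.
#' @export
gap_exists <- function(partition) {
  if (nrow(partition$intra) == 0L)
    stop("no intra-specific distances: gap verdict undefined")
  if (nrow(partition$inter) == 0L)
    stop("no inter-specific distances: gap verdict undefined")
  max_intra <- max(partition$intra$distance)
  min_inter <- min(partition$inter$distance)
  structure(list(
    verdict = if (min_inter > max_intra) "clear gap" else "overlap",
    margin = min_inter - max_intra,
    max_intra = max_intra, min_inter = min_inter), class = "gap_verdict")
}

#' @export
print.gap_verdict <- function(x, ...) {
  cat(sprintf("barcoding gap: %s (max intra %.6f, min inter %.6f, margin %+.6f)\n",
              x$verdict, x$max_intra, x$min_inter, x$margin))
  invisible(x)
}

#' Default histogram bin width for a region
#'
#' Encodes the conventional display widths per marker: 0.004 for ITS, nLSU
#' and mtSSU; 0.008 for IGS and tef1; 0.004 otherwise.
#'
#' @param region Region name (case-insensitive).
#' @return Bin width.
#' @export
default_bin_width <- function(region) {
  if (toupper(region) %in% c("IGS", "TEF1", "TEF1A", "TEF-1")) 0.008 else 0.004
}
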