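# Site-pattern counting and distance computation.
#
# All counting uses pairwise deletion by default: a site enters the
# comparison of a pair only if both residues are unambiguous bases
# (A, C, G or T). Transitions are the purine<->purine (A<->G) and
# pyrimidine<->pyrimidine (C<->T) mismatches; every other mismatch among
# the four bases is a transversion.

BASES <- c("A", "C", "G", "T")

.residues <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "", fixed = TRUE)[[1L]]
  else toupper(as.character(x))
}

#' Count site patterns between two aligned sequences
#'
#' Counts transitions (A<->G, C<->T), transversions (all other base
#' mismatches) and the number of compared sites under pairwise deletion:
#' sites where either residue is a gap or an ambiguity code are excluded.
#'
#' @param a,b Residue vectors or strings of equal length.
#' @return An object of class `pair_counts`: list with elements
#'   `transitions`, `transversions`, `compared_sites`.
#' @examples
#' count_site_patterns("ACGT", "GCGA")
#' @export
count_site_patterns <- function(a, b) {
  a <- toupper(.residues(a)); b <- toupper(.residues(b))
  if (length(a) != length(b))
    stop("sequences must be the same aligned length")
  ok <- a %in% BASES & b %in% BASES
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  ts <- sum(diff & ((a == "A" & b == "G") | (a == "G" & b == "A") |
                    (a == "C" & b == "T") | (a == "T" & b == "C")))
  structure(list(transitions = ts,
                 transversions = sum(diff) - ts,
                 compared_sites = length(a)),
            class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  cat(sprintf("site patterns: %d transitions, %d transversions over %d compared sites\n",
              x$transitions, x$transversions, x$compared_sites))
  invisible(x)
}

#' Kimura 2-parameter distance from site-pattern counts
#'
#' Evaluates the K2P correction
#' \deqn{d = -\frac{1}{2}\ln\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right]}
#' with \eqn{P} the transition and \eqn{Q} the transversion proportion over
#' the compared sites. The estimate is undefined (saturated) when
#' \eqn{1 - 2P - Q \le 0} or \eqn{1 - 2Q \le 0}; this raises an error of
#' class `saturation_error`.
#'
#' @param counts A `pair_counts` object (or list with the same fields).
#' @return Non-negative distance in substitutions per site.
#' @examples
#' k2p_from_counts(count_site_patterns("ACGT", "GCGA"))
#' @export
k2p_from_counts <- function(counts) {
  L <- counts$compared_sites
  if (is.null(L) || L <= 0L) stop("no comparable sites: distance undefined")
  P <- counts$transitions / L
  Q <- counts$transversions / L
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop(structure(class = c("saturation_error", "error", "condition"),
                   list(message = sprintf(
                     "K2P distance undefined (saturated): 1-2P-Q = %.4g, 1-2Q = %.4g",
                     w1, w2), call = sys.call(-1L))))
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Uncorrected p-distance from site-pattern counts
#'
#' Proportion of mismatching compared sites, `(s + v) / L`.
#' @inheritParams k2p_from_counts
#' @return Distance in `[0, 1]`.
#' @export
p_distance <- function(counts) {
  L <- counts$compared_sites
  if (is.null(L) || L <= 0L) stop("no comparable sites: distance undefined")
  (counts$transitions + counts$transversions) / L
}

#' Percent identity between two aligned sequences
#'
#' `100 * matches / compared_sites` under pairwise deletion.
#' @inheritParams count_site_patterns
#' @return Percentage in `[0, 100]`.
#' @export
percent_identity <- function(a, b) {
  cnt <- count_site_patterns(a, b)
  if (cnt$compared_sites == 0L) stop("no comparable sites: identity undefined")
  100 * (cnt$compared_sites - cnt$transitions - cnt$transversions) /
    cnt$compared_sites
}

# Indicator matrices (samples x sites) per base; the workhorse for the
# vectorized all-pairs counts used by pairwise_matrix() and the bootstrap.
.base_indicators <- function(aln) {
  lapply(stats::setNames(BASES, BASES), function(b) (aln == b) * 1)
}

# All-pairs transition / transversion / compared-site counts via
# crossproducts of the base indicator matrices. `cols` restricts (with
# repetition) to a column multiset, which is what the bootstrap resampler
# needs without re-deriving indicators.
.pair_count_matrices <- function(ind, cols = NULL) {
  if (!is.null(cols)) ind <- lapply(ind, function(m) m[, cols, drop = FALSE])
  valid <- ind$A + ind$C + ind$G + ind$T
  L <- tcrossprod(valid)
  matches <- tcrossprod(ind$A) + tcrossprod(ind$C) +
    tcrossprod(ind$G) + tcrossprod(ind$T)
  ts <- tcrossprod(ind$A, ind$G) + tcrossprod(ind$G, ind$A) +
    tcrossprod(ind$C, ind$T) + tcrossprod(ind$T, ind$C)
  list(S = ts, V = L - matches - ts, L = L)
}

.distance_from_counts <- function(cm, model) {
  n <- nrow(cm$L)
  if (model == "identity") {
    d <- ifelse(cm$L > 0, 100 * (cm$L - cm$S - cm$V) / cm$L, NA_real_)
    diag(d) <- 100
    return(d)
  }
  P <- ifelse(cm$L > 0, cm$S / cm$L, NA_real_)
  Q <- ifelse(cm$L > 0, cm$V / cm$L, NA_real_)
  if (model == "p") {
    d <- P + Q
  } else {
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    ok <- !is.na(w1) & w1 > 0 & w2 > 0
    d <- array(NA_real_, dim(w1))
    d[ok] <- -0.5 * log(w1[ok]) - 0.25 * log(w2[ok])
  }
  diag(d) <- 0
  d
}

#' Pairwise distance (or identity) matrix for an alignment
#'
#' Computes all unordered pairwise comparisons under the chosen model:
#' `"K2P"` (Kimura 2-parameter correction), `"p"` (uncorrected proportion of
#' differences) or `"identity"` (percent identity, a similarity). Gap
#' treatment is pairwise deletion by default; `"complete"` drops every column
#' containing a gap or ambiguity in any sequence before comparing.
#'
#' Pairs with no comparable sites, and K2P-saturated pairs, are returned as
#' `NA` (flagged, never silently zeroed); a warning reports how many.
#'
#' @param aln A `dna_alignment` with at least two sequences.
#' @param model `"K2P"`, `"p"` or `"identity"`.
#' @param gap_deletion `"pairwise"` or `"complete"`.
#' @return Square symmetric numeric matrix with sample ids as dimnames and
#'   attributes `model` and `n_undefined`.
#' @export
pairwise_matrix <- function(aln, model = c("K2P", "p", "identity"),
                            gap_deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  gap_deletion <- match.arg(gap_deletion)
  validate_alignment(aln)
  if (nrow(aln) < 2L) stop("need at least two sequences for a distance matrix")
  m <- unclass(aln)
  if (gap_deletion == "complete") {
    keep <- colSums(matrix(m %in% BASES, nrow(m))) == nrow(m)
    if (!any(keep)) stop("complete deletion removed every column")
    m <- m[, keep, drop = FALSE]
  }
  cm <- .pair_count_matrices(.base_indicators(m))
  d <- .distance_from_counts(cm, model)
  dimnames(d) <- list(rownames(aln), rownames(aln))
  n_undef <- sum(is.na(d[upper.tri(d)]))
  if (n_undef > 0L)
    warning(sprintf("%d pairwise %s undefined (saturated or no comparable sites); flagged as NA",
                    n_undef, if (model == "identity") "identities" else "distances"))
  structure(d, model = model, n_undefined = n_undef)
}

#' Write a distance matrix to file
#'
#' `"square"` writes a tab-delimited square matrix with a header row and a
#' label column; `"long"` writes the three-column unordered-pair form
#' (`id_a`, `id_b`, `distance`).
#'
#' @param m Matrix from [pairwise_matrix()].
#' @param path Output path.
#' @param format `"square"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path, format = c("square", "long")) {
  format <- match.arg(format)
  if (format == "square") {
    tab <- data.frame(sample_id = rownames(m), as.data.frame(unclass(m)),
                      check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(upper.tri(m), arr.ind = TRUE)
    tab <- data.frame(id_a = rownames(m)[idx[, 1L]],
                      id_b = colnames(m)[idx[, 2L]],
                      distance = m[idx])
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
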