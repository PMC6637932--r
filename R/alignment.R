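# Alignment container and FASTA / table I/O.
#
# An alignment is stored as a character matrix of single uppercase residues:
# one row per sample (rownames = sample ids), one column per aligned site.
# The region name travels as an attribute so downstream reports and default
# bin widths can be keyed on it.

# Residues accepted on input. Everything outside {A,C,G,T} is treated as
# missing by the distance layer (pairwise deletion).
DNA_ALPHABET <- c("A", "C", "G", "T", "-", "N",
                  "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Construct an aligned-sequence matrix
#'
#' Builds a validated alignment from a character matrix (rows = samples,
#' columns = aligned sites) or a named character vector / list of equal-length
#' residue strings. Residues are uppercase-normalized and checked against the
#' DNA alphabet (`A C G T -`, `N` and the IUPAC ambiguity codes).
#'
#' @param x Character matrix of single residues with rownames, or a named
#'   character vector/list of residue strings.
#' @param region Region (marker) name, e.g. `"ITS"`.
#' @return An object of class `dna_alignment`: a character matrix with a
#'   `region` attribute.
#' @examples
#' aln <- alignment(c(s1 = "ACGT", s2 = "ACGA"), region = "ITS")
#' n_sites(aln)
#' @export
alignment <- function(x, region = "region") {
  if (is.matrix(x)) {
    m <- x
  } else {
    x <- as.list(x)
    if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
      stop("every sequence must be named by its sample_id")
    chars <- lapply(x, function(s) {
      if (length(s) == 1L) strsplit(s, "", fixed = TRUE)[[1L]] else as.character(s)
    })
    lens <- lengths(chars)
    if (length(unique(lens)) > 1L) {
      bad <- names(x)[lens != lens[1L]]
      stop("sequences are not all the same length; offending records: ",
           paste(bad, collapse = ", "))
    }
    m <- do.call(rbind, chars)
    rownames(m) <- names(x)
  }
  m[] <- toupper(m)
  validate_alignment(m)
  structure(m, region = region, class = c("dna_alignment", "matrix", "array"))
}

validate_alignment <- function(m) {
  if (!is.character(m) || nrow(m) < 1L || ncol(m) < 1L)
    stop("alignment must contain at least one sequence with at least one site")
  ids <- rownames(m)
  if (is.null(ids) || any(ids == "")) stop("alignment rows must be named by sample_id")
  if (anyDuplicated(ids))
    stop("duplicate sample_id in alignment: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- !(m %in% DNA_ALPHABET)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(m)), arr.ind = TRUE)[1L, ]
    stop(sprintf("illegal character '%s' in record '%s' at position %d",
                 m[idx[1L], idx[2L]], ids[idx[1L]], idx[2L]))
  }
  invisible(m)
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("DNA alignment [%s]: %d sequences, %d aligned sites\n",
              region(x), nrow(x), ncol(x)))
  invisible(x)
}

#' Alignment accessors
#'
#' `region()` returns the marker name, `sample_ids()` the row names, and
#' `n_sites()` the aligned length.
#' @param aln A `dna_alignment`.
#' @return A character scalar, character vector, or integer respectively.
#' @export
region <- function(aln) attr(aln, "region")

#' @rdname region
#' @export
sample_ids <- function(aln) rownames(aln)

#' @rdname region
#' @export
n_sites <- function(aln) ncol(aln)

#' Ungapped sequence lengths
#'
#' Number of non-gap residues per sample, i.e. the length each sequence would
#' have before alignment. Used for the per-marker length-range report.
#' @param aln A `dna_alignment`.
#' @return Named integer vector.
#' @export
ungapped_lengths <- function(aln) {
  out <- rowSums(aln != "-")
  storage.mode(out) <- "integer"
  out
}

#' Read an aligned multi-FASTA file
#'
#' Parses a (wrapped or unwrapped) multi-record FASTA file into a validated
#' alignment. The sample id is the first whitespace-delimited token of each
#' header; the remainder of the header is ignored. Residues are
#' uppercase-normalized. Records of unequal length or with characters outside
#' the DNA alphabet are an error naming the offending record.
#'
#' @param path Path to the FASTA file.
#' @param region Region name to attach; defaults to the file name without
#'   extension.
#' @return A `dna_alignment`.
#' @export
read_fasta <- function(path, region = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (is.null(region))
    region <- sub("\\.[^.]*$", "", basename(path))
  recs <- seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE,
                             set.attributes = FALSE)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  alignment(recs, region = region)
}

#' Write an alignment to FASTA
#'
#' @param aln A `dna_alignment`.
#' @param path Output file path.
#' @param width Residues per line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, width = 60L) {
  seqinr::write.fasta(sequences = lapply(seq_len(nrow(aln)), function(i) aln[i, ]),
                      names = rownames(aln), file.out = path, nbchar = width)
  invisible(path)
}

#' Read a sample-to-species map
#'
#' Two-column tab-separated file: `sample_id`, `species`. A header line is
#' detected (first field equal to `sample_id`, `sample` or `id`,
#' case-insensitively) and skipped. Duplicate sample ids are an error.
#'
#' @param path Path to the TSV file.
#' @return Named character vector: species names, named by sample id.
#' @export
read_species_map <- function(path) {
  if (!file.exists(path)) stop("species map file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "")
  if (ncol(tab) < 2L) stop("species map must have two tab-separated columns")
  if (tolower(tab[1L, 1L]) %in% c("sample_id", "sample", "id"))
    tab <- tab[-1L, , drop = FALSE]
  if (nrow(tab) == 0L) stop("species map contains no rows")
  species_map(stats::setNames(tab[[2L]], tab[[1L]]))
}

#' Construct a species map
#'
#' @param x Named character vector (names = sample ids, values = species).
#' @return The validated named character vector.
#' @export
species_map <- function(x) {
  x <- unlist(x)
  if (is.null(names(x)) || any(names(x) == ""))
    stop("species map entries must be named by sample_id")
  if (anyDuplicated(names(x)))
    stop("duplicate sample_id in species map: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  x
}

#' Read a per-sample region status table
#'
#' Three tab-separated columns: `sample_id`, `amplified` (0/1), `sequenced`
#' (0/1). A successful sequencing implies a successful amplification; rows
#' violating that are an error.
#'
#' @param path Path to the TSV file.
#' @param region Optional region name attached as an attribute.
#' @return A data frame with columns `sample_id`, `amplified`, `sequenced`
#'   (logical).
#' @export
read_region_status <- function(path, region = NULL) {
  if (!file.exists(path)) stop("region status file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "")
  if (ncol(tab) < 3L)
    stop("region status must have three tab-separated columns ",
         "(sample_id, amplified, sequenced)")
  if (tolower(tab[1L, 1L]) %in% c("sample_id", "sample", "id"))
    tab <- tab[-1L, , drop = FALSE]
  region_status(data.frame(sample_id = tab[[1L]],
                           amplified = as.integer(tab[[2L]]) > 0L,
                           sequenced = as.integer(tab[[3L]]) > 0L,
                           stringsAsFactors = FALSE),
                region = region)
}

#' Construct / validate a region status table
#'
#' @param x Data frame with columns `sample_id`, `amplified`, `sequenced`.
#' @param region Optional region name.
#' @return The validated data frame.
#' @export
region_status <- function(x, region = NULL) {
  need <- c("sample_id", "amplified", "sequenced")
  if (!all(need %in% names(x)))
    stop("region status needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(x$sample_id)) stop("duplicate sample_id in region status")
  x$amplified <- as.logical(x$amplified)
  x$sequenced <- as.logical(x$sequenced)
  bad <- x$sequenced & !x$amplified
  if (any(bad))
    stop("sequenced implies amplified; violated for: ",
         paste(x$sample_id[bad], collapse = ", "))
  if (!is.null(region)) attr(x, "region") <- region
  x
}

#' Concatenate region alignments into a combined supermatrix
#'
#' Joins several region alignments sample-wise, in the given order. A sample
#' missing from a region contributes gap characters for that region's full
#' aligned length, so the combined length is always the sum of the region
#' lengths. A sample present in none of the regions is an error rather than an
#' all-gap row, since such a row has no defined distance to anything.
#'
#' @param alignments List of `dna_alignment` objects.
#' @param sample_universe Optional character vector fixing the output samples
#'   and their order; defaults to the union of samples in order of first
#'   appearance.
#' @return A `dna_alignment` whose region name joins the input names with "+".
#' @export
concatenate_regions <- function(alignments, sample_universe = NULL) {
  if (length(alignments) == 0L) stop("no alignments to concatenate")
  for (a in alignments) validate_alignment(a)
  if (is.null(sample_universe))
    sample_universe <- unique(unlist(lapply(alignments, rownames)))
  present <- vapply(sample_universe, function(s)
    any(vapply(alignments, function(a) s %in% rownames(a), logical(1L))),
    logical(1L))
  if (any(!present))
    stop("sample has no data in any region: ",
         paste(sample_universe[!present], collapse = ", "))
  blocks <- lapply(alignments, function(a) {
    out <- matrix("-", length(sample_universe), ncol(a),
                  dimnames = list(sample_universe, NULL))
    hit <- intersect(sample_universe, rownames(a))
    out[hit, ] <- a[hit, , drop = FALSE]
    out
  })
  combined <- do.call(cbind, blocks)
  alignment(combined,
            region = paste(vapply(alignments, region, character(1L)),
                           collapse = "+"))
}
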