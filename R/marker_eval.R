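# Per-marker accounting (amplification/sequencing success, length ranges)
# and the aggregated marker-evaluation report combining barcoding-gap and
# monophyly evidence.

# nearest integer, half away from zero upward (79.5 -> 80)
round_half_up <- function(x) floor(x + 0.5)

#' Amplification and sequencing success rates
#'
#' Percentages of samples that amplified and that were sequenced, rounded to
#' the nearest integer (half up).
#'
#' @param status Region status data frame (see [region_status()]).
#' @return List with `n_total`, `n_amplified`, `n_sequenced`, `pcr_rate`,
#'   `seq_rate`.
#' @examples
#' st <- region_status(data.frame(sample_id = paste0("s", 1:34),
#'                                amplified = TRUE,
#'                                sequenced = rep(c(TRUE, FALSE), c(27, 7))))
#' success_rates(st)$seq_rate  # 79
#' @export
success_rates <- function(status) {
  status <- region_status(status)
  n <- nrow(status)
  if (n < 1L) stop("region status table is empty")
  na <- sum(status$amplified)
  ns <- sum(status$sequenced)
  list(n_total = n, n_amplified = na, n_sequenced = ns,
       pcr_rate = round_half_up(100 * na / n),
       seq_rate = round_half_up(100 * ns / n))
}

#' Ungapped length range of a marker
#'
#' @param x Either a `dna_alignment` (ungapped per-sample lengths are
#'   computed) or a numeric vector of sequence lengths.
#' @return Integer vector `c(min, max)`.
#' @export
length_range <- function(x) {
  lens <- if (inherits(x, "dna_alignment")) ungapped_lengths(x) else x
  if (length(lens) == 0L) stop("no sequence lengths supplied")
  c(min = as.integer(min(lens)), max = as.integer(max(lens)))
}

#' Evaluate a candidate barcode marker end to end
#'
#' Composes the whole pipeline for one region: success accounting (if a
#' status table is given), ungapped length range, pairwise distances,
#' intra/inter partition, global gap verdict, NJ tree with bootstrap
#' supports, rooting (outgroup if given, midpoint otherwise) and per-species
#' monophyly. Samples marked unsequenced in `status` are excluded from the
#' sequence-based analyses.
#'
#' @inheritParams pairwise_matrix
#' @param sp Species map covering the analyzed samples (the outgroup may be
#'   absent from it).
#' @param status Optional region status table; `NULL` means every sample in
#'   the alignment is treated as sequenced.
#' @param bin_width Histogram bin width; defaults to
#'   [default_bin_width()] for the alignment's region.
#' @param B Bootstrap replicates.
#' @param seed Seed for the bootstrap resampling.
#' @param outgroup Optional sample id used to root the tree (excluded from
#'   the distance partition and monophyly scoring).
#' @return An object of class `marker_report`: list with the fields
#'   `region`, `n_total`, `n_amplified`, `n_sequenced`, `pcr_rate`,
#'   `seq_rate`, `length_min`, `length_max`, `gap_verdict`, `gap_margin`,
#'   `n_species`, `n_species_monophyletic`, `min_clade_support`, plus the
#'   underlying `histogram`, `species_summary`, `monophyly` and `tree`.
#' @export
evaluate_marker <- function(aln, sp, status = NULL, model = c("K2P", "p"),
                            bin_width = NULL, B = 1000L, seed = 1L,
                            outgroup = NULL,
                            gap_deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  gap_deletion <- match.arg(gap_deletion)
  validate_alignment(aln)
  if (is.null(bin_width)) bin_width <- default_bin_width(region(aln))

  if (!is.null(status)) {
    status <- region_status(status)
    if (nrow(status) == 0L) stop("region status table is empty")
    rates <- success_rates(status)
    keep <- status$sample_id[status$sequenced]
    aln_seq <- aln[intersect(rownames(aln), c(keep, outgroup)), , drop = FALSE]
    aln_seq <- alignment(aln_seq, region = region(aln))
  } else {
    rates <- list(n_total = nrow(aln), n_amplified = nrow(aln),
                  n_sequenced = nrow(aln), pcr_rate = 100, seq_rate = 100)
    aln_seq <- aln
  }
  ingroup <- setdiff(rownames(aln_seq), outgroup)
  if (length(ingroup) < 3L)
    stop("need at least three sequenced ingroup samples to evaluate a marker")
  unmapped <- setdiff(ingroup, names(sp))
  if (length(unmapped) > 0L)
    stop("samples missing from species map: ", paste(unmapped, collapse = ", "))

  lr <- length_range(aln_seq)
  m <- pairwise_matrix(aln_seq, model = model, gap_deletion = gap_deletion)
  part <- partition_distances(m[ingroup, ingroup], sp[ingroup])
  verdict <- gap_exists(part)
  hist <- build_histogram(part, bin_width)
  summary <- species_gap_summary(m[ingroup, ingroup], sp[ingroup])

  bs <- bootstrap_supports(aln_seq, model = model, B = B, seed = seed,
                           gap_deletion = gap_deletion)
  tree <- if (!is.null(outgroup) && outgroup %in% bs$tree$tip.label)
    root_with_outgroup(bs$tree, outgroup)
  else phangorn::midpoint(bs$tree)
  mono <- monophyly_check(tree, sp[ingroup])

  structure(list(
    region = region(aln), n_total = rates$n_total,
    n_amplified = rates$n_amplified, n_sequenced = rates$n_sequenced,
    pcr_rate = rates$pcr_rate, seq_rate = rates$seq_rate,
    length_min = lr[["min"]], length_max = lr[["max"]],
    gap_verdict = verdict$verdict, gap_margin = verdict$margin,
    n_species = nrow(mono),
    n_species_monophyletic = sum(mono$monophyletic),
    min_clade_support = if (all(is.na(mono$support))) NA_real_
                        else min(mono$support, na.rm = TRUE),
    histogram = hist, species_summary = summary, monophyly = mono,
    tree = tree, bootstrap = bs, bin_width = bin_width, model = model),
    class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  cat(sprintf("marker %s: %d/%d amplified (%d%%), %d/%d sequenced (%d%%)\n",
              x$region, x$n_amplified, x$n_total, x$pcr_rate,
              x$n_sequenced, x$n_total, x$seq_rate))
  cat(sprintf("  length %d-%d bp; %s (margin %+.4f); %d/%d species monophyletic",
              x$length_min, x$length_max, x$gap_verdict, x$gap_margin,
              x$n_species_monophyletic, x$n_species))
  if (!is.na(x$min_clade_support))
    cat(sprintf("; min clade support %d%%", as.integer(x$min_clade_support)))
  cat("\n")
  invisible(x)
}

#' Rank marker reports
#'
#' Orders reports by sequencing success rate, then by barcoding-gap margin,
#' both descending. A pure function of the report fields.
#'
#' @param reports List of `marker_report` objects.
#' @return Data frame, one row per marker in rank order, with the scalar
#'   report fields.
#' @export
rank_markers <- function(reports) {
  if (length(reports) == 0L) stop("no marker reports to rank")
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(region = r$region, n_total = r$n_total,
               n_amplified = r$n_amplified, n_sequenced = r$n_sequenced,
               pcr_rate = r$pcr_rate, seq_rate = r$seq_rate,
               length_min = r$length_min, length_max = r$length_max,
               gap_verdict = r$gap_verdict, gap_margin = r$gap_margin,
               n_species_monophyletic = r$n_species_monophyletic,
               min_clade_support = r$min_clade_support,
               stringsAsFactors = FALSE)))
  tab[order(-tab$seq_rate, -tab$gap_margin), , drop = FALSE]
}

#' Marker report writers
#'
#' `write_marker_report()` writes the scalar fields of one or more reports
#' as a TSV table or a JSON array.
#'
#' @param reports A `marker_report` or list of them.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_marker_report <- function(reports, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(reports, "marker_report")) reports <- list(reports)
  tab <- rank_markers(reports)
  if (format == "tsv")
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  else
    jsonlite::write_json(tab, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  invisible(path)
}

#' Bundled sequencing-outcome table for a 34-sample, five-marker study
#'
#' Returns the per-sample presence/absence of sequenced accessions across
#' five candidate barcode regions (ITS, IGS, nLSU, mtSSU, tef1) for the 34
#' *Lepista* samples of an eight-species study, as shipped in
#' `inst/extdata/lepista_region_presence.tsv`.
#'
#' @return Data frame with columns `sample_id`, `species` and one 0/1 column
#'   per region (`its`, `igs`, `nlsu`, `mtssu`, `tef1`).
#' @export
lepista_region_presence <- function() {
  path <- system.file("extdata", "lepista_region_presence.tsv",
                      package = "barcodegap", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname lepista_region_presence
#' @description `lepista_region_pcr()` returns the companion per-region lab
#'   bookkeeping (total samples, PCR successes and ungapped length ranges),
#'   which is declared input rather than something derivable from accession
#'   lists.
#' @export
lepista_region_pcr <- function() {
  path <- system.file("extdata", "lepista_region_pcr.tsv",
                      package = "barcodegap", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Region status tables from a presence/absence table
#'
#' Converts the wide presence table (one 0/1 column per region) plus
#' per-region PCR success counts into one [region_status()] table per
#' region. PCR failures are assigned to the samples lacking a sequence for
#' that region (a sample cannot be sequenced without amplifying), which
#' reproduces the per-region amplified/sequenced totals exactly.
#'
#' @param presence Data frame as returned by [lepista_region_presence()].
#' @param pcr Data frame as returned by [lepista_region_pcr()] (columns
#'   `region`, `n_amplified`); `NULL` treats every sample as amplified.
#' @return Named list of region status data frames.
#' @export
presence_to_status <- function(presence, pcr = NULL) {
  regions <- setdiff(names(presence), c("sample_id", "species"))
  out <- lapply(regions, function(rg) {
    sequenced <- presence[[rg]] > 0L
    amplified <- rep(TRUE, nrow(presence))
    if (!is.null(pcr)) {
      row <- pcr[tolower(pcr$region) == tolower(rg), , drop = FALSE]
      if (nrow(row) == 1L) {
        n_fail <- nrow(presence) - row$n_amplified
        unseq <- which(!sequenced)
        if (n_fail > length(unseq))
          stop("PCR failures exceed unsequenced samples for region ", rg)
        amplified[utils::head(unseq, n_fail)] <- FALSE
      }
    }
    region_status(data.frame(sample_id = presence$sample_id,
                             amplified = amplified, sequenced = sequenced,
                             stringsAsFactors = FALSE), region = rg)
  })
  stats::setNames(out, regions)
}
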