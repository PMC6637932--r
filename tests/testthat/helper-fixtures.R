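# Shared fixture builders. Everything is generated in code; no binary data.

# Write a FASTA file from named residue strings; returns the path.
write_fasta_fixture <- function(seqs, wrap = NULL) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  lines <- unlist(lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    body <- if (is.null(wrap)) s
            else substring(s, seq(1, nchar(s), wrap),
                           pmin(seq(1, nchar(s), wrap) + wrap - 1, nchar(s)))
    c(paste0(">", id), body)
  }))
  writeLines(lines, path)
  path
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Random additive distance matrix: path distances on a random binary tree
# with strictly positive edge lengths. Returns list(matrix, tree).
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) stats::runif(k, 0.5, 3))
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  list(m = ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label], tree = tr)
}

# The worked additive four-taxon matrix: tree ((A:1,B:2):1,C:3,D:4).
four_taxon_matrix <- function() {
  m <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  m
}

# Two clusters of identical sequences differing at half the sites (one
# quarter transitions, one quarter transversions, keeping K2P well inside
# its domain): the canonical high-support central-split alignment.
two_cluster_alignment <- function(n_per = 4L, n_sites = 1000L) {
  half <- n_sites %/% 2L
  quarter <- (n_sites - half) %/% 2L
  s1 <- strrep("A", n_sites)
  s2 <- paste0(strrep("A", half), strrep("G", quarter),
               strrep("C", n_sites - half - quarter))
  seqs <- c(stats::setNames(rep(s1, n_per), sprintf("c1_%d", seq_len(n_per))),
            stats::setNames(rep(s2, n_per), sprintf("c2_%d", seq_len(n_per))))
  alignment(seqs, region = "twoclust")
}
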