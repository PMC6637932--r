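# Seeded multi-species sequence simulator under the Kimura 2-parameter
# substitution process, with per-sample PCR/sequencing dropout.
#
# Rate convention: the instantaneous transition rate (A<->G, C<->T) is
# kappa times the rate of EACH of the two possible transversions, so the
# total substitution rate per site is alpha + 2*beta with alpha = kappa*beta.
# Branch "depth" is measured in expected substitutions per site, i.e.
# depth = (alpha + 2*beta) * t, which makes transition probabilities
# available in closed form and expected P/Q checkable analytically.

#' Simulation configuration
#'
#' Defaults emulate the structure of a small multi-region fungal barcoding
#' study: 8 species with sample sizes 1, 3, 8, 6, 3, 6, 5, 2 (34 samples),
#' aligned length 600 bp, shallow within-species divergence
#' (`intra_depth = 0.005` expected substitutions/site from the species
#' ancestor) against much deeper between-species divergence
#' (`inter_depth = 0.08` from the root to each species ancestor), a
#' transition/transversion rate ratio of 2, and no dropout.
#'
#' @param n_species Number of species.
#' @param samples_per_species Integer vector of per-species sample counts
#'   (recycled to `n_species` if scalar).
#' @param seq_length Aligned sequence length in bp.
#' @param inter_depth Expected substitutions/site from the root to each
#'   species ancestor (star species tree).
#' @param intra_depth Expected substitutions/site from a species ancestor to
#'   each of its samples.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param dropout_pcr Probability a sample fails PCR amplification.
#' @param dropout_seq Probability an amplified sample fails sequencing.
#' @param seed Integer seed; every draw in [simulate_dataset()] is
#'   reproducible from it.
#' @param region Region name stamped on the output alignment.
#' @param species_tree Optional `phylo` whose tips are species names
#'   `sp1..spk` and whose edge lengths are expected substitutions/site;
#'   overrides the star tree of depth `inter_depth`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_species = 8L,
                       samples_per_species = c(1L, 3L, 8L, 6L, 3L, 6L, 5L, 2L),
                       seq_length = 600L,
                       inter_depth = 0.08,
                       intra_depth = 0.005,
                       kappa = 2,
                       dropout_pcr = 0,
                       dropout_seq = 0,
                       seed = 1L,
                       region = "sim",
                       species_tree = NULL) {
  if (length(samples_per_species) == 1L)
    samples_per_species <- rep(samples_per_species, n_species)
  stopifnot(n_species >= 1L, length(samples_per_species) == n_species,
            all(samples_per_species >= 1L), seq_length >= 1L,
            inter_depth >= 0, intra_depth >= 0, kappa > 0,
            dropout_pcr >= 0, dropout_pcr <= 1,
            dropout_seq >= 0, dropout_seq <= 1)
  if (!is.null(species_tree)) {
    if (!inherits(species_tree, "phylo"))
      stop("species_tree must be a phylo object")
    if (!setequal(species_tree$tip.label, paste0("sp", seq_len(n_species))))
      stop("species_tree tips must be sp1..sp", n_species)
  }
  structure(list(n_species = as.integer(n_species),
                 samples_per_species = as.integer(samples_per_species),
                 seq_length = as.integer(seq_length),
                 inter_depth = inter_depth, intra_depth = intra_depth,
                 kappa = kappa, dropout_pcr = dropout_pcr,
                 dropout_seq = dropout_seq, seed = as.integer(seed),
                 region = region, species_tree = species_tree),
            class = "sim_config")
}

# K2P per-site transition-probability matrix at a given expected number of
# substitutions per site. Rows/columns in order A, C, G, T.
k2p_site_probs <- function(depth, kappa) {
  # beta*t from depth = (alpha + 2 beta) t, alpha = kappa * beta
  bt <- depth / (kappa + 2)
  at <- kappa * bt
  e1 <- exp(-4 * bt)                 # transversion-type decay
  e2 <- exp(-2 * (at + bt))          # transition-type decay
  p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1           # each of the two transversion targets
  out <- rbind(A = c(p_same, p_tv, p_ts, p_tv),
               C = c(p_tv, p_same, p_tv, p_ts),
               G = c(p_ts, p_tv, p_same, p_tv),
               T = c(p_tv, p_ts, p_tv, p_same))
  colnames(out) <- BASES
  out
}

#' Evolve a sequence along a branch under the K2P process
#'
#' Substitutes each site independently according to the K2P
#' transition-probability matrix at the given branch depth. Uses the current
#' R random-number state; seed externally (or via [simulate_dataset()]) for
#' reproducibility.
#'
#' @param seq Character vector of residues in `A C G T` (a string is also
#'   accepted).
#' @param depth Expected substitutions per site along the branch (>= 0).
#' @param kappa Transition/transversion rate ratio.
#' @return Character vector of residues, same length.
#' @export
evolve_branch <- function(seq, depth, kappa = 2) {
  seq <- .residues(seq)
  if (depth < 0) stop("depth must be non-negative")
  if (depth == 0) return(seq)
  P <- k2p_site_probs(depth, kappa)
  cum <- t(apply(P, 1L, cumsum))
  from <- match(seq, BASES)
  if (anyNA(from)) stop("evolve_branch input must be over A, C, G, T")
  u <- stats::runif(length(seq))
  pick <- 1L + (u > cum[from, 1L]) + (u > cum[from, 2L]) + (u > cum[from, 3L])
  BASES[pick]
}

#' Simulate a multi-species aligned dataset with dropout
#'
#' Draws a root sequence uniformly over `A C G T`, evolves one ancestor per
#' species (along a star tree of depth `inter_depth`, or along the supplied
#' species tree), evolves each sample from its species ancestor for
#' `intra_depth`, and draws independent per-sample PCR/sequencing dropout
#' flags. Sequences are gap-free and aligned by construction. Sample ids are
#' `sp<k>_<i>`; species are `sp1..spk`.
#'
#' The returned truth table holds the expected (true) pairwise distance for
#' every sample pair: `2 * intra_depth` within a species and the
#' species-tree path length plus `2 * intra_depth` between species
#' (`2 * (inter_depth + intra_depth)` on the star tree).
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_result` with elements `alignment`
#'   (`dna_alignment`), `species_map`, `status` (per-sample
#'   amplified/sequenced flags), `truth` (data frame `id_a`, `id_b`,
#'   `true_distance`) and `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$seq_length
  species <- paste0("sp", seq_len(cfg$n_species))
  root <- sample(BASES, L, replace = TRUE)

  ancestors <- if (is.null(cfg$species_tree)) {
    sapply(species, function(s)
      evolve_branch(root, cfg$inter_depth, cfg$kappa), simplify = FALSE)
  } else {
    .evolve_along_tree(root, cfg$species_tree, cfg$kappa)
  }

  ids <- character(0)
  seqs <- list()
  sp_of <- character(0)
  for (k in seq_len(cfg$n_species)) {
    for (i in seq_len(cfg$samples_per_species[k])) {
      id <- sprintf("%s_%d", species[k], i)
      ids <- c(ids, id)
      sp_of <- c(sp_of, species[k])
      seqs[[id]] <- evolve_branch(ancestors[[species[k]]],
                                  cfg$intra_depth, cfg$kappa)
    }
  }
  aln <- alignment(seqs, region = cfg$region)
  smap <- species_map(stats::setNames(sp_of, ids))

  n <- length(ids)
  amplified <- stats::runif(n) >= cfg$dropout_pcr
  sequenced <- amplified & (stats::runif(n) >= cfg$dropout_seq)
  status <- region_status(data.frame(sample_id = ids, amplified = amplified,
                                     sequenced = sequenced,
                                     stringsAsFactors = FALSE),
                          region = cfg$region)

  sp_dist <- if (is.null(cfg$species_tree)) {
    d <- matrix(2 * cfg$inter_depth, cfg$n_species, cfg$n_species,
                dimnames = list(species, species))
    diag(d) <- 0
    d
  } else {
    ape::cophenetic.phylo(cfg$species_tree)[species, species]
  }
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  truth <- data.frame(
    id_a = ids[idx[, 1L]], id_b = ids[idx[, 2L]],
    true_distance = sp_dist[cbind(sp_of[idx[, 1L]], sp_of[idx[, 2L]])] +
      2 * cfg$intra_depth,
    stringsAsFactors = FALSE)

  structure(list(alignment = aln, species_map = smap, status = status,
                 truth = truth, config = cfg),
            class = "sim_result")
}

# Evolve the root down a species tree (edge lengths in expected
# substitutions/site); returns one sequence per tip, named by tip label.
.evolve_along_tree <- function(root_seq, tree, kappa) {
  n <- length(tree$tip.label)
  root_node <- n + 1L
  seq_at <- list()
  seq_at[[root_node]] <- root_seq
  ord <- ape::reorder.phylo(tree, "cladewise")
  out <- list()
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1L]
    child <- ord$edge[e, 2L]
    s <- evolve_branch(seq_at[[parent]], ord$edge.length[e], kappa)
    if (child <= n) out[[ord$tip.label[child]]] <- s else seq_at[[child]] <- s
  }
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("simulated dataset: %d samples, %d species, %d bp [%s]\n",
              nrow(x$alignment), length(unique(x$species_map)),
              ncol(x$alignment), region(x$alignment)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the alignment (FASTA), species map (TSV), region status (TSV) and
#' truth table (TSV) into a directory, named `<region>.<ext>`.
#'
#' @param sim A `sim_result`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four paths, invisibly.
#' @export
write_sim_result <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rg <- region(sim$alignment)
  paths <- c(fasta = file.path(dir, paste0(rg, ".fasta")),
             species_map = file.path(dir, paste0(rg, ".species.tsv")),
             status = file.path(dir, paste0(rg, ".status.tsv")),
             truth = file.path(dir, paste0(rg, ".truth.tsv")))
  write_fasta(sim$alignment, paths["fasta"])
  utils::write.table(data.frame(sample_id = names(sim$species_map),
                                species = unname(sim$species_map)),
                     paths["species_map"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(sample_id = sim$status$sample_id,
                                amplified = as.integer(sim$status$amplified),
                                sequenced = as.integer(sim$status$sequenced)),
                     paths["status"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
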