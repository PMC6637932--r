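# Neighbor-joining tree construction, Newick I/O, bootstrap supports,
# outgroup rooting and per-species monophyly checks.
#
# Trees are "phylo" objects (ape), so the whole ape/phangorn toolbox applies
# to anything this module returns.

#' Build a neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - r(i) - r(j)` is joined, with the standard NJ
#' branch-length assignments. Ties on Q are broken deterministically by
#' joining the pair whose (sorted) cluster labels are lexicographically
#' smallest, a cluster being labelled by its smallest member leaf. The method
#' recovers the exact topology and edge lengths of any additive matrix.
#' Negative branch lengths, when the matrix is far from additive, are
#' retained (see [to_newick()] for optional clamping on output).
#'
#' @param m Square symmetric distance matrix with unique dimnames and at
#'   least three labels; all entries must be defined (no `NA` -- drop
#'   offending samples first).
#' @return An unrooted `phylo` with a basal trifurcation.
#' @export
nj_build <- function(m) {
  m <- as.matrix(m)
  labels <- rownames(m)
  n <- nrow(m)
  if (is.null(labels) || anyDuplicated(labels))
    stop("distance matrix needs unique row/column labels")
  if (n < 3L) stop("need at least three labels to build a tree")
  if (anyNA(m))
    stop("distance matrix has undefined entries; drop the offending samples ",
         "before tree building")

  D <- unname(m)
  node_id <- seq_len(n)          # phylo id of each active cluster
  clab <- labels                 # lexicographic tie-break key per cluster
  next_node <- n + 1L
  edge <- matrix(0L, 2L * n - 3L, 2L)
  elen <- numeric(2L * n - 3L)
  ne <- 0L
  add_edge <- function(parent, child, len) {
    ne <<- ne + 1L
    edge[ne, ] <<- c(parent, child)
    elen[ne] <<- len
  }

  while (length(node_id) > 3L) {
    na <- length(node_id)
    r <- rowSums(D)
    Q <- (na - 2L) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    if (nrow(cand) > 1L) {
      key <- apply(cand, 1L, function(p)
        paste(sort(c(clab[p[1L]], clab[p[2L]])), collapse = "\r"))
      cand <- cand[order(key)[1L], , drop = FALSE]
    }
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (na - 2L))
    vj <- D[i, j] - vi
    u <- next_node; next_node <- next_node + 1L
    add_edge(u, node_id[i], vi)
    add_edge(u, node_id[j], vj)
    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(na), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    node_id <- c(node_id[keep], u)
    clab <- c(clab[keep], min(clab[c(i, j)]))
  }

  # final trifurcation: closed-form three-taxon lengths
  u <- next_node
  d12 <- D[1L, 2L]; d13 <- D[1L, 3L]; d23 <- D[2L, 3L]
  add_edge(u, node_id[1L], (d12 + d13 - d23) / 2)
  add_edge(u, node_id[2L], (d12 + d23 - d13) / 2)
  add_edge(u, node_id[3L], (d13 + d23 - d12) / 2)

  # ape convention: tips 1..n, root n+1; the root here is the last-created
  # internal node, so rotate internal numbering accordingly
  n_internal <- n - 2L
  remap <- function(v) ifelse(v <= n, v,
                              ifelse(v == n + n_internal, n + 1L, v + 1L))
  edge <- matrix(as.integer(remap(edge)), ncol = 2L)
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = labels, Nnode = n_internal),
                   class = "phylo", order = "postorder")
  ape::reorder.phylo(phy, "cladewise")
}

#' Serialize / parse Newick
#'
#' `to_newick()` writes a `phylo` as a Newick string with branch lengths at
#' fixed precision; node labels (e.g. bootstrap supports) are preserved as
#' internal labels. `from_newick()` parses a Newick string or file.
#'
#' @param tree A `phylo`.
#' @param digits Decimal places for branch lengths.
#' @param clamp_negative If `TRUE`, negative branch lengths are written as 0
#'   (the in-memory tree is never modified).
#' @return `to_newick()`: a character scalar. `from_newick()`: a `phylo`.
#' @export
to_newick <- function(tree, digits = 6L, clamp_negative = FALSE) {
  if (clamp_negative && !is.null(tree$edge.length))
    tree$edge.length <- pmax(tree$edge.length, 0)
  ape::write.tree(tree, digits = digits)
}

#' @rdname to_newick
#' @param x Newick text, or path to a Newick file.
#' @export
from_newick <- function(x) {
  tr <- tryCatch(
    if (length(x) == 1L && !grepl("(", x, fixed = TRUE) && file.exists(x))
      ape::read.tree(file = x)
    else ape::read.tree(text = x),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("malformed Newick input")
  tr
}

#' Root a tree on the branch leading to an outgroup
#'
#' @param tree A `phylo`.
#' @param outgroup A tip label present in the tree.
#' @return A rooted `phylo`; internal (support) labels stay attached to the
#'   correct edges.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a tip of the tree")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE, edgelabel = TRUE)
}

#' Neighbor-joining tree with Felsenstein bootstrap supports
#'
#' Builds the reference NJ tree from the full alignment, then resamples
#' aligned columns uniformly with replacement (`B` pseudo-alignments of the
#' original length), rebuilds a tree from each, and scores every internal
#' bipartition of the reference tree by the percentage of replicate trees
#' containing it. Replicates whose distance matrix has undefined entries are
#' dropped and counted; more than 10% dropped is an error. Supports are
#' rounded to integer percentages (half up) and stored as node labels.
#'
#' @inheritParams pairwise_matrix
#' @param B Number of bootstrap replicates (1,000 is the conventional
#'   default).
#' @param seed Integer seed making the resampling reproducible.
#' @return List of class `bootstrap_result`: `tree` (reference `phylo` with
#'   supports as `node.label`), `supports` (numeric, per internal node),
#'   `n_replicates`, `n_used`, `n_dropped`, `seed`.
#' @export
bootstrap_supports <- function(aln, model = c("K2P", "p"), B = 1000L,
                               seed = NULL,
                               gap_deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  gap_deletion <- match.arg(gap_deletion)
  if (B < 1L) stop("B must be at least 1")
  if (!is.null(seed)) set.seed(seed)

  ref_m <- pairwise_matrix(aln, model = model, gap_deletion = gap_deletion)
  if (anyNA(ref_m))
    stop("reference distance matrix has undefined entries; drop the ",
         "offending samples before bootstrapping")
  ref <- nj_build(ref_m)

  m <- unclass(aln)
  if (gap_deletion == "complete") {
    keep <- colSums(matrix(m %in% BASES, nrow(m))) == nrow(m)
    m <- m[, keep, drop = FALSE]
  }
  ind <- .base_indicators(m)
  L <- ncol(m)
  ids <- rownames(m)

  trees <- vector("list", B)
  used <- 0L
  for (b in seq_len(B)) {
    cols <- sample.int(L, L, replace = TRUE)
    d <- .distance_from_counts(.pair_count_matrices(ind, cols), model)
    if (anyNA(d)) next
    dimnames(d) <- list(ids, ids)
    used <- used + 1L
    trees[[used]] <- nj_build(d)
  }
  dropped <- B - used
  if (dropped > 0.1 * B)
    stop(sprintf("%d of %d bootstrap replicates had undefined distances", dropped, B))
  if (dropped > 0L)
    warning(sprintf("%d bootstrap replicates dropped (undefined distances)", dropped))
  trees <- trees[seq_len(used)]
  class(trees) <- "multiPhylo"

  counts <- ape::prop.clades(ref, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- floor(100 * counts / used + 0.5)
  ref$node.label <- as.character(supports)
  structure(list(tree = ref, supports = supports, n_replicates = B,
                 n_used = used, n_dropped = dropped, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("NJ bootstrap: %d replicates (%d used, %d dropped), %d internal nodes\n",
              x$n_replicates, x$n_used, x$n_dropped, length(x$supports)))
  invisible(x)
}

#' Per-species monophyly check on a rooted tree
#'
#' A species is monophyletic when some clade of the tree contains exactly
#' that species' samples. Singleton species are monophyletic by convention
#' (support reported as `NA`). For multi-sample species the support is the
#' node label (bootstrap percentage) of the clade's ancestral node, when
#' labels are present.
#'
#' @param tree A rooted `phylo` whose tips are sample ids (outgroup tips may
#'   be absent from the species map and are then ignored).
#' @param sp Species map covering, for every species checked, samples that
#'   are all present in the tree.
#' @return Data frame with columns `species`, `n_samples`, `monophyletic`,
#'   `support`.
#' @export
monophyly_check <- function(tree, sp) {
  if (!ape::is.rooted(tree)) stop("monophyly_check needs a rooted tree")
  tips <- tree$tip.label
  species <- sort(unique(unname(sp)))
  clades <- ape::prop.part(tree)
  clade_keys <- vapply(clades, function(s) paste(sort(s), collapse = ","),
                       character(1L))
  labs <- tree$node.label
  rows <- lapply(species, function(s) {
    members <- names(sp)[unname(sp) == s]
    if (!all(members %in% tips))
      stop("species '", s, "' has samples absent from the tree: ",
           paste(setdiff(members, tips), collapse = ", "))
    nsam <- length(members)
    if (nsam == 1L)
      return(data.frame(species = s, n_samples = 1L, monophyletic = TRUE,
                        support = NA_real_, stringsAsFactors = FALSE))
    key <- paste(sort(match(members, tips)), collapse = ",")
    k <- which(clade_keys == key)
    mono <- length(k) == 1L
    supp <- NA_real_
    if (mono && !is.null(labs)) {
      val <- suppressWarnings(as.numeric(labs[k]))
      if (length(val) == 1L && !is.na(val)) supp <- val
    }
    data.frame(species = s, n_samples = nsam, monophyletic = mono,
               support = supp, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
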