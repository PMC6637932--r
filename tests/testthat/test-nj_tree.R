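test_that("NJ recovers the worked additive four-taxon case exactly", {
  m <- four_taxon_matrix()
  tr <- nj_build(m)
  expect_s3_class(tr, "phylo")
  expect_identical(length(tr$tip.label), 4L)
  # topology {A,B}|{C,D} with edge lengths (A:1, B:2, internal:1, C:3, D:4)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(m), colnames(m)], m,
               tolerance = 1e-12, ignore_attr = TRUE)
  lens <- stats::setNames(tr$edge.length, c(tr$tip.label,
                          rep(NA, tr$Nnode))[tr$edge[, 2]])
  expect_equal(lens[["A"]], 1)
  expect_equal(lens[["B"]], 2)
  expect_equal(lens[["C"]], 3)
  expect_equal(lens[["D"]], 4)
  expect_equal(unname(lens[is.na(names(lens))]), 1)  # the single internal edge
})

test_that("three taxa produce the forced topology with closed-form lengths", {
  ids <- c("x", "y", "z")
  m <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3, dimnames = list(ids, ids))
  tr <- nj_build(m)
  expect_identical(tr$Nnode, 1L)
  lens <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["x"]], 1)   # (3 + 4 - 5)/2
  expect_equal(lens[["y"]], 2)
  expect_equal(lens[["z"]], 3)
})

test_that("NJ is exact on random additive matrices and agrees with ape", {
  for (seed in 1:6) {
    n <- sample(4:8, 1)
    fix <- random_additive_matrix(n, seed)
    tr <- nj_build(fix$m)
    # additivity: path lengths reproduce the input matrix exactly
    expect_equal(ape::cophenetic.phylo(tr)[rownames(fix$m), colnames(fix$m)],
                 fix$m, tolerance = 1e-10, ignore_attr = TRUE)
    # topology identical to the generating tree and to an independent NJ
    expect_identical(ape::dist.topo(ape::unroot(fix$tree), tr)[1], 0)
    expect_identical(ape::dist.topo(ape::nj(as.dist(fix$m)), tr)[1], 0)
  }
})

test_that("NJ output is invariant under input-order permutation", {
  fix <- random_additive_matrix(7, seed = 21)
  tr1 <- nj_build(fix$m)
  set.seed(1)
  perm <- sample(7)
  tr2 <- nj_build(fix$m[perm, perm])
  expect_identical(ape::dist.topo(tr1, tr2)[1], 0)
  expect_equal(ape::cophenetic.phylo(tr2)[rownames(fix$m), colnames(fix$m)],
               ape::cophenetic.phylo(tr1)[rownames(fix$m), colnames(fix$m)])
})

test_that("NJ rejects degenerate inputs", {
  m <- four_taxon_matrix()
  m[1, 2] <- m[2, 1] <- NA
  expect_error(nj_build(m), "undefined")
  expect_error(nj_build(four_taxon_matrix()[1:2, 1:2]), "three")
  bad <- four_taxon_matrix(); rownames(bad) <- colnames(bad) <- rep("A", 4)
  expect_error(nj_build(bad), "unique")
})

test_that("Newick round-trips preserve topology, lengths and supports", {
  tr <- nj_build(four_taxon_matrix())
  txt <- to_newick(tr)
  expect_match(txt, "^\\(.*\\);$")
  back <- from_newick(txt)
  expect_identical(ape::dist.topo(tr, back)[1], 0)

  # 34-leaf random tree round-trip
  set.seed(13)
  big <- ape::rtree(34)
  big$edge.length <- round(big$edge.length, 6)
  back_big <- from_newick(to_newick(big))
  expect_identical(ape::dist.topo(ape::unroot(big), ape::unroot(back_big))[1], 0)
  expect_equal(sort(back_big$edge.length), sort(big$edge.length), tolerance = 1e-9)

  # supports serialized as internal node labels survive the round trip
  tr$node.label <- c("", "97")
  back2 <- from_newick(to_newick(tr))
  expect_true("97" %in% back2$node.label)

  expect_error(from_newick("(A:1,B:2"), "malformed|Newick")
  # negative lengths can be clamped on output only
  neg <- tr; neg$edge.length[1] <- -0.5
  expect_match(to_newick(neg, clamp_negative = TRUE), ":0")
  expect_equal(neg$edge.length[1], -0.5)
})

test_that("outgroup rooting places the outgroup sister to the ingroup", {
  tr <- nj_build(four_taxon_matrix())
  rooted <- root_with_outgroup(tr, "D")
  expect_true(ape::is.rooted(rooted))
  d_node <- which(rooted$tip.label == "D")
  root_children <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1L, 2]
  expect_true(d_node %in% root_children)
  # rooting then unrooting preserves the bipartition set
  expect_identical(ape::dist.topo(ape::unroot(rooted), tr)[1], 0)
  expect_error(root_with_outgroup(tr, "nope"), "not a tip")
})

test_that("bootstrap supports are reproducible, bounded, and near-certain for a deep split", {
  aln <- two_cluster_alignment(n_per = 4L, n_sites = 1000L)
  b1 <- bootstrap_supports(aln, B = 50L, seed = 42L)
  b2 <- bootstrap_supports(aln, B = 50L, seed = 42L)
  expect_identical(b1$supports, b2$supports)
  expect_true(all(b1$supports >= 0 & b1$supports <= 100))
  expect_identical(b1$n_used + b1$n_dropped, 50L)

  # the central bipartition of two clusters differing at 50% of sites
  rooted <- root_with_outgroup(b1$tree, "c1_1")
  mono <- monophyly_check(rooted, stats::setNames(rep(c("c1", "c2"), each = 4),
                                                  c(paste0("c1_", 1:4),
                                                    paste0("c2_", 1:4))))
  expect_gte(mono$support[mono$species == "c2"], 99)

  # B = 1 can only produce 0 or 100
  b3 <- bootstrap_supports(aln, B = 1L, seed = 7L)
  expect_true(all(b3$supports %in% c(0, 100)))
})

test_that("support bookkeeping covers the n-3 internal edges of an unrooted tree", {
  sim <- simulate_dataset(sim_config(n_species = 4L, samples_per_species = 3L,
                                     seq_length = 500L, seed = 31))
  bs <- bootstrap_supports(sim$alignment, B = 20L, seed = 31L)
  n <- nrow(sim$alignment)
  # Nnode = n - 2 internal nodes; the basal node carries the trivial split
  expect_identical(length(bs$supports), n - 2L)
  expect_identical(bs$tree$Nnode, n - 2L)
  expect_identical(sum(bs$tree$edge[, 2] > n), n - 3L)  # internal edges
})

test_that("monophyly is detected exactly from clades of a rooted tree", {
  tr <- from_newick("((a1:1,a2:1):1,(b1:1,b2:1):1);")
  sp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  res <- monophyly_check(tr, sp)
  expect_true(all(res$monophyletic))

  mixed <- from_newick("((a1:1,b1:1):1,(a2:1,b2:1):1);")
  res2 <- monophyly_check(mixed, sp)
  expect_false(any(res2$monophyletic))

  # singleton species are monophyletic by convention, support n/a
  tr3 <- from_newick("((a1:1,a2:1)90:1,c1:2);")
  res3 <- monophyly_check(tr3, c(a1 = "A", a2 = "A", c1 = "C"))
  expect_true(all(res3$monophyletic))
  expect_true(is.na(res3$support[res3$species == "C"]))
  expect_equal(res3$support[res3$species == "A"], 90)

  expect_error(monophyly_check(tr, c(sp, z9 = "Z")), "absent")
  expect_error(monophyly_check(nj_build(four_taxon_matrix()),
                               c(A = "x", B = "x", C = "y", D = "y")),
               "rooted")
})

test_that("well-separated simulated species form monophyletic clades", {
  sim <- simulate_dataset(sim_config(seed = 12))
  bs <- bootstrap_supports(sim$alignment, B = 30L, seed = 12L)
  rooted <- phangorn::midpoint(bs$tree)
  mono <- monophyly_check(rooted, sim$species_map)
  expect_identical(nrow(mono), 8L)
  expect_true(all(mono$monophyletic))
})
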