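# A toy matrix with a known structure, used by several blocks below:
# species A = {a1, a2} (intra 0.005), B = {b1, b2} (intra 0.004),
# C = {c1, c2} (intra 0.006); min inter d(A,B) = 0.02 < d(A,C) = 0.08.
toy_gap_matrix <- function() {
  ids <- c("a1", "a2", "b1", "b2", "c1", "c2")
  m <- matrix(0, 6, 6, dimnames = list(ids, ids))
  fill <- function(i, j, v) m[i, j] <<- m[j, i] <<- v
  fill("a1", "a2", 0.005); fill("b1", "b2", 0.004); fill("c1", "c2", 0.006)
  for (a in c("a1", "a2")) for (b in c("b1", "b2")) fill(a, b, 0.02)
  for (a in c("a1", "a2")) for (c_ in c("c1", "c2")) fill(a, c_, 0.08)
  for (b in c("b1", "b2")) for (c_ in c("c1", "c2")) fill(b, c_, 0.05)
  m
}
toy_species <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C", c2 = "C")

test_that("distance partition assigns every defined pair to one class", {
  m <- toy_gap_matrix()
  part <- partition_distances(m, toy_species)
  expect_identical(nrow(part$intra), 3L)
  expect_identical(nrow(part$inter), 12L)
  expect_identical(part$n_undefined, 0L)

  two_same <- matrix(c(0, .1, .1, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  p1 <- partition_distances(two_same, c(x = "S", y = "S"))
  expect_identical(c(nrow(p1$intra), nrow(p1$inter)), c(1L, 0L))
  p2 <- partition_distances(two_same, c(x = "S", y = "T"))
  expect_identical(c(nrow(p2$intra), nrow(p2$inter)), c(0L, 1L))

  expect_error(partition_distances(m, toy_species[-1]), "a1")
})

test_that("the study-sized design yields 75 intra and 486 inter pairs", {
  # sizes {1,3,8,6,3,6,5,2}: sum C(n_i,2) = 75 of C(34,2) = 561 pairs
  sim <- simulate_dataset(sim_config(seed = 2))
  m <- pairwise_matrix(sim$alignment)
  part <- partition_distances(m, sim$species_map)
  expect_identical(nrow(part$intra), 75L)
  expect_identical(nrow(part$inter), 486L)
  expect_identical(nrow(part$intra) + nrow(part$inter), 561L)
})

test_that("partition conservation holds for random species maps", {
  sim <- simulate_dataset(sim_config(n_species = 5L, samples_per_species = 3L,
                                     seq_length = 300L, seed = 8))
  m <- pairwise_matrix(sim$alignment)
  ids <- rownames(m)
  set.seed(99)
  for (rep in 1:10) {
    sp <- species_map(stats::setNames(sample(LETTERS[1:4], length(ids),
                                             replace = TRUE), ids))
    part <- partition_distances(m, sp)
    expect_identical(nrow(part$intra) + nrow(part$inter) + part$n_undefined,
                     as.integer(choose(length(ids), 2)))
  }
})

test_that("per-species summaries report nearest species and local gaps", {
  m <- toy_gap_matrix()
  s <- species_gap_summary(m, toy_species)
  a <- s[s$species == "A", ]
  expect_equal(a$max_intra, 0.005)
  expect_equal(a$min_inter, 0.02)
  expect_identical(a$nearest_species, "B")
  expect_true(a$gap_present)

  # brute-force cross-check of min_inter for every species
  part <- partition_distances(m, toy_species)
  for (i in seq_len(nrow(s))) {
    sel <- part$inter$species_a == s$species[i] | part$inter$species_b == s$species[i]
    expect_equal(s$min_inter[i], min(part$inter$distance[sel]))
  }

  # species whose intra variation exceeds its nearest neighbour has no gap
  m2 <- m
  m2["a1", "a2"] <- m2["a2", "a1"] <- 0.03
  s2 <- species_gap_summary(m2, toy_species)
  expect_false(s2[s2$species == "A", "gap_present"])
})

test_that("singleton species are scored on min_inter alone", {
  ids <- c("a1", "b1", "b2")
  m <- matrix(c(0, .02, .02, .02, 0, .004, .02, .004, 0), 3, 3,
              dimnames = list(ids, ids))
  s <- species_gap_summary(m, c(a1 = "A", b1 = "B", b2 = "B"))
  a <- s[s$species == "A", ]
  expect_true(is.na(a$max_intra))
  expect_true(a$gap_present)
  # a singleton identical to another species' sample: no gap
  m0 <- m; m0["a1", "b1"] <- m0["b1", "a1"] <- 0
  s0 <- species_gap_summary(m0, c(a1 = "A", b1 = "B", b2 = "B"))
  expect_false(s0[s0$species == "A", "gap_present"])
})

test_that("histograms bin half-open intervals and conserve totals", {
  part <- structure(list(
    intra = data.frame(species = "S", distance = c(0.001, 0.0039, 0.004)),
    inter = data.frame(species_a = "S", species_b = "T", distance = 0.011),
    n_undefined = 0L), class = "distance_partition")
  h4 <- build_histogram(part, 0.004)
  # boundary value 0.004 falls in the second bin
  expect_equal(h4$intra_count, c(2L, 1L, 0L))
  expect_equal(h4$inter_count, c(0L, 0L, 1L))
  expect_equal(h4$bin_start, c(0, 0.004, 0.008))

  h8 <- build_histogram(part, 0.008)
  expect_equal(h8$intra_count, c(3L, 0L))
  expect_equal(h8$inter_count, c(0L, 1L))

  all_zero <- structure(list(
    intra = data.frame(species = "S", distance = c(0, 0)),
    inter = data.frame(species_a = "S", species_b = "T", distance = 0),
    n_undefined = 0L), class = "distance_partition")
  hz <- build_histogram(all_zero, 0.004)
  expect_identical(nrow(hz), 1L)
  expect_equal(c(hz$intra_count, hz$inter_count), c(2L, 1L))

  expect_error(build_histogram(part, 0), "positive")
  # conservation on simulated data
  sim <- simulate_dataset(sim_config(seed = 4))
  p <- partition_distances(pairwise_matrix(sim$alignment), sim$species_map)
  h <- build_histogram(p, 0.004)
  expect_identical(sum(h$intra_count), nrow(p$intra))
  expect_identical(sum(h$inter_count), nrow(p$inter))
})

test_that("the global gap verdict is strict and reports its margin", {
  part <- structure(list(
    intra = data.frame(species = "S", distance = c(0.002, 0.01)),
    inter = data.frame(species_a = "S", species_b = "T", distance = c(0.05, 0.09)),
    n_undefined = 0L), class = "distance_partition")
  v <- gap_exists(part)
  expect_identical(v$verdict, "clear gap")
  expect_equal(v$margin, 0.04)

  part$inter$distance <- c(0.02, 0.09)
  part$intra$distance <- c(0.002, 0.03)
  expect_identical(gap_exists(part)$verdict, "overlap")
  # a tie counts as overlap
  part$intra$distance <- c(0.002, 0.02)
  expect_identical(gap_exists(part)$verdict, "overlap")

  empty <- part; empty$intra <- part$intra[0, ]
  expect_error(gap_exists(empty), "intra")
})

test_that("the verdict is invariant under species relabeling and sample order", {
  m <- toy_gap_matrix()
  v1 <- gap_exists(partition_distances(m, toy_species))
  relabeled <- stats::setNames(paste0("x_", toy_species), names(toy_species))
  v2 <- gap_exists(partition_distances(m, relabeled))
  perm <- c(5, 3, 1, 6, 2, 4)
  v3 <- gap_exists(partition_distances(m[perm, perm], toy_species))
  expect_identical(v1$verdict, v2$verdict)
  expect_equal(v1$margin, v2$margin)
  expect_equal(v1$margin, v3$margin)
})

test_that("simulated deep inter-specific divergence yields a clear gap reliably", {
  # inter/intra depth ratio 10 at 600 bp: expect a gap in nearly all seeds
  hits <- 0L
  for (s in 1:25) {
    sim <- simulate_dataset(sim_config(inter_depth = 0.05, intra_depth = 0.005,
                                       seq_length = 600L, seed = s))
    part <- partition_distances(pairwise_matrix(sim$alignment), sim$species_map)
    if (gap_exists(part)$verdict == "clear gap") hits <- hits + 1L
  }
  expect_gte(hits, 24L)
})

test_that("region defaults pick the conventional bin widths", {
  expect_equal(default_bin_width("ITS"), 0.004)
  expect_equal(default_bin_width("nLSU"), 0.004)
  expect_equal(default_bin_width("mtSSU"), 0.004)
  expect_equal(default_bin_width("IGS"), 0.008)
  expect_equal(default_bin_width("tef1"), 0.008)
})
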