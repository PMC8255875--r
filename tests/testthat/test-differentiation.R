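test_that("W&C F_ST matches the textbook oracle on the worked toy", {
  # pop1: 6 AA, 4 Aa; pop2: 2 AA, 3 Aa, 5 aa (dosage counts the a allele)
  g1 <- matrix(c(rep(0L, 6), rep(1L, 4)), ncol = 1)
  g2 <- matrix(c(rep(0L, 2), rep(1L, 3), rep(2L, 5)), ncol = 1)
  res <- wc_fst(fst_toy_dataset(g1, g2), "P1", "P2")
  orc <- wc_oracle(g1, g2)
  expect_equal(res$weighted, orc$weighted, tolerance = 1e-12)
  expect_equal(res$per_snp$a, orc$a, tolerance = 1e-12)
  expect_equal(res$per_snp$b, orc$b, tolerance = 1e-12)
  expect_equal(res$per_snp$c, orc$c, tolerance = 1e-12)
  expect_equal(res$weighted, 0.3032015, tolerance = 1e-6)  # frozen from oracle
})

test_that("W&C estimator equals the oracle on random toys", {
  set.seed(81)
  for (i in 1:50) {
    toy <- random_fst_toy()
    ds <- fst_toy_dataset(toy$g1, toy$g2)
    orc <- wc_oracle(toy$g1, toy$g2)
    if (!is.finite(orc$weighted)) next
    res <- wc_fst(ds, "P1", "P2")
    expect_equal(res$weighted, orc$weighted, tolerance = 1e-10,
                 info = sprintf("toy %d", i))
  }
})

test_that("F_ST null, maximal-differentiation and self-split behaviour", {
  set.seed(91)
  # identical source frequencies, no drift: estimate near 0
  est0 <- vapply(1:8, function(i) {
    f <- runif(80, 0.1, 0.9)
    g1 <- sapply(f, function(p) rbinom(50, 2, p))
    g2 <- sapply(f, function(p) rbinom(50, 2, p))
    wc_fst(fst_toy_dataset(g1, g2), "P1", "P2")$weighted
  }, 0)
  expect_lt(abs(mean(est0)), 0.01)
  # fixed difference at one SNP: per-SNP ratio near 1
  g1 <- matrix(0L, 100, 1); g2 <- matrix(2L, 100, 1)
  res <- wc_fst(fst_toy_dataset(g1, g2), "P1", "P2")
  expect_gt(res$per_snp$ratio, 0.98)
  # a breed split in halves against itself
  sim <- simulate_breeds(sim_config(
    genome = test_genome(2L, 40, 200L),
    breeds = data.frame(breed = "B", N = 60L, generations = 10L),
    samples_per_breed = 60L, missing_rate = 0, seed = 17))
  ds <- sim$dataset
  ds$samples$breed <- rep(c("H1", "H2"), 30L)
  expect_lt(abs(wc_fst(ds, "H1", "H2")$weighted), 0.02)
})

test_that("consensus sequences follow majority / IUPAC-tie / gap rules", {
  calls <- rbind(c(2L, 1L, NA, 0L),
                 c(2L, 1L, NA, 0L),
                 c(1L, 1L, NA, 0L),
                 c(2L, 1L, NA, 0L),
                 c(0L, 1L, NA, 0L))
  ds <- toy_dataset(calls, allele_a = c("A", "A", "C", "T"),
                    allele_b = c("G", "G", "T", "C"))
  cs <- consensus_sequence(ds, "B1")
  expect_equal(cs[1], "G")       # f_b = 0.7
  expect_equal(cs[2], "R")       # exact tie, A/G
  expect_equal(cs[3], "-")       # untyped
  expect_equal(cs[4], "T")       # f_b = 0
})

test_that("Tajima-Nei distance: identity, pairwise deletion, saturation", {
  x <- strsplit("ACGTACGTAC", "")[[1]]
  expect_equal(tajima_nei_distance(x, x), 0)
  # gaps at differing sites are deleted pairwise -> distance drops
  y <- x; y[1:2] <- c("G", "A")
  d_full <- tajima_nei_distance(x, y)
  y_gap <- y; y_gap[1] <- "-"
  expect_lt(tajima_nei_distance(x, y_gap), d_full)
  expect_error(tajima_nei_distance(x, rep("-", 10)), "no jointly")
  expect_error(tajima_nei_distance(x, c(x, "A")), "length")
  # heavily saturated pair
  expect_error(
    tajima_nei_distance(strsplit("ACACACACAC", "")[[1]],
                        strsplit("CACACACACA", "")[[1]]), "saturation")
})

test_that("Tajima-Nei reduces to Jukes-Cantor at equal base frequencies", {
  # 12 differing sites covering all 6 unordered pairs twice, 108 identical
  # sites with 27 of each base: g = (1/4,..), p = 0.1, b = 3/4 exactly
  pairs6 <- rbind(c("A", "C"), c("A", "G"), c("A", "T"),
                  c("C", "G"), c("C", "T"), c("G", "T"))
  x <- c(pairs6[, 1], pairs6[, 2], rep(c("A", "C", "G", "T"), each = 27))
  y <- c(pairs6[, 2], pairs6[, 1], rep(c("A", "C", "G", "T"), each = 27))
  d <- tajima_nei_distance(x, y)
  expect_equal(d, -0.75 * log(1 - 0.1 / 0.75), tolerance = 1e-9)
  expect_equal(d, 0.10732, tolerance = 1e-4)
})

test_that("distance_matrix is symmetric, zero-diagonal, near zero for clones", {
  set.seed(101)
  sim <- simulate_breeds(sim_config(
    genome = test_genome(1L, 30, 150L),
    breeds = data.frame(breed = "B", N = 40L, generations = 5L),
    samples_per_breed = 20L, missing_rate = 0, seed = 23))
  one <- sim$dataset
  # duplicate the same individuals as a second "breed": truly identical pools
  ds <- genotype_dataset(rbind(one$calls, one$calls),
                         samples = data.frame(
                           sample_id = c(one$samples$sample_id,
                                         paste0(one$samples$sample_id, "b")),
                           breed = rep(c("C1", "C2"), each = 20L)),
                         map = one$map, sort = FALSE)
  dmx <- distance_matrix(ds)
  expect_equal(dmx$fst, t(dmx$fst))
  expect_equal(diag(dmx$tajima_nei), c(C1 = 0, C2 = 0))
  expect_equal(dmx$tajima_nei["C1", "C2"], 0)           # identical consensus
  expect_lt(dmx$fst["C1", "C2"], 1e-8)                  # clamped at 0
})

test_that("nj_tree solves the 3-taxon system and validates input", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(dm)
  expect_match(tr$newick, "A:1")
  expect_match(tr$newick, "B:1")
  expect_match(tr$newick, "C:3")
  # ultrametric equidistant taxa: equal branches
  dmu <- matrix(2, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  diag(dmu) <- 0
  expect_match(nj_tree(dmu)$newick, "^\\(A:1,B:1,C:1\\);$")
  bad <- dm; bad[1, 2] <- 5
  expect_error(nj_tree(bad), "symmetric")
  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")
})

test_that("nj_tree exactly recovers additive 4-taxon metrics", {
  skip_if_not_installed("ape")
  # tree ((A:1,B:2):3,(C:4,D:5)) -> additive distances
  dm <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dm["A", "B"] <- dm["B", "A"] <- 3
  dm["A", "C"] <- dm["C", "A"] <- 8
  dm["A", "D"] <- dm["D", "A"] <- 9
  dm["B", "C"] <- dm["C", "B"] <- 9
  dm["B", "D"] <- dm["D", "B"] <- 10
  dm["C", "D"] <- dm["D", "C"] <- 9
  tr <- ape::read.tree(text = nj_tree(dm)$newick)
  expect_equal(sort(tr$tip.label), LETTERS[1:4])
  cd <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(cd, dm, tolerance = 1e-9)       # branch lengths recovered
  # correct split: A,B vs C,D
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::read.tree(
    text = "((A:1,B:2):3,C:4,D:5);"))), 0)
})

test_that("Newick output round-trips through an independent parser", {
  skip_if_not_installed("ape")
  set.seed(111)
  dm <- as.matrix(dist(matrix(rnorm(14), 7)))
  dimnames(dm) <- list(paste0("t", 1:7), paste0("t", 1:7))
  tr <- nj_tree(dm)
  ap <- ape::read.tree(text = tr$newick)
  expect_equal(sort(ap$tip.label), sort(tr$labels))
  expect_true(all(ap$edge.length >= 0))        # clamping guarantee
})
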