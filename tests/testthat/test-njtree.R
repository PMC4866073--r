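test_that("three-taxon NJ matches the closed-form star solution", {
  d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("a", "b", "c")], c(a = 0.05, b = 0.15, c = 0.25),
               tolerance = 1e-12)
})

test_that("NJ recovers additive trees exactly, agreeing with the ape oracle", {
  set.seed(31)
  for (case_i in 1:20) {
    ntaxa <- sample(4:8, 1)
    true <- ape::rtree(ntaxa)
    D <- ape::cophenetic.phylo(true)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    tr <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(true), tr), 0, ignore_attr = TRUE)
    got <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
    expect_lt(max(abs(got - D)), 1e-9)
    # ape's own NJ is the independent cross-check on topology
    expect_equal(ape::dist.topo(ape::nj(D), tr), 0, ignore_attr = TRUE)
  }
})

test_that("degenerate and invalid distance inputs are handled explicitly", {
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(z)
  expect_equal(sum(tr$edge.length), 0)
  expect_setequal(tr$tip.label, letters[1:4])

  ids <- paste0("s", 1:3)
  aln <- make_aln(setNames(c("AAAA", "GGGG", "AAAA"), ids))
  dm <- distance_matrix(aln)   # saturated pair -> undefined entries
  expect_error(nj_tree(dm), "undefined")
})

test_that("bootstrap gives full support to a clean split and is seed-stable", {
  ids <- paste0("s", 1:6)
  blockA <- strrep("A", 10)
  blockB <- paste0(strrep("G", 10))
  tail1 <- strrep("ACGT", 5)
  seqs <- setNames(c(rep(paste0(blockA, tail1), 3),
                     rep(paste0(blockB, tail1), 3)), ids)
  aln <- make_aln(seqs)
  bs1 <- bootstrap_nj(aln, n_replicates = 50, seed = 4)
  central <- grepl("s1,s2,s3|s4,s5,s6", names(bs1$support))
  expect_true(any(central))
  expect_equal(unname(bs1$support[central]), rep(100, sum(central)))
  bs2 <- bootstrap_nj(aln, n_replicates = 50, seed = 4)
  expect_identical(bs1$support, bs2$support)
  bs3 <- bootstrap_nj(aln, n_replicates = 50, seed = 5)
  expect_identical(names(bs3$support), names(bs1$support))

  inv <- make_aln(setNames(rep("ACGTACGT", 4), paste0("s", 1:4)))
  expect_warning(bsi <- bootstrap_nj(inv, n_replicates = 10, seed = 1),
                 "invariant")
  expect_true(all(is.na(bsi$support)) || length(bsi$support) == 0)
})

test_that("monophyly is judged by bipartitions with intruders reported", {
  sp <- make_specimens(c("x1", "x2", "y1", "y2"),
                       c("X_x", "X_x", "X_y", "X_y"), genus = "X")
  good <- ape::read.tree(text = "((x1:1,x2:1):1,(y1:1,y2:1):1);")
  mg <- monophyly(good, sp)
  expect_true(all(mg$monophyletic))
  expect_true(all(mg$intruders == ""))

  bad <- ape::read.tree(text = "((x1:1,y1:1):1,(x2:1,y2:1):1);")
  mb <- monophyly(bad, sp)
  expect_false(any(mb$monophyletic))

  # two intruding specimens of another species inside a clade
  sp6 <- make_specimens(c("a1", "a2", "a3", "p1", "p2", "p3"),
                        rep(c("X_arv", "X_pol"), each = 3), genus = "X")
  mixed <- ape::read.tree(
    text = "(((a1:1,(p1:1,p2:1):1):1,(a2:1,a3:1):1):1,p3:10);")
  mm <- monophyly(mixed, sp6)
  arv <- mm[mm$species == "X_arv", ]
  expect_false(arv$monophyletic)
  expect_setequal(attr(mm, "intruder_list")$X_arv, c("p1", "p2"))

  # single-specimen species is trivially monophyletic and flagged
  sp5 <- make_specimens(c("x1", "x2", "y1", "y2"),
                        c("X_x", "X_x", "X_y", "X_z"), genus = "X")
  mt <- monophyly(good, sp5)
  expect_true(all(mt$monophyletic[mt$species %in% c("X_y", "X_z")]))
  expect_true(all(mt$trivial[mt$species %in% c("X_y", "X_z")]))
})

test_that("bipartition supports do not depend on leaf input order", {
  set.seed(17)
  ids <- paste0("s", 1:6)
  base <- sample(c("A", "C", "G", "T"), 60, TRUE)
  m <- t(vapply(1:6, function(i) {
    x <- base; idx <- sample(60, 5); x[idx] <- sample(c("A", "C", "G", "T"),
                                                      5, TRUE); x
  }, character(60)))
  m[1:3, 1:6] <- "A"; m[4:6, 1:6] <- "T"
  rownames(m) <- ids
  b1 <- bootstrap_nj(make_aln(m), n_replicates = 30, seed = 8)
  b2 <- bootstrap_nj(make_aln(m[sample(6), ]), n_replicates = 30, seed = 8)
  shared <- intersect(names(b1$support), names(b2$support))
  expect_true(length(shared) >= 1)
})

test_that("fully private, clustered species come out monophyletic", {
  for (seed in c(2, 12)) {
    sim <- simulate_genus(preset_scenarios(seed = seed)$lonicera_like)
    bs <- bootstrap_nj(sim$alignments, n_replicates = 10, seed = seed)
    mono <- monophyly(bs$tree, sim$specimens)
    expect_true(all(mono$monophyletic))
  }
})
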