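two_locus_fixture <- function() {
  ids <- paste0("s", 1:3)
  sp <- make_specimens(ids, c("X_a", "X_a", "X_b"), genus = "X")
  alns <- list(
    locX = make_aln(setNames(c("AAAA", "AAAA", "AATA"), ids),
                    genus = "X", locus = "locX", specimens = sp),
    locY = make_aln(setNames(c("CCCC", "CGCC", "CGCC"), ids),
                    genus = "X", locus = "locY", specimens = sp))
  list(sp = sp, alns = alns)
}

test_that("haplotype collapse merges identical sequences per combination", {
  fx <- two_locus_fixture()
  hs <- collapse_haplotypes(fx$alns, "locX", fx$sp)
  expect_equal(length(hs$haplotypes), 2L)
  expect_setequal(vapply(hs$haplotypes, function(h) length(h$members), 0L),
                  c(2L, 1L))
  # combining loci refines: patterns (A,A,B) x (C,D,D) -> 3 haplotypes
  hs2 <- collapse_haplotypes(fx$alns, c("locX", "locY"), fx$sp)
  expect_equal(length(hs2$haplotypes), 3L)
  expect_error(collapse_haplotypes(fx$alns, character(0), fx$sp), "empty")
})

test_that("specimens missing a locus are excluded only from combinations using it", {
  ids <- paste0("s", 1:4)
  sp <- make_specimens(ids, rep("X_a", 4), genus = "X")
  alns <- list(
    matK = make_aln(setNames(rep("ACGT", 3), ids[1:3]),
                    genus = "X", locus = "matK", specimens = sp),
    trnH = make_aln(setNames(rep("GGCC", 4), ids),
                    genus = "X", locus = "trnH", specimens = sp))
  expect_equal(collapse_haplotypes(alns, "trnH", sp)$n_sequenced, 4L)
  expect_equal(collapse_haplotypes(alns, c("matK", "trnH"), sp)$n_sequenced, 3L)
})

test_that("assignment success counts individuals on species-private haplotypes", {
  # species X carries haplotypes {A, B}, species Y {B, C};
  # members A: 2, B: 3, C: 1 -> private A and C, 3 of 6 identified
  ids <- paste0("s", 1:6)
  sp <- make_specimens(ids, c("X_x", "X_x", "X_x", "X_y", "X_y", "X_y"),
                       genus = "X")
  seqs <- setNames(c("AA", "AA", "CC", "CC", "CC", "GG"), ids)
  alns <- list(l = make_aln(seqs, genus = "X", locus = "l", specimens = sp))
  row <- assignment_success(collapse_haplotypes(alns, "l", sp))
  expect_equal(row$n_haplotypes, 3L)
  expect_equal(row$n_private_haplotypes, 2L)
  expect_equal(row$n_individuals_identified, 3L)
  expect_equal(row$percent_identified, 50)

  # all haplotypes in one species: 100 %
  sp1 <- make_specimens(ids, rep("X_x", 6), genus = "X")
  expect_equal(assignment_success(
    collapse_haplotypes(alns, "l", sp1))$percent_identified, 100)

  # a single haplotype shared by every species: 0 %
  shared <- list(l = make_aln(setNames(rep("AA", 6), ids),
                              genus = "X", locus = "l", specimens = sp))
  expect_equal(assignment_success(
    collapse_haplotypes(shared, "l", sp))$percent_identified, 0)
})

test_that("haplotype membership partitions specimens and ignores input order", {
  set.seed(5)
  ids <- paste0("s", 1:12)
  sp <- make_specimens(ids, rep(c("X_a", "X_b", "X_c"), each = 4), genus = "X")
  seqs <- setNames(paste0(sample(c("AC", "AG", "TG"), 12, replace = TRUE),
                          sample(c("CC", "CT"), 12, replace = TRUE)), ids)
  alns <- list(l = make_aln(seqs, genus = "X", locus = "l", specimens = sp))
  hs <- collapse_haplotypes(alns, "l", sp)
  members <- unlist(lapply(hs$haplotypes, `[[`, "members"))
  expect_setequal(members, ids)
  expect_equal(length(members), hs$n_sequenced)

  perm <- sample(ids)
  alns_p <- list(l = make_aln(seqs[perm], genus = "X", locus = "l",
                              specimens = sp))
  hs_p <- collapse_haplotypes(alns_p, "l", sp)
  key <- function(h) sort(vapply(h$haplotypes,
                                 function(x) paste(sort(x$members), collapse = ","), ""))
  expect_equal(key(hs_p), key(hs))
})

test_that("N handling: strict keeps ambiguous sequences apart, compatible merges", {
  ids <- c("s1", "s2", "s3")
  sp <- make_specimens(ids, rep("X_a", 3), genus = "X")
  alns <- list(l = make_aln(setNames(c("ACGT", "ANGT", "ACGT"), ids),
                            genus = "X", locus = "l", specimens = sp))
  expect_equal(length(collapse_haplotypes(alns, "l", sp,
                                          ambiguity = "strict")$haplotypes), 2L)
  expect_equal(length(collapse_haplotypes(alns, "l", sp,
                                          ambiguity = "compatible")$haplotypes), 1L)
})

test_that("combination reports carry conventional option labels and rank sanely", {
  ids <- paste0("s", 1:4)
  sp <- make_specimens(ids, c("X_a", "X_a", "X_b", "X_b"), genus = "X")
  mk <- function(seqs, locus) make_aln(setNames(seqs, ids), genus = "X",
                                       locus = locus, specimens = sp)
  alns <- list(
    "matK" = mk(c("AA", "AA", "AT", "AT"), "matK"),
    "rpoC1" = mk(c("CC", "CC", "CC", "CC"), "rpoC1"),
    "rpoB" = mk(c("GG", "GG", "GG", "GG"), "rpoB"),
    "trnH-psbA" = mk(c("TT", "TA", "AA", "AA"), "trnH-psbA"))
  rep <- combination_report(alns, sp)
  expect_equal(nrow(rep), 15L)
  expect_equal(rep$option[rep$combination == "matK+rpoC1"], "Option1")
  expect_equal(rep$option[rep$combination == "matK+rpoC1+rpoB+trnH-psbA"],
               "Option11")
  sel <- best_barcode(rep)
  # matK alone fully discriminates; ties resolved toward fewer loci
  expect_equal(sel$best$percent_identified, 100)
  expect_equal(sel$best$n_loci, 1L)

  # a combination adding a dropout-ridden locus can rank below a single locus
  alns2 <- alns
  alns2$matK <- make_aln(setNames(c("AA", "AT"), ids[1:2]), genus = "X",
                         locus = "matK", specimens = sp)
  rep2 <- combination_report(alns2, sp)
  sel2 <- best_barcode(rep2)
  expect_equal(sel2$best$combination, "trnH-psbA")
  expect_equal(sel2$best$n_sequenced, 4L)
})

test_that("adding a locus refines haplotypes on the shared specimen set", {
  set.seed(21)
  for (case_i in 1:10) {
    ids <- paste0("s", 1:10)
    sp <- make_specimens(ids, rep(c("X_a", "X_b"), each = 5), genus = "X")
    r_seq <- function(L) vapply(seq_along(ids), function(i)
      paste(sample(c("A", "C"), L, TRUE), collapse = ""), "")
    alns <- list(
      l1 = make_aln(setNames(r_seq(4), ids), genus = "X", locus = "l1",
                    specimens = sp),
      l2 = make_aln(setNames(r_seq(4), ids), genus = "X", locus = "l2",
                    specimens = sp))
    one <- collapse_haplotypes(alns, "l1", sp)
    both <- collapse_haplotypes(alns, c("l1", "l2"), sp)
    ident <- function(hs) sort(unlist(lapply(
      Filter(function(h) h$private, hs$haplotypes), `[[`, "members")))
    expect_true(all(ident(one) %in% ident(both)))
  }
})
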