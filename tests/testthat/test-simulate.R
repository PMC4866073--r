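test_that("the same seed reproduces byte-identical on-disk datasets", {
  cfg <- preset_scenarios(seed = 13)$salix_like
  d1 <- tempfile(); d2 <- tempfile()
  write_scenario(simulate_genus(cfg), d1)
  write_scenario(simulate_genus(cfg), d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  d3 <- tempfile()
  cfg2 <- cfg; cfg2$seed <- 14L
  write_scenario(simulate_genus(cfg2), d3)
  expect_false(identical(
    readLines(file.path(d1, "Salix_trnH-psbA.fasta")),
    readLines(file.path(d3, "Salix_trnH-psbA.fasta"))))
})

test_that("designed step counts equal observed coded Hamming distances", {
  for (seed in 1:20) {
    sim <- simulate_genus(preset_scenarios(seed = seed)$gentiana_like)
    coded <- lapply(sim$alignments, code_alignment)
    cs <- coded_states(coded)
    th <- sim$truth$specimen_haplotypes
    # one representative specimen per ground-truth haplotype
    reps <- th[!duplicated(th$hap_id), ]
    for (a in seq_len(nrow(reps) - 1L)) for (b in (a + 1L):nrow(reps)) {
      va <- cs$states[reps$specimen_id[a], ]
      vb <- cs$states[reps$specimen_id[b], ]
      obs <- sum(va != vb, na.rm = TRUE)
      expect_equal(obs, sim$truth$steps[reps$hap_id[a], reps$hap_id[b]],
                   ignore_attr = TRUE)
    }
  }
})

test_that("designed assignment success equals the measured one without dropout", {
  for (seed in c(3, 8, 15)) {
    for (preset in c("lonicera_like", "salix_like", "acer_like")) {
      sim <- simulate_genus(preset_scenarios(seed = seed)[[preset]])
      row <- assignment_success(collapse_haplotypes(
        sim$alignments, names(sim$alignments), sim$specimens))
      expect_equal(row$percent_identified, sim$truth$percent_private_specimens)
    }
  }
})

test_that("a capture event yields a within-species pair at the designed distance", {
  sim <- simulate_genus(preset_scenarios(seed = 99)$gentiana_like)
  expect_equal(sim$truth$capture$within_recipient_steps, 63L)
  expect_equal(sim$truth$capture$to_donor_steps, 1L)
  # visible in the realized data: two alpina specimens 63 coded steps apart
  coded <- lapply(sim$alignments, code_alignment)
  cs <- coded_states(coded)
  th <- sim$truth$specimen_haplotypes
  cap <- th$specimen_id[th$hap_id == "capture1"][1]
  modal <- th$specimen_id[th$hap_id == "modal_Gentiana_alpina"][1]
  expect_equal(sum(cs$states[cap, ] != cs$states[modal, ], na.rm = TRUE), 63)

  cfg <- preset_scenarios(seed = 1)$gentiana_like
  cfg$capture_events$steps <- 5L   # below the interspecific modal distance
  expect_error(simulate_genus(cfg), "below")
})

test_that("per-locus dropout shrinks combinations that include the locus", {
  cfg <- preset_scenarios(seed = 6)$lonicera_like
  cfg$dropout <- c(matK = 0.4)
  sim <- simulate_genus(cfg)
  rep <- combination_report(sim$alignments, sim$specimens)
  n_trnH <- rep$n_sequenced[rep$combination == "trnH-psbA"]
  n_opt3 <- rep$n_sequenced[rep$combination == "matK+trnH-psbA"]
  expect_equal(n_trnH, 67L)
  expect_lt(n_opt3, n_trnH)
})

test_that("scenario validation rejects inconsistent configurations", {
  sp <- data.frame(name = c("G_a", "G_b"), n = c(5L, 5L))
  loci <- data.frame(name = "l1", length = 100, sub_rate = 1, indel_rate = 0)
  expect_error(scenario_config("G", sp, "(G_a:0.1,G_zz:0.1);", loci),
               "tree tips")
  expect_error(scenario_config("G", data.frame(name = "G_a", n = 0L),
                               "(G_a:0.1);", loci), "sample sizes")
  cfg <- scenario_config("G", sp, "(G_a:0.1,G_b:0.1);", loci,
                         variants = data.frame(species = "G_a", steps = 2L,
                                               n_specimens = 9L))
  expect_error(simulate_genus(cfg), "carriers claimed")
})

test_that("preset scenarios produce their advertised qualitative outcomes", {
  ps <- preset_scenarios(seed = 4)
  expect_setequal(names(ps), c("lonicera_like", "salix_like",
                               "gentiana_like", "acer_like"))
  acer <- simulate_genus(ps$acer_like)
  hs <- collapse_haplotypes(acer$alignments, names(acer$alignments),
                            acer$specimens)
  shared <- Filter(function(h) length(h$species) > 1L, hs$haplotypes)
  shared_pairs <- lapply(shared, `[[`, "species")
  expect_true(list(c("Acer_campestre", "Acer_platanoides")) %in% shared_pairs)
  expect_true(list(c("Acer_monspessulanum", "Acer_opalus")) %in% shared_pairs)
  # the outgroup species stays fully discriminated
  outg <- vapply(hs$haplotypes, function(h)
    "Acer_pseudoplatanus" %in% h$species && length(h$species) > 1L, TRUE)
  expect_false(any(outg))
})
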