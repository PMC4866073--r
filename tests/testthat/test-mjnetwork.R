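test_that("small canonical networks come out exactly right", {
  # single haplotype: one node, no edges
  net1 <- mj_network(matrix(c("A", "C"), 1, dimnames = list("H1", NULL)))
  expect_equal(nrow(net1$nodes), 1L)
  expect_equal(nrow(net1$edges), 0L)

  # AAA/AAG/AGA: star centred on AAA (its own quasi-median), two 1-step edges
  s <- rbind(H1 = c("A", "A", "A"), H2 = c("A", "A", "G"),
             H3 = c("A", "G", "A"))
  net <- mj_network(s)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(sort(net$edges$from), c("H1", "H1"))
  expect_equal(net$edges$steps, c(1, 1), ignore_attr = TRUE)

  # AA/GG/AG/GA: the 4-cycle reticulation is retained, no medians added
  s2 <- rbind(H1 = c("A", "A"), H2 = c("G", "G"),
              H3 = c("A", "G"), H4 = c("G", "A"))
  net2 <- mj_network(s2)
  expect_equal(nrow(net2$nodes), 4L)
  expect_equal(nrow(net2$edges), 4L)
  expect_true(all(net2$edges$steps == 1))

  expect_error(mj_network(rbind(H1 = c("A", "A"), H1b = c("A", "A"))),
               "duplicate")
})

test_that("edge steps equal the Hamming distance between endpoint vectors", {
  set.seed(23)
  for (case_i in 1:10) {
    k <- sample(2:4, 1); p <- sample(3:6, 1)
    s <- unique(matrix(sample(c("A", "G"), k * p, TRUE), k, p))
    rownames(s) <- paste0("H", seq_len(nrow(s)))
    net <- mj_network(s)
    for (r in seq_len(nrow(net$edges))) {
      a <- net$states[net$edges$from[r], ]
      b <- net$states[net$edges$to[r], ]
      expect_equal(net$edges$steps[r], sum(a != b, na.rm = TRUE))
    }
    # connectivity
    g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE,
                                       vertices = net$nodes$id)
    expect_true(igraph::is_connected(g) || nrow(net$nodes) == 1L)
  }
})

test_that("node set equals the brute-force quasi-median closure", {
  set.seed(29)
  key <- function(m) sort(unname(apply(m, 1L, function(r)
    paste(ifelse(is.na(r), "?", r), collapse = ""))))
  for (case_i in 1:30) {
    k <- sample(2:4, 1); p <- sample(2:6, 1)
    s <- unique(matrix(sample(c("A", "C", "G"), k * p, TRUE,
                              prob = c(.45, .45, .1)), k, p))
    rownames(s) <- paste0("H", seq_len(nrow(s)))
    net <- mj_network(s)
    expect_equal(key(net$states), mjn_closure_oracle(unname(s)))
  }
})

test_that("every minimum spanning tree of the final node set is contained", {
  set.seed(37)
  for (case_i in 1:50) {
    k <- sample(3:6, 1); p <- sample(4:8, 1)
    s <- unique(matrix(sample(c("A", "T"), k * p, TRUE), k, p))
    rownames(s) <- paste0("H", seq_len(nrow(s)))
    net <- mj_network(s)
    n <- nrow(net$states)
    if (n < 2L) next
    d <- hamming_oracle(net$states)
    g <- igraph::graph_from_adjacency_matrix(d, weighted = TRUE,
                                             mode = "undirected")
    mst <- igraph::as_edgelist(igraph::mst(g))
    netkeys <- paste(pmin(net$edges$from, net$edges$to),
                     pmax(net$edges$from, net$edges$to))
    ids <- net$nodes$id
    mstkeys <- paste(pmin(ids[as.integer(mst[, 1])], ids[as.integer(mst[, 2])]),
                     pmax(ids[as.integer(mst[, 1])], ids[as.integer(mst[, 2])]))
    expect_true(all(mstkeys %in% netkeys))
  }
})

test_that("a captured haplotype shows as a long within-species branch", {
  p <- 70
  anc <- rep("A", p)
  cl1 <- anc                                  # species 1 modal class
  cl2 <- anc; cl2[1:63] <- "G"                # second class, 63 steps away
  donor <- anc; donor[1:62] <- "G"            # other species, 1 step from cl2
  s <- rbind(sp1_main = cl1, sp1_cap = cl2, sp2_modal = donor)
  net <- mj_network(s)
  g <- igraph::graph_from_data_frame(
    data.frame(net$edges$from, net$edges$to, weight = net$edges$steps),
    directed = FALSE, vertices = net$nodes$id)
  dg <- igraph::distances(g)
  expect_equal(dg["sp1_main", "sp1_cap"], 63)
  expect_equal(dg["sp1_cap", "sp2_modal"], 1)
})

test_that("network summaries report private and shared specimen fractions", {
  ids <- paste0("s", 1:10)
  sp <- make_specimens(ids, rep(c("X_a", "X_b"), each = 5), genus = "X")
  seqs <- setNames(c(rep("AAAA", 3), rep("AATT", 2),
                     rep("AATT", 3), rep("GGTT", 2)), ids)
  alns <- list(l = make_aln(seqs, genus = "X", locus = "l", specimens = sp))
  hs <- collapse_haplotypes(alns, "l", sp)
  stv <- haplotype_states(hs, code_alignment(alns$l))
  net <- mj_network(stv$states, char_type = stv$char_type)
  sm <- network_summary(net, hs, sp)
  expect_equal(sum(sm$per_haplotype$n_members), 10L)
  expect_equal(sm$percent_private_specimens, 50)      # 3 + 2 of 10
  expect_equal(sm$percent_species_sharing, 100)
  # median nodes never carry specimens
  med <- net$nodes$id[!net$nodes$observed]
  expect_false(any(med %in% sm$per_haplotype$id))

  expect_error(mj_network(stv$states, char_type = c("sub")), "char_type")
})
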