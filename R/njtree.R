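#' Neighbour-joining tree from a K2P distance matrix
#'
#' Standard Saitou-Nei agglomeration on the Q criterion. Ties in the Q
#' minimisation are broken deterministically by the lowest (row, column)
#' index pair in the current node order. A negative estimated branch length
#' is clamped to zero and its deficit transferred to the sister branch, so
#' the path length through the joined pair is preserved.
#'
#' @param dm A `k2p_dist` or a symmetric numeric matrix with dimnames.
#' @return An unrooted `ape::phylo` tree whose tips are the matrix labels.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "k2p_dist")) {
    if (!all(dm$defined))
      stop("distance matrix contains undefined entries; exclude or impute ",
           "the affected specimens before tree building")
    D <- dm$d
  } else D <- as.matrix(dm)
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  if (anyNA(D)) stop("distance matrix contains NA entries")
  nodes <- rownames(D)           # newick fragment per current node

  clamp <- function(bi, bj) {
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    c(max(bi, 0), max(bj, 0))
  }
  fmt <- function(x) sprintf("%.12g", x)

  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # lowest (i, j), i < j, among minima
    qmin <- min(Q)
    hit <- which(Q == qmin, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- hit[1L, 1L]; j <- hit[1L, 2L]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    b <- clamp(bi, bj)
    newnode <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(b[1L]),
                       nodes[j], fmt(b[2L]))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nodes <- c(nodes[keep], newnode)
    rownames(D2) <- colnames(D2) <- NULL
    D <- D2
    n <- n - 1L
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  b <- pmax(c(b1, b2, b3), 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1], fmt(b[1]),
                 nodes[2], fmt(b[2]), nodes[3], fmt(b[3]))
  ape::read.tree(text = nwk)
}

# canonical string keys for the non-trivial bipartitions of an unrooted tree
bipartitions <- function(tree) {
  tips <- tree$tip.label
  ntip <- length(tips)
  internal <- tree$edge[, 2L][tree$edge[, 2L] > ntip]
  keys <- character(0)
  for (node in internal) {
    side <- tips[unlist(phangorn::Descendants(tree, node, "tips"))]
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    other <- setdiff(tips, side)
    a <- paste(sort(side), collapse = ",")
    b <- paste(sort(other), collapse = ",")
    keys <- c(keys, if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|"))
  }
  unique(keys)
}

#' Bootstrap support for a neighbour-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the K2P + NJ tree
#' for each replicate, and reports for every internal edge of the original
#' tree the percentage of replicates containing the same bipartition.
#' Replicates whose resampled distance matrix has undefined entries are
#' redrawn up to 10 times, then counted as supporting nothing.
#'
#' @param alignments `locus_alignment` or named list of them.
#' @param combination Loci to concatenate (multi-locus case).
#' @param n_replicates Number of bootstrap replicates (default 100).
#' @param seed Integer seed; same seed, same supports.
#' @return List with `tree` (the original NJ tree, internal node labels set
#'   to integer percent support; `NA` for the root node), `support` (named
#'   vector keyed by bipartition) and `n_failed_replicates`.
#' @export
bootstrap_nj <- function(alignments, combination = NULL, n_replicates = 100L,
                         seed = 1L) {
  m <- concat_alignment(alignments, combination)
  dm <- distance_matrix_from_chars(m)
  if (!all(dm$defined))
    stop("undefined distances in the full matrix; resolve before bootstrap")
  tree <- nj_tree(dm)
  obs <- bipartitions(tree)
  counts <- stats::setNames(numeric(length(obs)), obs)
  variable <- any(apply(m, 2L, function(col) {
    b <- col[col %in% c("A", "C", "G", "T")]
    length(unique(b)) > 1L
  }))
  n_failed <- 0L
  if (!variable) {
    warning("invariant alignment: bootstrap supports undefined")
    support <- stats::setNames(rep(NA_real_, length(obs)), obs)
  } else {
    set.seed(seed)
    for (rep_i in seq_len(n_replicates)) {
      ok <- FALSE
      for (try_i in 1:10) {
        cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
        dmb <- distance_matrix_from_chars(m[, cols, drop = FALSE])
        if (all(dmb$defined)) { ok <- TRUE; break }
      }
      if (!ok) { n_failed <- n_failed + 1L; next }
      bp <- bipartitions(nj_tree(dmb))
      hitb <- intersect(obs, bp)
      counts[hitb] <- counts[hitb] + 1
    }
    support <- 100 * counts / n_replicates
    if (n_failed > 0)
      message(n_failed, " bootstrap replicate(s) dropped ",
              "(undefined distances after 10 redraws)")
  }
  tree <- attach_support(tree, support)
  list(tree = tree, support = support, n_failed_replicates = n_failed)
}

# distance_matrix() on a plain character matrix
distance_matrix_from_chars <- function(m) {
  distance_matrix(structure(m, genus = "", locus = "",
                            class = c("locus_alignment", "matrix", "array")))
}

# write supports into node labels of the phylo object
attach_support <- function(tree, support) {
  ntip <- length(tree$tip.label)
  labs <- rep(NA_character_, tree$Nnode)
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    side <- tree$tip.label[unlist(phangorn::Descendants(tree, node, "tips"))]
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    other <- setdiff(tree$tip.label, side)
    a <- paste(sort(side), collapse = ",")
    b <- paste(sort(other), collapse = ",")
    key <- if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
    if (key %in% names(support) && !is.na(support[key]))
      labs[node - ntip] <- sprintf("%d", as.integer(round(support[key])))
  }
  tree$node.label <- labs
  tree
}

#' Species monophyly on an unrooted tree
#'
#' A species is monophyletic when some edge of the unrooted tree separates
#' exactly its specimens from all others. For non-monophyletic species the
#' intruders are the foreign specimens inside the smallest clade spanning
#' the species after midpoint rooting (rooting is used only for this
#' human-readable report; the test itself is bipartition-based).
#'
#' @param tree An `ape::phylo` whose tips are specimen ids.
#' @param specimens A `specimen_table`.
#' @return Object of class `monophyly_report`: data frame with species, n,
#'   monophyletic, trivial (single specimen), intruders (comma-separated);
#'   plus attribute `intruder_list` (named list of character vectors).
#' @export
monophyly <- function(tree, specimens) {
  sp <- species_of(specimens, tree$tip.label)
  if (anyNA(sp)) stop("tree tips missing from specimen table: ",
                      paste(tree$tip.label[is.na(sp)], collapse = ", "))
  species <- sort(unique(sp))
  if (length(species) < 2L) stop("need at least 2 species")
  keys <- bipartitions(tree)
  rooted <- phangorn::midpoint(tree)
  ntip <- length(tree$tip.label)
  rows <- list(); intruder_list <- list()
  for (s in species) {
    mine <- tree$tip.label[sp == s]
    trivial <- length(mine) == 1L
    if (trivial) {
      mono <- TRUE; intr <- character(0)
    } else {
      other <- setdiff(tree$tip.label, mine)
      a <- paste(sort(mine), collapse = ",")
      b <- paste(sort(other), collapse = ",")
      key <- if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
      mono <- length(mine) >= ntip - 1L || key %in% keys
      if (mono) {
        intr <- character(0)
      } else {
        mrca <- ape::getMRCA(rooted, mine)
        clade <- rooted$tip.label[unlist(phangorn::Descendants(rooted, mrca, "tips"))]
        intr <- sort(setdiff(clade, mine))
      }
    }
    intruder_list[[s]] <- intr
    rows[[length(rows) + 1L]] <- data.frame(
      species = s, n = length(mine), monophyletic = mono, trivial = trivial,
      intruders = paste(intr, collapse = ","), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "intruder_list") <- intruder_list
  class(out) <- c("monophyly_report", "data.frame")
  out
}
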