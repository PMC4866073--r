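#' Collapse sequences into haplotypes for a locus combination
#'
#' Unique-sequence counting is the one variation measure that sees
#' insertion/deletion and inversion events as well as substitutions: two
#' specimens share a haplotype when their full aligned sequences over all
#' loci of the combination are identical. Only specimens with data at every
#' locus of the combination enter, so `n_sequenced` varies between
#' combinations under sequencing dropout.
#'
#' @param alignments Named list of `locus_alignment` for one genus.
#' @param combination Character vector of locus names (non-empty subset of
#'   `names(alignments)`).
#' @param specimens A `specimen_table`.
#' @param ambiguity `"strict"` (default): `N` is a distinct token, so
#'   sequences differing only at an `N` position are not merged — the
#'   reproducible choice. `"compatible"`: specimens are merged when their
#'   sequences agree at every position where neither has `N`; the relation
#'   is closed transitively.
#' @return Object of class `haplotype_set`: list with `genus`, `combination`,
#'   `n_sequenced`, and `haplotypes`, a list of records with `id`, `members`
#'   (specimen ids), `species` (sorted unique species of the members),
#'   `private` (exactly one species).
#' @export
collapse_haplotypes <- function(alignments, combination, specimens,
                                ambiguity = c("strict", "compatible")) {
  ambiguity <- match.arg(ambiguity)
  if (!length(combination)) stop("empty locus combination")
  missing <- setdiff(combination, names(alignments))
  if (length(missing))
    stop("combination names absent from alignments: ",
         paste(missing, collapse = ", "))
  genus <- attr(alignments[[combination[1]]], "genus")
  ids <- Reduce(intersect, lapply(alignments[combination], rownames))
  seqs <- vapply(ids, function(id) {
    paste(vapply(combination, function(l) {
      paste(alignments[[l]][id, ], collapse = "")
    }, ""), collapse = "|")
  }, "")

  if (length(ids)) {
    if (ambiguity == "strict") {
      grp <- match(seqs, unique(seqs))
    } else {
      grp <- merge_compatible(seqs)
    }
  } else grp <- integer(0)

  haps <- lapply(sort(unique(grp)), function(g) {
    members <- ids[grp == g]
    sp <- sort(unique(species_of(specimens, members)))
    list(id = NA_character_, members = members, species = sp,
         private = length(sp) == 1L)
  })
  # stable ids: by decreasing frequency then first member
  ord <- order(-vapply(haps, function(h) length(h$members), 0L),
               vapply(haps, function(h) h$members[1], ""))
  haps <- haps[ord]
  for (k in seq_along(haps)) haps[[k]]$id <- sprintf("H%02d", k)
  structure(list(genus = genus, combination = combination,
                 n_sequenced = length(ids), haplotypes = haps),
            class = "haplotype_set")
}

# transitive closure of N-wildcard compatibility (union-find)
merge_compatible <- function(seqs) {
  n <- length(seqs)
  chars <- strsplit(seqs, "")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- chars[[i]]; b <- chars[[j]]
    ok <- all(a == b | a == "N" | b == "N")
    if (ok) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("Haplotype set %s [%s]: %d haplotypes from %d specimens\n",
              x$genus, paste(x$combination, collapse = "+"),
              length(x$haplotypes), x$n_sequenced))
  invisible(x)
}

#' Assignment success of one locus combination
#'
#' A haplotype is private when all its carriers belong to one species; the
#' specimens carrying a private haplotype are the individuals unambiguously
#' identified by this combination.
#'
#' @param hs A `haplotype_set`.
#' @return One-row data frame: combination, n_loci, n_sequenced,
#'   n_haplotypes, n_private_haplotypes, n_individuals_identified,
#'   percent_identified.
#' @export
assignment_success <- function(hs) {
  priv <- vapply(hs$haplotypes, `[[`, TRUE, "private")
  members <- vapply(hs$haplotypes, function(h) length(h$members), 0L)
  n_id <- sum(members[priv])
  data.frame(
    combination = paste(hs$combination, collapse = "+"),
    n_loci = length(hs$combination),
    n_sequenced = hs$n_sequenced,
    n_haplotypes = length(hs$haplotypes),
    n_private_haplotypes = sum(priv),
    n_individuals_identified = n_id,
    percent_identified = if (hs$n_sequenced > 0)
      100 * n_id / hs$n_sequenced else NA_real_,
    stringsAsFactors = FALSE)
}

CANONICAL_LOCI <- c("matK", "rpoC1", "rpoB", "trnH-psbA")

# the 11 conventional multi-locus option labels over the four canonical loci
canonical_option_label <- function(combination) {
  if (!all(combination %in% CANONICAL_LOCI) || length(combination) < 2L)
    return(NA_character_)
  combos <- c(utils::combn(CANONICAL_LOCI, 2L, simplify = FALSE),
              utils::combn(CANONICAL_LOCI, 3L, simplify = FALSE),
              list(CANONICAL_LOCI))
  key <- paste(sort(combination), collapse = "+")
  idx <- which(vapply(combos, function(cc) paste(sort(cc), collapse = "+"), "") == key)
  if (length(idx)) sprintf("Option%d", idx) else NA_character_
}

#' Assignment-success report over all locus combinations
#'
#' Evaluates every non-empty subset of the available loci (15 subsets when
#' all four canonical plastid loci are present; the 11 multi-locus subsets
#' then carry their conventional Option1-Option11 labels).
#'
#' @param alignments Named list of `locus_alignment` for one genus.
#' @param specimens A `specimen_table`.
#' @param loci Loci to combine (default all in `alignments`).
#' @param ... Passed to [collapse_haplotypes()].
#' @return Data frame of class `combination_report`, one row per
#'   combination, with an `option` label column.
#' @export
combination_report <- function(alignments, specimens,
                               loci = names(alignments), ...) {
  if (!length(loci)) stop("no loci to combine")
  ord <- if (all(loci %in% CANONICAL_LOCI))
    intersect(CANONICAL_LOCI, loci) else sort(loci)
  subsets <- unlist(lapply(seq_along(ord), function(k)
    utils::combn(ord, k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(subsets, function(cc) {
    hs <- collapse_haplotypes(alignments, cc, specimens, ...)
    row <- assignment_success(hs)
    row$option <- if (length(cc) == 1L) cc else canonical_option_label(cc)
    row
  })
  out <- do.call(rbind, rows)
  out <- out[c("option", setdiff(names(out), "option"))]
  class(out) <- c("combination_report", "data.frame")
  out
}

#' Rank locus combinations and select the best barcode
#'
#' Combinations are ranked by percent of individuals identified; ties are
#' broken in favour of fewer loci (parsimony of effort), then of larger
#' `n_sequenced` (less dropout).
#'
#' @param report A `combination_report`.
#' @return List with `ranking` (the report reordered, with a `rank` column)
#'   and `best` (the top row).
#' @export
best_barcode <- function(report) {
  if (!nrow(report)) stop("no combinations evaluated")
  ord <- order(-report$percent_identified, report$n_loci,
               -report$n_sequenced, report$combination)
  ranking <- report[ord, , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  list(ranking = ranking, best = ranking[1L, , drop = FALSE])
}
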