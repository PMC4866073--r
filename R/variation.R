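#' Classify one alignment column
#'
#' Gaps and `N` are treated as missing, not as a fifth character state:
#' indel information is scored separately by [code_alignment()].
#'
#' @param column Character vector over `A,C,G,T,N,-`.
#' @return One of `"conserved"`, `"variable_uninformative"`,
#'   `"parsimony_informative"`, `"excluded"`. A column is excluded when
#'   fewer than two comparable (non-missing) characters remain; parsimony
#'   informative when at least two bases each occur in at least two
#'   sequences.
#' @export
classify_column <- function(column) {
  if (!length(column)) stop("empty column")
  bad <- setdiff(unique(column), ALN_ALPHABET)
  if (length(bad))
    stop("character(s) outside alphabet: ", paste(bad, collapse = " "))
  bases <- column[column %in% c("A", "C", "G", "T")]
  if (length(bases) < 2L) return("excluded")
  tab <- table(bases)
  if (length(tab) <= 1L) return("conserved")
  if (sum(tab >= 2L) >= 2L) return("parsimony_informative")
  "variable_uninformative"
}

#' Per-alignment variation summary
#'
#' Computes the aligned length, sequencing success and the site-category
#' percentages used to compare locus variability across genera.
#'
#' @param aln A `locus_alignment` with at least two rows.
#' @param specimens A `specimen_table`; sequencing success is the percentage
#'   of the genus' specimens with a row in this alignment.
#' @param site_denominator `"all"` (default) counts percentages against every
#'   alignment column, as site percentages are conventionally reported
#'   against the aligned length; `"ungapped"` restricts the denominator to
#'   columns without any gap character.
#' @return A one-row data frame of class `variation_summary`: genus, locus,
#'   aligned_length, n_sequences, sequencing_success, conserved_sites,
#'   variable_sites, parsimony_informative_sites, excluded_sites
#'   (percentages, unrounded; round to one decimal for reporting).
#' @export
summarize_variation <- function(aln, specimens,
                                site_denominator = c("all", "ungapped")) {
  site_denominator <- match.arg(site_denominator)
  if (nrow(aln) < 2L)
    stop("variation undefined for fewer than 2 sequences")
  genus <- attr(aln, "genus")
  cls <- apply(unclass(aln), 2L, classify_column)
  keep <- rep(TRUE, ncol(aln))
  if (site_denominator == "ungapped")
    keep <- colSums(unclass(aln) == "-") == 0L
  denom <- sum(keep)
  if (denom == 0L) stop("no columns left under 'ungapped' denominator")
  counts <- table(factor(cls[keep], levels = c(
    "conserved", "variable_uninformative", "parsimony_informative", "excluded")))
  n_genus <- sum(specimens$genus == genus)
  if (n_genus == 0L) stop("no specimens of genus ", genus, " in table")
  out <- data.frame(
    genus = genus,
    locus = attr(aln, "locus"),
    aligned_length = ncol(aln),
    n_sequences = nrow(aln),
    sequencing_success = 100 * nrow(aln) / n_genus,
    conserved_sites = 100 * counts[["conserved"]] / denom,
    variable_sites = 100 * (counts[["variable_uninformative"]] +
                              counts[["parsimony_informative"]]) / denom,
    parsimony_informative_sites = 100 * counts[["parsimony_informative"]] / denom,
    excluded_sites = 100 * counts[["excluded"]] / denom,
    stringsAsFactors = FALSE)
  class(out) <- c("variation_summary", "data.frame")
  out
}

#' Variation table across genera and loci
#'
#' @param alignments Named list (genus -> named list of `locus_alignment`),
#'   as returned by [load_dataset()].
#' @param specimens A `specimen_table`.
#' @param ... Passed to [summarize_variation()].
#' @return Data frame with one row per genus x locus.
#' @export
variation_table <- function(alignments, specimens, ...) {
  rows <- list()
  for (genus in names(alignments))
    for (locus in names(alignments[[genus]]))
      rows[[length(rows) + 1L]] <-
        summarize_variation(alignments[[genus]][[locus]], specimens, ...)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
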