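ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-")
IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Construct a per-genus locus alignment
#'
#' @param seqs Named character vector of equal-length gapped sequences
#'   (names are specimen ids), or a character matrix with one row per
#'   specimen and one column per alignment position.
#' @param genus Genus name.
#' @param locus Locus label (e.g. `"matK"`, `"trnH-psbA"`).
#' @param specimens Optional `specimen_table`; when given, every row must be
#'   a specimen of `genus`.
#' @return A character matrix of class `locus_alignment` over the alphabet
#'   `A,C,G,T,N,-` with attributes `genus` and `locus`. Specimens with no
#'   sequence at this locus are simply absent: absence (sequencing dropout)
#'   and gap (indel) mean different things downstream.
#' @export
locus_alignment <- function(seqs, genus, locus, specimens = NULL) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop("sequences must be named by specimen_id")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1) {
      off <- names(seqs)[lens != lens[1]][1]
      stop(sprintf("ragged alignment in %s/%s: record '%s' has length %d, expected %d",
                   genus, locus, off, nchar(seqs[off]), lens[1]))
    }
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
  }
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty alignment for ", genus, "/", locus)
  m[m == "U"] <- "T"
  n_ambig <- sum(m %in% IUPAC_AMBIG)
  if (n_ambig > 0) {
    message(sprintf("%s/%s: %d IUPAC ambiguity character(s) mapped to N",
                    genus, locus, n_ambig))
    m[m %in% IUPAC_AMBIG] <- "N"
  }
  bad <- setdiff(unique(as.vector(m)), ALN_ALPHABET)
  if (length(bad))
    stop("alignment characters outside {A,C,G,T,N,-}: ", paste(bad, collapse = " "))
  allgap <- rowSums(m != "-") == 0
  if (any(allgap))
    stop("all-gap row(s): ", paste(rownames(m)[allgap], collapse = ", "))
  if (anyDuplicated(rownames(m)))
    stop("duplicate specimen_id in alignment: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (!is.null(specimens)) {
    unknown <- setdiff(rownames(m), specimens$specimen_id)
    if (length(unknown))
      stop("alignment row(s) not in specimen table: ", paste(unknown, collapse = ", "))
    gen <- specimens$genus[match(rownames(m), specimens$specimen_id)]
    wrong <- rownames(m)[gen != genus]
    if (length(wrong))
      stop("specimen(s) not of genus ", genus, ": ", paste(wrong, collapse = ", "))
  }
  structure(m, genus = genus, locus = locus,
            class = c("locus_alignment", class(m)))
}

#' Read an aligned FASTA file for one genus and locus
#'
#' @param path FASTA file; the first whitespace-delimited token of each
#'   header is the specimen id.
#' @param genus,locus Labels attached to the alignment.
#' @param specimens Optional `specimen_table` used to validate rows.
#' @return A [locus_alignment()]. Characters are upper-cased, `U` is mapped
#'   to `T`, and IUPAC ambiguity codes other than `N` are mapped to `N` with
#'   a message so the substitution can be audited.
#' @export
read_alignment <- function(path, genus, locus, specimens = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  seqs <- as.character(ss)
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  locus_alignment(seqs, genus = genus, locus = locus, specimens = specimens)
}

#' Write a locus alignment as aligned FASTA
#'
#' @param aln A `locus_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(aln_strings(aln))
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("Alignment %s/%s: %d sequences x %d bp\n",
              attr(x, "genus"), attr(x, "locus"), nrow(x), ncol(x)))
  invisible(x)
}

# alignment rows as strings, named by specimen id
aln_strings <- function(aln) {
  out <- apply(unclass(aln), 1L, paste, collapse = "")
  names(out) <- rownames(aln)
  out
}

#' Load and validate a full multi-genus dataset
#'
#' Scans a directory for files named `<genus>_<locus>.fasta`, reads each
#' against the specimen table, and returns the alignments grouped by genus
#' together with a manifest of row counts.
#'
#' @param dir Directory of aligned FASTA files named `<genus>_<locus>.fasta`
#'   (genus must not contain `_`; the locus label may).
#' @param specimens A `specimen_table` or path to one.
#' @return A list with elements `alignments` (named list: genus -> named list
#'   of `locus_alignment`), `specimens`, and `manifest` (data frame: genus,
#'   locus, n_sequences, length).
#' @export
load_dataset <- function(dir, specimens) {
  if (is.character(specimens)) specimens <- read_specimens(specimens)
  files <- list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  if (!length(files)) stop("no FASTA files found in ", dir)
  alignments <- list()
  rows <- list()
  for (f in files) {
    base <- sub("\\.(fa|fasta)$", "", basename(f))
    parts <- strsplit(base, "_")[[1]]
    if (length(parts) < 2)
      stop("cannot parse genus and locus from file name: ", basename(f))
    genus <- parts[1]
    locus <- paste(parts[-1], collapse = "_")
    aln <- read_alignment(f, genus = genus, locus = locus, specimens = specimens)
    alignments[[genus]][[locus]] <- aln
    rows[[length(rows) + 1L]] <- data.frame(
      genus = genus, locus = locus,
      n_sequences = nrow(aln), length = ncol(aln),
      stringsAsFactors = FALSE)
  }
  list(alignments = alignments, specimens = specimens,
       manifest = do.call(rbind, rows))
}
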