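#' Code an alignment into substitution, indel and structural characters
#'
#' Indels are scored by simple indel coding: every maximal run of gap
#' characters with a distinct (start, end) pair observed in the alignment
#' becomes one binary presence/absence character, so an indel of any length
#' counts as a single mutation step. A gap run strictly nested inside a
#' longer gap of another specimen is unobservable for that specimen and is
#' scored missing, not absent. User-annotated structural events (e.g.
#' inversions, which cannot be detected automatically) each become one
#' single-step character whose states are the distinct sequence variants of
#' the annotated region; the region's columns are masked from substitution
#' and indel coding so no event is counted twice.
#'
#' @param aln A `locus_alignment`.
#' @param annotations Optional data frame with columns `event_type`, `start`,
#'   `end` (1-based, inclusive alignment columns).
#' @return An object of class `coded_matrix`: a list with
#'   \describe{
#'     \item{specimen_ids}{row labels}
#'     \item{sub_pos}{alignment columns retained as variable substitution
#'       characters (1-based)}
#'     \item{sub_states}{character matrix (specimen x position), `NA` where a
#'       specimen has a gap or `N`}
#'     \item{indel_events}{data frame `start`, `end` of the variable coded
#'       gap characters}
#'     \item{indel_states}{integer matrix of 0/1/`NA`}
#'     \item{struct_events}{annotation data frame (possibly empty)}
#'     \item{struct_states}{character matrix of region variants}
#'   }
#' @export
code_alignment <- function(aln, annotations = NULL) {
  m <- unclass(aln)
  n <- nrow(m); L <- ncol(m)
  ids <- rownames(m)

  masked <- rep(FALSE, L)
  struct_events <- data.frame(event_type = character(0),
                              start = integer(0), end = integer(0))
  struct_states <- matrix(character(0), nrow = n, ncol = 0,
                          dimnames = list(ids, NULL))
  if (!is.null(annotations) && nrow(annotations)) {
    stopifnot(all(c("event_type", "start", "end") %in% names(annotations)))
    for (k in seq_len(nrow(annotations))) {
      a <- annotations$start[k]; b <- annotations$end[k]
      if (is.na(a) || is.na(b) || a < 1 || b > L || a > b)
        stop(sprintf("annotation %d (%s) outside alignment bounds 1..%d",
                     k, annotations$event_type[k], L))
      region <- apply(m[, a:b, drop = FALSE], 1L, paste, collapse = "")
      struct_states <- cbind(struct_states, region)
      masked[a:b] <- TRUE
    }
    struct_events <- annotations[c("event_type", "start", "end")]
    colnames(struct_states) <- paste0("struct", seq_len(ncol(struct_states)))
    # drop invariant structural characters
    keep <- apply(struct_states, 2L, function(s) length(unique(s)) > 1L)
    struct_states <- struct_states[, keep, drop = FALSE]
    struct_events <- struct_events[keep, , drop = FALSE]
  }

  # --- simple indel coding -------------------------------------------------
  runs_by_row <- lapply(seq_len(n), function(i) gap_runs(m[i, ], masked))
  all_runs <- unique(do.call(rbind, runs_by_row))
  indel_states <- matrix(integer(0), nrow = n, ncol = 0,
                         dimnames = list(ids, NULL))
  indel_events <- data.frame(start = integer(0), end = integer(0))
  if (!is.null(all_runs) && nrow(all_runs)) {
    all_runs <- all_runs[order(all_runs[, 1L], all_runs[, 2L]), , drop = FALSE]
    indel_states <- matrix(0L, nrow = n, ncol = nrow(all_runs),
                           dimnames = list(ids, NULL))
    for (i in seq_len(n)) {
      ri <- runs_by_row[[i]]
      for (k in seq_len(nrow(all_runs))) {
        a <- all_runs[k, 1L]; b <- all_runs[k, 2L]
        if (nrow(ri) && any(ri[, 1L] == a & ri[, 2L] == b)) {
          indel_states[i, k] <- 1L
        } else if (nrow(ri) &&
                   any(ri[, 1L] <= a & b <= ri[, 2L] &
                       !(ri[, 1L] == a & ri[, 2L] == b))) {
          # run strictly nested inside this specimen's longer gap: missing
          indel_states[i, k] <- NA_integer_
        }
      }
    }
    variable <- apply(indel_states, 2L, function(s) {
      s <- s[!is.na(s)]; length(unique(s)) > 1L
    })
    indel_states <- indel_states[, variable, drop = FALSE]
    indel_events <- data.frame(start = all_runs[variable, 1L],
                               end = all_runs[variable, 2L])
  }

  # --- variable substitution columns --------------------------------------
  sub <- m
  sub[sub == "-" | sub == "N"] <- NA_character_
  sub[, masked] <- NA_character_
  n_states <- apply(sub, 2L, function(col) length(unique(col[!is.na(col)])))
  sub_pos <- which(n_states > 1L)
  sub_states <- sub[, sub_pos, drop = FALSE]

  structure(list(specimen_ids = ids,
                 genus = attr(aln, "genus"), locus = attr(aln, "locus"),
                 aligned_length = L,
                 sub_pos = sub_pos, sub_states = sub_states,
                 indel_events = indel_events, indel_states = indel_states,
                 struct_events = struct_events, struct_states = struct_states),
            class = "coded_matrix")
}

# maximal runs of '-' in one sequence, ignoring masked columns;
# returns matrix with columns start, end (possibly 0 rows)
gap_runs <- function(row, masked = rep(FALSE, length(row))) {
  isgap <- row == "-" & !masked
  r <- rle(isgap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Coded state vectors for a set of specimens
#'
#' Concatenates substitution, indel and structural characters of one or more
#' coded matrices into one state vector per specimen; specimens without data
#' at a locus get all-missing states for that locus.
#'
#' @param coded A `coded_matrix` or list of them (same genus).
#' @param ids Specimen ids wanted (default: union of all).
#' @return List with `states` (character matrix, rows = ids; `NA` = missing)
#'   and `char_type` (per column: `"sub"`, `"indel"` or `"struct"`).
#' @export
coded_states <- function(coded, ids = NULL) {
  if (inherits(coded, "coded_matrix")) coded <- list(coded)
  if (is.null(ids)) ids <- unique(unlist(lapply(coded, `[[`, "specimen_ids")))
  blocks <- list(); types <- character(0)
  for (cm in coded) {
    for (part in c("sub_states", "indel_states", "struct_states")) {
      s <- cm[[part]]
      if (!ncol(s)) next
      block <- matrix(NA_character_, nrow = length(ids), ncol = ncol(s),
                      dimnames = list(ids, NULL))
      present <- intersect(ids, rownames(s))
      sp <- s[present, , drop = FALSE]
      block[present, ] <- matrix(as.character(sp), nrow = nrow(sp))
      blocks[[length(blocks) + 1L]] <- block
      types <- c(types, rep(switch(part, sub_states = "sub",
                                   indel_states = "indel", "struct"),
                            ncol(s)))
    }
  }
  states <- if (length(blocks)) do.call(cbind, blocks) else
    matrix(NA_character_, nrow = length(ids), ncol = 0,
           dimnames = list(ids, NULL))
  list(states = states, char_type = types)
}
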