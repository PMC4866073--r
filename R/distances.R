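TRANSITION_PAIRS <- c("AG", "GA", "CT", "TC")

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Sites where either sequence carries a gap or `N` are excluded pairwise.
#' With transition proportion P and transversion proportion Q over the
#' comparable sites, the distance is
#' \eqn{d = -\frac{1}{2}\ln(1 - 2P - Q) - \frac{1}{4}\ln(1 - 2Q)}.
#'
#' @param seq_a,seq_b Equal-length character vectors or single strings over
#'   `A,C,G,T,N,-`.
#' @return List: `distance` (substitutions/site, `NA` when undefined), `P`,
#'   `Q`, `n_sites`, and `defined` (`FALSE` when no comparable sites remain
#'   or a logarithm argument is non-positive, i.e. saturation).
#' @export
k2p <- function(seq_a, seq_b) {
  if (length(seq_a) == 1L && nchar(seq_a) > 1L) seq_a <- strsplit(seq_a, "")[[1]]
  if (length(seq_b) == 1L && nchar(seq_b) > 1L) seq_b <- strsplit(seq_b, "")[[1]]
  if (length(seq_a) != length(seq_b)) stop("sequences differ in length")
  ok <- seq_a %in% c("A", "C", "G", "T") & seq_b %in% c("A", "C", "G", "T")
  a <- seq_a[ok]; b <- seq_b[ok]
  n <- length(a)
  if (n == 0L)
    return(list(distance = NA_real_, P = NA_real_, Q = NA_real_,
                n_sites = 0L, defined = FALSE))
  diff <- a != b
  ts <- sum(diff & paste0(a, b) %in% TRANSITION_PAIRS)
  tv <- sum(diff) - ts
  P <- ts / n; Q <- tv / n
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    return(list(distance = NA_real_, P = P, Q = Q, n_sites = n, defined = FALSE))
  list(distance = -0.5 * log(w1) - 0.25 * log(w2), P = P, Q = Q,
       n_sites = n, defined = TRUE)
}

#' Pairwise K2P distance matrix
#'
#' For a multi-locus combination, only specimens sequenced at every locus
#' are included, and their sequences are concatenated before the distance is
#' computed. Undefined pairs (saturation, or zero comparable sites) are
#' flagged, never silently zeroed.
#'
#' @param alignments A single `locus_alignment`, or a named list of them
#'   with `combination` giving the loci to concatenate.
#' @param combination Locus names (default: all in the list).
#' @return Object of class `k2p_dist`: list with `labels`, `d` (symmetric
#'   matrix, `NA` where undefined), `n_sites` (comparable sites per pair)
#'   and `defined` (logical matrix).
#' @export
distance_matrix <- function(alignments, combination = NULL) {
  m <- concat_alignment(alignments, combination)
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  labels <- rownames(m)
  n <- nrow(m)
  # indicator matrices give all-pairs counts via four crossproducts
  ind <- lapply(c("A", "C", "G", "T"), function(ch) (m == ch) * 1)
  names(ind) <- c("A", "C", "G", "T")
  valid <- ind$A + ind$C + ind$G + ind$T
  sites <- tcrossprod(valid)
  matches <- Reduce(`+`, lapply(ind, tcrossprod))
  transitions <- tcrossprod(ind$A, ind$G) + tcrossprod(ind$G, ind$A) +
    tcrossprod(ind$C, ind$T) + tcrossprod(ind$T, ind$C)
  transversions <- sites - matches - transitions
  P <- ifelse(sites > 0, transitions / sites, NA)
  Q <- ifelse(sites > 0, transversions / sites, NA)
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  defined <- sites > 0 & w1 > 0 & w2 > 0
  defined[is.na(defined)] <- FALSE
  d <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  d[defined] <- -0.5 * log(w1[defined]) - 0.25 * log(w2[defined])
  diag(d) <- 0; diag(defined) <- TRUE
  structure(list(labels = labels, d = d,
                 n_sites = matrix(as.integer(round(sites)), n, n,
                                  dimnames = list(labels, labels)),
                 defined = defined),
            class = "k2p_dist")
}

# concatenate alignments over specimens present at all loci of a combination
concat_alignment <- function(alignments, combination = NULL) {
  if (inherits(alignments, "locus_alignment")) return(unclass(alignments))
  if (is.null(combination)) combination <- names(alignments)
  missing <- setdiff(combination, names(alignments))
  if (length(missing))
    stop("loci absent from alignments: ", paste(missing, collapse = ", "))
  ids <- Reduce(intersect, lapply(alignments[combination], rownames))
  if (!length(ids)) stop("no specimen sequenced at every locus of the combination")
  do.call(cbind, lapply(alignments[combination],
                        function(a) unclass(a)[ids, , drop = FALSE]))
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat(sprintf("K2P distances: %d taxa, %d undefined pair(s)\n",
              length(x$labels), sum(!x$defined[upper.tri(x$defined)])))
  invisible(x)
}

#' Barcoding-gap diagnostics
#'
#' Splits all pairwise distances into intra- and interspecific sets, and for
#' every species compares its maximum intraspecific divergence with its
#' nearest-neighbour distance (the minimum over other species of the mean
#' interspecific distance). A barcoding gap is present for a species when
#' the nearest neighbour is farther than its most divergent conspecific.
#'
#' @param dm A `k2p_dist`.
#' @param specimens A `specimen_table`.
#' @param bin_width Histogram bin width in substitutions/site for the
#'   pooled distance distributions (default 0.001).
#' @return Object of class `gap_summary`: list with `per_species` (data
#'   frame: species, n, max_intraspecific, nearest_neighbour, nearest_species,
#'   gap_present), `intra`, `inter` (pooled distance vectors), `breaks`,
#'   `intra_counts`, `inter_counts`, `n_undefined_dropped`.
#' @export
barcoding_gap <- function(dm, specimens, bin_width = 0.001) {
  sp <- species_of(specimens, dm$labels)
  if (anyNA(sp)) stop("specimens missing from table: ",
                      paste(dm$labels[is.na(sp)], collapse = ", "))
  species <- sort(unique(sp))
  if (length(species) < 2L) stop("need at least 2 species for gap analysis")
  ut <- upper.tri(dm$d)
  same <- outer(sp, sp, `==`)
  n_undef <- sum(ut & !dm$defined)
  if (n_undef > 0)
    message(n_undef, " undefined distance pair(s) dropped from gap analysis")
  intra <- dm$d[ut & same & dm$defined]
  inter <- dm$d[ut & !same & dm$defined]
  per <- lapply(species, function(s) {
    mine <- sp == s
    dd <- dm$d[mine, mine, drop = FALSE]
    max_intra <- if (sum(mine) >= 2L) {
      v <- dd[upper.tri(dd)]; v <- v[!is.na(v)]
      if (length(v)) max(v) else NA_real_
    } else NA_real_
    others <- setdiff(species, s)
    means <- vapply(others, function(o) {
      v <- dm$d[mine, sp == o, drop = FALSE]
      mean(v[!is.na(v)])
    }, 0)
    nn <- min(means)
    data.frame(species = s, n = sum(mine),
               max_intraspecific = max_intra,
               nearest_neighbour = nn,
               nearest_species = others[which.min(means)],
               gap_present = if (is.na(max_intra)) NA else nn > max_intra,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  hi <- max(c(intra, inter, bin_width))
  breaks <- seq(0, hi + bin_width, by = bin_width)
  structure(list(per_species = per, intra = intra, inter = inter,
                 breaks = breaks,
                 intra_counts = if (length(intra))
                   graphics::hist(intra, breaks = breaks, plot = FALSE)$counts else
                     integer(length(breaks) - 1L),
                 inter_counts = if (length(inter))
                   graphics::hist(inter, breaks = breaks, plot = FALSE)$counts else
                     integer(length(breaks) - 1L),
                 n_undefined_dropped = n_undef),
            class = "gap_summary")
}

#' @export
print.gap_summary <- function(x, ...) {
  gp <- x$per_species$gap_present
  cat(sprintf("Barcoding gap: %d/%d species with a gap (%d undetermined)\n",
              sum(gp, na.rm = TRUE), length(gp), sum(is.na(gp))))
  invisible(x)
}
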