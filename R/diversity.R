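#' Rarefaction sequence richness
#'
#' Expected number of distinct sequences recovered in a random subsample of
#' `g` individuals, computed from the observed haplotype frequencies:
#' \eqn{R_s = \sum_k \left[1 - \binom{N - N_k}{g} / \binom{N}{g}\right]}
#' with \eqn{\binom{a}{b} = 0} when \eqn{a < b}. This is the frequency-aware
#' interpolation used to compare species sampled at different depths; the
#' default subsample size is three individuals.
#'
#' @param frequencies Positive integer haplotype counts \eqn{N_k}.
#' @param g Subsample size, `1 <= g <= sum(frequencies)`.
#' @return `Rs`, a number in `[1, min(g, length(frequencies))]`.
#' @export
rarefied_richness <- function(frequencies, g = 3L) {
  if (!length(frequencies)) stop("empty frequency vector")
  if (any(frequencies < 1) || any(frequencies != round(frequencies)))
    stop("frequencies must be positive integers")
  N <- sum(frequencies)
  if (g < 1 || g > N) stop("subsample size g must be in 1..", N)
  # lchoose(a, b) is -Inf for a < b, so exp() gives the required 0
  sum(1 - exp(lchoose(N - frequencies, g) - lchoose(N, g)))
}

#' Rarefaction richness per species from a haplotype set
#'
#' @param hs A `haplotype_set`.
#' @param specimens A `specimen_table`.
#' @param g Subsample size (default 3).
#' @return Data frame: species, n, n_haplotypes, Rs (`NA` when fewer than
#'   `g` specimens were sequenced).
#' @export
rarefaction_table <- function(hs, specimens, g = 3L) {
  species <- sort(unique(unlist(lapply(hs$haplotypes, `[[`, "species"))))
  rows <- lapply(species, function(s) {
    freqs <- vapply(hs$haplotypes, function(h)
      sum(species_of(specimens, h$members) == s), 0L)
    freqs <- freqs[freqs > 0L]
    n <- sum(freqs)
    data.frame(species = s, n = n, n_haplotypes = length(freqs),
               Rs = if (n >= g) rarefied_richness(freqs, g) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson correlation with Fisher r-to-z inference
#'
#' Sample Pearson coefficient with the 95 percent confidence interval
#' \eqn{\tanh(\mathrm{atanh}(r) \pm 1.96/\sqrt{n-3})} and the normal-theory
#' probability of \eqn{z\sqrt{n-3}}. Both the two-tailed (default report)
#' and one-tailed probabilities are returned, since conventions differ
#' between tools.
#'
#' @param x,y Numeric vectors of equal length, `n >= 4`.
#' @return List of class `correlation_result`: `r`, `n`, `ci_low`, `ci_high`,
#'   `p_two_tailed`, `p_one_tailed`, `defined` (`FALSE` when either vector
#'   has zero variance).
#' @export
pearson_fisher <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations for r-to-z inference")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(list(r = NA_real_, n = n, ci_low = NA_real_,
                          ci_high = NA_real_, p_two_tailed = NA_real_,
                          p_one_tailed = NA_real_, defined = FALSE),
                     class = "correlation_result"))
  r <- stats::cor(x, y)
  se <- 1 / sqrt(n - 3)
  if (abs(r) >= 1) {
    # perfect correlation: atanh diverges; degenerate interval, floor p
    return(structure(list(r = r, n = n, ci_low = r, ci_high = r,
                          p_two_tailed = 0, p_one_tailed = 0, defined = TRUE),
                     class = "correlation_result"))
  }
  z <- atanh(r)
  structure(list(r = r, n = n,
                 ci_low = tanh(z - 1.96 * se), ci_high = tanh(z + 1.96 * se),
                 p_two_tailed = 2 * stats::pnorm(-abs(z) / se),
                 p_one_tailed = stats::pnorm(-abs(z) / se),
                 defined = TRUE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (!x$defined) cat("Correlation undefined (zero variance)\n")
  else cat(sprintf("r = %.3f (n = %d, 95%% CI %.3f..%.3f, two-tailed P = %.3g)\n",
                   x$r, x$n, x$ci_low, x$ci_high, x$p_two_tailed))
  invisible(x)
}

#' Correlation between sampling size and unique-sequence count
#'
#' @param tab Data frame with columns `n` (specimens sampled per species)
#'   and `n_haplotypes` (unique sequences), e.g. from [rarefaction_table()].
#' @return A `correlation_result`, or a flagged undefined result when fewer
#'   than 4 species are available.
#' @export
sampling_correlation <- function(tab) {
  stopifnot(all(c("n", "n_haplotypes") %in% names(tab)))
  if (nrow(tab) < 4L)
    return(structure(list(r = NA_real_, n = nrow(tab), ci_low = NA_real_,
                          ci_high = NA_real_, p_two_tailed = NA_real_,
                          p_one_tailed = NA_real_, defined = FALSE),
                     class = "correlation_result"))
  pearson_fisher(tab$n, tab$n_haplotypes)
}
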