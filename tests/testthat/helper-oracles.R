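# Independent brute-force oracles and fixture builders used across tests.

make_specimens <- function(ids, species, genus = "Genus") {
  validate_specimens(data.frame(specimen_id = ids, genus = genus,
                                species = species, stringsAsFactors = FALSE))
}

make_aln <- function(seqs, genus = "Genus", locus = "locusA", specimens = NULL) {
  locus_alignment(seqs, genus = genus, locus = locus, specimens = specimens)
}

# ---- simple indel coding oracle (string-based, direct from the definition)
gap_runs_str <- function(s) {
  v <- strsplit(s, "")[[1]]
  r <- rle(v == "-")
  end <- cumsum(r$lengths); start <- end - r$lengths + 1L
  cbind(start = start, end = end)[r$values, , drop = FALSE]
}

sic_oracle <- function(strings) {
  runs <- lapply(strings, gap_runs_str)
  events <- unique(do.call(rbind, runs))
  n <- length(strings)
  if (is.null(events) || nrow(events) == 0L)
    return(list(events = cbind(start = integer(0), end = integer(0)),
                states = matrix(integer(0), n, 0)))
  events <- events[order(events[, 1L], events[, 2L]), , drop = FALSE]
  states <- matrix(0L, n, nrow(events))
  for (i in seq_len(n)) {
    ri <- runs[[i]]
    for (k in seq_len(nrow(events))) {
      a <- events[k, 1L]; b <- events[k, 2L]
      if (nrow(ri) && any(ri[, 1L] == a & ri[, 2L] == b)) states[i, k] <- 1L
      else if (nrow(ri) && any(ri[, 1L] <= a & b <= ri[, 2L]))
        states[i, k] <- NA_integer_
    }
  }
  keep <- apply(states, 2L, function(s) {
    s <- s[!is.na(s)]; length(unique(s)) > 1L
  })
  list(events = events[keep, , drop = FALSE],
       states = states[, keep, drop = FALSE])
}

# ---- rarefaction oracle: exhaustive mean over all subsets of size g
rarefy_oracle <- function(freqs, g) {
  pool <- rep(seq_along(freqs), freqs)
  subsets <- utils::combn(length(pool), g)
  mean(apply(subsets, 2L, function(idx) length(unique(pool[idx]))))
}

# ---- Hamming distance oracle (naive)
hamming_oracle <- function(states) {
  n <- nrow(states)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(states[i, ]) & !is.na(states[j, ])
    d[i, j] <- sum(states[i, ok] != states[j, ok])
  }
  d
}

# ---- minimum spanning network oracle, straight from the definition:
# edge (i, j) of weight w belongs to the MSN iff i and j are in different
# connected components of the graph made of all strictly lighter edges
msn_oracle <- function(d) {
  n <- nrow(d)
  edges <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    w <- d[i, j]
    adj <- d < w
    diag(adj) <- FALSE
    reach <- reachable(adj, i)
    if (!reach[j]) edges <- rbind(edges, c(i, j, w))
  }
  edges
}

reachable <- function(adj, from) {
  n <- nrow(adj)
  seen <- rep(FALSE, n); seen[from] <- TRUE
  frontier <- from
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen
}

# ---- quasi-median closure oracle: iterate over all MSN-connected triples,
# with Floyd-Warshall geodesics for the final pruning step
quasi_median_oracle <- function(a, b, c) {
  opts <- lapply(seq_along(a), function(k) {
    v <- c(a[k], b[k], c[k]); v <- v[!is.na(v)]
    if (!length(v)) return(NA_character_)
    tab <- table(v)
    if (max(tab) >= 2L) names(tab)[which.max(tab)] else sort(unique(v))
  })
  as.matrix(expand.grid(opts, stringsAsFactors = FALSE))
}

mjn_closure_oracle <- function(states) {
  key <- function(m) apply(m, 1L, function(r)
    paste(ifelse(is.na(r), "?", r), collapse = ""))
  all_s <- states
  observed <- rep(TRUE, nrow(states))
  repeat {
    d <- hamming_oracle(all_s)
    e <- msn_oracle(d)
    adj <- matrix(FALSE, nrow(d), nrow(d))
    if (!is.null(e)) { adj[e[, 1:2, drop = FALSE]] <- TRUE; adj <- adj | t(adj) }
    new <- NULL
    nn <- nrow(all_s)
    if (nn >= 3L) for (i in 1:(nn - 2L)) for (j in (i + 1L):(nn - 1L))
      for (k in (j + 1L):nn) {
        if (adj[i, j] + adj[i, k] + adj[j, k] < 2L) next
        qm <- quasi_median_oracle(all_s[i, ], all_s[j, ], all_s[k, ])
        fresh <- !(key(qm) %in% c(key(all_s), if (!is.null(new)) key(new)))
        if (any(fresh)) new <- rbind(new, qm[fresh, , drop = FALSE])
      }
    if (is.null(new)) break
    all_s <- rbind(all_s, new)
    observed <- c(observed, rep(FALSE, nrow(new)))
  }
  # prune medians on no observed-observed geodesic (to a fixpoint)
  repeat {
    d <- hamming_oracle(all_s)
    e <- msn_oracle(d)
    n <- nrow(all_s)
    g <- matrix(Inf, n, n); diag(g) <- 0
    if (!is.null(e)) for (r in seq_len(nrow(e)))
      g[e[r, 1L], e[r, 2L]] <- g[e[r, 2L], e[r, 1L]] <- e[r, 3L]
    for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
      if (g[i, k] + g[k, j] < g[i, j]) g[i, j] <- g[i, k] + g[k, j]
    obs <- which(observed)
    keep <- observed
    for (m in which(!observed)) {
      hit <- FALSE
      for (ai in seq_along(obs)) for (bi in seq_along(obs)) {
        if (bi <= ai) next
        if (g[obs[ai], m] + g[m, obs[bi]] == g[obs[ai], obs[bi]]) hit <- TRUE
      }
      keep[m] <- hit
    }
    if (all(keep)) break
    all_s <- all_s[keep, , drop = FALSE]
    observed <- observed[keep]
  }
  sort(key(all_s))
}

# write a named character vector of sequences as a temporary FASTA
write_tmp_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  path
}
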