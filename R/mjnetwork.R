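mjn_key <- function(states) {
  apply(states, 1L, function(r) paste(ifelse(is.na(r), "?", r), collapse = "\x01"))
}

# equal-weight Hamming distance over positions non-missing in both vectors
hamming_all <- function(states) {
  n <- nrow(states)
  d <- matrix(0L, n, n)
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- states[i, ]; b <- states[j, ]
    ok <- !is.na(a) & !is.na(b)
    d[i, j] <- d[j, i] <- sum(a[ok] != b[ok])
  }
  d
}

# epsilon-relaxed minimum spanning network: an edge of weight w is kept iff
# its endpoints are not already connected by edges of weight < w - epsilon.
# At epsilon = 0 this is the union of all minimum spanning trees.
msn_edges <- function(d, epsilon = 0L) {
  n <- nrow(d)
  if (n < 2L) return(cbind(from = integer(0), to = integer(0), w = integer(0)))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ws <- d[pairs]
  ord <- order(ws, pairs[, 1L], pairs[, 2L])
  pairs <- pairs[ord, , drop = FALSE]
  ws <- ws[ord]
  components_upto <- function(maxw) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in which(ws <= maxw)) {
      ri <- find(pairs[k, 1L]); rj <- find(pairs[k, 2L])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
    vapply(seq_len(n), find, 0L)
  }
  kept <- logical(length(ws))
  for (w in unique(ws)) {
    comp <- components_upto(w - 1L - epsilon)
    sel <- which(ws == w)
    kept[sel[comp[pairs[sel, 1L]] != comp[pairs[sel, 2L]]]] <- TRUE
    if (length(unique(components_upto(w))) == 1L && epsilon == 0L) break
  }
  cbind(from = pairs[kept, 1L], to = pairs[kept, 2L], w = ws[kept])
}

# quasi-medians of a state triple: per character, the majority state; when no
# majority (all three distinct among non-missing), every observed state is a
# resolution and all combinations are enumerated.
quasi_medians <- function(a, b, c, max_nodes = 10000L) {
  p <- length(a)
  options <- vector("list", p)
  for (k in seq_len(p)) {
    v <- c(a[k], b[k], c[k])
    v <- v[!is.na(v)]
    if (!length(v)) { options[[k]] <- NA_character_; next }
    tab <- table(v)
    if (max(tab) >= 2L) options[[k]] <- names(tab)[which.max(tab)]
    else options[[k]] <- sort(unique(v))
  }
  n_comb <- prod(lengths(options))
  if (n_comb > max_nodes)
    stop("median enumeration exceeds ", max_nodes,
         " candidates; consider star contraction or fewer characters")
  g <- expand.grid(options, stringsAsFactors = FALSE)
  as.matrix(g)
}

#' Median-joining network of haplotypes
#'
#' Bandelt-Forster-Rohl construction over the coded characters, with
#' substitutions, indels and structural events all weighted as single steps:
#' iteratively build the epsilon-relaxed minimum spanning network, add the
#' quasi-medians of connected node triples, and finally discard median
#' vectors that lie on no shortest path between observed haplotypes.
#'
#' @param states Character matrix of coded state vectors, one row per
#'   observed haplotype (rownames = haplotype ids; `NA` = missing), e.g.
#'   from [haplotype_states()].
#' @param epsilon Non-negative integer relaxation (default 0, keeping the
#'   union of minimum spanning trees plus medians).
#' @param char_type Optional per-column labels (`"sub"`, `"indel"`,
#'   `"struct"`) used to annotate edge steps.
#' @param max_nodes Abort if median generation exceeds this many nodes.
#' @return Object of class `mj_network`: list with `nodes` (data frame: id,
#'   observed), `states` (matrix incl. median vectors), `edges` (data frame:
#'   from, to, steps, sub_steps, indel_steps, struct_steps) and `char_type`.
#' @export
mj_network <- function(states, epsilon = 0L, char_type = NULL,
                       max_nodes = 10000L) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1L)
  n_obs <- nrow(states)
  if (n_obs < 1L) stop("need at least one haplotype")
  if (is.null(rownames(states))) rownames(states) <- paste0("H", seq_len(n_obs))
  if (is.null(char_type)) char_type <- rep("sub", ncol(states))
  if (length(char_type) != ncol(states))
    stop("char_type length must match number of characters")

  all_states <- states
  observed <- rep(TRUE, n_obs)
  seen <- mjn_key(all_states)
  if (anyDuplicated(seen)) stop("duplicate haplotype state vectors")
  med_i <- 0L

  if (n_obs > 1L && ncol(states) > 0L) repeat {
    d <- hamming_all(all_states)
    e <- msn_edges(d, epsilon)
    adj <- matrix(FALSE, nrow(d), nrow(d))
    adj[e[, c("from", "to"), drop = FALSE]] <- TRUE
    adj <- adj | t(adj)
    new_states <- list()
    nn <- nrow(all_states)
    for (i in seq_len(nn - 1L)) for (j in (i + 1L):nn) {
      if (j < nn) for (k in (j + 1L):nn) {
        if (adj[i, j] + adj[i, k] + adj[j, k] < 2L) next
        qm <- quasi_medians(all_states[i, ], all_states[j, ],
                            all_states[k, ], max_nodes)
        for (r in seq_len(nrow(qm))) {
          key <- paste(ifelse(is.na(qm[r, ]), "?", qm[r, ]), collapse = "\x01")
          if (!(key %in% seen) &&
              !(key %in% vapply(new_states, attr, "", "key"))) {
            v <- qm[r, ]
            attr(v, "key") <- key
            new_states[[length(new_states) + 1L]] <- v
          }
        }
      }
    }
    if (!length(new_states)) break
    add <- do.call(rbind, lapply(new_states, as.vector))
    med_ids <- sprintf("mv%d", med_i + seq_len(nrow(add)))
    med_i <- med_i + nrow(add)
    rownames(add) <- med_ids
    all_states <- rbind(all_states, add)
    observed <- c(observed, rep(FALSE, nrow(add)))
    seen <- c(seen, vapply(new_states, attr, "", "key"))
    if (nrow(all_states) > max_nodes)
      stop("median generation exceeded ", max_nodes, " nodes")
  }

  # prune medians on no shortest observed-observed path, iterating to a fixpoint
  repeat {
    d <- hamming_all(all_states)
    e <- msn_edges(d, epsilon)
    if (all(observed)) break
    g <- igraph::graph_from_data_frame(
      data.frame(from = rownames(all_states)[e[, "from"]],
                 to = rownames(all_states)[e[, "to"]],
                 weight = pmax(e[, "w"], 1e-9)),
      directed = FALSE, vertices = rownames(all_states))
    gd <- igraph::distances(g)
    obs_ids <- rownames(all_states)[observed]
    keep <- observed
    for (m in which(!observed)) {
      mid <- rownames(all_states)[m]
      on_path <- FALSE
      for (ai in seq_along(obs_ids)) {
        if (on_path) break
        for (bi in seq_along(obs_ids)) {
          if (bi <= ai) next
          a <- obs_ids[ai]; b <- obs_ids[bi]
          if (abs(gd[a, mid] + gd[mid, b] - gd[a, b]) < 1e-6) {
            on_path <- TRUE; break
          }
        }
      }
      keep[m] <- on_path
    }
    if (all(keep)) break
    all_states <- all_states[keep, , drop = FALSE]
    observed <- observed[keep]
  }

  d <- hamming_all(all_states)
  e <- msn_edges(d, epsilon)
  step_breakdown <- function(i, j) {
    a <- all_states[i, ]; b <- all_states[j, ]
    ok <- !is.na(a) & !is.na(b) & a != b
    c(sub = sum(char_type[ok] == "sub"),
      indel = sum(char_type[ok] == "indel"),
      struct = sum(char_type[ok] == "struct"))
  }
  edges <- if (!is.null(e) && nrow(e)) {
    bk <- t(vapply(seq_len(nrow(e)),
                   function(r) step_breakdown(e[r, "from"], e[r, "to"]),
                   c(sub = 0, indel = 0, struct = 0)))
    data.frame(from = rownames(all_states)[e[, "from"]],
               to = rownames(all_states)[e[, "to"]],
               steps = e[, "w"], sub_steps = bk[, "sub"],
               indel_steps = bk[, "indel"], struct_steps = bk[, "struct"],
               stringsAsFactors = FALSE)
  } else data.frame(from = character(0), to = character(0),
                    steps = integer(0), sub_steps = integer(0),
                    indel_steps = integer(0), struct_steps = integer(0))
  structure(list(
    nodes = data.frame(id = rownames(all_states), observed = observed,
                       stringsAsFactors = FALSE),
    states = all_states, edges = edges, char_type = char_type,
    epsilon = epsilon), class = "mj_network")
}

#' @export
print.mj_network <- function(x, ...) {
  cat(sprintf("Median-joining network: %d observed + %d median nodes, %d edges\n",
              sum(x$nodes$observed), sum(!x$nodes$observed), nrow(x$edges)))
  invisible(x)
}

#' Coded state vectors of the haplotypes in a haplotype set
#'
#' Takes one representative specimen per haplotype from the coded matrices
#' of the combination's loci.
#'
#' @param hs A `haplotype_set`.
#' @param coded Named list of `coded_matrix` (one per locus of the
#'   combination), from [code_alignment()].
#' @return List with `states` (rows = haplotype ids), `char_type`, and
#'   `members`/`species` bookkeeping, ready for [mj_network()].
#' @export
haplotype_states <- function(hs, coded) {
  if (inherits(coded, "coded_matrix")) coded <- list(coded)
  loci <- vapply(coded, `[[`, "", "locus")
  if (!all(hs$combination %in% loci))
    stop("coded matrices missing for loci: ",
         paste(setdiff(hs$combination, loci), collapse = ", "))
  coded <- coded[match(hs$combination, loci)]
  reps <- vapply(hs$haplotypes, function(h) h$members[1], "")
  cs <- coded_states(coded, ids = reps)
  states <- cs$states
  rownames(states) <- vapply(hs$haplotypes, `[[`, "", "id")
  list(states = states, char_type = cs$char_type,
       members = lapply(hs$haplotypes, `[[`, "members"),
       species = lapply(hs$haplotypes, `[[`, "species"))
}

#' Haplotype-sharing summary of a network
#'
#' @param net An `mj_network` built from `hs`.
#' @param hs The `haplotype_set` behind the network's observed nodes.
#' @param specimens A `specimen_table`.
#' @return List with `per_haplotype` (id, n_members, species, shared),
#'   `per_species` (species, n, n_private, percent_private),
#'   `percent_private_specimens` (genus-wide) and
#'   `percent_species_sharing` (species involved in any sharing).
#' @export
network_summary <- function(net, hs, specimens) {
  ph <- do.call(rbind, lapply(hs$haplotypes, function(h) data.frame(
    id = h$id, n_members = length(h$members),
    species = paste(h$species, collapse = ";"),
    shared = length(h$species) > 1L, stringsAsFactors = FALSE)))
  species <- sort(unique(unlist(lapply(hs$haplotypes, `[[`, "species"))))
  per_sp <- do.call(rbind, lapply(species, function(s) {
    n <- 0L; npriv <- 0L
    for (h in hs$haplotypes) {
      k <- sum(species_of(specimens, h$members) == s)
      n <- n + k
      if (length(h$species) == 1L && h$species == s) npriv <- npriv + k
    }
    data.frame(species = s, n = n, n_private = npriv,
               percent_private = if (n > 0) 100 * npriv / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  sharing_sp <- unique(unlist(lapply(hs$haplotypes, function(h)
    if (length(h$species) > 1L) h$species else character(0))))
  list(per_haplotype = ph, per_species = per_sp,
       percent_private_specimens =
         100 * sum(per_sp$n_private) / max(sum(per_sp$n), 1L),
       percent_species_sharing = 100 * length(sharing_sp) / length(species))
}
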