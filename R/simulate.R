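#' Build a synthetic-genus scenario configuration
#'
#' Describes a genus-level study design: how many specimens per species, a
#' species tree with branch lengths in substitutions/site, per-locus lengths
#' and mutation rates, and the explicit haplotype-sharing processes that
#' confound barcoding in real plant genera — incomplete lineage sorting
#' (sister species retaining an ancestral haplotype), chloroplast capture
#' (a deeply divergent haplotype class introgressed from a donor species),
#' ad-hoc sharing of near-root haplotypes across many species, and per-locus
#' sequencing dropout. Sharing is injected by explicit events rather than by
#' a coalescent model because the downstream claims concern the resulting
#' patterns, not coalescent parameters.
#'
#' @param genus Genus name.
#' @param species Data frame with columns `name`, `n` (specimens sampled).
#' @param tree Newick string; tips must be exactly the species names, branch
#'   lengths in substitutions/site at reference rate 1.
#' @param loci Data frame with columns `name`, `length` (bp), `sub_rate`
#'   (rate multiplier), `indel_rate` (indel events relative to rate-1
#'   substitutions; set > 0 only for indel-rich non-coding loci).
#' @param variants Optional data frame `species`, `steps`, `n_specimens`:
#'   intraspecific haplotype classes `steps` mutations from the species'
#'   modal haplotype.
#' @param ils_events Optional data frame `species_a`, `species_b`, `n_a`,
#'   `n_b`: both species receive carriers of their ancestor's haplotype.
#' @param capture_events Optional data frame `donor`, `recipient`, `steps`,
#'   `n_carriers`: the recipient receives a haplotype class exactly `steps`
#'   mutations from its own modal haplotype, built through the donor's modal
#'   haplotype (so it stays close to the donor); `steps` must be at least
#'   the donor-recipient modal distance.
#' @param sharing_events Optional list of `list(steps =, carriers = )` where
#'   `carriers` is a named integer vector (species -> specimens): a
#'   haplotype `steps` mutations from the root haplotype shared across the
#'   named species.
#' @param dropout Optional named numeric vector, per-locus probability that
#'   a specimen's sequence is missing (sequencing failure).
#' @param counts `"exact"` (default): mutation counts per branch are
#'   `round(rate x length x branch)`, making every designed step count a
#'   deterministic function of the config; `"poisson"`: counts are Poisson
#'   with that mean.
#' @param seed Integer seed; same config and seed give byte-identical data.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(genus, species, tree, loci,
                            variants = NULL, ils_events = NULL,
                            capture_events = NULL, sharing_events = NULL,
                            dropout = NULL,
                            counts = c("exact", "poisson"), seed = 1L) {
  counts <- match.arg(counts)
  stopifnot(is.data.frame(species), all(c("name", "n") %in% names(species)),
            is.data.frame(loci),
            all(c("name", "length", "sub_rate", "indel_rate") %in% names(loci)))
  if (any(species$n < 1)) stop("species sample sizes must be >= 1")
  if (any(loci$length < 1) || any(loci$sub_rate < 0) || any(loci$indel_rate < 0))
    stop("locus lengths must be positive and rates non-negative")
  phy <- ape::read.tree(text = tree)
  if (is.null(phy)) stop("cannot parse species tree")
  if (!setequal(phy$tip.label, species$name))
    stop("tree tips and species names disagree")
  if (!is.null(capture_events) && any(capture_events$steps < 1))
    stop("capture divergence steps must be >= 1")
  if (!is.null(dropout)) {
    bad <- setdiff(names(dropout), loci$name)
    if (length(bad)) stop("dropout names not loci: ", paste(bad, collapse = ", "))
    if (any(dropout < 0 | dropout > 1)) stop("dropout must be in [0, 1]")
  }
  structure(list(genus = genus, species = species, tree = tree, loci = loci,
                 variants = variants, ils_events = ils_events,
                 capture_events = capture_events,
                 sharing_events = sharing_events, dropout = dropout,
                 counts = counts, seed = as.integer(seed)),
            class = "scenario_config")
}

# per-locus infinite-sites allocator: substitutions take successive entries
# of a random column permutation; indel blocks are carved from the right end
# with a one-column spacer so every gap run keeps its exact boundaries
new_locus_state <- function(length, seed_master) {
  env <- new.env(parent = emptyenv())
  env$L <- length
  env$master <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  env$perm <- sample.int(length)
  env$used <- rep(FALSE, length)
  env$ptr <- 1L
  env$sub_reg <- list()    # per event: list(col, to)
  env$ind_reg <- list()    # per event: list(start, end)
  env
}

mutate_base <- function(base) {
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  if (stats::runif(1) < 2 / 3) return(transition[[base]])
  tv <- setdiff(c("A", "C", "G", "T"), c(base, transition[[base]]))
  sample(tv, 1L)
}

new_sub_event <- function(ls) {
  repeat {
    if (ls$ptr > ls$L) stop("locus too short for infinite-sites simulation")
    col <- ls$perm[ls$ptr]; ls$ptr <- ls$ptr + 1L
    if (!ls$used[col]) break
  }
  ls$used[col] <- TRUE
  ls$sub_reg[[length(ls$sub_reg) + 1L]] <- list(col = col,
                                                to = mutate_base(ls$master[col]))
  length(ls$sub_reg)
}

new_indel_event <- function(ls) {
  len <- 1L + stats::rgeom(1L, 1 / 3)   # geometric lengths, mean 3 bp
  pos <- ls$L
  repeat {
    while (pos >= len + 1L && ls$used[pos]) pos <- pos - 1L
    if (pos < len + 1L) stop("locus too short for indel placement")
    if (all(!ls$used[(pos - len):pos])) break
    pos <- pos - 1L
  }
  block <- (pos - len + 1L):pos
  ls$used[(pos - len):pos] <- TRUE      # block plus left spacer
  ls$ind_reg[[length(ls$ind_reg) + 1L]] <- list(start = block[1L], end = pos)
  length(ls$ind_reg)
}

# haplotypes are per-locus sets of event ids; distance = symmetric difference
hap_distance <- function(h1, h2) {
  tot <- 0L
  for (l in names(h1$sub)) {
    tot <- tot + length(union(h1$sub[[l]], h2$sub[[l]])) -
      length(intersect(h1$sub[[l]], h2$sub[[l]]))
    tot <- tot + length(union(h1$ind[[l]], h2$ind[[l]])) -
      length(intersect(h1$ind[[l]], h2$ind[[l]]))
  }
  tot
}

hap_key <- function(h) {
  paste(vapply(names(h$sub), function(l)
    paste0(l, ":", paste(sort(h$sub[[l]]), collapse = ","), ";",
           paste(sort(h$ind[[l]]), collapse = ",")), ""), collapse = "|")
}

#' Simulate one genus under a scenario configuration
#'
#' Haplotypes evolve along the species tree under infinite sites (every
#' mutation hits a previously untouched alignment column, so all designed
#' step counts are exact and homoplasy-free), with a 2:1
#' transition:transversion ratio so simulated data sit inside the K2P model
#' class, and single indel events of geometric length (mean 3 bp). Sharing
#' events then inject ancestral, captured or near-root haplotypes into the
#' configured species' specimen pools, and dropout removes per-locus rows.
#'
#' @param cfg A [scenario_config()].
#' @return List of class `genus_simulation`: `alignments` (named list of
#'   `locus_alignment`), `specimens` (`specimen_table`) and `truth`, the
#'   ground-truth record: `specimen_haplotypes` (specimen -> haplotype id),
#'   `haplotype_species` (haplotype -> species set), `steps` (pairwise
#'   haplotype step-count matrix), `designed_gap` (named logical per
#'   species), `percent_private_specimens`, `capture` (realized within-
#'   recipient and to-donor step counts per event).
#' @export
simulate_genus <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  phy <- ape::read.tree(text = cfg$tree)
  ntip <- length(phy$tip.label)
  loci <- cfg$loci
  count_fun <- if (cfg$counts == "exact") function(x) as.integer(round(x))
  else function(x) stats::rpois(1L, x)

  ls_env <- lapply(seq_len(nrow(loci)), function(i) new_locus_state(loci$length[i]))
  names(ls_env) <- loci$name
  empty_hap <- list(sub = stats::setNames(vector("list", nrow(loci)), loci$name),
                    ind = stats::setNames(vector("list", nrow(loci)), loci$name))
  for (l in loci$name) { empty_hap$sub[[l]] <- integer(0); empty_hap$ind[[l]] <- integer(0) }

  add_steps <- function(hap, n_steps) {
    # apportion steps across loci by mutational target size
    w <- loci$sub_rate * loci$length
    if (sum(w) == 0) stop("no locus with positive substitution rate")
    per <- if (cfg$counts == "exact") apportion(n_steps, w)
    else tabulate(sample.int(nrow(loci), n_steps, replace = TRUE,
                             prob = w / sum(w)), nrow(loci))
    for (i in seq_len(nrow(loci))) {
      l <- loci$name[i]
      if (per[i] > 0)
        hap$sub[[l]] <- c(hap$sub[[l]],
                          vapply(seq_len(per[i]),
                                 function(k) new_sub_event(ls_env[[l]]), 0L))
    }
    hap
  }

  # evolve node haplotypes in preorder (cladewise order visits parents first)
  phy <- stats::reorder(phy, "cladewise")
  node_hap <- vector("list", ntip + phy$Nnode)
  root <- ntip + 1L
  node_hap[[root]] <- empty_hap
  for (e in seq_len(nrow(phy$edge))) {
    parent <- phy$edge[e, 1L]; child <- phy$edge[e, 2L]
    blen <- phy$edge.length[e]
    hap <- node_hap[[parent]]
    for (i in seq_len(nrow(loci))) {
      l <- loci$name[i]
      n_sub <- count_fun(blen * loci$sub_rate[i] * loci$length[i])
      n_ind <- count_fun(blen * loci$indel_rate[i] * loci$length[i])
      if (n_sub > 0)
        hap$sub[[l]] <- c(hap$sub[[l]],
                          vapply(seq_len(n_sub),
                                 function(k) new_sub_event(ls_env[[l]]), 0L))
      if (n_ind > 0)
        hap$ind[[l]] <- c(hap$ind[[l]],
                          vapply(seq_len(n_ind),
                                 function(k) new_indel_event(ls_env[[l]]), 0L))
    }
    node_hap[[child]] <- hap
  }
  modal <- stats::setNames(node_hap[seq_len(ntip)], phy$tip.label)

  # haplotype pool: modal plus event-generated classes, with carrier claims
  pool <- list(); claims <- list()
  add_pool <- function(hap, label) {
    pool[[label]] <<- hap
    label
  }
  for (s in cfg$species$name) add_pool(modal[[s]], paste0("modal_", s))
  shared_species <- character(0)
  if (!is.null(cfg$ils_events)) for (k in seq_len(nrow(cfg$ils_events))) {
    ev <- cfg$ils_events[k, ]
    mrca <- ape::getMRCA(phy, c(ev$species_a, ev$species_b))
    lab <- add_pool(node_hap[[mrca]], paste0("ils", k))
    claims[[length(claims) + 1L]] <- list(species = ev$species_a, hap = lab, n = ev$n_a)
    claims[[length(claims) + 1L]] <- list(species = ev$species_b, hap = lab, n = ev$n_b)
    shared_species <- c(shared_species, ev$species_a, ev$species_b)
  }
  capture_truth <- NULL
  if (!is.null(cfg$capture_events)) for (k in seq_len(nrow(cfg$capture_events))) {
    ev <- cfg$capture_events[k, ]
    d0 <- hap_distance(modal[[ev$donor]], modal[[ev$recipient]])
    if (ev$steps < d0)
      stop(sprintf("capture steps (%d) below donor-recipient modal distance (%d)",
                   ev$steps, d0))
    hap <- add_steps(modal[[ev$donor]], ev$steps - d0)
    lab <- add_pool(hap, paste0("capture", k))
    claims[[length(claims) + 1L]] <- list(species = ev$recipient, hap = lab,
                                          n = ev$n_carriers)
    # the recipient's gap is destroyed by the divergent captured class; the
    # donor's haplotypes stay private unless the capture is at zero offset
    shared_species <- c(shared_species, ev$recipient,
                        if (ev$steps == d0) ev$donor)
    capture_truth <- rbind(capture_truth, data.frame(
      donor = ev$donor, recipient = ev$recipient,
      within_recipient_steps = hap_distance(hap, modal[[ev$recipient]]),
      to_donor_steps = hap_distance(hap, modal[[ev$donor]]),
      stringsAsFactors = FALSE))
  }
  if (!is.null(cfg$sharing_events)) for (k in seq_along(cfg$sharing_events)) {
    ev <- cfg$sharing_events[[k]]
    hap <- add_steps(empty_hap, ev$steps)
    lab <- add_pool(hap, paste0("shared", k))
    for (s in names(ev$carriers)) {
      claims[[length(claims) + 1L]] <- list(species = s, hap = lab,
                                            n = ev$carriers[[s]])
      if (ev$carriers[[s]] > 0) shared_species <- c(shared_species, s)
    }
  }
  if (!is.null(cfg$variants)) for (k in seq_len(nrow(cfg$variants))) {
    ev <- cfg$variants[k, ]
    hap <- add_steps(modal[[ev$species]], ev$steps)
    lab <- add_pool(hap, paste0("variant", k, "_", ev$species))
    claims[[length(claims) + 1L]] <- list(species = ev$species, hap = lab,
                                          n = ev$n_specimens)
  }

  # assign specimens
  sp_rows <- list(); hap_of <- character(0)
  for (i in seq_len(nrow(cfg$species))) {
    s <- cfg$species$name[i]; n <- cfg$species$n[i]
    mine <- Filter(function(cl) cl$species == s, claims)
    claimed <- sum(vapply(mine, `[[`, 0, "n"))
    if (claimed > n)
      stop(sprintf("species %s: %d carriers claimed but only %d specimens", s, claimed, n))
    labels <- c(unlist(lapply(mine, function(cl) rep(cl$hap, cl$n))),
                rep(paste0("modal_", s), n - claimed))
    epithet <- gsub(".*_", "", s)
    if (sum(gsub(".*_", "", cfg$species$name) == epithet) > 1L)
      epithet <- paste0(epithet, i)   # disambiguate repeated epithets
    ids <- sprintf("%s_%s_%02d", abbreviate(cfg$genus, 3), epithet, seq_len(n))
    sp_rows[[i]] <- data.frame(specimen_id = ids, genus = cfg$genus, species = s,
                               latitude = NA_real_, longitude = NA_real_,
                               stringsAsFactors = FALSE)
    hap_of <- c(hap_of, stats::setNames(labels, ids))
  }
  specimens <- validate_specimens(do.call(rbind, sp_rows))

  # collapse pool entries with identical event sets (e.g. zero-length branches)
  keys <- vapply(pool, hap_key, "")
  canon <- names(pool)[match(keys, keys)]
  hap_of <- stats::setNames(canon[match(hap_of, names(pool))], names(hap_of))
  upool <- pool[unique(canon)]

  # realize alignments
  alignments <- list()
  for (i in seq_len(nrow(loci))) {
    l <- loci$name[i]
    ls <- ls_env[[l]]
    seq_of_hap <- lapply(upool, function(h) {
      x <- ls$master
      for (ev in h$sub[[l]]) x[ls$sub_reg[[ev]]$col] <- ls$sub_reg[[ev]]$to
      for (ev in h$ind[[l]]) {
        r <- ls$ind_reg[[ev]]
        x[r$start:r$end] <- "-"
      }
      x
    })
    prob <- if (!is.null(cfg$dropout) && l %in% names(cfg$dropout))
      cfg$dropout[[l]] else 0
    present <- specimens$specimen_id[stats::runif(nrow(specimens)) >= prob]
    if (length(present) == 0L) next
    m <- do.call(rbind, lapply(present, function(id) seq_of_hap[[hap_of[[id]]]]))
    rownames(m) <- present
    alignments[[l]] <- locus_alignment(m, genus = cfg$genus, locus = l,
                                       specimens = specimens)
  }

  # ground truth
  hap_ids <- names(upool)
  steps <- matrix(0L, length(hap_ids), length(hap_ids),
                  dimnames = list(hap_ids, hap_ids))
  if (length(hap_ids) > 1L)
    for (a in seq_along(hap_ids)[-length(hap_ids)])
      for (b in (a + 1L):length(hap_ids))
        steps[a, b] <- steps[b, a] <-
      hap_distance(upool[[a]], upool[[b]])
  hap_species <- lapply(hap_ids, function(h)
    sort(unique(specimens$species[hap_of[specimens$specimen_id] == h])))
  names(hap_species) <- hap_ids
  private_hap <- vapply(hap_species, function(x) length(x) == 1L, TRUE)
  n_private <- sum(private_hap[hap_of[specimens$specimen_id]])
  designed_gap <- stats::setNames(!(cfg$species$name %in% shared_species),
                                  cfg$species$name)
  truth <- list(
    specimen_haplotypes = data.frame(specimen_id = specimens$specimen_id,
                                     species = specimens$species,
                                     hap_id = unname(hap_of[specimens$specimen_id]),
                                     stringsAsFactors = FALSE),
    haplotype_species = hap_species,
    steps = steps,
    designed_gap = designed_gap,
    percent_private_specimens = 100 * n_private / nrow(specimens),
    capture = capture_truth)
  structure(list(alignments = alignments, specimens = specimens, truth = truth,
                 config = cfg),
            class = "genus_simulation")
}

# deterministic largest-remainder apportionment of n items to weights w
apportion <- function(n, w) {
  if (n == 0L) return(rep(0L, length(w)))
  share <- n * w / sum(w)
  base <- floor(share)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(-(share - base), seq_along(w))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' @export
print.genus_simulation <- function(x, ...) {
  cat(sprintf("Simulated genus %s: %d specimens, %d species, %d loci\n",
              x$config$genus, nrow(x$specimens),
              nrow(x$config$species), length(x$alignments)))
  invisible(x)
}

#' Write a simulated genus to disk
#'
#' Emits one aligned FASTA per locus (named `<genus>_<locus>.fasta`), a
#' `metadata.tsv` specimen table, and `ground_truth.json`.
#'
#' @param sim A `genus_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (l in names(sim$alignments))
    write_alignment(sim$alignments[[l]],
                    file.path(dir, sprintf("%s_%s.fasta", sim$config$genus, l)))
  write_specimens(sim$specimens, file.path(dir, "metadata.tsv"))
  truth <- sim$truth
  truth$steps <- as.data.frame(truth$steps)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Preset genus scenarios
#'
#' Four named configurations shaped like the qualitative outcomes seen in
#' alpine and annual plant genera:
#' \describe{
#'   \item{lonicera_like}{deeply diverged species, small private
#'     intraspecific variation, no sharing: a clear barcoding gap, complete
#'     assignment and full species monophyly are expected.}
#'   \item{salix_like}{very shallow divergence with three common haplotypes
#'     shared by all four species; only 10 of 69 specimens (14.5 percent)
#'     carry private sequences and no species shows a gap.}
#'   \item{gentiana_like}{chloroplast capture: the recipient species holds
#'     two haplotype classes exactly 63 mutation steps apart, the captured
#'     class one step from the donor's modal haplotype.}
#'   \item{acer_like}{incomplete lineage sorting: both sister-species pairs
#'     share their ancestral haplotype while the outgroup species stays
#'     fully discriminated.}
#' }
#'
#' @param seed Integer seed stored in every config.
#' @return Named list of `scenario_config` objects.
#' @export
preset_scenarios <- function(seed = 1L) {
  loci4 <- function(LmatK, LtrnH) data.frame(
    name = c("matK", "rpoC1", "rpoB", "trnH-psbA"),
    length = c(LmatK, 508, 349, LtrnH),
    sub_rate = c(1, 0.2, 0.2, 2.5),
    indel_rate = c(0, 0, 0, 0.25), stringsAsFactors = FALSE)

  lonicera <- scenario_config(
    genus = "Lonicera",
    species = data.frame(name = c("Lonicera_alpigena", "Lonicera_caerulea",
                                  "Lonicera_nigra", "Lonicera_xylosteum"),
                         n = c(20L, 16L, 16L, 15L), stringsAsFactors = FALSE),
    tree = paste0("((Lonicera_alpigena:0.012,Lonicera_caerulea:0.012):0.012,",
                  "(Lonicera_nigra:0.012,Lonicera_xylosteum:0.012):0.012);"),
    loci = loci4(850, 450),
    variants = data.frame(
      species = rep(c("Lonicera_alpigena", "Lonicera_caerulea",
                      "Lonicera_nigra", "Lonicera_xylosteum"), each = 2L),
      steps = rep(c(1L, 2L), 4L),
      n_specimens = rep(c(4L, 3L), 4L), stringsAsFactors = FALSE),
    seed = seed)

  salix_species <- c("Salix_herbacea", "Salix_reticulata",
                     "Salix_retusa", "Salix_serpillifolia")
  salix <- scenario_config(
    genus = "Salix",
    species = data.frame(name = salix_species, n = c(20L, 18L, 16L, 15L),
                         stringsAsFactors = FALSE),
    tree = paste0("(", paste0(salix_species, ":0.0012", collapse = ","), ");"),
    loci = data.frame(name = c("matK", "rpoC1", "rpoB", "trnH-psbA"),
                      length = c(855, 508, 349, 325),
                      sub_rate = c(1, 0.2, 0.2, 2.5),
                      indel_rate = c(0, 0, 0, 0.25), stringsAsFactors = FALSE),
    sharing_events = list(
      list(steps = 0L, carriers = c(Salix_herbacea = 8L, Salix_reticulata = 7L,
                                    Salix_retusa = 6L, Salix_serpillifolia = 6L)),
      list(steps = 1L, carriers = c(Salix_herbacea = 5L, Salix_reticulata = 4L,
                                    Salix_retusa = 4L, Salix_serpillifolia = 4L)),
      list(steps = 2L, carriers = c(Salix_herbacea = 4L, Salix_reticulata = 4L,
                                    Salix_retusa = 4L, Salix_serpillifolia = 3L))),
    seed = seed)

  gentiana <- scenario_config(
    genus = "Gentiana",
    species = data.frame(name = c("Gentiana_alpina", "Gentiana_clusii",
                                  "Gentiana_acaulis", "Gentiana_angustifolia"),
                         n = c(40L, 35L, 30L, 30L), stringsAsFactors = FALSE),
    tree = paste0("((Gentiana_alpina:0.014,Gentiana_clusii:0.014):0.02,",
                  "(Gentiana_acaulis:0.014,Gentiana_angustifolia:0.014):0.02);"),
    loci = data.frame(name = c("matK", "rpoC1", "rpoB", "trnH-psbA"),
                      length = c(761, 508, 349, 460),
                      sub_rate = c(1, 0.15, 0.15, 2.5),
                      indel_rate = c(0, 0, 0, 0.3), stringsAsFactors = FALSE),
    variants = data.frame(
      species = c("Gentiana_alpina", "Gentiana_clusii", "Gentiana_acaulis",
                  "Gentiana_angustifolia"),
      steps = 1L, n_specimens = 6L, stringsAsFactors = FALSE),
    capture_events = data.frame(donor = "Gentiana_clusii",
                                recipient = "Gentiana_alpina",
                                steps = 63L, n_carriers = 12L,
                                stringsAsFactors = FALSE),
    seed = seed)

  acer_species <- c("Acer_campestre", "Acer_platanoides", "Acer_opalus",
                    "Acer_monspessulanum", "Acer_pseudoplatanus")
  acer <- scenario_config(
    genus = "Acer",
    species = data.frame(name = acer_species, n = c(25L, 22L, 20L, 18L, 18L),
                         stringsAsFactors = FALSE),
    tree = paste0("(((Acer_campestre:0.004,Acer_platanoides:0.004):0.008,",
                  "(Acer_opalus:0.004,Acer_monspessulanum:0.004):0.008):0.01,",
                  "Acer_pseudoplatanus:0.01);"),
    loci = loci4(849, 512),
    variants = data.frame(species = acer_species, steps = 2L,
                          n_specimens = 3L, stringsAsFactors = FALSE),
    ils_events = data.frame(
      species_a = c("Acer_campestre", "Acer_opalus"),
      species_b = c("Acer_platanoides", "Acer_monspessulanum"),
      n_a = c(12L, 12L), n_b = c(12L, 12L), stringsAsFactors = FALSE),
    seed = seed)

  list(lonicera_like = lonicera, salix_like = salix,
       gentiana_like = gentiana, acer_like = acer)
}
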