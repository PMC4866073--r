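#' Write a tabular or structured report
#'
#' Data frames round-trip through TSV or JSON; arbitrary report lists
#' (gap summaries, genus reports) through JSON.
#'
#' @param results Data frame or list.
#' @param path Output path.
#' @param format `"tsv"` (data frames only) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!is.data.frame(results)) stop("TSV output requires a data frame")
    utils::write.table(as.data.frame(results), path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(strip_classes(results), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  invisible(path)
}

strip_classes <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(x, strip_classes))
  if (is.matrix(x)) return(as.data.frame(x))
  x
}

#' Read a report written by [write_report()]
#'
#' @param path File path.
#' @param format `"tsv"` or `"json"` (default: from the file extension).
#' @return Data frame (TSV) or list (JSON).
#' @export
read_report <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path)) "json" else "tsv"
  if (format == "tsv")
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Export a median-joining network
#'
#' Writes `<stem>_nodes.tsv`, `<stem>_edges.tsv` and `<stem>.graphml`.
#' Edge rows carry the per-step breakdown (substitution vs indel vs
#' structural), the conventional full-line/double-line rendering
#' distinction; node rows carry member counts and species composition so a
#' plotting layer can scale circles by frequency.
#'
#' @param net An `mj_network`.
#' @param stem Output path stem.
#' @param summary Optional result of [network_summary()] supplying member
#'   counts and species per observed node.
#' @return The graphml path, invisibly.
#' @export
export_network <- function(net, stem, summary = NULL) {
  nodes <- net$nodes
  nodes$n_members <- 0L
  nodes$species <- ""
  if (!is.null(summary)) {
    idx <- match(summary$per_haplotype$id, nodes$id)
    nodes$n_members[idx] <- summary$per_haplotype$n_members
    nodes$species[idx] <- summary$per_haplotype$species
  }
  utils::write.table(nodes, paste0(stem, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(net$edges, paste0(stem, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = nodes)
  path <- paste0(stem, ".graphml")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Run the full per-genus barcode evaluation
#'
#' Executes every stage for one genus: per-locus variation summaries,
#' haplotype collapse and assignment success over all locus combinations,
#' barcode selection, barcoding-gap diagnostics, bootstrapped NJ tree with
#' species-monophyly report, median-joining network with sharing summary,
#' rarefaction richness and the sampling-size correlation. Genera are never
#' pooled: the function takes one genus at a time by construction.
#'
#' @param alignments Named list of `locus_alignment` for one genus.
#' @param specimens A `specimen_table` (may contain other genera; only this
#'   genus' specimens are used).
#' @param g Rarefaction subsample size (default 3).
#' @param n_bootstrap NJ bootstrap replicates (default 100).
#' @param seed Integer seed for the bootstrap.
#' @param bin_width Gap-histogram bin width.
#' @param ambiguity Haplotype identity rule, see [collapse_haplotypes()].
#' @param rarefaction_locus Locus used for the per-species richness table
#'   (default `"trnH-psbA"` when present — the most variable locus shared by
#'   all genera — else the selected barcode combination).
#' @return List of class `genus_report` with elements `genus`, `variation`,
#'   `combinations`, `selected_barcode`, `ranking`, `gap`, `tree` (newick
#'   string with supports), `monophyly`, `network`, `network_summary`,
#'   `rarefaction`, `correlation`, `provenance`.
#' @export
run_genus <- function(alignments, specimens, g = 3L, n_bootstrap = 100L,
                      seed = 1L, bin_width = 0.001,
                      ambiguity = "strict", rarefaction_locus = "trnH-psbA") {
  genus <- attr(alignments[[1L]], "genus")
  specimens_g <- specimens[specimens$genus == genus, , drop = FALSE]
  class(specimens_g) <- class(specimens)
  n_species <- length(unique(specimens_g$species))

  variation <- variation_table(stats::setNames(list(alignments), genus),
                               specimens_g)
  combos <- combination_report(alignments, specimens_g, ambiguity = ambiguity)
  sel <- best_barcode(combos)
  best_loci <- strsplit(sel$best$combination, "+", fixed = TRUE)[[1L]]

  gap <- NULL; tree <- NULL; mono <- NULL
  if (n_species >= 2L) {
    dm <- distance_matrix(alignments, best_loci)
    gap <- barcoding_gap(dm, specimens_g, bin_width = bin_width)
    if (length(dm$labels) >= 3L && all(dm$defined)) {
      bs <- bootstrap_nj(alignments, best_loci, n_replicates = n_bootstrap,
                         seed = seed)
      tree <- bs
      mono <- monophyly(bs$tree, specimens_g)
    }
  }

  hs <- collapse_haplotypes(alignments, best_loci, specimens_g,
                            ambiguity = ambiguity)
  coded <- lapply(alignments[best_loci], code_alignment)
  stv <- haplotype_states(hs, coded)
  net <- mj_network(stv$states, char_type = stv$char_type)
  nsum <- network_summary(net, hs, specimens_g)

  rl <- if (rarefaction_locus %in% names(alignments)) rarefaction_locus else best_loci
  hs_r <- collapse_haplotypes(alignments, rl, specimens_g, ambiguity = ambiguity)
  rtab <- rarefaction_table(hs_r, specimens_g, g = g)
  corr <- sampling_correlation(rtab)

  structure(list(
    genus = genus,
    variation = variation,
    combinations = combos,
    selected_barcode = sel$best$combination,
    ranking = sel$ranking,
    gap = if (is.null(gap)) list(applicable = FALSE) else gap,
    tree = if (is.null(tree)) NULL else ape::write.tree(tree$tree),
    bootstrap_support = if (is.null(tree)) NULL else tree$support,
    monophyly = mono,
    network = net,
    network_summary = nsum,
    rarefaction = rtab,
    correlation = corr,
    provenance = list(seed = seed, n_bootstrap = n_bootstrap, g = g,
                      ambiguity = ambiguity,
                      package_version = as.character(utils::packageVersion("barcodegap")))),
    class = "genus_report")
}

#' @export
print.genus_report <- function(x, ...) {
  cat(sprintf("Genus report %s: best barcode %s (%.1f%% identified)\n",
              x$genus, x$selected_barcode,
              x$combinations$percent_identified[
                x$combinations$combination == x$selected_barcode]))
  invisible(x)
}

#' Run the pipeline over a dataset directory
#'
#' Reads `<genus>_<locus>.fasta` alignments plus a metadata table, runs
#' [run_genus()] independently for every genus, and serialises each report.
#' One genus failing does not abort the others; failures are recorded.
#'
#' @param dir Alignment directory.
#' @param metadata Specimen table (path or `specimen_table`).
#' @param out Optional output directory for per-genus JSON reports.
#' @param ... Passed to [run_genus()].
#' @return Named list of `genus_report` (or condition objects for failed
#'   genera), with attribute `failures` naming the failed genera.
#' @export
run_pipeline <- function(dir, metadata, out = NULL, ...) {
  specimens <- if (is.character(metadata)) read_specimens(metadata) else metadata
  files <- list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  if (!length(files)) stop("no FASTA files found in ", dir)
  base <- sub("\\.(fa|fasta)$", "", basename(files))
  parts <- strsplit(base, "_")
  genus_of <- vapply(parts, `[`, "", 1L)
  reports <- list(); failures <- character(0)
  for (genus in unique(genus_of)) {
    mine <- which(genus_of == genus)
    res <- tryCatch({
      alns <- list()
      for (k in mine) {
        locus <- paste(parts[[k]][-1L], collapse = "_")
        alns[[locus]] <- read_alignment(files[k], genus = genus,
                                        locus = locus, specimens = specimens)
      }
      rep <- run_genus(alns, specimens, ...)
      rep$provenance$input_md5 <- as.list(tools::md5sum(files[mine]))
      rep
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, genus)
      message("genus ", genus, " failed: ", conditionMessage(res))
    }
    reports[[genus]] <- res
    if (!is.null(out) && !inherits(res, "error")) {
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_report(genus_report_json(res),
                   file.path(out, paste0(genus, "_report.json")), "json")
    }
  }
  attr(reports, "failures") <- failures
  reports
}

# JSON-friendly view of a genus report
genus_report_json <- function(rep) {
  list(genus = rep$genus,
       variation = rep$variation,
       combinations = rep$combinations,
       selected_barcode = rep$selected_barcode,
       gap = if (is.list(rep$gap) && !is.null(rep$gap$per_species))
         list(per_species = rep$gap$per_species,
              n_undefined_dropped = rep$gap$n_undefined_dropped)
       else list(applicable = FALSE),
       tree = rep$tree,
       bootstrap_support = as.list(rep$bootstrap_support),
       monophyly = if (!is.null(rep$monophyly)) as.data.frame(rep$monophyly),
       network = list(nodes = rep$network$nodes, edges = rep$network$edges),
       network_summary = rep$network_summary,
       rarefaction = rep$rarefaction,
       correlation = unclass(rep$correlation),
       provenance = rep$provenance)
}
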