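#' Read a specimen metadata table
#'
#' Reads the tab-separated specimen table that anchors every analysis:
#' one row per sampled individual, mapping its identifier to a genus and a
#' species, with optional collection coordinates.
#'
#' @param path Path to a TSV file with header columns
#'   `specimen_id`, `genus`, `species` and optionally `latitude`, `longitude`
#'   (decimal degrees).
#' @return A `data.frame` of class `specimen_table`, validated by
#'   [validate_specimens()].
#' @export
read_specimens <- function(path) {
  if (!file.exists(path)) stop("specimen table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("specimen_id", "genus", "species")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("specimen table lacks column(s): ", paste(missing, collapse = ", "))
  for (col in c("latitude", "longitude")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
    else df[[col]] <- NA_real_
  }
  validate_specimens(df[c(required, "latitude", "longitude")])
}

#' Construct and validate a specimen table
#'
#' @param df Data frame with at least `specimen_id`, `genus`, `species`.
#' @return The validated data frame with class `specimen_table`.
#' @details Enforces the two structural invariants on which downstream
#'   bookkeeping relies: specimen identifiers are unique, and each species
#'   name belongs to exactly one genus.
#' @export
validate_specimens <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("specimen_id", "genus", "species")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("specimen table lacks column(s): ", paste(missing, collapse = ", "))
  dup <- df$specimen_id[duplicated(df$specimen_id)]
  if (length(dup))
    stop("duplicate specimen_id: ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(df$specimen_id)) || any(!nzchar(df$species)))
    stop("empty specimen_id or species name")
  gen_per_sp <- tapply(df$genus, df$species, function(g) length(unique(g)))
  bad <- names(gen_per_sp)[gen_per_sp > 1]
  if (length(bad))
    stop("species mapped to more than one genus: ", paste(bad, collapse = ", "))
  if (!"latitude" %in% names(df)) df$latitude <- NA_real_
  if (!"longitude" %in% names(df)) df$longitude <- NA_real_
  class(df) <- c("specimen_table", "data.frame")
  df
}

#' @export
print.specimen_table <- function(x, ...) {
  cat(sprintf("Specimen table: %d specimens, %d species, %d genera\n",
              nrow(x), length(unique(x$species)), length(unique(x$genus))))
  invisible(x)
}

#' Write a specimen table to TSV
#'
#' @param specimens A `specimen_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_specimens <- function(specimens, path) {
  utils::write.table(as.data.frame(specimens), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# species -> specimen ids lookup restricted to one genus
species_of <- function(specimens, ids) {
  specimens$species[match(ids, specimens$specimen_id)]
}
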