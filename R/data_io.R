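# Trait-table ingestion and validation.
#
# The analysis-ready table holds one row per predator species with its
# taxonomy (order/family/genus), foraging environment (aquatic/terrestrial),
# body mass and the minimum/maximum mass of its prey, all in kg, plus the
# log10-derived columns every downstream module consumes. Prey-mass range is
# computed on the raw kg scale (max - min) and only then log10-transformed.

.raw_cols <- c("species", "order", "family", "genus", "environment",
               "predator_mass", "prey_min", "prey_max")
.derived_cols <- c("log_mass", "log_prey_min", "log_prey_max", "log_prey_range")
.environments <- c("aquatic", "terrestrial")

#' Normalize species names to Newick tip-label convention
#'
#' Trims whitespace and replaces internal runs of whitespace with a single
#' underscore, so `"Canis lupus"` and `"Canis_lupus"` compare equal.
#'
#' @param x character vector of species names.
#' @return character vector of normalized names.
#' @export
normalize_species <- function(x) gsub("\\s+", "_", trimws(as.character(x)))

#' Construct a validated trait table
#'
#' Validates the raw columns (positivity of masses, `prey_max >= prey_min`,
#' unique species, genus equal to the first name token, known environment
#' labels), normalizes species names, and appends the derived log10 columns.
#' Rows with `prey_min == prey_max` are retained for min/max analyses but
#' their `log_prey_range` is `NA` (log of a zero range is undefined); they are
#' flagged in the validation report and a warning is raised.
#'
#' @param df data.frame with columns `species`, `order`, `family`, `genus`,
#'   `environment` (`"aquatic"` or `"terrestrial"`), `predator_mass`,
#'   `prey_min`, `prey_max` (kg, strictly positive).
#' @return a `trait_table`: the data.frame with derived columns
#'   `log_mass`, `log_prey_min`, `log_prey_max`, `log_prey_range` and an
#'   attached `validation_report` attribute (row counts by environment and
#'   flagged zero-range species).
#' @export
trait_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing <- setdiff(.raw_cols, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[, c(.raw_cols, setdiff(names(df), c(.raw_cols, .derived_cols)))]
  df$species <- normalize_species(df$species)
  for (col in c("order", "family", "genus", "environment"))
    df[[col]] <- trimws(as.character(df[[col]]))

  bad_env <- !df$environment %in% .environments
  if (any(bad_env))
    stop("unknown environment label(s) for species: ",
         paste(df$species[bad_env], collapse = ", "),
         " (expected 'aquatic' or 'terrestrial')")

  for (col in c("predator_mass", "prey_min", "prey_max")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- !is.finite(v) | v <= 0
    if (any(bad))
      stop("non-positive or non-numeric ", col, " for species: ",
           paste(df$species[bad], collapse = ", "))
    df[[col]] <- v
  }
  if (anyDuplicated(df$species))
    stop("duplicate species: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  inverted <- df$prey_max < df$prey_min
  if (any(inverted))
    stop("prey_max < prey_min for species: ",
         paste(df$species[inverted], collapse = ", "))
  first_token <- sub("_.*$", "", df$species)
  bad_genus <- df$genus != first_token
  if (any(bad_genus))
    stop("genus does not match first token of species name for: ",
         paste(df$species[bad_genus], collapse = ", "))

  df$log_mass <- log10(df$predator_mass)
  df$log_prey_min <- log10(df$prey_min)
  df$log_prey_max <- log10(df$prey_max)
  zero_range <- df$prey_max == df$prey_min
  df$log_prey_range <- ifelse(zero_range, NA_real_, log10(df$prey_max - df$prey_min))
  if (any(zero_range))
    warning("prey_min == prey_max (log range undefined, row kept) for: ",
            paste(df$species[zero_range], collapse = ", "))

  report <- list(
    n_rows = nrow(df),
    n_aquatic = sum(df$environment == "aquatic"),
    n_terrestrial = sum(df$environment == "terrestrial"),
    zero_range_species = df$species[zero_range]
  )
  attr(df, "validation_report") <- report
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Read a trait table from CSV
#'
#' Reads a comma-separated, UTF-8, headered file and validates it with
#' [trait_table()]. Files transcribed with different headers are handled via
#' `config`, a named list/vector mapping canonical column names to the
#' headers present in the file, e.g.
#' `list(species = "Species", predator_mass = "Mass.kg")`.
#'
#' @param path path to a CSV file.
#' @param config optional named mapping canonical -> file header.
#' @return a validated [trait_table()]; the validation report is available
#'   via `attr(x, "validation_report")`.
#' @export
read_trait_table <- function(path, config = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 fileEncoding = "UTF-8")
  if (!is.null(config)) {
    config <- unlist(config)
    unknown <- setdiff(names(config), .raw_cols)
    if (length(unknown))
      stop("config maps unknown canonical column(s): ",
           paste(unknown, collapse = ", "))
    absent <- setdiff(unname(config), names(df))
    if (length(absent))
      stop("mapped column(s) absent from file: ", paste(absent, collapse = ", "))
    for (canon in names(config)) names(df)[names(df) == config[[canon]]] <- canon
  }
  trait_table(df)
}

#' Write a trait table to CSV
#'
#' Raw mass columns are serialized with 17 significant digits so that
#' `read_trait_table(write_trait_table(x))` reproduces them bit-identically.
#'
#' @param table a `trait_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  stopifnot(inherits(table, "trait_table"))
  out <- as.data.frame(table)[, c(.raw_cols, .derived_cols)]
  for (col in c("predator_mass", "prey_min", "prey_max", .derived_cols))
    out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Species set of a trait table
#'
#' The normalized species names, used as the tip-label set when pruning the
#' phylogeny.
#'
#' @param table a `trait_table`.
#' @return character vector of species names (unique by construction).
#' @export
species_set <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  table$species
}

#' @export
print.trait_table <- function(x, ...) {
  rep <- attr(x, "validation_report")
  cat(sprintf("trait_table: %d species (%d aquatic, %d terrestrial)\n",
              rep$n_rows, rep$n_aquatic, rep$n_terrestrial))
  if (length(rep$zero_range_species))
    cat("  zero prey-mass range (log range NA):",
        paste(rep$zero_range_species, collapse = ", "), "\n")
  NextMethod()
}

# subsetting a trait_table keeps the class but the report reflects the
# original read; recompute on demand
#' @export
`[.trait_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(.raw_cols %in% names(out))) {
    class(out) <- c("trait_table", "data.frame")
    attr(out, "validation_report") <- list(
      n_rows = nrow(out),
      n_aquatic = sum(out$environment == "aquatic"),
      n_terrestrial = sum(out$environment == "terrestrial"),
      zero_range_species = out$species[out$prey_max == out$prey_min]
    )
  }
  out
}
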