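# Canonical column names and the header synonyms accepted for each.
# Matching is case-insensitive after squeezing whitespace/punctuation.
config_header_synonyms <- list(
  genus = c("genus"),
  species = c("species", "species name", "specific epithet"),
  button = c("button", "button?", "button yes/no", "button (yes/no)"),
  button_label = c("button label", "abbreviation", "label", "button text"),
  category = c("category", "higher category", "group", "higher group",
               "higher level category", "list")
)

normalize_header <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]_]+", " ", x)
}

#' Read a taxa configuration file
#'
#' The counting interface is populated entirely from a tab-delimited text
#' file listing the taxa to count: the mandatory `genus`, `species` and
#' `button` (yes/no) columns, an abbreviation used as the button label when
#' `button` is yes, and an optional higher-level `category` used to organize
#' long lists into groups. Header names are matched case-insensitively
#' against a synonym table ([config_synonyms()]); unrecognized columns (for
#' example a recognition name used only by voice-entry front ends) are
#' preserved untouched in an `extras` list-column and ignored everywhere
#' else.
#'
#' The stable `taxon_id` is `"genus species"` with whitespace squeezed;
#' duplicate (genus, species) pairs are an error.
#'
#' @param path Path to a tab-delimited text file with a header row.
#' @param synonyms Header synonym table, normally [config_synonyms()];
#'   extend it with `config_synonyms(list(category = "family"))` to ingest
#'   files from other counting programs.
#' @return A tibble with columns `taxon_id`, `genus`, `species`, `button`
#'   (logical), `button_label`, `category`, `extras` (named-list column of
#'   preserved unrecognized cells), in file row order.
#' @export
read_taxa_config <- function(path, synonyms = config_synonyms()) {
  if (!file.exists(path)) abort(sprintf("No such file: '%s'.", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  if (nrow(raw) == 0) abort(sprintf("Configuration file '%s' is empty.", path))
  headers <- normalize_header(names(raw))
  canon <- rep(NA_character_, length(headers))
  for (key in names(synonyms)) {
    hit <- headers %in% synonyms[[key]]
    if (sum(hit) > 1) abort(sprintf("Multiple columns match '%s'.", key))
    canon[hit] <- key
  }
  for (key in c("genus", "species", "button")) {
    if (!key %in% canon) {
      abort(sprintf("Missing mandatory column '%s' in '%s'.", key, path))
    }
  }
  get_col <- function(key, default = "") {
    if (key %in% canon) trimws(raw[[which(canon == key)]]) else
      rep(default, nrow(raw))
  }
  genus <- get_col("genus")
  species <- get_col("species")
  for (i in seq_len(nrow(raw))) {
    if (genus[i] == "" || species[i] == "") {
      abort(sprintf("Row %d of '%s' is missing a mandatory genus/species cell.",
                    i, path))
    }
  }
  button <- parse_yes_no(get_col("button"), path)
  button_label <- get_col("button_label")
  taxon_id <- paste(gsub("[[:space:]]+", " ", genus),
                    gsub("[[:space:]]+", " ", species))
  missing_label <- button & button_label == ""
  if (any(missing_label)) {
    # a button needs a short label to fit; fall back to an abbreviation
    warn(sprintf(
      "Row %s: button = yes without a button label; using an abbreviation.",
      paste(which(missing_label), collapse = ", ")))
    button_label[missing_label] <- paste0(
      substr(genus[missing_label], 1, 1), ". ", species[missing_label])
  }
  dup <- duplicated(taxon_id)
  if (any(dup)) {
    abort(sprintf("Duplicate (genus, species) pair '%s' at row %d.",
                  taxon_id[dup][[1]], which(dup)[[1]]))
  }
  extra_idx <- which(is.na(canon))
  extras <- purrr::map(seq_len(nrow(raw)), function(i) {
    as.list(setNames(as.character(raw[i, extra_idx]), names(raw)[extra_idx]))
  })
  tibble(
    taxon_id = taxon_id, genus = genus, species = species,
    button = button, button_label = button_label,
    category = get_col("category"), extras = extras
  )
}

parse_yes_no <- function(x, path) {
  lx <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[lx %in% c("yes", "y", "true", "t", "1")] <- TRUE
  out[lx %in% c("no", "n", "false", "f", "0", "")] <- FALSE
  if (anyNA(out)) {
    abort(sprintf("Row %d of '%s': cannot interpret button value '%s'.",
                  which(is.na(out))[[1]], path, x[is.na(out)][[1]]))
  }
  out
}

#' The header synonym table used by [read_taxa_config()]
#'
#' Exposed so files from other counting programs can be ingested: pass the
#' extended table to [read_taxa_config()].
#'
#' @param extra Optional named list of additional synonyms to merge, e.g.
#'   `list(category = "family")`.
#' @return Named list mapping canonical column names to accepted headers.
#' @export
config_synonyms <- function(extra = NULL) {
  out <- config_header_synonyms
  for (nm in names(extra)) {
    out[[nm]] <- unique(c(out[[nm]], normalize_header(extra[[nm]])))
  }
  out
}

#' Write a taxa configuration back to tab-text
#'
#' Inverse of [read_taxa_config()]: canonical columns plus any preserved
#' extra columns, so that write-then-read round-trips to an equal table.
#'
#' @param taxa A tibble from [read_taxa_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxa_config <- function(taxa, path) {
  out <- tibble(
    genus = taxa$genus, species = taxa$species,
    button = ifelse(taxa$button, "yes", "no"),
    `button label` = taxa$button_label,
    category = taxa$category
  )
  if ("extras" %in% names(taxa) && length(taxa$extras) &&
      length(taxa$extras[[1]])) {
    for (nm in names(taxa$extras[[1]])) {
      out[[nm]] <- purrr::map_chr(taxa$extras, ~ .x[[nm]] %||% "")
    }
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Group taxa by higher-level category
#'
#' Splits a parsed configuration into per-category lists in first-appearance
#' order, the structure from which a counting interface builds its menus.
#' Taxa with an empty category are collected under `default_label`. The
#' groups partition the input: every taxon appears in exactly one group.
#'
#' @param taxa A tibble from [read_taxa_config()] (or any data frame with
#'   `taxon_id` and `category` columns).
#' @param default_label Group name for taxa without a category.
#' @return A named list of tibbles, one per category.
#' @export
group_by_category <- function(taxa, default_label = "Uncategorized") {
  if (!is.data.frame(taxa) || !"category" %in% names(taxa)) {
    abort("`taxa` must have a `category` column.")
  }
  cat <- ifelse(is.na(taxa$category) | taxa$category == "",
                default_label, taxa$category)
  split(as_tibble(taxa), factor(cat, levels = unique(cat)))
}
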