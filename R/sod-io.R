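# -------------------------------------------------------------------------
# SOD (Stratigraphic Occurrence Data) format: a versioned tab-text grid in
# four blocks — file metadata upper-left (A), sample metadata upper-right
# (B), taxa metadata lower-left (C), occurrence counts lower-right (D).
# Every value cell has an adjacent label cell, so files are self-describing
# and spreadsheet-openable. Two dialects: "O" (ocean-drilling samples named
# Site-Hole-Core-Section-Interval) and "L" (land sections with formation /
# lithology / level). Field definitions are data, not code: new file types
# or versions are added by extending the definition table.
# -------------------------------------------------------------------------

sod_taxa_labels <- c("Genus", "Species", "Author")
sod_counts_label <- "Counts:"

#' Field definition table for the SOD format
#'
#' Returns the table that gives, for one file type and format version, the
#' ordered labels of every metadata field and whether each is required.
#' Reading and writing code is driven entirely by this table, so the format
#' is open to expansion by editing data rather than code. A user-edited
#' definition can be supplied to [read_sod()] / [write_sod()] as a
#' replacement, or loaded from a tab-text file with
#' `readr::read_tsv(system.file("extdata", "sod_field_definitions.tsv",
#' package = "raricount"))`.
#'
#' @param file_type `"O"` (ocean drilling) or `"L"` (land section).
#' @param version Format version string; `"1"` is the only built-in.
#' @return A tibble with columns `file_type`, `version`, `block`
#'   (`"file"` or `"sample"`), `key` (machine name), `label` (the text in
#'   the label cell), `required` (logical).
#' @export
sod_field_definitions <- function(file_type = c("O", "L"), version = "1") {
  file_type <- match.arg(file_type)
  if (!identical(version, "1")) {
    abort(sprintf("Unknown SOD version '%s'; '1' is the only built-in.",
                  version))
  }
  def <- function(block, key, label, required = FALSE) {
    tibble(file_type = file_type, version = version, block = block,
           key = key, label = label, required = required)
  }
  common_head <- dplyr::bind_rows(
    def("file", "version", "SOD version", TRUE),
    def("file", "file_type", "File type", TRUE)
  )
  common_tail <- dplyr::bind_rows(
    def("file", "fossil_group", "Fossil group"),
    def("file", "observer", "Observer"),
    def("file", "date", "Date"),
    def("file", "source", "Source")
  )
  rare_fields <- dplyr::bind_rows(
    def("sample", "tracks_full", "Tracks full"),
    def("sample", "tracks_rare", "Tracks rare"),
    def("sample", "threshold", "Exclusion threshold"),
    def("sample", "excluded_taxa", "Excluded taxa")
  )
  if (file_type == "O") {
    dplyr::bind_rows(
      common_head,
      def("file", "leg", "Leg"),
      def("file", "site", "Site", TRUE),
      def("file", "hole", "Hole", TRUE),
      def("file", "latitude", "Latitude"),
      def("file", "longitude", "Longitude"),
      def("file", "ocean", "Ocean"),
      common_tail,
      def("sample", "sample_id", "Sample ID", TRUE),
      def("sample", "core", "Core"),
      def("sample", "section", "Section"),
      def("sample", "interval", "Interval"),
      def("sample", "depth", "Depth (mbsf)"),
      def("sample", "zone", "Zone"),
      def("sample", "age", "Age (Ma)"),
      rare_fields
    )
  } else {
    dplyr::bind_rows(
      common_head,
      def("file", "region", "Region"),
      def("file", "section", "Section", TRUE),
      def("file", "latitude", "Latitude"),
      def("file", "longitude", "Longitude"),
      def("file", "formation", "Formation"),
      def("file", "lithology", "Lithology"),
      common_tail,
      def("sample", "sample_id", "Sample name", TRUE),
      def("sample", "level", "Level (m)"),
      def("sample", "zone", "Zone"),
      def("sample", "age", "Age (Ma)"),
      rare_fields
    )
  }
}

#' Construct a SOD document
#'
#' @param file_type `"O"` or `"L"`.
#' @param file_metadata Named list of file-level metadata, keyed by the
#'   `key` column of [sod_field_definitions()] (e.g. `site`, `hole`,
#'   `observer`); `version` and `file_type` are filled automatically.
#' @param samples A data frame with one row per sample, columns keyed as in
#'   the definition's sample block; must include `sample_id`.
#' @param taxa A data frame with `taxon_id`, `genus`, `species` and
#'   optionally `author` columns.
#' @param occurrences A data frame with a `taxon_id` column plus one integer
#'   count column per sample (column names = sample ids), taxa in the same
#'   order as `taxa`.
#' @param version Format version string.
#' @return An object of class `sod_document`.
#' @export
sod_document <- function(file_type, file_metadata = list(), samples,
                         taxa, occurrences, version = "1") {
  if (!file_type %in% c("O", "L")) abort("`file_type` must be 'O' or 'L'.")
  samples <- as_tibble(samples)
  if (!"sample_id" %in% names(samples) || nrow(samples) == 0) {
    abort("`samples` must have a sample_id column and at least one row.")
  }
  taxa <- as_tibble(taxa)
  if (!"author" %in% names(taxa)) taxa$author <- ""
  occurrences <- as_tibble(occurrences)
  # normalize against the field definition: every defined field is present
  # (empty when unset) and in definition order, so written grids are stable
  definition <- sod_field_definitions(file_type, version)
  file_metadata$version <- version
  file_metadata$file_type <- file_type
  file_keys <- definition$key[definition$block == "file"]
  for (k in setdiff(file_keys, names(file_metadata))) file_metadata[[k]] <- ""
  file_metadata <- file_metadata[c(file_keys,
                                   setdiff(names(file_metadata), file_keys))]
  sample_keys <- definition$key[definition$block == "sample"]
  for (k in setdiff(sample_keys, names(samples))) samples[[k]] <- ""
  samples <- samples[, c(sample_keys,
                         setdiff(names(samples), sample_keys))]
  doc <- structure(
    list(version = version, file_type = file_type,
         file_metadata = file_metadata,
         samples = dplyr::mutate(samples,
                                 dplyr::across(dplyr::everything(),
                                               as.character)),
         taxa = taxa[, c("taxon_id", "genus", "species", "author")],
         occurrences = occurrences),
    class = "sod_document"
  )
  doc
}

#' @export
print.sod_document <- function(x, ...) {
  cat(sprintf("<sod_document v%s type %s: %d taxa x %d sample(s)>\n",
              x$version, x$file_type, nrow(x$taxa), nrow(x$samples)))
  invisible(x)
}

#' Validate a SOD document
#'
#' Checks a document against its field definition and the format's
#' structural invariants, returning findings as data rather than raising:
#' an empty result means the document is valid. Coordinates are 1-based
#' row/column positions in the written grid (spreadsheet convention).
#'
#' @param doc A [sod_document()].
#' @param definition Optional replacement field definition table.
#' @return A tibble of findings with columns `severity` (`"error"` /
#'   `"warning"`), `block`, `label`, `row`, `col`, `message`.
#' @export
validate_sod <- function(doc, definition = NULL) {
  findings <- list()
  add <- function(severity, block, label, row, col, message) {
    findings[[length(findings) + 1]] <<- tibble(
      severity = severity, block = block, label = label,
      row = as.integer(row), col = as.integer(col), message = message
    )
  }
  if (!inherits(doc, "sod_document")) {
    abort("`doc` must be a sod_document.")
  }
  if (!nzchar(doc$version %||% "")) {
    add("error", "A", "SOD version", 1, 2, "Missing format version.")
  }
  if (!doc$file_type %in% c("O", "L")) {
    add("error", "A", "File type", 2, 2,
        sprintf("Unknown file type '%s'.", doc$file_type))
  }
  definition <- definition %||% sod_field_definitions(doc$file_type,
                                                      doc$version)
  file_def <- definition[definition$block == "file", ]
  sample_def <- definition[definition$block == "sample", ]
  layout <- sod_layout(doc, definition)

  for (i in seq_len(nrow(file_def))) {
    key <- file_def$key[[i]]
    val <- doc$file_metadata[[key]]
    if (file_def$required[[i]] && !nzchar(as.character(val %||% ""))) {
      add("error", "A", file_def$label[[i]], i, 2,
          sprintf("Required file field '%s' is empty.", file_def$label[[i]]))
    }
  }
  unknown_file <- setdiff(names(doc$file_metadata), file_def$key)
  for (key in unknown_file) {
    add("warning", "A", key, NA, NA,
        sprintf("File field '%s' is not in the v%s definition.",
                key, doc$version))
  }
  for (i in seq_len(nrow(sample_def))) {
    key <- sample_def$key[[i]]
    if (sample_def$required[[i]]) {
      vals <- doc$samples[[key]]
      if (is.null(vals) || any(!nzchar(as.character(vals)))) {
        add("error", "B", sample_def$label[[i]], i, layout$value_col0 + 1,
            sprintf("Required sample field '%s' is empty.",
                    sample_def$label[[i]]))
      }
    }
  }
  unknown_sample <- setdiff(names(doc$samples), sample_def$key)
  for (key in unknown_sample) {
    add("warning", "B", key, NA, NA,
        sprintf("Sample field '%s' is not in the v%s definition.",
                key, doc$version))
  }

  occ <- doc$occurrences
  sample_ids <- doc$samples$sample_id
  if (!"taxon_id" %in% names(occ) ||
      !setequal(setdiff(names(occ), "taxon_id"), sample_ids) ||
      nrow(occ) != nrow(doc$taxa) ||
      !identical(occ$taxon_id, doc$taxa$taxon_id)) {
    add("error", "D", "occurrences", layout$header_row, layout$value_col0,
        "Occurrence matrix does not match taxa rows x sample columns.")
  } else {
    for (sid in sample_ids) {
      v <- occ[[sid]]
      bad <- which(!is.finite(v) | v < 0)
      for (b in bad) {
        add("error", "D", sid, layout$header_row + b,
            layout$value_col0 + match(sid, sample_ids),
            sprintf("Negative or non-finite count for taxon '%s'.",
                    occ$taxon_id[[b]]))
      }
    }
  }
  if (length(findings)) dplyr::bind_rows(findings) else {
    tibble(severity = character(), block = character(), label = character(),
           row = integer(), col = integer(), message = character())
  }
}

# Grid geometry for a document: where each block lands in the written file.
sod_layout <- function(doc, definition) {
  n_file <- sum(definition$block == "file")
  n_sample <- sum(definition$block == "sample")
  header_row <- max(n_file, n_sample) + 2  # one blank separator row
  list(
    n_file = n_file, n_sample = n_sample,
    header_row = header_row,
    label_col = 4,      # block B label column
    value_col0 = 4      # sample values start at value_col0 + 1
  )
}

#' Write a SOD document to a tab-text file
#'
#' Lays the document out as the four-block grid: file metadata upper-left,
#' per-sample metadata upper-right, taxa name parts lower-left, occurrence
#' counts lower-right, with the format version in the first metadata field.
#' A single sample per file is the native output of a counting session, but
#' sample columns may repeat indefinitely to the right.
#'
#' @param doc A [sod_document()].
#' @param path Output path.
#' @param definition Optional replacement field definition table.
#' @return `path`, invisibly. Errors if [validate_sod()] reports any
#'   error-severity finding.
#' @export
write_sod <- function(doc, path, definition = NULL) {
  definition <- definition %||% sod_field_definitions(doc$file_type,
                                                      doc$version)
  findings <- validate_sod(doc, definition)
  errs <- findings[findings$severity == "error", ]
  if (nrow(errs)) {
    abort(paste0("Refusing to write an invalid SOD document:\n",
                 paste("-", errs$message, collapse = "\n")))
  }
  file_def <- definition[definition$block == "file", ]
  sample_def <- definition[definition$block == "sample", ]
  lay <- sod_layout(doc, definition)
  n_samples <- nrow(doc$samples)
  width <- lay$value_col0 + n_samples
  grid <- matrix("", nrow = lay$header_row + nrow(doc$taxa), ncol = width)

  for (i in seq_len(nrow(file_def))) {
    grid[i, 1] <- file_def$label[[i]]
    grid[i, 2] <- as.character(doc$file_metadata[[file_def$key[[i]]]] %||% "")
  }
  for (i in seq_len(nrow(sample_def))) {
    key <- sample_def$key[[i]]
    grid[i, lay$label_col] <- sample_def$label[[i]]
    vals <- doc$samples[[key]]
    if (is.null(vals)) vals <- rep("", n_samples)
    grid[i, lay$value_col0 + seq_len(n_samples)] <- as.character(vals)
  }
  grid[lay$header_row, seq_along(sod_taxa_labels)] <- sod_taxa_labels
  grid[lay$header_row, lay$label_col] <- sod_counts_label
  grid[lay$header_row, lay$value_col0 + seq_len(n_samples)] <-
    doc$samples$sample_id
  for (t in seq_len(nrow(doc$taxa))) {
    r <- lay$header_row + t
    grid[r, 1:3] <- c(doc$taxa$genus[[t]], doc$taxa$species[[t]],
                      doc$taxa$author[[t]])
    for (s in seq_len(n_samples)) {
      grid[r, lay$value_col0 + s] <-
        as.character(doc$occurrences[[doc$samples$sample_id[[s]]]][[t]])
    }
  }
  lines <- apply(grid, 1, paste, collapse = "\t")
  writeLines(sub("\t+$", "", lines), path, useBytes = TRUE)
  invisible(path)
}

#' Read a SOD file
#'
#' Parses a four-block SOD grid back into a [sod_document()]. The file type
#' and version are taken from the first metadata fields and used to select
#' the field definition; labels in the file are matched against it, with
#' unknown labels preserved (and reported by [validate_sod()] as warnings).
#' `read_sod(write_sod(doc))` reproduces `doc` field-for-field with counts
#' bit-exact.
#'
#' @param path Path to a SOD tab-text file.
#' @param definition Optional replacement field definition table.
#' @return A [sod_document()].
#' @export
read_sod <- function(path, definition = NULL) {
  if (!file.exists(path)) abort(sprintf("No such file: '%s'.", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(r, c) {
    row <- if (r <= length(cells)) cells[[r]] else character()
    if (c <= length(row)) trimws(row[[c]]) else ""
  }
  header_row <- which(vapply(seq_along(cells), function(r) {
    identical(get(r, 1), sod_taxa_labels[[1]])
  }, logical(1)))
  if (length(header_row) != 1) {
    abort(sprintf(
      "'%s': expected exactly one taxa header row starting with '%s' in column 1; found %d.",
      path, sod_taxa_labels[[1]], length(header_row)))
  }
  if (!identical(get(header_row, 2), sod_taxa_labels[[2]]) ||
      !identical(get(header_row, 3), sod_taxa_labels[[3]])) {
    abort(sprintf(
      "'%s': taxa header labels at row %d, columns 2-3 must be '%s', '%s' (found '%s', '%s').",
      path, header_row, sod_taxa_labels[[2]], sod_taxa_labels[[3]],
      get(header_row, 2), get(header_row, 3)))
  }
  if (!identical(get(header_row, 4), sod_counts_label)) {
    abort(sprintf(
      "'%s': expected counts label '%s' at row %d, column 4 (found '%s').",
      path, sod_counts_label, header_row, get(header_row, 4)))
  }
  header <- cells[[header_row]]
  sample_ids <- trimws(header[-(1:4)])
  sample_ids <- sample_ids[nzchar(sample_ids)]
  n_samples <- length(sample_ids)
  if (n_samples == 0) abort(sprintf("'%s': no sample columns found.", path))

  # blocks A and B live above the header row
  file_meta_raw <- list()
  sample_meta_raw <- list()
  for (r in seq_len(header_row - 1)) {
    lab_a <- get(r, 1)
    if (nzchar(lab_a)) file_meta_raw[[lab_a]] <- get(r, 2)
    lab_b <- get(r, 4)
    if (nzchar(lab_b)) {
      sample_meta_raw[[lab_b]] <- vapply(seq_len(n_samples),
                                         function(s) get(r, 4 + s),
                                         character(1))
    }
  }
  version <- file_meta_raw[["SOD version"]] %||% ""
  file_type <- file_meta_raw[["File type"]] %||% ""
  if (!nzchar(version)) {
    abort(sprintf("'%s': missing 'SOD version' in block A (row 1, column 1).",
                  path))
  }
  if (!file_type %in% c("O", "L")) {
    abort(sprintf("'%s': unrecognized file type '%s' (expected O or L).",
                  path, file_type))
  }
  definition <- definition %||% sod_field_definitions(file_type, version)
  label_to_key <- function(block, labels) {
    d <- definition[definition$block == block, ]
    keys <- d$key[match(labels, d$label)]
    ifelse(is.na(keys), labels, keys)
  }
  file_metadata <- setNames(file_meta_raw,
                            label_to_key("file", names(file_meta_raw)))
  samples <- as_tibble(setNames(sample_meta_raw,
                                label_to_key("sample",
                                             names(sample_meta_raw))))
  if (!"sample_id" %in% names(samples)) {
    abort(sprintf("'%s': block B has no sample identifier row.", path))
  }
  if (!identical(unname(samples$sample_id), unname(sample_ids))) {
    abort(sprintf(
      "'%s': sample ids in block B do not match the count column labels at row %d.",
      path, header_row))
  }

  taxa_rows <- seq(header_row + 1, length(cells))
  taxa_rows <- taxa_rows[vapply(taxa_rows,
                                function(r) nzchar(get(r, 1)), logical(1))]
  genus <- vapply(taxa_rows, function(r) get(r, 1), character(1))
  species <- vapply(taxa_rows, function(r) get(r, 2), character(1))
  author <- vapply(taxa_rows, function(r) get(r, 3), character(1))
  taxon_id <- trimws(gsub("[[:space:]]+", " ", paste(genus, species)))
  counts <- lapply(seq_len(n_samples), function(s) {
    vals <- vapply(taxa_rows, function(r) get(r, 4 + s), character(1))
    if (any(!nzchar(vals))) {
      abort(sprintf(
        "'%s': ragged occurrence block — empty count cell at row %d, column %d.",
        path, taxa_rows[which(!nzchar(vals))[[1]]], 4 + s))
    }
    num <- suppressWarnings(as.numeric(vals))
    if (anyNA(num)) {
      abort(sprintf("'%s': non-numeric count '%s' at row %d, column %d.",
                    path, vals[is.na(num)][[1]],
                    taxa_rows[which(is.na(num))[[1]]], 4 + s))
    }
    if (all(num == floor(num))) as.integer(num) else num
  })
  occurrences <- tibble(taxon_id = taxon_id)
  for (s in seq_len(n_samples)) occurrences[[sample_ids[[s]]]] <- counts[[s]]

  sod_document(
    file_type = file_type,
    file_metadata = file_metadata[setdiff(names(file_metadata),
                                          c("version", "file_type"))],
    samples = samples,
    taxa = tibble(taxon_id = taxon_id, genus = genus, species = species,
                  author = author),
    occurrences = occurrences,
    version = version
  )
}

#' Convert a completed counting session to a SOD document
#'
#' Stores the raw per-taxon totals as counts (block D stays raw and
#' integer), and records the per-phase track counters, the exclusion
#' threshold and the excluded taxa in the sample metadata, so the
#' effort-scaled combined estimates are recomputable from the file alone
#' (see [sod_estimates()]).
#'
#' @param session A completed [count_session].
#' @param metadata Named list with `file_type` (`"O"` or `"L"`), file-level
#'   fields (e.g. `site`, `hole` for O; `section` for L), and sample-level
#'   fields (at least `sample_id`). Session metadata is consulted for
#'   `observer`, `date`, `fossil_group`, `sample_id` when not given here.
#' @return A validated [sod_document()] with one sample column.
#' @export
session_to_sod <- function(session, metadata = list()) {
  check_session(session)
  meta <- modifyList(session$metadata, metadata)
  file_type <- meta$file_type %||% "O"
  definition <- sod_field_definitions(file_type)
  file_keys <- definition$key[definition$block == "file"]
  sample_keys <- definition$key[definition$block == "sample"]
  file_metadata <- meta[intersect(names(meta), file_keys)]
  sample_id <- as.character(meta$sample_id %||% "")
  if (!nzchar(sample_id)) {
    abort("A sample_id is required to write a SOD file.")
  }
  tal <- tally(session)
  samples <- tibble(sample_id = sample_id)
  for (key in setdiff(sample_keys, "sample_id")) {
    val <- switch(key,
      tracks_full = session$tracks_full,
      tracks_rare = session$tracks_rare,
      threshold = if (is.na(session$threshold)) "" else session$threshold,
      excluded_taxa = paste(session$exclusions, collapse = "; "),
      meta[[key]] %||% ""
    )
    samples[[key]] <- as.character(val)
  }
  occurrences <- tibble(taxon_id = tal$taxon_id)
  occurrences[[sample_id]] <- as.integer(tal$n_total)
  taxa <- tibble(
    taxon_id = session$taxa$taxon_id,
    genus = session$taxa$genus, species = session$taxa$species,
    author = ""
  )
  doc <- sod_document(file_type, file_metadata, samples, taxa, occurrences)
  findings <- validate_sod(doc, definition)
  errs <- findings[findings$severity == "error", ]
  if (nrow(errs)) {
    abort(paste0("Session metadata incomplete for SOD ", file_type,
                 " output:\n", paste("-", errs$message, collapse = "\n")))
  }
  doc
}

#' Recompute effort-scaled abundance estimates from a SOD document
#'
#' Uses only information stored in the file — raw totals, excluded-taxa
#' list, per-phase track counters — to reproduce the combined estimates of
#' [combined_estimates()]. This is the recomputability guarantee of the
#' format: nothing about the estimate lives outside the saved data.
#'
#' @param doc A [sod_document()] written by [session_to_sod()].
#' @param sample Sample id; defaults to the document's only sample.
#' @return A tibble like [combined_estimates()]'s.
#' @export
sod_estimates <- function(doc, sample = NULL) {
  sample <- sample %||% doc$samples$sample_id[[1]]
  row <- doc$samples[doc$samples$sample_id == sample, ]
  if (nrow(row) != 1) abort(sprintf("No sample '%s' in document.", sample))
  excl_raw <- row$excluded_taxa %||% ""
  exclusions <- trimws(strsplit(excl_raw, ";", fixed = TRUE)[[1]])
  exclusions <- exclusions[nzchar(exclusions)]
  tracks_full <- as.numeric(row$tracks_full %||% 0)
  tracks_rare <- as.numeric(row$tracks_rare %||% 0)
  # excluded taxa were never counted in rare mode, so their stored total is
  # pure full-phase count; non-excluded totals enter the estimator as-is
  tal <- tibble(taxon_id = doc$occurrences$taxon_id,
                n_full = as.numeric(doc$occurrences[[sample]]),
                n_rare = 0)
  combine_counts(tal, exclusions, tracks_full, tracks_rare)
}

#' Flatten a SOD document to a tidy long table
#'
#' @param doc A [sod_document()].
#' @param drop_zero If `TRUE`, zero-count rows are dropped (sparse policy);
#'   the default keeps the dense taxa-by-samples product.
#' @return A tibble with columns `sample`, `taxon_id`, `genus`, `species`,
#'   `count`; lossless with respect to counts under the dense policy.
#' @export
sod_to_long <- function(doc, drop_zero = FALSE) {
  long <- doc$occurrences |>
    tidyr::pivot_longer(-"taxon_id", names_to = "sample",
                        values_to = "count") |>
    dplyr::left_join(doc$taxa[, c("taxon_id", "genus", "species")],
                     by = "taxon_id") |>
    dplyr::select("sample", "taxon_id", "genus", "species", "count") |>
    dplyr::arrange(match(.data$sample, doc$samples$sample_id))
  if (drop_zero) long <- dplyr::filter(long, .data$count != 0)
  long
}
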