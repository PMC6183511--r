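#' Create a counting session
#'
#' A `count_session` is the event-sourced state of one sample's count. Every
#' user action — counting a specimen, scanning a track, entering rare mode,
#' adding a taxon on the fly — is appended to an ordered action log, and the
#' whole session state is a pure function of the initial taxa list plus that
#' log ([replay_session()] reproduces it exactly). This is what makes undo,
#' checkpoint/resume and post-hoc auditing safe.
#'
#' @param taxa A data frame of countable taxa with at least a `taxon_id`
#'   column (normally from [read_taxa_config()], which also supplies `genus`,
#'   `species`, `button`, `button_label`, `category`).
#' @param metadata Named list of sample metadata (observer, date, fossil
#'   group, sample identification, ...).
#'
#' @return An object of class `count_session`.
#' @export
count_session <- function(taxa, metadata = list()) {
  taxa <- normalize_taxa(taxa)
  structure(
    list(
      metadata = metadata,
      taxa = taxa,
      log = list(),           # ordered action records
      mode = "full",
      exclusions = character(),
      threshold = NA_real_,   # recorded at rare-mode entry, for provenance
      tracks_full = 0L,
      tracks_rare = 0L,
      format_version = "1"
    ),
    class = "count_session"
  )
}

normalize_taxa <- function(taxa) {
  if (!is.data.frame(taxa) || !"taxon_id" %in% names(taxa)) {
    abort("`taxa` must be a data frame with a `taxon_id` column.")
  }
  defaults <- list(genus = "", species = "", button = FALSE,
                   button_label = "", category = "")
  for (nm in names(defaults)) {
    if (!nm %in% names(taxa)) taxa[[nm]] <- defaults[[nm]]
  }
  if (anyDuplicated(taxa$taxon_id)) abort("Duplicate taxon_id in taxa list.")
  as_tibble(taxa)[, c("taxon_id", names(defaults))]
}

#' @export
print.count_session <- function(x, ...) {
  tal <- tally(x)
  cat(sprintf(
    "<count_session: %d taxa, %d events (%d full / %d rare), mode=%s, tracks %d+%d>\n",
    nrow(x$taxa), sum(tal$n_full) + sum(tal$n_rare), sum(tal$n_full),
    sum(tal$n_rare), x$mode, x$tracks_full, x$tracks_rare
  ))
  if (length(x$exclusions)) {
    cat("  excluded in rare mode:", paste(x$exclusions, collapse = ", "), "\n")
  }
  invisible(x)
}

append_action <- function(session, action) {
  action$seq <- length(session$log) + 1L
  session$log[[action$seq]] <- action
  session
}

#' Record one counted specimen
#'
#' Appends a count event for `taxon_id` in the session's current phase.
#' In rare mode, counting a taxon that was excluded at the mode switch is a
#' hard error (`raricount_rare_mode_violation`) — the equivalent of that
#' taxon's button being greyed out — so excluded taxa can never contaminate
#' the rare-phase record.
#'
#' @param session A [count_session].
#' @param taxon_id Identifier of the counted taxon; must be in the session's
#'   taxa list.
#' @return The updated session.
#' @export
record_count <- function(session, taxon_id) {
  check_session(session)
  if (!taxon_id %in% session$taxa$taxon_id) {
    abort(sprintf("Unknown taxon '%s'.", taxon_id),
          class = "raricount_unknown_taxon")
  }
  if (session$mode == "rare" && taxon_id %in% session$exclusions) {
    abort(sprintf("Taxon '%s' is excluded in rare count mode.", taxon_id),
          class = "raricount_rare_mode_violation")
  }
  append_action(session, list(type = "count", taxon_id = taxon_id,
                              phase = session$mode))
}

#' Record one track of observational effort
#'
#' Increments the track counter of the current phase. Tracks are the unit of
#' effort that later allows full- and rare-phase counts to be combined.
#'
#' @param session A [count_session].
#' @return The updated session.
#' @export
increment_track <- function(session) {
  check_session(session)
  session <- append_action(session, list(type = "track", phase = session$mode))
  if (session$mode == "full") {
    session$tracks_full <- session$tracks_full + 1L
  } else {
    session$tracks_rare <- session$tracks_rare + 1L
  }
  session
}

#' Undo the most recent action
#'
#' Count events, track increments and on-the-fly taxon additions form a
#' single linear history, and `undo_last()` is the exact inverse of the most
#' recent one. Undo stops at the rare-mode boundary: entering rare mode
#' freezes the exclusion set and cannot be undone.
#'
#' @param session A [count_session].
#' @return The updated session.
#' @export
undo_last <- function(session) {
  check_session(session)
  n <- length(session$log)
  if (n == 0) abort("Nothing to undo: the session has no actions.")
  last <- session$log[[n]]
  if (last$type == "rare_mode") {
    abort("Cannot undo entering rare count mode.")
  }
  if (last$type == "track") {
    if (last$phase == "full") {
      session$tracks_full <- session$tracks_full - 1L
    } else {
      session$tracks_rare <- session$tracks_rare - 1L
    }
  }
  if (last$type == "add_taxon") {
    session$taxa <- session$taxa[session$taxa$taxon_id != last$taxon$taxon_id, ]
  }
  session$log[[n]] <- NULL
  session
}

#' Enter rare count mode
#'
#' Switches the session from full to rare counting. The exclusion set — the
#' common taxa that will no longer be counted — is chosen once, at this
#' moment, from taxa actually seen during the full phase, and is frozen for
#' the rest of the session. Rare mode can be entered at most once.
#'
#' @param session A [count_session] in full mode.
#' @param exclusions Character vector of taxon_ids to stop counting; every
#'   one must have a positive full-phase count. May be empty.
#' @param threshold Optional abundance threshold (share of full-phase
#'   specimens) that produced `exclusions`; stored for provenance so output
#'   files are self-describing.
#' @return The updated session, in rare mode.
#' @export
enter_rare_mode <- function(session, exclusions = character(),
                            threshold = NA_real_) {
  check_session(session)
  if (session$mode == "rare") {
    abort("Rare mode can be entered only once per session.")
  }
  exclusions <- unique(as.character(exclusions))
  if (length(exclusions)) {
    tal <- tally(session)
    seen <- tal$taxon_id[tal$n_full > 0]
    bad <- setdiff(exclusions, seen)
    if (length(bad)) {
      abort(sprintf("Cannot exclude taxa never seen in full mode: %s.",
                    paste(bad, collapse = ", ")))
    }
  }
  session <- append_action(session, list(type = "rare_mode",
                                         exclusions = exclusions,
                                         threshold = threshold))
  session$mode <- "rare"
  session$exclusions <- exclusions
  session$threshold <- threshold
  session
}

#' Add a taxon to the counting list on the fly
#'
#' Registers a taxon not present in the configuration file so it can be
#' counted immediately — a routine event when an unexpected species turns up
#' mid-count. A taxon added during rare mode is countable (it is never in
#' the frozen exclusion set).
#'
#' @param session A [count_session].
#' @param taxon A one-row data frame (or named list) with at least
#'   `taxon_id`; `genus`, `species`, `button`, `button_label`, `category`
#'   are filled with defaults when absent.
#' @return The updated session.
#' @export
add_taxon <- function(session, taxon) {
  check_session(session)
  if (!is.data.frame(taxon)) taxon <- as_tibble(taxon[!vapply(taxon, is.null, TRUE)])
  taxon <- normalize_taxa(taxon)
  if (nrow(taxon) != 1) abort("`taxon` must describe exactly one taxon.")
  if (taxon$taxon_id %in% session$taxa$taxon_id) {
    abort(sprintf("Taxon '%s' already present.", taxon$taxon_id))
  }
  session <- append_action(session, list(type = "add_taxon",
                                         taxon = as.list(taxon)))
  session$taxa <- dplyr::bind_rows(session$taxa, taxon)
  session
}

#' Events of a session
#'
#' @param session A [count_session].
#' @return A tibble with one row per count event: `seq` (1-based event
#'   number), `taxon_id`, `phase` (`"full"` or `"rare"`).
#' @export
session_events <- function(session) {
  check_session(session)
  counts <- purrr::keep(session$log, ~ .x$type == "count")
  tibble(
    seq = seq_along(counts),
    taxon_id = purrr::map_chr(counts, "taxon_id"),
    phase = purrr::map_chr(counts, "phase")
  )
}

#' Tally a session's counts per taxon and phase
#'
#' @param session A [count_session].
#' @return A tibble with one row per taxon in the session's list (zeros
#'   included): `taxon_id`, `n_full`, `n_rare`, `n_total`, `excluded`.
#' @export
tally <- function(session) {
  check_session(session)
  ev <- session_events(session)
  base <- tibble(taxon_id = session$taxa$taxon_id)
  wide <- ev |>
    dplyr::count(.data$taxon_id, .data$phase) |>
    tidyr::pivot_wider(names_from = "phase", values_from = "n",
                       values_fill = 0L)
  for (col in c("full", "rare")) {
    if (!col %in% names(wide)) wide[[col]] <- 0L
  }
  base |>
    dplyr::left_join(wide, by = "taxon_id") |>
    dplyr::mutate(
      n_full = dplyr::coalesce(.data$full, 0L),
      n_rare = dplyr::coalesce(.data$rare, 0L),
      n_total = .data$n_full + .data$n_rare,
      excluded = .data$taxon_id %in% session$exclusions
    ) |>
    dplyr::select("taxon_id", "n_full", "n_rare", "n_total", "excluded")
}

#' Replay a session's action log from scratch
#'
#' Rebuilds the session state by applying the action log to a fresh session
#' with the same initial taxa list and metadata. Because the session is
#' event-sourced, `replay_session(session)` is identical to `session`; the
#' function exists for integrity checks and for replaying logs saved by the
#' interactive interface.
#'
#' @param session A [count_session], or a list with `taxa`, `metadata` and
#'   `log` entries.
#' @return A reconstructed [count_session].
#' @export
replay_session <- function(session) {
  initial_taxa <- session$taxa
  added <- purrr::keep(session$log, ~ .x$type == "add_taxon")
  for (a in added) {
    initial_taxa <- initial_taxa[initial_taxa$taxon_id != a$taxon$taxon_id, ]
  }
  out <- count_session(initial_taxa, metadata = session$metadata)
  for (action in session$log) {
    out <- switch(action$type,
      count = record_count(out, action$taxon_id),
      track = increment_track(out),
      rare_mode = enter_rare_mode(out, action$exclusions, action$threshold),
      add_taxon = add_taxon(out, action$taxon),
      abort(sprintf("Unknown action type '%s' in log.", action$type))
    )
  }
  out
}

check_session <- function(session) {
  if (!inherits(session, "count_session")) {
    abort("Expected a `count_session` object.")
  }
  invisible(session)
}

#' Save a partial count to a checkpoint file
#'
#' Checkpoints use a versioned JSON-based structured-text format meant only
#' for internal save/resume use — deliberately not the SOD output format,
#' which is reserved for completed, validated counts.
#'
#' @param session A [count_session].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @seealso [resume_session()]
#' @export
checkpoint_session <- function(session, path) {
  check_session(session)
  payload <- list(
    format = "raricount-checkpoint",
    format_version = session$format_version,
    metadata = session$metadata,
    taxa = session$taxa,
    log = session$log
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Resume a session from a checkpoint file
#'
#' Restores the exact session state — event order, counting mode, frozen
#' exclusions, track counters — so counting continues where it stopped.
#'
#' @param path Checkpoint file written by [checkpoint_session()].
#' @return A [count_session].
#' @export
resume_session <- function(path) {
  if (!file.exists(path)) abort(sprintf("Checkpoint '%s' does not exist.", path))
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) abort(sprintf("Corrupt checkpoint '%s': %s",
                                      path, conditionMessage(e)))
  )
  if (!identical(payload$format, "raricount-checkpoint")) {
    abort(sprintf("'%s' is not a raricount checkpoint.", path))
  }
  if (!identical(as.character(payload$format_version), "1")) {
    abort(sprintf("Unsupported checkpoint version '%s'.",
                  payload$format_version))
  }
  taxa <- dplyr::bind_rows(purrr::map(payload$taxa, as_tibble)) |>
    dplyr::mutate(button = as.logical(.data$button))
  log <- purrr::map(payload$log, function(a) {
    a$seq <- as.integer(a$seq)
    if (a$type == "rare_mode") {
      a$exclusions <- as.character(unlist(a$exclusions))
      a$threshold <- if (is.null(a$threshold)) NA_real_ else as.numeric(a$threshold)
    }
    if (a$type == "add_taxon") {
      a$taxon <- purrr::map(a$taxon, ~ .x %||% NA)
      a$taxon$button <- as.logical(a$taxon$button)
    }
    a
  })
  skeleton <- list(taxa = taxa, metadata = payload$metadata, log = log)
  replay_session(skeleton)
}
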