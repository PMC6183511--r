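make_demo_doc <- function(file_type = "O", n_samples = 1) {
  taxa <- tibble::tibble(
    taxon_id = c("Antarctissa strelkovi", "Antarctissa denticulata",
                 "Lithomelissa setosa"),
    genus = c("Antarctissa", "Antarctissa", "Lithomelissa"),
    species = c("strelkovi", "denticulata", "setosa"),
    author = c("Petrushevskaya", "", "Jorgensen")
  )
  ids <- paste0("751A-6H-", seq_len(n_samples))
  samples <- tibble::tibble(sample_id = ids)
  occ <- tibble::tibble(taxon_id = taxa$taxon_id)
  for (i in seq_len(n_samples)) occ[[ids[[i]]]] <- c(120L, 80L, 3L) + i
  meta <- if (file_type == "O") {
    list(site = "751", hole = "A", leg = "120", latitude = "-57.7",
         observer = "tester", fossil_group = "radiolarians")
  } else {
    list(region = "Apennines", section = "Contessa", formation = "Scaglia",
         lithology = "limestone", observer = "tester")
  }
  sod_document(file_type, meta, samples, taxa, occ)
}

test_that("SOD write-read round-trips bit-exactly", {
  for (ft in c("O", "L")) {
    doc <- make_demo_doc(ft)
    path <- tempfile(fileext = ".sod")
    write_sod(doc, path)
    back <- read_sod(path)
    expect_identical(back$file_type, ft)
    expect_identical(back$version, "1")
    expect_identical(back$occurrences, doc$occurrences)
    expect_identical(back$taxa, doc$taxa)
    expect_identical(back$samples, doc$samples)
    expect_identical(
      lapply(back$file_metadata, as.character)[names(doc$file_metadata)],
      lapply(doc$file_metadata, as.character)
    )
  }
})

test_that("multi-sample columns repeat indefinitely to the right", {
  doc <- make_demo_doc("O", n_samples = 3)
  path <- tempfile(fileext = ".sod")
  write_sod(doc, path)
  back <- read_sod(path)
  expect_equal(nrow(back$samples), 3)
  expect_identical(back$occurrences, doc$occurrences)

  long <- sod_to_long(back)
  expect_equal(nrow(long), 9)   # dense: 3 taxa x 3 samples
})

test_that("the written grid is self-describing: every value has a label", {
  doc <- make_demo_doc("O")
  path <- tempfile(fileext = ".sod")
  write_sod(doc, path)
  cells <- strsplit(readLines(path), "\t", fixed = TRUE)
  cell1 <- vapply(cells, function(r) if (length(r)) r[[1]] else "",
                  character(1))
  header_row <- which(cell1 == "Genus")
  # above the header: col-2 values labelled in col 1, col-5+ values in col 4
  for (r in seq_len(header_row - 1)) {
    row <- cells[[r]]
    if (length(row) >= 2 && nzchar(row[[2]])) expect_true(nzchar(row[[1]]))
    if (length(row) >= 5 && any(nzchar(row[5:length(row)]))) {
      expect_true(nzchar(row[[4]]))
    }
  }
  # below: every count column is labelled by its sample id in the header row
  header <- cells[[header_row]]
  expect_true(all(nzchar(header[5:length(header)])))
})

test_that("validation reports findings as data with coordinates", {
  doc <- make_demo_doc("O")
  expect_equal(nrow(validate_sod(doc)), 0)

  neg <- doc
  neg$occurrences[[neg$samples$sample_id[[1]]]][2] <- -5L
  f <- validate_sod(neg)
  expect_true(any(f$severity == "error" & f$block == "D"))
  expect_true(all(is.finite(f$row)))
  expect_error(write_sod(neg, tempfile()), "invalid")

  # missing required field refuses to write
  nover <- doc
  nover$file_metadata$site <- ""
  expect_error(write_sod(nover, tempfile()), "Site")

  # unknown label is a warning, not an error
  extra <- make_demo_doc("O")
  extra$file_metadata$cruise_ship <- "JOIDES"
  f2 <- validate_sod(extra)
  expect_true(any(f2$severity == "warning"))
  expect_false(any(f2$severity == "error"))
})

test_that("dialect-specific fields are enforced", {
  # O files need site/hole; L files need a section
  o <- make_demo_doc("O")
  o$file_metadata$hole <- ""
  expect_true(any(grepl("Hole", validate_sod(o)$message)))

  l <- make_demo_doc("L")
  expect_equal(nrow(validate_sod(l)), 0)
  l$file_metadata$section <- ""
  expect_true(any(grepl("Section", validate_sod(l)$message)))

  # L-type carries formation/lithology labels in its grid
  path <- tempfile(fileext = ".sod")
  write_sod(make_demo_doc("L"), path)
  txt <- readLines(path)
  expect_true(any(grepl("^Formation\t", txt)))
  expect_true(any(grepl("^Lithology\t", txt)))
})

test_that("malformed grids produce informative errors naming the cell", {
  doc <- make_demo_doc("O")
  path <- tempfile(fileext = ".sod")
  write_sod(doc, path)

  lines <- readLines(path)
  shuffled <- sub("^Genus\tSpecies", "Species\tGenus", lines)
  p2 <- tempfile(); writeLines(shuffled, p2)
  expect_error(read_sod(p2), "header|column 1")

  ragged <- lines
  i <- grep("^Lithomelissa", ragged)
  ragged[i] <- sub("\t[0-9]+$", "\t", ragged[i])
  p3 <- tempfile(); writeLines(ragged, p3)
  expect_error(read_sod(p3), "row [0-9]+, column [0-9]+")

  noversion <- sub("^SOD version\t1", "SOD version\t", lines)
  p4 <- tempfile(); writeLines(noversion, p4)
  expect_error(read_sod(p4), "version")

  expect_error(read_sod(tempfile()), "No such file")
})

test_that("sessions convert to SOD with estimates recomputable from the file", {
  s <- simulate_session(uneven_assemblage(), 600, threshold = 0.05,
                        rare_tracks = 12, specimens_per_track = 100,
                        seed = 31)
  doc <- session_to_sod(s, metadata = demo_sod_metadata())
  expect_equal(nrow(doc$occurrences), nrow(s$taxa))
  expect_equal(doc$samples$tracks_full, "6")
  expect_equal(doc$samples$tracks_rare, "12")

  path <- tempfile(fileext = ".sod")
  write_sod(doc, path)
  from_file <- sod_estimates(read_sod(path))
  in_memory <- combined_estimates(s)
  m <- match(in_memory$taxon_id, from_file$taxon_id)
  expect_lt(max(abs(from_file$estimated_count[m] -
                    in_memory$estimated_count)), 1e-9)
  expect_lt(max(abs(from_file$proportion[m] - in_memory$proportion)), 1e-9)

  # O-type without site/hole refuses to convert
  expect_error(
    session_to_sod(s, metadata = list(file_type = "O",
                                      sample_id = "x")),
    "Site|Hole"
  )
})

test_that("long-format conversion is lossless and policy-aware", {
  doc <- make_demo_doc("O", n_samples = 2)
  doc$occurrences[[doc$samples$sample_id[[1]]]][3] <- 0L
  dense <- sod_to_long(doc)
  expect_equal(nrow(dense), 6)
  sparse <- sod_to_long(doc, drop_zero = TRUE)
  expect_equal(nrow(sparse), 5)
  expect_true(all(sparse$count != 0))
  # dense counts reproduce the matrix
  wide <- tidyr::pivot_wider(dense[, c("sample", "taxon_id", "count")],
                             names_from = "sample", values_from = "count")
  expect_equal(wide[[doc$samples$sample_id[[2]]]],
               doc$occurrences[[doc$samples$sample_id[[2]]]])
})
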