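# Shared fixtures, built in code at test time.

`%||%` <- function(x, y) if (is.null(x)) y else x

# strongly uneven assemblage: 6 common species at 12.5% each (75% total)
# plus 200 equally rare species sharing the remaining 25%
uneven_assemblage <- function() {
  make_abundances("explicit", weights = c(rep(0.125, 6), rep(0.25 / 200, 200)))
}

write_config_fixture <- function(path = tempfile(fileext = ".tsv"),
                                 lines = NULL) {
  lines <- lines %||% c(
    "genus\tspecies\tbutton\tbutton label\tcategory\trecognition name",
    "Antarctissa\tstrelkovi\tyes\tAstr\tPlagiacanthidae\tantarctissa strelkovi",
    "Antarctissa\tdenticulata\tyes\tAden\tPlagiacanthidae\tantarctissa denticulata",
    "Cycladophora\tdavisiana\tyes\tCdav\tTheopiliidae\tcycladophora davisiana",
    "Lithomelissa\tsetosa\tno\t\tPlagiacanthidae\tlithomelissa setosa"
  )
  writeLines(lines, path)
  path
}

demo_taxa <- function(ids = c("A", "B", "C", "D")) {
  tibble::tibble(taxon_id = ids, genus = ids, species = "",
                 button = FALSE, button_label = "", category = "")
}

# session with a scripted history: full phase A,A,A,B,B,C + 2 tracks,
# then rare mode excluding A, rare phase B,C,C + 1 track
demo_session <- function() {
  s <- count_session(demo_taxa())
  for (id in c("A", "A", "A", "B", "B", "C")) s <- record_count(s, id)
  s <- increment_track(s)
  s <- increment_track(s)
  s <- enter_rare_mode(s, "A", threshold = 0.4)
  for (id in c("B", "C", "C")) s <- record_count(s, id)
  s <- increment_track(s)
  s
}

demo_sod_metadata <- function() {
  list(file_type = "O", site = "751", hole = "A", leg = "120",
       observer = "tester", date = "2026-01-01", fossil_group = "radiolarians",
       sample_id = "751A-6H-6, 98-100")
}
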