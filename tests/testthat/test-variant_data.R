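# Parsing, validation and the catalogue-curation rules.

test_that("read_fasta handles empty, toy and malformed inputs", {
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_length(read_fasta(empty), 0L)

  toy <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "MKV", ">P2", "acd", "efg"), toy)
  recs <- read_fasta(toy)
  expect_identical(names(recs), c("P1", "P2"))
  expect_identical(recs$P1$sequence, "MKV")
  expect_identical(recs$P2$sequence, "ACDEFG") # uppercased, joined

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("MKV", ">P1"), bad)
  expect_error(read_fasta(bad), "line 1", class = "savanno_parse")

  noseq <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1", ">P2", "MKV"), noseq)
  expect_error(read_fasta(noseq), "empty sequence", class = "savanno_parse")
})

test_that("fasta write/read round-trips arbitrary record lists", {
  set.seed(7)
  recs <- lapply(1:5, function(i) {
    protein_record(sprintf("Q%d", i),
                   paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                sample(30:200, 1), replace = TRUE), collapse = ""))
  })
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, path)
  back <- read_fasta(path)
  expect_identical(vapply(back, `[[`, "", "sequence"),
                   vapply(protein_map(recs), `[[`, "", "sequence"))
})

test_that("substitution tokens parse identically in both dialects", {
  expect_identical(parse_substitution("A123V"), parse_substitution("p.Ala123Val"))
  expect_identical(parse_substitution("p.Met1Lys"),
                   list(wt = "M", position = 1L, mut = "K"))
  expect_error(parse_substitution("A12"), class = "savanno_parse")
  expect_error(parse_substitution("p.Foo12Bar"), class = "savanno_parse")
})

write_variant_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("accession\tsubstitution\tlabel\tsomatic\tdisease_ids\tsource", lines), path)
  path
}

test_that("read_variant_table validates against the sequence", {
  prot <- list(protein_record("P1", "ACD"))
  ok <- write_variant_lines("P1\tA1V\tPLP\tfalse\tOMIM:1\tCLINVAR")
  v <- read_variant_table(ok, prot)
  expect_identical(v$position, 1L)
  expect_identical(v$wt, "A")
  expect_identical(v$mut, "V")
  expect_identical(v$label, "PLP")

  hgvs <- write_variant_lines("P1\tp.Ala1Val\tPLP\tfalse\tOMIM:1\tCLINVAR")
  expect_identical(read_variant_table(hgvs, prot), read_variant_table(ok, prot))

  mism <- write_variant_lines("P1\tC1V\tPLP\tfalse\t\tOTHER")
  expect_error(read_variant_table(mism, prot), "position 1",
               class = "savanno_wt_mismatch")

  oob <- write_variant_lines("P1\tA9V\tPLP\tfalse\t\tOTHER")
  expect_error(read_variant_table(oob, prot), class = "savanno_position")

  orphan <- write_variant_lines(c("P1\tA1V\tBLB\tfalse\t\tOTHER",
                                  "NOPE\tA1V\tBLB\tfalse\t\tOTHER"))
  v2 <- read_variant_table(orphan, prot)
  expect_identical(nrow(v2), 1L)
  expect_identical(attr(v2, "excluded")$reason, "no_sequence")
  expect_error(read_variant_table(orphan, prot, on_missing = "error"),
               class = "savanno_unknown_accession")
})

test_that("curate applies each exclusion rule once and only once", {
  prots <- toy_proteins()
  # M K V L W A A L L G ; X at P3 position 7
  recs <- as_sav(
    make_variant_row("P1", 1, "M", "K", "PLP", disease = "OMIM:1"),  # kept
    make_variant_row("P1", 2, "K", "R", "PLP"),                      # no_disease_id
    make_variant_row("P1", 3, "V", "I", "BLB"),                      # kept
    make_variant_row("P1", 4, "L", "F", "US"),                       # uncertain
    make_variant_row("P1", 5, "W", "C", "BLB", somatic = TRUE),      # somatic
    make_variant_row("P2", 1, "A", "G", "PLP", disease = "OMIM:2", source = "HUMSAVAR"), # conflict
    make_variant_row("P2", 1, "A", "G", "BLB", source = "CLINVAR"),  # conflict
    make_variant_row("P3", 7, "X", "A", "BLB"),                      # ambiguous_residue
    make_variant_row("ZZ", 1, "M", "K", "BLB"))                      # no_sequence
  cur <- curate(recs, prots)
  expect_identical(nrow(cur$variants), 2L)
  expect_setequal(paste0(cur$variants$wt, cur$variants$position, cur$variants$mut),
                  c("M1K", "V3I"))
  expect_identical(sort(cur$exclusions$reason),
                   sort(c("no_disease_id", "uncertain", "somatic", "conflict",
                          "conflict", "ambiguous_residue", "no_sequence")))
  # conservation: every input either kept or logged
  expect_identical(nrow(cur$variants) + nrow(cur$exclusions), nrow(recs))
  expect_false(any(cur$variants$label == "US"))
})

test_that("concordant duplicates collapse with reason 'duplicate'", {
  prots <- toy_proteins()
  recs <- as_sav(
    make_variant_row("P1", 1, "M", "K", "PLP", disease = "OMIM:1", source = "HUMSAVAR"),
    make_variant_row("P1", 1, "M", "K", "PLP", disease = "OMIM:1", source = "CLINVAR"))
  cur <- curate(recs, prots)
  expect_identical(nrow(cur$variants), 1L)
  expect_identical(cur$exclusions$reason, "duplicate")
})

test_that("curate is idempotent and US never survives (randomised)", {
  set.seed(11)
  prots <- toy_proteins()
  for (rep in 1:10) {
    n <- sample(5:25, 1)
    recs <- do.call(as_sav, lapply(seq_len(n), function(i) {
      acc <- sample(c("P1", "P2"), 1)
      pos <- sample(1:10, 1)
      seqc <- if (acc == "P1") "MKVLWAALLG" else "ACDEFGHIKL"
      wt <- substr(seqc, pos, pos)
      make_variant_row(acc, pos, wt, sample(setdiff(c("A", "K", "V"), wt), 1),
                       label = sample(c("PLP", "BLB", "US"), 1),
                       somatic = sample(c(TRUE, FALSE), 1, prob = c(.2, .8)),
                       disease = sample(c("", "OMIM:9"), 1))
    }))
    cur1 <- curate(recs, prots)
    cur2 <- curate(cur1$variants, prots)
    expect_identical(cur2$variants, cur1$variants)
    expect_identical(nrow(cur2$exclusions), 0L)
    expect_identical(nrow(cur1$variants) + nrow(cur1$exclusions), nrow(recs))
    expect_false(any(cur1$variants$label == "US"))
  }
})

test_that("variant table write/read round-trips", {
  prots <- toy_proteins()
  recs <- as_sav(make_variant_row("P1", 1, "M", "K", "PLP", disease = "OMIM:1;MONDO:5"),
                 make_variant_row("P2", 3, "D", "E", "BLB"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(recs, path)
  back <- read_variant_table(path, prots)
  expect_identical(back$disease_ids, recs$disease_ids)
  expect_identical(back[, c("accession", "position", "wt", "mut", "label")],
                   recs[, c("accession", "position", "wt", "mut", "label")])
})
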