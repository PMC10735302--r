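refs2 <- function() seq_records(c("refA", "refB"),
                                c("MKLVNDAEQW", "HHWYCCPG"),
                                alphabet = "amino_acid")

tab_row <- function(qid = "c1", sid = "refA", sstart = 1, send = 5,
                    qseq = "MKLVN", sseq = "MKLVN", frame = 1,
                    qstart = 1, qend = 15, bit = 25.1, ev = 1e-10)
  paste(qid, sid, "100.0", nchar(qseq), 0, 0, qstart, qend, sstart, send,
        ev, bit, frame, qseq, sseq, sep = "\t")

test_that("parse_tabular reads the 15-column dialect and groups by reference", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", tab_row()), p)
  got <- parse_tabular(p, refs2())
  expect_named(got, "refA")
  r <- got$refA[[1]]
  expect_s3_class(r, "aligned_region")
  expect_equal(r$ref_first, 1L)
  expect_equal(r$ref_last, 5L)
  expect_equal(r$frame, 1L)
  expect_equal(r$bitscore, 25.1)
  expect_equal(r$raw_score,
               score_columns(list(query_gapped = "MKLVN", ref_gapped = "MKLVN"),
                             scoring_scheme()))

  writeLines(c(tab_row(qid = "c1"), tab_row(qid = "c2", sid = "refB",
                                            sstart = 2, send = 5,
                                            qseq = "HWYC", sseq = "HWYC"),
               tab_row(qid = "c3")), p)
  got <- parse_tabular(p, refs2())
  expect_equal(lengths(got), c(refA = 2L, refB = 1L))
})

test_that("parse_tabular rejects malformed rows with informative errors", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(tab_row(sstart = 6, send = 2), p)
  expect_error(parse_tabular(p, refs2()), "row 1")
  writeLines(tab_row(sid = "nope"), p)
  expect_error(parse_tabular(p, refs2()), "unknown reference")
  writeLines(tab_row(sstart = 8, send = 12), p)
  expect_error(parse_tabular(p, refs2()), "exceeds reference length")
  writeLines(paste("c1", "refA", "100", "5", sep = "\t"), p)
  expect_error(parse_tabular(p, refs2()), "mismatch")
  writeLines(character(0), p)
  expect_length(parse_tabular(p, refs2()), 0L)
})

test_that("tabular output round-trips through the parser", {
  fx <- small_fixture(n = 3, seed = 9)
  hits <- builtin_search(fx$contigs, fx$references)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_tabular(hits, p)
  back <- parse_tabular(p, fx$references, queries = fx$contigs)
  flat_a <- unlist(hits, recursive = FALSE)
  flat_b <- unlist(back, recursive = FALSE)
  expect_equal(length(flat_a), length(flat_b))
  key <- function(rs) order(vapply(rs, function(r)
    paste(r$ref_id, r$ref_first, r$query_id, r$frame), character(1)))
  flat_a <- flat_a[key(flat_a)]; flat_b <- flat_b[key(flat_b)]
  for (fld in c("query_id", "ref_id", "query_aa", "ref_aa", "ref_first",
                "ref_last", "frame", "raw_score", "query_first",
                "query_last", "codons"))
    expect_equal(lapply(flat_a, `[[`, fld), lapply(flat_b, `[[`, fld))
  expect_equal(vapply(flat_a, `[[`, numeric(1), "bitscore"),
               vapply(flat_b, `[[`, numeric(1), "bitscore"), tolerance = 0.05)
})

test_that("frameshift characters are treated as unaligned, with a warning", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(tab_row(qseq = "MK/VN", sseq = "MKLVN"), p)
  expect_warning(got <- parse_tabular(p, refs2()), "frameshift")
  r <- got$refA[[1]]
  expect_equal(r$query_aa, "MK-VN")
  expect_equal(r$ref_aa, "MKLVN")
})

test_that("builtin_search finds an exact back-translation on both strands", {
  ref <- seq_records("r1", "MKLVNDAEQWHHWYCCPG", alphabet = "amino_acid")
  bt <- backtranslate <- vapply(strsplit(ref$seq, "")[[1]], function(a) {
    gc <- Biostrings::GENETIC_CODE
    min(names(gc)[gc == a])
  }, character(1))
  nt <- paste(bt, collapse = "")
  q <- seq_records(c("fwd", "rev"), c(nt, revcomp(nt)))
  hits <- builtin_search(q, ref, min_score = 20)
  expect_named(hits, "r1")
  fwd <- Filter(function(r) r$query_id == "fwd", hits$r1)
  rev <- Filter(function(r) r$query_id == "rev", hits$r1)
  for (h in c(fwd, rev)) {
    expect_equal(h$ref_first, 1L)
    expect_equal(h$ref_last, nchar(ref$seq))
    expect_equal(h$query_aa, ref$seq)
  }
  expect_equal(fwd[[1]]$frame, 1L)
  expect_lt(rev[[1]]$frame, 0L)
  # codon provenance reconstructs the coding-strand nucleotides
  expect_equal(paste(rev[[1]]$codons, collapse = ""), nt)
})

test_that("dissimilar queries yield no hits at min_score 30", {
  ref <- seq_records("r1", random_aa(60), alphabet = "amino_acid")
  polyA <- seq_records("pa", strrep("A", 300))
  expect_length(builtin_search(polyA, ref, min_score = 30), 0L)
  # oracle: the best local score over all six frames is itself below 30
  s <- scoring_scheme()
  best <- max(vapply(six_frame_translations(polyA$seq), function(aa)
    if (nchar(aa) < 2) 0 else bf_affine_score(aa, ref$seq, s, "local"),
    numeric(1)))
  expect_lt(best, 30)
})

test_that("emitted raw scores are recomputable from the gapped strings", {
  fx <- small_fixture(n = 4, seed = 21)
  s <- scoring_scheme()
  hits <- builtin_search(fx$contigs, fx$references, s)
  expect_gt(sum(lengths(hits)), 0L)
  for (r in unlist(hits, recursive = FALSE))
    expect_identical(score_columns(list(query_gapped = r$query_aa,
                                        ref_gapped = r$ref_aa), s),
                     r$raw_score)
})

test_that("ground-truth intervals explain every hit on error-free fixtures", {
  fx <- small_fixture(n = 6, seed = 13)
  hits <- builtin_search(fx$contigs, fx$references)
  expect_setequal(names(hits), fx$references$id)
  for (rid in names(hits)) {
    refseq <- fx$references$seq[match(rid, fx$references$id)]
    hit_cov <- integer(0)
    for (h in hits[[rid]]) {
      # error-free data: every aligned column is an identity; intron
      # bridges appear only as insertion columns, never as mismatches
      qc <- strsplit(h$query_aa, "")[[1]]
      rc <- strsplit(h$ref_aa, "")[[1]]
      expect_true(all(rc == "-" | qc == rc),
                  info = paste("hit", h$query_id, rid))
      expect_equal(paste(rc[rc != "-"], collapse = ""),
                   substr(refseq, h$ref_first, h$ref_last))
      rows <- fx$truth[fx$truth$fragment_id == h$query_id &
                       fx$truth$ref_id == rid, , drop = FALSE]
      truth_cov <- unlist(mapply(seq, rows$ref_first, rows$ref_last,
                                 SIMPLIFY = FALSE))
      # hit ends may reach a residue or two past a coding interval only
      # through accidental identities at an anchored terminus
      outside <- setdiff(seq(h$ref_first, h$ref_last), truth_cov)
      expect_lte(length(outside), 5L)
      hit_cov <- c(hit_cov, seq(h$ref_first, h$ref_last))
    }
    # the search recovers every coding position the fragments carry
    truth_all <- fx$truth[fx$truth$ref_id == rid, , drop = FALSE]
    expect_true(all(unlist(mapply(seq, truth_all$ref_first,
                                  truth_all$ref_last,
                                  SIMPLIFY = FALSE)) %in% hit_cov))
  }
})

test_that("the external blastx wrapper finds a planted homolog", {
  fx <- small_fixture(n = 2, seed = 17, intron_count_range = c(0, 0),
                      both_strands = FALSE)
  out <- withr::local_tempdir()
  sr <- run_external_search(fx$paths$contigs, fx$paths$references, out,
                            aligner = "blastx")
  expect_true(file.exists(sr$tabular))
  got <- parse_tabular(sr$tabular, fx$references, queries = fx$contigs)
  expect_gt(sum(lengths(got)), 0L)
  expect_true(all(names(got) %in% fx$references$id))
  expect_true(file.exists(sr$log))
  log1 <- jsonlite::fromJSON(readLines(sr$log)[1])
  expect_true(nzchar(log1$command))

  # empty query file: empty tabular output, no aligner crash
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  sr2 <- run_external_search(empty, fx$paths$references,
                             withr::local_tempdir(), aligner = "blastx")
  expect_length(parse_tabular(sr2$tabular, fx$references), 0L)
})
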