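region_from <- function(qa, ra, from = 1L) {
  rg <- strsplit(ra, "")[[1]]
  aligned_region("q", "ref", qa, ra, from, from + sum(rg != "-") - 1L, 1L,
                 raw_score = score_columns(
                   list(query_gapped = qa, ref_gapped = ra), scoring_scheme()))
}

test_that("masking removes insertions, ambiguous residues and stops", {
  p <- mask_policy()
  expect_setequal(p$ambiguous_set, c("B", "J", "X", "Z"))

  r <- region_from("MKL", "MKL")
  expect_equal(mask_region(r, p)$query_aa, "MKL")

  r <- region_from("MXK", "MLK")
  expect_equal(mask_region(r, p)$query_aa, "M-K")

  r <- region_from("M*K", "MLK")
  expect_equal(mask_region(r, mask_policy(retain_stops = TRUE))$query_aa,
               "M*K")
  expect_equal(mask_region(r, p)$query_aa, "M-K")

  # insertion column dropped, ambiguous residue masked (column-walk case)
  r <- region_from("MABK", "M-LK")
  m <- mask_region(r, p)
  expect_equal(m$query_aa, "M-K")
  expect_equal(m$ref_aa, "MLK")
  expect_equal(m$ref_first, r$ref_first)
  expect_equal(m$ref_last, r$ref_last)

  r <- region_from("MZBK", "MLVK")
  expect_equal(mask_region(r, mask_policy(retain_ambiguous = TRUE))$query_aa,
               "MZBK")
})

test_that("masking is idempotent and leaves a clean alphabet by default", {
  set.seed(41)
  dirty <- c(AA_STD, "B", "J", "X", "Z", "*")
  for (i in 1:25) {
    n <- sample(5:20, 1)
    qa <- paste(sample(dirty, n, TRUE), collapse = "")
    ins <- sample(c(TRUE, FALSE), n, TRUE, prob = c(0.2, 0.8))
    ra <- strsplit(random_aa(n), "")[[1]]
    ra[ins] <- "-"
    if (all(ins)) ra[1] <- "V"
    r <- region_from(qa, paste(ra, collapse = ""))
    m1 <- mask_region(r)
    m2 <- mask_region(m1)
    expect_identical(m2$query_aa, m1$query_aa)
    expect_identical(m2$ref_aa, m1$ref_aa)
    expect_false(grepl("[BJXZ*]", m1$query_aa))
    expect_false(grepl("-", m1$ref_aa, fixed = TRUE))
  }
})

mk_aln <- function(qa, ra, mode = "semiglobal")
  structure(list(query_gapped = qa, ref_gapped = ra,
                 score = score_columns(list(query_gapped = qa, ref_gapped = ra)),
                 mode = mode), class = "pairwise_alignment")

test_that("trimming removes a planted low-identity block and spares flanks", {
  # 20 zero-identity columns flanked by perfect matches, window 10,
  # threshold 0.5. A block column survives only via a window reaching far
  # enough into a flank to dilute the mismatches to <= 0.5, so the five
  # columns adjacent to each flank are protected (the single-bad-match
  # safeguard) while the block interior is cut.
  set.seed(42)
  flank <- random_aa(10)
  mid_ref <- random_aa(20)
  mid_bad <- paste(vapply(strsplit(mid_ref, "")[[1]], function(a)
    sample(setdiff(AA_STD, a), 1), character(1)), collapse = "")
  flank2 <- random_aa(10)
  aln <- mk_aln(paste0(flank, mid_bad, flank2),
                paste0(flank, mid_ref, flank2))
  tp <- trim_policy(window_size = 10, distance_threshold = 0.5)
  tr <- trim_alignment(aln, tp)
  keep <- attr(tr, "kept_query_residues")
  oracle <- trim_oracle_keep(strsplit(aln$query_gapped, "")[[1]],
                             strsplit(aln$ref_gapped, "")[[1]], 10, 0.5)
  expect_equal(keep, oracle)
  expect_equal(substr(tr$query_gapped, 16, 25), strrep("-", 10))
  expect_equal(substr(tr$query_gapped, 1, 10), flank)
  expect_equal(substr(tr$query_gapped, 31, 40), flank2)
  expect_equal(substr(tr$query_gapped, 11, 15), substr(mid_bad, 1, 5))
})

test_that("perfect alignments and threshold 1.0 are never trimmed", {
  set.seed(43)
  q <- random_aa(40)
  aln <- mk_aln(q, q)
  expect_equal(trim_alignment(aln, trim_policy())$query_gapped, q)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    qa <- random_aa(n)
    ra <- paste(ifelse(runif(n) < 0.3, "-",
                       strsplit(random_aa(n), "")[[1]]), collapse = "")
    if (!grepl("[A-Z]", ra)) ra <- sub("-", "W", ra)
    aln <- mk_aln(qa, ra)
    tr <- trim_alignment(aln, trim_policy(distance_threshold = 1.0))
    expect_equal(tr$query_gapped, qa)
  }
})

test_that("trimming matches the window-scan oracle on random alignments", {
  set.seed(44)
  for (i in 1:40) {
    n <- sample(8:60, 1)
    qa <- strsplit(random_aa(n), "")[[1]]
    ra <- strsplit(random_aa(n), "")[[1]]
    same <- runif(n) < 0.6
    ra[same] <- qa[same]
    gaps <- runif(n) < 0.15
    qa[gaps & !same] <- "-"
    w <- sample(3:15, 1); th <- runif(1)
    aln <- mk_aln(paste(qa, collapse = ""), paste(ra, collapse = ""))
    tr <- trim_alignment(aln, trim_policy(w, th))
    oracle <- trim_oracle_keep(qa, ra, w, th)
    expect_equal(attr(tr, "kept_query_residues"), oracle[qa != "-"],
                 info = paste("instance", i, "w", w, "th", round(th, 3)))
  }
})

test_that("trimming is idempotent and monotone in the threshold", {
  set.seed(45)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    qa <- strsplit(random_aa(n), "")[[1]]
    ra <- strsplit(random_aa(n), "")[[1]]
    same <- runif(n) < runif(1, 0.3, 0.9)
    ra[same] <- qa[same]
    aln <- mk_aln(paste(qa, collapse = ""), paste(ra, collapse = ""))
    w <- sample(5:15, 1)
    ths <- sort(runif(3))
    kept <- lapply(ths, function(th)
      sum(attr(trim_alignment(aln, trim_policy(w, th)), "kept_query_residues")))
    expect_true(kept[[1]] <= kept[[2]] && kept[[2]] <= kept[[3]])
    tr1 <- trim_alignment(aln, trim_policy(w, ths[2]))
    tr2 <- trim_alignment(tr1, trim_policy(w, ths[2]))
    expect_equal(tr2$query_gapped, tr1$query_gapped)
    expect_equal(tr2$ref_gapped, tr1$ref_gapped)
  }
})

test_that("disabled trimming returns the alignment unchanged", {
  aln <- mk_aln("MKLV", "MKAV")
  tr <- trim_alignment(aln, trim_policy(enabled = FALSE))
  expect_equal(tr$query_gapped, aln$query_gapped)
  expect_true(all(attr(tr, "kept_query_residues")))
})

test_that("finalize recovers full and split exact regions verbatim", {
  set.seed(46)
  ref <- list(id = "ref", seq = random_aa(30))
  full <- stitch(list(make_region(ref$seq, 1, 30)), ref)
  m <- finalize_marker(full, ref)
  expect_equal(m$final_aa, ref$seq)
  expect_equal(marker_stats(m, ref)$identity, 100)
  expect_equal(marker_stats(m, ref)$query_coverage, 100)

  halves <- stitch(list(make_region(ref$seq, 1, 15, qid = "h1"),
                        make_region(ref$seq, 16, 30, qid = "h2")), ref)
  m2 <- finalize_marker(halves, ref)
  expect_equal(m2$final_aa, ref$seq)

  expect_null(finalize_marker(list(), ref))
})

test_that("finalize reproduces the known coding translation of an intron fixture", {
  fx <- small_fixture(n = 3, seed = 31)
  hits <- builtin_search(fx$contigs, fx$references)
  scheme <- scoring_scheme()
  for (rid in names(hits)) {
    ref <- list(id = rid,
                seq = fx$references$seq[match(rid, fx$references$id)])
    st <- stitch(hits[[rid]], ref, scheme)
    masked <- lapply(st, mask_region, scheme = scheme)
    m <- finalize_marker(masked, ref, scheme)
    expect_equal(m$final_aa, ref$seq)
    expect_equal(nchar(m$final_nt), 3L * nchar(m$final_aa))
    expect_equal(translate_nt(m$final_nt, 1), m$final_aa)
  }
})
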