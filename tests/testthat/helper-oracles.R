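# Independent oracles and small builders used across the test files.

AA_STD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(n) paste(sample(AA_STD, n, replace = TRUE), collapse = "")

# Plain-R affine-gap dynamic program (textbook Gotoh, score only), written
# independently of the compiled aligner. A gap of length L costs
# gap_open + L * gap_extend.
bf_affine_score <- function(q, r, scheme, mode = c("global", "local")) {
  mode <- match.arg(mode)
  qc <- strsplit(q, "", fixed = TRUE)[[1L]]
  rc <- strsplit(r, "", fixed = TRUE)[[1L]]
  m <- length(qc); n <- length(rc)
  mat <- scheme$matrix; go <- scheme$gap_open; ge <- scheme$gap_extend
  if (m == 0L || n == 0L) {
    if (mode == "local") return(0L)
    if (m == 0L && n == 0L) return(0L)
    return(-(go + max(m, n) * ge))
  }
  NEG <- -1e9
  M <- matrix(NEG, m + 1L, n + 1L)
  E <- matrix(NEG, m + 1L, n + 1L)  # gap in ref (consumes query)
  F <- matrix(NEG, m + 1L, n + 1L)  # gap in query (consumes ref)
  M[1L, 1L] <- 0
  if (mode == "global") {
    for (i in 2L:(m + 1L)) E[i, 1L] <- -(go + (i - 1L) * ge)
    for (j in 2L:(n + 1L)) F[1L, j] <- -(go + (j - 1L) * ge)
  } else {
    M[, 1L] <- 0; M[1L, ] <- 0
  }
  best <- 0
  for (i in 2L:(m + 1L)) {
    for (j in 2L:(n + 1L)) {
      s <- mat[qc[i - 1L], rc[j - 1L]]
      M[i, j] <- max(M[i - 1L, j - 1L], E[i - 1L, j - 1L], F[i - 1L, j - 1L]) + s
      if (mode == "local" && M[i, j] < 0) M[i, j] <- 0
      E[i, j] <- max(M[i - 1L, j] - go - ge, E[i - 1L, j] - ge,
                     F[i - 1L, j] - go - ge)
      F[i, j] <- max(M[i, j - 1L] - go - ge, E[i, j - 1L] - go - ge,
                     F[i, j - 1L] - ge)
      if (mode == "local" && M[i, j] > best) best <- M[i, j]
    }
  }
  if (mode == "local") best else max(M[m + 1L, n + 1L], E[m + 1L, n + 1L],
                                     F[m + 1L, n + 1L])
}

# Build a gapless aligned_region as a (possibly mutated) slice of a
# reference protein.
make_region <- function(refseq, from, to, n_mut = 0L, qid = "q1",
                        scheme = scoring_scheme()) {
  res <- strsplit(substr(refseq, from, to), "", fixed = TRUE)[[1L]]
  if (n_mut > 0L) {
    pos <- sample(seq_along(res), min(n_mut, length(res)))
    res[pos] <- vapply(res[pos], function(a) sample(setdiff(AA_STD, a), 1L),
                       character(1))
  }
  qa <- paste(res, collapse = "")
  ra <- substr(refseq, from, to)
  raw <- score_columns(list(query_gapped = qa, ref_gapped = ra), scheme)
  aligned_region(qid, "ref", qa, ra, from, to, frame = 1L, raw_score = raw)
}

# Score of the finalized concatenation of a set of non-overlapping regions
# (the quantity the stitching enumeration oracle compares).
final_concat_score <- function(regions, refseq, scheme = scoring_scheme()) {
  first <- vapply(regions, `[[`, integer(1), "ref_first")
  regions <- regions[order(first)]
  res <- unlist(lapply(regions, function(r) {
    cols <- strsplit(r$query_aa, "", fixed = TRUE)[[1L]]
    cols[cols != "-"]
  }))
  if (length(res) == 0L) return(NA_integer_)
  align(paste(res, collapse = ""), refseq, scheme, mode = "semiglobal")$score
}

# Exhaustive enumeration of per-overlap winner assignments: branches the
# stack procedure at every overlap resolution (winner = either candidate)
# and returns the final concatenated-realignment score of every leaf.
enumerate_stitch_scores <- function(regions, refseq, scheme = scoring_scheme()) {
  sort_key <- function(rs) {
    first <- vapply(rs, `[[`, integer(1), "ref_first")
    last <- vapply(rs, `[[`, integer(1), "ref_last")
    qid <- vapply(rs, `[[`, character(1), "query_id")
    rs[order(first, -(last - first), qid, method = "radix")]
  }
  resolve_forced <- function(a, b, winner) {
    o1 <- max(a$ref_first, b$ref_first); o2 <- min(a$ref_last, b$ref_last)
    first <- if (a$ref_first < b$ref_first ||
                 (a$ref_first == b$ref_first &&
                  (a$ref_last > b$ref_last ||
                   (a$ref_last == b$ref_last && a$query_id <= b$query_id))))
      a else b
    rightmost <- if (a$ref_last > b$ref_last) a
                 else if (b$ref_last > a$ref_last) b else NULL
    parts <- list()
    if (o1 > first$ref_first)
      parts <- c(parts, list(slice_region(first, first$ref_first, o1 - 1L, scheme)))
    parts <- c(parts, list(slice_region(winner, o1, o2, scheme)))
    if (!is.null(rightmost) && rightmost$ref_last > o2)
      parts <- c(parts, list(slice_region(rightmost, o2 + 1L, rightmost$ref_last, scheme)))
    parts
  }
  recurse <- function(rs) {
    rs <- sort_key(rs)
    # find the first overlapping pair the stack walk would hit
    for (i in seq_len(length(rs) - 1L)) {
      a <- rs[[i]]; b <- rs[[i + 1L]]
      if (a$ref_last >= b$ref_first && b$ref_last >= a$ref_first) {
        rest <- rs[-c(i, i + 1L)]
        return(c(
          recurse(c(rest, resolve_forced(a, b, a))),
          recurse(c(rest, resolve_forced(a, b, b)))))
      }
    }
    final_concat_score(rs, refseq, scheme)
  }
  recurse(regions)
}

# Independent window-scan trimming oracle: per-column verdict computed by
# direct looping over every window.
trim_oracle_keep <- function(qg, rg, window, threshold) {
  n <- length(qg)
  if (n == 0L) return(logical(0))
  w <- min(window, n)
  keep <- logical(n)
  for (s in seq_len(n - w + 1L)) {
    idx <- s:(s + w - 1L)
    aligned <- qg[idx] != "-" & rg[idx] != "-"
    d <- if (sum(aligned) == 0L) 1 else
      1 - sum(aligned & qg[idx] == rg[idx]) / sum(aligned)
    if (d <= threshold) keep[idx] <- TRUE
  }
  keep
}

# small fixture spec used by several files (fast to generate)
small_fixture <- function(n = 5L, seed = 3L, ...)
  generate_markers(fixture_spec(n_markers = n, seed = seed, ...),
                   out_dir = tempfile("fx"))
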