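# Translated-search hit acquisition: parse external tabular results, run an
# external aligner, or use the built-in six-frame translated local search.

TABULAR_FIELDS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                    "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                    "bitscore", "qframe", "qseq_translated", "sseq")

# batched frame translation of many nucleotide strings
translate_many <- function(nt, frame) {
  nt <- toupper(chartr("Uu", "Tt", nt))
  if (frame < 0L)
    nt <- vapply(nt, revcomp, character(1), USE.NAMES = FALSE)
  off <- abs(frame)
  len <- pmax(0L, ((nchar(nt) - off + 1L) %/% 3L) * 3L)
  sub <- substr(nt, off, off + len - 1L)
  sub[nchar(nt) < off + 2L] <- ""
  out <- character(length(sub))
  nonempty <- nchar(sub) >= 3L
  if (any(nonempty))
    out[nonempty] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(sub[nonempty]), if.fuzzy.codon = "solve"))
  out
}

# codon provenance for aligned translated-query residues
# aa_pos: 1-based residue positions in the frame translation
codons_for_positions <- function(query_nt, frame, aa_pos) {
  if (length(aa_pos) == 0L) return(character(0))
  s <- toupper(chartr("Uu", "Tt", query_nt))
  if (frame > 0L) {
    starts <- frame + 3L * (aa_pos - 1L)
    substring(s, starts, starts + 2L)
  } else {
    rc <- revcomp(s)
    starts <- abs(frame) + 3L * (aa_pos - 1L)
    substring(rc, starts, starts + 2L)
  }
}

# nucleotide coordinates (original query, BLAST convention) for a run of
# frame-translation residue positions p1..pn
nt_span <- function(query_len, frame, p_first, p_last) {
  if (frame > 0L) {
    c(frame + 3L * (p_first - 1L), frame + 3L * p_last - 1L)
  } else {
    r1 <- abs(frame) + 3L * (p_first - 1L)
    rn <- abs(frame) + 3L * p_last - 1L
    c(query_len - r1 + 1L, query_len - rn + 1L)
  }
}

#' Parse tabular translated-search results
#'
#' Reads the 15-column tabular dialect
#' `qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore qframe qseq_translated sseq`
#' (tab-separated, no header, `#` comment lines ignored) -- the 12
#' canonical tabular columns extended with the aligned translated query,
#' aligned subject and query frame, which the stitching stage needs.
#' Frameshift placeholder characters (`/`, `\\`) occasionally emitted by
#' frameshift-aware aligners are treated as unaligned (the column becomes a
#' deletion) and reported via a warning.
#'
#' @param path tabular file path.
#' @param references [seq_records] of the pooled reference proteins; every
#'   `sseqid` must be present.
#' @param queries optional nucleotide [seq_records]; when given, codon
#'   provenance is attached so nucleotide output can be produced.
#' @param scheme [scoring_scheme()] used to recompute raw scores.
#' @return A named list (one element per `sseqid`, in order of first
#'   appearance) of lists of [aligned_region()]s, file order preserved
#'   within each reference.
#' @export
parse_tabular <- function(path, references, queries = NULL,
                          scheme = scoring_scheme()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(con <- gzfile(path, "rt")); close(con)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(structure(list(), names = character(0)))
  rows <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(rows, length, integer(1))
  if (any(nf < length(TABULAR_FIELDS))) {
    bad <- which(nf < length(TABULAR_FIELDS))[1L]
    stop(sprintf("row %d has %d fields; missing required column '%s'",
                 bad, nf[bad], TABULAR_FIELDS[nf[bad] + 1L]), call. = FALSE)
  }
  ref_len <- setNames(nchar(references$seq), references$id)
  had_frameshift <- FALSE
  regions <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    sid <- f[2L]
    if (!sid %in% names(ref_len))
      stop(sprintf("row %d: unknown reference id '%s'", i, sid), call. = FALSE)
    sstart <- as.integer(f[9L]); send <- as.integer(f[10L])
    if (is.na(sstart) || is.na(send) || sstart > send)
      stop(sprintf("row %d: invalid subject coordinates sstart=%s send=%s",
                   i, f[9L], f[10L]), call. = FALSE)
    if (send > ref_len[[sid]])
      stop(sprintf("row %d: send=%d exceeds reference length %d for '%s'",
                   i, send, ref_len[[sid]], sid), call. = FALSE)
    qseq <- f[14L]; sseq <- f[15L]
    if (grepl("[/\\\\]", qseq)) {
      had_frameshift <- TRUE
      qg <- strsplit(qseq, "", fixed = TRUE)[[1L]]
      rg <- strsplit(sseq, "", fixed = TRUE)[[1L]]
      shift <- qg %in% c("/", "\\")
      qg[shift] <- "-"
      drop <- qg == "-" & rg == "-"
      qseq <- paste(qg[!drop], collapse = "")
      sseq <- paste(rg[!drop], collapse = "")
    }
    frame <- as.integer(f[13L])
    qstart <- as.integer(f[7L]); qend <- as.integer(f[8L])
    codons <- NULL
    if (!is.null(queries) && f[1L] %in% queries$id) {
      qnt <- queries$seq[match(f[1L], queries$id)]
      qg <- strsplit(qseq, "", fixed = TRUE)[[1L]]
      res_cols <- which(qg != "-")
      # residue k of the aligned query sits at frame-translation position
      # derived from qstart (nt coordinate of the hit's first base)
      p0 <- if (frame > 0L) (qstart - frame) %/% 3L + 1L
            else (nchar(qnt) - qstart + 1L - abs(frame)) %/% 3L + 1L
      cd <- codons_for_positions(qnt, frame, p0 + seq_along(res_cols) - 1L)
      codons <- rep(NA_character_, length(qg))
      codons[res_cols] <- cd
    }
    raw <- score_columns(list(query_gapped = qseq, ref_gapped = sseq), scheme)
    regions[[i]] <- aligned_region(f[1L], sid, qseq, sseq, sstart, send,
                                   frame, raw_score = raw,
                                   bitscore = as.numeric(f[12L]),
                                   codons = codons,
                                   query_first = qstart, query_last = qend,
                                   evalue = if (f[11L] %in% c("NA", ""))
                                     NA_real_ else as.numeric(f[11L]))
  }
  if (had_frameshift)
    warning("frameshift characters ('/', '\\') found in ", path,
            "; affected columns treated as unaligned")
  group_regions(regions)
}

group_regions <- function(regions) {
  ids <- vapply(regions, `[[`, character(1), "ref_id")
  split(regions, factor(ids, levels = unique(ids)))
}

#' Write aligned regions to the tabular dialect
#'
#' Inverse of [parse_tabular()]; derived columns (`pident`, `length`,
#' `mismatch`, `gapopen`) are recomputed from the gapped strings.
#'
#' @param regions_by_ref output of [parse_tabular()] / [builtin_search()],
#'   or a flat list of [aligned_region()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tabular <- function(regions_by_ref, path) {
  regions <- if (length(regions_by_ref) > 0L &&
                 inherits(regions_by_ref[[1L]], "aligned_region"))
    regions_by_ref else unlist(regions_by_ref, recursive = FALSE)
  lines <- vapply(regions, function(rg) {
    cols <- region_columns(rg)
    aligned <- cols$q != "-" & cols$r != "-"
    n_id <- sum(aligned & cols$q == cols$r)
    gaprun <- function(mask) sum(rle(mask)$values)
    paste(c(rg$query_id, rg$ref_id,
            sprintf("%.1f", 100 * n_id / length(cols$q)),
            length(cols$q), sum(aligned) - n_id,
            gaprun(cols$q == "-") + gaprun(cols$r == "-"),
            rg$query_first, rg$query_last, rg$ref_first, rg$ref_last,
            format(rg$evalue), sprintf("%.1f", rg$bitscore), rg$frame,
            rg$query_aa, rg$ref_aa), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Built-in six-frame translated local search
#'
#' A dependency-free translated search for moderate problem sizes: every
#' query is translated in all six frames; frames sharing an exact
#' amino-acid seed of `seed_length` residues with a reference are locally
#' aligned against it (affine-gap Smith-Waterman under `scheme`).
#' Non-overlapping secondary hits are recovered by recursively re-searching
#' the query translation to the left and right of each reported hit.
#' Alignments with raw score below `min_score` are discarded.
#'
#' Hit ends are anchored the same way hits are seeded: terminal alignment
#' columns are trimmed back to the outermost run of `seed_length`
#' consecutive identical residues, so a hit never ends in an unanchored
#' (and typically spurious, e.g. read-through into noncoding sequence)
#' extension. Hits without any such run are dropped.
#'
#' @param queries nucleotide [seq_records] (contigs or reads).
#' @param references amino-acid [seq_records].
#' @param scheme a [scoring_scheme()].
#' @param min_score minimum raw alignment score for a hit (default 40,
#'   roughly a 22-bit hit under BLOSUM62 11/1), applied after end
#'   anchoring.
#' @param seed_length exact-match seed length for the prefilter and for
#'   end anchoring (default 5).
#' @return Named list of [aligned_region()] lists, grouped by reference id.
#' @export
builtin_search <- function(queries, references, scheme = scoring_scheme(),
                           min_score = 40L, seed_length = 5L) {
  stopifnot(nrow(references) > 0L)
  k <- as.integer(seed_length)
  # seed index: k-mer -> reference row indices
  ref_kmers <- lapply(references$seq, function(s) {
    n <- nchar(s)
    if (n < k) character(0) else unique(substring(s, 1:(n - k + 1L), k:n))
  })
  kmer_map <- split(rep(seq_len(nrow(references)),
                        lengths(ref_kmers)), unlist(ref_kmers))

  regions <- list()
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  for (f in frames) {
    aa_all <- translate_many(queries$seq, f)
    for (qi in seq_len(nrow(queries))) {
      aa <- aa_all[qi]
      n <- nchar(aa)
      if (n < k) next
      qk <- unique(substring(aa, 1:(n - k + 1L), k:n))
      cand <- unique(unlist(kmer_map[qk], use.names = FALSE))
      if (length(cand) == 0L) next
      for (ri in cand) {
        hits <- local_hits(aa, references$seq[ri], scheme, min_score,
                           anchor = k)
        for (h in hits) {
          p1 <- h$query_start; pn <- h$query_end
          span <- nt_span(nchar(queries$seq[qi]), f, p1, pn)
          qg <- strsplit(h$query_gapped, "", fixed = TRUE)[[1L]]
          res_cols <- which(qg != "-")
          codons <- rep(NA_character_, length(qg))
          codons[res_cols] <- codons_for_positions(
            queries$seq[qi], f, p1 + seq_along(res_cols) - 1L)
          regions[[length(regions) + 1L]] <- aligned_region(
            queries$id[qi], references$id[ri],
            h$query_gapped, h$ref_gapped, h$ref_start, h$ref_end,
            frame = f, raw_score = h$score, codons = codons,
            query_first = span[1L], query_last = span[2L])
        }
      }
    }
  }
  if (length(regions) == 0L) return(structure(list(), names = character(0)))
  group_regions(regions)
}

# all local hits of one translated query against one reference, found by
# best-hit extraction plus recursion on the flanking query translation;
# hit ends are trimmed back to the outermost `anchor`-long identity run
local_hits <- function(aa, refseq, scheme, min_score, anchor = 5L,
                       offset = 0L) {
  if (nchar(aa) < 2L) return(list())
  aln <- align(aa, refseq, scheme, mode = "local")
  if (aln$score < min_score || aln$query_end == 0L) return(list())
  flanks <- c(
    if (aln$query_start > 1L)
      local_hits(substr(aa, 1L, aln$query_start - 1L), refseq, scheme,
                 min_score, anchor, offset),
    if (aln$query_end < nchar(aa))
      local_hits(substr(aa, aln$query_end + 1L, nchar(aa)), refseq, scheme,
                 min_score, anchor, offset + aln$query_end))
  hit <- anchor_hit(aln, scheme, anchor)
  if (is.null(hit) || hit$score < min_score) return(flanks)
  hit$query_start <- offset + hit$query_start
  hit$query_end <- offset + hit$query_end
  c(list(hit), flanks)
}

# trim terminal alignment columns back to the outermost run of `anchor`
# consecutive identity columns; NULL when no such run exists
anchor_hit <- function(aln, scheme, anchor) {
  qc <- strsplit(aln$query_gapped, "", fixed = TRUE)[[1L]]
  rc <- strsplit(aln$ref_gapped, "", fixed = TRUE)[[1L]]
  m <- qc != "-" & qc == rc
  r <- rle(m)
  qual <- which(r$values & r$lengths >= anchor)
  if (length(qual) == 0L) return(NULL)
  ends <- cumsum(r$lengths)
  first <- ends[qual[1L]] - r$lengths[qual[1L]] + 1L
  last <- ends[qual[length(qual)]]
  dropped_q_left <- sum(qc[seq_len(first - 1L)] != "-")
  dropped_r_left <- sum(rc[seq_len(first - 1L)] != "-")
  dropped_q_right <- if (last < length(qc))
    sum(qc[(last + 1L):length(qc)] != "-") else 0L
  dropped_r_right <- if (last < length(rc))
    sum(rc[(last + 1L):length(rc)] != "-") else 0L
  qg <- paste(qc[first:last], collapse = "")
  rg <- paste(rc[first:last], collapse = "")
  list(query_gapped = qg, ref_gapped = rg,
       score = score_columns(list(query_gapped = qg, ref_gapped = rg), scheme),
       query_start = aln$query_start + dropped_q_left,
       query_end = aln$query_end - dropped_q_right,
       ref_start = aln$ref_start + dropped_r_left,
       ref_end = aln$ref_end - dropped_r_right)
}

#' Run an external translated aligner (DIAMOND blastx or NCBI blastx)
#'
#' Builds (or reuses) a protein database from the pooled references, runs
#' the aligner with the 15-column tabular output this package consumes, and
#' logs the command line, tool version and exit status. The database and
#' tabular files are kept in `out_dir` for reuse.
#'
#' @param query_path nucleotide FASTA/FASTQ query file.
#' @param reference_path pooled reference protein FASTA (see
#'   [pool_references()]); ignored when `db` is given.
#' @param out_dir output directory (created if absent).
#' @param aligner `"blastx"` (NCBI BLAST+) or `"diamond"`.
#' @param db optional path/prefix of a prebuilt database to reuse.
#' @param options list of pass-through options: `ultra_sensitive`,
#'   `frameshift` (integer), `masking` (0 disables query low-complexity
#'   masking; the default, which raises query coverage), `evalue`, and
#'   `extra` (character vector of verbatim arguments).
#' @param threads number of aligner threads.
#' @return List with `tabular` (hit file path), `db` (database prefix) and
#'   `log` (JSON-lines run log path).
#' @export
run_external_search <- function(query_path, reference_path, out_dir,
                                aligner = c("blastx", "diamond"), db = NULL,
                                options = list(), threads = 1L) {
  aligner <- match.arg(aligner)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  exe <- Sys.which(if (aligner == "diamond") "diamond" else "blastx")
  if (!nzchar(exe))
    stop(aligner, " executable not found on PATH; install NCBI BLAST+ ",
         "(or DIAMOND) or use the builtin/tabular input modes", call. = FALSE)
  tabular <- file.path(out_dir, "search_hits.tsv")
  log_path <- file.path(out_dir, "search_log.jsonl")
  logcon <- file(log_path, "at"); on.exit(close(logcon))
  log_line <- function(...) writeLines(jsonlite::toJSON(
    c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), list(...)),
    auto_unbox = TRUE), logcon)

  masking <- if (is.null(options$masking)) 0L else as.integer(options$masking)
  version <- tryCatch(
    paste(suppressWarnings(system2(exe, "-version", stdout = TRUE,
                                   stderr = TRUE))[1L]),
    error = function(e) NA_character_)

  # short-circuit empty queries: an empty tabular result, no aligner call
  qr <- tryCatch(read_fasta(query_path), error = function(e) NULL)
  if (!is.null(qr) && nrow(qr) == 0L) {
    writeLines(character(0), tabular)
    log_line(stage = "search", aligner = aligner, note = "empty query file",
             tabular = tabular)
    return(list(tabular = tabular, db = db, log = log_path))
  }

  if (is.null(db)) {
    db <- file.path(out_dir, "reference_db")
    mk <- if (aligner == "diamond") {
      c("makedb", "--in", reference_path, "-d", db)
    } else NULL
    if (aligner == "diamond") {
      st <- system2(exe, mk, stdout = TRUE, stderr = TRUE)
      code <- attr(st, "status") %||% 0L
      log_line(stage = "makedb", command = paste(c(exe, mk), collapse = " "),
               version = version, exit_status = code)
      if (code != 0L) stop("diamond makedb failed:\n",
                           paste(st, collapse = "\n"), call. = FALSE)
    } else {
      mdb <- Sys.which("makeblastdb")
      args <- c("-in", reference_path, "-dbtype", "prot", "-out", db)
      st <- system2(mdb, args, stdout = TRUE, stderr = TRUE)
      code <- attr(st, "status") %||% 0L
      log_line(stage = "makeblastdb", command = paste(c(mdb, args), collapse = " "),
               version = version, exit_status = code)
      if (code != 0L) stop("makeblastdb failed:\n",
                           paste(st, collapse = "\n"), call. = FALSE)
    }
  }

  args <- if (aligner == "diamond") {
    c("blastx", "-q", query_path, "-d", db, "-o", tabular,
      "--outfmt", "6", TABULAR_FIELDS[1:13], "qseq_translated", "sseq",
      "--masking", masking, "-p", threads,
      if (isTRUE(options$ultra_sensitive)) "--ultra-sensitive",
      if (!is.null(options$frameshift)) c("--frameshift", options$frameshift),
      if (!is.null(options$evalue)) c("--evalue", options$evalue),
      options$extra)
  } else {
    c("-query", query_path, "-db", db, "-out", tabular,
      "-outfmt", paste(c("6", TABULAR_FIELDS[1:13], "qseq", "sseq"),
                       collapse = " "),
      "-seg", if (masking == 0L) "no" else "yes",
      "-num_threads", threads,
      if (!is.null(options$evalue)) c("-evalue", options$evalue),
      options$extra)
  }
  st <- system2(exe, shQuote(as.character(args)), stdout = TRUE, stderr = TRUE)
  code <- attr(st, "status") %||% 0L
  log_line(stage = "search", aligner = aligner,
           command = paste(c(exe, as.character(args)), collapse = " "),
           version = version, exit_status = code, masking = masking,
           tabular = tabular, database = db)
  if (code != 0L)
    stop(aligner, " search failed (exit ", code, "):\n",
         paste(st, collapse = "\n"), call. = FALSE)
  list(tabular = tabular, db = db, log = log_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
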