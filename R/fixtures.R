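# Synthetic genome-skimming fixtures with known ground truth: reference
# proteins, back-translated genes interrupted by introns, fragmentation
# into short contigs (low N50), optional substitution noise, and
# paired-end reads.

#' Fixture generation parameters
#'
#' Describes a synthetic data set: reference proteins are drawn at random,
#' back-translated (deterministically, alphabetically first codon per
#' residue), interrupted by random introns ("genes in pieces"), optionally
#' mutated, and cut into overlapping fragments that emulate a fragmented
#' low-N50 assembly. All randomness is fixed by `seed`.
#'
#' @param n_markers number of reference proteins/genes.
#' @param marker_length_range protein length range (residues).
#' @param intron_count_range introns per gene.
#' @param intron_length_range intron length range (nt).
#' @param fragment_length_range contig length range (nt); controls N50.
#' @param fragment_overlap overlap between consecutive fragments (nt);
#'   must be smaller than the minimum fragment length.
#' @param min_exon_length minimum exon length (nt) enforced when placing
#'   introns, so every coding stretch is long enough to be found.
#' @param substitution_rate per-site substitution probability applied to
#'   the genomic sequence (and reused as the per-base read error rate).
#' @param read_length,insert_size,coverage paired-end read simulation
#'   parameters (nt, nt, fold).
#' @param both_strands randomly reverse-complement fragments.
#' @param codon_aligned_introns place intron boundaries only between
#'   codons (default); `FALSE` allows phase-breaking introns, which
#'   exercise graceful degradation of trimming rather than exact recovery.
#' @param seed random seed fixing all randomness.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(n_markers = 50L,
                         marker_length_range = c(120L, 300L),
                         intron_count_range = c(1L, 3L),
                         intron_length_range = c(60L, 300L),
                         fragment_length_range = c(300L, 500L),
                         fragment_overlap = 90L,
                         min_exon_length = 45L,
                         substitution_rate = 0,
                         read_length = 100L, insert_size = 300L,
                         coverage = 10, both_strands = TRUE,
                         codon_aligned_introns = TRUE, seed = 1L) {
  chk_range <- function(r, what) {
    if (length(r) != 2L || any(is.na(r)) || r[1L] > r[2L] || r[1L] < 0)
      stop("invalid ", what, " range", call. = FALSE)
    as.integer(r)
  }
  spec <- list(n_markers = as.integer(n_markers),
               marker_length_range = chk_range(marker_length_range, "marker length"),
               intron_count_range = chk_range(intron_count_range, "intron count"),
               intron_length_range = chk_range(intron_length_range, "intron length"),
               fragment_length_range = chk_range(fragment_length_range, "fragment length"),
               fragment_overlap = as.integer(fragment_overlap),
               min_exon_length = as.integer(min_exon_length),
               substitution_rate = substitution_rate,
               read_length = as.integer(read_length),
               insert_size = as.integer(insert_size),
               coverage = coverage, both_strands = isTRUE(both_strands),
               codon_aligned_introns = isTRUE(codon_aligned_introns),
               seed = as.integer(seed))
  if (spec$substitution_rate < 0 || spec$substitution_rate > 1)
    stop("substitution_rate must lie in [0, 1]", call. = FALSE)
  if (spec$fragment_overlap >= spec$fragment_length_range[1L])
    stop("fragment_overlap must be smaller than the minimum fragment length",
         call. = FALSE)
  if (spec$n_markers < 1L) stop("n_markers must be >= 1", call. = FALSE)
  structure(spec, class = "fixture_spec")
}

# deterministic back-translation: alphabetically first codon per residue
backtranslate_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  aa <- sort(unique(gc))
  setNames(vapply(aa, function(a) min(names(gc)[gc == a]), character(1)), aa)
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

sample_range <- function(r) if (r[1L] == r[2L]) r[1L] else sample(r[1L]:r[2L], 1L)

mutate_nt <- function(s, rate) {
  if (rate <= 0) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- runif(length(chars)) < rate
  if (any(hit))
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  paste(chars, collapse = "")
}

#' Generate a synthetic marker fixture with ground truth
#'
#' See [fixture_spec()] for the model. Writes `references.fasta`
#' (proteins), `contigs.fasta` (genomic fragments) and `truth.tsv`
#' (fragment_id, ref_id, ref_first, ref_last, frame: every complete-codon
#' coding stretch each fragment carries). Byte-identical across runs at a
#' fixed spec.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if absent).
#' @return List with `references`, `contigs` ([seq_records]), `truth`
#'   (data frame) and `paths`.
#' @export
generate_markers <- function(spec, out_dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bt <- backtranslate_codons()

  refs <- vector("list", spec$n_markers)
  contigs <- list()
  truth <- list()
  for (m in seq_len(spec$n_markers)) {
    ref_id <- sprintf("ref%04d", m)
    plen <- sample_range(spec$marker_length_range)
    protein <- paste(sample(AA20, plen, replace = TRUE), collapse = "")
    coding <- paste(bt[strsplit(protein, "", fixed = TRUE)[[1L]]], collapse = "")
    C <- nchar(coding)

    # place introns, keeping every exon at least min_exon_length long
    n_int <- sample_range(spec$intron_count_range)
    cuts <- integer(0)
    if (n_int > 0L) {
      for (attempt in seq_len(200L)) {
        cand <- if (spec$codon_aligned_introns)
          seq(3L, C - 3L, by = 3L) else seq_len(C - 1L)
        cand <- cand[cand >= spec$min_exon_length &
                     cand <= C - spec$min_exon_length]
        if (length(cand) < n_int) { n_int <- n_int - 1L; next }
        cuts <- sort(sample(cand, n_int))
        if (n_int <= 1L || min(diff(cuts)) >= spec$min_exon_length) break
        if (attempt == 200L) stop("could not place introns; ranges infeasible",
                                  call. = FALSE)
      }
    }
    # build genomic sequence and exon coordinate map
    bounds <- c(0L, cuts, C)                     # coding cut points
    exon_cs <- bounds[-length(bounds)] + 1L      # coding start of each exon
    exon_ce <- bounds[-1L]
    genome <- character(0)
    exon_gs <- integer(length(exon_cs)); exon_ge <- integer(length(exon_cs))
    gpos <- 0L
    for (e in seq_along(exon_cs)) {
      ex <- substr(coding, exon_cs[e], exon_ce[e])
      exon_gs[e] <- gpos + 1L
      gpos <- gpos + nchar(ex)
      exon_ge[e] <- gpos
      genome <- c(genome, ex)
      if (e < length(exon_cs)) {
        il <- sample_range(spec$intron_length_range)
        genome <- c(genome, paste(sample(c("A", "C", "G", "T"), il,
                                         replace = TRUE), collapse = ""))
        gpos <- gpos + il
      }
    }
    genome <- paste(genome, collapse = "")
    genome <- mutate_nt(genome, spec$substitution_rate)
    G <- nchar(genome)

    # fragment into overlapping contigs
    start <- 1L; frag_i <- 0L
    repeat {
      L <- sample_range(spec$fragment_length_range)
      fs <- start; fe <- min(start + L - 1L, G)
      frag_i <- frag_i + 1L
      frag_id <- sprintf("%s_frag%03d", ref_id, frag_i)
      fseq <- substr(genome, fs, fe)
      minus <- spec$both_strands && runif(1L) < 0.5
      if (minus) fseq <- revcomp(fseq)
      contigs[[length(contigs) + 1L]] <-
        list(id = frag_id, seq = fseq)
      # truth rows: complete codons of each exon inside this fragment
      for (e in seq_along(exon_cs)) {
        os <- max(fs, exon_gs[e]); oe <- min(fe, exon_ge[e])
        if (os > oe) next
        cs_cut <- exon_cs[e] + (os - exon_gs[e])
        ce_cut <- exon_cs[e] + (oe - exon_gs[e])
        cs_full <- cs_cut + (3L - (cs_cut - 1L) %% 3L) %% 3L
        ce_full <- ce_cut - ce_cut %% 3L
        if (ce_full < cs_full + 2L) next
        g0 <- exon_gs[e] + (cs_full - exon_cs[e])       # genome pos of codon start
        # negative frames follow the BLAST convention: translate the
        # reverse complement of the contig with the given offset; for a
        # flipped fragment that reverse complement is the genome window
        frame <- if (!minus) ((g0 - fs) %% 3L) + 1L
                 else -(((g0 - fs) %% 3L) + 1L)
        truth[[length(truth) + 1L]] <- data.frame(
          fragment_id = frag_id, ref_id = ref_id,
          ref_first = (cs_full - 1L) %/% 3L + 1L,
          ref_last = ce_full %/% 3L, frame = frame,
          stringsAsFactors = FALSE)
      }
      if (fe == G) break
      start <- start + (L - spec$fragment_overlap)
    }
    refs[[m]] <- list(id = ref_id, seq = protein)
  }

  references <- seq_records(vapply(refs, `[[`, character(1), "id"),
                            vapply(refs, `[[`, character(1), "seq"),
                            alphabet = "amino_acid")
  contig_recs <- seq_records(vapply(contigs, `[[`, character(1), "id"),
                             vapply(contigs, `[[`, character(1), "seq"),
                             alphabet = "nucleotide")
  truth_df <- do.call(rbind, truth)
  paths <- list(references = file.path(out_dir, "references.fasta"),
                contigs = file.path(out_dir, "contigs.fasta"),
                truth = file.path(out_dir, "truth.tsv"))
  write_fasta(references, paths$references)
  write_fasta(contig_recs, paths$contigs)
  write.table(truth_df, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(references = references, contigs = contig_recs, truth = truth_df,
       paths = paths)
}

#' Simulate paired-end reads from templates
#'
#' Draws read pairs at the requested fold coverage from each template
#' (pair count per template is Poisson with mean
#' `coverage * length / (2 * read_length)`), applies per-base substitution
#' errors at `spec$substitution_rate`, and writes two FASTQ files with
#' mate-paired records in matching order. Templates shorter than the read
#' length are skipped with a warning; insert sizes are clamped to the
#' template length.
#'
#' @param templates nucleotide [seq_records] (genes or contigs).
#' @param spec a [fixture_spec()] (uses `read_length`, `insert_size`,
#'   `coverage`, `substitution_rate`, `seed`).
#' @param out_prefix output path prefix; writes `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq`.
#' @return List with `r1`, `r2` (paths) and `n_pairs`.
#' @export
simulate_reads <- function(templates, spec, out_prefix = tempfile("reads")) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1L)
  rl <- spec$read_length
  r1 <- character(0); r2 <- character(0); ids <- character(0)
  for (t in seq_len(nrow(templates))) {
    tl <- nchar(templates$seq[t])
    if (rl > tl) {
      warning("template ", templates$id[t], " shorter than read length; skipped")
      next
    }
    ins <- min(spec$insert_size, tl)
    n <- rpois(1L, spec$coverage * tl / (2 * rl))
    if (n == 0L) next
    starts <- sample.int(tl - ins + 1L, n, replace = TRUE)
    fwd <- substring(templates$seq[t], starts, starts + rl - 1L)
    rev <- vapply(substring(templates$seq[t], starts + ins - rl,
                            starts + ins - 1L), revcomp, character(1),
                  USE.NAMES = FALSE)
    if (spec$substitution_rate > 0) {
      fwd <- vapply(fwd, mutate_nt, character(1), spec$substitution_rate,
                    USE.NAMES = FALSE)
      rev <- vapply(rev, mutate_nt, character(1), spec$substitution_rate,
                    USE.NAMES = FALSE)
    }
    ids <- c(ids, sprintf("%s_p%05d", templates$id[t], seq_len(n)))
    r1 <- c(r1, fwd); r2 <- c(r2, rev)
  }
  p1 <- paste0(out_prefix, "_R1.fastq"); p2 <- paste0(out_prefix, "_R2.fastq")
  write_fastq(seq_records(paste0(ids, "/1"), r1), p1)
  write_fastq(seq_records(paste0(ids, "/2"), r2), p2)
  list(r1 = p1, r2 = p2, n_pairs = length(ids))
}

#' Randomly subsample corresponding read pairs
#'
#' Selects read pairs at random (each pair kept independently with the
#' requested probability), preserving mate pairing: record `i` of the R1
#' output always corresponds to record `i` of the R2 output. Operates on
#' raw 4-line FASTQ records, so retained records are byte-identical to the
#' input. Deterministic under `seed`.
#'
#' @param fastq_r1,fastq_r2 input FASTQ paths (optionally gzipped).
#' @param fraction probability of keeping each pair, in `[0, 1]`.
#' @param out_r1,out_r2 output FASTQ paths.
#' @param seed random seed.
#' @return List with `n_in` and `n_kept` pair counts.
#' @export
subsample_pairs <- function(fastq_r1, fastq_r2, fraction,
                            out_r1, out_r2, seed = 1L) {
  if (fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  read_blocks <- function(path) {
    lines <- readLines(con <- gzfile(path, "rt")); close(con)
    if (length(lines) %% 4L != 0L)
      stop("truncated FASTQ file: ", path, call. = FALSE)
    lines
  }
  l1 <- read_blocks(fastq_r1); l2 <- read_blocks(fastq_r2)
  n1 <- length(l1) %/% 4L; n2 <- length(l2) %/% 4L
  if (n1 != n2)
    stop(sprintf("unequal pair counts: %d reads in %s, %d in %s",
                 n1, fastq_r1, n2, fastq_r2), call. = FALSE)
  set.seed(seed)
  keep <- runif(n1) < fraction
  pick <- function(lines, keep) {
    idx <- rep((which(keep) - 1L) * 4L, each = 4L) + seq_len(4L)
    lines[idx]
  }
  wl <- function(lines, path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    writeLines(lines, con); close(con)
  }
  wl(pick(l1, keep), out_r1)
  wl(pick(l2, keep), out_r2)
  list(n_in = n1, n_kept = sum(keep))
}
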