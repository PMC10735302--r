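#' Pipeline configuration
#'
#' Assembles and validates the full run configuration. Exactly one hit
#' source is active: `tabular` (a precomputed tabular search result),
#' `database` (a prebuilt aligner database to search against), or plain
#' query-vs-reference search (built-in or external, per `engine`). The
#' resolved configuration is serialized as YAML into the output directory
#' for reproducibility.
#'
#' @param query character vector of query FASTA/FASTQ paths.
#' @param references character vector of reference protein FASTA paths.
#' @param out output directory.
#' @param mode `"contigs"` or `"reads"` (input flavour; reads are searched
#'   the same way, the label is recorded in the run log).
#' @param engine `"builtin"`, `"blastx"` or `"diamond"`.
#' @param tabular optional precomputed tabular hit file (skips searching).
#' @param database optional prebuilt external-aligner database prefix.
#' @param matrix optional NCBI-format substitution-matrix file.
#' @param gap_open,gap_extend affine gap penalties (defaults 11 / 1).
#' @param retain_stops,retain_ambiguous masking flags (see
#'   [mask_policy()]).
#' @param window_size,distance_threshold,no_trim trimming controls (see
#'   [trim_policy()]).
#' @param min_bitscore optional bit-score filter applied to hits before
#'   stitching (default: none; all hits enter stitching).
#' @param min_score raw-score cutoff of the built-in search.
#' @param masking,frameshift,ultra_sensitive external-aligner pass-through
#'   options (query low-complexity masking defaults to off, which raises
#'   query coverage).
#' @param query_label taxon/sample label used in output FASTA headers
#'   (default: basename of the first query file).
#' @param seed random seed recorded and applied to any stochastic step.
#' @param threads external-aligner threads.
#' @return A `run_config` object.
#' @export
run_config <- function(query = NULL, references, out,
                       mode = c("contigs", "reads"),
                       engine = c("builtin", "blastx", "diamond"),
                       tabular = NULL, database = NULL,
                       matrix = NULL, gap_open = 11L, gap_extend = 1L,
                       retain_stops = FALSE, retain_ambiguous = FALSE,
                       window_size = 15L, distance_threshold = 0.5,
                       no_trim = FALSE, min_bitscore = NULL, min_score = 40L,
                       masking = 0L, frameshift = NULL,
                       ultra_sensitive = FALSE,
                       query_label = NULL, seed = 1L, threads = 1L) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  n_sources <- (!is.null(tabular)) + (!is.null(database))
  if (n_sources > 1L)
    stop("use at most one of 'tabular' and 'database'", call. = FALSE)
  if (is.null(tabular) && is.null(query))
    stop("query sequences are required unless 'tabular' is given", call. = FALSE)
  if (!is.null(database) && engine == "builtin")
    stop("'database' requires an external engine (blastx or diamond)",
         call. = FALSE)
  scheme <- scoring_scheme(
    matrix = if (is.null(matrix)) NULL else read_score_matrix(matrix),
    gap_open = gap_open, gap_extend = gap_extend,
    name = if (is.null(matrix)) "BLOSUM62" else basename(matrix))
  if (is.null(query_label))
    query_label <- if (!is.null(query))
      tools::file_path_sans_ext(basename(query[1L]), compression = TRUE)
    else "query"
  structure(list(query = query, references = references, out = out,
                 mode = mode, engine = engine, tabular = tabular,
                 database = database, scheme = scheme,
                 mask = mask_policy(retain_stops, retain_ambiguous),
                 trim = trim_policy(window_size, distance_threshold,
                                    enabled = !isTRUE(no_trim)),
                 min_bitscore = min_bitscore, min_score = as.integer(min_score),
                 masking = as.integer(masking), frameshift = frameshift,
                 ultra_sensitive = isTRUE(ultra_sensitive),
                 query_label = query_label, seed = as.integer(seed),
                 threads = as.integer(threads)),
            class = "run_config")
}

read_queries <- function(paths) {
  recs <- lapply(paths, function(p) {
    base <- sub("\\.gz$", "", p)
    if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) read_fastq(p)
    else read_fasta(p, alphabet = "nucleotide")
  })
  out <- do.call(rbind, recs)
  class(out) <- c("seq_records", "data.frame")
  validate_records(out, "query input")
  out
}

#' Run the full marker-recovery pipeline
#'
#' One call drives every stage: reference pooling, hit acquisition
#' (built-in search, external aligner, or a precomputed tabular file),
#' stitching, masking, final realignment with sliding-window trimming, and
#' reporting. Outputs written to `config$out`:
#' `markers_aa.fasta` / `markers_nt.fasta` (headers
#' `<query_label>@<ref_id>`), `report_per_marker.tsv`,
#' `report_aggregate.tsv`, the pooled reference FASTA, any reusable
#' tabular/database artifacts, `run_log.jsonl` (stage timings, counts, and
#' per-reference stitching decisions) and `config.yaml`.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `markers` (named list of
#'   `stitched_marker`s), `reports` (per-marker data frame), `aggregate`
#'   and `out` (the output directory).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  logcon <- file(file.path(out, "run_log.jsonl"), "wt")
  on.exit(close(logcon))
  t0 <- Sys.time()
  log_line <- function(stage, ...) writeLines(jsonlite::toJSON(
    list(stage = stage, elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 3),
         ...), auto_unbox = TRUE, null = "null", digits = NA), logcon)

  pooled <- pool_references(config$references, file.path(out, "references_pooled.fasta"))
  references <- pooled$records
  log_line("pool_references", n_files = length(config$references),
           n_references = nrow(references))

  scheme <- config$scheme
  queries <- if (!is.null(config$query)) read_queries(config$query) else NULL

  if (!is.null(config$tabular)) {
    hits <- parse_tabular(config$tabular, references, queries, scheme)
    log_line("parse_tabular", file = config$tabular,
             n_hits = sum(lengths(hits)))
  } else if (config$engine == "builtin") {
    hits <- builtin_search(queries, references, scheme,
                           min_score = config$min_score)
    log_line("builtin_search", n_queries = nrow(queries),
             n_hits = sum(lengths(hits)), min_score = config$min_score)
  } else {
    qpath <- config$query[1L]
    base <- sub("\\.gz$", "", qpath)
    if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) {
      qpath <- file.path(out, "query_as_fasta.fasta")
      write_fasta(queries, qpath)
    }
    sr <- run_external_search(
      qpath, pooled$path, out, aligner = config$engine,
      db = config$database,
      options = list(masking = config$masking,
                     frameshift = config$frameshift,
                     ultra_sensitive = config$ultra_sensitive),
      threads = config$threads)
    hits <- parse_tabular(sr$tabular, references, queries, scheme)
    log_line("external_search", engine = config$engine,
             tabular = sr$tabular, n_hits = sum(lengths(hits)))
  }

  if (!is.null(config$min_bitscore)) {
    n_before <- sum(lengths(hits))
    hits <- lapply(hits, function(rs)
      Filter(function(r) r$bitscore >= config$min_bitscore, rs))
    hits <- hits[lengths(hits) > 0L]
    log_line("bitscore_filter", min_bitscore = config$min_bitscore,
             n_before = n_before, n_after = sum(lengths(hits)))
  }

  markers <- list()
  reports <- list()
  for (rid in names(hits)) {
    ref <- list(id = rid, seq = references$seq[match(rid, references$id)])
    stack <- stitch(hits[[rid]], ref, scheme)
    masked <- lapply(stack, mask_region, policy = config$mask, scheme = scheme)
    marker <- finalize_marker(masked, ref, scheme, config$trim)
    log_line("stitch", ref_id = rid, n_hits = length(hits[[rid]]),
             n_regions = length(stack), passes = attr(stack, "passes"),
             overlaps_resolved = attr(stack, "overlaps_resolved"),
             recovered = !is.null(marker))
    if (is.null(marker)) next
    markers[[rid]] <- marker
    reports[[rid]] <- marker_stats(marker, ref)
  }
  reports <- if (length(reports) > 0L) do.call(rbind, reports) else
    data.frame()

  label <- config$query_label
  ids <- if (length(markers) > 0L) paste0(label, "@", names(markers))
         else character(0)
  aa_recs <- seq_records(
    id = ids, seq = vapply(markers, `[[`, character(1), "final_aa"),
    alphabet = "amino_acid")
  write_fasta(aa_recs, file.path(out, "markers_aa.fasta"))
  nts <- vapply(markers, `[[`, character(1), "final_nt")
  has_nt <- !is.na(nts)
  write_fasta(seq_records(ids[has_nt], nts[has_nt]),
              file.path(out, "markers_nt.fasta"))

  aggregate <- aggregate_reports(reports,
                                 total_ref_len = sum(nchar(references$seq)))
  write_reports(reports, aggregate, out)
  log_line("report", n_markers = aggregate$n_markers_recovered,
           p_identical_cov = aggregate$p_identical_cov)

  cfg <- list(query = config$query, references = config$references,
              out = out, mode = config$mode, engine = config$engine,
              tabular = config$tabular, database = config$database,
              scoring = list(matrix = config$scheme$name,
                             gap_open = config$scheme$gap_open,
                             gap_extend = config$scheme$gap_extend),
              mask = unclass(config$mask), trim = unclass(config$trim),
              min_bitscore = config$min_bitscore,
              min_score = config$min_score, masking = config$masking,
              frameshift = config$frameshift,
              ultra_sensitive = config$ultra_sensitive,
              query_label = config$query_label, seed = config$seed,
              threads = config$threads)
  yaml::write_yaml(cfg, file.path(out, "config.yaml"))
  invisible(list(markers = markers, reports = reports,
                 aggregate = aggregate, out = out))
}

#' Concatenate homologous markers from multiple taxa
#'
#' Collects the per-taxon `markers_aa.fasta` outputs (headers
#' `<taxon>@<ref_id>`) and writes one FASTA per reference containing the
#' marker of every taxon that recovered it -- the per-locus files fed to
#' downstream multiple alignment. Taxa missing a marker are simply absent
#' (no placeholder).
#'
#' @param marker_fastas character vector of per-taxon marker FASTA paths
#'   (e.g. `<run>/markers_aa.fasta`), or run output directories.
#' @param out_dir output directory for the per-marker FASTA files.
#' @return Invisibly, a named character vector mapping `ref_id` to file
#'   path.
#' @export
concat_taxa <- function(marker_fastas, out_dir) {
  stopifnot(length(marker_fastas) >= 1L)
  paths <- ifelse(dir.exists(marker_fastas),
                  file.path(marker_fastas, "markers_aa.fasta"), marker_fastas)
  recs <- lapply(paths, read_fasta, alphabet = "amino_acid")
  taxa <- lapply(recs, function(r) sub("@.*$", "", r$id))
  labels <- vapply(taxa, function(t) unique(t)[1L], character(1))
  if (anyDuplicated(labels))
    stop("duplicate taxon label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all <- do.call(rbind, recs)
  marker_of <- sub("^[^@]*@", "", all$id)
  taxon_of <- sub("@.*$", "", all$id)
  out <- character(0)
  for (rid in unique(marker_of)) {
    sel <- marker_of == rid
    path <- file.path(out_dir, paste0(rid, ".fasta"))
    write_fasta(seq_records(taxon_of[sel], all$seq[sel],
                            alphabet = "amino_acid"), path)
    out[rid] <- path
  }
  invisible(out)
}
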