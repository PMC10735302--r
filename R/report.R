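#' Per-marker recovery statistics
#'
#' Computes the per-reference statistics row from a finalized marker's
#' alignment against its reference: reference and query lengths, matches,
#' mismatches, deletions, query coverage and gap-excluded identity.
#'
#' Identity uses aligned (non-gap) columns only:
#' `100 * matches / (matches + mismatches)`. Query coverage is the percent
#' of reference positions aligned to query residues. Deletions count
#' reference positions unmatched *within* the aligned span (terminal
#' uncovered reference tails count against coverage only, keeping the two
#' variables non-redundant).
#'
#' @param marker a `stitched_marker` from [finalize_marker()].
#' @param reference the corresponding reference record (list with `id`,
#'   `seq`).
#' @return A one-row data frame with columns `ref_id`, `reference_length`,
#'   `query_length`, `matches`, `mismatches`, `deletions`,
#'   `query_coverage`, `identity`.
#' @export
marker_stats <- function(marker, reference) {
  aln <- marker$final_alignment
  qg <- strsplit(aln$query_gapped, "", fixed = TRUE)[[1L]]
  rg <- strsplit(aln$ref_gapped, "", fixed = TRUE)[[1L]]
  aligned <- qg != "-" & rg != "-"
  matches <- sum(aligned & qg == rg)
  mismatches <- sum(aligned) - matches
  qpos <- which(qg != "-")
  span <- if (length(qpos) == 0L) integer(0) else qpos[1L]:qpos[length(qpos)]
  deletions <- sum(qg[span] == "-" & rg[span] != "-")
  ref_len <- nchar(reference$seq)
  data.frame(ref_id = marker$ref_id,
             reference_length = ref_len,
             query_length = nchar(marker$final_aa),
             matches = matches, mismatches = mismatches,
             deletions = deletions,
             query_coverage = 100 * sum(aligned) / ref_len,
             identity = if (matches + mismatches == 0L) NA_real_
                        else 100 * matches / (matches + mismatches),
             stringsAsFactors = FALSE)
}

#' Combined accuracy/completeness measure
#'
#' Accuracy and completeness measured jointly: percent identical aligned
#' positions multiplied by the fraction of reference positions recovered,
#' `100 * (n_match / n_aligned) * (total_recovered_len / total_ref_len)`.
#' Using either factor alone can flatter a method (e.g. few markers
#' recovered but at high identity); the product does not.
#'
#' @param n_match total identical aligned columns across all markers.
#' @param n_aligned total non-gap aligned columns (returns 0 when 0).
#' @param total_recovered_len summed length of all recovered markers.
#' @param total_ref_len summed length of all reference sequences (> 0).
#' @return The combined measure in percent.
#' @export
combined_measure <- function(n_match, n_aligned, total_recovered_len,
                             total_ref_len) {
  if (any(c(n_match, n_aligned, total_recovered_len, total_ref_len) < 0))
    stop("combined_measure inputs must be non-negative", call. = FALSE)
  if (n_aligned > 0 && n_match > n_aligned)
    stop("n_match cannot exceed n_aligned", call. = FALSE)
  if (total_ref_len <= 0) stop("total_ref_len must be positive", call. = FALSE)
  if (n_aligned == 0) return(0)
  100 * (n_match / n_aligned) * (total_recovered_len / total_ref_len)
}

#' Aggregate per-marker reports
#'
#' Mean/min/median/max for every report variable (median of an even-sized
#' set is the mean of the central pair), the number of recovered markers,
#' and the combined accuracy/completeness measure over totals.
#'
#' @param reports data frame of [marker_stats()] rows (possibly 0 rows).
#' @param total_ref_len total reference length for the coverage
#'   denominator; defaults to the summed `reference_length` of the reports
#'   (i.e. references without a recovered marker are excluded unless the
#'   full-set total is supplied).
#' @return An `aggregate_report`: list with `summary` (data frame
#'   variable/mean/min/median/max), `n_markers_recovered` and
#'   `p_identical_cov`.
#' @export
aggregate_reports <- function(reports,
                              total_ref_len = sum(reports$reference_length)) {
  vars <- c("reference_length", "query_length", "matches", "mismatches",
            "deletions", "query_coverage", "identity")
  if (is.null(reports) || nrow(reports) == 0L) {
    summary <- data.frame(variable = vars, mean = NA_real_, min = NA_real_,
                          median = NA_real_, max = NA_real_)
    return(structure(list(summary = summary, n_markers_recovered = 0L,
                          p_identical_cov = 0),
                     class = "aggregate_report"))
  }
  summary <- do.call(rbind, lapply(vars, function(v) {
    x <- reports[[v]]
    data.frame(variable = v, mean = mean(x), min = min(x),
               median = median(x), max = max(x))
  }))
  p <- combined_measure(sum(reports$matches),
                        sum(reports$matches) + sum(reports$mismatches),
                        sum(reports$query_length), total_ref_len)
  structure(list(summary = summary, n_markers_recovered = nrow(reports),
                 p_identical_cov = p),
            class = "aggregate_report")
}

#' @export
print.aggregate_report <- function(x, ...) {
  cat(sprintf("aggregate_report: %d marker(s), p_identical_cov %.1f%%\n",
              x$n_markers_recovered, x$p_identical_cov))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write per-marker and aggregate report files
#'
#' Emits `report_per_marker.tsv` (one row per recovered reference, header
#' matching the per-marker variables) and `report_aggregate.tsv`
#' (variable/mean/min/median/max, plus `n_markers_recovered` and
#' `p_identical_cov` rows).
#'
#' @param reports data frame of [marker_stats()] rows.
#' @param aggregate an `aggregate_report` from [aggregate_reports()].
#' @param out_dir output directory.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_reports <- function(reports, aggregate, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  per <- file.path(out_dir, "report_per_marker.tsv")
  agg <- file.path(out_dir, "report_aggregate.tsv")
  write.table(reports, per, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- aggregate$summary
  s <- rbind(s,
             data.frame(variable = "n_markers_recovered",
                        mean = aggregate$n_markers_recovered, min = NA,
                        median = NA, max = NA),
             data.frame(variable = "p_identical_cov",
                        mean = aggregate$p_identical_cov, min = NA,
                        median = NA, max = NA))
  write.table(s, agg, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(per, agg))
}
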