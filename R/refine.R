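#' Masking and trimming policies
#'
#' `mask_policy()` controls which residues are removed from stitched query
#' sequences: query insertions (columns unaligned to the reference) are
#' always removed; ambiguous amino acids (`B`, `J`, `X`, `Z` -- letters
#' that do not determine a unique residue: B = D/N, J = I/L, X = unknown,
#' Z = E/Q) are removed unless `retain_ambiguous`; stop codons (`*`) are
#' removed unless `retain_stops`.
#'
#' `trim_policy()` controls the sliding-window alignment trimmer: a window
#' of `window_size` alignment columns passes when its gap-excluded distance
#' `1 - identical / aligned` is at or below `distance_threshold`; a column
#' is retained iff it lies in at least one passing window (so overlapping
#' passing windows protect a single bad-but-correct match). Windows with no
#' aligned columns have distance 1. `enabled = FALSE` skips trimming.
#'
#' @param retain_stops keep `*` residues (default `FALSE`).
#' @param retain_ambiguous keep `B J X Z` residues (default `FALSE`).
#' @param window_size window width in alignment columns (default 15).
#' @param distance_threshold maximum tolerated window distance in `[0, 1]`
#'   (default 0.5; removal uses strictly-above semantics, so 1.0 keeps
#'   everything).
#' @param enabled apply trimming at all (default `TRUE`).
#' @return A `mask_policy` / `trim_policy` object.
#' @export
mask_policy <- function(retain_stops = FALSE, retain_ambiguous = FALSE) {
  structure(list(retain_stops = isTRUE(retain_stops),
                 retain_ambiguous = isTRUE(retain_ambiguous),
                 ambiguous_set = c("B", "J", "X", "Z")),
            class = "mask_policy")
}

#' @rdname mask_policy
#' @export
trim_policy <- function(window_size = 15L, distance_threshold = 0.5,
                        enabled = TRUE) {
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 1L)
    stop("window_size must be a positive integer", call. = FALSE)
  if (distance_threshold < 0 || distance_threshold > 1)
    stop("distance_threshold must lie in [0, 1]", call. = FALSE)
  structure(list(window_size = window_size,
                 distance_threshold = distance_threshold,
                 enabled = isTRUE(enabled)),
            class = "trim_policy")
}

#' Mask unwanted residues in an aligned region
#'
#' Removes insertion columns (gap in the reference row, i.e. query
#' residues unaligned to the reference) entirely, and -- subject to the
#' policy flags -- replaces ambiguous residues and stop codons with
#' deletions so that reference coordinates are preserved. Idempotent.
#'
#' @param region an [aligned_region()].
#' @param policy a [mask_policy()].
#' @param scheme [scoring_scheme()] used to recompute the region score.
#' @return The masked `aligned_region` (same reference interval).
#' @export
mask_region <- function(region, policy = mask_policy(),
                        scheme = scoring_scheme()) {
  cols <- region_columns(region)
  keep_col <- cols$r != "-"
  qg <- cols$q[keep_col]
  rg <- cols$r[keep_col]
  codons <- if (is.null(region$codons)) NULL else region$codons[keep_col]
  drop_set <- character(0)
  if (!policy$retain_ambiguous) drop_set <- c(drop_set, policy$ambiguous_set)
  if (!policy$retain_stops) drop_set <- c(drop_set, "*")
  masked <- qg %in% drop_set
  qg[masked] <- "-"
  if (!is.null(codons)) codons[masked] <- NA_character_
  qa <- paste(qg, collapse = ""); ra <- paste(rg, collapse = "")
  raw <- score_columns(list(query_gapped = qa, ref_gapped = ra), scheme)
  aligned_region(region$query_id, region$ref_id, qa, ra,
                 region$ref_first, region$ref_last, region$frame,
                 raw_score = raw, codons = codons,
                 query_first = region$query_first,
                 query_last = region$query_last, evalue = region$evalue)
}

#' Sliding-window trimming of a pairwise alignment
#'
#' Scans the alignment left to right with a window of
#' `policy$window_size` columns and cuts every column that lies in no
#' window whose gap-excluded distance (`1 - identical/aligned`) is at or
#' below `policy$distance_threshold`. Cut columns become deletions against
#' the reference (cut insertion columns are dropped outright), so
#' reference coordinates are preserved. An alignment shorter than the
#' window is treated as a single window. Idempotent at fixed policy, and
#' monotone: lowering the threshold never retains more columns.
#'
#' @param aln a `pairwise_alignment` (see [align()]).
#' @param policy a [trim_policy()]; when `enabled` is `FALSE` the input is
#'   returned unchanged.
#' @param scheme [scoring_scheme()] used to rescore the trimmed alignment.
#' @return A `pairwise_alignment` with attribute `kept_query_residues`, a
#'   logical vector over the input's ungapped query residues marking which
#'   survived.
#' @export
trim_alignment <- function(aln, policy = trim_policy(),
                           scheme = scoring_scheme()) {
  qg <- strsplit(aln$query_gapped, "", fixed = TRUE)[[1L]]
  rg <- strsplit(aln$ref_gapped, "", fixed = TRUE)[[1L]]
  n <- length(qg)
  if (!policy$enabled || n == 0L) {
    attr(aln, "kept_query_residues") <- rep(TRUE, sum(qg != "-"))
    return(aln)
  }
  w <- min(policy$window_size, n)
  aligned <- qg != "-" & rg != "-"
  ident <- aligned & qg == rg
  ca <- cumsum(aligned); ci <- cumsum(ident)
  starts <- seq_len(n - w + 1L)
  n_aligned <- ca[starts + w - 1L] - c(0L, ca)[starts]
  n_ident <- ci[starts + w - 1L] - c(0L, ci)[starts]
  dist <- ifelse(n_aligned == 0L, 1, 1 - n_ident / n_aligned)
  passing <- dist <= policy$distance_threshold
  keep <- logical(n)
  for (s in starts[passing]) keep[s:(s + w - 1L)] <- TRUE

  cut <- !keep
  kept_query <- (qg != "-" & !cut)[qg != "-"]
  qg[cut] <- "-"
  drop_col <- cut & rg == "-"
  qg <- qg[!drop_col]; rg <- rg[!drop_col]
  out <- structure(list(query_gapped = paste(qg, collapse = ""),
                        ref_gapped = paste(rg, collapse = ""),
                        score = NA_integer_, mode = aln$mode,
                        query_start = aln$query_start, query_end = aln$query_end,
                        ref_start = aln$ref_start, ref_end = aln$ref_end),
                   class = "pairwise_alignment")
  out$score <- score_columns(out, scheme)
  attr(out, "kept_query_residues") <- kept_query
  out
}

#' Concatenate, realign and trim stitched regions into a final marker
#'
#' The ordered, non-overlapping (stitched and masked) regions for one
#' reference are concatenated into one continuous amino-acid sequence,
#' realigned to the reference (semiglobal: the marker aligns end to end,
#' unaligned reference overhangs are free), and the realignment is trimmed
#' with the sliding window. The final sequence is returned in amino acids
#' and -- when codon provenance is available -- in nucleotides
#' (codon-for-residue back-mapping).
#'
#' @param regions a `region_stack` from [stitch()] (regions already
#'   masked via [mask_region()]).
#' @param reference the reference record (list with `id`, `seq`).
#' @param scheme a [scoring_scheme()].
#' @param trim a [trim_policy()].
#' @return A `stitched_marker` (list with `ref_id`, `regions`, `final_aa`,
#'   `final_nt`, `final_alignment`, `score`), or `NULL` when nothing
#'   remains (marker absent).
#' @export
finalize_marker <- function(regions, reference, scheme = scoring_scheme(),
                            trim = trim_policy()) {
  if (length(regions) == 0L) return(NULL)
  pieces <- lapply(regions, region_query_residues)
  residues <- unlist(lapply(pieces, `[[`, "residues"))
  codons <- unlist(lapply(pieces, `[[`, "codons"))
  if (length(residues) == 0L) return(NULL)
  concat <- paste(residues, collapse = "")
  aln <- align(concat, reference$seq, scheme, mode = "semiglobal")
  trimmed <- trim_alignment(aln, trim, scheme)
  kept <- attr(trimmed, "kept_query_residues")
  final_res <- residues[kept]
  if (length(final_res) == 0L) return(NULL)
  final_codons <- codons[kept]
  final_nt <- if (anyNA(final_codons)) NA_character_
              else paste(final_codons, collapse = "")
  structure(list(ref_id = reference$id, regions = regions,
                 final_aa = paste(final_res, collapse = ""),
                 final_nt = final_nt,
                 final_alignment = trimmed, score = trimmed$score),
            class = "stitched_marker")
}

#' @export
print.stitched_marker <- function(x, ...) {
  cat(sprintf("stitched_marker %s: %d aa from %d region(s), score %d\n",
              x$ref_id, nchar(x$final_aa), length(x$regions), x$score))
  invisible(x)
}
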