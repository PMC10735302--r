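#' Affine-gap pairwise amino-acid alignment
#'
#' Optimal pairwise alignment under a [scoring_scheme()] via an affine-gap
#' (Gotoh) dynamic program. Three modes:
#' * `"local"` -- Smith-Waterman; used by the built-in translated search.
#' * `"global"` -- Needleman-Wunsch with penalized terminal gaps; used to
#'   realign the overlapping interval of two hit regions during stitching.
#' * `"semiglobal"` -- the query is aligned end to end but unaligned
#'   reference overhangs (terminal gap runs in the query row) are free;
#'   used for the final realignment of a concatenated marker against its
#'   full-length reference.
#'
#' Traceback ties are broken with fixed priority diagonal > up > left, so
#' results are bit-reproducible.
#'
#' @param query,ref amino-acid strings. Both must be non-empty for local
#'   mode; global/semiglobal accept empty inputs (all-gap result).
#' @param scheme a [scoring_scheme()]; default BLOSUM62 with gap open 11,
#'   gap extend 1.
#' @param mode `"local"`, `"global"` or `"semiglobal"`.
#' @return A `pairwise_alignment`: list with `query_gapped`, `ref_gapped`
#'   (equal-length gapped strings, no gap/gap column), `score`, `mode`, and
#'   1-based coordinates `query_start`, `query_end`, `ref_start`, `ref_end`
#'   of the aligned portion (0s for an empty local alignment).
#' @export
align <- function(query, ref, scheme = scoring_scheme(),
                  mode = c("global", "local", "semiglobal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "scoring_scheme"))
  if (mode == "local" && (!nzchar(query) || !nzchar(ref)))
    stop("local alignment requires non-empty query and reference", call. = FALSE)
  qi <- encode_residues(query, scheme, "query")
  ri <- encode_residues(ref, scheme, "ref")
  res <- .gotoh_align(qi, ri, scheme$matrix, scheme$gap_open, scheme$gap_extend,
                      switch(mode, global = 0L, local = 1L, semiglobal = 2L))
  qchars <- strsplit(toupper(query), "", fixed = TRUE)[[1L]]
  rchars <- strsplit(toupper(ref), "", fixed = TRUE)[[1L]]
  qg <- rep("-", length(res$q_col)); qsel <- res$q_col >= 0L
  qg[qsel] <- qchars[res$q_col[qsel] + 1L]
  rg <- rep("-", length(res$r_col)); rsel <- res$r_col >= 0L
  rg[rsel] <- rchars[res$r_col[rsel] + 1L]
  structure(list(query_gapped = paste(qg, collapse = ""),
                 ref_gapped = paste(rg, collapse = ""),
                 score = res$score, mode = mode,
                 query_start = res$q_start, query_end = res$q_end,
                 ref_start = res$r_start, ref_end = res$r_end),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment (%s), score %d\n  Q: %s\n  R: %s\n",
              x$mode, x$score, x$query_gapped, x$ref_gapped))
  invisible(x)
}

#' Recompute an alignment score from its gapped strings
#'
#' Sums substitution-matrix values over aligned columns and subtracts
#' affine gap costs (`gap_open + L * gap_extend` per gap run). For
#' semiglobal alignments, terminal gap runs in the query row are free,
#' matching [align()]. Equals the `score` field of any [align()] output.
#'
#' @param aln a `pairwise_alignment` (or any list with `query_gapped`,
#'   `ref_gapped` and optionally `mode`).
#' @param scheme the [scoring_scheme()] the alignment was computed under.
#' @return Integer score.
#' @export
score_columns <- function(aln, scheme = scoring_scheme()) {
  qg <- strsplit(aln$query_gapped, "", fixed = TRUE)[[1L]]
  rg <- strsplit(aln$ref_gapped, "", fixed = TRUE)[[1L]]
  if (length(qg) != length(rg))
    stop("gapped strings differ in length", call. = FALSE)
  if (length(qg) == 0L) return(0L)
  qgap <- qg == "-"; rgap <- rg == "-"
  if (any(qgap & rgap)) stop("gap/gap column in alignment", call. = FALSE)
  score <- 0L
  aligned <- !qgap & !rgap
  if (any(aligned)) {
    qi <- match(toupper(qg[aligned]), rownames(scheme$matrix))
    ri <- match(toupper(rg[aligned]), rownames(scheme$matrix))
    if (anyNA(qi) || anyNA(ri))
      stop("residue outside the matrix alphabet", call. = FALSE)
    score <- sum(scheme$matrix[cbind(qi, ri)])
  }
  gap_run_cost <- function(gapmask, drop_terminal) {
    r <- rle(gapmask)
    lens <- r$lengths[r$values]
    if (drop_terminal && length(lens) > 0L) {
      keep <- rep(TRUE, length(lens))
      if (r$values[1L]) keep[1L] <- FALSE
      if (r$values[length(r$values)]) keep[length(lens)] <- FALSE
      lens <- lens[keep]
    }
    if (length(lens) == 0L) return(0L)
    sum(scheme$gap_open + lens * scheme$gap_extend)
  }
  semi <- identical(aln$mode, "semiglobal")
  score - gap_run_cost(qgap, drop_terminal = semi) - gap_run_cost(rgap, FALSE)
}
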