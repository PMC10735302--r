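#' Aligned hit regions
#'
#' One translated-search hit: the aligned translated query residues against
#' an interval of a reference protein. `query_aa` and `ref_aa` are gapped
#' strings of equal length with no gap/gap column; `-` in `ref_aa` marks a
#' query insertion, `-` in `query_aa` a deletion relative to the reference.
#' `ref_first`/`ref_last` are 1-based inclusive reference coordinates;
#' the non-gap residues of `ref_aa` cover exactly that interval.
#'
#' `codons`, when available, holds the source codon (coding-strand
#' nucleotide triplet) for each alignment column with a query residue
#' (`NA` elsewhere) and is what lets the pipeline emit nucleotide output.
#'
#' @param query_id,ref_id sequence identifiers.
#' @param query_aa,ref_aa gapped aligned strings.
#' @param ref_first,ref_last 1-based inclusive reference interval.
#' @param frame reading frame of the hit, in `{1,2,3,-1,-2,-3}`.
#' @param bitscore bit score (recomputed from `raw_score` when `NULL`).
#' @param raw_score integer alignment raw score, recomputable from the
#'   gapped strings under the run's [scoring_scheme()].
#' @param codons optional character vector, one element per alignment
#'   column (`NA` at deletion columns).
#' @param query_first,query_last optional 1-based nucleotide coordinates of
#'   the hit on the original (untranslated) query; `query_first >
#'   query_last` for negative frames, following BLAST convention.
#' @param evalue optional expectation value (kept for tabular round-trips).
#' @return An `aligned_region` object.
#' @export
aligned_region <- function(query_id, ref_id, query_aa, ref_aa,
                           ref_first, ref_last, frame,
                           raw_score, bitscore = NULL, codons = NULL,
                           query_first = NA_integer_, query_last = NA_integer_,
                           evalue = NA_real_) {
  qg <- strsplit(query_aa, "", fixed = TRUE)[[1L]]
  rg <- strsplit(ref_aa, "", fixed = TRUE)[[1L]]
  if (length(qg) != length(rg))
    stop("query_aa and ref_aa differ in length", call. = FALSE)
  if (length(qg) == 0L) stop("empty aligned region", call. = FALSE)
  if (any(qg == "-" & rg == "-")) stop("gap/gap column in region", call. = FALSE)
  ref_first <- as.integer(ref_first); ref_last <- as.integer(ref_last)
  if (is.na(ref_first) || is.na(ref_last) || ref_first < 1L || ref_first > ref_last)
    stop(sprintf("invalid reference interval [%s, %s]", ref_first, ref_last),
         call. = FALSE)
  if (sum(rg != "-") != ref_last - ref_first + 1L)
    stop("reference residue count does not match [ref_first, ref_last]",
         call. = FALSE)
  if (!is.null(codons) && length(codons) != length(qg))
    stop("codons must have one element per alignment column", call. = FALSE)
  structure(list(query_id = query_id, ref_id = ref_id,
                 query_aa = query_aa, ref_aa = ref_aa,
                 ref_first = ref_first, ref_last = ref_last,
                 frame = as.integer(frame),
                 raw_score = as.integer(raw_score),
                 bitscore = if (is.null(bitscore)) bit_from_raw(raw_score)
                            else as.numeric(bitscore),
                 codons = codons,
                 query_first = as.integer(query_first),
                 query_last = as.integer(query_last),
                 evalue = as.numeric(evalue)),
            class = "aligned_region")
}

#' @export
print.aligned_region <- function(x, ...) {
  cat(sprintf("aligned_region %s -> %s [%d..%d] frame %+d raw %d bit %.1f\n  Q: %s\n  R: %s\n",
              x$query_id, x$ref_id, x$ref_first, x$ref_last, x$frame,
              x$raw_score, x$bitscore, x$query_aa, x$ref_aa))
  invisible(x)
}

# Karlin-Altschul bit score for gapped BLOSUM62 11/1 (lambda 0.267, K 0.041).
bit_from_raw <- function(raw) (0.267 * raw - log(0.041)) / log(2)

region_columns <- function(region) {
  list(q = strsplit(region$query_aa, "", fixed = TRUE)[[1L]],
       r = strsplit(region$ref_aa, "", fixed = TRUE)[[1L]])
}

# Reference anchor position per alignment column: reference-consuming
# columns carry their own position; insertion columns (gap in ref) carry
# the position they follow. Insertions before the first reference-consuming
# column anchor to ref_first so that a full-extent slice is the identity.
region_anchors <- function(region) {
  cols <- region_columns(region)
  consumes <- cols$r != "-"
  anchor <- integer(length(consumes))
  anchor[consumes] <- seq(region$ref_first, region$ref_last)
  pos <- cumsum(consumes)
  anchor[!consumes] <- ifelse(pos[!consumes] == 0L, region$ref_first,
                              region$ref_first + pos[!consumes] - 1L)
  anchor
}

# Non-gap query residues of a region, in order, with their codons.
region_query_residues <- function(region) {
  cols <- region_columns(region)
  keep <- cols$q != "-"
  list(residues = cols$q[keep],
       codons = if (is.null(region$codons)) rep(NA_character_, sum(keep))
                else region$codons[keep])
}

#' Slice an aligned region to a reference sub-interval
#'
#' Keeps exactly the alignment columns anchored inside
#' `[ref_from, ref_to]`: reference-consuming columns in the interval, plus
#' insertion columns whose anchoring reference position (the position they
#' follow) lies inside it. Scores are recomputed for the sliced columns.
#'
#' @param region an [aligned_region()].
#' @param ref_from,ref_to 1-based inclusive interval; must lie within
#'   `[region$ref_first, region$ref_last]`.
#' @param scheme [scoring_scheme()] used to recompute the sliced raw score.
#' @return The sliced `aligned_region` covering exactly `[ref_from, ref_to]`.
#' @export
slice_region <- function(region, ref_from, ref_to, scheme = scoring_scheme()) {
  stopifnot(inherits(region, "aligned_region"))
  if (ref_from < region$ref_first || ref_to > region$ref_last || ref_from > ref_to)
    stop(sprintf("slice [%d, %d] outside region [%d, %d]",
                 ref_from, ref_to, region$ref_first, region$ref_last),
         call. = FALSE)
  if (ref_from == region$ref_first && ref_to == region$ref_last) return(region)
  anchor <- region_anchors(region)
  keep <- anchor >= ref_from & anchor <= ref_to
  cols <- region_columns(region)
  qg <- cols$q[keep]; rg <- cols$r[keep]
  codons <- if (is.null(region$codons)) NULL else region$codons[keep]
  qa <- paste(qg, collapse = ""); ra <- paste(rg, collapse = "")
  raw <- score_columns(list(query_gapped = qa, ref_gapped = ra), scheme)
  aligned_region(region$query_id, region$ref_id, qa, ra, ref_from, ref_to,
                 region$frame, raw_score = raw, codons = codons,
                 query_first = region$query_first,
                 query_last = region$query_last, evalue = region$evalue)
}
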