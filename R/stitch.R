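#' Stitch overlapping hit regions into an ordered, non-overlapping set
#'
#' Implements the stack-based hit-stitching procedure. Regions for one
#' reference are sorted by how they align to it (by `ref_first`, then
#' longer regions first, then `query_id`) and pushed onto a stack. When the
#' region on top of the stack overlaps the next region, the top is popped
#' and both candidates are realigned -- only over the reference interval in
#' which they overlap -- against the corresponding reference slice; the
#' higher-scoring candidate is retained at the overlap and up to three
#' sliced parts are pushed back as new, separate regions: the left flank
#' from the earlier region, the winning overlap segment, and the right
#' flank from the region extending further right. Passes repeat until no
#' overlaps remain (new slices may themselves overlap other regions).
#' Containment is the degenerate case where the overlap is the inner
#' region's full extent. Regions from the same query contig may end up
#' stitched together.
#'
#' Overlap realignment uses global alignment of each candidate's overlap
#' residues against the fixed reference slice, so candidate scores are
#' directly comparable. Score ties keep the earlier region's segment
#' (lower `ref_first`, then lexicographically smaller `query_id`).
#'
#' @param regions list of [aligned_region()]s sharing one `ref_id`.
#' @param reference the corresponding reference [seq_records] row (or any
#'   list with `id` and `seq`).
#' @param scheme [scoring_scheme()] used for overlap realignment.
#' @param trace record every overlap decision (interval, both candidate
#'   realignment scores, winner) in a `trace` attribute for auditing.
#' @return A `region_stack`: list of non-overlapping `aligned_region`s in
#'   reference order, with attributes `passes` (iterations used) and
#'   `overlaps_resolved` (count of pairwise overlap resolutions); with
#'   `trace = TRUE` also a `trace` data frame.
#' @export
stitch <- function(regions, reference, scheme = scoring_scheme(),
                   trace = FALSE) {
  stopifnot(length(regions) >= 1L)
  ids <- unique(vapply(regions, `[[`, character(1), "ref_id"))
  if (length(ids) != 1L)
    stop("regions mix reference ids: ", paste(ids, collapse = ", "),
         call. = FALSE)
  ref_len <- nchar(reference$seq)
  too_far <- vapply(regions, function(r) r$ref_last > ref_len, logical(1))
  if (any(too_far))
    stop("region extends beyond reference length ", ref_len, call. = FALSE)

  passes <- 0L; resolved <- 0L
  decisions <- list()
  repeat {
    passes <- passes + 1L
    if (passes > 10000L) stop("stitching did not converge", call. = FALSE)
    regions <- sort_regions(regions)
    stack <- list(regions[[1L]])
    changed <- FALSE
    for (b in regions[-1L]) {
      a <- stack[[length(stack)]]
      # sliced parts pushed mid-pass can start after the next region, so
      # the disjointness test must look both ways; any ordering left
      # behind here is restored by the re-sort at the next pass
      if (a$ref_last < b$ref_first || b$ref_last < a$ref_first) {
        stack[[length(stack) + 1L]] <- b
        next
      }
      changed <- TRUE
      resolved <- resolved + 1L
      stack[[length(stack)]] <- NULL
      res <- resolve_overlap(a, b, reference, scheme)
      if (trace) decisions[[length(decisions) + 1L]] <- res$decision
      for (p in res$parts) stack[[length(stack) + 1L]] <- p
    }
    regions <- stack
    if (!changed) break
  }
  out <- structure(regions, class = "region_stack", passes = passes,
                   overlaps_resolved = resolved)
  if (trace)
    attr(out, "trace") <- if (length(decisions) > 0L)
      do.call(rbind, decisions) else NULL
  out
}

sort_regions <- function(regions) {
  first <- vapply(regions, `[[`, integer(1), "ref_first")
  last <- vapply(regions, `[[`, integer(1), "ref_last")
  qid <- vapply(regions, `[[`, character(1), "query_id")
  regions[order(first, -(last - first), qid, method = "radix")]
}

# TRUE when x sorts before y: lower ref_first, then longer, then query_id
earlier_region <- function(x, y) {
  if (x$ref_first != y$ref_first) return(x$ref_first < y$ref_first)
  if (x$ref_last != y$ref_last) return(x$ref_last > y$ref_last)
  x$query_id <= y$query_id
}

# pop-and-slice resolution of one overlapping pair; returns <= 3 regions
# plus a one-row decision record
resolve_overlap <- function(a, b, reference, scheme) {
  o_start <- max(a$ref_first, b$ref_first)
  o_end <- min(a$ref_last, b$ref_last)
  ref_slice <- substr(reference$seq, o_start, o_end)

  overlap_score <- function(region) {
    sl <- slice_region(region, o_start, o_end, scheme)
    qres <- paste(region_query_residues(sl)$residues, collapse = "")
    align(qres, ref_slice, scheme, mode = "global")$score
  }
  sa <- overlap_score(a); sb <- overlap_score(b)
  winner <- if (sa > sb) a else if (sb > sa) b
            else if (earlier_region(a, b)) a else b

  first <- if (earlier_region(a, b)) a else b
  rightmost <- if (a$ref_last > b$ref_last) a
               else if (b$ref_last > a$ref_last) b else NULL

  parts <- list()
  if (o_start > first$ref_first)
    parts[[length(parts) + 1L]] <-
      slice_region(first, first$ref_first, o_start - 1L, scheme)
  parts[[length(parts) + 1L]] <- slice_region(winner, o_start, o_end, scheme)
  if (!is.null(rightmost) && rightmost$ref_last > o_end)
    parts[[length(parts) + 1L]] <-
      slice_region(rightmost, o_end + 1L, rightmost$ref_last, scheme)
  list(parts = parts,
       decision = data.frame(o_start = o_start, o_end = o_end,
                             score_a = sa, score_b = sb,
                             winner_score = if (identical(winner, a)) sa else sb,
                             loser_score = if (identical(winner, a)) sb else sa,
                             stringsAsFactors = FALSE))
}

#' @export
print.region_stack <- function(x, ...) {
  cat(sprintf("region_stack: %d non-overlapping region(s), %d pass(es)\n",
              length(x), attr(x, "passes")))
  for (r in x)
    cat(sprintf("  [%d..%d] %s raw %d\n", r$ref_first, r$ref_last,
                r$query_id, r$raw_score))
  invisible(x)
}
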