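#' Scoring schemes for amino-acid alignment
#'
#' A scoring scheme bundles a symmetric substitution matrix with affine gap
#' penalties. A gap of length `L` costs `gap_open + L * gap_extend` (BLAST
#' convention: a length-1 gap under the default 11/1 scheme costs 12). The
#' default matrix is BLOSUM62 over the 25-letter alphabet
#' `A R N D C Q E G H I L K M F P S T W Y V B J Z X *`.
#'
#' @param matrix square integer substitution matrix with identical row and
#'   column names (single residues). Default: BLOSUM62 as shipped with
#'   Biostrings.
#' @param gap_open non-negative gap opening penalty (default 11).
#' @param gap_extend non-negative gap extension penalty (default 1).
#' @param name label for logs and reports.
#' @return A `scoring_scheme` object.
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 11L, gap_extend = 1L,
                           name = if (is.null(matrix)) "BLOSUM62" else "custom") {
  if (is.null(matrix)) matrix <- blosum62()
  storage.mode(matrix) <- "integer"
  if (nrow(matrix) != ncol(matrix) || is.null(rownames(matrix)) ||
      !identical(rownames(matrix), colnames(matrix)))
    stop("substitution matrix must be square with identical row/column names",
         call. = FALSE)
  if (!isTRUE(all.equal(matrix, t(matrix), check.attributes = FALSE)))
    stop("substitution matrix must be symmetric", call. = FALSE)
  if (gap_open < 0 || gap_extend < 0)
    stop("gap penalties must be non-negative", call. = FALSE)
  if (gap_open < gap_extend)
    warning("gap_open < gap_extend is unusual for affine gap costs")
  structure(list(matrix = matrix, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), name = name),
            class = "scoring_scheme")
}

# cached default matrix
.blosum_env <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix (25 x 25, including B, J, Z, X and *)
#' @return Integer matrix with residue row/column names.
#' @export
blosum62 <- function() {
  if (is.null(.blosum_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    storage.mode(m) <- "integer"
    .blosum_env$BLOSUM62 <- m
  }
  .blosum_env$BLOSUM62
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix format used by BLAST-family tools: `#`
#' comment lines, one header line of column residues, then one row per
#' residue.
#'
#' @param path path to the matrix file.
#' @return Integer matrix with residue row/column names, usable as the
#'   `matrix` argument of [scoring_scheme()].
#' @export
read_score_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L) stop("not an NCBI-format matrix file: ", path, call. = FALSE)
  cols <- strsplit(lines[1L], "\\s+")[[1L]]
  rows <- strsplit(lines[-1L], "\\s+")
  rn <- vapply(rows, `[[`, character(1), 1L)
  vals <- lapply(rows, function(r) as.integer(r[-1L]))
  if (any(vapply(vals, length, integer(1)) != length(cols)))
    stop("matrix row length does not match header in ", path, call. = FALSE)
  m <- do.call(rbind, vals)
  dimnames(m) <- list(rn, cols)
  m[rn, rn, drop = FALSE]
}

# Encode an amino-acid string as 0-based indices into the scheme alphabet;
# errors name the first offending position.
encode_residues <- function(aa, scheme, what = "sequence") {
  if (!nzchar(aa)) return(integer(0))
  chars <- strsplit(toupper(aa), "", fixed = TRUE)[[1L]]
  idx <- match(chars, rownames(scheme$matrix))
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1L]
    stop(sprintf("residue '%s' at position %d of %s is outside the matrix alphabet",
                 chars[p], p, what), call. = FALSE)
  }
  idx - 1L
}
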