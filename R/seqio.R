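#' Sequence records
#'
#' A lightweight container for named sequences: a data frame with columns
#' `id` (first whitespace-delimited token of the header), `desc` (remainder
#' of the header), `seq` (residue string) and `alphabet` (`"nucleotide"` or
#' `"amino_acid"`).
#'
#' @param id character vector of identifiers.
#' @param seq character vector of residue strings.
#' @param desc character vector of descriptions (header remainders).
#' @param alphabet `"nucleotide"` or `"amino_acid"` (recycled).
#' @return A `seq_records` data frame.
#' @export
seq_records <- function(id, seq, desc = "", alphabet = "nucleotide") {
  stopifnot(length(id) == length(seq))
  out <- data.frame(id = as.character(id), desc = rep_len(as.character(desc), length(id)),
                    seq = as.character(seq),
                    alphabet = rep_len(match.arg(alphabet, c("nucleotide", "amino_acid")),
                                       length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  out
}

validate_records <- function(records, context = "input") {
  if (nrow(records) == 0L) return(invisible(records))
  empty <- records$id[!nzchar(records$seq)]
  if (length(empty) > 0L)
    stop(sprintf("record(s) with empty sequence in %s: %s", context,
                 paste(empty, collapse = ", ")), call. = FALSE)
  dup <- unique(records$id[duplicated(records$id)])
  if (length(dup) > 0L)
    stop(sprintf("duplicate sequence id(s) in %s: %s", context,
                 paste(dup, collapse = ", ")), call. = FALSE)
  invisible(records)
}

split_header <- function(headers) {
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  list(id = id, desc = desc)
}

#' Read a FASTA file
#'
#' Plain or gzip-compressed FASTA. The record id is the first
#' whitespace-delimited token of the header; the remainder becomes the
#' description. Records with empty sequences and duplicate ids are errors.
#'
#' @param path path to a FASTA file (optionally `.gz`).
#' @param alphabet `"auto"` (default), `"nucleotide"` or `"amino_acid"`.
#'   `"auto"` classifies as nucleotide when all residues are IUPAC DNA/RNA
#'   codes.
#' @return A [seq_records] data frame, in file order.
#' @export
read_fasta <- function(path, alphabet = c("auto", "nucleotide", "amino_acid")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) return(seq_records(character(), character()))
  hd <- split_header(names(set))
  seqs <- as.character(set)
  if (alphabet == "auto") {
    nt <- all(grepl("^[ACGTUNRYSWKMBDHVacgtunryswkmbdhv.-]*$", seqs))
    alphabet <- if (nt) "nucleotide" else "amino_acid"
  }
  out <- seq_records(hd$id, seqs, hd$desc, alphabet)
  validate_records(out, path)
  out
}

#' Write a FASTA file
#'
#' Sequences are wrapped at 80 columns; a `.gz` suffix selects gzip output.
#'
#' @param records a [seq_records] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(setNames(records$seq, NULL))
  names(set) <- ifelse(nzchar(records$desc),
                       paste(records$id, records$desc), records$id)
  Biostrings::writeXStringSet(set, path, width = 80L,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file
#'
#' Four-line-per-record FASTQ, optionally gzip-compressed. Quality strings
#' are discarded; records come back as nucleotide [seq_records].
#'
#' @param path path to a FASTQ file (optionally `.gz`).
#' @return A [seq_records] data frame.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(con <- gzfile(path, "rt")); close(con)
  if (length(lines) == 0L) return(seq_records(character(), character()))
  if (length(lines) %% 4L != 0L)
    stop(sprintf("truncated FASTQ record at record %d in %s",
                 length(lines) %/% 4L + 1L, path), call. = FALSE)
  idx <- seq(1L, length(lines), by = 4L)
  if (!all(startsWith(lines[idx], "@")))
    stop(sprintf("malformed FASTQ header at record %d in %s",
                 which(!startsWith(lines[idx], "@"))[1L], path), call. = FALSE)
  hd <- split_header(sub("^@", "", lines[idx]))
  out <- seq_records(hd$id, lines[idx + 1L], hd$desc, "nucleotide")
  validate_records(out, path)
  out
}

#' Write a FASTQ file (constant quality)
#'
#' Companion writer for the fixture generator and subsampler; qualities are
#' written as a constant `I` (Phred 40). A `.gz` suffix selects gzip.
#'
#' @param records a [seq_records] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(records) > 0L) {
    hdr <- ifelse(nzchar(records$desc),
                  paste(records$id, records$desc), records$id)
    writeLines(paste0("@", hdr, "\n", records$seq, "\n+\n",
                      strrep("I", nchar(records$seq))), con)
  }
  invisible(path)
}

#' Pool reference protein files into a single FASTA
#'
#' All reference proteins, regardless of how many files they are spread
#' across, are pooled into one FASTA (the database/search input). Ids must
#' be unique across the whole pool.
#'
#' @param paths character vector of amino-acid FASTA paths (>= 1).
#' @param pooled_path output path for the pooled FASTA.
#' @return A list with `path` (the pooled FASTA) and `records`
#'   (the pooled [seq_records]).
#' @export
pool_references <- function(paths, pooled_path = tempfile(fileext = ".fasta")) {
  stopifnot(length(paths) >= 1L)
  sets <- lapply(paths, read_fasta, alphabet = "amino_acid")
  all_ids <- unlist(lapply(sets, `[[`, "id"))
  if (anyDuplicated(all_ids)) {
    dup <- unique(all_ids[duplicated(all_ids)])
    src <- vapply(dup, function(d) {
      paste(paths[vapply(sets, function(s) d %in% s$id, logical(1))],
            collapse = " and ")
    }, character(1))
    stop("duplicate reference id(s) across files: ",
         paste(sprintf("%s (%s)", dup, src), collapse = "; "), call. = FALSE)
  }
  records <- do.call(rbind, sets)
  class(records) <- c("seq_records", "data.frame")
  write_fasta(records, pooled_path)
  list(path = pooled_path, records = records)
}

#' Reverse-complement a nucleotide string
#'
#' @param nt nucleotide string (IUPAC codes allowed).
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(nt) {
  if (!nzchar(nt)) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(chartr("Uu", "Tt", nt))))
}

#' Translate a nucleotide string in a given reading frame
#'
#' Standard genetic code. Positive frames 1-3 read the forward strand with
#' offsets 0-2; negative frames read the reverse complement. Trailing
#' partial codons are dropped. Stop codons become `*`; codons containing
#' ambiguity codes translate to a residue only when every resolution agrees
#' (e.g. `GCN` -> `A`), otherwise `X`.
#'
#' @param nt nucleotide string.
#' @param frame integer in `{1, 2, 3, -1, -2, -3}`.
#' @return Amino-acid string (possibly empty).
#' @export
translate_nt <- function(nt, frame = 1L) {
  stopifnot(frame %in% c(1L, 2L, 3L, -1L, -2L, -3L))
  if (!nzchar(nt)) return("")
  s <- toupper(chartr("Uu", "Tt", nt))
  if (frame < 0L) s <- revcomp(s)
  off <- abs(frame)
  if (nchar(s) < off + 2L) return("")
  s <- substr(s, off, off + ((nchar(s) - off + 1L) %/% 3L) * 3L - 1L)
  if (!nzchar(s)) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "solve"))
}

#' Translate all six reading frames
#'
#' @param nt nucleotide string.
#' @return Named character vector of translations for frames
#'   `1, 2, 3, -1, -2, -3`.
#' @export
six_frame_translations <- function(nt) {
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  setNames(vapply(frames, function(f) translate_nt(nt, f), character(1)),
           as.character(frames))
}
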