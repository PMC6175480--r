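#' Construct a transcript model
#'
#' A `transcript_model` couples an mRNA sequence with its coordinate system:
#' the leader (5' UTR) occupies the first `utr5_length` bases and the main ORF
#' (mORF) starts immediately after, at the annotated start codon (sAUG).
#' External coordinates follow HGVS c. convention (c.1 is the A of the sAUG,
#' negative positions count into the leader, there is no position 0); internal
#' indices are ordinary 1-based R positions.
#'
#' @param sequence Nucleotide string. Lowercase is uppercased and RNA `U` is
#'   mapped to `T`, so DNA and RNA spellings behave identically. Only
#'   `A`, `C`, `G`, `T` and `N` are accepted; `N` in the leader triggers a
#'   warning (positions containing `N` never match AUG or stop codons).
#' @param utr5_length Number of leader nucleotides (>= 0). The sAUG must start
#'   at position `utr5_length + 1`.
#' @param id Text label for the transcript.
#' @param variants Optional character vector recording variants already applied
#'   to this sequence (set by [apply_variants()]).
#'
#' @return An object of class `transcript_model`: a list with elements `id`,
#'   `sequence`, `utr5_length`, `cds_start` (1-based index of the A of the
#'   sAUG) and `variants`.
#' @examples
#' tx <- transcript_model(paste0(strrep("C", 30), "ATGCATTAA"), utr5_length = 30)
#' tx
#' @seealso [read_transcript()], [c_to_index()], [index_to_c()]
#' @export
transcript_model <- function(sequence, utr5_length, id = "transcript",
                             variants = character()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  utr5_length <- as.integer(utr5_length)
  if (is.na(utr5_length) || utr5_length < 0L) {
    abort("`utr5_length` must be a non-negative integer.")
  }
  seq <- normalize_sequence(sequence)
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) {
    abort(sprintf(
      "Transcript '%s' contains unsupported characters: %s (only A/C/G/T/N allowed).",
      id, paste(bad, collapse = ", ")
    ))
  }
  if (nchar(seq) < utr5_length + 3L) {
    abort(sprintf(
      "Transcript '%s' is too short (%d nt) for utr5_length = %d plus a start codon.",
      id, nchar(seq), utr5_length
    ))
  }
  cds_start <- utr5_length + 1L
  if (substr(seq, cds_start, cds_start + 2L) != "ATG") {
    abort(sprintf(
      "Transcript '%s': declared CDS start (position %d) is '%s', not ATG.",
      id, cds_start, substr(seq, cds_start, cds_start + 2L)
    ))
  }
  if (utr5_length > 0L && grepl("N", substr(seq, 1L, utr5_length), fixed = TRUE)) {
    warn(sprintf(
      "Transcript '%s': leader contains N; positions with N are excluded from AUG/stop matching.",
      id
    ))
  }
  structure(
    list(id = id, sequence = seq, utr5_length = utr5_length,
         cds_start = cds_start, variants = as.character(variants)),
    class = "transcript_model"
  )
}

normalize_sequence <- function(x) {
  chartr("U", "T", toupper(x))
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s\n", x$id))
  cat(sprintf("  length: %d nt (leader %d nt + CDS %d nt)\n",
              nchar(x$sequence), x$utr5_length, nchar(x$sequence) - x$utr5_length))
  cat(sprintf("  sAUG at index %d (c.1_3)\n", x$cds_start))
  if (length(x$variants)) {
    cat(sprintf("  applied variants: %s\n", paste(x$variants, collapse = ", ")))
  }
  invisible(x)
}

#' Read a transcript from a FASTA file
#'
#' Loads one record from a (possibly multi-record) FASTA file and attaches the
#' coordinate system. The CDS start is declared either as the leader length
#' (`utr5_length`) or as the 1-based position of the A of the start codon
#' (`cds_start`); exactly one must be given.
#'
#' @param path Path to a FASTA file.
#' @param utr5_length Leader length in nucleotides.
#' @param cds_start 1-based position of the first CDS base (equivalent to
#'   `utr5_length + 1`).
#' @param record Record id to select in a multi-record file; defaults to the
#'   first record. Matching is on the first whitespace-delimited token of the
#'   FASTA header.
#' @return A [transcript_model()].
#' @export
read_transcript <- function(path, utr5_length = NULL, cds_start = NULL,
                            record = NULL) {
  if (is.null(utr5_length) == is.null(cds_start)) {
    abort("Declare the CDS start with exactly one of `utr5_length` or `cds_start`.")
  }
  if (!is.null(cds_start)) utr5_length <- as.integer(cds_start) - 1L
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) abort(sprintf("No FASTA records found in '%s'.", path))
  ids <- sub("\\s.*$", "", names(seqs))
  i <- 1L
  if (!is.null(record)) {
    i <- match(record, ids)
    if (is.na(i)) {
      abort(sprintf("Record '%s' not found in '%s' (records: %s).",
                    record, path, paste(ids, collapse = ", ")))
    }
  }
  transcript_model(as.character(seqs[[i]]), utr5_length = utr5_length, id = ids[[i]])
}

#' Write a transcript to a FASTA file
#'
#' @param model A [transcript_model()].
#' @param path Output FASTA path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(model, path, width = 70L) {
  x <- Biostrings::DNAStringSet(model$sequence)
  names(x) <- model$id
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Convert between HGVS c. positions and sequence indices
#'
#' `c_to_index()` maps HGVS c. positions to 1-based indices into the model
#' sequence; `index_to_c()` is its exact inverse. For a leader of length L,
#' c.-N maps to index `L - N + 1` and c.M (M > 0) to `L + M`; position 0 does
#' not exist, so c.-1 and c.1 are adjacent indices. Both functions are
#' vectorised.
#'
#' @param model A [transcript_model()].
#' @param cpos Integer vector of non-zero HGVS c. positions.
#' @param index Integer vector of 1-based sequence indices.
#' @return An integer vector of indices (`c_to_index`) or c. positions
#'   (`index_to_c`).
#' @examples
#' tx <- transcript_model(paste0(strrep("C", 30), "ATGCATTAA"), utr5_length = 30)
#' c_to_index(tx, c(-30, -1, 1))
#' index_to_c(tx, c(1, 30, 31))
#' @export
c_to_index <- function(model, cpos) {
  cpos <- as.integer(cpos)
  if (any(is.na(cpos) | cpos == 0L)) {
    abort("HGVS c. positions are non-zero integers (position 0 does not exist).")
  }
  L <- model$utr5_length
  idx <- ifelse(cpos < 0L, L + cpos + 1L, L + cpos)
  bad <- idx < 1L | idx > nchar(model$sequence)
  if (any(bad)) {
    abort(sprintf(
      "Position c.%s out of range for transcript '%s' (leader %d nt, length %d nt).",
      paste(cpos[bad], collapse = ", c."), model$id, L, nchar(model$sequence)
    ))
  }
  as.integer(idx)
}

#' @rdname c_to_index
#' @export
index_to_c <- function(model, index) {
  index <- as.integer(index)
  if (any(is.na(index) | index < 1L | index > nchar(model$sequence))) {
    abort(sprintf("Index out of bounds for transcript '%s' (length %d).",
                  model$id, nchar(model$sequence)))
  }
  L <- model$utr5_length
  as.integer(ifelse(index <= L, index - L - 1L, index - L))
}

#' One-row summary of a transcript model
#'
#' @param x A [transcript_model()].
#' @param ... Unused.
#' @return A one-row tibble with the transcript id, total and leader lengths,
#'   leader GC fraction and the number of leader AUGs.
#' @method glance transcript_model
#' @export
glance.transcript_model <- function(x, ...) {
  leader <- substr(x$sequence, 1L, x$utr5_length)
  gc <- if (nchar(leader)) {
    mean(strsplit(leader, "")[[1]] %in% c("G", "C"))
  } else NA_real_
  tibble(
    id = x$id,
    length_nt = nchar(x$sequence),
    utr5_length = x$utr5_length,
    leader_gc = gc,
    n_leader_augs = length(find_augs(x)),
    n_variants_applied = length(x$variants)
  )
}
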