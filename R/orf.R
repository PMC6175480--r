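#' Find AUG codons in a transcript region
#'
#' Exhaustive, overlap-aware scan for `ATG` triplets whose first base lies in
#' the given region. The default region is the leader (5' UTR), which is the
#' screen used to establish that a wild-type leader carries no upstream AUG.
#'
#' @param model A [transcript_model()].
#' @param region Either `"leader"` (default), `"all"`, or an integer pair of
#'   1-based sequence indices `c(from, to)` delimiting where the first base of
#'   a match may lie.
#' @return Ascending integer vector of HGVS c. positions of every AUG first
#'   base in the region (empty when none).
#' @examples
#' tx <- transcript_model(paste0("GATGATGGC", strrep("C", 21), "ATGCATTAA"), 30)
#' find_augs(tx)  # overlapping AUGs both reported
#' @export
find_augs <- function(model, region = "leader") {
  stopifnot(inherits(model, "transcript_model"))
  if (identical(region, "leader")) {
    region <- c(1L, model$utr5_length)
  } else if (identical(region, "all")) {
    region <- c(1L, nchar(model$sequence))
  }
  from <- as.integer(region[1]); to <- as.integer(region[2])
  if (from > to) return(integer())
  if (from < 1L || to > nchar(model$sequence)) {
    abort(sprintf("Region [%d, %d] outside transcript '%s' (length %d).",
                  from, to, model$id, nchar(model$sequence)))
  }
  hits <- gregexpr("(?=ATG)", model$sequence, perl = TRUE)[[1]]
  hits <- hits[hits > 0L]
  hits <- hits[hits >= from & hits <= to & hits + 2L <= nchar(model$sequence)]
  if (length(hits) == 0L) return(integer())
  index_to_c(model, sort(hits))
}

#' Reading-frame offset of an upstream AUG relative to the main ORF
#'
#' For a leader AUG at c.-N, the distance to the sAUG (c.1) is exactly N
#' nucleotides, so the AUG is in frame with the main ORF iff N is divisible
#' by 3. The offset is `N mod 3`: 0 means in frame.
#'
#' @param cpos Integer vector of negative HGVS c. positions (uAUG first
#'   bases). Positive positions are rejected: frame offsets are defined for
#'   upstream AUGs only.
#' @return Integer vector of offsets in `{0, 1, 2}`.
#' @examples
#' frame_offset(c(-255, -263, -3))
#' @export
frame_offset <- function(cpos) {
  cpos <- as.integer(cpos)
  if (any(cpos >= 0L)) {
    abort("Frame offsets are defined for upstream (negative c.) AUG positions only.")
  }
  abs(cpos) %% 3L
}

#' Delineate the open reading frame initiated at an upstream AUG
#'
#' Walks codon by codon from a leader AUG and classifies the resulting ORF:
#'
#' * `uORF_terminating_in_leader` — the first in-frame stop (`TAA`/`TAG`/`TGA`)
#'   lies wholly within the leader: a classic upstream ORF. Length and the two
#'   intercistronic-distance conventions are reported (see Details).
#' * `inframe_readthrough_extension` — the AUG is in frame with the main ORF
#'   and no stop intervenes before c.1: translation reads through into the CDS
#'   and adds `extension_codons = N/3` residues N-terminally.
#' * `overlapping_oORF` — the AUG is out of frame and its ORF crosses the sAUG
#'   into the CDS (including the case of a stop codon straddling the
#'   leader/CDS boundary), terminating at the first downstream in-frame stop.
#'
#' @details Two distance conventions are in circulation for the gap between a
#' uORF and the main ORF and both are reported: `dist_stop_end` counts the
#' bases strictly between the last stop base and c.1 (`|stop_last| - 1`),
#' `dist_stop_start` counts from the first stop base through c.-1 inclusive
#' (`|stop_first|`); they differ by 3 for the same stop. Codon counts are
#' likewise given both including and excluding the terminating stop.
#'
#' @param model A [transcript_model()] (typically after [apply_variants()]).
#' @param start HGVS c. position (negative) of a leader AUG; an error is
#'   raised if the sequence does not carry `ATG` there.
#' @return A one-row tibble: `start`, `frame`, `kind`, `stop_first`,
#'   `stop_last`, `length_nt`, `codons_incl_stop`, `codons_excl_stop`,
#'   `dist_stop_end`, `dist_stop_start`, `extension_codons`. Stop and distance
#'   fields are `NA` where not applicable (readthrough has no stop; distances
#'   are upstream-only quantities, reported just for leader-terminating uORFs).
#' @examples
#' leader <- paste0(strrep("C", 6), "ATGGGG", "TAA", strrep("C", 15))
#' tx <- transcript_model(paste0(leader, "ATGCATTAA"), utr5_length = 30)
#' delineate_orf(tx, -24)
#' @export
delineate_orf <- function(model, start) {
  stopifnot(inherits(model, "transcript_model"))
  start <- as.integer(start)
  if (length(start) != 1L || is.na(start) || start > -3L) {
    abort("`start` must be a single c. position <= -3 (an AUG wholly within the leader).")
  }
  i <- c_to_index(model, start)
  if (substr(model$sequence, i, i + 2L) != "ATG") {
    abort(sprintf("No ATG at c.%d on transcript '%s' (found '%s').",
                  start, model$id, substr(model$sequence, i, i + 2L)))
  }
  L <- model$utr5_length
  n <- nchar(model$sequence)
  offset <- frame_offset(start)

  starts <- seq.int(i, n - 2L, by = 3L)
  codons <- substring(model$sequence, starts, starts + 2L)
  is_stop <- codons %in% STOP_CODONS
  # in-frame AUGs stop scanning at c.1 when in frame with the mORF
  if (offset == 0L) {
    before_cds <- starts < model$cds_start
    first_stop <- match(TRUE, is_stop & before_cds)
  } else {
    first_stop <- match(TRUE, is_stop)
  }

  rec <- tibble(
    start = start, frame = offset, kind = NA_character_,
    stop_first = NA_integer_, stop_last = NA_integer_,
    length_nt = NA_integer_, codons_incl_stop = NA_integer_,
    codons_excl_stop = NA_integer_,
    dist_stop_end = NA_integer_, dist_stop_start = NA_integer_,
    extension_codons = NA_integer_
  )

  if (offset == 0L && is.na(first_stop)) {
    rec$kind <- "inframe_readthrough_extension"
    rec$extension_codons <- abs(start) %/% 3L
    return(rec)
  }
  if (is.na(first_stop)) {
    # out of frame, runs off the 3' end without a stop: still an overlapping ORF
    rec$kind <- "overlapping_oORF"
    return(rec)
  }
  s1 <- starts[first_stop]
  s3 <- s1 + 2L
  rec$stop_first <- index_to_c(model, s1)
  rec$stop_last <- index_to_c(model, s3)
  rec$length_nt <- s3 - i + 1L
  rec$codons_incl_stop <- rec$length_nt %/% 3L
  rec$codons_excl_stop <- rec$codons_incl_stop - 1L
  if (s3 <= L) {
    rec$kind <- "uORF_terminating_in_leader"
    rec$dist_stop_end <- L - s3                 # == |stop_last| - 1
    rec$dist_stop_start <- L - s1 + 1L          # == |stop_first|
  } else {
    rec$kind <- "overlapping_oORF"
  }
  rec
}

#' Compare leader AUG and uORF-stop content between two sequences
#'
#' Computes which upstream AUGs a variant (set) creates or destroys, and — for
#' AUGs present in both sequences — which in-frame leader stop codons it
#' creates or destroys (a stop change reshapes an existing uORF without
#' touching its start). Both directions matter: variants that introduce and
#' variants that disrupt upstream ORFs are documented disease mechanisms.
#'
#' @param ref_model A [transcript_model()]: the reference.
#' @param alt The altered sequence: a `transcript_model` (same coordinate
#'   system) or a plain character sequence of identical length.
#' @return A list with integer c.-position vectors `created`, `destroyed`
#'   (uAUG first bases), and `uorf_stop_created`, `uorf_stop_destroyed`
#'   (first bases of in-frame leader stops downstream of a shared uAUG).
#' @export
diff_uaug_events <- function(ref_model, alt) {
  stopifnot(inherits(ref_model, "transcript_model"))
  alt_model <- if (inherits(alt, "transcript_model")) alt else {
    m <- ref_model
    m$sequence <- normalize_sequence(alt)
    m
  }
  if (nchar(alt_model$sequence) != nchar(ref_model$sequence)) {
    abort("Sequences differ in length; only substitutions are comparable.")
  }
  ref_augs <- find_augs(ref_model)
  alt_augs <- find_augs(alt_model)
  shared <- intersect(ref_augs, alt_augs)
  stops_of <- function(model, aug) {
    i <- c_to_index(model, aug)
    if (i + 3L > model$utr5_length - 2L) return(integer())
    starts <- seq.int(i + 3L, model$utr5_length - 2L, by = 3L)
    if (length(starts) == 0L) return(integer())
    codons <- substring(model$sequence, starts, starts + 2L)
    index_to_c(model, starts[codons %in% STOP_CODONS])
  }
  ref_stops <- sort(unique(unlist(lapply(shared, stops_of, model = ref_model))))
  alt_stops <- sort(unique(unlist(lapply(shared, stops_of, model = alt_model))))
  list(
    created = as.integer(setdiff(alt_augs, ref_augs)),
    destroyed = as.integer(setdiff(ref_augs, alt_augs)),
    uorf_stop_created = as.integer(setdiff(alt_stops, ref_stops)),
    uorf_stop_destroyed = as.integer(setdiff(ref_stops, alt_stops))
  )
}
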