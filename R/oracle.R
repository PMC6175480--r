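# Brute-force ORF oracle.
#
# Deliberately written as a plain character-by-character walk, independent of
# the vectorised scanner in orf.R: it is the ground truth for property tests
# and for labelling spiked variants, so it must not share code paths with the
# implementation it checks.

orf_oracle <- function(sequence, utr5_length, start_cpos) {
  L <- utr5_length
  i <- L + start_cpos + 1L            # index of the A of the uAUG
  n <- nchar(sequence)
  in_frame <- (abs(start_cpos) %% 3L) == 0L
  pos <- i
  repeat {
    if (pos + 2L > n) {
      return(list(kind = if (in_frame) "inframe_readthrough_extension" else "overlapping_oORF",
                  stop_first = NA_integer_, n_codons = NA_integer_))
    }
    if (in_frame && pos == L + 1L) {
      return(list(kind = "inframe_readthrough_extension",
                  stop_first = NA_integer_, n_codons = NA_integer_))
    }
    codon <- paste0(substr(sequence, pos, pos), substr(sequence, pos + 1L, pos + 1L),
                    substr(sequence, pos + 2L, pos + 2L))
    if (codon == "TAA" || codon == "TAG" || codon == "TGA") {
      kind <- if (pos + 2L <= L) "uORF_terminating_in_leader" else "overlapping_oORF"
      cstop <- if (pos <= L) pos - L - 1L else pos - L
      return(list(kind = kind, stop_first = as.integer(cstop),
                  n_codons = as.integer((pos + 2L - i + 1L) / 3L)))
    }
    pos <- pos + 3L
  }
}

# Leader AUG scan by the same pedestrian route.
aug_oracle <- function(sequence, utr5_length) {
  out <- integer()
  if (utr5_length < 1L) return(out)
  for (p in seq_len(utr5_length)) {
    if (p + 2L <= nchar(sequence) &&
        substr(sequence, p, p + 2L) == "ATG") {
      out <- c(out, p - utr5_length - 1L)
    }
  }
  out
}

# Expected classification of a cis SNV set, derived purely from the oracles.
oracle_classification <- function(model, variants) {
  seq <- model$sequence
  for (k in seq_len(nrow(variants))) {
    i <- model$utr5_length + variants$cpos[k] + (if (variants$cpos[k] < 0L) 1L else 0L)
    substr(seq, i, i) <- variants$alt[k]
  }
  L <- model$utr5_length
  ref_augs <- aug_oracle(model$sequence, L)
  alt_augs <- aug_oracle(seq, L)
  created <- setdiff(alt_augs, ref_augs)
  destroyed <- setdiff(ref_augs, alt_augs)
  if (length(created) > 0L) {
    kind <- orf_oracle(seq, L, min(created))$kind
    return(switch(kind,
      uORF_terminating_in_leader = "UAUG_CREATED_UORF",
      inframe_readthrough_extension = "UAUG_CREATED_INFRAME_EXTENSION",
      overlapping_oORF = "UAUG_CREATED_OVERLAPPING_OORF"
    ))
  }
  if (length(destroyed) > 0L) return("UAUG_DESTROYED")
  shared <- intersect(ref_augs, alt_augs)
  stops_in_frame <- function(s, aug) {
    res <- integer()
    p <- L + aug + 1L + 3L
    while (p + 2L <= L) {
      codon <- substr(s, p, p + 2L)
      if (codon %in% c("TAA", "TAG", "TGA")) res <- c(res, p - L - 1L)
      p <- p + 3L
    }
    res
  }
  ref_stops <- sort(unique(unlist(lapply(shared, stops_in_frame, s = model$sequence))))
  alt_stops <- sort(unique(unlist(lapply(shared, stops_in_frame, s = seq))))
  if (length(setdiff(alt_stops, ref_stops)) > 0L) return("UORF_STOP_CREATED")
  if (length(setdiff(ref_stops, alt_stops)) > 0L) return("UORF_STOP_DESTROYED")
  "NO_UAUG_CHANGE"
}
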