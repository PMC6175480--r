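#' Generate a random transcript
#'
#' Draws a leader of the requested length and GC content, appends a short CDS
#' (an ATG, a random body, and a terminator cassette carrying a stop codon in
#' each of the three reading frames so downstream ORFs always terminate).
#' Used for property-style testing of the ORF scanner against the brute-force
#' oracle; real leaders are neither iid nor stop-free, and no claim is made
#' that these resemble biological sequence beyond base composition.
#'
#' @param utr5_length Leader length (>= 0).
#' @param gc_fraction Target leader GC fraction in (0, 1).
#' @param seed Integer seed; identical arguments reproduce identical models.
#' @param forbid_leader_aug If `TRUE`, rejection-sample until the leader
#'   carries no ATG (errors after 10000 attempts).
#' @param cds_body_length Length of the random CDS body between the ATG and
#'   the terminator cassette.
#' @return A [transcript_model()].
#' @export
random_transcript <- function(utr5_length, gc_fraction = 0.6, seed = 1L,
                              forbid_leader_aug = FALSE, cds_body_length = 30L) {
  stopifnot(utr5_length >= 0, gc_fraction > 0, gc_fraction < 1)
  prob <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
            (1 - gc_fraction) / 2)
  withr::with_seed(seed, {
    draw_leader <- function() {
      paste(sample(c("A", "C", "G", "T"), utr5_length, replace = TRUE, prob = prob),
            collapse = "")
    }
    leader <- draw_leader()
    if (forbid_leader_aug) {
      tries <- 1L
      while (grepl("ATG", leader, fixed = TRUE)) {
        tries <- tries + 1L
        if (tries > 10000L) {
          abort("Could not draw an AUG-free leader within the rejection budget.")
        }
        leader <- draw_leader()
      }
    }
    body <- paste(sample(c("A", "C", "G", "T"), cds_body_length, replace = TRUE,
                         prob = prob), collapse = "")
    transcript_model(paste0(leader, "ATG", body, "TAACTGACTAG"),
                     utr5_length = utr5_length,
                     id = sprintf("random_utr%d_seed%d", utr5_length, seed))
  })
}

#' Spike labelled single-nucleotide variants into a transcript
#'
#' Enumerates every possible leader SNV of the model, labels each candidate
#' with the classification it should receive — computed by the brute-force
#' triplet-enumeration oracle, not by the annotation pipeline itself — and
#' samples a class-stratified mixture. On a leader that already carries AUGs,
#' the mixture includes uAUG-destroying and uORF-stop-creating/destroying
#' edits; on an AUG-free leader those classes are simply unavailable and the
#' mixture covers the creating and inert classes.
#'
#' @param model A [transcript_model()].
#' @param n Number of spiked cases to return (0 gives an empty table).
#' @param seed Integer seed for the stratified sampling.
#' @return A tibble with columns `case_id`, `spec` (HGVS label), `variants`
#'   (list-column of one-row parsed variant tibbles) and
#'   `expected_classification` (oracle-derived ground truth).
#' @export
spike_variants <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "transcript_model"))
  n <- as.integer(n)
  if (n == 0L) {
    return(tibble(case_id = integer(), spec = character(),
                  variants = list(), expected_classification = character()))
  }
  L <- model$utr5_length
  leader <- strsplit(substr(model$sequence, 1L, L), "")[[1]]
  cand <- list()
  for (idx in seq_len(L)) {
    ref <- leader[idx]
    if (!ref %in% c("A", "C", "G", "T")) next
    cpos <- idx - L - 1L
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      v <- tibble(label = sprintf("c.%d%s>%s", cpos, ref, alt),
                  cpos = as.integer(cpos), ref = ref, alt = alt)
      cand[[length(cand) + 1L]] <- tibble(
        spec = v$label, variants = list(v),
        expected_classification = oracle_classification(model, v)
      )
    }
  }
  cand <- list_rbind(cand)
  withr::with_seed(seed, {
    classes <- split(seq_len(nrow(cand)), cand$expected_classification)
    # round-robin over available classes so rare events are represented
    picked <- integer()
    pools <- lapply(classes, \(ix) sample(ix))
    while (length(picked) < n && any(lengths(pools) > 0L)) {
      for (cl in names(pools)) {
        if (length(picked) >= n) break
        if (length(pools[[cl]]) > 0L) {
          picked <- c(picked, pools[[cl]][1])
          pools[[cl]] <- pools[[cl]][-1]
        }
      }
    }
    if (length(picked) < n) {
      # more cases requested than distinct SNVs exist; recycle inert ones
      extra <- sample(seq_len(nrow(cand)), n - length(picked), replace = TRUE)
      picked <- c(picked, extra)
    }
    out <- cand[picked, , drop = FALSE]
    out$case_id <- seq_len(nrow(out))
    out[, c("case_id", "spec", "variants", "expected_classification")]
  })
}
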