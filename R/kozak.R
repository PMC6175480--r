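#' Kozak position-weight model
#'
#' A transparent scoring scheme for the translation-initiation context
#' `gccRccAUGG` (positions -6..-1 around the AUG plus +4). The two positions
#' with the strongest experimental support — a purine at -3 and a G at +4 —
#' carry a dominant weight; the remaining consensus positions contribute a
#' small match bonus. The defaults guarantee that any context differing only
#' at -3 (pyrimidine to purine) or +4 (to G) scores strictly higher, and that
#' dominance at -3/+4 can never be overturned by the minor positions combined
#' (5 x 0.5 < 3).
#'
#' @param weights Named list overriding per-position base weights. Names are
#'   `"-6"`, `"-5"`, `"-4"`, `"-3"`, `"-2"`, `"-1"`, `"+4"`; each element a
#'   named numeric vector of base weights (bases absent from the vector score
#'   0, as does `N`).
#' @return A `kozak_model` object with elements `weights` and `consensus`
#'   (`"GCCACCATGG"`, the DNA rendering of gccRccAUGG, which attains the
#'   maximal score).
#' @examples
#' km <- kozak_model()
#' kozak_evaluate("GCCACCATGG", km)
#' @export
kozak_model <- function(weights = NULL) {
  default <- list(
    `-6` = c(G = 0.5), `-5` = c(C = 0.5), `-4` = c(C = 0.5),
    `-3` = c(A = 3, G = 3),
    `-2` = c(C = 0.5), `-1` = c(C = 0.5),
    `+4` = c(G = 3)
  )
  if (!is.null(weights)) {
    for (nm in names(weights)) {
      if (!nm %in% names(default)) {
        abort(sprintf("Unknown Kozak position '%s' (known: %s).",
                      nm, paste(names(default), collapse = ", ")))
      }
      default[[nm]] <- weights[[nm]]
    }
  }
  structure(list(weights = default, consensus = "GCCACCATGG"),
            class = "kozak_model")
}

#' Read a Kozak weight override from a YAML config
#'
#' The file maps position keys (`"-6"` .. `"-1"`, `"+4"`) to base: weight
#' maps, e.g. `"-3": {A: 3, G: 3}`.
#'
#' @param path YAML file path.
#' @return A [kozak_model()].
#' @export
read_kozak_config <- function(path) {
  raw <- yaml::read_yaml(path)
  kozak_model(weights = lapply(raw, \(w) unlist(w)))
}

#' @export
print.kozak_model <- function(x, ...) {
  cat("<kozak_model> consensus", x$consensus, "\n")
  for (nm in names(x$weights)) {
    w <- x$weights[[nm]]
    cat(sprintf("  %3s: %s\n", nm,
                paste(sprintf("%s=%g", names(w), w), collapse = " ")))
  }
  invisible(x)
}

#' Weight table of a Kozak model as a tibble
#'
#' @param x A [kozak_model()].
#' @param ... Unused.
#' @return A tibble with columns `position`, `base`, `weight`.
#' @method tidy kozak_model
#' @export
tidy.kozak_model <- function(x, ...) {
  list_rbind(map2(names(x$weights), x$weights, \(p, w) {
    tibble(position = p, base = names(w), weight = unname(w))
  }))
}

# window positions of the 10-mer, AUG occupying characters 7..9
KOZAK_POSITIONS <- c("-6", "-5", "-4", "-3", "-2", "-1", "AUG", "AUG", "AUG", "+4")

#' Extract the translation-initiation context around an AUG
#'
#' Returns the 10-mer covering positions -6..+4 relative to an AUG (the AUG
#' itself occupies characters 7–9 of the window). Positions falling outside
#' the sequence are padded with `N`, which scores 0.
#'
#' @param model A [transcript_model()], or a plain nucleotide string.
#' @param at The AUG location: an HGVS c. position when `model` is a
#'   transcript model, or a 1-based index when `model` is a string.
#' @return A 10-character context string.
#' @examples
#' extract_context("ATGGCCCCC", 1)  # "NNNNNNATGG"
#' @export
extract_context <- function(model, at) {
  if (inherits(model, "transcript_model")) {
    seq <- model$sequence
    i <- c_to_index(model, at)
  } else {
    seq <- normalize_sequence(model)
    i <- as.integer(at)
  }
  if (substr(seq, i, i + 2L) != "ATG") {
    abort(sprintf("No ATG at the requested position (found '%s').",
                  substr(seq, i, i + 2L)))
  }
  idx <- seq.int(i - 6L, i + 3L)
  chars <- rep("N", 10L)
  ok <- idx >= 1L & idx <= nchar(seq)
  chars[ok] <- substring(seq, idx[ok], idx[ok])
  paste(chars, collapse = "")
}

#' Score and classify a translation-initiation context
#'
#' Scores a -6..+4 context 10-mer under a [kozak_model()] and assigns a
#' strength class from the two dominant determinants alone: `strong` when -3
#' is a purine and +4 is G, `adequate` when exactly one of the two holds,
#' `weak` when neither does. The class is therefore invariant to every other
#' window position; the score breaks ties within a class.
#'
#' @param context Character vector of 10-mers over `{A,C,G,T,N}` with `ATG` at
#'   characters 7–9 (as from [extract_context()]); `N` contributes 0.
#' @param model A [kozak_model()].
#' @return A tibble with one row per context: `context`, `score`, `strength`,
#'   `minus3`, `plus4`.
#' @examples
#' kozak_evaluate(c("GCCACCATGG", "GCCTCCATGC"))
#' @export
kozak_evaluate <- function(context, model = kozak_model()) {
  stopifnot(inherits(model, "kozak_model"))
  context <- toupper(context)
  ok <- nchar(context) == 10L &
    !grepl("[^ACGTN]", context) &
    substr(context, 7L, 9L) == "ATG"
  if (any(!ok)) {
    abort(sprintf("Malformed context (need 10 chars over A/C/G/T/N with ATG at 7-9): %s.",
                  paste(sQuote(context[!ok]), collapse = ", ")))
  }
  score_one <- function(ctx) {
    chars <- strsplit(ctx, "")[[1]]
    s <- 0
    for (k in seq_len(10L)) {
      pos <- KOZAK_POSITIONS[k]
      if (pos == "AUG") next
      w <- model$weights[[pos]]
      v <- unname(w[chars[k]])
      s <- s + if (length(v) == 1L && !is.na(v)) v else 0
    }
    unname(s)
  }
  minus3 <- substr(context, 4L, 4L)
  plus4 <- substr(context, 10L, 10L)
  good3 <- minus3 %in% c("A", "G")
  good4 <- plus4 == "G"
  tibble(
    context = context,
    score = map_dbl(context, score_one),
    strength = dplyr::case_when(
      good3 & good4 ~ "strong",
      good3 | good4 ~ "adequate",
      .default = "weak"
    ),
    minus3 = minus3,
    plus4 = plus4
  )
}

#' Kozak evaluation of an AUG in place
#'
#' Convenience wrapper: extracts the context around an AUG of a transcript and
#' evaluates it in one step.
#'
#' @param model A [transcript_model()].
#' @param at HGVS c. position of the AUG first base.
#' @param kozak A [kozak_model()].
#' @return A one-row tibble as from [kozak_evaluate()], with a `pos` column
#'   prepended.
#' @export
kozak_at <- function(model, at, kozak = kozak_model()) {
  ctx <- extract_context(model, at)
  dplyr::bind_cols(tibble(pos = as.integer(at)), kozak_evaluate(ctx, kozak))
}
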