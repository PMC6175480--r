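#' Annotation configuration
#'
#' Tunable thresholds of the consequence classifier. The repression heuristic
#' codifies the two geometric properties known to govern whether a uORF
#' represses downstream initiation: its length (long uORFs disfavour
#' reinitiation) and the intercistronic distance (short gaps leave no room to
#' re-acquire initiation competence). The defaults are deliberately
#' conservative operating points, not biological constants, and are exposed
#' for tuning.
#'
#' @param min_repressive_uorf_codons A uORF at least this many codons long
#'   (stop included) is flagged repressive regardless of distance. Default 10.
#' @param min_safe_reinit_distance_nt A uORF whose stop ends closer than this
#'   to the sAUG (stop-end convention, nt) is flagged repressive. Default 200.
#' @param avg_residue_mass_da Average amino-acid residue mass used to predict
#'   the size of an N-terminal extension. Default 110 Da.
#' @param kozak A [kozak_model()] used for context scoring.
#' @return An `annotation_config` object.
#' @export
annotation_config <- function(min_repressive_uorf_codons = 10L,
                              min_safe_reinit_distance_nt = 200L,
                              avg_residue_mass_da = 110,
                              kozak = kozak_model()) {
  if (min_repressive_uorf_codons <= 0 || min_safe_reinit_distance_nt <= 0 ||
      avg_residue_mass_da <= 0) {
    abort("All annotation thresholds must be strictly positive.")
  }
  structure(
    list(
      min_repressive_uorf_codons = as.integer(min_repressive_uorf_codons),
      min_safe_reinit_distance_nt = as.integer(min_safe_reinit_distance_nt),
      avg_residue_mass_da = avg_residue_mass_da,
      kozak = kozak
    ),
    class = "annotation_config"
  )
}

#' Read annotation configuration from a YAML file
#'
#' Recognised keys: `min_repressive_uorf_codons`, `min_safe_reinit_distance_nt`,
#' `avg_residue_mass_da`, and an optional nested `kozak_weights` map (see
#' [read_kozak_config()] for its layout). Missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @return An [annotation_config()].
#' @export
read_annotation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  kz <- if (!is.null(raw$kozak_weights)) {
    kozak_model(weights = lapply(raw$kozak_weights, \(w) unlist(w)))
  } else {
    kozak_model()
  }
  annotation_config(
    min_repressive_uorf_codons = raw$min_repressive_uorf_codons %||% 10L,
    min_safe_reinit_distance_nt = raw$min_safe_reinit_distance_nt %||% 200L,
    avg_residue_mass_da = raw$avg_residue_mass_da %||% 110,
    kozak = kz
  )
}

#' Predicted mass of an N-terminal extension
#'
#' @param extension_codons Number of codons added upstream of the sAUG by
#'   in-frame readthrough (> 0).
#' @param config An [annotation_config()] supplying the average residue mass.
#' @return A one-row tibble: `extension_codons`, `mass_kda` (raw) and
#'   `mass_kda_round` (nearest integer, the "~N kDa" a reader would quote).
#' @examples
#' predicted_extension_mass(85)  # 9.35 kDa, ~9 kDa
#' @export
predicted_extension_mass <- function(extension_codons, config = annotation_config()) {
  extension_codons <- as.integer(extension_codons)
  if (any(is.na(extension_codons) | extension_codons <= 0L)) {
    abort("`extension_codons` must be a positive integer.")
  }
  mass <- extension_codons * config$avg_residue_mass_da / 1000
  tibble(extension_codons = extension_codons, mass_kda = mass,
         mass_kda_round = round(mass))
}

# fixed column schema of a consequence report row
empty_report_row <- function() {
  tibble(
    variants = NA_character_, classification = NA_character_,
    uaug_pos = NA_integer_, frame = NA_integer_,
    stop_first = NA_integer_, stop_last = NA_integer_,
    length_nt = NA_integer_, codons_incl_stop = NA_integer_,
    codons_excl_stop = NA_integer_,
    dist_stop_end = NA_integer_, dist_stop_start = NA_integer_,
    extension_codons = NA_integer_, extension_mass_kda = NA_real_,
    kozak_uaug_context = NA_character_, kozak_uaug_score = NA_real_,
    kozak_uaug_strength = NA_character_,
    kozak_saug_context = NA_character_, kozak_saug_score = NA_real_,
    kozak_saug_strength = NA_character_,
    repression_flag = NA_character_, notes = ""
  )
}

repression_for_orf <- function(orf, config) {
  switch(orf$kind,
    uORF_terminating_in_leader = {
      if (orf$codons_incl_stop >= config$min_repressive_uorf_codons ||
          orf$dist_stop_end < config$min_safe_reinit_distance_nt) {
        "predicted_repressive"
      } else {
        "predicted_tolerated"
      }
    },
    inframe_readthrough_extension = "predicted_repressive",
    overlapping_oORF = "predicted_repressive"
  )
}

#' Classify the translational consequence of a cis variant set
#'
#' Applies the variants in cis to the transcript, diffs leader AUG and
#' uORF-stop content against the reference, and reports the predicted
#' consequence of the highest-impact event. Event precedence is: uAUG created
#' > uAUG destroyed > uORF stop created > uORF stop destroyed > nothing. When
#' several uAUGs are created, the most 5' one is classified — the scanning
#' ribosome meets it first — and the rest are listed in `notes`.
#'
#' Classifications and their repression flags:
#' * `UAUG_CREATED_UORF` — a new upstream ORF terminating in the leader;
#'   repressive when it is long (>= `min_repressive_uorf_codons` codons,
#'   stop included) or ends close to the sAUG
#'   (< `min_safe_reinit_distance_nt` nt, stop-end convention), otherwise
#'   tolerated.
#' * `UAUG_CREATED_INFRAME_EXTENSION` — in-frame readthrough into the main
#'   ORF; flagged repressive (an N-terminally extended protein is typically
#'   unstable, and initiation at the uAUG competes with the sAUG; which
#'   mechanism dominates is noted as unresolved). `extension_mass_kda` is the
#'   predicted added mass.
#' * `UAUG_CREATED_OVERLAPPING_OORF` — out-of-frame ORF overlapping the sAUG;
#'   repressive (its stop lies downstream of the sAUG, precluding
#'   reinitiation).
#' * `UAUG_DESTROYED`, `UORF_STOP_CREATED`, `UORF_STOP_DESTROYED` — changes to
#'   pre-existing leader AUGs/uORFs; stop changes are re-delineated and
#'   re-flagged from the new geometry.
#' * `NO_UAUG_CHANGE` — nothing detected; flag `not_applicable`.
#'
#' @param model The reference [transcript_model()].
#' @param variants A character vector of HGVS c. strings or a parsed variant
#'   tibble (see [parse_hgvs()]); all applied together (cis).
#' @param config An [annotation_config()].
#' @return A one-row tibble with the fixed report schema (see
#'   [annotate_variants()] for the column list).
#' @examples
#' tx <- build_fixture()
#' classify_variants(tx, c("c.-281G>T", "c.-263C>A"))
#' @export
classify_variants <- function(model, variants, config = annotation_config()) {
  stopifnot(inherits(model, "transcript_model"), inherits(config, "annotation_config"))
  if (is.character(variants)) variants <- parse_hgvs(variants)
  variants <- as_tibble(variants)
  alt_model <- apply_variants(model, variants)
  ev <- diff_uaug_events(model, alt_model)

  row <- empty_report_row()
  row$variants <- paste(variants$label, collapse = ",")
  notes <- character()

  fill_orf <- function(row, orf) {
    row$uaug_pos <- orf$start
    row$frame <- orf$frame
    row$stop_first <- orf$stop_first
    row$stop_last <- orf$stop_last
    row$length_nt <- orf$length_nt
    row$codons_incl_stop <- orf$codons_incl_stop
    row$codons_excl_stop <- orf$codons_excl_stop
    row$dist_stop_end <- orf$dist_stop_end
    row$dist_stop_start <- orf$dist_stop_start
    row$extension_codons <- orf$extension_codons
    row
  }
  fill_kozak <- function(row, uaug_pos) {
    if (!is.na(uaug_pos)) {
      kz <- kozak_at(alt_model, uaug_pos, config$kozak)
      row$kozak_uaug_context <- kz$context
      row$kozak_uaug_score <- kz$score
      row$kozak_uaug_strength <- kz$strength
    }
    ks <- kozak_at(alt_model, 1L, config$kozak)
    row$kozak_saug_context <- ks$context
    row$kozak_saug_score <- ks$score
    row$kozak_saug_strength <- ks$strength
    row
  }

  if (length(ev$created) > 0L) {
    lead <- min(ev$created)
    if (length(ev$created) > 1L) {
      notes <- c(notes, sprintf("additional uAUG(s) created at c.%s; classified by the most 5' (scanned first)",
                                paste(setdiff(ev$created, lead), collapse = ", c.")))
    }
    orf <- delineate_orf(alt_model, lead)
    row <- fill_orf(row, orf)
    row$classification <- switch(orf$kind,
      uORF_terminating_in_leader = "UAUG_CREATED_UORF",
      inframe_readthrough_extension = "UAUG_CREATED_INFRAME_EXTENSION",
      overlapping_oORF = "UAUG_CREATED_OVERLAPPING_OORF"
    )
    row$repression_flag <- repression_for_orf(orf, config)
    if (orf$kind == "inframe_readthrough_extension") {
      mass <- predicted_extension_mass(orf$extension_codons, config)
      row$extension_mass_kda <- mass$mass_kda
      notes <- c(notes, sprintf(
        "in-frame readthrough would add %d residues (~%d kDa); whether repression acts via an unstable extended protein or suppressed sAUG initiation is unresolved",
        orf$extension_codons, mass$mass_kda_round))
    }
    if (orf$kind == "overlapping_oORF") {
      notes <- c(notes, "out-of-frame ORF overlaps the sAUG; termination downstream of the start precludes reinitiation")
    }
    row <- fill_kozak(row, lead)
  } else if (length(ev$destroyed) > 0L) {
    row$classification <- "UAUG_DESTROYED"
    row$uaug_pos <- min(ev$destroyed)
    row$repression_flag <- "not_applicable"
    notes <- c(notes, sprintf("uAUG(s) at c.%s lost; any repression by their ORFs is relieved",
                              paste(ev$destroyed, collapse = ", c.")))
    row <- fill_kozak(row, NA_integer_)
  } else if (length(ev$uorf_stop_created) > 0L || length(ev$uorf_stop_destroyed) > 0L) {
    created <- length(ev$uorf_stop_created) > 0L
    row$classification <- if (created) "UORF_STOP_CREATED" else "UORF_STOP_DESTROYED"
    stop_pos <- if (created) min(ev$uorf_stop_created) else min(ev$uorf_stop_destroyed)
    # re-delineate the most 5' pre-existing uAUG in frame with the changed stop
    shared <- intersect(find_augs(model), find_augs(alt_model))
    affected <- shared[frame_offset(shared) == frame_offset(stop_pos) & shared < stop_pos]
    if (length(affected) > 0L) {
      orf <- delineate_orf(alt_model, min(affected))
      row <- fill_orf(row, orf)
      row$repression_flag <- repression_for_orf(orf, config)
      row <- fill_kozak(row, min(affected))
    } else {
      row$repression_flag <- "not_applicable"
      row <- fill_kozak(row, NA_integer_)
    }
    notes <- c(notes, sprintf("in-frame leader stop %s at c.%d",
                              if (created) "created" else "destroyed", stop_pos))
  } else {
    row$classification <- "NO_UAUG_CHANGE"
    row$repression_flag <- "not_applicable"
  }
  row$notes <- paste(notes, collapse = "; ")
  row
}

#' Annotate a table of cis variant sets
#'
#' The main tabular verb: takes one annotation unit per row and returns one
#' report row per unit, in input order. Identical inputs and configuration
#' always give byte-identical reports.
#'
#' @param variant_sets A tibble as from [read_variant_sets()] (columns
#'   `set_id`, `spec`, `variants`), or a character vector where each element
#'   is a comma-separated cis set of HGVS c. SNVs.
#' @param model The reference [transcript_model()].
#' @param config An [annotation_config()].
#' @return A tibble with one row per annotation unit and columns `set_id`,
#'   `variants`, `classification`, `uaug_pos`, `frame`, `stop_first`,
#'   `stop_last`, `length_nt`, `codons_incl_stop`, `codons_excl_stop`,
#'   `dist_stop_end`, `dist_stop_start`, `extension_codons`,
#'   `extension_mass_kda`, `kozak_uaug_context`, `kozak_uaug_score`,
#'   `kozak_uaug_strength`, `kozak_saug_context`, `kozak_saug_score`,
#'   `kozak_saug_strength`, `repression_flag`, `notes`. The column order is
#'   fixed so serialized reports diff cleanly.
#' @examples
#' tx <- build_fixture()
#' annotate_variants(c("c.-281G>T,c.-263C>A", "c.-255G>A"), tx)
#' @export
annotate_variants <- function(variant_sets, model, config = annotation_config()) {
  if (is.character(variant_sets)) {
    variant_sets <- tibble(
      set_id = seq_along(variant_sets),
      spec = variant_sets,
      variants = map(strsplit(variant_sets, ","), \(v) parse_hgvs(stringr::str_trim(v)))
    )
  }
  rows <- map(variant_sets$variants, \(v) classify_variants(model, v, config))
  out <- dplyr::bind_cols(tibble(set_id = variant_sets$set_id), list_rbind(rows))
  class(out) <- c("uorf_report", class(out))
  attr(out, "model") <- model
  out
}

#' One-row summary of a consequence report
#'
#' @param x A report from [annotate_variants()].
#' @param ... Unused.
#' @return A one-row tibble counting annotation units by predicted impact.
#' @method glance uorf_report
#' @export
glance.uorf_report <- function(x, ...) {
  tibble(
    n_units = nrow(x),
    n_uaug_created = sum(startsWith(x$classification, "UAUG_CREATED"), na.rm = TRUE),
    n_predicted_repressive = sum(x$repression_flag == "predicted_repressive", na.rm = TRUE),
    n_no_change = sum(x$classification == "NO_UAUG_CHANGE", na.rm = TRUE)
  )
}
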