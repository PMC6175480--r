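#' Inventory the upstream AUGs of a transcript leader
#'
#' Lists every AUG in the (reference or mutated) leader with its reading
#' frame and Kozak context evaluation — the standalone screen that documents,
#' for an AUG-free leader, that no upstream initiation site exists.
#'
#' @param model A [transcript_model()].
#' @param apply Optional character vector of HGVS c. SNVs (comma-joined sets
#'   allowed) applied before scanning.
#' @param kozak A [kozak_model()].
#' @return A tibble with one row per leader AUG: `pos`, `frame`, `context`,
#'   `score`, `strength`, `minus3`, `plus4` (zero rows when the leader has no
#'   AUG).
#' @examples
#' scan_leader(build_fixture())                       # 0 rows
#' scan_leader(build_fixture(), apply = "c.-255G>A")  # the created uAUG
#' @export
scan_leader <- function(model, apply = NULL, kozak = kozak_model()) {
  if (!is.null(apply)) {
    variants <- parse_hgvs(stringr::str_trim(unlist(strsplit(apply, ","))))
    model <- apply_variants(model, variants)
  }
  augs <- find_augs(model)
  if (length(augs) == 0L) {
    return(tibble(pos = integer(), frame = integer(), context = character(),
                  score = double(), strength = character(),
                  minus3 = character(), plus4 = character()))
  }
  kz <- list_rbind(map(augs, \(p) kozak_at(model, p, kozak)))
  dplyr::bind_cols(tibble(pos = augs, frame = frame_offset(augs)),
                   kz[, c("context", "score", "strength", "minus3", "plus4")])
}

#' Serialize a consequence report
#'
#' `write_report_tsv()` writes the fixed-column TSV with a `##`-prefixed
#' header line carrying the package version and the annotation thresholds
#' (ignored by TSV parsers as a comment); `write_report_json()` writes one
#' JSON object per annotation unit. Both are byte-stable for identical inputs
#' and configuration.
#'
#' @param report A report tibble from [annotate_variants()].
#' @param path Output file path.
#' @param config The [annotation_config()] used, echoed into the header.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path, config = annotation_config()) {
  header <- sprintf(
    "## uorfann %s | min_repressive_uorf_codons=%d min_safe_reinit_distance_nt=%d avg_residue_mass_da=%g",
    as.character(utils::packageVersion("uorfann")),
    config$min_repressive_uorf_codons, config$min_safe_reinit_distance_nt,
    config$avg_residue_mass_da
  )
  readr::write_lines(header, path)
  readr::write_tsv(report, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
write_report_json <- function(report, path, config = annotation_config()) {
  payload <- list(
    tool = "uorfann",
    version = as.character(utils::packageVersion("uorfann")),
    config = list(
      min_repressive_uorf_codons = config$min_repressive_uorf_codons,
      min_safe_reinit_distance_nt = config$min_safe_reinit_distance_nt,
      avg_residue_mass_da = config$avg_residue_mass_da
    ),
    report = report
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a TSV consequence report back into a tibble
#'
#' @param path Path written by [write_report_tsv()].
#' @return The report tibble (header comment dropped).
#' @export
read_report_tsv <- function(path) {
  readr::read_tsv(path, comment = "##", show_col_types = FALSE)
}

#' Annotate a variant file against a transcript, end to end
#'
#' File-level orchestration of the pipeline: load the transcript, read the
#' variants in one of three input modes, annotate every unit in input order,
#' and serialize the report. Units that fail (unparsable token, REF mismatch)
#' become error rows with the message in `notes` rather than aborting the
#' whole run, so one bad line cannot sink a batch; an empty input yields an
#' empty report with a warning.
#'
#' @param transcript A [transcript_model()] or a FASTA path.
#' @param variants Path to the variant input: HGVS lines (`mode = "hgvs"`), a
#'   4-column genomic TSV (`mode = "genomic"`, requires `map`), or a minimal
#'   VCF of SNVs (`mode = "vcf"`, requires `map`).
#' @param out Optional output path; when `NULL` the report tibble is returned
#'   without serialization.
#' @param format `"tsv"` or `"json"`.
#' @param mode Variant input mode, see `variants`.
#' @param map A [genomic_map()] or path to a map TSV (genomic/vcf modes).
#' @param config An [annotation_config()].
#' @param utr5_length,record Passed to [read_transcript()] when `transcript`
#'   is a path.
#' @return The report tibble, invisibly when `out` is given. An attribute
#'   `n_failed` counts error rows.
#' @export
annotate_file <- function(transcript, variants, out = NULL,
                          format = c("tsv", "json"), mode = c("hgvs", "genomic", "vcf"),
                          map = NULL, config = annotation_config(),
                          utr5_length = NULL, record = NULL) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  model <- if (inherits(transcript, "transcript_model")) transcript else {
    read_transcript(transcript, utr5_length = utr5_length, record = record)
  }
  if (mode != "hgvs") {
    if (is.null(map)) abort("Genomic and VCF modes require a coordinate `map`.")
    if (is.character(map)) map <- read_genomic_map(map)
    gv <- if (mode == "genomic") read_genomic_variants(variants) else read_vcf_snvs(variants)
    cv <- map_genomic_to_c(gv, map)
    sets <- tibble(
      set_id = seq_len(nrow(cv)),
      spec = cv$label,
      variants = purrr::map(seq_len(nrow(cv)), \(i) cv[i, c("label", "cpos", "ref", "alt")])
    )
  } else {
    sets <- read_variant_sets(variants)
  }
  if (nrow(sets) == 0L) {
    warn("No variants found in input; writing an empty report.")
    report <- dplyr::bind_cols(tibble(set_id = integer()),
                               empty_report_row()[0, ])
  } else {
    rows <- purrr::map(seq_len(nrow(sets)), function(i) {
      tryCatch(
        classify_variants(model, sets$variants[[i]], config),
        error = function(e) {
          row <- empty_report_row()
          row$variants <- sets$spec[i]
          row$classification <- "ERROR"
          row$repression_flag <- "not_applicable"
          row$notes <- conditionMessage(e)
          row
        }
      )
    })
    report <- dplyr::bind_cols(tibble(set_id = sets$set_id), list_rbind(rows))
  }
  attr(report, "n_failed") <- sum(report$classification == "ERROR")
  if (!is.null(out)) {
    if (format == "tsv") write_report_tsv(report, out, config)
    else write_report_json(report, out, config)
    return(invisible(report))
  }
  report
}
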