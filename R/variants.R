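#' Parse HGVS c. single-nucleotide substitutions
#'
#' Accepts strings of the form `c.{position}{REF}>{ALT}` where the position is
#' a non-zero signed integer in HGVS c. convention (negative = 5' UTR). Parsing
#' tolerates whitespace around `>` and the unicode minus/hyphen variants that
#' journals substitute for ASCII `-`. Anything outside this sublanguage —
#' position 0, indel/dup/del syntax, intronic offsets such as `c.-10+5G>A` —
#' is rejected with an error naming the offending token: an SNV mis-read as a
#' different SNV is worse than a refusal.
#'
#' @param x Character vector of HGVS c. SNV strings.
#' @return A tibble with one row per variant: `label` (normalised HGVS
#'   spelling), `cpos`, `ref`, `alt`.
#' @examples
#' parse_hgvs(c("c.-263C>A", "c.-255G>A"))
#' @export
parse_hgvs <- function(x) {
  stopifnot(is.character(x))
  cleaned <- stringr::str_replace_all(x, "[‐‑‒–—−-]", "-")
  cleaned <- stringr::str_replace_all(cleaned, "\\s+", "")
  m <- stringr::str_match(cleaned, "^c\\.(-?\\d+)([ACGTacgt])>([ACGTacgt])$")
  bad <- is.na(m[, 1])
  if (any(bad)) {
    abort(sprintf(
      "Cannot parse as HGVS c. SNV: %s (expected e.g. 'c.-263C>A'; indels, duplications and intronic offsets are not supported).",
      paste(sQuote(x[bad]), collapse = ", ")
    ))
  }
  cpos <- as.integer(m[, 2])
  if (any(cpos == 0L)) {
    abort(sprintf("HGVS c. has no position 0 (offending token: %s).",
                  paste(sQuote(x[cpos == 0L]), collapse = ", ")))
  }
  ref <- toupper(m[, 3])
  alt <- toupper(m[, 4])
  same <- ref == alt
  if (any(same)) {
    abort(sprintf("REF and ALT alleles are identical in %s.",
                  paste(sQuote(x[same]), collapse = ", ")))
  }
  tibble(
    label = sprintf("c.%d%s>%s", cpos, ref, alt),
    cpos = cpos, ref = ref, alt = alt
  )
}

#' Read cis-grouped variant sets from a file
#'
#' One annotation unit per line; variants listed on the same line
#' (comma-separated) are in cis and applied together, separate lines are
#' annotated independently. `#` starts a comment; blank lines are skipped.
#'
#' @param path Path to the variant list file.
#' @return A tibble with one row per annotation unit: `set_id` (1-based line
#'   order), `spec` (the normalised comma-joined labels) and `variants`, a
#'   list-column of parsed variant tibbles (see [parse_hgvs()]).
#' @export
read_variant_sets <- function(path) {
  lines <- readr::read_lines(path)
  lines <- stringr::str_trim(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(set_id = integer(), spec = character(), variants = list()))
  }
  variants <- map(strsplit(lines, ","), \(v) parse_hgvs(stringr::str_trim(v)))
  tibble(
    set_id = seq_along(lines),
    spec = map_chr(variants, \(v) paste(v$label, collapse = ",")),
    variants = variants
  )
}

#' Build a genomic-to-transcript coordinate map
#'
#' For a contiguous (single-exon) transcript segment, one anchor pair — a
#' genomic position and the c. position of the same base — plus the strand
#' fully determines the mapping. On the minus strand, moving downstream in
#' transcript coordinates means decreasing genomic position and alleles are
#' complemented.
#'
#' @param chrom Chromosome name.
#' @param anchor_gpos 1-based genomic position of the anchor base.
#' @param anchor_cpos HGVS c. position of the same base (non-zero integer).
#' @param strand `"+"` or `"-"`.
#' @return A `genomic_map` object.
#' @export
genomic_map <- function(chrom, anchor_gpos, anchor_cpos, strand) {
  anchor_cpos <- as.integer(anchor_cpos)
  if (is.na(anchor_cpos) || anchor_cpos == 0L) abort("`anchor_cpos` must be a non-zero integer.")
  if (!strand %in% c("+", "-")) abort("`strand` must be '+' or '-'.")
  structure(
    list(chrom = as.character(chrom), anchor_gpos = as.integer(anchor_gpos),
         anchor_cpos = anchor_cpos, strand = strand),
    class = "genomic_map"
  )
}

#' Read a genomic map from a TSV file
#'
#' Expects columns `chrom`, `anchor_gpos`, `anchor_cpos`, `strand` (header
#' required); only the first row is used.
#'
#' @param path Path to the map TSV.
#' @return A [genomic_map()].
#' @export
read_genomic_map <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("chrom", "anchor_gpos", "anchor_cpos", "strand")
  if (!all(need %in% names(tab))) {
    abort(sprintf("Genomic map file '%s' must have columns: %s.",
                  path, paste(need, collapse = ", ")))
  }
  genomic_map(tab$chrom[1], tab$anchor_gpos[1], tab$anchor_cpos[1], tab$strand[1])
}

complement_base <- function(b) chartr("ACGT", "TGCA", b)

# c. arithmetic with no position 0: shift a non-zero anchor by a signed delta.
shift_cpos <- function(anchor_cpos, delta) {
  raw <- anchor_cpos + delta
  raw <- ifelse(anchor_cpos < 0L & raw >= 0L, raw + 1L, raw)
  ifelse(anchor_cpos > 0L & raw <= 0L, raw - 1L, raw)
}

#' Map genomic SNVs onto transcript (HGVS c.) coordinates
#'
#' @param gvariants A data frame with columns `chrom`, `gpos`, `ref`, `alt`
#'   (1-based genomic SNVs, alleles on the plus strand of the genome).
#' @param map A [genomic_map()].
#' @return A tibble of transcript-space variants as from [parse_hgvs()], plus
#'   the originating `chrom` and `gpos`.
#' @examples
#' map <- genomic_map("chr7", 19117602, -281, "-")
#' gv <- tibble::tibble(chrom = "chr7", gpos = 19117584, ref = "G", alt = "T")
#' map_genomic_to_c(gv, map)  # c.-263C>A
#' @export
map_genomic_to_c <- function(gvariants, map) {
  stopifnot(inherits(map, "genomic_map"))
  gvariants <- as_tibble(gvariants)
  need <- c("chrom", "gpos", "ref", "alt")
  if (!all(need %in% names(gvariants))) {
    abort(sprintf("Genomic variants need columns: %s.", paste(need, collapse = ", ")))
  }
  mism <- gvariants$chrom != map$chrom
  if (any(mism)) {
    abort(sprintf("Chromosome mismatch: variants on %s but map anchored on %s.",
                  paste(unique(gvariants$chrom[mism]), collapse = ", "), map$chrom))
  }
  delta <- if (map$strand == "-") map$anchor_gpos - gvariants$gpos else gvariants$gpos - map$anchor_gpos
  cpos <- shift_cpos(map$anchor_cpos, as.integer(delta))
  ref <- toupper(gvariants$ref)
  alt <- toupper(gvariants$alt)
  if (map$strand == "-") {
    ref <- complement_base(ref)
    alt <- complement_base(alt)
  }
  tibble(
    label = sprintf("c.%d%s>%s", cpos, ref, alt),
    cpos = as.integer(cpos), ref = ref, alt = alt,
    chrom = gvariants$chrom, gpos = gvariants$gpos
  )
}

#' @rdname map_genomic_to_c
#' @param cvariants A data frame with columns `cpos`, `ref`, `alt` (transcript
#'   space), as produced by [parse_hgvs()].
#' @export
map_c_to_genomic <- function(cvariants, map) {
  stopifnot(inherits(map, "genomic_map"))
  cvariants <- as_tibble(cvariants)
  # invert the 0-skipping shift: signed distance between two c. positions
  delta <- cvariants$cpos - map$anchor_cpos
  crosses <- sign(cvariants$cpos) != sign(map$anchor_cpos)
  delta <- delta - ifelse(crosses, sign(delta), 0L)
  gpos <- if (map$strand == "-") map$anchor_gpos - delta else map$anchor_gpos + delta
  ref <- toupper(cvariants$ref)
  alt <- toupper(cvariants$alt)
  if (map$strand == "-") {
    ref <- complement_base(ref)
    alt <- complement_base(alt)
  }
  tibble(chrom = map$chrom, gpos = as.integer(gpos), ref = ref, alt = alt)
}

#' Read genomic SNVs from a 4-column TSV or a minimal VCF
#'
#' `read_genomic_variants()` reads a TSV with columns `chrom`, `gpos`, `ref`,
#' `alt`. `read_vcf_snvs()` reads SNV records from a VCF (via the vcfR
#' package); multi-allelic records are split and non-SNV records are dropped
#' with a warning. Genotypes are not needed.
#'
#' @param path Input file path.
#' @return A tibble with columns `chrom`, `gpos`, `ref`, `alt`.
#' @export
read_genomic_variants <- function(path) {
  # alleles must never be sniffed as logicals (a lone "T" column would be)
  tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("chrom", "gpos", "ref", "alt")
  if (!all(need %in% names(tab))) {
    abort(sprintf("Genomic variant file '%s' must have columns: %s.",
                  path, paste(need, collapse = ", ")))
  }
  tibble(chrom = as.character(tab$chrom), gpos = as.integer(tab$gpos),
         ref = toupper(tab$ref), alt = toupper(tab$alt))
}

#' @rdname read_genomic_variants
#' @export
read_vcf_snvs <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("Package 'vcfR' is required for VCF input.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  out <- tibble(
    chrom = fix$CHROM, gpos = as.integer(fix$POS),
    ref = toupper(fix$REF), alt = toupper(fix$ALT)
  ) |>
    tidyr_separate_alt()
  snv <- nchar(out$ref) == 1L & nchar(out$alt) == 1L &
    out$ref %in% c("A", "C", "G", "T") & out$alt %in% c("A", "C", "G", "T")
  if (any(!snv)) {
    warn(sprintf("Dropped %d non-SNV VCF record(s).", sum(!snv)))
  }
  out[snv, , drop = FALSE]
}

# split comma-separated ALT alleles into one row each
tidyr_separate_alt <- function(tab) {
  alts <- strsplit(tab$alt, ",", fixed = TRUE)
  n <- lengths(alts)
  tibble(
    chrom = rep(tab$chrom, n), gpos = rep(tab$gpos, n),
    ref = rep(tab$ref, n), alt = unlist(alts)
  )
}

#' Apply SNVs in cis to a transcript
#'
#' Substitutes each variant's ALT base into the model sequence. Every REF
#' allele must match the sequence — a mismatch aborts, naming the position and
#' both bases, which guards against annotating variants on the wrong
#' transcript — and positions must be distinct. The input model is not
#' modified; sequence length is always preserved (SNVs only).
#'
#' @param model A [transcript_model()].
#' @param variants A data frame from [parse_hgvs()] (columns `cpos`, `ref`,
#'   `alt`, optionally `label`), or a character vector of HGVS c. strings.
#' @return A new `transcript_model` carrying the mutated sequence; applied
#'   variant labels accumulate in `$variants`.
#' @examples
#' tx <- transcript_model(paste0(strrep("C", 29), "TATGCATTAA"), utr5_length = 30)
#' mut <- apply_variants(tx, "c.-30C>A")
#' substr(mut$sequence, 1, 1)
#' @export
apply_variants <- function(model, variants) {
  stopifnot(inherits(model, "transcript_model"))
  if (is.character(variants)) variants <- parse_hgvs(variants)
  variants <- as_tibble(variants)
  if (nrow(variants) == 0L) return(model)
  if (anyDuplicated(variants$cpos)) {
    abort(sprintf("Duplicate variant positions in one cis set: c.%s.",
                  paste(variants$cpos[duplicated(variants$cpos)], collapse = ", c.")))
  }
  idx <- c_to_index(model, variants$cpos)
  seq <- model$sequence
  observed <- substring(seq, idx, idx)
  mism <- observed != variants$ref
  if (any(mism)) {
    i <- which(mism)[1]
    abort(sprintf(
      "REF mismatch at c.%d on transcript '%s': variant says %s, sequence has %s.",
      variants$cpos[i], model$id, variants$ref[i], observed[i]
    ))
  }
  for (k in seq_len(nrow(variants))) {
    substr(seq, idx[k], idx[k]) <- variants$alt[k]
  }
  labels <- if ("label" %in% names(variants)) variants$label else
    sprintf("c.%d%s>%s", variants$cpos, variants$ref, variants$alt)
  out <- model
  out$sequence <- seq
  out$variants <- c(model$variants, labels)
  out
}
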