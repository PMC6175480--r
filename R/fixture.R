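# Fixed bases of the synthetic TWIST1-like leader, keyed by HGVS c. position.
# Each entry realises a positional constraint the annotation pipeline must be
# able to exercise: variant-created AUGs, engineered stop-ready triplets, the
# native uORF stop, and the -3/+4 context bases.
fixture_fixed_leader <- function() {
  fixed <- c(
    `-283` = "C", `-282` = "C", `-281` = "G", `-280` = "C", `-279` = "C",
    `-266` = "G",                       # purine at -3 of the -263 uAUG
    `-263` = "C", `-262` = "T", `-261` = "G",  # CTG: C>A creates ATG
    `-260` = "G",                       # G at +4 of the -263 uAUG
    `-258` = "G",                       # purine at -3 of the -255 uAUG
    `-255` = "G", `-254` = "T", `-253` = "G",  # GTG: G>A creates ATG
    `-252` = "T",                       # T>A completes TGA at c.-254_-252
    `-246` = "C", `-245` = "G", `-244` = "A",  # CGA: C>T completes TGA
    `-75` = "C", `-74` = "G", `-73` = "A",     # CGA: C>T completes TGA
    `-62` = "T", `-61` = "G", `-60` = "A",     # native uORF stop
    `-3` = "G"                          # purine at -3 of the sAUG
  )
  fixed
}

# 60-nt CDS with ATG, C at c.4 (so the sAUG +4 context is not G) and the first
# stop of every reading frame placed >= 30 nt downstream of c.1, so that
# overlapping ORFs entering the CDS always terminate, but not immediately.
fixture_cds <- function() {
  paste0(
    "ATG", "C",
    "GCCGGCGCCGGCGCCGGCGCCGGCGCCGG",  # c.5..33, G/C only: no stop, no ATG
    "TAA", "C", "TGA", "C", "TAG",    # frame-0/1/2 stops at c.34/38/42
    "CGGCGCCGGCGCCGGC"                # c.45..60
  )
}

#' Build the synthetic TWIST1-like transcript fixture
#'
#' Constructs a leader + CDS transcript that satisfies, by design, every
#' positional constraint the annotation pipeline needs for its reference
#' analyses: a reference `CTG` at c.-263_-261 (so `c.-263C>A` creates an AUG),
#' `GTG` at c.-255_-253 (so `c.-255G>A` creates an in-frame AUG), an in-frame
#' `TGA` stop at c.-62_-60, stop-ready triplets at c.-254_-252 (`c.-252T>A`),
#' c.-246_-244 and c.-75_-73 (`C>T`), a purine at -3 of all three candidate
#' start sites, G at +4 of the -263 uAUG but not of the sAUG, no AUG anywhere
#' in the wild-type leader, and no premature stop in either variant reading
#' frame. Unconstrained positions are filled GC-rich (leader GC >= 60%),
#' mimicking the GC-rich leaders these analyses target. This is a synthetic
#' stand-in: it reproduces the published coordinate geometry of the TWIST1
#' leader, not its actual sequence.
#'
#' @param utr5_length Leader length in nucleotides (>= 283 so that every
#'   constrained position is addressable; default 300).
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @param id Transcript id for the model.
#' @return A [transcript_model()] that passes every [validate_fixture()] check.
#' @examples
#' tx <- build_fixture()
#' validate_fixture(tx)
#' @export
build_fixture <- function(utr5_length = 300L, seed = 1L, id = "TWIST1like_synthetic") {
  L <- as.integer(utr5_length)
  if (L < 283L) {
    abort(sprintf(
      "utr5_length = %d cannot host the fixture constraints (positions down to c.-283 are fixed); use >= 283.", L))
  }
  fixed <- fixture_fixed_leader()
  fixed_idx <- L + as.integer(names(fixed)) + 1L

  leader <- withr::with_seed(seed, {
    x <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                prob = c(0.2, 0.3, 0.3, 0.2))
    x[fixed_idx] <- unname(fixed)
    x
  })
  free <- !(seq_len(L) %in% fixed_idx)
  seq_full <- paste0(paste(leader, collapse = ""), fixture_cds())

  # Repair pass: a free position set to C or G can never create an AUG or a
  # stop codon, so each fix strictly reduces the violation count.
  repair_triplet <- function(leader, start_idx) {
    cand <- start_idx + 0:2
    cand <- cand[cand >= 1 & cand <= L & free[pmin(pmax(cand, 1), L)]]
    cand <- cand[leader[cand] %in% c("A", "T")]
    if (length(cand) == 0L) {
      abort(sprintf("Fixture repair impossible at leader index %d (all bases constrained).", start_idx))
    }
    leader[cand[1]] <- "C"
    leader
  }
  violations <- function(leader) {
    s <- paste(leader, collapse = "")
    v <- integer()
    hits <- gregexpr("(?=ATG)", s, perl = TRUE)[[1]]
    v <- c(v, hits[hits > 0L])
    frame_starts <- function(aug_c, last_c) L + seq.int(aug_c + 3L, last_c, by = 3L) + 1L
    for (st in frame_starts(-263L, -65L)) {
      if (substr(s, st, st + 2L) %in% STOP_CODONS) v <- c(v, st)
    }
    for (st in frame_starts(-255L, -3L)) {
      if (substr(s, st, st + 2L) %in% STOP_CODONS) v <- c(v, st)
    }
    sort(unique(v))
  }
  for (pass in 1:400) {
    v <- violations(leader)
    if (length(v) == 0L) break
    leader <- repair_triplet(leader, v[1])
  }
  if (length(violations(leader)) > 0L) {
    abort("Fixture construction failed to converge; raise utr5_length.")
  }
  # Guarantee the documented GC floor by promoting free A/T positions.
  gc_floor <- 0.60
  at_free <- which(free & leader %in% c("A", "T"))
  k <- 0L
  while (mean(leader %in% c("G", "C")) < gc_floor && k < length(at_free)) {
    k <- k + 1L
    leader[at_free[k]] <- "C"
  }

  transcript_model(paste0(paste(leader, collapse = ""), fixture_cds()),
                   utr5_length = L, id = id)
}

#' Validate the fixture constraints on a transcript
#'
#' Checks every positional constraint [build_fixture()] promises, one row per
#' constraint, reporting offending positions on failure. Useful both as a
#' self-test of the generator and as a guard when substituting a real
#' transcript for the synthetic one.
#'
#' @param model A [transcript_model()].
#' @return A tibble with columns `constraint`, `pass`, `detail`.
#' @export
validate_fixture <- function(model) {
  stopifnot(inherits(model, "transcript_model"))
  L <- model$utr5_length
  res <- list()
  add <- function(name, pass, detail = "") {
    res[[length(res) + 1L]] <<- tibble(constraint = name, pass = pass, detail = detail)
  }
  triplet <- function(cpos) {
    i <- c_to_index(model, cpos)
    substr(model$sequence, i, i + 2L)
  }
  base_at <- function(cpos) {
    i <- c_to_index(model, cpos)
    substr(model$sequence, i, i)
  }
  expect_triplet <- function(name, cpos, want) {
    got <- triplet(cpos)
    add(name, got == want,
        if (got == want) "" else sprintf("c.%d_%d is %s, want %s", cpos, cpos + 2L, got, want))
  }
  expect_base <- function(name, cpos, want) {
    got <- base_at(cpos)
    add(name, got == want,
        if (got == want) "" else sprintf("c.%d is %s, want %s", cpos, got, want))
  }

  expect_triplet("ref CTG at c.-263_-261 (C>A creates uAUG)", -263L, "CTG")
  expect_triplet("ref GTG at c.-255_-253 (G>A creates uAUG)", -255L, "GTG")
  expect_base("T at c.-252 (T>A completes TGA at c.-254_-252)", -252L, "T")
  expect_triplet("stop-ready CGA at c.-246_-244", -246L, "CGA")
  expect_triplet("stop-ready CGA at c.-75_-73", -75L, "CGA")
  expect_triplet("native stop TGA at c.-62_-60", -62L, "TGA")

  expect_base("G at c.-281", -281L, "G")
  alt_safe <- vapply(c("T", "A"), function(alt) {
    alt_model <- tryCatch(
      apply_variants(model, tibble(cpos = -281L, ref = "G", alt = alt,
                                   label = paste0("c.-281G>", alt))),
      error = function(e) NULL)
    if (is.null(alt_model)) return(FALSE)
    length(find_augs(alt_model)) == length(find_augs(model))
  }, logical(1))
  add("neither c.-281G>T nor c.-281G>A creates an AUG", all(alt_safe),
      if (all(alt_safe)) "" else "a -281 alt allele creates an AUG")

  expect_base("purine (G) at -3 of the -263 uAUG (c.-266)", -266L, "G")
  expect_base("purine (G) at -3 of the -255 uAUG (c.-258)", -258L, "G")
  expect_base("purine (G) at -3 of the sAUG (c.-3)", -3L, "G")
  expect_base("G at +4 of the -263 uAUG (c.-260)", -260L, "G")
  add("sAUG +4 (c.4) is not G", base_at(4L) != "G",
      if (base_at(4L) != "G") "" else "c.4 is G")

  augs <- find_augs(model)
  add("no ATG anywhere in the WT leader", length(augs) == 0L,
      if (length(augs) == 0L) "" else sprintf("ATG at c.%s", paste(augs, collapse = ", c.")))

  frame_stops <- function(aug_c, last_c) {
    starts <- seq.int(aug_c + 3L, last_c, by = 3L)
    bad <- starts[vapply(starts, \(p) triplet(p) %in% STOP_CODONS, logical(1))]
    bad
  }
  bad263 <- frame_stops(-263L, -65L)
  add("no stop in the -263 frame between c.-263 and c.-63", length(bad263) == 0L,
      if (length(bad263) == 0L) "" else sprintf("stop at c.%s", paste(bad263, collapse = ", c.")))
  bad255 <- frame_stops(-255L, -3L)
  add("no stop in the -255 frame between c.-255 and c.-1", length(bad255) == 0L,
      if (length(bad255) == 0L) "" else sprintf("stop at c.%s", paste(bad255, collapse = ", c.")))

  cds_len <- nchar(model$sequence) - L
  frame_ok <- vapply(1:3, function(f) {
    starts <- seq.int(f, cds_len - 2L, by = 3L)
    codons <- substring(model$sequence, L + starts, L + starts + 2L)
    first <- match(TRUE, codons %in% STOP_CODONS)
    !is.na(first) && starts[first] >= 31L
  }, logical(1))
  add("first CDS stop in every frame exists and lies >= 30 nt downstream of c.1",
      all(frame_ok),
      if (all(frame_ok)) "" else sprintf("offending frame(s): %s",
                                         paste(which(!frame_ok), collapse = ", ")))

  leader_gc <- mean(strsplit(substr(model$sequence, 1L, L), "")[[1]] %in% c("G", "C"))
  add("leader GC fraction >= 0.60", leader_gc >= 0.60,
      sprintf("GC = %.3f", leader_gc))

  list_rbind(res)
}

#' The reference variant and construct inputs for the fixture
#'
#' The annotation units of the reference analysis: the two patient variants
#' (one of them a cis pair), each variant alone, and the engineered
#' stop-codon constructs that shorten the variant-created ORFs.
#'
#' @return A named character vector; each element is one annotation unit
#'   (comma-separated cis set of HGVS c. SNVs).
#' @export
fixture_variant_sets <- function() {
  c(
    family1_dual = "c.-281G>T,c.-263C>A",
    family1_281_alone = "c.-281G>T",
    family1_263_alone = "c.-263C>A",
    family1_263_252stop = "c.-263C>A,c.-252T>A",
    family2_255 = "c.-255G>A",
    family2_255_246stop = "c.-255G>A,c.-246C>T",
    family2_255_75stop = "c.-255G>A,c.-75C>T"
  )
}

#' Genomic anchor map matching the fixture coordinates
#'
#' The gene sits on the minus strand of chr7; the anchor ties genomic position
#' 19117602 to c.-281, so the three published genomic SNVs land on their HGVS
#' c. counterparts.
#'
#' @return A [genomic_map()].
#' @export
fixture_genomic_map <- function() {
  genomic_map("chr7", 19117602L, -281L, "-")
}

#' Write the fixture bundle to a directory
#'
#' Emits the synthetic transcript FASTA, the constraint-validation report, the
#' reference variant/construct input file, the genomic-mode inputs (4-column
#' SNV TSV plus anchor map TSV), and a small YAML sidecar with the leader
#' length.
#'
#' @param dir Output directory (created if absent).
#' @param utr5_length,seed Passed to [build_fixture()].
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_fixture_files <- function(dir, utr5_length = 300L, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  model <- build_fixture(utr5_length = utr5_length, seed = seed)
  paths <- c(
    fasta = file.path(dir, "twist1like_synthetic.fa"),
    constraints = file.path(dir, "fixture_constraints.tsv"),
    variants = file.path(dir, "paper_variants.txt"),
    genomic = file.path(dir, "genomic_variants.tsv"),
    map = file.path(dir, "genomic_map.tsv"),
    config = file.path(dir, "transcript.yaml")
  )
  write_transcript(model, paths[["fasta"]])
  readr::write_tsv(validate_fixture(model), paths[["constraints"]])
  sets <- fixture_variant_sets()
  readr::write_lines(
    c("# reference variant/construct inputs (one cis set per line)",
      sprintf("%s  # %s", unname(sets), names(sets))),
    paths[["variants"]])
  map <- fixture_genomic_map()
  fam <- parse_hgvs(c("c.-281G>T", "c.-263C>A", "c.-255G>A"))
  gv <- map_c_to_genomic(fam, map)
  readr::write_tsv(gv, paths[["genomic"]])
  readr::write_tsv(
    tibble(chrom = map$chrom, anchor_gpos = map$anchor_gpos,
           anchor_cpos = map$anchor_cpos, strand = map$strand),
    paths[["map"]])
  yaml::write_yaml(list(id = model$id, utr5_length = model$utr5_length),
                   paths[["config"]])
  invisible(paths)
}
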