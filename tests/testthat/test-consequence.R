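test_that("the reference variant sets classify as published", {
  tx <- fixture_tx()
  dual <- classify_variants(tx, c("c.-281G>T", "c.-263C>A"))
  expect_identical(dual$classification, "UAUG_CREATED_UORF")
  expect_identical(dual$repression_flag, "predicted_repressive")
  expect_identical(dual$codons_incl_stop, 68L)

  shortened <- classify_variants(tx, c("c.-263C>A", "c.-252T>A"))
  expect_identical(shortened$codons_incl_stop, 4L)
  expect_identical(shortened$dist_stop_end, 251L)
  expect_identical(shortened$repression_flag, "predicted_tolerated")

  inert <- classify_variants(tx, "c.-281G>T")
  expect_identical(inert$classification, "NO_UAUG_CHANGE")
  expect_identical(inert$repression_flag, "not_applicable")
  expect_true(is.na(inert$uaug_pos))

  ext <- classify_variants(tx, "c.-255G>A")
  expect_identical(ext$classification, "UAUG_CREATED_INFRAME_EXTENSION")
  expect_identical(ext$extension_codons, 85L)
  expect_false(is.na(ext$extension_mass_kda))
  expect_identical(ext$repression_flag, "predicted_repressive")
  expect_match(ext$notes, "unresolved")
})

test_that("stop changes against an AUG-bearing reference are classified and re-flagged", {
  m263 <- fixture_tx_263()
  stopc <- classify_variants(m263, "c.-252T>A")
  expect_identical(stopc$classification, "UORF_STOP_CREATED")
  expect_identical(stopc$codons_incl_stop, 4L)
  expect_identical(stopc$repression_flag, "predicted_tolerated")

  stopd <- classify_variants(m263, "c.-62T>C")
  expect_identical(stopd$classification, "UORF_STOP_DESTROYED")

  destroyed <- classify_variants(m263, "c.-263A>C")
  expect_identical(destroyed$classification, "UAUG_DESTROYED")
  expect_identical(destroyed$repression_flag, "not_applicable")
})

test_that("extension mass is linear in codon count and rounds to the reported value", {
  m <- predicted_extension_mass(85)
  expect_equal(m$mass_kda, 9.35)
  expect_equal(m$mass_kda_round, 9)
  expect_equal(predicted_extension_mass(100)$mass_kda, 11)
  expect_error(predicted_extension_mass(0), "positive")
})

test_that("identical inputs and configuration give identical reports", {
  tx <- fixture_tx()
  sets <- unname(fixture_variant_sets())
  r1 <- annotate_variants(sets, tx)
  r2 <- annotate_variants(sets, tx)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("lengthening a uORF never flips repressive to tolerated", {
  cfg <- annotation_config()
  flag_for <- function(codons, dist_end) {
    orf <- tibble::tibble(
      kind = "uORF_terminating_in_leader",
      codons_incl_stop = codons, dist_stop_end = dist_end
    )
    uorfann:::repression_for_orf(orf, cfg)
  }
  for (dist in c(50L, 150L, 205L, 251L, 400L)) {
    flags <- vapply(2:80, flag_for, character(1), dist_end = dist)
    repressive <- flags == "predicted_repressive"
    # once repressive, always repressive as the uORF grows
    expect_true(all(diff(repressive) >= 0), info = sprintf("dist %d", dist))
  }
  # the engineered-construct contrast: same stop position class, longer uORF
  expect_identical(flag_for(4L, 243L), "predicted_tolerated")
  expect_identical(flag_for(61L, 72L), "predicted_repressive")
})

test_that("the classifier recovers every oracle-derived label on spiked variants", {
  for (base in list(fixture_tx(), fixture_tx_263())) {
    cases <- spike_variants(base, 30, seed = 5)
    got <- vapply(cases$variants,
                  \(v) classify_variants(base, v)$classification, character(1))
    expect_identical(got, cases$expected_classification)
  }
})

test_that("multiple created uAUGs classify by the most 5' with the rest noted", {
  # two AUG-creating edits in cis: -263 (scanned first) and a downstream one
  tx <- fixture_tx()
  dualaug <- classify_variants(tx, c("c.-263C>A", "c.-255G>A"))
  expect_identical(dualaug$uaug_pos, -263L)
  expect_match(dualaug$notes, "c.-255")
})

test_that("configuration must be positive and is honoured by the flag", {
  expect_error(annotation_config(min_repressive_uorf_codons = 0), "positive")
  lax <- annotation_config(min_safe_reinit_distance_nt = 10L,
                           min_repressive_uorf_codons = 100L)
  r <- classify_variants(fixture_tx(), "c.-263C>A", lax)
  # 68 codons < 100 and 59 nt >= 10: under this config the uORF is tolerated
  expect_identical(r$repression_flag, "predicted_tolerated")
})
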