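test_that("the wild-type fixture leader carries no AUG; variant leaders carry exactly the created one", {
  expect_identical(find_augs(fixture_tx()), integer())
  m255 <- apply_variants(fixture_tx(), "c.-255G>A")
  expect_identical(find_augs(m255), -255L)
})

test_that("overlapping AUG matches are all reported, in ascending order", {
  tx <- transcript_model(paste0("CATGATGGC", strrep("C", 21), "ATGCATTAA"), 30)
  expect_identical(find_augs(tx), c(-29L, -26L))
  expect_identical(diff(c_to_index(tx, find_augs(tx))), 3L)
})

test_that("frame offset is the uAUG-to-sAUG distance modulo 3", {
  expect_identical(frame_offset(c(-255L, -263L, -3L)), c(0L, 2L, 0L))
  expect_error(frame_offset(1L), "upstream")
})

test_that("the Family-1 uORF is delineated with the published geometry", {
  orf <- delineate_orf(fixture_tx_263(), -263)
  expect_identical(orf$kind, "uORF_terminating_in_leader")
  expect_identical(orf$stop_first, -62L)
  expect_identical(orf$stop_last, -60L)
  expect_identical(orf$length_nt, 204L)
  expect_identical(orf$codons_incl_stop, 68L)
  expect_identical(orf$codons_excl_stop, 67L)
  expect_identical(orf$dist_stop_end, 59L)
  expect_identical(orf$dist_stop_start, 62L)
})

test_that("the Family-2 uAUG reads through in frame, adding 85 codons", {
  m255 <- apply_variants(fixture_tx(), "c.-255G>A")
  orf <- delineate_orf(m255, -255)
  expect_identical(orf$kind, "inframe_readthrough_extension")
  expect_identical(orf$extension_codons, 85L)
  expect_true(is.na(orf$stop_first))
})

test_that("engineered stops reshape the variant ORFs as designed", {
  short <- apply_variants(fixture_tx(), c("c.-263C>A", "c.-252T>A"))
  orf <- delineate_orf(short, -263)
  expect_identical(orf$codons_incl_stop, 4L)
  expect_identical(orf$stop_first, -254L)
  expect_identical(orf$dist_stop_end, 251L)

  mid <- apply_variants(fixture_tx(), c("c.-255G>A", "c.-75C>T"))
  orf75 <- delineate_orf(mid, -255)
  expect_identical(orf75$kind, "uORF_terminating_in_leader")
  expect_identical(orf75$codons_incl_stop, 61L)
})

test_that("delineation requires an AUG at the start and a leader position", {
  expect_error(delineate_orf(fixture_tx(), -263), "No ATG")
  expect_error(delineate_orf(fixture_tx_263(), -2), "<= -3")
})

test_that("delineation agrees with the brute-force oracle on random transcripts", {
  checked <- 0L
  for (seed in 1:200) {
    len <- 50L + (seed * 37L) %% 351L
    tx <- random_transcript(len, gc_fraction = 0.45, seed = seed)
    for (aug in find_augs(tx)) {
      orf <- delineate_orf(tx, aug)
      want <- uorfann:::orf_oracle(tx$sequence, tx$utr5_length, aug)
      expect_identical(orf$kind, want$kind,
                       info = sprintf("seed %d, uAUG c.%d", seed, aug))
      expect_identical(orf$stop_first, want$stop_first,
                       info = sprintf("seed %d, uAUG c.%d", seed, aug))
      # arithmetic identities when a stop exists
      if (!is.na(orf$stop_last)) {
        expect_identical(orf$length_nt, orf$codons_incl_stop * 3L)
        expect_identical(orf$codons_incl_stop, want$n_codons)
        if (orf$kind == "uORF_terminating_in_leader") {
          # frame consistency holds on the leader side of the origin
          expect_identical(abs(aug) %% 3L, abs(orf$stop_first) %% 3L)
          expect_identical(orf$length_nt, abs(aug) - abs(orf$stop_last) + 1L)
          expect_identical(orf$dist_stop_end, abs(orf$stop_last) - 1L)
          expect_identical(orf$dist_stop_start, abs(orf$stop_first))
          expect_identical(orf$dist_stop_start - orf$dist_stop_end, 3L)
        }
      }
      if (orf$kind == "inframe_readthrough_extension") {
        expect_identical(orf$extension_codons, abs(aug) %/% 3L)
      }
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 100L)  # the sample must actually exercise the scanner
})

test_that("uAUG diffing reports creations, disruptions and in-frame stop changes", {
  tx <- fixture_tx()
  ev <- diff_uaug_events(tx, apply_variants(tx, "c.-263C>A"))
  expect_identical(ev$created, -263L)
  expect_identical(ev$destroyed, integer())

  ev281 <- diff_uaug_events(tx, apply_variants(tx, "c.-281G>T"))
  expect_identical(lengths(ev281), c(created = 0L, destroyed = 0L,
                                     uorf_stop_created = 0L, uorf_stop_destroyed = 0L))

  m263 <- fixture_tx_263()
  ev252 <- diff_uaug_events(m263, apply_variants(m263, "c.-252T>A"))
  expect_identical(ev252$uorf_stop_created, -254L)
  expect_identical(ev252$created, integer())

  # disrupting the native stop of the -263 uORF is seen in the other direction
  evstop <- diff_uaug_events(m263, apply_variants(m263, "c.-62T>C"))
  expect_identical(evstop$uorf_stop_destroyed, -62L)

  expect_error(diff_uaug_events(tx, substr(tx$sequence, 1, 100)), "length")
})
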