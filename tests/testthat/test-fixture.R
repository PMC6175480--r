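test_that("the default fixture satisfies every positional constraint", {
  v <- validate_fixture(fixture_tx())
  expect_true(all(v$pass), info = paste(v$constraint[!v$pass], collapse = "; "))
  expect_gte(nrow(v), 15L)
})

test_that("fixture construction is deterministic per seed and valid across seeds", {
  expect_identical(build_fixture(seed = 1)$sequence, build_fixture(seed = 1)$sequence)
  expect_false(identical(build_fixture(seed = 1)$sequence,
                         build_fixture(seed = 2)$sequence))
  for (seed in c(2, 17, 101)) {
    expect_true(all(validate_fixture(build_fixture(seed = seed))$pass),
                info = sprintf("seed %d", seed))
  }
})

test_that("a leader too short for the constrained positions is refused", {
  expect_error(build_fixture(utr5_length = 100), "constraints")
})

test_that("validation pinpoints planted violations", {
  tx <- fixture_tx()
  seq <- tx$sequence
  substr(seq, c_to_index(tx, -100L), c_to_index(tx, -98L)) <- "ATG"
  broken <- transcript_model(seq, tx$utr5_length, id = tx$id)
  v <- validate_fixture(broken)
  row <- v[v$constraint == "no ATG anywhere in the WT leader", ]
  expect_false(row$pass)
  expect_match(row$detail, "c.-100")

  seq2 <- tx$sequence
  substr(seq2, c_to_index(tx, -62L), c_to_index(tx, -60L)) <- "CCC"
  nostop <- transcript_model(seq2, tx$utr5_length, id = tx$id)
  v2 <- validate_fixture(nostop)
  expect_false(v2$pass[v2$constraint == "native stop TGA at c.-62_-60"])
})

test_that("random transcripts are reproducible, AUG-free on request, and hit the GC target", {
  a <- random_transcript(200, 0.6, seed = 1, forbid_leader_aug = TRUE)
  b <- random_transcript(200, 0.6, seed = 1, forbid_leader_aug = TRUE)
  expect_identical(a$sequence, b$sequence)
  expect_identical(find_augs(a), integer())

  gc <- vapply(1:200, function(s) {
    leader <- substr(random_transcript(150, 0.6, seed = s)$sequence, 1, 150)
    mean(strsplit(leader, "")[[1]] %in% c("G", "C"))
  }, numeric(1))
  expect_lt(abs(mean(gc) - 0.6), 0.05)
})

test_that("spiked variant tables are stratified, labelled and edge-case safe", {
  empty <- spike_variants(fixture_tx(), 0)
  expect_identical(nrow(empty), 0L)

  cases <- spike_variants(fixture_tx_263(), 35, seed = 3)
  expect_identical(nrow(cases), 35L)
  # on an AUG-bearing leader the mixture spans all seven classes
  expect_setequal(
    unique(cases$expected_classification),
    c("NO_UAUG_CHANGE", "UAUG_CREATED_UORF", "UAUG_CREATED_INFRAME_EXTENSION",
      "UAUG_CREATED_OVERLAPPING_OORF", "UAUG_DESTROYED",
      "UORF_STOP_CREATED", "UORF_STOP_DESTROYED")
  )
  # every spiked REF matches the underlying sequence
  for (i in seq_len(nrow(cases))) {
    v <- cases$variants[[i]]
    idx <- c_to_index(fixture_tx_263(), v$cpos)
    expect_identical(substr(fixture_tx_263()$sequence, idx, idx), v$ref)
  }
})

test_that("an in-frame AUG-creating edit with no downstream leader stop is labelled as extension", {
  # the fixture's own -255 GTG>ATG edit is exactly this constructed case
  cases <- spike_variants(fixture_tx(), 200, seed = 1)
  lbl <- cases$expected_classification[cases$spec == "c.-255G>A"]
  expect_identical(lbl, "UAUG_CREATED_INFRAME_EXTENSION")
})

test_that("the fixture bundle writes coherent files", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(dir)
  expect_true(all(file.exists(paths)))
  cons <- readr::read_tsv(paths[["constraints"]], show_col_types = FALSE)
  expect_true(all(cons$pass))
  tx <- read_transcript(paths[["fasta"]],
                        utr5_length = yaml::read_yaml(paths[["config"]])$utr5_length)
  expect_identical(tx$sequence, fixture_tx()$sequence)
  sets <- read_variant_sets(paths[["variants"]])
  expect_identical(nrow(sets), length(fixture_variant_sets()))
})
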