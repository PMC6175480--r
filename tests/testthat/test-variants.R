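test_that("HGVS c. SNVs parse, including unicode hyphens and stray spaces", {
  v <- parse_hgvs(c("c.-263C>A", "c.-255G>A", "c.‐281G > T", " c.-75 C>T"))
  expect_identical(v$cpos, c(-263L, -255L, -281L, -75L))
  expect_identical(v$ref, c("C", "G", "G", "C"))
  expect_identical(v$alt, c("A", "A", "T", "T"))
  expect_identical(v$label[3], "c.-281G>T")  # labels normalised to ASCII
})

test_that("non-SNV and malformed HGVS tokens are rejected, naming the token", {
  expect_error(parse_hgvs("c.0A>G"), "position 0")
  expect_error(parse_hgvs("c.-10_-9del"), "c.-10_-9del")
  expect_error(parse_hgvs("c.-10+5G>A"), "c.-10\\+5G>A")
  expect_error(parse_hgvs("c.-10dupA"), "dup")
  expect_error(parse_hgvs("c.-10G>G"), "identical")
})

test_that("published genomic SNVs land on their HGVS c. counterparts (minus strand)", {
  map <- fixture_genomic_map()  # chr7:19117602 <-> c.-281, minus strand
  gv <- tibble::tibble(
    chrom = "chr7",
    gpos = c(19117602L, 19117584L, 19117576L),
    ref = c("C", "G", "C"),
    alt = c("A", "T", "T")
  )
  cv <- map_genomic_to_c(gv, map)
  expect_identical(cv$label, c("c.-281G>T", "c.-263C>A", "c.-255G>A"))
})

test_that("genomic mapping round-trips on both strands, including across the c.0 gap", {
  for (strand in c("+", "-")) {
    map <- genomic_map("chrT", 5000L, -281L, strand)
    cv <- parse_hgvs(c("c.-281G>T", "c.-263C>A", "c.-1A>G", "c.1A>T", "c.40G>C"))
    gv <- map_c_to_genomic(cv, map)
    back <- map_genomic_to_c(gv, map)
    expect_identical(back$cpos, cv$cpos, info = strand)
    expect_identical(back$ref, cv$ref, info = strand)
    expect_identical(back$alt, cv$alt, info = strand)
  }
})

test_that("chromosome mismatches are refused", {
  map <- fixture_genomic_map()
  gv <- tibble::tibble(chrom = "chr8", gpos = 19117602L, ref = "C", alt = "A")
  expect_error(map_genomic_to_c(gv, map), "mismatch")
})

test_that("applying the reference variants creates exactly the expected AUGs", {
  tx <- fixture_tx()
  m263 <- apply_variants(tx, "c.-263C>A")
  expect_identical(find_augs(m263), -263L)
  m281 <- apply_variants(tx, "c.-281G>T")
  expect_identical(find_augs(m281), integer())
  dual <- apply_variants(tx, c("c.-281G>T", "c.-263C>A"))
  expect_identical(find_augs(dual), -263L)
  # input model untouched
  expect_identical(find_augs(tx), integer())
})

test_that("substitution preserves length and is undone by the inverse SNV", {
  tx <- fixture_tx()
  cases <- spike_variants(tx, 25, seed = 11)
  for (i in seq_len(nrow(cases))) {
    v <- cases$variants[[i]]
    mut <- apply_variants(tx, v)
    expect_identical(nchar(mut$sequence), nchar(tx$sequence))
    inverse <- v
    inverse$ref <- v$alt
    inverse$alt <- v$ref
    expect_identical(apply_variants(mut, inverse)$sequence, tx$sequence)
  }
})

test_that("REF mismatches and duplicate positions abort with precise messages", {
  tx <- fixture_tx()
  expect_error(apply_variants(tx, "c.-263G>A"),
               "c\\.-263.*variant says G.*sequence has C")
  expect_error(apply_variants(tx, c("c.-263C>A", "c.-263C>T")), "Duplicate")
})

test_that("cis-grouped variant files parse one annotation unit per line", {
  path <- withr::local_tempfile(lines = c(
    "# reference inputs",
    "c.-281G>T,c.-263C>A",
    "",
    "c.-255G>A  # family 2"
  ))
  sets <- read_variant_sets(path)
  expect_identical(nrow(sets), 2L)
  expect_identical(sets$spec, c("c.-281G>T,c.-263C>A", "c.-255G>A"))
  expect_identical(nrow(sets$variants[[1]]), 2L)
})
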