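# Shared fixtures, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

fixture_tx <- function() {
  if (is.null(.fixture_cache$tx)) .fixture_cache$tx <- build_fixture()
  .fixture_cache$tx
}

# fixture with the Family-1 uORF-creating variant already applied
fixture_tx_263 <- function() {
  if (is.null(.fixture_cache$tx263)) {
    .fixture_cache$tx263 <- apply_variants(fixture_tx(), "c.-263C>A")
  }
  .fixture_cache$tx263
}
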