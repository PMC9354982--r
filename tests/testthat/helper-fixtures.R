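# Shared barcode-assignment fixture: a mid-sized spaced whitelist and a
# trained model, built once per test run (training needs enough reads for a
# populated false class).
.fixture_env <- new.env(parent = emptyenv())

shared_assign_fixture <- function() {
  if (is.null(.fixture_env$fx)) {
    wl <- make_whitelist(80, 16, seed = 23, min_hamming = 5)
    lay <- read_layout()
    em <- error_model(0.04, 0.04, 0.04)
    model <- train_barcode_model(wl, lay, em, n_reads = 4000, seed = 51)
    .fixture_env$fx <- list(wl = wl, lay = lay, em = em, model = model)
  }
  .fixture_env$fx
}
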