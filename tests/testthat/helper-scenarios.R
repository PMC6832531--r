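## Scenario cache: each canned scenario is generated once per test run.

.scn_cache <- new.env(parent = emptyenv())

get_scenario <- function(name, seed = 1L) {
  key <- paste0(name, "_", seed)
  if (is.null(.scn_cache[[key]])) {
    .scn_cache[[key]] <- simulate_scenario(name, seed = seed)
  }
  .scn_cache[[key]]
}

run_catalog <- function(sc, ...) {
  isoform_catalog(sc$sim$reads, sc$sim$chains, sc$models, sc$clusters, ...)
}

.cat_cache <- new.env(parent = emptyenv())

get_catalog <- function(name, seed = 1L) {
  key <- paste0(name, "_", seed)
  if (is.null(.cat_cache[[key]])) {
    .cat_cache[[key]] <- run_catalog(get_scenario(name, seed))
  }
  .cat_cache[[key]]
}

## variant row containing a given read id
variant_of_read <- function(catalog, read_id) {
  hit <- grepl(paste0("(^|,)", read_id, "(,|$)"), catalog$variants$read_ids)
  catalog$variants[hit, , drop = FALSE]
}
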