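## Shared fixtures, built once per test run and memoized.  The reduced
## volume (1/16 of the reference base area) keeps every stage fast while
## exercising the same code paths as the full reconstruction.

.fix <- new.env(parent = emptyenv())

fixture_config <- function() {
  if (is.null(.fix$cfg)) .fix$cfg <- make_fixture(1 / 16)
  .fix$cfg
}

fixture_placement <- function() {
  if (is.null(.fix$placement))
    .fix$placement <- suppressWarnings(place_cells(fixture_config(), seed = 42))
  .fix$placement
}

fixture_connectome <- function() {
  if (is.null(.fix$connectome))
    .fix$connectome <- build_connectome(fixture_placement(), seed = 42)
  .fix$connectome
}

## Hand-built placement for toy connectivity tests: positions are chosen, not
## sampled, so expected candidate sets can be enumerated by brute force.
toy_placement <- function(cells, cfg = scaffold_config(scale = 0.25),
                          aa_height = NULL) {
  cells <- data.table::as.data.table(cells)
  cells$cell_id <- seq_len(nrow(cells))
  cells$type_code <- cfg$neurons$type_code[match(cells$type, cfg$neurons$name)]
  grc_ids <- cells$cell_id[cells$type == "GrC"]
  aa <- data.table::data.table(
    cell_id = grc_ids,
    aa_height = if (is.null(aa_height)) rep(181, length(grc_ids)) else aa_height)
  structure(list(cells = cells, aa = aa, seed = 0L, config = cfg),
            class = "scaffold_placement")
}

## All-pairs minimum distance, the brute-force non-overlap oracle.
min_pair_dist <- function(m) {
  if (nrow(m) < 2) return(Inf)
  min(dist(m))
}
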