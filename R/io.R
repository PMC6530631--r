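## File schemas.  All artifacts are plain tab-separated text with a YAML
## sidecar manifest (<stem>.manifest.yaml) recording the schema version,
## seed and a configuration hash, so a pipeline stage can verify its inputs.

SCHEMA_VERSION <- "1"

config_hash <- function(cfg) {
  ser <- yaml::as.yaml(lapply(unclass(cfg), function(x)
    if (is.data.frame(x)) as.list(x) else x), precision = 15)
  ## small rolling hash; stdlib-only, stable across sessions
  bytes <- utf8ToInt(ser)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%x", h)
}

write_manifest <- function(stem, kind, seed, cfg, extra = list()) {
  m <- c(list(kind = kind, schema_version = SCHEMA_VERSION,
              seed = as.integer(seed), config_hash = config_hash(cfg),
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
         extra)
  yaml::write_yaml(m, paste0(stem, ".manifest.yaml"))
}

read_manifest <- function(stem, kind) {
  path <- paste0(stem, ".manifest.yaml")
  if (!file.exists(path)) stop("missing manifest: ", path)
  m <- yaml::read_yaml(path)
  if (!identical(m$schema_version, SCHEMA_VERSION))
    stop("unsupported schema version '", m$schema_version, "' in ", path)
  if (!identical(m$kind, kind))
    stop("manifest kind '", m$kind, "' where '", kind, "' expected: ", path)
  m
}

#' Write a placement to disk
#'
#' One TSV with columns `cell_id`, `type_code`, `x`, `y`, `z`, a second TSV
#' (`<stem>.aa.tsv`) with the per-granule-cell ascending-axon heights, and a
#' manifest with the seed and configuration hash.
#'
#' @param placement A `scaffold_placement`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_placement <- function(placement, path) {
  stem <- sub("\\.tsv$", "", path)
  data.table::fwrite(placement$cells[, c("cell_id", "type_code", "x", "y", "z"),
                                     with = FALSE],
                     path, sep = "\t")
  data.table::fwrite(placement$aa, paste0(stem, ".aa.tsv"), sep = "\t")
  write_manifest(stem, "placement", placement$seed, placement$config,
                 list(n_cells = nrow(placement$cells)))
  save_config(placement$config, paste0(stem, ".config.yaml"))
  invisible(path)
}

#' Read a placement from disk
#'
#' @param path Path written by [write_placement()].
#' @return A `scaffold_placement`.
#' @export
read_placement <- function(path) {
  stem <- sub("\\.tsv$", "", path)
  m <- read_manifest(stem, "placement")
  cfg <- load_config(paste0(stem, ".config.yaml"))
  cells <- data.table::fread(path, sep = "\t")
  cells$type <- cfg$neurons$name[match(cells$type_code, cfg$neurons$type_code)]
  if (anyNA(cells$type)) stop("placement file contains unknown type codes")
  aa <- data.table::fread(paste0(stem, ".aa.tsv"), sep = "\t")
  out <- list(cells = cells, aa = aa, seed = m$seed, config = cfg)
  class(out) <- "scaffold_placement"
  out
}

#' Write a connectome to disk
#'
#' One TSV per connection type (`<stem>.<connection>.tsv`, columns `pre_id`,
#' `post_id`, `dist`), plus the intermediate GoC-Glom edge set and a
#' manifest.
#'
#' @param connectome A `scaffold_connectome`.
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_connectome <- function(connectome, stem) {
  for (nm in names(connectome$edges))
    data.table::fwrite(connectome$edges[[nm]],
                       paste0(stem, ".", nm, ".tsv"), sep = "\t")
  data.table::fwrite(connectome$goc_glom, paste0(stem, ".goc_glom.tsv"),
                     sep = "\t")
  write_manifest(stem, "connectome", connectome$seed, connectome$config,
                 list(connections = names(connectome$edges)))
  save_config(connectome$config, paste0(stem, ".config.yaml"))
  invisible(stem)
}

#' Read a connectome from disk
#'
#' @param stem Path stem used in [write_connectome()].
#' @return A `scaffold_connectome`.
#' @export
read_connectome <- function(stem) {
  m <- read_manifest(stem, "connectome")
  cfg <- load_config(paste0(stem, ".config.yaml"))
  unknown <- setdiff(unlist(m$connections), cfg$synapses$connection)
  if (length(unknown))
    stop("connectome file lists unknown connection name(s): ",
         paste(unknown, collapse = ", "))
  edges <- lapply(cfg$synapses$connection, function(nm)
    data.table::fread(paste0(stem, ".", nm, ".tsv"), sep = "\t"))
  names(edges) <- cfg$synapses$connection
  out <- list(edges = edges,
              goc_glom = data.table::fread(paste0(stem, ".goc_glom.tsv"),
                                           sep = "\t"),
              seed = m$seed, config = cfg)
  class(out) <- "scaffold_connectome"
  out
}

#' Write spikes to disk
#'
#' Two-column TSV `id`, `t` (ms).
#'
#' @param spikes A `scaffold_spikes`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(spikes, path) {
  data.table::fwrite(as.data.frame(spikes)[, c("id", "t")], path, sep = "\t")
  invisible(path)
}

#' Reduced-volume configuration for fast runs
#'
#' Scales the cortical and DCN base dimensions by `sqrt(scale)` keeping the
#' layer heights, densities and all connection rules, so cell counts scale by
#' approximately `scale`.
#'
#' @param scale Area fraction in (0, 1].
#' @param orthogonal_plexus Passed through to [scaffold_config()].
#' @return A `scaffold_config`.
#' @examples
#' expected_counts(make_fixture(1 / 16))  # ~6k cells
#' @export
make_fixture <- function(scale, orthogonal_plexus = FALSE) {
  stopifnot(scale > 0, scale <= 1)
  scaffold_config(scale = sqrt(scale), orthogonal_plexus = orthogonal_plexus)
}
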