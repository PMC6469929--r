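# Lossless directory serialization: one TSV per record family plus
# metadata.json. Numeric columns use shortest-round-trip formatting, so
# write_dataset() %>% read_dataset() is the exact identity on doubles.

DATASET_TABLES <- c("flanks", "compartments", "interfaces", "events",
                    "intensities", "snapshots")

#' Write an embryo dataset to a directory of TSV tables
#'
#' Serializes each record family to a tab-separated table (`flanks.tsv`,
#' `compartments.tsv`, `interfaces.tsv`, `events.tsv`, `intensities.tsv`,
#' `snapshots.tsv`, optionally `replicates.tsv`) plus a `metadata.json`
#' holding the embryo id, genotype label, timeline block and simulator
#' provenance. Empty tables are written header-only. Missing values are
#' serialized as `NA`.
#'
#' @param ds A validated [embryo_dataset()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  validate_dataset(ds)
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create dataset directory: ", path)
  }
  for (tab in DATASET_TABLES) {
    write_tsv_table(ds[[tab]], file.path(path, paste0(tab, ".tsv")))
  }
  if (!is.null(ds$replicates)) {
    write_tsv_table(ds$replicates, file.path(path, "replicates.tsv"))
  }
  meta <- list(
    embryo_id = ds$embryo_id,
    genotype_label = ds$genotype_label,
    timeline = list(
      t_E = ds$timeline$t_E,
      t_F = as.list(ds$timeline$t_F),
      frame_interval_length = ds$timeline$frame_interval_length,
      frame_interval_count = ds$timeline$frame_interval_count
    ),
    provenance = ds$provenance
  )
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(path)
}

#' Read an embryo dataset from a directory written by [write_dataset()]
#'
#' Rebuilds and validates the dataset; missing values are preserved as
#' missing. Schema violations raise a `fusefid_validation_error` naming
#' the offending table, row and column.
#'
#' @param path Dataset directory.
#' @return An [embryo_dataset()].
#' @export
read_dataset <- function(path) {
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path)) {
    abort_validation("metadata.json not found", file = meta_path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = FALSE)
  tabs <- list()
  for (tab in DATASET_TABLES) {
    f <- file.path(path, paste0(tab, ".tsv"))
    if (!file.exists(f)) abort_validation("required table missing", file = basename(f))
    tabs[[tab]] <- read_tsv_table(f, TABLE_SCHEMAS[[tab]])
  }
  rep_path <- file.path(path, "replicates.tsv")
  replicates <- if (file.exists(rep_path)) {
    read_tsv_table(rep_path, TABLE_SCHEMAS$replicates)
  } else {
    NULL
  }
  tl <- meta$timeline
  timeline <- timeline_convention(
    t_E = as.numeric(tl$t_E),
    t_F = unlist(tl$t_F),
    frame_interval_length = as.numeric(tl$frame_interval_length),
    frame_interval_count = as.numeric(tl$frame_interval_count)
  )
  embryo_dataset(
    embryo_id = meta$embryo_id,
    genotype_label = meta$genotype_label,
    timeline = timeline,
    flanks = tabs$flanks, compartments = tabs$compartments,
    interfaces = tabs$interfaces, events = tabs$events,
    intensities = tabs$intensities, snapshots = tabs$snapshots,
    replicates = replicates,
    provenance = meta$provenance
  )
}

#' Read every embryo dataset below a directory
#'
#' @param path Directory whose immediate subdirectories each hold one
#'   dataset (as written by [write_dataset()]).
#' @return Named list of [embryo_dataset()] objects.
#' @export
read_datasets <- function(path) {
  subdirs <- list.dirs(path, recursive = FALSE)
  subdirs <- subdirs[file.exists(file.path(subdirs, "metadata.json"))]
  if (!length(subdirs)) stop("no datasets found under ", path)
  out <- lapply(subdirs, read_dataset)
  names(out) <- vapply(out, function(d) d$embryo_id, "")
  out
}
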