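# End-to-end helpers: writing a full synthetic study to disk and the
# command-line dispatcher used by inst/cli/tadcore-cli.R.

#' Write a complete synthetic study to a directory
#'
#' Generates genome, structures, clusters, contacts, per-cell pairs,
#' expression, features and ground truth with [sim_config()] defaults (or a
#' supplied config) and writes them as plain-text files:
#' `tads.bed`, `clusters.tsv`, `contacts.coo`, `cells/*.pairs`,
#' `structures/*.tsv`, `imaging.csv`, `expression.bedgraph`, `features.bed`,
#' `truth.tsv`, plus a JSON `manifest.json` recording parameters and file
#' checksums. Per-cell file outputs are limited to `max_cell_files` cells to
#' keep directories small; the in-memory generators are not limited.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created).
#' @param max_cell_files per-cell .pairs / structure files to write
#'   (default 20).
#' @param max_imaging_cells cells included in `imaging.csv` (default 50).
#' @return invisibly, the manifest list.
#' @export
simulate_study <- function(cfg, out_dir, max_cell_files = 20L,
                           max_imaging_cells = 50L) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "cells"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "structures"), showWarnings = FALSE)
  genome <- gen_genome(cfg)
  structures <- gen_structures(cfg, genome)
  clusters <- gen_sprite(cfg, structures)
  contacts <- gen_contacts(cfg, structures)
  signals <- gen_signals(cfg, genome, structures$tendency)
  index <- genome$index

  write_bed(genome$tads, file.path(out_dir, "tads.bed"))
  write_sprite_clusters(clusters, index, file.path(out_dir, "clusters.tsv"))
  write_contacts_coo(contacts, index, file.path(out_dir, "contacts.coo"))
  all_cells <- unique(structures$cells$cell_id)
  few <- head(all_cells, max_cell_files)
  pairs <- gen_pairs(cfg, structures, cell_ids = few)
  for (cid in few) {
    write_pairs_file(pairs[[cid]], index,
                     file.path(out_dir, "cells", paste0(cid, ".pairs")))
    write_structure(structures$cells[cell_id == cid, .(bin, x, y, z)], index,
                    file.path(out_dir, "structures", paste0(cid, ".tsv")))
  }
  img_cells <- head(all_cells, max_imaging_cells)
  write_imaging(structures$cells[cell_id %in% img_cells,
                                 .(cell_id, bin, x, y, z)],
                index, file.path(out_dir, "imaging.csv"))
  fwrite(structures$segmentation[cell_id %in% img_cells],
         file.path(out_dir, "segmentation.tsv"), sep = "\t")
  write_bedgraph(signals$expression, file.path(out_dir, "expression.bedgraph"))
  write_bed(signals$features, file.path(out_dir, "features.bed"))
  bt <- bin_table(index)
  bt[, tendency := structures$tendency]
  fwrite(bt[, .(chrom, start, end, tendency)],
         file.path(out_dir, "truth.tsv"), sep = "\t", na = "NA")

  manifest <- run_manifest("simulate", cfg[setdiff(names(cfg), "")],
                           out_dir = out_dir, seed = cfg$seed)
  invisible(manifest)
}

#' Write a JSON run manifest
#'
#' Records the command, parameters, seed, package version, timestamp and
#' md5 checksums of the files currently in `out_dir`, then writes
#' `manifest.json` there.
#'
#' @param command command name.
#' @param parameters named list of parameters.
#' @param out_dir directory whose files are checksummed.
#' @param seed RNG seed used (or `NA`).
#' @return the manifest list, invisibly.
#' @export
run_manifest <- function(command, parameters, out_dir, seed = NA) {
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    command = command,
    parameters = parameters,
    seed = seed,
    tool_version = as.character(utils::packageVersion("tadcore")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Command-line dispatcher
#'
#' Backs the `inst/cli/tadcore-cli.R` script. Subcommands:
#' `simulate`, `ratio` (`--mode sprite|hic|pairs|structure|imaging`),
#' `scdomains`, `classify`, `shuffle`, `enrich`. Flags are `--key value`
#' pairs; every run writes its outputs plus a `manifest.json` into `--out`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
tadcore_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: tadcore-cli.R <simulate|ratio|scdomains|classify|shuffle|enrich>",
    "[--key value ...]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  handler <- switch(cmd,
    simulate = .cli_simulate, ratio = .cli_ratio, scdomains = .cli_scdomains,
    classify = .cli_classify, shuffle = .cli_shuffle, enrich = .cli_enrich,
    NULL)
  if (is.null(handler)) {
    message("unknown subcommand: ", cmd, "\n", usage)
    return(invisible(1L))
  }
  status <- tryCatch({ handler(.parse_flags(args[-1])); 0L },
                     error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

.parse_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("unexpected argument: ", args[i])
    key <- sub("^--", "", args[i])
    if (i + 1L > length(args)) stop("flag --", key, " needs a value")
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

.need <- function(opts, key) {
  if (is.null(opts[[key]])) stop("missing required flag --", key)
  opts[[key]]
}

.opt_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

.cli_index_from_tads <- function(tads, bin_size, pad = 1L) {
  td <- as.data.table(tads)
  sizes <- td[, .(len = max(end)), by = chrom]
  bin_index(setNames(sizes$len, sizes$chrom), as.integer(bin_size))
}

.cli_simulate <- function(opts) {
  out <- .need(opts, "out")
  cfg_args <- opts[names(opts) %in% names(formals(sim_config))]
  cfg_args <- lapply(cfg_args, as.numeric)
  cfg_args$seed <- as.integer(.need(opts, "seed"))
  cfg <- do.call(sim_config, cfg_args)
  simulate_study(cfg, out)
}

.cli_ratio <- function(opts) {
  mode <- .need(opts, "mode")
  out <- .need(opts, "out")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  tads <- read_tads(.need(opts, "tads"))
  bin_size <- as.integer(.opt_num(opts, "bin-size", 10000))
  index <- .cli_index_from_tads(tads, bin_size)
  track <- switch(mode,
    sprite = {
      sp <- read_sprite(.need(opts, "clusters"), index,
                        min_size = .opt_num(opts, "min-size", 2),
                        max_size = .opt_num(opts, "max-size", 1000))
      sprite_ratio(sp$clusters, tads, index,
                   min_bin_support = .opt_num(opts, "min-bin-support", 100))
    },
    hic = contact_ratio(read_contacts_coo(.need(opts, "contacts"), index),
                        tads, index),
    pairs = {
      files <- list.files(.need(opts, "pairs-dir"), pattern = "\\.pairs$",
                          full.names = TRUE)
      pairs_ratio(read_pairs(files, index), tads, index)$average
    },
    structure = {
      files <- list.files(.need(opts, "structure-dir"), pattern = "\\.tsv$",
                          full.names = TRUE)
      structure_ratio(lapply(files, read_structure, index = index), tads,
                      index, k = as.integer(.opt_num(opts, "k", 10)))
    },
    imaging = {
      img <- read_imaging(.need(opts, "imaging"), index)
      seg <- fread(.need(opts, "segmentation"))
      average_cell_tracks(
        imaging_ratio(img, seg, index,
                      radius = .opt_num(opts, "radius", 500)), index)
    },
    stop("unknown ratio mode: ", mode))
  write_ratio_track(track, file.path(out, "ratio.tsv"))
  run_manifest(paste0("ratio-", mode), opts, out,
               seed = .opt_num(opts, "seed", NA))
}

.cli_scdomains <- function(opts) {
  out <- .need(opts, "out")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  bin_size <- as.integer(.opt_num(opts, "bin-size", 10000))
  tads <- read_tads(.need(opts, "tads"))
  index <- .cli_index_from_tads(tads, bin_size)
  img <- read_imaging(.need(opts, "imaging"), index)
  segs <- img[, call_scdomains(.SD,
                window_w = as.integer(.opt_num(opts, "window", 5)),
                boundary_prominence = .opt_num(opts, "prominence", 1.2),
                merge_threshold = .opt_num(opts, "merge", 0.9))$labels,
              by = cell_id]
  fwrite(segs, file.path(out, "segmentation.tsv"), sep = "\t")
  run_manifest("scdomains", opts, out)
}

.cli_classify <- function(opts) {
  out <- .need(opts, "out")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  tads <- read_tads(.need(opts, "tads"))
  bin_size <- as.integer(.opt_num(opts, "bin-size", 10000))
  index <- .cli_index_from_tads(tads, bin_size)
  track <- read_ratio_track(.need(opts, "ratios"), index)
  labels <- classify_surface_core(track, tads)
  frac <- .opt_num(opts, "exclude-boundary", NA)
  if (!is.na(frac)) labels <- exclude_boundaries(labels, frac)
  bt <- bin_table(index)
  fwrite(labels[, .(chrom = bt$chrom[bin], start = bt$start[bin],
                    end = bt$end[bin], tad_id, label)],
         file.path(out, "labels.tsv"), sep = "\t", na = "NA")
  run_manifest("classify", opts, out)
}

.cli_shuffle <- function(opts) {
  out <- .need(opts, "out")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  tads <- read_tads(.need(opts, "tads"))
  n <- as.integer(.opt_num(opts, "n", 1))
  seed <- as.integer(.need(opts, "seed"))
  for (i in seq_len(n))
    write_bed(shuffle_tads(tads, seed + i - 1L),
              file.path(out, sprintf("shuffled_%03d.bed", i)))
  run_manifest("shuffle", opts, out, seed = seed)
}

.cli_enrich <- function(opts) {
  out <- .need(opts, "out")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  labels <- fread(.need(opts, "labels"), na.strings = "NA")
  tads <- read_tads(.need(opts, "tads"))
  bin_size <- as.integer(.opt_num(opts, "bin-size", 10000))
  index <- .cli_index_from_tads(tads, bin_size)
  feats <- read_intervals(.need(opts, "features"))
  labels[, bin := assign_bin(index, chrom, start)]
  universe <- labels$bin
  target_lab <- if (is.null(opts[["target"]])) "surface" else opts[["target"]]
  target <- labels[label == target_lab, bin]
  sets <- label_feature_bins(feats, index)
  res <- rbindlist(lapply(names(sets), function(nm)
    cbind(category = nm, enrichment(sets[[nm]], universe, target))))
  fwrite(res, file.path(out, "enrichment.tsv"), sep = "\t")
  run_manifest("enrich", opts, out)
}
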