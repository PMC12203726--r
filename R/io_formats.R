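# Readers/writers for the external text formats the pipeline touches.
# All coordinates are converted to 0-based half-open at this boundary.
# Malformed lines are counted; more than `tolerance` of them is a hard error.

.check_malformed <- function(n_bad, n_total, tolerance, what) {
  if (n_bad > 0) {
    frac <- n_bad / max(n_total, 1L)
    if (frac > tolerance)
      stop(sprintf("%d/%d malformed line(s) in %s (tolerance %.3f)",
                   n_bad, n_total, what, tolerance))
    warning(sprintf("%d malformed line(s) skipped in %s", n_bad, what))
  }
  invisible(n_bad)
}

#' Read TAD intervals from a BED file
#'
#' Expects at least 3 tab-separated columns (chrom, start, end) and uses the
#' 4th as `tad_id` when present. Overlapping intervals are rejected.
#'
#' @param path path to a BED file.
#' @param tolerance maximum tolerated fraction of malformed lines (default 0).
#' @return a [tad_set()].
#' @export
read_tads <- function(path, tolerance = 0) {
  dt <- .read_bedlike(path, min_cols = 3, tolerance = tolerance)
  rec <- dt[, .(chrom = V1, start = as.numeric(V2), end = as.numeric(V3))]
  if (ncol(dt) >= 4) rec[, tad_id := dt$V4]
  tad_set(rec)
}

#' Read labeled feature intervals from a BED file
#'
#' Column 4 carries the feature label (cCRE category, TF name, subcompartment,
#' ...); files without a 4th column get the label `"feature"`.
#'
#' @inheritParams read_tads
#' @return `data.table` of class `interval_set` with columns
#'   `chrom`, `start`, `end`, `label`.
#' @export
read_intervals <- function(path, tolerance = 0) {
  dt <- .read_bedlike(path, min_cols = 3, tolerance = tolerance)
  out <- dt[, .(chrom = V1, start = as.numeric(V2), end = as.numeric(V3))]
  lab <- if (ncol(dt) >= 4) dt$V4 else rep("feature", nrow(dt))
  lab[is.na(lab)] <- "feature"
  out[, label := lab]
  if (any(out$start < 0)) stop("negative coordinate in ", path)
  if (any(out$end <= out$start)) stop("interval end must exceed start in ", path)
  if (any(!nzchar(out$label))) stop("empty feature label in ", path)
  setattr(out, "class", c("interval_set", class(out)))
  out[]
}

.read_bedlike <- function(path, min_cols, tolerance) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) stop("no records in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  ok <- ncols >= min_cols
  ok[ok] <- vapply(parts[ok], function(p)
    !anyNA(suppressWarnings(as.numeric(p[2:3]))), logical(1))
  .check_malformed(sum(!ok), length(lines), tolerance, path)
  parts <- parts[ok]
  maxc <- min(max(lengths(parts)), 6L)
  as.data.table(do.call(rbind, lapply(parts, function(p) p[seq_len(maxc)])))
}

#' Read a bedGraph-like per-bin signal
#'
#' Each record (chrom, start, end, value) is distributed over the bins it
#' overlaps; a bin's value is the coverage-weighted mean of overlapping
#' records. Bins covered by no record are `NA`.
#'
#' @param path bedGraph path.
#' @param index a [bin_index()].
#' @param tolerance malformed-line tolerance.
#' @return a [signal_track()].
#' @export
read_signal <- function(path, index, tolerance = 0) {
  dt <- .read_bedlike(path, min_cols = 4, tolerance = tolerance)
  rec <- dt[, .(chrom = V1, start = as.numeric(V2), end = as.numeric(V3),
                value = suppressWarnings(as.numeric(V4)))]
  if (anyNA(rec$value)) stop("non-numeric signal value in ", path)
  if (any(rec$start < 0)) stop("negative coordinate in ", path)
  signal_track(.intervals_to_bin_mean(rec, index), index)
}

.intervals_to_bin_mean <- function(rec, index) {
  bt <- bin_table(index)
  setkey(bt, chrom, start, end)
  qq <- rec[chrom %in% names(index$chrom_sizes)]
  if (!nrow(qq)) return(rep(NA_real_, n_bins(index)))
  ov <- foverlaps(qq, bt, by.x = c("chrom", "start", "end"), nomatch = NULL)
  ov[, w := pmin(i.end, end) - pmax(i.start, start)]
  ov <- ov[w > 0]
  agg <- ov[, .(value = sum(value * w) / sum(w)), by = bin]
  out <- rep(NA_real_, n_bins(index))
  out[agg$bin] <- agg$value
  out
}

#' Write / read a ratio track as TSV
#'
#' Columns: chrom, start, end, ratio, support; missing ratios are written as
#' `NA`. The round trip is lossless to the written precision (full double
#' precision by default).
#'
#' @param track a [ratio_track()].
#' @param path output path.
#' @return `write_ratio_track` returns `path` invisibly; `read_ratio_track`
#'   returns a [ratio_track()].
#' @export
write_ratio_track <- function(track, path) {
  stopifnot(inherits(track, "ratio_track"))
  bt <- bin_table(track$index)
  bt[, `:=`(ratio = track$value, support = track$support)]
  out <- bt[, .(chrom, start = format(start, scientific = FALSE, trim = TRUE),
                end = format(end, scientific = FALSE, trim = TRUE),
                ratio = formatC(ratio, digits = 17, format = "g"),
                support = support)]
  fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_ratio_track
#' @param index a [bin_index()] matching the file.
#' @export
read_ratio_track <- function(path, index) {
  dt <- fread(path, sep = "\t", na.strings = "NA")
  if (nrow(dt) != n_bins(index)) stop("ratio TSV does not match bin index")
  bin <- assign_bin(index, dt$chrom, dt$start)
  value <- rep(NA_real_, n_bins(index)); support <- integer(n_bins(index))
  value[bin] <- dt$ratio; support[bin] <- dt$support
  ratio_track(value, support, index)
}

#' Read SPRITE multi-contact clusters
#'
#' One cluster per line: a barcode followed by tab-separated reads of the form
#' `chrom:pos`. Reads are mapped to bins and deduplicated, so a cluster is a
#' set of unique bins and the cluster size `C_j` counts unique bins. Clusters
#' whose unique-bin count falls outside `[min_size, max_size]` are dropped
#' (and counted).
#'
#' @param path cluster file path.
#' @param index a [bin_index()].
#' @param min_size,max_size retained range of unique-bin cluster sizes
#'   (defaults 2 and 1000).
#' @param tolerance malformed-line tolerance.
#' @return list with `clusters` (list of integer bin-id vectors, named by
#'   barcode) and `log` (counts: `n_lines`, `n_malformed`, `n_dropped_small`,
#'   `n_dropped_large`, `n_kept`).
#' @export
read_sprite <- function(path, index, min_size = 2L, max_size = 1000L,
                        tolerance = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty SPRITE cluster file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 2
  .check_malformed(sum(!ok), length(lines), tolerance, path)
  parts <- parts[ok]
  barcodes <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(barcodes)) stop("duplicated cluster barcode in ", path)
  reads <- lapply(parts, function(p) p[-1])
  flat <- unlist(reads, use.names = FALSE)
  cid <- rep(seq_along(reads), lengths(reads))
  m <- regmatches(flat, regexec("^([^:]+):([0-9]+)$", flat))
  bad <- lengths(m) != 3
  if (any(bad)) stop("unparseable read '", flat[which(bad)[1]], "' in ", path)
  chrom <- vapply(m, `[[`, character(1), 2L)
  pos <- as.numeric(vapply(m, `[[`, character(1), 3L))
  bin <- assign_bin(index, chrom, pos)
  dt <- unique(data.table(cid = cid, bin = bin))
  dt[, size := .N, by = cid]
  sizes <- dt[, size[1], by = cid]$V1
  keep <- dt[size >= min_size & size <= max_size]
  clusters <- split(keep$bin, keep$cid)
  names(clusters) <- barcodes[as.integer(names(clusters))]
  list(clusters = unname(lapply(clusters, as.integer)),
       barcodes = names(clusters),
       log = list(n_lines = length(lines), n_malformed = sum(!ok),
                  n_dropped_small = sum(sizes < min_size),
                  n_dropped_large = sum(sizes > max_size),
                  n_kept = length(clusters)))
}

#' Read bulk contacts in COO text form
#'
#' Five whitespace-separated columns: chrom1 start1 chrom2 start2 weight.
#' Weights of duplicate and transposed pairs are accumulated onto one
#' unordered bin pair; self-pairs are retained here (downstream ratio code
#' excludes them). Negative weights are a hard error.
#'
#' @param path COO text path.
#' @param index a [bin_index()].
#' @return `data.table` with columns `bin1 <= bin2`, `weight`.
#' @export
read_contacts_coo <- function(path, index) {
  dt <- fread(path, header = FALSE,
              col.names = c("chrom1", "start1", "chrom2", "start2", "weight"))
  if (any(dt$weight < 0)) stop("negative contact weight in ", path)
  b1 <- assign_bin(index, dt$chrom1, dt$start1)
  b2 <- assign_bin(index, dt$chrom2, dt$start2)
  pairs <- data.table(bin1 = pmin(b1, b2), bin2 = pmax(b1, b2),
                      weight = as.numeric(dt$weight))
  pairs[, .(weight = sum(weight)), by = .(bin1, bin2)]
}

#' Read per-cell contacts in 4DN .pairs format
#'
#' Header lines start with `#`; data columns are readID, chrom1, pos1,
#' chrom2, pos2, strand1, strand2 (strands optional and ignored). Each
#' contact is normalized to an unordered bin pair.
#'
#' @param paths character vector of .pairs files, one per cell.
#' @param index a [bin_index()].
#' @return named list (by file base name) of `data.table`s with columns
#'   `bin1 <= bin2`, `weight` (accumulated counts).
#' @export
read_pairs <- function(paths, index) {
  out <- lapply(paths, function(p) {
    lines <- readLines(p)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines))
      return(data.table(bin1 = integer(), bin2 = integer(), weight = numeric()))
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(f) < 5)) stop("short .pairs record in ", p)
    chrom1 <- vapply(f, `[[`, character(1), 2L)
    pos1 <- as.numeric(vapply(f, `[[`, character(1), 3L))
    chrom2 <- vapply(f, `[[`, character(1), 4L)
    pos2 <- as.numeric(vapply(f, `[[`, character(1), 5L))
    b1 <- assign_bin(index, chrom1, pos1)
    b2 <- assign_bin(index, chrom2, pos2)
    data.table(bin1 = pmin(b1, b2), bin2 = pmax(b1, b2),
               weight = 1)[, .(weight = sum(weight)), by = .(bin1, bin2)]
  })
  names(out) <- basename(paths)
  out
}

#' Read a 3D structural model table
#'
#' Tab-separated columns: chrom (with an optional haplotype tag in
#' parentheses, e.g. `chr1(pat)`), start, x, y, z. At most one row per
#' (haplotype-tagged chrom, start).
#'
#' @param path structure table path.
#' @param index a [bin_index()] at the model's resolution.
#' @return `data.table` of class `structure_table` with columns `bin`,
#'   `hap` (`NA` when untagged), `x`, `y`, `z`.
#' @export
read_structure <- function(path, index) {
  dt <- fread(path, header = FALSE,
              col.names = c("chrom", "start", "x", "y", "z"))
  m <- regexec("^([^()]+)(\\(([^()]+)\\))?$", dt$chrom)
  mm <- regmatches(dt$chrom, m)
  chrom <- vapply(mm, `[[`, character(1), 2L)
  hap <- vapply(mm, function(g) if (nzchar(g[4])) g[4] else NA_character_, character(1))
  if (anyDuplicated(data.table(chrom = dt$chrom, start = dt$start)))
    stop("duplicated (chrom, start) row in ", path)
  if (any(!is.finite(dt$x) | !is.finite(dt$y) | !is.finite(dt$z)))
    stop("non-finite coordinate in ", path)
  out <- data.table(bin = assign_bin(index, chrom, dt$start), hap = hap,
                    x = as.numeric(dt$x), y = as.numeric(dt$y),
                    z = as.numeric(dt$z))
  setattr(out, "class", c("structure_table", class(out)))
  out[]
}

#' Read chromatin-tracing imaging coordinates
#'
#' CSV with header `cell_id,chrom,start,end,x,y,z`; coordinates are in
#' nanometers and empty fields mark missing coordinates (such rows are kept
#' with `NA` coordinates). (cell_id, chrom, start) must be unique.
#'
#' @param path imaging CSV path.
#' @param index a [bin_index()] at the imaging resolution.
#' @return `data.table` with columns `cell_id`, `bin`, `x`, `y`, `z`.
#' @export
read_imaging <- function(path, index) {
  dt <- fread(path, header = TRUE)
  need <- c("cell_id", "chrom", "start", "end", "x", "y", "z")
  if (!all(need %in% names(dt))) stop("imaging CSV needs columns ",
                                      paste(need, collapse = ","))
  if (anyDuplicated(dt[, .(cell_id, chrom, start)]))
    stop("duplicated (cell_id, chrom, start) in ", path)
  data.table(cell_id = as.character(dt$cell_id),
             bin = assign_bin(index, dt$chrom, dt$start),
             x = as.numeric(dt$x), y = as.numeric(dt$y), z = as.numeric(dt$z))
}
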