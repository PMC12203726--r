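# Writers for the simulator's on-disk formats; each is the mirror image of a
# reader in io_formats.R so that generated files re-read losslessly.

#' Write TADs / intervals as BED
#'
#' @param tads a [tad_set()] or `interval_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(tads, path) {
  dt <- as.data.table(tads)
  name <- if ("tad_id" %in% names(dt)) dt$tad_id else
    if ("label" %in% names(dt)) dt$label else "."
  out <- dt[, .(chrom,
                start = format(start, scientific = FALSE, trim = TRUE),
                end = format(end, scientific = FALSE, trim = TRUE))]
  out[, name := name]
  fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write SPRITE-style clusters
#'
#' One line per cluster: barcode, then one `chrom:pos` read per member bin
#' (at the bin start).
#'
#' @param clusters list of integer bin-id vectors.
#' @param index the [bin_index()] the bins live on.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sprite_clusters <- function(clusters, index, path) {
  bt <- bin_table(index)
  lines <- vapply(seq_along(clusters), function(i) {
    b <- clusters[[i]]
    paste(c(sprintf("cluster%06d", i),
            paste0(bt$chrom[b], ":",
                   format(bt$start[b], scientific = FALSE, trim = TRUE))),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write accumulated contacts as COO text
#'
#' @param contacts `data.table(bin1, bin2, weight)`.
#' @param index the [bin_index()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contacts_coo <- function(contacts, index, path) {
  bt <- bin_table(index)
  dt <- as.data.table(contacts)
  out <- data.table(chrom1 = bt$chrom[dt$bin1],
                    start1 = format(bt$start[dt$bin1], scientific = FALSE, trim = TRUE),
                    chrom2 = bt$chrom[dt$bin2],
                    start2 = format(bt$start[dt$bin2], scientific = FALSE, trim = TRUE),
                    weight = dt$weight)
  fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write one cell's contacts in 4DN .pairs format
#'
#' @param pairs `data.table(bin1, bin2, weight)`; each pair is written
#'   `weight` times (integer weights expected).
#' @param index the [bin_index()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs_file <- function(pairs, index, path) {
  bt <- bin_table(index)
  dt <- as.data.table(pairs)
  dt <- dt[rep(seq_len(.N), pmax(1L, as.integer(round(weight))))]
  header <- c("## pairs format v1.0",
              paste0("#chromsize: ",
                     paste(names(index$chrom_sizes),
                           format(index$chrom_sizes, scientific = FALSE, trim = TRUE),
                           collapse = " ")),
              "#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2")
  body <- sprintf("read%06d\t%s\t%s\t%s\t%s\t+\t-",
                  seq_len(nrow(dt)),
                  bt$chrom[dt$bin1],
                  format(bt$start[dt$bin1], scientific = FALSE, trim = TRUE),
                  bt$chrom[dt$bin2],
                  format(bt$start[dt$bin2], scientific = FALSE, trim = TRUE))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a per-cell structure table
#'
#' @param cell `data.table(bin, x, y, z)` with optional `hap` column.
#' @param index the [bin_index()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(cell, index, path) {
  bt <- bin_table(index)
  dt <- as.data.table(cell)
  chrom <- bt$chrom[dt$bin]
  if ("hap" %in% names(dt) && any(!is.na(dt$hap)))
    chrom <- ifelse(is.na(dt$hap), chrom, paste0(chrom, "(", dt$hap, ")"))
  out <- data.table(chrom = chrom,
                    start = format(bt$start[dt$bin], scientific = FALSE, trim = TRUE),
                    x = dt$x, y = dt$y, z = dt$z)
  fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write imaging coordinates as CSV
#'
#' @param cells `data.table(cell_id, bin, x, y, z)`.
#' @param index the [bin_index()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_imaging <- function(cells, index, path) {
  bt <- bin_table(index)
  dt <- as.data.table(cells)
  out <- data.table(cell_id = dt$cell_id, chrom = bt$chrom[dt$bin],
                    start = bt$start[dt$bin], end = bt$end[dt$bin],
                    x = dt$x, y = dt$y, z = dt$z)
  fwrite(out, path, quote = FALSE, na = "")
  invisible(path)
}

#' Write a per-bin signal as bedGraph
#'
#' Bins with `NA` signal are omitted.
#'
#' @param track a [signal_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  bt <- bin_table(track$index)
  bt[, value := track$value]
  out <- bt[!is.na(value),
            .(chrom, start = format(start, scientific = FALSE, trim = TRUE),
              end = format(end, scientific = FALSE, trim = TRUE),
              value = formatC(value, digits = 17, format = "g"))]
  fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}
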