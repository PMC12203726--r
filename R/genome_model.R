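#' @import data.table
#' @importFrom stats median quantile cor t.test lm pnorm phyper rnorm runif setNames sd complete.cases coef
#' @importFrom utils head tail
NULL

#' Genomic bin index
#'
#' A `bin_index` tiles a set of named chromosomes with fixed-size, half-open,
#' 0-based bins `[start, start + bin_size)`. The last bin of a chromosome may be
#' short. Bin ids are dense 1-based integers ordered by (chromosome, start), and
#' form the coordinate frame for every track, cluster and structure in the
#' package.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in base pairs.
#' @param bin_size positive integer bin width in base pairs (default 10000).
#' @return An object of class `bin_index`.
#' @examples
#' idx <- bin_index(c(chrS = 1e6), bin_size = 10000)
#' n_bins(idx)
#' @export
bin_index <- function(chrom_sizes, bin_size = 10000L) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (anyDuplicated(names(chrom_sizes)))
    stop("duplicated chromosome names")
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be positive")
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size <= 0) stop("bin_size must be a positive integer")
  sizes <- as.numeric(chrom_sizes)
  nb <- as.integer(ceiling(sizes / bin_size))
  structure(list(
    chrom_sizes = setNames(sizes, names(chrom_sizes)),
    bin_size = bin_size,
    bins_per_chrom = setNames(nb, names(chrom_sizes)),
    chrom_offset = setNames(cumsum(c(0L, nb[-length(nb)])), names(chrom_sizes))
  ), class = "bin_index")
}

#' @export
print.bin_index <- function(x, ...) {
  cat(sprintf("<bin_index> %d chromosome(s), bin_size %d bp, %d bins\n",
              length(x$chrom_sizes), x$bin_size, n_bins(x)))
  invisible(x)
}

#' Total number of bins in a bin index
#' @param index a [bin_index()].
#' @return integer.
#' @export
n_bins <- function(index) {
  stopifnot(inherits(index, "bin_index"))
  as.integer(sum(index$bins_per_chrom))
}

#' Map genomic positions to bin ids
#'
#' Positions are 0-based; each position belongs to exactly one half-open bin.
#'
#' @param index a [bin_index()].
#' @param chrom character vector of chromosome names.
#' @param pos numeric vector of 0-based positions (recycled against `chrom`).
#' @return integer vector of 1-based bin ids.
#' @examples
#' idx <- bin_index(c(chrS = 1e5), 10000)
#' assign_bin(idx, "chrS", c(0, 9999, 10000, 25000))
#' @export
assign_bin <- function(index, chrom, pos) {
  stopifnot(inherits(index, "bin_index"))
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  unknown <- !(chrom %in% names(index$chrom_sizes))
  if (any(unknown))
    stop("unknown chromosome(s): ", paste(unique(chrom[unknown]), collapse = ", "))
  lim <- index$chrom_sizes[chrom]
  bad <- is.na(pos) | pos < 0 | pos >= lim
  if (any(bad))
    stop("position out of range for ", chrom[which(bad)[1]], ": ", pos[which(bad)[1]])
  as.integer(index$chrom_offset[chrom] + pos %/% index$bin_size + 1)
}

#' Table of all bins in an index
#'
#' @param index a [bin_index()].
#' @return `data.table` with columns `bin`, `chrom`, `start`, `end`
#'   (half-open, end clipped at the chromosome length).
#' @export
bin_table <- function(index) {
  stopifnot(inherits(index, "bin_index"))
  chrom <- rep(names(index$bins_per_chrom), index$bins_per_chrom)
  within <- unlist(lapply(index$bins_per_chrom, seq_len), use.names = FALSE) - 1L
  start <- as.numeric(within) * index$bin_size
  end <- pmin(start + index$bin_size, index$chrom_sizes[chrom])
  data.table(bin = seq_along(chrom), chrom = chrom, start = start, end = end)
}

#' TAD interval set
#'
#' Validates a set of labeled, non-overlapping topologically associating
#' domain (TAD) intervals. Coordinates are 0-based half-open (BED convention).
#'
#' @param records data.frame with columns `chrom`, `start`, `end` and
#'   optionally `tad_id` (auto-generated as `TAD1..TADn` when absent).
#' @return A `tad_set`: a `data.table` keyed by (chrom, start).
#' @export
tad_set <- function(records) {
  dt <- as.data.table(records)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(dt))) stop("records need columns chrom, start, end")
  if (!"tad_id" %in% names(dt)) dt[, tad_id := paste0("TAD", .I)]
  dt <- dt[, .(chrom = as.character(chrom), start = as.numeric(start),
               end = as.numeric(end), tad_id = as.character(tad_id))]
  if (any(dt$start < 0)) stop("negative TAD start coordinate")
  if (any(dt$end <= dt$start)) stop("TAD end must exceed start")
  if (anyDuplicated(dt$tad_id)) stop("duplicated tad_id")
  setkey(dt, chrom, start)
  # reject overlap, naming the offending pair
  dt[, prev_end := shift(end), by = chrom]
  bad <- which(!is.na(dt$prev_end) & dt$start < dt$prev_end)
  if (length(bad)) {
    i <- bad[1]
    stop(sprintf("overlapping TADs: %s and %s on %s",
                 dt$tad_id[i - 1L], dt$tad_id[i], dt$chrom[i]))
  }
  dt[, prev_end := NULL]
  setattr(dt, "class", c("tad_set", class(dt)))
  dt[]
}

#' Assign bins to TADs by bin midpoint
#'
#' A bin belongs to a TAD iff its midpoint lies inside the TAD's half-open
#' interval; bins outside all TADs are `NA`. Each bin is assigned to at most
#' one TAD because TADs do not overlap.
#'
#' @param tads a [tad_set()].
#' @param index a [bin_index()].
#' @return integer vector of length `n_bins(index)` giving the row of `tads`
#'   each bin belongs to (`NA` = unassigned), with attribute `tad_ids`
#'   (character vector, `tads$tad_id`).
#' @export
bin_tad_map <- function(tads, index) {
  stopifnot(inherits(tads, "tad_set"), inherits(index, "bin_index"))
  bt <- bin_table(index)
  bt[, mid := (start + end) / 2]
  td <- as.data.table(tads)[, .(chrom, tstart = start, tend = end)]
  td[, row := .I]
  setkey(td, chrom, tstart, tend)
  qq <- bt[, .(chrom, tstart = mid, tend = mid, bin)]
  ov <- foverlaps(qq, td, type = "within", nomatch = NULL)
  # "within" with a point query gives tstart <= mid <= tend; enforce the
  # half-open end, then keep at most one TAD per bin (touching TADs can both
  # match a midpoint sitting exactly on their shared border)
  hit <- unique(ov[i.tstart < tend], by = "bin")
  map <- rep(NA_integer_, n_bins(index))
  map[hit$bin] <- hit$row
  attr(map, "tad_ids") <- tads$tad_id
  map
}

#' Per-TAD bin counts
#'
#' `n_k`, the number of bins assigned to each TAD under a bin index
#' (midpoint rule).
#'
#' @inheritParams bin_tad_map
#' @return named integer vector over `tads$tad_id` (zero where no bin maps).
#' @export
tad_bin_counts <- function(tads, index) {
  map <- bin_tad_map(tads, index)
  tab <- tabulate(map, nbins = nrow(tads))
  setNames(as.integer(tab), tads$tad_id)
}

#' Per-bin ratio track
#'
#' Holds the intra-TAD (or intra-scDomain) ratio `r_i` per bin together with
#' the number of supporting observations (clusters, contacts, cells or model
#' points). `support == 0` iff the value is missing.
#'
#' @param value numeric vector in `[0, 1]` or `NA`, length `n_bins(index)`.
#' @param support non-negative integer vector of the same length.
#' @param index the [bin_index()] the track lives on.
#' @return An object of class `ratio_track`.
#' @export
ratio_track <- function(value, support, index) {
  stopifnot(inherits(index, "bin_index"))
  nb <- n_bins(index)
  if (length(value) != nb || length(support) != nb)
    stop("value/support length must equal n_bins(index)")
  value <- as.numeric(value)
  support <- as.integer(support)
  if (any(support < 0, na.rm = TRUE)) stop("negative support")
  support[is.na(support)] <- 0L
  value[support == 0L] <- NA_real_
  support[is.na(value)] <- 0L
  if (any(!is.na(value))) {
    rng <- range(value, na.rm = TRUE)
    if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12)
      stop("ratio values must lie in [0, 1]")
  }
  structure(list(value = value, support = support, index = index),
            class = "ratio_track")
}

#' @export
print.ratio_track <- function(x, ...) {
  cat(sprintf("<ratio_track> %d bins, %d non-missing, mean %.4f\n",
              length(x$value), sum(!is.na(x$value)),
              mean(x$value, na.rm = TRUE)))
  invisible(x)
}

#' Per-bin signal track
#'
#' A plain per-bin numeric signal (e.g. averaged fold-change over control, or
#' log expression); `NA` marks bins without signal.
#'
#' @param value numeric vector of length `n_bins(index)`.
#' @param index a [bin_index()].
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(value, index) {
  stopifnot(inherits(index, "bin_index"))
  if (length(value) != n_bins(index))
    stop("value length must equal n_bins(index)")
  structure(list(value = as.numeric(value), index = index),
            class = "signal_track")
}
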