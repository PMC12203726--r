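# Surface/core classification of bins within TADs at the q_k = n_k^(-1/3)
# quantile of intra-TAD ratio, boundary-region exclusion, and the
# shuffled-TAD null that preserves TAD-size and gap-size multisets.

#' Classify TAD bins into domain surface and core
#'
#' Within each TAD `k`, bins whose ratio is smaller than or equal to the
#' `q_k`-th empirical quantile (linear interpolation between order statistics)
#' of the TAD's non-missing ratios are labeled `surface`; the rest `core`.
#' `q_k = n_k^(-1/3)` with `n_k` the TAD's bin count, the surface-to-volume
#' scaling of a sphere. The inclusive rule means ties at the threshold all go
#' to the surface, so a TAD's surface is never empty when it has any
#' non-missing bin.
#'
#' @param track a [ratio_track()].
#' @param tads a [tad_set()] on the same [bin_index()].
#' @param tad_map optional precomputed [bin_tad_map()].
#' @return `data.table(bin, tad_id, value, label)` over TAD-assigned bins
#'   (`label` in surface/core, `NA` where the ratio is missing), with
#'   attribute `tad_summary`: `data.table(tad_id, n_k, q_k, threshold,
#'   n_surface, n_core)`.
#' @export
classify_surface_core <- function(track, tads, tad_map = NULL) {
  stopifnot(inherits(track, "ratio_track"))
  index <- track$index
  tad_map <- .as_tad_map(tads, index, tad_map)
  dt <- data.table(bin = seq_along(tad_map), row = tad_map)[!is.na(row)]
  dt[, tad_id := tads$tad_id[row]]
  dt[, value := track$value[bin]]
  dt[, n_k := .N, by = tad_id]
  dt[, q_k := n_k^(-1 / 3)]
  dt[, threshold := {
    v <- value[!is.na(value)]
    if (length(v)) quantile(v, q_k[1], type = 7, names = FALSE) else NA_real_
  }, by = tad_id]
  dt[, label := ifelse(is.na(value), NA_character_,
                       ifelse(value <= threshold, "surface", "core"))]
  summ <- dt[, .(n_k = .N, q_k = q_k[1], threshold = threshold[1],
                 n_surface = sum(label == "surface", na.rm = TRUE),
                 n_core = sum(label == "core", na.rm = TRUE)), by = tad_id]
  out <- dt[, .(bin, tad_id, value, label)]
  setattr(out, "tad_summary", summ)
  out
}

#' Exclude TAD boundary regions from surface/core labels
#'
#' Relabels as excluded (`NA`) the first and last bin of each TAD plus the
#' adjacent `ceiling(fraction * n_k)` bins on each flank, removing the
#' 1D-boundary neighborhood whose low ratios are a boundary effect rather
#' than a 3D-surface one.
#'
#' @param labels output of [classify_surface_core()].
#' @param fraction fraction of each TAD's bin count excluded per flank on top
#'   of the terminal bins (default 0.10).
#' @return the labels table with boundary-region labels set to `NA`; the
#'   `tad_summary` attribute is recomputed.
#' @export
exclude_boundaries <- function(labels, fraction = 0.10) {
  dt <- copy(as.data.table(labels))
  dt[, n_k := .N, by = tad_id]
  setorder(dt, tad_id, bin)
  dt[, pos := seq_len(.N), by = tad_id]
  dt[, m := ceiling(fraction * n_k)]
  dt[pos <= 1L + m | pos > n_k - 1L - m, label := NA_character_]
  summ <- dt[, .(n_k = n_k[1],
                 n_surface = sum(label == "surface", na.rm = TRUE),
                 n_core = sum(label == "core", na.rm = TRUE),
                 n_excluded = sum(is.na(label))), by = tad_id]
  out <- dt[, .(bin, tad_id, value, label)]
  setattr(out, "tad_summary", summ)
  out
}

#' Shuffled-TAD null: permute the interleaved TAD/gap length list
#'
#' Per chromosome, the ordered, interleaved list of TAD lengths and gap
#' lengths (including a leading gap when the first TAD does not start at 0)
#' is randomly permuted — TAD lengths among the TAD slots and gap lengths
#' among the gap slots, keeping the interleaving pattern — and laid down from
#' the chromosome start. Keeping each length in a slot of its own kind is
#' what makes the conservation exact: the realized genome preserves the
#' multiset of TAD sizes, the multiset of inter-TAD gap sizes, and the total
#' span, whereas a free permutation of the tagged list would let adjacent
#' gaps merge and trailing gaps vanish.
#'
#' @param tads a [tad_set()].
#' @param seed integer RNG seed.
#' @return a [tad_set()] with the same `tad_id`s attached to the permuted
#'   lengths.
#' @export
shuffle_tads <- function(tads, seed) {
  set.seed(as.integer(seed))
  td <- as.data.table(tads)
  setorder(td, chrom, start)
  out <- td[, {
    lens <- end - start
    gaps <- c(start[1], start[-1] - end[-.N])
    perm <- sample(.N)
    gperm <- sample(length(gaps))
    new_lens <- lens[perm]
    new_gaps <- gaps[gperm]
    starts <- cumsum(new_gaps + c(0, head(new_lens, -1L)))
    .(start = starts, end = starts + new_lens, tad_id = tad_id[perm])
  }, by = chrom]
  tad_set(out)
}
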