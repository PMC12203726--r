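# Intra-TAD ratio computation from the five data modalities.
#
# The per-cluster statistic for a TAD-assigned bin i in multiplex cluster j is
#   r_ij = N_ij / (C_j - 1)
# where N_ij counts cluster members sharing bin i's TAD and C_j is the number
# of unique bins in the cluster. A bin's intra-TAD ratio r_i is the unweighted
# mean of its r_ij over all clusters containing it. Members without a TAD
# assignment are genuine parts of the molecular complex: they stay in C_j but
# never contribute to N_ij and get no record themselves.

.as_tad_map <- function(tads, index, tad_map = NULL) {
  if (is.null(tad_map)) bin_tad_map(tads, index) else tad_map
}

#' Per-cluster intra-TAD ratios
#'
#' Computes `r_ij = N_ij / (C_j - 1)` for every TAD-assigned bin of one
#' multiplex cluster.
#'
#' @param bins integer vector of unique bin ids forming the cluster (size >= 2).
#' @param tad_map per-bin TAD assignment from [bin_tad_map()].
#' @return `data.table` with one row per TAD-assigned member: `bin`,
#'   `n_intra` (N_ij), `cluster_size` (C_j), `ratio` (r_ij).
#' @export
cluster_ratios <- function(bins, tad_map) {
  bins <- unique(as.integer(bins))
  C <- length(bins)
  if (C < 2) stop("cluster must contain at least 2 unique bins")
  tad <- tad_map[bins]
  keep <- !is.na(tad)
  if (!any(keep))
    return(data.table(bin = integer(), n_intra = integer(),
                      cluster_size = integer(), ratio = numeric()))
  cnt <- table(tad[keep])
  n_intra <- as.integer(cnt[as.character(tad[keep])]) - 1L
  data.table(bin = bins[keep], n_intra = n_intra, cluster_size = C,
             ratio = n_intra / (C - 1))
}

#' Intra-TAD ratio track from SPRITE clusters
#'
#' Averages `r_ij` over all clusters containing each bin (one cluster, one
#' vote). Bins supported by fewer than `min_bin_support` clusters are set
#' missing. In `mode = "intrachrom"` each cluster is first partitioned into
#' per-chromosome sub-clusters, `C_j` is re-derived per sub-cluster, and
#' sub-clusters collapsing below 2 bins are dropped. With
#' `exclude_adjacent = TRUE`, cluster members lying in the two TADs 1D-adjacent
#' to bin i's TAD are removed from both `N_ij` and the `C_j - 1` denominator,
#' which isolates the ratio from interactions that merely cross one boundary.
#'
#' @param clusters list of integer bin-id vectors (unique bins per cluster,
#'   e.g. `read_sprite(...)$clusters` or [gen_sprite()]).
#' @param tads a [tad_set()].
#' @param index a [bin_index()].
#' @param min_bin_support minimum number of supporting clusters per bin
#'   (default 100).
#' @param mode `"genomewide"` (default; clusters used as-is, trans members
#'   included) or `"intrachrom"`.
#' @param exclude_adjacent drop members in 1D-adjacent TADs (default FALSE).
#' @param tad_map optional precomputed [bin_tad_map()].
#' @return a [ratio_track()].
#' @export
sprite_ratio <- function(clusters, tads, index, min_bin_support = 100L,
                         mode = c("genomewide", "intrachrom"),
                         exclude_adjacent = FALSE, tad_map = NULL) {
  mode <- match.arg(mode)
  if (!length(clusters)) stop("empty cluster list")
  tad_map <- .as_tad_map(tads, index, tad_map)
  dt <- data.table(cid = rep(seq_along(clusters), lengths(clusters)),
                   bin = as.integer(unlist(clusters, use.names = FALSE)))
  if (mode == "intrachrom") {
    bt_chrom <- bin_table(index)$chrom
    dt[, cid := paste0(cid, "|", bt_chrom[bin])]
  }
  dt[, C := .N, by = cid]
  dt <- dt[C >= 2L]
  dt[, tad := tad_map[bin]]
  asg <- dt[!is.na(tad)]
  if (!nrow(asg)) stop("no cluster member falls inside a TAD")
  asg[, nt := .N, by = .(cid, tad)]
  if (exclude_adjacent) {
    adj <- .tad_adjacency(tads)
    cnt <- asg[, .N, by = .(cid, tad)]
    prev_cnt <- cnt[, .(cid, tad = adj$nxt[tad], A1 = N)][!is.na(tad)]
    next_cnt <- cnt[, .(cid, tad = adj$prv[tad], A2 = N)][!is.na(tad)]
    asg <- merge(asg, prev_cnt, by = c("cid", "tad"), all.x = TRUE)
    asg <- merge(asg, next_cnt, by = c("cid", "tad"), all.x = TRUE)
    asg[is.na(A1), A1 := 0L][is.na(A2), A2 := 0L]
    asg[, denom := C - 1L - A1 - A2]
    asg <- asg[denom >= 1L]
    asg[, r := (nt - 1L) / denom]
  } else {
    asg[, r := (nt - 1L) / (C - 1L)]
  }
  agg <- asg[, .(s = sum(r), n = .N), by = bin]
  value <- rep(NA_real_, n_bins(index)); support <- integer(n_bins(index))
  value[agg$bin] <- agg$s / agg$n
  support[agg$bin] <- agg$n
  value[support < min_bin_support] <- NA_real_
  support[is.na(value)] <- 0L
  ratio_track(value, support, index)
}

# prv/nxt TAD row neighbours along each chromosome (1D adjacency)
.tad_adjacency <- function(tads) {
  td <- as.data.table(tads)[, row := .I]
  setorder(td, chrom, start)
  td[, `:=`(p = shift(row), n = shift(row, type = "lead")), by = chrom]
  prv <- rep(NA_integer_, nrow(td)); nxt <- rep(NA_integer_, nrow(td))
  prv[td$row] <- td$p; nxt[td$row] <- td$n
  list(prv = prv, nxt = nxt)
}

#' Intra-TAD ratio track from accumulated pairwise contacts
#'
#' For each TAD-assigned bin, the ratio of contact weight to same-TAD partners
#' over total contact weight involving the bin. Self-pairs are excluded from
#' both numerator and denominator; partners without a TAD assignment count in
#' the denominator only. By default only intra-chromosomal contacts enter the
#' denominator (`include_trans = TRUE` adds inter-chromosomal ones).
#'
#' @param contacts `data.table(bin1, bin2, weight)` with accumulated unordered
#'   pairs (see [read_contacts_coo()] or [gen_contacts()]).
#' @param tads a [tad_set()].
#' @param index a [bin_index()].
#' @param include_trans include inter-chromosomal contacts in the denominator.
#' @param tad_map optional precomputed [bin_tad_map()].
#' @return a [ratio_track()]; support counts distinct contact records.
#' @export
contact_ratio <- function(contacts, tads, index, include_trans = FALSE,
                          tad_map = NULL) {
  tad_map <- .as_tad_map(tads, index, tad_map)
  dt <- as.data.table(contacts)
  long <- rbind(dt[, .(bin = bin1, other = bin2, w = weight)],
                dt[bin1 != bin2, .(bin = bin2, other = bin1, w = weight)])
  long <- long[bin != other & w > 0]
  if (!include_trans) {
    chrom <- bin_table(index)$chrom
    long <- long[chrom[bin] == chrom[other]]
  }
  long[, t1 := tad_map[bin]]
  long <- long[!is.na(t1)]
  long[, t2 := tad_map[other]]
  agg <- long[, .(num = sum(w[!is.na(t2) & t2 == t1]), den = sum(w), n = .N),
              by = bin]
  agg <- agg[den > 0]
  value <- rep(NA_real_, n_bins(index)); support <- integer(n_bins(index))
  value[agg$bin] <- agg$num / agg$den
  support[agg$bin] <- agg$n
  ratio_track(value, support, index)
}

#' Per-cell and cell-averaged intra-TAD ratio from single-cell contacts
#'
#' Applies [contact_ratio()] to each cell's contact list, then averages per
#' bin over the cells where the bin is observed; support is the number of
#' contributing cells.
#'
#' @param cell_contacts list of per-cell contact `data.table`s
#'   (see [read_pairs()] or [gen_pairs()]).
#' @inheritParams contact_ratio
#' @return list with `per_cell` (list of [ratio_track()]) and `average`
#'   (a [ratio_track()]).
#' @export
pairs_ratio <- function(cell_contacts, tads, index, include_trans = FALSE,
                        tad_map = NULL) {
  tad_map <- .as_tad_map(tads, index, tad_map)
  per_cell <- lapply(cell_contacts, contact_ratio, tads = tads, index = index,
                     include_trans = include_trans, tad_map = tad_map)
  vals <- vapply(per_cell, function(t) t$value, numeric(n_bins(index)))
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = length(per_cell))
  n_obs <- rowSums(!is.na(vals))
  avg <- ifelse(n_obs > 0, rowMeans(vals, na.rm = TRUE), NA_real_)
  list(per_cell = per_cell,
       average = ratio_track(avg, as.integer(n_obs), index))
}

#' Intra-TAD ratio from 3D structural models
#'
#' For every positioned bin of a model, finds its `k` Euclidean nearest
#' neighbors among all positioned bins of that model and takes the fraction
#' belonging to the same TAD (and, when `haplotype_aware`, the same
#' chromosome haplotype). Ties at the k-th distance are broken by ascending
#' bin id. Ratios are averaged per bin over all models supplied; models with
#' fewer than `k + 1` points are skipped with a warning.
#'
#' @param structures a `structure_table` (see [read_structure()]) or a list of
#'   them, one per model/cell.
#' @param tads a [tad_set()].
#' @param index a [bin_index()] at the structures' resolution.
#' @param k nearest-neighbor count (default 10).
#' @param haplotype_aware require same haplotype for intra-TAD neighbors
#'   (default TRUE; rows with `NA` haplotype are all treated as one haplotype).
#' @param split_to optional finer [bin_index()]; each parent bin's averaged
#'   ratio is duplicated onto the child bins it contains.
#' @param tad_map optional precomputed [bin_tad_map()].
#' @return a [ratio_track()] on `index` (or on `split_to` when given);
#'   support counts contributing model points.
#' @export
structure_ratio <- function(structures, tads, index, k = 10L,
                            haplotype_aware = TRUE, split_to = NULL,
                            tad_map = NULL) {
  if (is.data.frame(structures)) structures <- list(structures)
  tad_map <- .as_tad_map(tads, index, tad_map)
  nb <- n_bins(index)
  ssum <- numeric(nb); scnt <- integer(nb)
  n_skipped <- 0L
  for (st in structures) {
    st <- as.data.table(st)
    st <- st[is.finite(x) & is.finite(y) & is.finite(z)]
    n <- nrow(st)
    if (n < k + 1L) { n_skipped <- n_skipped + 1L; next }
    r <- .knn_intra_fraction(as.matrix(st[, .(x, y, z)]), st$bin,
                             if (haplotype_aware) st$hap else rep("", n),
                             tad_map, k)
    ok <- !is.na(r)
    if (any(ok)) {
      b <- st$bin[ok]
      ssum[b] <- ssum[b] + r[ok]
      scnt[b] <- scnt[b] + 1L
    }
  }
  if (n_skipped > 0)
    warning(n_skipped, " model(s) with fewer than k+1 points skipped")
  value <- ifelse(scnt > 0, ssum / pmax(scnt, 1L), NA_real_)
  track <- ratio_track(value, scnt, index)
  if (!is.null(split_to)) track <- split_track(track, split_to)
  track
}

# fraction of the k nearest neighbors sharing TAD (and haplotype tag) with
# each point; NA for points without TAD assignment
.knn_intra_fraction <- function(X, bins, haps, tad_map, k) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  tad <- tad_map[bins]
  haps[is.na(haps)] <- ""
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(tad[i])) next
    ord <- order(D[i, ], bins, method = "radix")
    ord <- ord[ord != i][seq_len(k)]
    out[i] <- sum(tad[ord] == tad[i] & haps[ord] == haps[i], na.rm = TRUE) / k
  }
  out
}

#' Duplicate a coarse ratio track onto a finer bin index
#'
#' Every child bin whose start falls inside a parent bin inherits the parent's
#' value (e.g. a 20 kb model bin split into two virtual 10 kb bins).
#'
#' @param track a [ratio_track()] on a coarse index.
#' @param fine_index a [bin_index()] with the same chromosomes and a bin size
#'   dividing the coarse one.
#' @return a [ratio_track()] on `fine_index`.
#' @export
split_track <- function(track, fine_index) {
  stopifnot(inherits(track, "ratio_track"), inherits(fine_index, "bin_index"))
  coarse <- track$index
  ft <- bin_table(fine_index)
  parent <- assign_bin(coarse, ft$chrom, ft$start)
  ratio_track(track$value[parent], track$support[parent], fine_index)
}

#' Per-cell intra-scDomain ratio from imaging coordinates
#'
#' For each imaged bin of each cell, the neighborhood is the set of other
#' imaged bins within `radius` (nm) of its coordinates; the intra-scDomain
#' ratio is the fraction of the neighborhood sharing the bin's single-cell
#' domain. Bins with missing coordinates or an empty neighborhood are missing.
#'
#' @param imaging `data.table(cell_id, bin, x, y, z)` (see [read_imaging()]).
#' @param segmentation `data.table(cell_id, bin, domain)` per-cell scDomain
#'   labels (see [call_scdomains()] or [gen_structures()]).
#' @param index a [bin_index()] at the imaging resolution.
#' @param radius neighborhood radius in nanometers (default 500).
#' @return `data.table(cell_id, bin, value, n_neighbors)` of class
#'   `cell_tracks`.
#' @export
imaging_ratio <- function(imaging, segmentation, index, radius = 500) {
  img <- merge(as.data.table(imaging),
               as.data.table(segmentation)[, .(cell_id, bin, domain)],
               by = c("cell_id", "bin"))
  img <- img[is.finite(x) & is.finite(y) & is.finite(z) & !is.na(domain)]
  res <- img[, .process_cell_imaging(.SD, radius), by = cell_id]
  setattr(res, "class", c("cell_tracks", class(res)))
  res[]
}

.process_cell_imaging <- function(sd, radius) {
  n <- nrow(sd)
  if (n < 2) return(data.table(bin = sd$bin, value = NA_real_, n_neighbors = 0L))
  D <- as.matrix(stats::dist(as.matrix(sd[, .(x, y, z)])))
  diag(D) <- Inf
  inr <- D <= radius
  nn <- rowSums(inr)
  same <- outer(sd$domain, sd$domain, "==")
  val <- ifelse(nn > 0, rowSums(inr & same) / nn, NA_real_)
  data.table(bin = sd$bin, value = val, n_neighbors = as.integer(nn))
}

#' Average per-cell tracks into one ratio track
#'
#' @param cell_tracks a `cell_tracks` table (e.g. from [imaging_ratio()]).
#' @param index the [bin_index()] the bins live on.
#' @return a [ratio_track()]; support = number of cells with a value.
#' @export
average_cell_tracks <- function(cell_tracks, index) {
  agg <- as.data.table(cell_tracks)[!is.na(value),
                                    .(v = mean(value), n = .N), by = bin]
  value <- rep(NA_real_, n_bins(index)); support <- integer(n_bins(index))
  value[agg$bin] <- agg$v; support[agg$bin] <- agg$n
  ratio_track(value, support, index)
}

#' Correlation of cell-subsampled averages with a reference track
#'
#' Each repeat draws `x` cells without replacement, averages the per-cell
#' ratios over the drawn cells (per bin, over non-missing cells), and
#' correlates the average with the reference over jointly non-missing bins.
#' With a fixed seed the whole distribution is reproducible.
#'
#' @param cell_tracks a `cell_tracks` table (`cell_id`, `bin`, `value`).
#' @param reference a [ratio_track()] on the same bins.
#' @param x cells per draw.
#' @param repeats number of repeats (default 100).
#' @param seed integer RNG seed.
#' @return `data.table(rep, pearson, spearman, n_bins)`.
#' @export
subsample_correlation <- function(cell_tracks, reference, x, repeats = 100L,
                                  seed) {
  ct <- as.data.table(cell_tracks)[!is.na(value)]
  cells <- unique(ct$cell_id)
  if (x > length(cells)) stop("x exceeds the number of cells")
  nb <- n_bins(reference$index)
  set.seed(as.integer(seed))
  out <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    drawn <- sample(cells, x)
    agg <- ct[cell_id %in% drawn, .(v = mean(value)), by = bin]
    avg <- rep(NA_real_, nb); avg[agg$bin] <- agg$v
    ok <- !is.na(avg) & !is.na(reference$value)
    out[[r]] <- data.table(
      rep = r,
      pearson = cor(avg[ok], reference$value[ok]),
      spearman = cor(avg[ok], reference$value[ok], method = "spearman"),
      n_bins = sum(ok))
  }
  rbindlist(out)
}
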