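# Synthetic single-cell chromatin-domain simulator.
#
# The generator emulates the data model the analysis assumes: one chromosome
# tiled by consensus domains (TADs); per cell, domain 1D boundaries jittered
# around the consensus; per cell, each domain is a ball of radius
# domain_radius_scale * m^(1/3) nm (m = per-cell domain size in bins) whose
# center follows a momentum-smoothed 3D random walk with step length equal to
# the sum of adjacent radii; each bin's normalized radial position in its ball
# mixes a persistent per-bin target with fresh ball-uniform noise according to
# coreness_persistence. Ground-truth coreness is 1 minus the persistent
# normalized radius. Read-outs are sampled from the geometry: SPRITE-like
# clusters as spatially proximal bin sets, contacts as distance-thresholded
# pairs, expression with a stated negative dependence on coreness, features
# implanted on surface-tendency bins at a stated fold.
#
# All randomness flows from cfg$seed through fixed per-stage offsets
# (genome +1, structures +2, clusters +3, signals +5), so each artifact can
# be regenerated in isolation.

#' Simulation configuration
#'
#' Defaults describe a TAD-scale system: 20 domains of ~50 bins of 10 kb
#' (a 10 Mb chromosome of 500 kb domains), 500 cells, domain radius
#' ~370 nm for a 50-bin domain (100 nm x 50^(1/3)), SPRITE capture radius
#' 250 nm, contact (proximity-ligation) threshold 250 nm, per-cell domain
#' boundaries wobbling by ~1 bin around the consensus. At this scale the
#' 500 nm imaging neighborhood of [imaging_ratio()] is sub-domain sized,
#' as it is in chromatin-tracing data.
#'
#' @param n_domains number of consensus domains.
#' @param bins_per_domain mean domain size in bins.
#' @param dispersion coefficient of variation of domain sizes (0 = equal).
#' @param gap_bins inter-domain gap in bins (default 0).
#' @param n_cells number of cells.
#' @param bin_size bin width in bp.
#' @param domain_radius_scale nm of radius per cube-root bin.
#' @param boundary_jitter s.d. (bins) of the per-cell shift of each domain
#'   boundary.
#' @param coreness_persistence in `[0, 1]`; weight of a bin's persistent
#'   radial target versus fresh ball-uniform noise.
#' @param walk_momentum direction persistence of the domain-center walk.
#' @param cluster_radius nm; SPRITE-like capture radius around an anchor.
#' @param clusters_per_cell clusters sampled per cell.
#' @param contact_threshold nm; pairwise-contact distance threshold.
#' @param expression_effect slope of log-expression on coreness (negative:
#'   core genes are less expressed).
#' @param expression_intercept baseline log-expression.
#' @param noise_sd s.d. of expression noise.
#' @param gene_density fraction of TAD bins carrying a gene TSS.
#' @param feature_fold target surface enrichment fold of implanted features.
#' @param n_features number of implanted feature bins.
#' @param chrom_name name of the synthetic chromosome.
#' @param seed integer RNG seed (mandatory).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_domains = 20L, bins_per_domain = 50L,
                       dispersion = 0.1, gap_bins = 0L, n_cells = 500L,
                       bin_size = 10000L, domain_radius_scale = 100,
                       boundary_jitter = 1, coreness_persistence = 0.8,
                       walk_momentum = 0.6, cluster_radius = 250,
                       clusters_per_cell = 200L, contact_threshold = 250,
                       expression_effect = -2, expression_intercept = 3,
                       noise_sd = 1, gene_density = 0.4, feature_fold = 3,
                       n_features = 300L, chrom_name = "chrS", seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  num <- c("n_domains", "bins_per_domain", "n_cells", "bin_size",
           "domain_radius_scale", "cluster_radius", "clusters_per_cell",
           "contact_threshold", "gene_density", "feature_fold", "n_features")
  for (f in num) if (cfg[[f]] <= 0) stop(f, " must be positive")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (cfg$coreness_persistence < 0 || cfg$coreness_persistence > 1)
    stop("coreness_persistence must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' Generate the synthetic genome: bin index and consensus TADs
#'
#' One chromosome tiled by `n_domains` domains with sizes drawn around
#' `bins_per_domain` (normal, CV = `dispersion`, minimum 10 bins), separated
#' by `gap_bins` gaps.
#'
#' @param cfg a [sim_config()].
#' @return list with `index` ([bin_index()]), `tads` ([tad_set()]) and
#'   `domain_bins` (integer domain sizes in bins).
#' @export
gen_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(cfg$seed) + 1L)
  sizes <- pmax(10L, as.integer(round(
    rnorm(cfg$n_domains, cfg$bins_per_domain,
          cfg$bins_per_domain * cfg$dispersion))))
  gap <- as.integer(cfg$gap_bins)
  starts_bins <- cumsum(c(0L, head(sizes, -1L) + gap))
  total_bins <- starts_bins[length(starts_bins)] + sizes[length(sizes)]
  chrom_len <- as.numeric(total_bins) * cfg$bin_size
  index <- bin_index(setNames(chrom_len, cfg$chrom_name), cfg$bin_size)
  tads <- tad_set(data.table(
    chrom = cfg$chrom_name,
    start = as.numeric(starts_bins) * cfg$bin_size,
    end = as.numeric(starts_bins + sizes) * cfg$bin_size,
    tad_id = sprintf("D%02d", seq_along(sizes))))
  list(index = index, tads = tads, domain_bins = sizes)
}

#' Generate per-cell 3D structures, segmentations and ground-truth coreness
#'
#' @param cfg a [sim_config()].
#' @param genome output of [gen_genome()].
#' @return list with `cells` (`data.table(cell_id, bin, x, y, z, domain)`,
#'   nm), `segmentation` (`data.table(cell_id, bin, domain)`), `tendency`
#'   (numeric per bin: ground-truth coreness in `[0, 1]`), and
#'   `radial_target` (the persistent normalized radius, `1 - tendency`).
#' @export
gen_structures <- function(cfg, genome) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(cfg$seed) + 2L)
  index <- genome$index
  nb <- n_bins(index)
  sizes <- genome$domain_bins
  map <- bin_tad_map(genome$tads, index)
  # persistent radial target: ball-uniform marginal so a single cell is a
  # uniform ball in the persistence-1 limit
  radial_target <- runif(nb)^(1 / 3)
  tendency <- 1 - radial_target
  tendency[is.na(map)] <- NA_real_
  dom_of_bin <- map
  p <- cfg$coreness_persistence
  out <- vector("list", cfg$n_cells)
  for (ci in seq_len(cfg$n_cells)) {
    dom <- .jitter_domains(dom_of_bin, cfg$boundary_jitter)
    keep <- !is.na(dom)
    m <- tabulate(dom[keep], nbins = length(sizes))
    radii <- cfg$domain_radius_scale * pmax(m, 1L)^(1 / 3)
    centers <- .center_walk(radii, cfg$walk_momentum)
    bins <- which(keep)
    rho <- p * radial_target[bins] + (1 - p) * runif(length(bins))^(1 / 3)
    rho <- pmin(pmax(rho, 0), 1)
    dirs <- .unit_sphere(length(bins))
    d <- dom[bins]
    xyz <- centers[d, , drop = FALSE] + dirs * (rho * radii[d])
    out[[ci]] <- data.table(cell_id = sprintf("cell%04d", ci), bin = bins,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            domain = d)
  }
  cells <- rbindlist(out)
  list(cells = cells,
       segmentation = cells[, .(cell_id, bin, domain)],
       tendency = tendency, radial_target = radial_target)
}

# shift each internal consensus boundary by a discretized normal amount,
# keeping boundaries strictly increasing; returns per-bin domain ids (NA
# outside all domains keeps NA membership of gap bins)
.jitter_domains <- function(dom_of_bin, jitter) {
  if (jitter <= 0) return(dom_of_bin)
  nb <- length(dom_of_bin)
  runs <- rle(ifelse(is.na(dom_of_bin), 0L, dom_of_bin))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  is_dom <- runs$values > 0L
  # jitter the borders between consecutive domain runs (contiguous domains)
  for (k in which(is_dom[-length(is_dom)] & is_dom[-1])) {
    shift <- as.integer(round(rnorm(1, 0, jitter)))
    b <- ends[k] + shift
    b <- min(max(b, starts[k] + 1L), ends[k + 1L] - 1L)
    ends[k] <- b
    starts[k + 1L] <- b + 1L
  }
  out <- rep(NA_integer_, nb)
  for (k in which(is_dom)) out[starts[k]:ends[k]] <- runs$values[k]
  out
}

# momentum-smoothed 3D random walk of domain centers; step length is the sum
# of adjacent radii so consecutive balls touch
.center_walk <- function(radii, momentum) {
  nd <- length(radii)
  centers <- matrix(0, nd, 3)
  dir <- .unit_sphere(1)[1, ]
  for (k in seq_len(nd)[-1]) {
    dir <- momentum * dir + (1 - momentum) * .unit_sphere(1)[1, ]
    dir <- dir / sqrt(sum(dir^2))
    centers[k, ] <- centers[k - 1, ] + dir * (radii[k - 1] + radii[k])
  }
  centers
}

.unit_sphere <- function(n) {
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

#' Sample SPRITE-like multiplex clusters from the structures
#'
#' Each cluster picks a random cell and a random anchor bin, collects the
#' bins of that cell within `cluster_radius` of the anchor, and subsamples
#' them to a log-uniform target size in `[2, 1000]`. Anchors whose
#' neighborhood holds fewer than 2 bins are discarded.
#'
#' @param cfg a [sim_config()].
#' @param structures output of [gen_structures()].
#' @return list of integer bin-id vectors (one cluster each).
#' @export
gen_sprite <- function(cfg, structures) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(cfg$seed) + 3L)
  r2 <- cfg$cluster_radius^2
  cells <- split(structures$cells, by = "cell_id", keep.by = FALSE)
  clusters <- vector("list", length(cells) * cfg$clusters_per_cell)
  ci <- 0L
  for (cell in cells) {
    X <- as.matrix(cell[, .(x, y, z)])
    n <- nrow(X)
    anchors <- sample.int(n, cfg$clusters_per_cell, replace = TRUE)
    targets <- round(exp(runif(cfg$clusters_per_cell, log(2), log(1000))))
    A <- X[anchors, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(X^2), "+") - 2 * tcrossprod(A, X)
    for (j in seq_along(anchors)) {
      members <- which(d2[j, ] <= r2)
      if (length(members) < 2L) next
      size <- min(targets[j], length(members))
      if (size < 2L) next
      ci <- ci + 1L
      clusters[[ci]] <- cell$bin[sample(members, size)]
    }
  }
  clusters[seq_len(ci)]
}

#' Distance-thresholded pairwise contacts from the structures
#'
#' All bin pairs of a cell within `contact_threshold` nm become contacts;
#' `gen_contacts` accumulates them over cells into a bulk contact table,
#' `gen_pairs` keeps them per cell.
#'
#' @param cfg a [sim_config()].
#' @param structures output of [gen_structures()].
#' @return `gen_contacts`: `data.table(bin1, bin2, weight)`;
#'   `gen_pairs`: named list of such tables, one per cell.
#' @export
gen_contacts <- function(cfg, structures) {
  agg <- rbindlist(gen_pairs(cfg, structures))
  agg[, .(weight = sum(weight)), by = .(bin1, bin2)]
}

#' @rdname gen_contacts
#' @param cell_ids optional subset of cells.
#' @export
gen_pairs <- function(cfg, structures, cell_ids = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  cells <- split(structures$cells, by = "cell_id", keep.by = FALSE)
  if (!is.null(cell_ids)) cells <- cells[cell_ids]
  thr <- cfg$contact_threshold
  lapply(cells, function(cell) {
    if (nrow(cell) < 2 || thr <= 0)
      return(data.table(bin1 = integer(), bin2 = integer(), weight = numeric()))
    D <- as.matrix(stats::dist(as.matrix(cell[, .(x, y, z)])))
    hit <- which(D <= thr & upper.tri(D), arr.ind = TRUE)
    if (!nrow(hit))
      return(data.table(bin1 = integer(), bin2 = integer(), weight = numeric()))
    b1 <- cell$bin[hit[, 1]]; b2 <- cell$bin[hit[, 2]]
    data.table(bin1 = pmin(b1, b2), bin2 = pmax(b1, b2),
               weight = 1)[, .(weight = sum(weight)), by = .(bin1, bin2)]
  })
}

#' Generate expression and implanted feature tracks
#'
#' Log-expression at gene bins is
#' `intercept + expression_effect * coreness + Normal(0, noise_sd)`; with a
#' negative effect, core bins are less expressed. Features are implanted so
#' that the expected measured surface enrichment fold equals `feature_fold`:
#' each feature bin lands on the truth-surface set (bins whose coreness lies
#' at or below the `n_k^(-1/3)` within-domain quantile) with probability
#' `feature_fold * b / a` and uniformly otherwise.
#'
#' @param cfg a [sim_config()].
#' @param genome output of [gen_genome()].
#' @param tendency per-bin ground-truth coreness (from [gen_structures()]).
#' @return list with `expression` ([signal_track()], `NA` off gene bins),
#'   `gene_bins`, `features` (an `interval_set`), `feature_bins`, and
#'   `surface_truth` (integer bin ids of the truth-surface set).
#' @export
gen_signals <- function(cfg, genome, tendency) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(cfg$seed) + 5L)
  index <- genome$index
  map <- bin_tad_map(genome$tads, index)
  tad_bins <- which(!is.na(map))
  gene_bins <- sort(sample(tad_bins, round(cfg$gene_density * length(tad_bins))))
  expr <- rep(NA_real_, n_bins(index))
  expr[gene_bins] <- cfg$expression_intercept +
    cfg$expression_effect * tendency[gene_bins] +
    rnorm(length(gene_bins), 0, cfg$noise_sd)
  # truth-surface set: per domain, coreness <= its n_k^(-1/3) quantile
  surf <- unlist(lapply(split(tad_bins, map[tad_bins]), function(b) {
    q <- length(b)^(-1 / 3)
    thr <- quantile(tendency[b], q, type = 7, names = FALSE)
    b[tendency[b] <= thr]
  }), use.names = FALSE)
  a <- length(tad_bins); b <- length(surf)
  p_surf <- cfg$feature_fold * b / a
  if (p_surf > 1) {
    warning("feature_fold too high for the surface fraction; capping")
    p_surf <- 1
  }
  n_surf_feat <- min(rbinom(1, cfg$n_features, p_surf), b)
  core_pool <- setdiff(tad_bins, surf)
  n_core_feat <- min(cfg$n_features - n_surf_feat, length(core_pool))
  feature_bins <- sort(c(sample(surf, n_surf_feat),
                         sample(core_pool, n_core_feat)))
  bt <- bin_table(index)
  features <- bt[feature_bins, .(chrom, start, end)][, label := "implanted"]
  setattr(features, "class", c("interval_set", class(features)))
  list(expression = signal_track(expr, index), gene_bins = gene_bins,
       features = features[], feature_bins = feature_bins,
       surface_truth = sort(surf))
}
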