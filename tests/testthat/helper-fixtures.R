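# Shared fixtures. The full-scale simulation used by the acceptance tests is
# generated once and cached for the whole run.

library(data.table)

# tiny coordinate frame: one 1 Mb chromosome of 10 kb bins
toy_index <- function(len = 1e6, bin_size = 1e4, chrom = "chrS") {
  bin_index(setNames(len, chrom), bin_size)
}

toy_tads <- function(bounds_kb = c(0, 300, 600, 1000), chrom = "chrS") {
  n <- length(bounds_kb) - 1
  tad_set(data.table(chrom = chrom, start = bounds_kb[-length(bounds_kb)] * 1e3,
                     end = bounds_kb[-1] * 1e3, tad_id = paste0("T", seq_len(n))))
}

# small simulation for module tests (fast; ~6 domains, 30 cells)
small_sim <- function(seed = 11, n_cells = 30L, ...) {
  cfg <- sim_config(seed = seed, n_domains = 6L, bins_per_domain = 25L,
                    n_cells = n_cells, clusters_per_cell = 60L, ...)
  genome <- gen_genome(cfg)
  structures <- gen_structures(cfg, genome)
  list(cfg = cfg, genome = genome, structures = structures,
       map = bin_tad_map(genome$tads, genome$index),
       truth = structures$tendency)
}

.accept_cache <- new.env(parent = emptyenv())

# full default-scale study (20 domains x ~50 bins, 500 cells), cached
acceptance_sim <- function() {
  if (!is.null(.accept_cache$sim)) return(.accept_cache$sim)
  cfg <- sim_config(seed = 7)
  genome <- gen_genome(cfg)
  structures <- gen_structures(cfg, genome)
  map <- bin_tad_map(genome$tads, genome$index)
  .accept_cache$sim <- list(cfg = cfg, genome = genome,
                            structures = structures, map = map,
                            truth = structures$tendency)
  .accept_cache$sim
}

acceptance_sprite_track <- function() {
  if (!is.null(.accept_cache$sprite)) return(.accept_cache$sprite)
  sim <- acceptance_sim()
  clusters <- gen_sprite(sim$cfg, sim$structures)
  .accept_cache$sprite <- sprite_ratio(clusters, sim$genome$tads,
                                       sim$genome$index, tad_map = sim$map)
  .accept_cache$sprite
}

acceptance_contacts <- function() {
  if (!is.null(.accept_cache$contacts)) return(.accept_cache$contacts)
  sim <- acceptance_sim()
  .accept_cache$contacts <- gen_contacts(sim$cfg, sim$structures)
  .accept_cache$contacts
}

# brute-force oracle for r_ij: enumerate all unordered member pairs
brute_cluster_ratios <- function(bins, tad_map) {
  bins <- unique(as.integer(bins))
  C <- length(bins)
  res <- list()
  for (b in bins) {
    t <- tad_map[b]
    if (is.na(t)) next
    n_intra <- 0L
    for (o in setdiff(bins, b))
      if (!is.na(tad_map[o]) && tad_map[o] == t) n_intra <- n_intra + 1L
    res[[length(res) + 1L]] <- data.table(bin = b, n_intra = n_intra,
                                          cluster_size = C,
                                          ratio = n_intra / (C - 1))
  }
  if (!length(res)) return(data.table(bin = integer(), n_intra = integer(),
                                      cluster_size = integer(),
                                      ratio = numeric()))
  rbindlist(res)
}

# exhaustive enumeration oracle for the hypergeometric upper tail:
# all C(a, c) draws of c bins from a universe with b successes
enum_hyper_p <- function(a, b, c, d) {
  draws <- utils::combn(a, c)
  succ <- colSums(draws <= b)       # successes are items 1..b
  mean(succ >= d)
}

# independent convex-hull oracle: scipy.spatial.ConvexHull via python
scipy_hull_vertices <- function(X) {
  js <- jsonlite::toJSON(X)
  out <- system2("python", c("-c", shQuote(paste0(
    "import sys,json;import numpy as np;from scipy.spatial import ConvexHull;",
    "X=np.array(json.load(sys.stdin));",
    "print(json.dumps(sorted((ConvexHull(X).vertices+1).tolist())))"))),
    input = as.character(js), stdout = TRUE)
  as.integer(jsonlite::fromJSON(out))
}
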