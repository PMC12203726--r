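test_that("genome arithmetic and determinism hold", {
  cfg <- sim_config(seed = 1, dispersion = 0)
  g <- gen_genome(cfg)
  # 20 domains x 50 bins x 10 kb -> 10 Mb, 20 TADs
  expect_equal(unname(g$index$chrom_sizes), 1e7)
  expect_identical(nrow(g$tads), 20L)
  expect_true(all(g$domain_bins == 50L))
  expect_identical(gen_genome(cfg)$tads, g$tads)
  # dispersion creates unequal sizes but respects the floor
  g2 <- gen_genome(sim_config(seed = 1, dispersion = 0.3))
  expect_gt(length(unique(g2$domain_bins)), 1L)
  expect_true(all(g2$domain_bins >= 10L))
})

test_that("persistence limits behave as specified", {
  # a single large domain keeps the empirical centroid close to the true
  # center, so per-cell radii are a clean read-out of the radial draw
  radii_by_cell <- function(persistence, seed = 3) {
    cfg <- sim_config(seed = seed, n_domains = 1L, bins_per_domain = 200L,
                      n_cells = 8L, coreness_persistence = persistence)
    st <- gen_structures(cfg, gen_genome(cfg))
    rr <- st$cells[, {
      r <- sqrt((x - mean(x))^2 + (y - mean(y))^2 + (z - mean(z))^2)
      .(bin = bin, r = r)
    }, by = cell_id]
    as.matrix(dcast(rr, bin ~ cell_id, value.var = "r")[, -1])
  }
  pairwise_rho <- function(m) {
    cm <- cor(m, method = "spearman", use = "pairwise")
    cm[upper.tri(cm)]
  }
  # persistence 1: radial ranks repeat across cells
  expect_gt(min(pairwise_rho(radii_by_cell(1))), 0.9)
  # persistence 0: radial positions are independent across cells
  expect_lt(mean(abs(pairwise_rho(radii_by_cell(0)))), 0.2)
})

test_that("jitter 0 reproduces the consensus segmentation in every cell", {
  cfg <- sim_config(seed = 4, n_domains = 5L, bins_per_domain = 20L,
                    n_cells = 6L, boundary_jitter = 0)
  g <- gen_genome(cfg)
  st <- gen_structures(cfg, g)
  map <- bin_tad_map(g$tads, g$index)
  for (cid in unique(st$segmentation$cell_id)) {
    seg <- st$segmentation[cell_id == cid][order(bin)]
    expect_identical(seg$domain, unname(map[seg$bin]))
  }
})

test_that("cluster and contact read-outs respect their geometry knobs", {
  cfg <- sim_config(seed = 5, n_domains = 4L, bins_per_domain = 20L,
                    n_cells = 5L, clusters_per_cell = 40L)
  g <- gen_genome(cfg)
  st <- gen_structures(cfg, g)
  cl <- gen_sprite(cfg, st)
  expect_true(all(lengths(cl) >= 2))
  expect_identical(gen_sprite(cfg, st), cl)   # same seed, same clusters
  # capture radius below inter-domain spacing: clusters stay single-domain
  cfg_tight <- sim_config(seed = 5, n_domains = 4L, bins_per_domain = 20L,
                          n_cells = 5L, clusters_per_cell = 40L,
                          cluster_radius = 40)
  st_t <- gen_structures(cfg_tight, gen_genome(cfg_tight))
  cl_t <- gen_sprite(cfg_tight, st_t)
  map <- bin_tad_map(gen_genome(cfg_tight)$tads, gen_genome(cfg_tight)$index)
  single <- vapply(cl_t, function(b) length(unique(map[b])) == 1L, logical(1))
  expect_gt(mean(single), 0.9)
  # zero contact threshold -> no contacts
  cfg0 <- sim_config(seed = 5, n_domains = 4L, bins_per_domain = 20L,
                     n_cells = 3L)
  st0 <- gen_structures(cfg0, gen_genome(cfg0))
  cfg0$contact_threshold <- 0
  expect_identical(nrow(gen_contacts(cfg0, st0)), 0L)
})

test_that("expression tracks encode the stated coreness dependence", {
  cfg <- sim_config(seed = 6, n_domains = 6L, bins_per_domain = 30L,
                    n_cells = 2L, noise_sd = 0)
  g <- gen_genome(cfg)
  st <- gen_structures(cfg, g)
  sg <- gen_signals(cfg, g, st$tendency)
  # noise 0: expression is an exact affine map of coreness -> rho = -1 per TAD
  track <- ratio_track(st$tendency, as.integer(!is.na(st$tendency)), g$index)
  res <- per_tad_correlation(track, sg$expression, g$tads)
  expect_equal(res$correlations$rho, rep(-1, res$n_tads))
  # zero effect: no dependence (single large-sample check)
  cfg0 <- sim_config(seed = 6, n_domains = 6L, bins_per_domain = 30L,
                     n_cells = 2L, expression_effect = 0, gene_density = 1)
  sg0 <- gen_signals(cfg0, g, st$tendency)
  rho <- cor(st$tendency, sg0$expression$value, use = "pairwise",
             method = "spearman")
  expect_lt(abs(rho), 0.2)
})

test_that("feature implantation at fold 1 is calibrated to fold ~ 1", {
  cfg <- sim_config(seed = 7, n_domains = 6L, bins_per_domain = 30L,
                    n_cells = 2L, feature_fold = 1)
  g <- gen_genome(cfg)
  st <- gen_structures(cfg, g)
  map <- bin_tad_map(g$tads, g$index)
  folds <- vapply(1:20, function(i) {
    cfg_i <- cfg; cfg_i$seed <- cfg$seed + i
    sg <- gen_signals(cfg_i, g, st$tendency)
    enrichment(sg$feature_bins, which(!is.na(map)), sg$surface_truth)$fold
  }, numeric(1))
  expect_gt(mean(folds), 0.8)
  expect_lt(mean(folds), 1.25)
})

test_that("a written study re-reads losslessly", {
  d <- withr::local_tempdir()
  cfg <- sim_config(seed = 8, n_domains = 4L, bins_per_domain = 15L,
                    n_cells = 4L, clusters_per_cell = 30L,
                    feature_fold = 1, n_features = 20L)
  simulate_study(cfg, d, max_cell_files = 2, max_imaging_cells = 3)
  g <- gen_genome(cfg)
  st <- gen_structures(cfg, g)
  idx <- g$index
  expect_identical(read_tads(file.path(d, "tads.bed")), g$tads)
  cl <- gen_sprite(cfg, st)
  back <- read_sprite(file.path(d, "clusters.tsv"), idx, min_size = 2,
                      max_size = 1000)
  expect_identical(lapply(back$clusters, sort), lapply(cl, sort))
  ct <- gen_contacts(cfg, st)
  back_ct <- read_contacts_coo(file.path(d, "contacts.coo"), idx)
  expect_equal(back_ct[order(bin1, bin2)], ct[order(bin1, bin2)])
  pr <- gen_pairs(cfg, st, cell_ids = "cell0001")[[1]]
  back_pr <- read_pairs(file.path(d, "cells", "cell0001.pairs"), idx)[[1]]
  expect_equal(back_pr[order(bin1, bin2)], pr[order(bin1, bin2)])
  stru <- read_structure(file.path(d, "structures", "cell0001.tsv"), idx)
  cell1 <- st$cells[cell_id == "cell0001"]
  expect_identical(stru$bin, cell1$bin)
  expect_equal(stru$x, cell1$x, tolerance = 1e-6)
  img <- read_imaging(file.path(d, "imaging.csv"), idx)
  expect_identical(sort(unique(img$cell_id)), sprintf("cell%04d", 1:3))
  expr <- read_signal(file.path(d, "expression.bedgraph"), idx)
  sg <- gen_signals(cfg, g, st$tendency)
  expect_equal(expr$value, sg$expression$value)
  feats <- read_intervals(file.path(d, "features.bed"))
  expect_identical(nrow(feats), length(sg$feature_bins))
  expect_true(file.exists(file.path(d, "manifest.json")))
})
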