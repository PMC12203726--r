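test_that("cluster_ratios matches the spec examples", {
  idx <- toy_index(1e5)
  tads <- tad_set(data.table(chrom = "chrS", start = c(0, 50000),
                             end = c(50000, 100000), tad_id = c("T1", "T2")))
  map <- bin_tad_map(tads, idx)
  # b1-b3 in T1, b4 in T2
  cr <- cluster_ratios(c(1L, 2L, 3L, 6L), map)
  expect_equal(cr[bin == 1, ratio], 2 / 3)
  expect_equal(cr[bin == 6, ratio], 0)
  # entirely inside one TAD
  expect_true(all(cluster_ratios(1:4, map)$ratio == 1))
  # two bins in different TADs
  expect_true(all(cluster_ratios(c(1L, 6L), map)$ratio == 0))
  expect_error(cluster_ratios(5L, map), "at least 2")
  # unassigned members count in C_j but are not emitted
  map2 <- map; map2[3] <- NA
  cr2 <- cluster_ratios(c(1L, 2L, 3L), map2)
  expect_identical(nrow(cr2), 2L)
  expect_equal(cr2$ratio, c(0.5, 0.5))
})

test_that("cluster_ratios agrees with brute-force pair enumeration", {
  set.seed(42)
  nb <- 200
  for (i in 1:200) {
    map <- sample(c(NA, 1:8), nb, replace = TRUE)
    bins <- sample.int(nb, sample(2:30, 1))
    got <- cluster_ratios(bins, map)[order(bin)]
    want <- brute_cluster_ratios(bins, map)[order(bin)]
    expect_equal(got, want)
  }
})

test_that("same-TAD members never decrease the brute-force r_ij", {
  set.seed(43)
  for (i in 1:50) {
    map <- sample(1:4, 60, replace = TRUE)
    bins <- sample.int(60, sample(3:10, 1))
    b <- bins[1]
    extra <- setdiff(which(map == map[b]), bins)[1]
    if (is.na(extra)) next
    before <- brute_cluster_ratios(bins, map)[bin == b, ratio]
    after <- brute_cluster_ratios(c(bins, extra), map)[bin == b, ratio]
    expect_gte(after, before)
  }
})

test_that("sprite_ratio averages clusters and applies the support filter", {
  idx <- toy_index(1e5)
  tads <- tad_set(data.table(chrom = "chrS", start = c(0, 50000),
                             end = c(50000, 100000)))
  # bin 1 in two clusters: all-intra (r = 1) and fully-inter (r = 0)
  cl <- list(c(1L, 2L), c(1L, 6L))
  tr <- sprite_ratio(cl, tads, idx, min_bin_support = 1)
  expect_equal(tr$value[1], 0.5)
  expect_identical(tr$support[1], 2L)
  # one fewer supporting cluster than the threshold -> missing
  cl99 <- rep(list(c(1L, 2L)), 99)
  tr99 <- sprite_ratio(cl99, tads, idx, min_bin_support = 100)
  expect_true(is.na(tr99$value[1]))
  tr100 <- sprite_ratio(c(cl99, list(c(1L, 3L))), tads, idx,
                        min_bin_support = 100)
  expect_false(is.na(tr100$value[1]))
  expect_error(sprite_ratio(list(), tads, idx), "empty")
})

test_that("intrachrom mode partitions clusters by chromosome", {
  idx <- bin_index(c(A = 1e5, B = 1e5), 1e4)
  tads <- tad_set(data.table(chrom = c("A", "B"), start = 0, end = 1e5))
  # cluster mixes chromosomes: A sub-cluster {1,2}, B sub-cluster {11} (size
  # 1, dropped)
  cl <- list(c(1L, 2L, 11L))
  tr <- sprite_ratio(cl, tads, idx, min_bin_support = 1, mode = "intrachrom")
  expect_equal(tr$value[1:2], c(1, 1))   # C_j re-derived per sub-cluster
  expect_true(is.na(tr$value[11]))
  expect_identical(tr$support[11], 0L)
  # genomewide mode keeps the mixed denominator
  trg <- sprite_ratio(cl, tads, idx, min_bin_support = 1)
  expect_equal(trg$value[1], 0.5)
})

test_that("adjacent-TAD exclusion removes flanking TADs from both sides", {
  idx <- toy_index(1e5)
  tads <- tad_set(data.table(chrom = "chrS", start = c(0, 30000, 60000),
                             end = c(30000, 60000, 100000),
                             tad_id = c("T1", "T2", "T3")))
  # bins 1 (T1), 4,5 (T2), 7 (T3)
  cl <- list(c(1L, 4L, 5L, 7L))
  tr <- sprite_ratio(cl, tads, idx, min_bin_support = 1,
                     exclude_adjacent = TRUE)
  # bin 1: T2 members (2) removed; denominator 3-2 = 1; no same-TAD -> 0
  expect_equal(tr$value[1], 0)
  # bin 4: T1 and T3 members removed; denominator 3-2 = 1; one T2 partner
  expect_equal(tr$value[4], 1)
  # bin 7: T2 members removed; denominator 1; no partner in T3 -> 0
  expect_equal(tr$value[7], 0)
  # without exclusion, bin 4 sees 1 intra / 3
  tr0 <- sprite_ratio(cl, tads, idx, min_bin_support = 1)
  expect_equal(tr0$value[4], 1 / 3)
})

test_that("sprite support accounting is conserved", {
  sim <- small_sim()
  cl <- gen_sprite(sim$cfg, sim$structures)
  tr <- sprite_ratio(cl, sim$genome$tads, sim$genome$index,
                     min_bin_support = 1, tad_map = sim$map)
  assigned_members <- sum(vapply(cl, function(b)
    sum(!is.na(sim$map[b])), integer(1)))
  expect_identical(sum(tr$support), assigned_members)
  expect_true(all(tr$value >= 0 & tr$value <= 1, na.rm = TRUE))
})

test_that("contact_ratio follows the weighted-sum rule", {
  idx <- toy_index(1e5)
  tads <- tad_set(data.table(chrom = "chrS", start = c(0, 50000),
                             end = c(50000, 100000)))
  ct <- data.table(bin1 = c(1L, 1L), bin2 = c(2L, 6L), weight = c(3, 1))
  tr <- contact_ratio(ct, tads, idx)
  expect_equal(tr$value[1], 0.75)
  expect_equal(tr$value[2], 1)     # all partners same TAD
  expect_equal(tr$value[6], 0)
  # bin with only a self-contact is missing
  self_only <- data.table(bin1 = 3L, bin2 = 3L, weight = 5)
  expect_true(is.na(contact_ratio(self_only, tads, idx)$value[3]))
  # trans contacts enter the denominator only on request
  idx2 <- bin_index(c(A = 1e5, B = 1e5), 1e4)
  tads2 <- tad_set(data.table(chrom = c("A", "B"), start = 0, end = 1e5))
  ct2 <- data.table(bin1 = c(1L, 1L), bin2 = c(2L, 11L), weight = c(1, 1))
  expect_equal(contact_ratio(ct2, tads2, idx2)$value[1], 1)
  expect_equal(contact_ratio(ct2, tads2, idx2, include_trans = TRUE)$value[1], 0.5)
})

test_that("pairs_ratio averages cells over available values", {
  idx <- toy_index(1e5)
  tads <- tad_set(data.table(chrom = "chrS", start = c(0, 50000),
                             end = c(50000, 100000)))
  cells <- list(
    c1 = data.table(bin1 = 1L, bin2 = 2L, weight = 1),        # bin1 r = 1
    c2 = data.table(bin1 = 1L, bin2 = 6L, weight = 1),        # bin1 r = 0
    c3 = data.table(bin1 = 3L, bin2 = 4L, weight = 1))        # bin1 absent
  pr <- pairs_ratio(cells, tads, idx)
  expect_equal(pr$average$value[1], 0.5)
  expect_identical(pr$average$support[1], 2L)
  expect_equal(pr$average$value[3], 1)   # observed in one cell only
  expect_identical(pr$average$support[3], 1L)
  expect_true(is.na(pr$average$value[9]))
})

test_that("sprite_ratio on 2-bin clusters equals contact_ratio exactly", {
  sim <- small_sim()
  cl <- gen_sprite(sim$cfg, sim$structures)
  cl2 <- cl[lengths(cl) == 2L]
  expect_gt(length(cl2), 30)
  tr_sp <- sprite_ratio(cl2, sim$genome$tads, sim$genome$index,
                        min_bin_support = 1, tad_map = sim$map)
  induced <- rbindlist(lapply(cl2, function(b)
    data.table(bin1 = min(b), bin2 = max(b), weight = 1)))
  induced <- induced[, .(weight = sum(weight)), by = .(bin1, bin2)]
  tr_ct <- contact_ratio(induced, sim$genome$tads, sim$genome$index,
                         tad_map = sim$map)
  expect_identical(tr_sp$value, tr_ct$value)
})

test_that("structure_ratio separates well-separated domains and averages", {
  idx <- toy_index(3e5)
  tads <- tad_set(data.table(chrom = "chrS", start = c(0, 120000),
                             end = c(120000, 300000), tad_id = c("A", "B")))
  set.seed(5)
  # 12 A points near origin, 12 B points 100 units away: full separation
  st <- data.table(bin = 1:24, hap = NA_character_,
                   x = c(rnorm(12, 0, 1), rnorm(12, 100, 1)),
                   y = rnorm(24, 0, 1), z = rnorm(24, 0, 1))
  tr <- structure_ratio(st, tads, idx, k = 10)
  expect_true(all(tr$value[1:24] == 1))
  # two models average per bin
  st2 <- copy(st); st2[bin == 1, x := 100]   # bin 1 moved into the B blob
  tr2 <- structure_ratio(list(st, st2), tads, idx, k = 10)
  expect_equal(tr2$value[1], (1 + 0) / 2)
  expect_identical(tr2$support[1], 2L)
  # fewer than k+1 points: skipped with a warning
  expect_warning(structure_ratio(st[1:5], tads, idx, k = 10), "skipped")
})

test_that("haplotype-aware neighbors require the same haplotype", {
  idx <- toy_index(1e5)
  tads <- tad_set(data.table(chrom = "chrS", start = 0, end = 1e5))
  set.seed(6)
  # one TAD, two haplotypes co-located: same TAD but different haplotype
  st <- data.table(bin = rep(1:6, 2), hap = rep(c("pat", "mat"), each = 6),
                   x = rnorm(12), y = rnorm(12), z = rnorm(12))
  tr_aware <- structure_ratio(st, tads, idx, k = 5, haplotype_aware = TRUE)
  tr_blind <- structure_ratio(st, tads, idx, k = 5, haplotype_aware = FALSE)
  expect_lt(mean(tr_aware$value[1:6]), 1)
  expect_true(all(tr_blind$value[1:6] == 1))
})

test_that("split_track duplicates parent values onto children", {
  coarse <- bin_index(c(chrS = 40000), 20000)
  fine <- bin_index(c(chrS = 40000), 10000)
  tr <- ratio_track(c(0.7, 0.2), c(3L, 4L), coarse)
  sp <- split_track(tr, fine)
  expect_equal(sp$value, c(0.7, 0.7, 0.2, 0.2))
  expect_identical(sp$support, c(3L, 3L, 4L, 4L))
})

test_that("imaging_ratio counts in-sphere same-domain fractions", {
  idx <- toy_index(1e5)
  # bin 1 at origin; 4 neighbors within 500 nm (3 same domain), 1 far away
  img <- data.table(cell_id = "c1", bin = 1:6,
                    x = c(0, 100, 200, 300, 400, 5000),
                    y = 0, z = 0)
  seg <- data.table(cell_id = "c1", bin = 1:6,
                    domain = c(1L, 1L, 1L, 1L, 2L, 2L))
  ct <- imaging_ratio(img, seg, idx, radius = 500)
  expect_equal(ct[bin == 1, value], 3 / 4)
  expect_true(is.na(ct[bin == 6, value]))       # empty neighborhood
  expect_identical(ct[bin == 6, n_neighbors], 0L)
  # all bins in one domain -> every ratio 1
  seg1 <- data.table(cell_id = "c1", bin = 1:6, domain = 1L)
  expect_true(all(imaging_ratio(img[1:5], seg1, idx, radius = 500)$value == 1))
})

test_that("subsample_correlation is seeded and handles degenerate draws", {
  idx <- toy_index(1e5)
  set.seed(9)
  base <- runif(10)
  ct <- rbindlist(lapply(1:4, function(i)
    data.table(cell_id = paste0("c", i), bin = 1:10, value = base)))
  ref <- ratio_track(base, rep(1L, 10), idx)
  # identical cells: every repeat's average equals the common track
  out <- subsample_correlation(ct, ref, x = 1, repeats = 5, seed = 1)
  expect_true(all(abs(out$pearson - 1) < 1e-12))
  # x = all cells: all repeats identical
  out2 <- subsample_correlation(ct, ref, x = 4, repeats = 3, seed = 1)
  expect_identical(out2$pearson, rep(out2$pearson[1], 3))
  # determinism under a fixed seed
  a <- subsample_correlation(ct, ref, x = 2, repeats = 10, seed = 33)
  b <- subsample_correlation(ct, ref, x = 2, repeats = 10, seed = 33)
  expect_identical(a, b)
  expect_error(subsample_correlation(ct, ref, x = 5, repeats = 2, seed = 1),
               "exceeds")
})
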