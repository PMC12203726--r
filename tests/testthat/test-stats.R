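test_that("enrichment fold and p follow the a,b,c,d formulas", {
  # hand arithmetic: a=100, b=20, c=10, d=6 -> fold (6/10)/(20/100) = 3
  res <- enrichment(feature_bins = c(1:6, 50:53), universe_bins = 1:100,
                    target_bins = 1:20)
  expect_identical(c(res$a, res$b, res$c, res$d), c(100L, 20L, 10L, 6L))
  expect_equal(res$fold, 3.0)
  expect_equal(res$p_value, phyper(5, 20, 80, 10, lower.tail = FALSE))
  # null case: d/c = b/a
  res0 <- enrichment(c(1:2, 21:28), 1:100, 1:20)
  expect_equal(res0$fold, 1.0)
  # degenerate: no target bins
  resb <- enrichment(1:5, 1:10, integer())
  expect_true(is.na(resb$fold))
  expect_error(enrichment(1:5, 1:10, 11L), "subset")
})

test_that("hypergeometric p matches exhaustive enumeration", {
  # scripted grid over small populations, including the a=10,b=5,c=4,d=4 case
  for (a in c(6, 10, 15, 20, 25)) {
    for (b in unique(c(1, a %/% 3, a %/% 2, a - 1))) {
      for (c_ in unique(c(1, 2, 4, min(5, a - 1)))) {
        feature <- seq_len(c_)        # overlap computed from bin sets
        for (d in unique(c(0, 1, min(c_, b)))) {
          p_pkg <- phyper(d - 1, b, a - b, c_, lower.tail = FALSE)
          expect_equal(p_pkg, enum_hyper_p(a, b, c_, d), tolerance = 1e-9)
        }
      }
    }
  }
  expect_equal(enrichment(1:4, 1:10, 1:5)$p_value, enum_hyper_p(10, 5, 4, 4),
               tolerance = 1e-9)
})

test_that("feature bins are labeled per category regardless of overlap", {
  idx <- toy_index(5e4)
  iv <- data.table(chrom = "chrS",
                   start = c(1000, 2000, 15000, 32000),
                   end = c(1500, 2500, 16000, 33000),
                   label = c("pELS", "PLS", "pELS", "Low-DNase"))
  setattr(iv, "class", c("interval_set", class(iv)))
  sets <- label_feature_bins(iv, idx)
  expect_setequal(names(sets), c("pELS", "PLS"))
  expect_true(1L %in% sets$pELS && 1L %in% sets$PLS)  # both categories
  expect_identical(sets$pELS, c(1L, 2L))
  expect_false(4L %in% unlist(sets))                  # Low-DNase dropped
  empty <- iv[label == "nope"]
  expect_identical(length(label_feature_bins(empty, idx)), 0L)
})

test_that("quantile groups are balanced with ties kept together", {
  expect_identical(as.integer(table(quantile_groups(1:10, 5))),
                   rep(2L, 5))
  sizes <- table(quantile_groups(rnorm(10), 3))
  expect_true(all(sizes %in% 3:4))
  expect_warning(g <- quantile_groups(rep(1, 6), 3), "ties")
  expect_identical(unique(g), 1L)
  # tied values never straddle a group border
  v <- c(1, 1, 1, 1, 2, 3, 4, 5)
  g2 <- suppressWarnings(quantile_groups(v, 4))
  expect_identical(length(unique(g2[v == 1])), 1L)
})

test_that("per-TAD correlation screens TADs and detects direction", {
  idx <- toy_index(6e5)
  tads <- toy_tads(c(0, 200, 400, 600))
  set.seed(8)
  r <- runif(60)
  # expression strictly decreasing in ratio within TAD 1; TAD 2 has only 4
  # genes; TAD 3 none
  e <- rep(NA_real_, 60)
  e[1:20] <- 10 - 5 * r[1:20]
  e[21:24] <- rnorm(4)
  track <- ratio_track(r, rep(1L, 60), idx)
  expr <- signal_track(e, idx)
  expect_error(per_tad_correlation(track, expr, tads), "fewer than 2")
  # add a second qualifying TAD so the t-test applies
  e[41:60] <- 1 - 2 * r[41:60]
  res <- per_tad_correlation(track, signal_track(e, idx), tads)
  expect_identical(res$n_tads, 2L)
  expect_false("T2" %in% res$correlations$tad_id)   # below min_genes
  expect_equal(res$correlations$rho, c(-1, -1))
  # invariant to per-TAD monotone transforms of expression
  e2 <- e; e2[1:20] <- exp(e[1:20]); e2[41:60] <- e[41:60]^3
  res2 <- per_tad_correlation(track, signal_track(e2, idx), tads)
  expect_equal(res2$correlations$rho, res$correlations$rho)
})

test_that("Mann-Whitney exact enumeration matches closed cases", {
  same <- group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_identical(same$method, "exact enumeration")
  # complete separation at n = 5 per group: p = 2 / C(10,5)
  res <- group_compare(6:10, 1:5)
  expect_equal(res$p_value, 2 / choose(10, 5))
  expect_equal(res$U, 25)
  # large samples: normal approximation agrees with wilcox.test
  set.seed(10)
  a <- rnorm(60); b <- rnorm(60, 0.5)
  res2 <- group_compare(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(res2$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(group_compare(numeric(), 1:3), "non-empty")
})

test_that("interaction regression recovers exact coefficients", {
  idx <- toy_index(4e6)
  set.seed(11)
  x1 <- runif(400); x2 <- runif(400)
  y <- 1 + 2 * x1 + 3 * x2 - 1 * x1 * x2
  y <- (y - min(y)) / diff(range(y))   # keep in [0,1] for the track
  # recover on the transformed scale: refit expectations via lm oracle
  fit <- suppressWarnings(   # summary.lm flags the deliberately perfect fit
    interaction_regression(ratio_track(y, rep(1L, 400), idx),
                           signal_track(x1, idx), signal_track(x2, idx)))
  oracle <- coef(lm(y ~ x1 * x2))
  expect_equal(fit$coefficients$estimate, unname(oracle), tolerance = 1e-8)
  expect_false(fit$rank_deficient)
  # degenerate design: x2 constant zero
  fit0 <- interaction_regression(ratio_track(y, rep(1L, 400), idx),
                                 signal_track(x1, idx),
                                 signal_track(rep(0, 400), idx))
  expect_true(fit0$rank_deficient)
  expect_true(anyNA(fit0$coefficients$estimate))
})

test_that("track correlation handles self, negation and stratification", {
  idx <- toy_index(2e6)
  set.seed(12)
  v <- runif(200)
  a <- ratio_track(v, rep(1L, 200), idx)
  b <- ratio_track(1 - v, rep(1L, 200), idx)
  expect_equal(track_correlation(a, a)$spearman, 1)
  expect_equal(track_correlation(a, b)$spearman, -1)
  by <- rep(c("A1", "B2"), each = 100)
  res <- track_correlation(a, a, by = by)
  expect_setequal(res$level, c("A1", "B2"))
  expect_equal(res$pearson, c(1, 1))
  # independent tracks decorrelate
  set.seed(13)
  cors <- replicate(10, {
    x <- ratio_track(runif(200), rep(1L, 200), idx)
    y <- ratio_track(runif(200), rep(1L, 200), idx)
    track_correlation(x, y)$pearson
  })
  expect_true(all(abs(cors) < 0.25))
})
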