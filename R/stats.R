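# Enrichment statistics and association analyses linking ratio tracks to
# signals, features and groupings.

#' Enrichment of a feature bin set on a target bin set
#'
#' With `a` universe bins, `b` target (e.g. domain surface) bins, `c` feature
#' bins in the universe and `d` feature bins in the target, the enrichment
#' fold is `(d/c) / (b/a)` and the p-value is the upper-tail hypergeometric
#' probability `P(X >= d)` of drawing `c` bins from a population of `a` with
#' `b` successes. Raw p-values are reported (add multiplicity correction
#' across features with [stats::p.adjust()] as needed).
#'
#' @param feature_bins integer bin ids carrying the feature.
#' @param universe_bins integer bin ids of the universe (e.g. all TAD bins).
#' @param target_bins integer bin ids of the target; must be a subset of the
#'   universe.
#' @return one-row `data.table(a, b, c, d, fold, p_value)`; `fold` is `NA`
#'   when `b == 0` or `c == 0`.
#' @export
enrichment <- function(feature_bins, universe_bins, target_bins) {
  universe <- unique(as.integer(universe_bins))
  target <- unique(as.integer(target_bins))
  if (!all(target %in% universe)) stop("target_bins must be a subset of universe_bins")
  feature <- intersect(unique(as.integer(feature_bins)), universe)
  a <- length(universe); b <- length(target)
  c_ <- length(feature); d <- length(intersect(feature, target))
  fold <- if (b > 0 && c_ > 0) (d / c_) / (b / a) else NA_real_
  p <- if (c_ > 0) phyper(d - 1L, b, a - b, c_, lower.tail = FALSE) else NA_real_
  data.table(a = a, b = b, c = c_, d = d, fold = fold, p_value = p)
}

#' Per-category feature bin sets from labeled intervals
#'
#' A bin carries a category iff it overlaps at least one interval of that
#' category, regardless of its overlap with intervals of other categories.
#' Excluded labels (by default the "Low-DNase" cCRE class, which marks
#' unlikely regulatory regions) are dropped before overlapping.
#'
#' @param intervals an `interval_set` (see [read_intervals()]).
#' @param index a [bin_index()].
#' @param exclude_labels labels dropped before overlap (default "Low-DNase").
#' @return named list of sorted integer bin-id vectors, one per retained
#'   category (empty list for an empty interval set).
#' @export
label_feature_bins <- function(intervals, index,
                               exclude_labels = "Low-DNase") {
  iv <- as.data.table(intervals)[!(label %in% exclude_labels)]
  if (!nrow(iv)) return(setNames(list(), character()))
  bt <- bin_table(index)
  setkey(bt, chrom, start, end)
  ov <- foverlaps(iv[, .(chrom, start, end, label)], bt,
                  by.x = c("chrom", "start", "end"), nomatch = NULL)
  ov <- ov[pmin(i.end, end) - pmax(i.start, start) > 0]
  lapply(split(ov$bin, ov$label), function(b) sort(unique(b)))
}

#' Partition values into near-equal-count quantile groups
#'
#' Groups contain approximately equal numbers of values; when values are
#' distinct the sizes differ by at most one. Tied values are kept together in
#' a single group (sizes then only approximate). `NA` values get `NA` group.
#'
#' @param values numeric vector.
#' @param n_groups number of groups.
#' @return integer vector of group ids (1 = lowest values); warns when the
#'   effective number of groups collapses below `n_groups`.
#' @export
quantile_groups <- function(values, n_groups) {
  n_groups <- as.integer(n_groups)
  stopifnot(n_groups >= 1)
  out <- rep(NA_integer_, length(values))
  ok <- which(!is.na(values))
  if (!length(ok)) return(out)
  v <- values[ok]
  ord <- order(v)
  base <- integer(length(v))
  # balanced sizes differing by <= 1, lowest groups take the extras
  sizes <- rep(length(v) %/% n_groups, n_groups)
  extra <- length(v) %% n_groups
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  base[ord] <- rep(seq_len(n_groups), sizes)
  # ties stay with the group of their first (lowest-rank) occurrence
  first_grp <- tapply(base, v, min)
  grp <- as.integer(first_grp[as.character(v)])
  if (length(unique(grp)) < n_groups)
    warning("ties reduced the effective number of groups to ",
            length(unique(grp)))
  out[ok] <- grp
  out
}

#' Per-TAD rank correlation of a ratio track with expression
#'
#' For each TAD containing at least `min_genes` bins with both a non-missing
#' ratio and a non-missing expression value, computes the Spearman
#' correlation across those bins, then tests the collected correlations
#' against zero with a two-sided one-sample t-test. A negative mean indicates
#' that highly expressed genes sit at low intra-TAD ratio, i.e. on domain
#' surfaces.
#'
#' @param track a [ratio_track()].
#' @param expression a [signal_track()] with values only at gene (TSS) bins.
#' @param tads a [tad_set()].
#' @param min_genes minimum qualifying bins per TAD (default 5).
#' @param tad_map optional precomputed [bin_tad_map()].
#' @return list with `correlations` (`data.table(tad_id, n, rho)`),
#'   `mean_rho`, `t_statistic`, `p_value`, `n_tads`.
#' @export
per_tad_correlation <- function(track, expression, tads, min_genes = 5L,
                                tad_map = NULL) {
  stopifnot(inherits(track, "ratio_track"), inherits(expression, "signal_track"))
  tad_map <- .as_tad_map(tads, track$index, tad_map)
  dt <- data.table(bin = seq_along(tad_map), row = tad_map,
                   r = track$value, e = expression$value)
  dt <- dt[!is.na(row) & !is.na(r) & !is.na(e)]
  dt[, tad_id := tads$tad_id[row]]
  cors <- dt[, if (.N >= min_genes && sd(r) > 0 && sd(e) > 0)
    .(n = .N, rho = cor(r, e, method = "spearman")), by = tad_id]
  if (nrow(cors) < 2) stop("fewer than 2 TADs qualify for the location test")
  if (sd(cors$rho) <= 1e-12 * max(1, abs(mean(cors$rho)))) {
    # degenerate but well-defined: identical correlations in every TAD
    t_stat <- if (mean(cors$rho) == 0) 0 else sign(mean(cors$rho)) * Inf
    p <- if (mean(cors$rho) == 0) 1 else 0
  } else {
    tt <- t.test(cors$rho, mu = 0, alternative = "two.sided")
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  list(correlations = cors, mean_rho = mean(cors$rho),
       t_statistic = t_stat, p_value = p, n_tads = nrow(cors))
}

#' Two-sided Mann-Whitney U comparison of two groups
#'
#' Exact enumeration over all group assignments when both groups have at most
#' `exact_max` observations (ties handled by the midrank U statistic);
#' otherwise the normal approximation with tie correction and continuity
#' correction.
#'
#' @param values_a,values_b numeric vectors (both non-empty).
#' @param exact_max enumeration limit per group (default 8).
#' @return `data.table(U, p_value, method, n_a, n_b)` where `U` counts
#'   pairs with a > b plus half the ties.
#' @export
group_compare <- function(values_a, values_b, exact_max = 8L) {
  a <- values_a[!is.na(values_a)]; b <- values_b[!is.na(values_b)]
  n1 <- as.numeric(length(a)); n2 <- as.numeric(length(b))
  if (!n1 || !n2) stop("both groups must be non-empty")
  pooled <- c(a, b)
  rk <- rank(pooled)
  U_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- utils::combn(as.integer(n1 + n2), as.integer(n1))
    Us <- colSums(matrix(rk[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    ties <- table(rk)
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U_obs - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
    method <- "normal approximation"
  }
  data.table(U = U_obs, p_value = p, method = method, n_a = n1, n_b = n2)
}

#' Regression of a ratio track on two signals and their interaction
#'
#' Ordinary least squares of `y` on `x1`, `x2` and `x1 * x2` over the bins
#' where all three are non-missing (optionally restricted by `mask`). Rank
#' deficiency (e.g. a constant signal) is reported rather than silently
#' dropped.
#'
#' @param y a [ratio_track()] (response).
#' @param x1,x2 [signal_track()]s (explanatory).
#' @param mask optional logical vector over bins restricting the fit.
#' @return list with `coefficients` (`data.table(term, estimate, std_error)`,
#'   `NA` estimates for aliased terms), `rank_deficient` flag, `n`.
#' @export
interaction_regression <- function(y, x1, x2, mask = NULL) {
  stopifnot(inherits(y, "ratio_track"))
  df <- data.frame(y = y$value, x1 = x1$value, x2 = x2$value)
  keep <- complete.cases(df)
  if (!is.null(mask)) keep <- keep & mask
  df <- df[keep, ]
  if (nrow(df) < 4) stop("fewer than 4 complete observations")
  fit <- lm(y ~ x1 + x2 + x1:x2, data = df)
  cf <- summary(fit)$coefficients
  terms <- c("(Intercept)", "x1", "x2", "x1:x2")
  co <- data.table(term = terms,
                   estimate = NA_real_, std_error = NA_real_)
  hit <- match(rownames(cf), terms)
  co[hit, `:=`(estimate = cf[, 1], std_error = cf[, 2])]
  ali <- is.na(coef(fit))[terms]
  list(coefficients = co,
       rank_deficient = fit$rank < 4L || any(ali, na.rm = TRUE),
       n = nrow(df))
}

#' Correlation between two per-bin tracks
#'
#' Pairwise-complete Pearson and Spearman correlations over jointly
#' non-missing bins, optionally stratified by a per-bin label (e.g.
#' subcompartment).
#'
#' @param track_a,track_b [ratio_track()] or [signal_track()] objects on the
#'   same index.
#' @param by optional per-bin label vector (character/factor); `NA` bins are
#'   dropped from stratified results.
#' @return `data.table(level, n, pearson, spearman)`; `level` is `"all"`
#'   when `by` is `NULL`.
#' @export
track_correlation <- function(track_a, track_b, by = NULL) {
  va <- track_a$value; vb <- track_b$value
  if (length(va) != length(vb)) stop("tracks are on different indexes")
  dt <- data.table(a = va, b = vb,
                   level = if (is.null(by)) "all" else as.character(by))
  dt <- dt[!is.na(a) & !is.na(b) & !is.na(level)]
  dt[, .(n = .N,
         pearson = if (.N >= 3) cor(a, b) else NA_real_,
         spearman = if (.N >= 3) cor(a, b, method = "spearman") else NA_real_),
     by = level]
}
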