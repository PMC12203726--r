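# Single-cell domain segmentation from 3D coordinates, convex-hull vertex
# labeling, TAD/scDomain co-membership counting, and a geometric coreness
# score used as ground truth for synthetic data.

#' Call single-cell domains from 3D coordinates by spatial insulation
#'
#' For each candidate boundary between consecutive positioned bins, the
#' spatial insulation score is the median pairwise distance between the `w`
#' upstream and `w` downstream bins divided by the median of the pairwise
#' distances within those two windows. Positions that are local maxima of the
#' score within `w` positions on either side and exceed
#' `boundary_prominence` times the cell's median score become domain
#' boundaries; scaling by the median makes the rule robust to the baseline
#' score level, which differs between crumpled and extended structures.
#' Adjacent domains whose cross-domain median distance falls below
#' `merge_threshold` times the pooled within-domain median are then merged
#' (they are two halves of one spatial structure, not two structures).
#'
#' Bins with missing coordinates are skipped: windows slide over the sequence
#' of positioned bins, and a window with fewer than 3 usable bins yields no
#' score at that position.
#'
#' @param coords `data.table(bin, x, y, z)` for one cell, any order; rows with
#'   non-finite coordinates are ignored.
#' @param window_w window half-width in bins (default 5).
#' @param boundary_prominence minimum insulation score at a boundary, as a
#'   multiple of the cell's median score (default 2: a boundary must double
#'   the baseline insulation, which sits well above the sampling noise of
#'   small-window medians and well below genuine spatial junctions).
#' @param merge_threshold merge factor for similar adjacent domains
#'   (default 0.9).
#' @return list with `labels` (`data.table(bin, domain)` over positioned
#'   bins), `boundaries` (bin ids starting each non-first domain) and `score`
#'   (`data.table(bin, score)`).
#' @export
call_scdomains <- function(coords, window_w = 5L, boundary_prominence = 2,
                           merge_threshold = 0.9) {
  cd <- as.data.table(coords)[is.finite(x) & is.finite(y) & is.finite(z)]
  if (!nrow(cd)) stop("all coordinates missing")
  setorder(cd, bin)
  n <- nrow(cd)
  X <- as.matrix(cd[, .(x, y, z)])
  w <- as.integer(window_w)
  score <- rep(NA_real_, n)
  D <- as.matrix(stats::dist(X))
  if (n >= 2L * w) {
    for (p in (w + 1L):(n - w + 1L)) {
      up <- (p - w):(p - 1L); dn <- p:(p + w - 1L)
      if (length(up) < 3L || length(dn) < 3L) next
      cross <- D[up, dn]
      within <- c(D[up, up][upper.tri(diag(length(up)))],
                  D[dn, dn][upper.tri(diag(length(dn)))])
      med_w <- median(within)
      if (!is.finite(med_w) || med_w <= 0) next
      score[p] <- median(cross) / med_w
    }
  }
  is_b <- rep(FALSE, n)
  cut <- boundary_prominence * median(score, na.rm = TRUE)
  for (p in seq_len(n)) {
    s <- score[p]
    if (is.na(s) || is.na(cut) || s <= cut) next
    left <- if (p > 1L) score[max(1L, p - w):(p - 1L)] else numeric()
    right <- if (p < n) score[(p + 1L):min(n, p + w)] else numeric()
    # strict on the left, non-strict on the right: plateaus yield one boundary
    if (all(s > left, na.rm = TRUE) && all(s >= right, na.rm = TRUE))
      is_b[p] <- TRUE
  }
  dom <- cumsum(c(TRUE, is_b[-1L]))
  dom <- .merge_similar_domains(D, dom, merge_threshold)
  labels <- data.table(bin = cd$bin, domain = dom)
  list(labels = labels,
       boundaries = cd$bin[which(c(FALSE, diff(dom) != 0))],
       score = data.table(bin = cd$bin, score = score))
}

# iteratively merge adjacent domains whose cross median distance is below
# threshold x pooled within-domain median; always merge the closest pair first
.merge_similar_domains <- function(D, dom, merge_threshold) {
  repeat {
    ids <- unique(dom)
    if (length(ids) < 2L) break
    best <- NULL; best_ratio <- Inf
    for (j in seq_len(length(ids) - 1L)) {
      a <- which(dom == ids[j]); b <- which(dom == ids[j + 1L])
      cross <- median(D[a, b])
      within <- c(if (length(a) > 1) D[a, a][upper.tri(diag(length(a)))],
                  if (length(b) > 1) D[b, b][upper.tri(diag(length(b)))])
      if (!length(within)) next
      ratio <- cross / median(within)
      if (is.finite(ratio) && ratio < best_ratio) {
        best_ratio <- ratio; best <- c(ids[j], ids[j + 1L])
      }
    }
    if (is.null(best) || best_ratio >= merge_threshold) break
    dom[dom == best[2L]] <- best[1L]
  }
  as.integer(factor(dom, levels = unique(dom)))
}

#' Vertices of the 3D convex hull of a point cloud
#'
#' Quickhull in three dimensions. Returns the indices of the points that are
#' extreme points (hull vertices). Degenerate clouds (fewer than 4 points, or
#' all points collinear/coplanar within tolerance) return every index, the
#' convention used for small single-cell domains.
#'
#' @param X numeric matrix with 3 columns.
#' @param tol relative tolerance for "above a facet" tests (default 1e-9).
#' @return sorted integer vector of row indices of hull vertices.
#' @export
convex_hull_vertices <- function(X, tol = 1e-9) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == 3)
  n <- nrow(X)
  if (n < 4L) return(seq_len(n))
  scale <- max(apply(X, 2, function(v) diff(range(v))))
  if (scale <= 0) return(seq_len(n))
  eps <- tol * scale

  # initial simplex: farthest axis-extreme pair, then farthest from the line,
  # then farthest from the plane
  ext <- unique(c(apply(X, 2, which.min), apply(X, 2, which.max)))
  pr <- as.matrix(expand.grid(ext, ext))
  d2 <- rowSums((X[pr[, 1], , drop = FALSE] - X[pr[, 2], , drop = FALSE])^2)
  i1 <- pr[which.max(d2), 1]; i2 <- pr[which.max(d2), 2]
  if (sqrt(max(d2)) <= eps) return(seq_len(n))
  u <- X[i2, ] - X[i1, ]; u <- u / sqrt(sum(u^2))
  rel <- sweep(X, 2, X[i1, ])
  perp <- rel - outer(drop(rel %*% u), u)
  dl <- sqrt(rowSums(perp^2))
  i3 <- which.max(dl)
  if (dl[i3] <= eps) return(seq_len(n))  # collinear
  nrm <- .cross3(X[i2, ] - X[i1, ], X[i3, ] - X[i1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  dp <- drop(rel %*% nrm)
  i4 <- which.max(abs(dp))
  if (abs(dp[i4]) <= eps) return(seq_len(n))  # coplanar
  interior <- colMeans(X[c(i1, i2, i3, i4), ])

  faces <- list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  faces <- lapply(faces, function(f) .orient_face(f, X, interior))
  remaining <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  outside <- lapply(faces, function(f) {
    d <- .face_dist(f, X, remaining)
    remaining[d > eps]
  })
  # points outside several faces may appear in several outside sets; fine.

  repeat {
    fi <- which(lengths(outside) > 0)
    if (!length(fi)) break
    fi <- fi[1]
    cand <- outside[[fi]]
    p <- cand[which.max(.face_dist(faces[[fi]], X, cand))]
    visible <- which(vapply(faces, function(f)
      .face_dist(f, X, p) > eps, logical(1)))
    horizon <- .horizon_edges(faces[visible])
    orphan <- unique(unlist(outside[visible], use.names = FALSE))
    faces <- faces[-visible]; outside <- outside[-visible]
    newf <- lapply(horizon, function(e)
      .orient_face(c(e, p), X, interior))
    orphan <- setdiff(orphan, p)
    newo <- lapply(newf, function(f) {
      if (!length(orphan)) return(integer())
      orphan[.face_dist(f, X, orphan) > eps]
    })
    faces <- c(faces, newf)
    outside <- c(outside, newo)
  }
  sort(unique(unlist(lapply(faces, attr, "verts"), use.names = FALSE)))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# a face is its (unit outward normal, offset) with vertex indices attached
.orient_face <- function(verts, X, interior) {
  nrm <- .cross3(X[verts[2], ] - X[verts[1], ], X[verts[3], ] - X[verts[1], ])
  nn <- sqrt(sum(nrm^2))
  if (nn > 0) nrm <- nrm / nn
  if (sum(nrm * (interior - X[verts[1], ])) > 0) nrm <- -nrm
  structure(list(normal = nrm, point = X[verts[1], ]), verts = verts)
}

.face_dist <- function(face, X, idx) {
  if (!length(idx)) return(numeric())
  drop(sweep(X[idx, , drop = FALSE], 2, face$point) %*% face$normal)
}

# boundary edges of a set of faces: edges used by exactly one face in the set
.horizon_edges <- function(faces) {
  edges <- do.call(rbind, lapply(faces, function(f) {
    v <- attr(f, "verts")
    rbind(sort(c(v[1], v[2])), sort(c(v[1], v[3])), sort(c(v[2], v[3])))
  }))
  key <- paste(edges[, 1], edges[, 2])
  once <- names(which(table(key) == 1))
  lapply(once, function(k) as.integer(strsplit(k, " ")[[1]]))
}

#' Label hull vertices within each single-cell domain
#'
#' For each domain of a cell's segmentation, flags the bins whose 3D
#' coordinates are vertices of the domain's convex hull. Domains with fewer
#' than 4 points, or degenerate (collinear/coplanar) geometry, have all their
#' bins labeled vertex by convention.
#'
#' @param coords `data.table(bin, x, y, z)` for one cell.
#' @param labels `data.table(bin, domain)` for the same cell
#'   (e.g. `call_scdomains(...)$labels`).
#' @return `data.table(bin, domain, vertex)` with logical `vertex`.
#' @export
hull_vertices <- function(coords, labels) {
  cd <- merge(as.data.table(coords), as.data.table(labels), by = "bin")
  cd <- cd[is.finite(x) & is.finite(y) & is.finite(z) & !is.na(domain)]
  cd[, vertex := {
    idx <- convex_hull_vertices(cbind(x, y, z))
    seq_len(.N) %in% idx
  }, by = domain]
  cd[, .(bin, domain, vertex)]
}

#' Count same-scDomain co-membership of bin pairs across cells
#'
#' For every pair of bins at each 1D separation, counts the cells in which
#' both bins are imaged and carry the same single-cell domain label, and
#' groups pairs by whether they share a consensus TAD.
#'
#' @param tads a [tad_set()].
#' @param segmentation `data.table(cell_id, bin, domain)` over all cells.
#' @param index a [bin_index()].
#' @param separations separations in base pairs (multiples of the bin size).
#' @return `data.table(separation, bin1, bin2, same_tad, n_same_domain,
#'   n_both_imaged)`.
#' @export
comembership_counts <- function(tads, segmentation, index, separations) {
  map <- bin_tad_map(tads, index)
  bt <- bin_table(index)
  seg <- as.data.table(segmentation)[!is.na(domain)]
  out <- vector("list", length(separations))
  for (si in seq_along(separations)) {
    ds <- as.integer(separations[si] / index$bin_size)
    if (ds < 1) stop("separation below one bin")
    pairs <- data.table(bin1 = bt$bin, bin2 = bt$bin + ds)
    pairs <- pairs[bin2 <= nrow(bt) & bt$chrom[bin1] == bt$chrom[bin2]]
    a <- seg[, .(cell_id, bin1 = bin, d1 = domain)]
    b <- seg[, .(cell_id, bin2 = bin, d2 = domain)]
    m <- merge(merge(pairs[, .(bin1, bin2)], a, by = "bin1",
                     allow.cartesian = TRUE),
               b, by = c("cell_id", "bin2"))
    cnt <- m[, .(n_same_domain = sum(d1 == d2), n_both_imaged = .N),
             by = .(bin1, bin2)]
    cnt <- merge(pairs, cnt, by = c("bin1", "bin2"), all.x = TRUE)
    cnt[is.na(n_same_domain), `:=`(n_same_domain = 0L, n_both_imaged = 0L)]
    cnt[, same_tad := !is.na(map[bin1]) & !is.na(map[bin2]) &
          map[bin1] == map[bin2]]
    cnt[, separation := separations[si]]
    out[[si]] <- cnt[, .(separation, bin1, bin2, same_tad,
                         n_same_domain, n_both_imaged)]
  }
  rbindlist(out)
}

#' Geometric coreness of bins within their single-cell domains
#'
#' `1 - d_i / max_j d_j`, where `d_i` is a bin's distance to its domain's
#' centroid and the maximum runs over the domain: 1 is the deepest core, 0
#' the farthest point. Used as synthetic ground truth.
#'
#' @param coords `data.table(bin, x, y, z)` for one cell.
#' @param labels `data.table(bin, domain)` for the same cell.
#' @return `data.table(bin, domain, coreness)`.
#' @export
geometric_coreness <- function(coords, labels) {
  cd <- merge(as.data.table(coords), as.data.table(labels), by = "bin")
  cd <- cd[is.finite(x) & is.finite(y) & is.finite(z) & !is.na(domain)]
  cd[, coreness := {
    cx <- mean(x); cy <- mean(y); cz <- mean(z)
    d <- sqrt((x - cx)^2 + (y - cy)^2 + (z - cz)^2)
    if (max(d) > 0) 1 - d / max(d) else rep(1, .N)
  }, by = domain]
  cd[, .(bin, domain, coreness)]
}
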