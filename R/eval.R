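#' Threshold and binarize a Z-scored map
#'
#' In-mask voxels with value > z are set to 1. At the default z = 1.6 a
#' standard-normal map retains roughly the upper 5% of its voxels;
#' alternative thresholds (e.g. 2, 2.3) are accepted.
#'
#' @param map 3D Z-scored map (zero outside the mask).
#' @param mask cord [volume_mask()].
#' @param z threshold (default 1.6).
#' @param source optional provenance (method, scope, component index).
#' @return list of class `binary_map`: `data` (3D 0/1), `z_threshold`,
#'   `source`.
#' @export
threshold_binarize <- function(map, mask, z = 1.6, source = NULL) {
  map <- as_array(map, 3L, "map")
  if (!all(dim(map) == dim(mask$data))) stop("map and mask grids differ")
  inmask <- mask$data > 0
  if (var(map[inmask]) <= 0) stop("cannot threshold a zero-variance map")
  b <- array(0L, dim(map))
  b[inmask & map > z] <- 1L
  structure(list(data = b, z_threshold = z, source = source),
            class = "binary_map")
}

binarize_components <- function(cs, z = 1.6) {
  lapply(seq_len(cs$K), function(k) {
    threshold_binarize(cs$maps[, , , k, drop = TRUE], cs$mask, z = z,
                       source = list(method = cs$method, scope = cs$scope,
                                     component = k))
  })
}

#' Dice coefficient between two binary maps
#'
#' 2|A intersect B| / (|A| + |B|). If both maps are empty the coefficient
#' is undefined and `NA` is returned (callers exclude it from summaries).
#'
#' @param a,b `binary_map` objects (or plain 3D binary arrays).
#' @return value in `[0, 1]`, or `NA` for two empty maps.
#' @export
dice <- function(a, b) {
  av <- if (inherits(a, "binary_map")) a$data else a
  bv <- if (inherits(b, "binary_map")) b$data else b
  if (!all(dim(av) == dim(bv))) stop("maps are on different grids")
  na <- sum(av > 0); nb <- sum(bv > 0)
  if (na + nb == 0) {
    warning("Dice undefined for two empty maps")
    return(NA_real_)
  }
  2 * sum(av > 0 & bv > 0) / (na + nb)
}

#' Cosine similarity between two unthresholded maps
#'
#' Inner product of the in-mask voxel vectors over the product of their
#' norms (equivalently 1 minus the cosine distance).
#'
#' @param a,b 3D maps on a shared grid.
#' @param mask [volume_mask()] restricting the comparison.
#' @return value in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b, mask) {
  av <- as_array(a, 3L, "map")[mask$data > 0]
  bv <- as_array(b, 3L, "map")[mask$data > 0]
  sum(av * bv) / (sqrt(sum(av^2)) * sqrt(sum(bv^2)))
}

#' Maximum-weight one-to-one matching
#'
#' Assignment between two component sets (rows and columns of a weight
#' matrix) maximizing the total weight, via maximum-weight bipartite
#' matching; with unequal set sizes, min(nA, nB) pairs are returned and
#' the surplus indices are reported unmatched.
#'
#' @param weights nA x nB matrix of finite pairwise weights (e.g. Dice).
#' @return list of class `matching`: `pairs` (data.frame a, b, weight),
#'   `unmatched_a`, `unmatched_b`, `total_weight`.
#' @export
match_components <- function(weights) {
  weights <- as.matrix(weights)
  if (!all(is.finite(weights))) stop("weights must be finite")
  nA <- nrow(weights); nB <- ncol(weights)
  # shift so all edges are strictly positive: every assignment keeps the
  # same cardinality min(nA, nB), so the argmax is unchanged
  shift <- 1e-9 - min(0, min(weights))
  g <- igraph::graph_from_biadjacency_matrix(weights + shift, weighted = TRUE)
  m <- igraph::max_bipartite_match(g)$matching
  a_idx <- seq_len(nA)
  partner <- m[a_idx]
  matched <- !is.na(partner)
  b_idx <- as.integer(partner[matched]) - nA
  pairs <- data.frame(a = a_idx[matched], b = b_idx,
                      weight = weights[cbind(a_idx[matched], b_idx)])
  pairs <- pairs[order(pairs$a), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 unmatched_a = setdiff(a_idx, pairs$a),
                 unmatched_b = setdiff(seq_len(nB), pairs$b),
                 total_weight = sum(pairs$weight)),
            class = "matching")
}

#' Percent overlap of a component with each segmental level
#'
#' Percentage of the component's (thresholded, binarized) voxels falling in
#' each atlas level, plus an outside-atlas bin; the vector sums to 100.
#'
#' @param component a `binary_map`.
#' @param atlas a [level_atlas()].
#' @return named numeric vector `level_1` ... `level_L`, `outside`.
#' @export
level_overlap <- function(component, atlas) {
  b <- component$data
  if (!all(dim(b) == dim(atlas$labels))) stop("component and atlas grids differ")
  n <- sum(b > 0)
  if (n == 0) stop("empty map")
  lab <- atlas$labels[b > 0]
  counts <- tabulate(lab + 1L, nbins = atlas$L + 1L)  # slot 1 = outside (0)
  pct <- 100 * counts / n
  names(pct) <- c("outside", sprintf("level_%d", seq_len(atlas$L)))
  pct[c(sprintf("level_%d", seq_len(atlas$L)), "outside")]
}

# Dice matrix between two lists of binary maps
dice_matrix <- function(maps_a, maps_b) {
  m <- matrix(NA_real_, length(maps_a), length(maps_b))
  for (i in seq_along(maps_a)) for (j in seq_along(maps_b)) {
    m[i, j] <- suppressWarnings(dice(maps_a[[i]], maps_b[[j]]))
  }
  m
}

#' Match a component set to atlas levels by Dice
#'
#' Binarizes the maps at `z`, computes Dice against each level's binary
#' mask and applies [match_components()].
#'
#' @param cs a [component_set()].
#' @param atlas a [level_atlas()].
#' @param z threshold (default 1.6).
#' @return list: `matching`, `dice` (component x level matrix),
#'   `mean_matched_dice`.
#' @export
match_to_atlas <- function(cs, atlas, z = 1.6) {
  bm <- binarize_components(cs, z)
  lv <- lapply(seq_len(atlas$L), function(l) {
    structure(list(data = (atlas$labels == l) * 1L, z_threshold = NA,
                   source = list(level = l)), class = "binary_map")
  })
  D <- dice_matrix(bm, lv)
  D0 <- D; D0[is.na(D0)] <- 0
  m <- match_components(D0)
  list(matching = m, dice = D,
       mean_matched_dice = mean(m$pairs$weight))
}

#' Mean percent overlap of matched components with their segmental levels
#'
#' Matches a component set to the atlas ([match_to_atlas()]) and averages,
#' over matched pairs, the percentage of each component's voxels falling in
#' its matched level. Components whose thresholded map is empty are
#' extraction failures and are excluded from the mean (with their count
#' reported in the `n_empty` attribute).
#'
#' @param cs a [component_set()].
#' @param atlas a [level_atlas()].
#' @param z threshold (default 1.6).
#' @return mean matched overlap percentage (attribute `n_empty`).
#' @export
matched_level_overlap <- function(cs, atlas, z = 1.6) {
  mt <- match_to_atlas(cs, atlas, z)
  bm <- binarize_components(cs, z)
  vals <- vapply(seq_len(nrow(mt$matching$pairs)), function(i) {
    p <- mt$matching$pairs[i, ]
    if (sum(bm[[p$a]]$data) == 0) return(NA_real_)
    unname(level_overlap(bm[[p$a]], atlas)[sprintf("level_%d", p$b)])
  }, numeric(1))
  out <- mean(vals, na.rm = TRUE)
  attr(out, "n_empty") <- sum(is.na(vals))
  out
}

#' Z center of mass of a map, in mm
#'
#' Intensity-weighted (or membership-weighted, for binary maps) mean of the
#' 0-based z index times the z voxel size. With `largest_cluster_only`,
#' only the largest 26-connected cluster of the map's support contributes.
#'
#' @param map `binary_map` or 3D non-negative map.
#' @param voxel_size_z z voxel size in mm.
#' @param largest_cluster_only restrict to the largest cluster.
#' @return z coordinate in mm.
#' @export
center_of_mass_z <- function(map, voxel_size_z = 1,
                             largest_cluster_only = FALSE) {
  m <- if (inherits(map, "binary_map")) map$data else as_array(map, 3L, "map")
  m[m < 0] <- 0
  if (sum(m) == 0) stop("empty map")
  if (largest_cluster_only) {
    lab <- label_clusters_26(m > 0)
    sizes <- tabulate(lab[lab > 0])
    m[lab != which.max(sizes)] <- 0
  }
  dims <- dim(m)
  z0 <- rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2])
  sum(as.vector(m) * z0) / sum(m) * voxel_size_z
}

#' @rdname center_of_mass_z
#' @param a,b maps passed to [center_of_mass_z()].
#' @param ... forwarded to [center_of_mass_z()].
#' @export
com_distance <- function(a, b, voxel_size_z = 1, ...) {
  abs(center_of_mass_z(a, voxel_size_z, ...) -
        center_of_mass_z(b, voxel_size_z, ...))
}

# 26-connectivity cluster labelling (iterative BFS; volumes are small)
label_clusters_26 <- function(bin) {
  dims <- dim(bin)
  lab <- array(0L, dims)
  idx <- which(bin)
  if (!length(idx)) return(lab)
  coord <- arrayInd(idx, dims)
  key <- function(x, y, z) (z - 1L) * dims[1] * dims[2] + (y - 1L) * dims[1] + x
  inb <- array(FALSE, dims); inb[idx] <- TRUE
  cur <- 0L
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  for (i in seq_along(idx)) {
    if (lab[idx[i]] != 0L) next
    cur <- cur + 1L
    queue <- idx[i]
    lab[idx[i]] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      ci <- arrayInd(v, dims)
      nb <- sweep(off, 2, as.integer(ci), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      nk <- key(nb[, 1], nb[, 2], nb[, 3])
      nk <- nk[inb[nk] & lab[nk] == 0L]
      if (length(nk)) {
        lab[nk] <- cur
        queue <- c(queue, nk)
      }
    }
  }
  lab
}

#' Individual-level component heatmaps
#'
#' Each subject's K maps are binarized at `z`, sorted rostro-caudally by
#' the center of mass of their largest 26-connected cluster, and summed
#' slot-wise across subjects: heatmap slot k counts, per voxel, how many
#' participants show component k there.
#'
#' @param subject_sets list of per-subject [component_set()]s (same K).
#' @param z threshold (default 1.6).
#' @param voxel_size_z z voxel size in mm (for the sorting key).
#' @return 4D array (x, y, z, K) of counts.
#' @export
individual_heatmap <- function(subject_sets, z = 1.6, voxel_size_z = 1) {
  stopifnot(length(subject_sets) >= 1)
  K <- subject_sets[[1]]$K
  dims <- dim(subject_sets[[1]]$maps)[1:3]
  heat <- array(0, c(dims, K))
  for (cs in subject_sets) {
    if (cs$K != K) stop("subject component sets must share K")
    bm <- binarize_components(cs, z)
    coms <- vapply(bm, function(b) {
      if (sum(b$data) == 0) return(Inf)
      center_of_mass_z(b, voxel_size_z, largest_cluster_only = TRUE)
    }, numeric(1))
    ord <- order(coms)
    for (slot in seq_len(K)) {
      heat[, , , slot] <- heat[, , , slot] + bm[[ord[slot]]]$data
    }
  }
  heat
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone in the input ranks, capped at 1).
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
fdr_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}
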