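## ---- neighbor search -------------------------------------------------------

## grid-bucket fixed-radius neighbor pairs; returns 2-column index matrix
## (i < j) of points within `r` of each other. O(n) buckets, expected
## O(n log n) overall at bounded density.
radius_pairs <- function(x, y, r) {
  n <- length(x)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  gx <- floor(x / r); gy <- floor(y / r)
  key <- paste(gx, gy)
  bucket <- split(seq_len(n), key)
  coords <- unique(cbind(gx, gy))
  out <- vector("list", nrow(coords) * 5)
  oi <- 0L
  lookup <- function(cx, cy) bucket[[paste(cx, cy)]]
  for (b in seq_len(nrow(coords))) {
    cx <- coords[b, 1]; cy <- coords[b, 2]
    here <- lookup(cx, cy)
    ## same-cell pairs
    if (length(here) > 1) {
      cmb <- utils::combn(here, 2)
      oi <- oi + 1L; out[[oi]] <- t(cmb)
    }
    ## half the neighboring cells (avoids double counting)
    for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
      there <- lookup(cx + d[1], cy + d[2])
      if (length(there) > 0) {
        oi <- oi + 1L
        out[[oi]] <- cbind(rep(here, each = length(there)),
                           rep(there, length(here)))
      }
    }
  }
  prs <- do.call(rbind, out[seq_len(oi)])
  if (is.null(prs) || nrow(prs) == 0) return(matrix(integer(0), ncol = 2))
  d2 <- (x[prs[, 1]] - x[prs[, 2]])^2 + (y[prs[, 1]] - y[prs[, 2]])^2
  prs <- prs[d2 <= r^2, , drop = FALSE]
  cbind(pmin(prs[, 1], prs[, 2]), pmax(prs[, 1], prs[, 2]))
}

## connected components from an edge list over n nodes (union-find)
components_from_pairs <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs) > 0) for (e in seq_len(nrow(pairs))) {
    ri <- find(pairs[e, 1]); rj <- find(pairs[e, 2])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

## ---- TLS-like community detection -----------------------------------------

#' Detect TLS-like communities by 10-micron linkage of seed-marker cells
#'
#' Connected components, under the "within `link_dist_um` of each other"
#' adjacency, of the subgraph induced by cells positive for any seed marker
#' (CD3, CD8 or CD20 by default). Components smaller than
#' `min_community_size` are discarded. Marker-negative cells never enter a
#' community.
#'
#' @param cells data.frame with `x_um`, `y_um` and logical marker columns.
#' @param seed_markers marker columns whose union seeds the communities.
#' @param link_dist_um linkage distance in microns (default 10).
#' @param min_community_size smallest reported community (default 10).
#' @return A list of class `tls_communities`: `membership` (data.frame
#'   `index` into `cells`, `community_id`) and `communities` (id, n_cells).
#'   Empty membership when no seed-positive cells exist.
#' @export
detect_tls_communities <- function(cells,
                                   seed_markers = c("CD3", "CD8", "CD20"),
                                   link_dist_um = 10,
                                   min_community_size = 10) {
  stopifnot(link_dist_um > 0, all(seed_markers %in% names(cells)))
  pos <- rowSums(as.matrix(cells[, seed_markers, drop = FALSE])) > 0
  idx <- which(pos)
  empty <- list(membership = data.frame(index = integer(0),
                                        community_id = integer(0)),
                communities = data.frame(community_id = integer(0),
                                         n_cells = integer(0)))
  class(empty) <- "tls_communities"
  if (length(idx) == 0) return(empty)
  prs <- radius_pairs(cells$x_um[idx], cells$y_um[idx], link_dist_um)
  comp <- components_from_pairs(length(idx), prs)
  sizes <- tabulate(comp)
  keep <- which(sizes >= min_community_size)
  if (length(keep) == 0) return(empty)
  sel <- comp %in% keep
  new_id <- match(comp[sel], keep)
  ## stable ids ordered by size, ties by first-seen index
  ord <- order(-sizes[keep])
  relabel <- match(seq_along(keep), ord)
  membership <- data.frame(index = idx[sel],
                           community_id = relabel[new_id])
  membership <- membership[order(membership$community_id,
                                 membership$index), ]
  rownames(membership) <- NULL
  comm <- as.data.frame(table(membership$community_id),
                        stringsAsFactors = FALSE)
  names(comm) <- c("community_id", "n_cells")
  comm$community_id <- as.integer(comm$community_id)
  structure(list(membership = membership, communities = comm),
            class = "tls_communities")
}

#' @export
print.tls_communities <- function(x, ...) {
  cat(sprintf("<tls_communities> %d communities over %d cells\n",
              nrow(x$communities), nrow(x$membership)))
  invisible(x)
}

## ---- geometry helpers ------------------------------------------------------

## convex-hull area by the shoelace formula; 0 for degenerate input
convex_hull_area <- function(x, y) {
  if (length(x) < 3) return(0)
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

## flat-kernel mean shift mode over the given points
mean_shift_mode <- function(x, y, bandwidth, start = NULL,
                            tol = 1e-6, max_iter = 200) {
  p <- start %||% c(mean(x), mean(y))
  for (i in seq_len(max_iter)) {
    d2 <- (x - p[1])^2 + (y - p[2])^2
    nb <- d2 <= bandwidth^2
    if (!any(nb)) break
    q <- c(mean(x[nb]), mean(y[nb]))
    if (sum((q - p)^2) < tol^2) { p <- q; break }
    p <- q
  }
  p
}

#' Exact area of a union of equal-radius disks
#'
#' Green's-theorem arc decomposition: each circle's boundary arcs not
#' covered by another disk bound the union; summing their line-integral
#' contributions gives the exact area (holes included). Disks fully inside
#' another contribute nothing.
#'
#' @param x,y disk centers; @param r common radius.
#' @return union area.
#' @export
disk_union_area <- function(x, y, r) {
  n <- length(x)
  if (n == 0) return(0)
  area <- 0
  for (i in seq_len(n)) {
    dx <- x - x[i]; dy <- y - y[i]
    d <- sqrt(dx^2 + dy^2)
    others <- which(d < 2 * r & seq_len(n) != i)
    ## drop exact duplicates (d == 0): keep only the first index
    dup <- others[d[others] == 0]
    if (any(dup < i)) next
    others <- setdiff(others, dup)
    if (length(others) == 0) {
      area <- area + pi * r^2  # isolated disk
      next
    }
    ## angular intervals of circle i's boundary covered by circle j:
    ## center angle theta_j, half width acos(d/(2r)) for equal radii
    th <- atan2(dy[others], dx[others])
    hw <- acos(pmin(1, d[others] / (2 * r)))
    ints <- cbind(th - hw, th + hw)
    ## normalize to [0, 2pi) and split wrap-around intervals
    ints <- ints %% (2 * pi)
    wrap <- ints[, 1] > ints[, 2]
    if (any(wrap))
      ints <- rbind(ints[!wrap, , drop = FALSE],
                    cbind(ints[wrap, 1], 2 * pi),
                    cbind(0, ints[wrap, 2]))
    ints <- ints[order(ints[, 1]), , drop = FALSE]
    ## merge and take complement = free arcs
    free <- list(); cur <- 0
    for (k in seq_len(nrow(ints))) {
      if (ints[k, 1] > cur) free[[length(free) + 1]] <- c(cur, ints[k, 1])
      cur <- max(cur, ints[k, 2])
    }
    if (cur < 2 * pi) free[[length(free) + 1]] <- c(cur, 2 * pi)
    if (length(free) == 0) next  # boundary fully covered
    for (arc in free) {
      a <- arc[1]; b <- arc[2]
      area <- area + 0.5 * (x[i] * r * (sin(b) - sin(a)) +
                              y[i] * r * (cos(a) - cos(b)) +
                              r^2 * (b - a))
    }
  }
  area
}

## ---- radial profiles -------------------------------------------------------

#' Radial cumulative density profile of a community
#'
#' The community centroid is the flat-kernel mean-shift mode (bandwidth
#' `bandwidth_um`) seeded at the member coordinate mean. The effective
#' radius is `sqrt(hull_area / pi)`; ring radii `r_k = R_eff sqrt(k / n)`
#' give equal-area disks each covering ~1/n of the effective community
#' area, with the outermost ring extended to the farthest member if needed.
#' Cumulative marker densities at ring k count marker-positive cells among
#' ALL cells (not just members) within `r_k` of the centroid, divided by
#' `pi r_k^2`.
#'
#' @param member_idx integer indices of community members into `cells`.
#' @param cells the full centroid table.
#' @param n_rings number of rings (default 10).
#' @param bandwidth_um mean-shift bandwidth (default 20, ~2 cell diameters).
#' @param markers markers to profile.
#' @return list of class `radial_profile`: `centroid`, `hull_area_um2`,
#'   `ring_radii`, `cum_counts` and `cum_density` (marker x ring matrices),
#'   `degenerate_hull` flag.
#' @export
radial_profile <- function(member_idx, cells, n_rings = 10,
                           bandwidth_um = 20,
                           markers = c("CD20", "CD3", "CD8", "MZB1")) {
  stopifnot(length(member_idx) >= 3)
  mx <- cells$x_um[member_idx]; my <- cells$y_um[member_idx]
  centroid <- mean_shift_mode(mx, my, bandwidth_um)
  A <- convex_hull_area(mx, my)
  degenerate <- A <= .Machine$double.eps
  if (degenerate) {
    warning("degenerate (collinear) hull; using bounding-circle area",
            call. = FALSE)
    R <- max(sqrt((mx - centroid[1])^2 + (my - centroid[2])^2))
    A <- pi * R^2
  }
  R_eff <- sqrt(A / pi)
  radii <- R_eff * sqrt(seq_len(n_rings) / n_rings)
  max_member_d <- max(sqrt((mx - centroid[1])^2 + (my - centroid[2])^2))
  radii[n_rings] <- max(radii[n_rings], max_member_d)
  d_all <- sqrt((cells$x_um - centroid[1])^2 + (cells$y_um - centroid[2])^2)
  cum_counts <- t(vapply(markers, function(mk) {
    pos <- d_all[cells[[mk]]]
    vapply(radii, function(r) sum(pos <= r), numeric(1))
  }, numeric(n_rings)))
  cum_density <- sweep(cum_counts, 2, pi * radii^2, "/")
  dimnames(cum_counts) <- dimnames(cum_density) <-
    list(markers, paste0("ring", seq_len(n_rings)))
  structure(list(centroid = centroid, hull_area_um2 = A,
                 ring_radii = radii, cum_counts = cum_counts,
                 cum_density = cum_density, degenerate_hull = degenerate),
            class = "radial_profile")
}

## ---- radial-gradient aggregates and enrichment ----------------------------

default_phenotypes <- function() {
  list(MZB1_pos   = function(c) c$MZB1,
       CD3_CD8    = function(c) c$CD3 & c$CD8,
       CD68_pos   = function(c) c$CD68,
       CD20_pos   = function(c) c$CD20,
       Treg       = function(c) c$CD3 & !c$CD8 & c$FOXP3)
}

#' Radial-gradient immune aggregates and phenotype enrichment
#'
#' Grows aggregates from every cell positive for any of 1-3 query markers by
#' iteratively connecting query-positive cells within `radius_um`
#' (approximately one cell diameter); overlapping regions merge. The
#' aggregate area is the exact area of the union of `radius_um` disks around
#' members. Phenotype enrichment is the cell density inside aggregates over
#' the density outside (field = bounding box of all cells).
#'
#' @param cells centroid table with logical marker columns.
#' @param query_markers 1 to 3 marker names.
#' @param radius_um connection radius (default 10).
#' @param phenotypes named list of predicate functions on `cells`.
#' @return list of class `aggregate_enrichment`: `aggregates` (id,
#'   n_members, area_um2), `enrichment` (phenotype, counts, densities,
#'   ratio), `total_aggregate_area_um2`, `field_area_um2`.
#' @export
aggregate_enrichment <- function(cells, query_markers, radius_um = 10,
                                 phenotypes = default_phenotypes()) {
  stopifnot(length(query_markers) >= 1, length(query_markers) <= 3,
            all(query_markers %in% names(cells)))
  pos <- rowSums(as.matrix(cells[, query_markers, drop = FALSE])) > 0
  idx <- which(pos)
  if (length(idx) == 0) {
    return(structure(list(aggregates = data.frame(), enrichment = data.frame(),
                          total_aggregate_area_um2 = 0,
                          field_area_um2 = NA_real_),
                     class = "aggregate_enrichment"))
  }
  prs <- radius_pairs(cells$x_um[idx], cells$y_um[idx], radius_um)
  comp <- components_from_pairs(length(idx), prs)
  aggs <- split(idx, comp)
  areas <- vapply(aggs, function(m)
    disk_union_area(cells$x_um[m], cells$y_um[m], radius_um), numeric(1))
  agg_df <- data.frame(aggregate_id = seq_along(aggs),
                       n_members = lengths(aggs), area_um2 = areas)
  rownames(agg_df) <- NULL

  ## inside = within radius_um of any member of any aggregate
  inside <- rep(FALSE, nrow(cells))
  mem_x <- cells$x_um[idx]; mem_y <- cells$y_um[idx]
  ## grid query: any cell within radius of a member
  all_pairs <- radius_pairs(c(mem_x, cells$x_um), c(mem_y, cells$y_um),
                            radius_um)
  nm <- length(idx)
  touch <- all_pairs[xor(all_pairs[, 1] <= nm, all_pairs[, 2] <= nm), ,
                     drop = FALSE]
  cell_side <- ifelse(touch[, 1] > nm, touch[, 1], touch[, 2]) - nm
  inside[cell_side] <- TRUE
  inside[idx] <- TRUE

  field_area <- diff(range(cells$x_um)) * diff(range(cells$y_um))
  a_in <- sum(areas)
  a_out <- max(field_area - a_in, .Machine$double.eps)
  enr <- do.call(rbind, lapply(names(phenotypes), function(ph) {
    sel <- phenotypes[[ph]](cells)
    n_in <- sum(sel & inside); n_out <- sum(sel & !inside)
    d_in <- n_in / a_in; d_out <- n_out / a_out
    data.frame(phenotype = ph, n_inside = n_in, n_outside = n_out,
               density_inside = d_in, density_outside = d_out,
               enrichment = ifelse(d_out > 0, d_in / d_out, Inf),
               stringsAsFactors = FALSE)
  }))
  rownames(enr) <- NULL
  structure(list(aggregates = agg_df, enrichment = enr,
                 total_aggregate_area_um2 = a_in,
                 field_area_um2 = field_area),
            class = "aggregate_enrichment")
}

## ---- KNN/Leiden infiltration scoring --------------------------------------

## symmetric (union) k-nearest-neighbor edge list, blockwise distances
knn_edges <- function(x, y, k) {
  n <- length(x)
  stopifnot(k < n)
  edges <- vector("list", ceiling(n / 512))
  bi <- 0L
  for (start in seq(1, n, by = 512)) {
    end <- min(start + 511, n)
    block <- start:end
    d2 <- outer(x[block], x, "-")^2 + outer(y[block], y, "-")^2
    nb <- t(apply(d2, 1, function(row) order(row)[2:(k + 1)]))
    bi <- bi + 1L
    edges[[bi]] <- cbind(rep(block, each = k), as.vector(t(nb)))
  }
  e <- do.call(rbind, edges)
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Plasma-cell infiltration scores from a KNN/Leiden partition
#'
#' Builds an undirected k-nearest-neighbor graph (k = 10) over all cell
#' centroids (union symmetrization), partitions it with the Leiden
#' algorithm (modularity objective, fixed RNG seed), and scores each
#' community as the fraction of MZB1+ cells. The patient/section-level
#' score is the unweighted mean over communities.
#'
#' @param cells centroid table with `x_um`, `y_um` and an `MZB1` column.
#' @param k neighbors (default 10).
#' @param resolution Leiden resolution (default 1).
#' @param leiden_seed RNG seed for the partition (default 0).
#' @return list of class `infiltration_result`: `communities`
#'   (community_id, n_cells, n_mzb1_pos, infiltration_score), `mean_score`.
#' @export
infiltration_scores <- function(cells, k = 10, resolution = 1,
                                leiden_seed = 0L) {
  n <- nrow(cells)
  if (k >= n)
    stop("k = ", k, " must be smaller than the number of cells (", n,
         "); choose a smaller k", call. = FALSE)
  e <- knn_edges(cells$x_um, cells$y_um, k)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(leiden_seed)
  part <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
  memb <- igraph::membership(part)
  comm <- lapply(split(seq_len(n), memb), function(ix) {
    data.frame(n_cells = length(ix), n_mzb1_pos = sum(cells$MZB1[ix]),
               infiltration_score = sum(cells$MZB1[ix]) / length(ix))
  })
  df <- do.call(rbind, comm)
  df <- cbind(community_id = as.integer(names(comm)), df)
  rownames(df) <- NULL
  structure(list(communities = df,
                 mean_score = mean(df$infiltration_score)),
            class = "infiltration_result")
}

#' Compare patient-level infiltration scores between groups
#'
#' @param scores numeric vector of patient mean scores.
#' @param group factor/character of group labels (two levels).
#' @return list with `p_value` (two-sided Wilcoxon rank-sum) and group means.
#' @export
compare_infiltration <- function(scores, group) {
  lv <- sort(unique(group))
  stopifnot(length(lv) == 2)
  wt <- stats::wilcox.test(scores[group == lv[1]], scores[group == lv[2]],
                           exact = FALSE)
  list(p_value = wt$p.value,
       means = tapply(scores, group, mean))
}
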