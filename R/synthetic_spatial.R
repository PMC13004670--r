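#' Generate a synthetic multiplex-IHC field with ground-truth communities
#'
#' Places `n_aggregates` lymphoid-aggregate-like clusters whose members are
#' laid down sequentially within 8 um of an existing member (guaranteeing a
#' single connected component under the 10-um linkage rule) and no farther
#' than `aggregate_radius_um` from the aggregate center, on top of a uniform
#' background. Aggregate centers are rejection-sampled so that members of
#' different aggregates are separated by more than `min_aggregate_gap_um`.
#'
#' Two generator guarantees keep ground truth exactly recoverable:
#' every aggregate member carries at least one seed marker (CD3/CD8/CD20),
#' and background cells within 12 um of any aggregate member have their seed
#' markers forced negative, so no background cell can bridge into or between
#' aggregates under 10-um linkage.
#'
#' @param spec a [spatial_spec()].
#' @return A list of class `spatial_data`: `cells` (x_um, y_um and logical
#'   marker columns) and `truth` (character labels, `"aggregate_<i>"` or
#'   `"background"`).
#' @export
gen_spatial_tissue <- function(spec) {
  stopifnot(inherits(spec, "spatial_spec"))
  set.seed(spec$seed)
  W <- spec$field_width_um; H <- spec$field_height_um
  R <- spec$aggregate_radius_um
  margin <- R + 5

  ## aggregate centers: pairwise member separation > gap is ensured by
  ## center separation > gap + 2R
  centers <- matrix(numeric(0), ncol = 2)
  if (spec$n_aggregates > 0) {
    if (2 * margin >= min(W, H))
      stop_field("aggregate_radius_um", "aggregates do not fit in the field")
    min_center_gap <- spec$min_aggregate_gap_um + 2 * R
    tries <- 0L
    while (nrow(centers) < spec$n_aggregates) {
      cand <- c(stats::runif(1, margin, W - margin),
                stats::runif(1, margin, H - margin))
      ok <- nrow(centers) == 0 ||
        all(sqrt(rowSums(sweep(centers, 2, cand)^2)) > min_center_gap)
      if (ok) centers <- rbind(centers, cand)
      tries <- tries + 1L
      if (tries > 5000L)
        stop("could not place aggregates without violating the minimum gap; ",
             "reduce n_aggregates or min_aggregate_gap_um", call. = FALSE)
    }
  }

  agg_pts <- list()
  for (a in seq_len(spec$n_aggregates)) {
    pts <- matrix(centers[a, ], ncol = 2)
    while (nrow(pts) < spec$cells_per_aggregate) {
      anchor <- pts[sample.int(nrow(pts), 1), ]
      placed <- FALSE
      for (try in 1:100) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- 8 * sqrt(stats::runif(1))
        cand <- anchor + rad * c(cos(ang), sin(ang))
        if (sum((cand - centers[a, ])^2) <= R^2 &&
            cand[1] > 0 && cand[1] < W && cand[2] > 0 && cand[2] < H) {
          pts <- rbind(pts, cand); placed <- TRUE; break
        }
      }
      if (!placed) { # fall back: step back toward the center
        cand <- (anchor + centers[a, ]) / 2
        pts <- rbind(pts, cand)
      }
    }
    agg_pts[[a]] <- pts
  }

  n_bg <- stats::rpois(1, spec$background_density * W * H)
  bg <- cbind(stats::runif(n_bg, 0, W), stats::runif(n_bg, 0, H))

  xy <- rbind(do.call(rbind, agg_pts),
              if (n_bg > 0) bg else matrix(numeric(0), ncol = 2))
  labels <- c(rep(sprintf("aggregate_%d", seq_len(spec$n_aggregates)),
                  each = spec$cells_per_aggregate),
              rep("background", n_bg))
  n <- nrow(xy)

  draw_markers <- function(probs, m) {
    out <- sapply(SPATIAL_MARKERS, function(mk)
      stats::runif(m) < probs[[mk]])
    matrix(out, nrow = m, dimnames = list(NULL, SPATIAL_MARKERS))
  }
  is_agg <- labels != "background"
  mk <- matrix(FALSE, n, length(SPATIAL_MARKERS),
               dimnames = list(NULL, SPATIAL_MARKERS))
  if (any(is_agg))
    mk[is_agg, ] <- draw_markers(spec$marker_probs_in_aggregate, sum(is_agg))
  if (any(!is_agg))
    mk[!is_agg, ] <- draw_markers(spec$marker_probs_background, sum(!is_agg))

  seed_mk <- c("CD3", "CD8", "CD20")
  ## aggregate members must carry >= 1 seed marker (TLS are T/B aggregates)
  p_seed <- spec$marker_probs_in_aggregate[seed_mk]
  if (sum(p_seed) == 0) p_seed <- c(CD3 = 1, CD8 = 0, CD20 = 1)
  need <- is_agg & rowSums(mk[, seed_mk, drop = FALSE]) == 0
  if (any(need)) {
    forced <- sample(seed_mk, sum(need), replace = TRUE, prob = p_seed)
    mk[cbind(which(need), match(forced, SPATIAL_MARKERS))] <- TRUE
  }
  ## background cells near an aggregate cannot carry seed markers
  if (any(is_agg) && any(!is_agg)) {
    agg_xy <- xy[is_agg, , drop = FALSE]
    bgi <- which(!is_agg)
    near <- vapply(bgi, function(i) {
      d2 <- (agg_xy[, 1] - xy[i, 1])^2 + (agg_xy[, 2] - xy[i, 2])^2
      any(d2 < 12^2)
    }, logical(1))
    mk[bgi[near], seed_mk] <- FALSE
  }

  cells <- data.frame(x_um = xy[, 1], y_um = xy[, 2], mk)
  rownames(cells) <- NULL
  structure(list(cells = cells, truth = labels), class = "spatial_data")
}
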