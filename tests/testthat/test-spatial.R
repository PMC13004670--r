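uniform_field <- function(n, seed, w = 1000, h = 1000, probs = NULL) {
  set.seed(seed)
  probs <- probs %||% c(CD3 = .3, CD8 = .2, CD20 = .3, CD68 = .1,
                        FOXP3 = .05, MZB1 = .2)
  df <- data.frame(x_um = runif(n, 0, w), y_um = runif(n, 0, h))
  for (mk in names(probs)) df[[mk]] <- runif(n) < probs[[mk]]
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("hand-geometry community detection", {
  cells <- data.frame(
    x_um = c(0, 5, 10, 100, 50), y_um = 0,
    CD3 = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    CD8 = FALSE,
    CD20 = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    CD68 = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    FOXP3 = FALSE, MZB1 = FALSE)
  ## min size 1: two components, sizes 3 and 1; CD68-only cell excluded
  cm1 <- detect_tls_communities(cells, min_community_size = 1)
  expect_identical(sort(cm1$communities$n_cells), c(1L, 3L))
  expect_false(5 %in% cm1$membership$index)
  ## min size 2: single community of the 3-chain
  cm2 <- detect_tls_communities(cells, min_community_size = 2)
  expect_identical(cm2$communities$n_cells, 3L)
  expect_setequal(cm2$membership$index, 1:3)
  ## no marker-positive cells -> empty result
  none <- cells; none[humoralkit:::SPATIAL_MARKERS] <- FALSE
  expect_identical(nrow(detect_tls_communities(none)$membership), 0L)
})

test_that("linkage communities equal brute-force BFS partitions", {
  for (s in 1:5) {
    f <- uniform_field(250, seed = 60 + s, w = 400, h = 400)
    cm <- detect_tls_communities(f, link_dist_um = 10,
                                 min_community_size = 1)
    pos <- which(f$CD3 | f$CD8 | f$CD20)
    bf <- bf_components(f$x_um[pos], f$y_um[pos], 10)
    expect_setequal(cm$membership$index, pos)
    det <- cm$membership$community_id[match(pos, cm$membership$index)]
    expect_equal(adjusted_rand_index(det, bf), 1)
  }
})

test_that("ring radii realize equal-area disks on the equivalent circle", {
  d <- gen_spatial_tissue(spatial_spec(n_aggregates = 2, seed = 8))
  cm <- detect_tls_communities(d$cells)
  ix <- cm$membership$index[cm$membership$community_id == 1]
  pr <- radial_profile(ix, d$cells)
  A <- pr$hull_area_um2
  ## pi r_k^2 = (k/10) hull area for k < 10 (last ring may extend)
  for (k in 1:9)
    expect_equal(pi * pr$ring_radii[k]^2, k / 10 * A, tolerance = 1e-9)
  expect_equal(pr$ring_radii[10],
               max(sqrt(A / pi),
                   max(sqrt((d$cells$x_um[ix] - pr$centroid[1])^2 +
                              (d$cells$y_um[ix] - pr$centroid[2])^2))))
  ## cumulative counts are monotone for every marker
  expect_true(all(apply(pr$cum_counts, 1, function(v) all(diff(v) >= 0))))
})

test_that("radial profile gradients match their constructions", {
  ## uniform marker field: cumulative density flat across rings. Ring
  ## values are cumulative (serially correlated), so the slope is tested
  ## across replicate fields rather than within one profile.
  slopes <- vapply(1:10, function(s) {
    f <- uniform_field(5000, seed = 70 + s)
    ix <- which(f$x_um > 400 & f$x_um < 600 & f$y_um > 400 & f$y_um < 600)
    pr <- radial_profile(ix, f, bandwidth_um = 50)
    dens <- pr$cum_density["CD20", ]
    unname(stats::coef(stats::lm(dens ~ seq_along(dens)))[2])
  }, numeric(1))
  ci <- stats::t.test(slopes)$conf.int
  expect_true(ci[1] <= 0 && ci[2] >= 0)
  ## and the slope is tiny relative to the density itself
  expect_lt(mean(abs(slopes)), 0.1 * 5000 * 0.3 / 1e6)
  ## tight central MZB1 blob: cumulative MZB1 density strictly decreasing
  set.seed(72)
  blob <- data.frame(x_um = c(rnorm(300, 500, 5), runif(700, 0, 1000)),
                     y_um = c(rnorm(300, 500, 5), runif(700, 0, 1000)))
  blob$CD3 <- blob$CD8 <- blob$CD20 <- FALSE
  blob$CD68 <- blob$FOXP3 <- FALSE
  blob$MZB1 <- c(rep(TRUE, 300), rep(FALSE, 700))
  members <- which(abs(blob$x_um - 500) < 60 & abs(blob$y_um - 500) < 60)
  prb <- radial_profile(members, blob, bandwidth_um = 30)
  expect_true(all(diff(prb$cum_density["MZB1", ]) < 0))
})

test_that("degenerate collinear hull falls back with a warning", {
  line <- data.frame(x_um = seq(0, 40, 5), y_um = 0,
                     CD3 = TRUE, CD8 = FALSE, CD20 = FALSE, CD68 = FALSE,
                     FOXP3 = FALSE, MZB1 = FALSE)
  expect_warning(pr <- radial_profile(seq_len(nrow(line)), line),
                 "degenerate")
  expect_gt(pr$hull_area_um2, 0)
})

test_that("union-of-disks area is exact", {
  r <- 10
  expect_equal(disk_union_area(0, 0, r), pi * r^2, tolerance = 1e-12)
  ## two disks exactly r apart: closed-form lens overlap
  d <- r
  lens <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  expect_equal(disk_union_area(c(0, d), c(0, 0), r), 2 * pi * r^2 - lens,
               tolerance = 1e-10)
  expect_lt(disk_union_area(c(0, d), c(0, 0), r), 2 * pi * r^2)
  ## coincident disks count once
  expect_equal(disk_union_area(c(3, 3), c(4, 4), r), pi * r^2,
               tolerance = 1e-12)
  ## random configurations vs deterministic grid quadrature
  set.seed(81)
  for (rep in 1:4) {
    n <- sample(3:8, 1)
    x <- runif(n, 0, 30); y <- runif(n, 0, 30)
    expect_equal(disk_union_area(x, y, r), bf_disk_union_grid(x, y, r),
                 tolerance = 5e-3)
  }
})

test_that("radial-gradient aggregates: areas and enrichment", {
  ## one isolated reference cell -> a single pi r^2 disk
  one <- data.frame(x_um = 50, y_um = 50, CD3 = FALSE, CD8 = FALSE,
                    CD20 = FALSE, CD68 = FALSE, FOXP3 = FALSE, MZB1 = TRUE)
  field <- rbind(one, data.frame(x_um = c(0, 100), y_um = c(0, 100),
                                 CD3 = FALSE, CD8 = FALSE, CD20 = FALSE,
                                 CD68 = TRUE, FOXP3 = FALSE, MZB1 = FALSE))
  ae <- aggregate_enrichment(field, "MZB1")
  expect_equal(ae$aggregates$area_um2, pi * 100, tolerance = 1e-9)
  ## two members exactly radius apart merge with overlap subtracted
  two <- field
  two <- rbind(two, transform(one, x_um = 60))
  ae2 <- aggregate_enrichment(two, "MZB1")
  expect_identical(nrow(ae2$aggregates), 1L)
  lens <- 2 * 100 * acos(0.5) - 5 * sqrt(300)
  expect_equal(ae2$aggregates$area_um2, 2 * pi * 100 - lens,
               tolerance = 1e-9)
  expect_error(aggregate_enrichment(field, c("a", "b", "c", "d")))
  ## a phenotype disjoint from a sparse query marker is unenriched
  ## (overlapping phenotypes are inflated by construction: every
  ## query-positive cell seeds its own aggregate)
  f <- uniform_field(5000, seed = 91, probs = c(CD3 = 0, CD8 = 0,
                                                CD20 = .02, CD68 = 0,
                                                FOXP3 = 0, MZB1 = 0))
  f$CD68 <- !f$CD20 & runif(nrow(f)) < .3
  aeu <- aggregate_enrichment(f, "CD20")
  enr <- aeu$enrichment$enrichment[aeu$enrichment$phenotype == "CD68_pos"]
  expect_gt(enr, 0.8); expect_lt(enr, 1.2)
})

test_that("infiltration scoring: ratios, calibration, invariances", {
  f <- uniform_field(800, seed = 101)
  f$MZB1 <- TRUE
  inf_all <- infiltration_scores(f)
  expect_true(all(inf_all$communities$infiltration_score == 1))
  expect_error(infiltration_scores(f[1:5, ]), "smaller k")
  ## score definition: n_mzb1 / n_cells exactly
  f2 <- uniform_field(600, seed = 102)
  inf2 <- infiltration_scores(f2)
  expect_equal(inf2$communities$infiltration_score,
               inf2$communities$n_mzb1_pos / inf2$communities$n_cells)
  expect_identical(sum(inf2$communities$n_cells), nrow(f2))
  ## rigid motion leaves the partition and scores unchanged
  th <- 0.7
  f3 <- f2
  f3$x_um <- cos(th) * f2$x_um - sin(th) * f2$y_um + 250
  f3$y_um <- sin(th) * f2$x_um + cos(th) * f2$y_um - 100
  inf3 <- infiltration_scores(f3)
  expect_equal(sort(inf3$communities$infiltration_score),
               sort(inf2$communities$infiltration_score))
  expect_equal(inf3$mean_score, inf2$mean_score)
  ## fixed seed -> reproducible partition
  expect_identical(infiltration_scores(f2)$communities, inf2$communities)
})

test_that("two disjoint blobs separate and average correctly", {
  set.seed(111)
  blob <- function(cx, cy, p_mzb1) {
    data.frame(x_um = rnorm(200, cx, 30), y_um = rnorm(200, cy, 30),
               CD3 = FALSE, CD8 = FALSE, CD20 = FALSE, CD68 = FALSE,
               FOXP3 = FALSE, MZB1 = runif(200) < p_mzb1)
  }
  f <- rbind(blob(0, 0, 0.5), blob(2000, 2000, 0))
  inf <- infiltration_scores(f)
  expect_gte(nrow(inf$communities), 2L)
  ## no community mixes the blobs: scores are either ~0 or ~0.5
  expect_true(all(inf$communities$infiltration_score < 0.05 |
                    inf$communities$infiltration_score > 0.3))
  expect_gt(inf$mean_score, 0.15)
  expect_lt(inf$mean_score, 0.35)
})
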