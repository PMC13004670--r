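test_that("cohort generator is deterministic and validates its spec", {
  sp <- cohort_spec(n_patients_R = 2, n_patients_NR = 2,
                    cells_per_sample = 60, seed = 7)
  a <- gen_cohort_repertoire(sp)
  b <- gen_cohort_repertoire(sp)
  expect_identical(a, b)

  expect_error(cohort_spec(n_patients_R = 0), "n_patients_R")
  expect_error(cohort_spec(dirichlet_precision = -1), "dirichlet_precision")
  expect_error(cohort_spec(clone_size_distribution = 0.9),
               "clone_size_distribution")
  expect_error(cohort_spec(cluster_baseline_props = rep(0.2, 10)),
               "cluster_baseline_props")
  expect_error(cohort_spec(tissues = "liver"), "tissues")
})

test_that("cohort output tables are mutually consistent", {
  d <- gen_cohort_repertoire(tiny_cohort(3))
  expect_false(anyDuplicated(d$annotation$cell_id) > 0)
  expect_setequal(d$airr$cell_id, d$annotation$cell_id)
  expect_setequal(d$ighc$cell_id, d$annotation$cell_id)
  expect_setequal(d$truth$cells$cell_id, d$annotation$cell_id)
  ## AIRR rows agree with the ground-truth clone registry
  ag <- merge(d$airr, d$truth$cells, by = "cell_id")
  reg <- d$truth$clones
  expect_identical(ag$junction,
                   reg$junction[match(ag$clone_id, reg$clone_id)])
  expect_identical(translate_junction(ag$junction), ag$junction_aa)
  ## clone sizes in the registry match the per-cell assignment
  sz <- table(d$truth$cells$clone_id)
  expect_identical(as.integer(sz[reg$clone_id]), reg$size)
  ## c_call, when present, equals the true isotype
  has <- ag$c_call != ""
  expect_identical(ag$c_call[has], ag$true_isotype[has])
})

test_that("shared_clone_fraction = 0 confines every clone to one compartment", {
  sp <- cohort_spec(n_patients_R = 2, n_patients_NR = 2,
                    cells_per_sample = 80, shared_clone_fraction = 0,
                    seed = 11)
  d <- gen_cohort_repertoire(sp)
  m <- merge(d$airr, d$annotation, by = "cell_id")
  comp <- paste(m$tissue, m$timepoint)
  ncomp <- tapply(comp, paste(m$patient, m$junction),
                  function(x) length(unique(x)))
  expect_true(all(ncomp == 1))
})

test_that("null IgG1-PC effect leaves arms indistinguishable", {
  sp <- cohort_spec(n_patients_R = 4, n_patients_NR = 4,
                    cells_per_sample = 2000, tissues = "tumor",
                    igg1_pc_logfc_R = 0, dirichlet_precision = 1e5,
                    seed = 5)
  d <- gen_cohort_repertoire(sp)
  m <- merge(d$annotation, d$truth$cells, by = "cell_id")
  igg1pc <- m$cluster %in% c("PC1", "PC2", "PC3") & m$true_isotype == "IGHG1"
  pR <- mean(igg1pc[m$response == "R"])
  pNR <- mean(igg1pc[m$response == "NR"])
  n <- sum(m$response == "R")
  se <- sqrt(pR * (1 - pR) / n + pNR * (1 - pNR) / n)
  expect_lt(abs(pR - pNR), 2 * se)
})

test_that("pooled generated proportions match the Dirichlet marginal (KS)", {
  ## with the group effect off and huge per-sample depth, each category's
  ## sample proportion is Beta(a_c, a_0 - a_c)
  base <- c(a = .3, b = .25, c = .15, d = .15, e = .10, f = .05)
  prec <- 50
  comp <- simulate_composition(n_per_arm = 500, base_props = base,
                               logfc = 0, target = "f", precision = prec,
                               n_cells = 50000, seed = 21)
  p_obs <- unclass(comp)[, "f"] / rowSums(unclass(comp))
  ## ties warning is expected: proportions are multiples of 1/50000
  ks <- suppressWarnings(
    stats::ks.test(p_obs, stats::pbeta,
                   shape1 = base["f"] * prec,
                   shape2 = (1 - base["f"]) * prec))
  expect_gt(ks$p.value, 0.01)
})

test_that("spatial generator honors its construction guarantees", {
  sp <- spatial_spec(n_aggregates = 3, min_aggregate_gap_um = 50, seed = 2)
  d <- gen_spatial_tissue(sp)
  expect_identical(sort(unique(d$truth)),
                   sort(c(paste0("aggregate_", 1:3), "background")))
  ## internal 10-um connectivity of each aggregate
  for (a in paste0("aggregate_", 1:3)) {
    ix <- which(d$truth == a)
    lab <- bf_components(d$cells$x_um[ix], d$cells$y_um[ix], 10)
    expect_identical(length(unique(lab)), 1L)
  }
  ## members of different aggregates farther apart than the gap
  ix1 <- d$truth == "aggregate_1"; ix2 <- d$truth == "aggregate_2"
  dmin <- min(sqrt(outer(d$cells$x_um[ix1], d$cells$x_um[ix2], "-")^2 +
                     outer(d$cells$y_um[ix1], d$cells$y_um[ix2], "-")^2))
  expect_gt(dmin, sp$min_aggregate_gap_um)
  ## every member carries a seed marker
  seeds <- rowSums(d$cells[d$truth != "background",
                           c("CD3", "CD8", "CD20")])
  expect_true(all(seeds > 0))

  d0 <- gen_spatial_tissue(spatial_spec(n_aggregates = 0, seed = 4))
  expect_true(all(d0$truth == "background"))

  r1 <- gen_spatial_tissue(sp)
  expect_identical(d, r1)

  expect_error(spatial_spec(min_aggregate_gap_um = 5), "min_aggregate_gap")
  expect_error(
    gen_spatial_tissue(spatial_spec(n_aggregates = 200,
                                    field_width_um = 400,
                                    field_height_um = 400, seed = 1)),
    "could not place")
})

test_that("serology generator crosses the cutoff exactly at the true titer", {
  sp <- serology_spec(readout_noise_sd = 0, seed = 9)
  d <- gen_serology(sp)
  tt <- sp$true_titers
  for (i in which(!is.na(tt$titer))) {
    cur <- d$elisa[d$elisa$sample == tt$sample[i] &
                     d$elisa$antigen == tt$antigen[i], ]
    ## linear in log10(dilution), hits cutoff at the titer
    fit <- stats::lm(readout ~ log10(dilution), data = cur)
    t_cross <- 10^((sp$cutoff_readout - coef(fit)[1]) / coef(fit)[2])
    expect_equal(t_cross, tt$titer[i], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  ## seronegative curves sit below the cutoff at every dilution
  for (i in which(is.na(tt$titer))) {
    cur <- d$elisa[d$elisa$sample == tt$sample[i] &
                     d$elisa$antigen == tt$antigen[i], ]
    expect_true(all(cur$readout < sp$cutoff_readout))
  }
  ## higher-titer curve reads higher at the lowest dilution
  sp2 <- serology_spec(readout_noise_sd = 0, true_titers = data.frame(
    sample = c("lo", "hi"), antigen = "AG", titer = c(200, 1600)), seed = 1)
  d2 <- gen_serology(sp2)$elisa
  r_lo <- d2$readout[d2$sample == "lo" & d2$dilution == 100]
  r_hi <- d2$readout[d2$sample == "hi" & d2$dilution == 100]
  expect_gt(r_hi, r_lo)
  ## out-of-range titer flagged
  expect_warning(
    gen_serology(serology_spec(true_titers = data.frame(
      sample = "S", antigen = "A", titer = 1e6), seed = 1)),
    "extrapolation")
  ## determinism
  expect_identical(gen_serology(sp), d)
})
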