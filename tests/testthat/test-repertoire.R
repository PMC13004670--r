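make_airr <- function(cell_id, c_call = "", junction_aa = "CARW",
                      junction = "TGTGCACGATGG", v_call = "IGHV3-23*01",
                      j_call = "IGHJ4*01", productive = "T") {
  if (length(cell_id) == 0)
    return(data.frame(cell_id = character(0), locus = character(0),
                      v_call = character(0), j_call = character(0),
                      c_call = character(0), junction = character(0),
                      junction_aa = character(0),
                      productive = character(0)))
  data.frame(cell_id = cell_id, locus = "IGH", v_call = v_call,
             j_call = j_call, c_call = c_call, junction = junction,
             junction_aa = junction_aa, productive = productive,
             stringsAsFactors = FALSE)
}

make_ann <- function(cell_id, patient = "P1", tissue = "tumor",
                     timepoint = "post", cluster = "PC1", response = "R") {
  data.frame(cell_id = cell_id, patient = patient,
             sample = paste(patient, tissue, timepoint, sep = "_"),
             tissue = tissue, timepoint = timepoint, cluster = cluster,
             response = response, stringsAsFactors = FALSE)
}

make_umis <- function(cell_id, ...) {
  if (length(cell_id) == 0) {
    out <- data.frame(cell_id = character(0))
    for (g in humoralkit:::ISOTYPES) out[[g]] <- numeric(0)
    return(out)
  }
  base <- as.list(stats::setNames(rep(0, 9), humoralkit:::ISOTYPES))
  over <- list(...)
  base[names(over)] <- over
  data.frame(cell_id = cell_id, base, stringsAsFactors = FALSE)
}

test_that("isotype assignment: BCR calls, rescue arithmetic, ties", {
  airr <- make_airr(c("c1", "c2", "c3"), c_call = c("IGHG1*01", "", ""))
  umis <- rbind(make_umis("c2", IGHG1 = 9, IGHM = 1),
                make_umis("c3", IGHG1 = 2, IGHA1 = 2))
  out <- assign_isotypes(airr, umis, rescue_min_umis = 3,
                         rescue_min_fraction = 0.6)
  calls <- out$calls
  expect_identical(calls$isotype[calls$cell_id == "c1"], "IGHG1")
  expect_identical(calls$source[calls$cell_id == "c1"], "bcr")
  expect_identical(calls$isotype[calls$cell_id == "c2"], "IGHG1")
  expect_identical(calls$source[calls$cell_id == "c2"],
                   "expression_rescue")
  expect_equal(calls$dominant_fraction[calls$cell_id == "c2"], 0.9)
  ## tie -> ambiguous even though counts pass neither threshold anyway
  expect_identical(calls$isotype[calls$cell_id == "c3"], "ambiguous")
})

test_that("isotype assignment edge cases", {
  ## sub-threshold UMIs -> ambiguous
  out <- assign_isotypes(make_airr("c1", c_call = ""),
                         make_umis("c1", IGHG1 = 2))
  expect_identical(out$calls$isotype, "ambiguous")
  ## empty inputs -> empty output, no error
  empty <- assign_isotypes(make_airr(character(0)),
                           make_umis(character(0)))
  expect_identical(nrow(empty$calls), 0L)
  ## multiple productive chains: highest duplicate_count wins, flagged
  a2 <- make_airr(c("c1", "c1"), c_call = c("IGHM", "IGHG1"))
  a2$duplicate_count <- c(1, 5)
  out2 <- assign_isotypes(a2, make_umis(character(0)))
  expect_identical(out2$calls$isotype, "IGHG1")
  expect_true(out2$calls$multi_chain)
  ## concordance matrix counts cells with both sources
  out3 <- assign_isotypes(make_airr("c1", c_call = "IGHG1"),
                          make_umis("c1", IGHG1 = 7))
  expect_identical(sum(out3$concordance), 1L)
  expect_identical(out3$concordance["IGHG1", "IGHG1"], 1L)
})

test_that("expression rescue recovers ground truth on generator data", {
  d <- gen_cohort_repertoire(tiny_cohort(13, cells = 120))
  out <- assign_isotypes(d$airr, d$ighc)
  m <- merge(out$calls, d$truth$cells, by = "cell_id")
  resc <- m[m$source == "expression_rescue" & m$isotype != "ambiguous", ]
  expect_gt(nrow(resc), 10)
  expect_gt(mean(resc$isotype == resc$true_isotype), 0.95)
  ## concordance diagonal dominance
  cc <- out$concordance
  shared <- intersect(rownames(cc), colnames(cc))
  expect_gt(sum(diag(cc[shared, shared])), 0.8 * sum(cc))
})

test_that("clonotype grouping is within patient and keyed correctly", {
  airr <- make_airr(c("a", "b", "c"), junction_aa = c("CARW", "CARW", "CXW"),
                    junction = c("TGTGCACGATGG", "TGTGCACGATGG",
                                 "TGTAAATGG"))
  ann <- rbind(make_ann(c("a", "b")), make_ann("c", patient = "P2"))
  cl <- build_clonotypes(airr, ann)
  expect_identical(nrow(cl), 2L)
  expect_setequal(cl$size, c(2L, 1L))
  expect_identical(cl$expanded, cl$size >= 2)
  ## same key in two patients -> two clones
  airr2 <- make_airr(c("a", "c"))
  ann2 <- rbind(make_ann("a"), make_ann("c", patient = "P2"))
  expect_identical(nrow(build_clonotypes(airr2, ann2)), 2L)
  ## all-distinct junctions -> all singletons, none expanded
  airr3 <- make_airr(letters[1:10],
                     junction_aa = paste0("CAR", LETTERS[1:10], "W"))
  cl3 <- build_clonotypes(airr3, make_ann(letters[1:10]))
  expect_identical(nrow(cl3), 10L)
  expect_false(any(cl3$expanded))
  ## malformed nt junction skipped in nt mode
  airr4 <- make_airr(c("a", "b"),
                     junction = c("TGTNNNTGG", "TGTGCATGG"))
  expect_message(cl4 <- build_clonotypes(airr4, make_ann(c("a", "b")),
                                         key_mode = "junction_nt"),
                 "skipped")
  expect_identical(nrow(attr(cl4, "cells")), 1L)
})

test_that("clonotypes partition cells; nt keys refine aa keys", {
  d <- gen_cohort_repertoire(tiny_cohort(17, cells = 100))
  cl_aa <- build_clonotypes(d$airr, d$annotation, "junction_aa")
  cells <- attr(cl_aa, "cells")
  expect_identical(sort(cells$cell_id), sort(d$annotation$cell_id))
  expect_identical(sum(cl_aa$size), nrow(d$annotation))
  expect_false(anyDuplicated(cells$cell_id) > 0)
  cl_nt <- build_clonotypes(d$airr, d$annotation, "junction_nt")
  ## refinement: cells sharing an nt clone always share the aa clone
  nt_cells <- attr(cl_nt, "cells")
  aa_of <- stats::setNames(cells$clone_id, cells$cell_id)
  per_nt <- tapply(aa_of[nt_cells$cell_id], nt_cells$clone_id,
                   function(x) length(unique(x)))
  expect_true(all(per_nt == 1))
  expect_gte(nrow(cl_nt), nrow(cl_aa))
})

test_that("expansion summary matches hand counts and handles degenerates", {
  ## clones sized 3,1,1 -> 3/5 expanded
  airr <- make_airr(c("a", "b", "c", "d", "e"),
                    junction_aa = c("CAAW", "CAAW", "CAAW", "CBBW", "CCCW"))
  cl <- build_clonotypes(airr, make_ann(letters[1:5]))
  es <- expansion_summary(cl)
  expect_equal(es$fraction_expanded, 0.6)
  expect_identical(es$n_cells, 5L)
  ## one clone of size n -> 1.0
  airr1 <- make_airr(letters[1:4])
  expect_equal(
    expansion_summary(build_clonotypes(airr1,
                                       make_ann(letters[1:4])))$fraction_expanded,
    1.0)
  ## all singletons -> 0.0
  airrS <- make_airr(letters[1:4],
                     junction_aa = paste0("CAR", LETTERS[1:4], "W"))
  expect_equal(
    expansion_summary(build_clonotypes(airrS,
                                       make_ann(letters[1:4])))$fraction_expanded,
    0.0)
})

test_that("expansion summary equals brute-force recount on generator data", {
  for (s in 1:3) {
    d <- gen_cohort_repertoire(tiny_cohort(100 + s, cells = 60))
    cl <- build_clonotypes(d$airr, d$annotation)
    es <- expansion_summary(cl)
    flags <- bf_expansion_flags(d$airr, d$annotation)
    expect_equal(es$fraction_expanded, mean(flags))
    expect_identical(es$n_expanded_cells, sum(flags))
  }
})

test_that("shared-clone tracking reports only multi-compartment clones", {
  airr <- make_airr(c("a", "b", "c"),
                    junction_aa = c("CAAW", "CAAW", "CBBW"))
  ann <- rbind(make_ann("a", tissue = "lymph_node"),
               make_ann("b", tissue = "tumor"),
               make_ann("c", tissue = "tumor"))
  cl <- build_clonotypes(airr, ann)
  tr <- track_shared_clones(cl)
  expect_identical(length(unique(tr$clone_id)), 1L)
  expect_true(all(tr$n_compartments == 2))
  expect_setequal(tr$tissue, c("lymph_node", "tumor"))
  expect_identical(
    length(clones_shared_between(tr, "tissue", c("lymph_node", "tumor"))),
    1L)
  ## single-compartment world -> empty tracking table
  d0 <- gen_cohort_repertoire(
    cohort_spec(n_patients_R = 1, n_patients_NR = 1, cells_per_sample = 40,
                tissues = c("tumor", "lymph_node"),
                shared_clone_fraction = 0, seed = 31))
  expect_identical(nrow(track_shared_clones(
    build_clonotypes(d0$airr, d0$annotation))), 0L)
})

test_that("observed shared-clone fraction tracks the generator parameter", {
  f <- 0.3
  d <- gen_cohort_repertoire(
    cohort_spec(n_patients_R = 3, n_patients_NR = 3, cells_per_sample = 150,
                tissues = c("tumor", "lymph_node"),
                shared_clone_fraction = f, seed = 41))
  cl <- build_clonotypes(d$airr, d$annotation)
  elig <- cl$size >= 2
  obs <- mean(cl$n_compartments[elig] >= 2)
  n <- sum(elig)
  ## binomial CI around f (generator may fail to split when a sample runs
  ## dry, so allow the lower side a bit more room)
  expect_lt(abs(obs - f), 3 * sqrt(f * (1 - f) / n) + 0.05)
  ## tracked clones match the ground-truth registry's shared clones
  tr <- track_shared_clones(cl)
  truth_shared <- d$truth$clones$clone_id[d$truth$clones$shared]
  truth_cells <- d$truth$cells[d$truth$cells$clone_id %in% truth_shared, ]
  sig_truth <- bf_partition_signature(truth_cells$clone_id,
                                      truth_cells$cell_id)
  cells <- attr(cl, "cells")
  det_cells <- cells[cells$clone_id %in% unique(tr$clone_id), ]
  sig_det <- bf_partition_signature(det_cells$clone_id, det_cells$cell_id)
  expect_identical(sig_det, sig_truth)
})

test_that("isotype composition proportions behave", {
  ann <- make_ann(letters[1:5])
  calls <- data.frame(cell_id = letters[1:5],
                      isotype = c(rep("IGHG1", 4), "IGHM"),
                      source = "bcr", dominant_fraction = NA_real_,
                      stringsAsFactors = FALSE)
  comp <- isotype_composition(ann, calls, "sample")
  expect_equal(comp$IGHG1, 0.8)
  expect_equal(comp$IGHM, 0.2)
  expect_equal(rowSums(comp[, c(humoralkit:::ISOTYPES, "ambiguous")]), 1,
               ignore_attr = TRUE)
  ## all ambiguous
  calls$isotype <- "ambiguous"
  expect_equal(isotype_composition(ann, calls, "sample")$ambiguous, 1.0)
  ## order invariance
  calls$isotype <- c(rep("IGHG1", 4), "IGHM")
  perm <- c(3, 5, 1, 4, 2)
  c1 <- isotype_composition(ann, calls, "sample")
  c2 <- isotype_composition(ann[perm, ], calls[rev(seq_len(5)), ], "sample")
  expect_equal(c1, c2)
  ## missing call errors
  expect_error(isotype_composition(ann, calls[-1, ], "sample"), "missing")
})
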