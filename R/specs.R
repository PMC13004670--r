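#' Cohort generator specification
#'
#' Describes a synthetic patient cohort for the repertoire/abundance stages:
#' responder and non-responder arms, per-sample cell yield, the baseline
#' composition over ten B/plasma-cell states, and the responder-tumor IgG1
#' plasma-cell effect. The generated world mirrors a neoadjuvant
#' checkpoint-blockade discovery cohort (8 responders vs 19 non-responders,
#' tumor / adjacent liver / draining lymph node, pre and post treatment);
#' all distributional choices beyond that are stand-ins, not estimates.
#'
#' @param n_patients_R,n_patients_NR number of patients per response arm.
#' @param cells_per_sample B/PC cells generated for every sample.
#' @param tissues subset of `c("tumor","adjacent","lymph_node","blood")`.
#' @param cluster_baseline_props probability vector over the 10 cell states
#'   (names `humoralkit:::CLUSTERS`), summing to 1.
#' @param igg1_pc_logfc_R log2 effect added to the IgG1+ plasma-cell
#'   proportion in responder tumor samples.
#' @param dirichlet_precision concentration of the per-sample Dirichlet draw;
#'   larger = less sample-to-sample variation.
#' @param clone_size_distribution power-law exponent (> 1) for clone sizes.
#' @param shared_clone_fraction probability that a clone of size >= 2 spans
#'   two compartments of its patient.
#' @param bcr_c_call_fraction fraction of cells whose AIRR row carries a
#'   constant-region call; the rest rely on expression rescue.
#' @param seed integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients_R = 8L,
                        n_patients_NR = 19L,
                        cells_per_sample = 500L,
                        tissues = c("tumor", "adjacent", "lymph_node"),
                        cluster_baseline_props = NULL,
                        igg1_pc_logfc_R = 1.0,
                        dirichlet_precision = 50,
                        clone_size_distribution = 2.5,
                        shared_clone_fraction = 0.15,
                        bcr_c_call_fraction = 0.8,
                        seed = 1L) {
  if (is.null(cluster_baseline_props)) {
    cluster_baseline_props <- c(
      naive_B = 0.18, memory_B = 0.22, activated_B = 0.10, switched_B = 0.12,
      unswitched_B = 0.08, atypical_B = 0.06, plasmablast = 0.08,
      PC1 = 0.06, PC2 = 0.05, PC3 = 0.05)
  }
  spec <- list(
    n_patients_R = check_count(n_patients_R, "n_patients_R"),
    n_patients_NR = check_count(n_patients_NR, "n_patients_NR"),
    cells_per_sample = check_count(cells_per_sample, "cells_per_sample"),
    tissues = tissues,
    cluster_baseline_props =
      check_prob_vector(cluster_baseline_props, "cluster_baseline_props", 10),
    igg1_pc_logfc_R = as.numeric(igg1_pc_logfc_R),
    dirichlet_precision = check_positive(dirichlet_precision,
                                         "dirichlet_precision"),
    clone_size_distribution = check_positive(clone_size_distribution,
                                             "clone_size_distribution"),
    shared_clone_fraction = check_prob(shared_clone_fraction,
                                       "shared_clone_fraction"),
    bcr_c_call_fraction = check_prob(bcr_c_call_fraction,
                                     "bcr_c_call_fraction"),
    seed = check_count(abs(seed) + 1L, "seed") - 1L)
  spec$seed <- as.integer(seed)
  if (!all(tissues %in% TISSUES))
    stop_field("tissues", paste("must be drawn from",
                                paste(TISSUES, collapse = ", ")))
  if (length(tissues) < 1) stop_field("tissues", "needs at least one tissue")
  if (spec$clone_size_distribution <= 1)
    stop_field("clone_size_distribution", "power-law exponent must be > 1")
  if (is.na(spec$igg1_pc_logfc_R))
    stop_field("igg1_pc_logfc_R", "must be a number")
  names(spec$cluster_baseline_props) <- CLUSTERS
  structure(spec, class = "cohort_spec")
}

#' Spatial tissue generator specification
#'
#' Describes a synthetic multiplex-IHC field: marker-positive lymphoid
#' aggregates (internally connected well under the 10-micron linkage rule)
#' on a uniform background. Aggregate centers are kept far enough apart
#' that ground-truth communities are separable by construction.
#'
#' @param field_width_um,field_height_um field extent in microns.
#' @param n_aggregates number of aggregates (0 allowed).
#' @param aggregate_radius_um maximum member distance from aggregate center.
#' @param cells_per_aggregate cells per aggregate.
#' @param background_density background cells per square micron.
#' @param marker_probs_in_aggregate,marker_probs_background named per-marker
#'   positivity probabilities over CD3, CD8, CD20, CD68, FOXP3, MZB1.
#' @param min_aggregate_gap_um minimum nearest-member gap between aggregates;
#'   must exceed the 10-micron linkage distance.
#' @param seed integer RNG seed.
#' @return An object of class `spatial_spec`.
#' @export
spatial_spec <- function(field_width_um = 2000,
                         field_height_um = 2000,
                         n_aggregates = 5L,
                         aggregate_radius_um = 60,
                         cells_per_aggregate = 80L,
                         background_density = 2e-4,
                         marker_probs_in_aggregate = c(
                           CD3 = 0.50, CD8 = 0.30, CD20 = 0.50,
                           CD68 = 0.10, FOXP3 = 0.05, MZB1 = 0.30),
                         marker_probs_background = c(
                           CD3 = 0.15, CD8 = 0.08, CD20 = 0.05,
                           CD68 = 0.15, FOXP3 = 0.03, MZB1 = 0.10),
                         min_aggregate_gap_um = 50,
                         seed = 1L) {
  chk_probs <- function(p, field) {
    if (!all(SPATIAL_MARKERS %in% names(p)))
      stop_field(field, "must name all of CD3, CD8, CD20, CD68, FOXP3, MZB1")
    if (any(p < 0 | p > 1)) stop_field(field, "probabilities must be in [0,1]")
    p[SPATIAL_MARKERS]
  }
  if (min_aggregate_gap_um <= 10)
    stop_field("min_aggregate_gap_um",
               "must exceed the 10-micron linkage distance")
  if (length(n_aggregates) != 1 || n_aggregates < 0 ||
      n_aggregates != round(n_aggregates))
    stop_field("n_aggregates", "must be a single non-negative integer")
  structure(list(
    field_width_um = check_positive(field_width_um, "field_width_um"),
    field_height_um = check_positive(field_height_um, "field_height_um"),
    n_aggregates = as.integer(n_aggregates),
    aggregate_radius_um = check_positive(aggregate_radius_um,
                                         "aggregate_radius_um"),
    cells_per_aggregate = check_count(cells_per_aggregate,
                                      "cells_per_aggregate"),
    background_density = check_positive(background_density,
                                        "background_density"),
    marker_probs_in_aggregate = chk_probs(marker_probs_in_aggregate,
                                          "marker_probs_in_aggregate"),
    marker_probs_background = chk_probs(marker_probs_background,
                                        "marker_probs_background"),
    min_aggregate_gap_um = check_positive(min_aggregate_gap_um,
                                          "min_aggregate_gap_um"),
    seed = as.integer(seed)), class = "spatial_spec")
}

#' Serology generator specification
#'
#' Describes ELISA titration plates (fourfold dilutions 1:100 to 1:6,400 by
#' default), ELISpot wells and a duplicate-spotted protein-microarray
#' (seromics) experiment with class-structured autoantibody hits.
#'
#' @param dilutions strictly increasing reciprocal dilutions.
#' @param true_titers data.frame with columns `sample`, `antigen`,
#'   `titer` (reciprocal titer; `NA` = seronegative). `NULL` gives a small
#'   default panel.
#' @param readout_noise_sd additive readout noise SD (same units as readout).
#' @param cutoff_readout readout level the titration curve crosses at the
#'   true titer.
#' @param slope_per_log10 readout decrease per log10 dilution step.
#' @param n_antigens_by_class named counts for seromics antigen classes
#'   CTA / tumor_associated / other (default keeps the 186-member CTA panel).
#' @param n_samples_R,n_samples_NR seromics samples per response arm.
#' @param hit_mean_R,hit_mean_NR named per-class Poisson means for the number
#'   of true hit antigens per sample (responder / non-responder).
#' @param n_neg_control_antigens negative-control spots per array.
#' @param elispot_means named mean spot counts per test condition.
#' @param elispot_background_mean mean background (DMSO) spot count.
#' @param seed integer RNG seed.
#' @return An object of class `serology_spec`.
#' @export
serology_spec <- function(dilutions = c(100, 400, 1600, 6400),
                          true_titers = NULL,
                          readout_noise_sd = 0.05,
                          cutoff_readout = 1.0,
                          slope_per_log10 = 1.0,
                          n_antigens_by_class = c(CTA = 186L,
                                                  tumor_associated = 120L,
                                                  other = 500L),
                          n_samples_R = 8L,
                          n_samples_NR = 8L,
                          hit_mean_R = c(CTA = 4, tumor_associated = 2,
                                         other = 2),
                          hit_mean_NR = c(CTA = 1, tumor_associated = 1,
                                          other = 2),
                          n_neg_control_antigens = 40L,
                          elispot_means = c(NY_ESO_1_pre = 20,
                                            NY_ESO_1_post = 120,
                                            flu = 80),
                          elispot_background_mean = 1,
                          seed = 1L) {
  if (length(dilutions) < 2 || any(diff(dilutions) <= 0))
    stop_field("dilutions", "must be strictly increasing, length >= 2")
  if (is.null(true_titers)) {
    true_titers <- data.frame(
      sample = rep(c("S1", "S2", "S3", "S4"), each = 2),
      antigen = rep(c("NY-ESO-1", "MAGE-A4"), 4),
      titer = c(800, 3200, 200, NA, NA, NA, 1600, 400))
  }
  if (!all(c("sample", "antigen", "titer") %in% names(true_titers)))
    stop_field("true_titers", "needs columns sample, antigen, titer")
  if (length(readout_noise_sd) != 1 || readout_noise_sd < 0)
    stop_field("readout_noise_sd", "must be a single number >= 0")
  cls <- c("CTA", "tumor_associated", "other")
  if (!all(cls %in% names(n_antigens_by_class)))
    stop_field("n_antigens_by_class", "must name CTA, tumor_associated, other")
  structure(list(
    dilutions = as.numeric(dilutions),
    true_titers = true_titers,
    readout_noise_sd = as.numeric(readout_noise_sd),
    cutoff_readout = check_positive(cutoff_readout, "cutoff_readout"),
    slope_per_log10 = check_positive(slope_per_log10, "slope_per_log10"),
    n_antigens_by_class = vapply(n_antigens_by_class[cls], check_count,
                                 integer(1), field = "n_antigens_by_class"),
    n_samples_R = check_count(n_samples_R, "n_samples_R"),
    n_samples_NR = check_count(n_samples_NR, "n_samples_NR"),
    hit_mean_R = hit_mean_R[cls],
    hit_mean_NR = hit_mean_NR[cls],
    n_neg_control_antigens = check_count(n_neg_control_antigens,
                                         "n_neg_control_antigens"),
    elispot_means = elispot_means,
    elispot_background_mean = as.numeric(elispot_background_mean),
    seed = as.integer(seed)), class = "serology_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> %d R + %d NR patients, %d cells/sample, ",
                     "tissues: %s\n  IgG1-PC log2FC (R, tumor) = %.2f, ",
                     "precision = %.0f, clone exponent = %.2f, seed = %d\n"),
              x$n_patients_R, x$n_patients_NR, x$cells_per_sample,
              paste(x$tissues, collapse = "/"), x$igg1_pc_logfc_R,
              x$dirichlet_precision, x$clone_size_distribution, x$seed))
  invisible(x)
}

#' @export
print.spatial_spec <- function(x, ...) {
  cat(sprintf(paste0("<spatial_spec> %.0fx%.0f um field, %d aggregates ",
                     "(r = %.0f um, %d cells, gap > %.0f um), background ",
                     "%.1e cells/um^2, seed = %d\n"),
              x$field_width_um, x$field_height_um, x$n_aggregates,
              x$aggregate_radius_um, x$cells_per_aggregate,
              x$min_aggregate_gap_um, x$background_density, x$seed))
  invisible(x)
}

#' @export
print.serology_spec <- function(x, ...) {
  cat(sprintf(paste0("<serology_spec> dilutions %s, noise sd %.3f, ",
                     "%d+%d+%d antigens (CTA/TA/other), seed = %d\n"),
              paste(x$dilutions, collapse = ","), x$readout_noise_sd,
              x$n_antigens_by_class[1], x$n_antigens_by_class[2],
              x$n_antigens_by_class[3], x$seed))
  invisible(x)
}
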