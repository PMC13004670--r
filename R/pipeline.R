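#' Build a pipeline run configuration
#'
#' All tunables default to the values the underlying assays prescribe where
#' stated (10-um linkage, k = 10, expansion at >= 2 cells, seropositivity at
#' reciprocal titer > 100, fourfold dilutions 100-6,400) and to documented
#' package defaults otherwise. Synthetic generator blocks may be overridden
#' with full spec objects.
#'
#' @param seed global seed; per-stage child seeds are derived from it.
#' @param stages named logical toggles (`repertoire`, `abundance`,
#'   `spatial`, `serology`).
#' @param cohort,spatial,serology optional [cohort_spec()], [spatial_spec()],
#'   [serology_spec()] overrides (their seeds are re-derived from `seed`).
#' @param key_mode,rescue_min_umis,rescue_min_fraction repertoire tunables.
#' @param link_dist_um,min_community_size,knn_k,leiden_resolution spatial
#'   tunables.
#' @param z_threshold seromics hit threshold.
#' @return list of class `run_config` with a stable `hash`.
#' @export
run_config <- function(seed = 1L,
                       stages = c(repertoire = TRUE, abundance = TRUE,
                                  spatial = TRUE, serology = TRUE),
                       cohort = NULL, spatial = NULL, serology = NULL,
                       key_mode = "junction_aa",
                       rescue_min_umis = 3, rescue_min_fraction = 0.6,
                       link_dist_um = 10, min_community_size = 10,
                       knn_k = 10, leiden_resolution = 1,
                       z_threshold = 3) {
  seed <- as.integer(seed)
  cohort <- cohort %||% cohort_spec()
  spatial <- spatial %||% spatial_spec()
  serology <- serology %||% serology_spec()
  cohort$seed <- derive_seed(seed, "cohort")
  spatial$seed <- derive_seed(seed, "spatial")
  serology$seed <- derive_seed(seed, "serology")
  cfg <- list(seed = seed, stages = stages, cohort = cohort,
              spatial = spatial, serology = serology, key_mode = key_mode,
              rescue_min_umis = rescue_min_umis,
              rescue_min_fraction = rescue_min_fraction,
              link_dist_um = link_dist_um,
              min_community_size = min_community_size, knn_k = knn_k,
              leiden_resolution = leiden_resolution,
              z_threshold = z_threshold)
  cfg$hash <- short_hash(jsonlite::toJSON(cfg, force = TRUE, digits = NA))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized top-level keys mirror [run_config()] arguments; generator
#' blocks (`cohort:`, `spatial:`, `serology:`) hold the corresponding spec
#' fields.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, block) {
    if (is.null(block)) return(NULL)
    do.call(ctor, block)
  }
  args <- y[setdiff(names(y), c("cohort", "spatial", "serology"))]
  args$cohort <- build(cohort_spec, y$cohort)
  args$spatial <- build(spatial_spec, y$spatial)
  args$serology <- build(serology_spec, y$serology)
  if (!is.null(args$stages)) args$stages <- unlist(args$stages)
  do.call(run_config, args)
}

stage_on <- function(config, stage) {
  isTRUE(config$stages[[stage]] %||% TRUE)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Stages execute in dependency order (generators feed repertoire, which
#' feeds abundance; spatial and serology are independent). Every output
#' table is written as TSV with a provenance header (schema version, config
#' hash, seed); a JSON manifest records the configuration hash, seed,
#' package version and per-stage row counts. Re-running with an identical
#' configuration reproduces byte-identical tables.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return the manifest (invisibly also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  h <- config$hash; sd <- config$seed
  manifest <- list(config_hash = h, seed = sd,
                   package_version = as.character(
                     utils::packageVersion("humoralkit")),
                   stages = list())
  emit <- function(df, name) {
    write_tsv_header(df, file.path(out_dir, paste0(name, ".tsv")), h, sd)
    nrow(df)
  }

  say("stage: generate (cohort, spatial tissue, serology)")
  cohort <- gen_cohort_repertoire(config$cohort)
  tissue <- gen_spatial_tissue(config$spatial)
  sero <- gen_serology(config$serology)
  manifest$stages$generate <- list(
    n_cells = emit(cohort$annotation, "cell_annotation"),
    n_airr_rows = emit(cohort$airr, "airr_rearrangements"),
    n_ighc_rows = emit(cohort$ighc, "ighc_umis"),
    n_spatial_cells = emit(tissue$cells, "spatial_centroids"),
    n_elisa_rows = emit(sero$elisa, "elisa_plate"),
    n_elispot_rows = emit(sero$elispot, "elispot_wells"),
    n_seromics_rows = emit(sero$seromics, "seromics_intensities"))
  jsonlite::write_json(cohort$truth, file.path(out_dir, "ground_truth.json"),
                       dataframe = "columns", digits = NA)

  iso <- clones <- NULL
  if (stage_on(config, "repertoire")) {
    say("stage: repertoire")
    iso <- assign_isotypes(cohort$airr, cohort$ighc,
                           config$rescue_min_umis,
                           config$rescue_min_fraction)
    clones <- build_clonotypes(cohort$airr, cohort$annotation,
                               config$key_mode)
    expn <- expansion_summary(clones, c("response", "cluster"),
                              cohort$annotation)
    track <- track_shared_clones(clones)
    comp_iso <- isotype_composition(cohort$annotation, iso$calls,
                                    c("sample", "response"))
    manifest$stages$repertoire <- list(
      n_isotype_calls = emit(iso$calls, "isotype_calls"),
      n_clonotypes = emit(as.data.frame(clones), "clonotypes"),
      n_expansion_groups = emit(expn, "expansion_summary"),
      n_tracked = emit(track, "clone_tracking"),
      n_isotype_strata = emit(comp_iso, "isotype_composition"))
  } else manifest$stages$repertoire <- "skipped"

  if (stage_on(config, "abundance")) {
    say("stage: abundance")
    ann_tumor <- cohort$annotation[cohort$annotation$tissue == "tumor" &
                                     cohort$annotation$timepoint == "post", ]
    comp <- composition_from_annotation(ann_tumor)
    da <- differential_abundance(comp, "response", ref_level = "NR")
    comp_all <- composition_from_annotation(cohort$annotation)
    enr <- tumor_enrichment(comp_all)
    manifest$stages$abundance <- list(
      n_categories = emit(as.data.frame(da), "differential_abundance"),
      lrt_p = attr(da, "lrt_p"),
      n_enrichment_rows = emit(enr, "tumor_enrichment"))
  } else manifest$stages$abundance <- "skipped"

  if (stage_on(config, "spatial")) {
    say("stage: spatial")
    comm <- detect_tls_communities(tissue$cells,
                                   link_dist_um = config$link_dist_um,
                                   min_community_size =
                                     config$min_community_size)
    profs <- lapply(split(comm$membership$index,
                          comm$membership$community_id),
                    function(ix) radial_profile(ix, tissue$cells))
    prof_long <- do.call(rbind, lapply(names(profs), function(id) {
      p <- profs[[id]]
      data.frame(community_id = as.integer(id),
                 ring = rep(seq_along(p$ring_radii),
                            each = nrow(p$cum_density)),
                 radius_um = rep(p$ring_radii, each = nrow(p$cum_density)),
                 marker = rep(rownames(p$cum_density),
                              length(p$ring_radii)),
                 cum_density = as.vector(p$cum_density),
                 stringsAsFactors = FALSE)
    })) %||% data.frame()
    infil <- infiltration_scores(tissue$cells, k = config$knn_k,
                                 resolution = config$leiden_resolution)
    manifest$stages$spatial <- list(
      n_communities = emit(comm$communities, "tls_communities"),
      n_membership = emit(comm$membership, "tls_membership"),
      n_profile_rows = emit(prof_long, "radial_profiles"),
      n_leiden_communities = emit(infil$communities, "infiltration_scores"),
      mean_infiltration = infil$mean_score)
  } else manifest$stages$spatial <- "skipped"

  if (stage_on(config, "serology")) {
    say("stage: serology")
    titers <- titer_table(sero$elisa)
    bg <- sero$elispot$spots[sero$elispot$is_background]
    es <- do.call(rbind, lapply(
      unique(sero$elispot$condition[!sero$elispot$is_background]),
      function(cn) {
        r <- elispot_positive(
          sero$elispot$spots[sero$elispot$condition == cn], bg)
        data.frame(condition = cn, positive = r$positive,
                   mean_test = r$mean_test,
                   mean_background = r$mean_background,
                   background_flag = r$background_flag,
                   stringsAsFactors = FALSE)
      }))
    hits <- seromics_hits(sero$seromics, config$z_threshold)
    hsum <- hit_class_summary(hits)
    manifest$stages$serology <- list(
      n_titers = emit(titers, "elisa_titers"),
      n_elispot_conditions = emit(es, "elispot_calls"),
      n_hits = emit(hits[hits$hit, , drop = FALSE], "seromics_hits"),
      n_hit_counts = emit(hsum$counts, "hit_class_counts"),
      n_hit_tests = emit(hsum$tests, "hit_class_tests"))
  } else manifest$stages$serology <- "skipped"

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a markdown summary report from a pipeline output directory
#'
#' Assembles the run's analogues of the study's headline panels: isotype
#' composition by response group, expansion fractions, differential
#' abundance effects and FDR, infiltration scores and serology hit
#' summaries. Missing stage outputs are marked "not run". Regeneration from
#' the same directory is idempotent.
#'
#' @param out_dir directory produced by [run_pipeline()].
#' @param file report path (default `report.md` inside `out_dir`).
#' @return the report path, invisibly.
#' @export
write_report <- function(out_dir, file = file.path(out_dir, "report.md")) {
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  ln <- c(sprintf("# humoralkit run report"),
          sprintf("- config hash: `%s`", manifest$config_hash),
          sprintf("- seed: %s", manifest$seed),
          sprintf("- package version: %s", manifest$package_version), "")
  tab <- function(name, title, cols = NULL, max_rows = 15) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    if (!file.exists(path))
      return(c(paste0("## ", title), "", "_not run_", ""))
    df <- read_tsv_header(path)
    if (!is.null(cols)) df <- df[, intersect(cols, names(df)), drop = FALSE]
    if (nrow(df) > max_rows) df <- utils::head(df, max_rows)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    header <- paste("|", paste(names(df), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
    body <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "),
                                           "|"))
    c(paste0("## ", title), "", header, sep, body, "")
  }
  ln <- c(ln,
          tab("isotype_composition", "Isotype composition (per sample)"),
          tab("expansion_summary", "Clonal expansion by response and cluster",
              c("group", "n_cells", "n_expanded_cells", "fraction_expanded",
                "max_size")),
          tab("differential_abundance",
              "Differential abundance (responder vs non-responder)",
              c("category", "log2fc", "p_value", "fdr")),
          tab("tumor_enrichment", "Tumor vs adjacent enrichment"),
          tab("infiltration_scores", "Plasma-cell infiltration (Leiden)"),
          tab("elisa_titers", "ELISA reciprocal titers"),
          tab("elispot_calls", "ELISpot positivity"),
          tab("hit_class_tests", "Seromics hits by class (R vs NR)"))
  writeLines(ln, file)
  invisible(file)
}
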