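## per-cluster isotype usage profiles (rows sum to 1); stand-in values:
## naive/unswitched cells are IgM/IgD, switched memory is IgG/IgA,
## plasmablasts and PCs skew IgG1 with IgG2/IgA admixture
cluster_isotype_profiles <- function() {
  p <- rbind(
    naive_B      = c(IGHM = .60, IGHD = .35, IGHG1 = .01, IGHG2 = .01,
                     IGHG3 = .01, IGHG4 = .00, IGHA1 = .01, IGHA2 = .01,
                     IGHE = .00),
    memory_B     = c(.30, .05, .20, .10, .05, .02, .18, .08, .02),
    activated_B  = c(.25, .05, .25, .10, .05, .02, .18, .08, .02),
    switched_B   = c(.02, .01, .35, .15, .10, .05, .22, .09, .01),
    unswitched_B = c(.55, .35, .02, .02, .02, .00, .02, .02, .00),
    atypical_B   = c(.40, .10, .15, .10, .10, .02, .08, .04, .01),
    plasmablast  = c(.08, .01, .45, .18, .05, .02, .15, .05, .01),
    PC1          = c(.06, .01, .48, .18, .05, .02, .14, .05, .01),
    PC2          = c(.06, .01, .48, .18, .05, .02, .14, .05, .01),
    PC3          = c(.06, .01, .48, .18, .05, .02, .14, .05, .01))
  colnames(p) <- ISOTYPES
  sweep(p, 1, rowSums(p), "/")
}

## draw clone sizes from a discrete power law P(s) ~ s^-gamma truncated at smax
rpowerlaw <- function(n, gamma, smax) {
  s <- seq_len(smax)
  sample(s, n, replace = TRUE, prob = s^(-gamma))
}

non_stop_codons <- function() {
  names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]
}

## random in-frame heavy-chain junction: canonical Cys...Trp, 36-60 nt
random_junctions <- function(n) {
  lens <- sample(seq(36L, 60L, 3L), n, replace = TRUE)
  codons <- non_stop_codons()
  vapply(lens, function(L) {
    mid <- sample(codons, L / 3 - 2, replace = TRUE)
    paste0("TGT", paste(mid, collapse = ""), "TGG")
  }, character(1))
}

IGHV_POOL <- c("IGHV1-2*02", "IGHV1-69*01", "IGHV3-7*01", "IGHV3-23*01",
               "IGHV4-34*01", "IGHV4-59*01", "IGHV5-51*01")
IGHJ_POOL <- paste0("IGHJ", 1:6, "*01")

#' Generate a synthetic cohort: annotation, AIRR rearrangements, IGHC UMIs
#'
#' Draws per-sample cluster-by-isotype compositions from a
#' Dirichlet-multinomial whose IgG1+ plasma-cell (PC1-PC3) mean is shifted
#' by `2^igg1_pc_logfc_R` in responder tumor samples, assigns cells to
#' power-law-sized clonotypes within patient (a configurable fraction of
#' multi-cell clones spans two compartments), and emits an AIRR
#' rearrangement table plus a per-cell IGH constant-region UMI table in
#' which the true isotype dominates (negative-binomial mean 8, dispersion 2,
#' vs Poisson 0.2 background). A ground-truth registry allows exact scoring
#' of every downstream stage.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `cohort_data` with elements `annotation`
#'   (cell metadata), `airr` (AIRR Rearrangement rows), `ighc` (UMI counts,
#'   one row per cell), and `truth` (list: `cells`, `clones`).
#' @export
gen_cohort_repertoire <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  iso_prof <- cluster_isotype_profiles()
  joint <- sweep(iso_prof, 1, spec$cluster_baseline_props, "*")
  base_joint <- as.vector(t(joint))                # cluster-major, 90 cats
  cat_cluster <- rep(CLUSTERS, each = length(ISOTYPES))
  cat_isotype <- rep(ISOTYPES, times = length(CLUSTERS))

  shifted_joint <- base_joint
  idx_igg1_pc <- cat_cluster %in% c("PC1", "PC2", "PC3") &
    cat_isotype == "IGHG1"
  shifted_joint[idx_igg1_pc] <- shifted_joint[idx_igg1_pc] *
    2^spec$igg1_pc_logfc_R
  shifted_joint <- shifted_joint / sum(shifted_joint)

  patients <- c(sprintf("R%02d", seq_len(spec$n_patients_R)),
                sprintf("N%02d", seq_len(spec$n_patients_NR)))
  responses <- rep(c("R", "NR"), c(spec$n_patients_R, spec$n_patients_NR))

  ann <- list(); truth_cells <- list(); airr <- list()
  clone_registry <- list()
  umi_iso <- character(0)

  for (pi in seq_along(patients)) {
    pat <- patients[pi]
    cells <- list()
    for (tis in spec$tissues) for (tp in TIMEPOINTS) {
      p0 <- if (responses[pi] == "R" && tis == "tumor") shifted_joint
            else base_joint
      alpha <- p0 * spec$dirichlet_precision
      g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
      props <- g / sum(g)
      counts <- as.vector(stats::rmultinom(1, spec$cells_per_sample, props))
      keep <- counts > 0
      smp <- paste(pat, tis, tp, sep = "_")
      cells[[smp]] <- data.frame(
        patient = pat, sample = smp, tissue = tis, timepoint = tp,
        response = responses[pi],
        cluster = rep(cat_cluster[keep], counts[keep]),
        isotype = rep(cat_isotype[keep], counts[keep]),
        stringsAsFactors = FALSE)
    }
    pcells <- do.call(rbind, cells)
    pcells <- pcells[sample.int(nrow(pcells)), , drop = FALSE]
    pcells$cell_id <- sprintf("%s_c%05d", pat, seq_len(nrow(pcells)))

    ## clone assignment: consume cells sample-by-sample with power-law sizes
    avail <- split(pcells$cell_id, pcells$sample)
    n_tot <- nrow(pcells)
    sizes <- rpowerlaw(n_tot, spec$clone_size_distribution,
                       spec$cells_per_sample)
    clone_cells <- character(n_tot); clone_of <- character(n_tot); ci <- 0L
    pos <- 0L; k <- 0L
    take <- function(smp, m) {
      ids <- avail[[smp]][seq_len(m)]
      avail[[smp]] <<- avail[[smp]][-seq_len(m)]
      ids
    }
    reg_rows <- list()
    while (any(lengths(avail) > 0)) {
      k <- k + 1L
      s <- if (k <= length(sizes)) sizes[k] else 1L
      open <- names(avail)[lengths(avail) > 0]
      shared <- s >= 2 && length(open) >= 2 &&
        stats::runif(1) < spec$shared_clone_fraction
      ci <- ci + 1L
      cid <- sprintf("%s_cl%05d", pat, ci)
      if (shared) {
        pick <- sample(open, 2, prob = lengths(avail)[open])
        s1 <- min(length(avail[[pick[1]]]), max(1L, s %/% 2))
        s2 <- min(length(avail[[pick[2]]]), max(1L, s - s1))
        ids <- c(take(pick[1], s1), take(pick[2], s2))
      } else {
        pick <- if (length(open) == 1) open else
          sample(open, 1, prob = lengths(avail)[open])
        ids <- take(pick, min(s, length(avail[[pick]])))
      }
      clone_cells[pos + seq_along(ids)] <- ids
      clone_of[pos + seq_along(ids)] <- cid
      pos <- pos + length(ids)
      reg_rows[[ci]] <- data.frame(
        clone_id = cid, patient = pat, size = length(ids),
        shared = shared && length(unique(pick)) == 2,
        stringsAsFactors = FALSE)
    }
    reg <- do.call(rbind, reg_rows)
    reg$junction <- random_junctions(nrow(reg))
    reg$junction_aa <- translate_junction(reg$junction)
    reg$v_call <- sample(IGHV_POOL, nrow(reg), replace = TRUE)
    reg$j_call <- sample(IGHJ_POOL, nrow(reg), replace = TRUE)

    map <- match(pcells$cell_id, clone_cells)
    pcells$clone_id <- clone_of[map]
    ri <- match(pcells$clone_id, reg$clone_id)
    has_c <- stats::runif(nrow(pcells)) < spec$bcr_c_call_fraction
    airr[[pat]] <- data.frame(
      cell_id = pcells$cell_id, locus = "IGH",
      v_call = reg$v_call[ri], j_call = reg$j_call[ri],
      c_call = ifelse(has_c, pcells$isotype, ""),
      junction = reg$junction[ri], junction_aa = reg$junction_aa[ri],
      productive = "T", stringsAsFactors = FALSE)
    ann[[pat]] <- pcells[, c("cell_id", "patient", "sample", "tissue",
                             "timepoint", "cluster", "response")]
    truth_cells[[pat]] <- data.frame(
      cell_id = pcells$cell_id, clone_id = pcells$clone_id,
      true_isotype = pcells$isotype, stringsAsFactors = FALSE)
    clone_registry[[pat]] <- reg
    umi_iso <- c(umi_iso, pcells$isotype)
  }

  annotation <- do.call(rbind, ann); rownames(annotation) <- NULL
  airr_tab <- do.call(rbind, airr); rownames(airr_tab) <- NULL
  truth_cells <- do.call(rbind, truth_cells); rownames(truth_cells) <- NULL
  clones <- do.call(rbind, clone_registry); rownames(clones) <- NULL

  ## IGHC UMI counts: dominant isotype NB(mu 8, size 2), others Poisson(0.2)
  n <- nrow(annotation)
  umi <- matrix(stats::rpois(n * length(ISOTYPES), 0.2), nrow = n,
                dimnames = list(NULL, ISOTYPES))
  dom <- stats::rnbinom(n, size = 2, mu = 8)
  umi[cbind(seq_len(n), match(umi_iso, ISOTYPES))] <- dom
  ighc <- data.frame(cell_id = annotation$cell_id, umi,
                     stringsAsFactors = FALSE)

  structure(list(annotation = annotation, airr = airr_tab, ighc = ighc,
                 truth = list(cells = truth_cells, clones = clones)),
            class = "cohort_data")
}

#' Simulate a composition table with a known group effect
#'
#' Direct Dirichlet-multinomial simulation of per-sample category counts for
#' calibration and power studies of the abundance module: the responder arm's
#' mean proportion for `target` is multiplied by `2^logfc` and the vector
#' renormalized.
#'
#' @param n_per_arm samples per arm (responder / non-responder).
#' @param base_props named baseline mean proportions (sum to 1).
#' @param logfc log2 multiplier applied to `target` in the responder arm.
#' @param target name of the affected category.
#' @param precision Dirichlet concentration.
#' @param n_cells cells per sample.
#' @param seed RNG seed.
#' @return A `composition_table`: integer count matrix (samples x categories)
#'   with a `meta` attribute carrying sample / response metadata.
#' @export
simulate_composition <- function(n_per_arm = 30L,
                                 base_props = c(naive_B = .30, memory_B = .25,
                                                switched_B = .15,
                                                plasmablast = .15,
                                                PC_IgA = .10, PC_IgG1 = .05),
                                 logfc = 1.0, target = "PC_IgG1",
                                 precision = 50, n_cells = 1000L,
                                 seed = 1L) {
  base_props <- check_prob_vector(base_props, "base_props")
  stopifnot(target %in% names(base_props))
  set.seed(seed)
  pR <- base_props
  pR[target] <- pR[target] * 2^logfc
  pR <- pR / sum(pR)
  draw <- function(p, n) {
    t(vapply(seq_len(n), function(i) {
      g <- stats::rgamma(length(p), shape = p * precision, rate = 1)
      as.vector(stats::rmultinom(1, n_cells, g / sum(g)))
    }, numeric(length(p))))
  }
  counts <- rbind(draw(pR, n_per_arm), draw(base_props, n_per_arm))
  colnames(counts) <- names(base_props)
  rownames(counts) <- sprintf("s%02d", seq_len(2 * n_per_arm))
  meta <- data.frame(sample = rownames(counts),
                     response = rep(c("R", "NR"), each = n_per_arm),
                     stringsAsFactors = FALSE)
  composition_table(counts, meta)
}
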