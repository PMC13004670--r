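## strip the allele suffix from a constant-region gene call: "IGHG1*01" -> IGHG1
c_call_gene <- function(x) sub("\\*.*$", "", trimws(x))

#' Assign immunoglobulin isotypes from BCR constant calls with expression rescue
#'
#' Cells with a productive IGH rearrangement carrying a constant-region call
#' (`c_call`) are assigned that isotype (`source = "bcr"`). Cells without a
#' usable `c_call` are rescued from the IGH constant-region UMI table: the
#' argmax IGHC gene is assigned iff its UMI count is at least
#' `rescue_min_umis` and its fraction of total IGHC UMIs is at least
#' `rescue_min_fraction`; ties and sub-threshold cells are `"ambiguous"`.
#' Cells present in neither source of evidence are `"ambiguous"`.
#'
#' @param airr AIRR Rearrangement data.frame (`cell_id`, `locus`, `c_call`,
#'   `productive`; optional `duplicate_count` used to pick among multiple
#'   productive IGH chains).
#' @param ighc data.frame with `cell_id` and one column per IGHC gene
#'   (IGHM, IGHD, IGHG1-4, IGHA1-2, IGHE) of UMI counts.
#' @param rescue_min_umis,rescue_min_fraction rescue thresholds (defaults 3
#'   and 0.6; unstated upstream, chosen so ties and low counts fall out as
#'   ambiguous rather than guessed).
#' @return A list: `calls` (data.frame `cell_id`, `isotype`, `source`,
#'   `dominant_fraction`, `multi_chain`), and `concordance` (BCR isotype x
#'   expression-argmax isotype contingency matrix over cells with both).
#' @export
assign_isotypes <- function(airr, ighc, rescue_min_umis = 3,
                            rescue_min_fraction = 0.6) {
  if ((is.null(airr) || nrow(airr) == 0) &&
      (is.null(ighc) || nrow(ighc) == 0)) {
    return(list(calls = data.frame(cell_id = character(0),
                                   isotype = character(0),
                                   source = character(0),
                                   dominant_fraction = numeric(0),
                                   multi_chain = logical(0)),
                concordance = matrix(0L, 0, 0)))
  }
  airr <- airr[airr$locus == "IGH" &
                 airr$productive %in% c("T", "TRUE", TRUE), , drop = FALSE]
  multi <- character(0)
  if (nrow(airr) > 0 && anyDuplicated(airr$cell_id)) {
    multi <- unique(airr$cell_id[duplicated(airr$cell_id)])
    ord <- if ("duplicate_count" %in% names(airr))
      order(airr$cell_id, -airr$duplicate_count) else seq_len(nrow(airr))
    airr <- airr[ord, , drop = FALSE]
    airr <- airr[!duplicated(airr$cell_id), , drop = FALSE]
  }
  bcr_iso <- c_call_gene(airr$c_call)
  bcr_iso[!(bcr_iso %in% ISOTYPES)] <- NA_character_
  names(bcr_iso) <- airr$cell_id

  umi_mat <- NULL; expr_argmax <- NULL; expr_frac <- NULL
  if (!is.null(ighc) && nrow(ighc) > 0) {
    genes <- intersect(ISOTYPES, names(ighc))
    umi_mat <- as.matrix(ighc[, genes, drop = FALSE])
    rownames(umi_mat) <- ighc$cell_id
    top <- apply(umi_mat, 1, max)
    tot <- rowSums(umi_mat)
    is_tie <- rowSums(umi_mat == top) > 1 & top > 0
    amax <- genes[max.col(umi_mat, ties.method = "first")]
    expr_argmax <- ifelse(top == 0 | is_tie, NA_character_, amax)
    expr_frac <- ifelse(tot > 0, top / tot, NA_real_)
    ok <- !is.na(expr_argmax) & top >= rescue_min_umis &
      expr_frac >= rescue_min_fraction
    names(expr_argmax) <- names(expr_frac) <- ighc$cell_id
    rescue_ok <- ok; names(rescue_ok) <- ighc$cell_id
  }

  cell_ids <- union(airr$cell_id, if (is.null(ighc)) character(0)
                    else ighc$cell_id)
  iso <- rep("ambiguous", length(cell_ids))
  src <- rep("expression_rescue", length(cell_ids))
  domf <- rep(NA_real_, length(cell_ids))
  b <- bcr_iso[cell_ids]
  has_bcr <- !is.na(b)
  iso[has_bcr] <- b[has_bcr]
  src[has_bcr] <- "bcr"
  if (!is.null(umi_mat)) {
    e <- expr_argmax[cell_ids]; f <- expr_frac[cell_ids]
    ok <- rescue_ok[cell_ids]; ok[is.na(ok)] <- FALSE
    use <- !has_bcr & ok
    iso[use] <- e[use]
    domf[!has_bcr & !is.na(f)] <- f[!has_bcr & !is.na(f)]
  }
  src[!has_bcr & iso == "ambiguous" & is.na(domf)] <- "expression_rescue"
  calls <- data.frame(cell_id = cell_ids, isotype = iso, source = src,
                      dominant_fraction = domf,
                      multi_chain = cell_ids %in% multi,
                      stringsAsFactors = FALSE)

  ## validation panel: cells with both a c_call and an expression argmax
  concordance <- matrix(0L, 0, 0)
  if (!is.null(umi_mat)) {
    both <- cell_ids[has_bcr & !is.na(expr_argmax[cell_ids])]
    if (length(both) > 0)
      concordance <- table(bcr = bcr_iso[both],
                           expression = expr_argmax[both])
  }
  list(calls = calls, concordance = concordance)
}

#' Group cells into CDR3-keyed clonotypes within patient
#'
#' One clonotype per distinct (patient, key); the key is the heavy-chain
#' junction at amino-acid or nucleotide resolution, optionally prefixed by
#' V and J gene identity. Grouping never crosses patients.
#'
#' @param airr AIRR Rearrangement data.frame (`cell_id`, `junction`,
#'   `junction_aa`, `v_call`, `j_call`).
#' @param annotation cell annotation data.frame (`cell_id`, `patient`,
#'   `tissue`, `timepoint`, `cluster`).
#' @param key_mode `"junction_aa"` (default), `"junction_nt"` or
#'   `"vj_junction_aa"`.
#' @return A data.frame of class `clonotype_table`: `clone_id`, `patient`,
#'   `key`, `size`, `expanded` (size >= 2), `n_compartments`; the per-cell
#'   assignment is in `attr(, "cells")` (`cell_id`, `clone_id`, plus tissue /
#'   timepoint / cluster metadata).
#' @export
build_clonotypes <- function(airr, annotation,
                             key_mode = c("junction_aa", "junction_nt",
                                          "vj_junction_aa")) {
  key_mode <- match.arg(key_mode)
  df <- merge(airr, annotation, by = "cell_id")
  df <- df[!duplicated(df$cell_id), , drop = FALSE]
  key <- switch(key_mode,
    junction_aa = df$junction_aa,
    junction_nt = df$junction,
    vj_junction_aa = paste(c_call_gene(sub("\\*.*$", "", df$v_call)),
                           sub("\\*.*$", "", df$j_call), df$junction_aa,
                           sep = "|"))
  bad <- is.na(key) | key == ""
  if (key_mode == "junction_nt")
    bad <- bad | grepl("[^ACGT]", key)
  if (any(bad))
    message(sum(bad), " rows skipped (missing or malformed junction)")
  df <- df[!bad, , drop = FALSE]; key <- key[!bad]

  grp <- paste(df$patient, key, sep = "\r")
  ids <- vapply(unique(grp), function(g)
    paste0("cl_", digest::digest(g, algo = "xxhash64", serialize = FALSE)),
    character(1))
  df$clone_id <- ids[match(grp, unique(grp))]
  df$compartment <- paste(df$tissue, df$timepoint, sep = ":")

  sizes <- table(df$clone_id)
  first <- df[!duplicated(df$clone_id), c("clone_id", "patient")]
  ncomp <- tapply(df$compartment, df$clone_id,
                  function(x) length(unique(x)))
  keys <- tapply(key, df$clone_id, function(x) x[1])
  clones <- data.frame(
    clone_id = first$clone_id, patient = first$patient,
    key = as.vector(keys[first$clone_id]),
    size = as.integer(sizes[first$clone_id]),
    n_compartments = as.integer(ncomp[first$clone_id]),
    stringsAsFactors = FALSE)
  clones$expanded <- clones$size >= 2L
  cells_attr <- df[, c("cell_id", "clone_id", "patient", "sample", "tissue",
                       "timepoint", "cluster", "compartment")]
  rownames(clones) <- rownames(cells_attr) <- NULL
  structure(clones, cells = cells_attr, key_mode = key_mode,
            class = c("clonotype_table", "data.frame"))
}

#' Summarize clonal expansion per metadata group
#'
#' `fraction_expanded` is the number of cells belonging to clones of two or
#' more cells divided by all clonotype-assigned cells in the group
#' (expansion is defined at the clone level, over the whole patient, not
#' within the group).
#'
#' @param clonotypes a [build_clonotypes()] result.
#' @param group_by character vector of cell metadata fields (subset of
#'   `patient`, `sample`, `tissue`, `timepoint`, `cluster`, or fields joined
#'   from `annotation`); empty = one overall row.
#' @param annotation optional annotation to supply extra grouping fields
#'   (e.g. `response`).
#' @return data.frame with `n_cells`, `n_expanded_cells`, `fraction_expanded`
#'   (NA when the group is empty) and clone-size quantiles (q50/q75/q90/max)
#'   over distinct clones represented in the group.
#' @export
expansion_summary <- function(clonotypes, group_by = character(0),
                              annotation = NULL) {
  cells <- attr(clonotypes, "cells")
  if (!is.null(annotation)) {
    extra <- setdiff(names(annotation), names(cells))
    cells <- merge(cells, annotation[, c("cell_id", extra), drop = FALSE],
                   by = "cell_id", sort = FALSE)
  }
  cells$clone_size <- clonotypes$size[match(cells$clone_id,
                                            clonotypes$clone_id)]
  grp <- if (length(group_by) == 0) rep("all", nrow(cells)) else
    do.call(paste, c(cells[group_by], sep = "|"))
  out <- lapply(split(seq_len(nrow(cells)), grp), function(ix) {
    sz <- cells$clone_size[ix]
    csz <- cells[ix, c("clone_id", "clone_size")]
    csz <- csz[!duplicated(csz$clone_id), "clone_size"]
    q <- stats::quantile(csz, c(.5, .75, .9, 1), names = FALSE)
    data.frame(n_cells = length(ix), n_clones = length(csz),
               n_expanded_cells = sum(sz >= 2),
               fraction_expanded = sum(sz >= 2) / length(ix),
               q50 = q[1], q75 = q[2], q90 = q[3], max_size = q[4])
  })
  res <- do.call(rbind, out)
  res <- cbind(group = names(out), res)
  rownames(res) <- NULL
  res
}

#' Track clones shared across tissue/timepoint compartments
#'
#' Keeps only clones observed in two or more (tissue, timepoint)
#' compartments of a patient and reports their per-compartment sizes, to
#' support trafficking (lymph node vs tumor) and persistence (pre vs post)
#' queries.
#'
#' @param clonotypes a [build_clonotypes()] result.
#' @return data.frame of class `clone_track`: `clone_id`, `patient`,
#'   `tissue`, `timepoint`, `n_cells`, `n_compartments` (long format; zero
#'   rows if nothing is shared).
#' @export
track_shared_clones <- function(clonotypes) {
  cells <- attr(clonotypes, "cells")
  shared <- clonotypes$clone_id[clonotypes$n_compartments >= 2]
  cells <- cells[cells$clone_id %in% shared, , drop = FALSE]
  if (nrow(cells) == 0) {
    return(structure(data.frame(clone_id = character(0),
                                patient = character(0), tissue = character(0),
                                timepoint = character(0),
                                n_cells = integer(0),
                                n_compartments = integer(0)),
                     class = c("clone_track", "data.frame")))
  }
  agg <- stats::aggregate(cell_id ~ clone_id + patient + tissue + timepoint,
                          data = cells, FUN = length)
  names(agg)[names(agg) == "cell_id"] <- "n_cells"
  agg$n_compartments <- clonotypes$n_compartments[
    match(agg$clone_id, clonotypes$clone_id)]
  agg <- agg[order(agg$clone_id, agg$tissue, agg$timepoint), ]
  rownames(agg) <- NULL
  structure(agg, class = c("clone_track", "data.frame"))
}

#' Clones shared between two levels of a compartment field
#'
#' @param track a [track_shared_clones()] result.
#' @param field `"tissue"` or `"timepoint"`.
#' @param levels two levels, e.g. `c("lymph_node", "tumor")` or
#'   `c("pre", "post")`.
#' @return character vector of clone ids present at both levels.
#' @export
clones_shared_between <- function(track, field, levels) {
  stopifnot(field %in% c("tissue", "timepoint"), length(levels) == 2)
  a <- unique(track$clone_id[track[[field]] == levels[1]])
  b <- unique(track$clone_id[track[[field]] == levels[2]])
  intersect(a, b)
}

#' Isotype composition per stratum
#'
#' Per-stratum proportions over the nine isotypes plus an explicit
#' `ambiguous` column; rows sum to 1. Strata with zero cells are omitted.
#'
#' @param annotation cell annotation (`cell_id` plus stratification fields).
#' @param isotype_calls `calls` data.frame from [assign_isotypes()]; every
#'   annotated cell must have exactly one call.
#' @param stratify_by character vector of annotation fields.
#' @return data.frame: stratification fields, `n_cells`, one proportion
#'   column per isotype and `ambiguous`.
#' @export
isotype_composition <- function(annotation, isotype_calls,
                                stratify_by = "sample") {
  m <- merge(annotation, isotype_calls[, c("cell_id", "isotype")],
             by = "cell_id")
  if (nrow(m) < nrow(annotation))
    stop("every annotated cell needs an isotype call; ",
         nrow(annotation) - nrow(m), " cells are missing one", call. = FALSE)
  lv <- c(ISOTYPES, "ambiguous")
  grp <- do.call(paste, c(m[stratify_by], sep = "|"))
  tab <- table(grp, factor(m$isotype, levels = lv))
  props <- sweep(tab, 1, rowSums(tab), "/")
  keys <- do.call(rbind, strsplit(rownames(tab), "|", fixed = TRUE))
  out <- data.frame(keys, n_cells = as.integer(rowSums(tab)),
                    as.data.frame.matrix(props), stringsAsFactors = FALSE)
  names(out)[seq_along(stratify_by)] <- stratify_by
  ## deterministic order regardless of input row order
  out <- out[order(do.call(paste, c(out[stratify_by], sep = "|"))), ]
  rownames(out) <- NULL
  out
}
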