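#' Generate synthetic ELISA, ELISpot and seromics data
#'
#' ELISA readouts are linear in log10(reciprocal dilution) and cross
#' `cutoff_readout` exactly at the true reciprocal titer before noise;
#' negative-control wells are centered at `cutoff_readout - 3 * noise_sd`, so
#' the default downstream cutoff rule (negative mean + 3 SD) recovers the
#' construction cutoff in expectation and exactly when `readout_noise_sd = 0`.
#' Seronegative curves sit 0.3 readout units below the cutoff at every
#' dilution. ELISpot wells are Poisson around configured means. The seromics
#' matrix carries duplicate spots per antigen around a log-normal baseline,
#' with per-sample hit antigens elevated eightfold; hit counts per class are
#' Poisson with arm-specific means so responders carry more CTA hits.
#'
#' @param spec a [serology_spec()].
#' @return A list of class `serology_data`: `elisa` (long plate table),
#'   `elispot` (well counts), `seromics` (long duplicate-spot table) and
#'   `truth` (true titers and the per-sample hit antigen registry).
#' @export
gen_serology <- function(spec) {
  stopifnot(inherits(spec, "serology_spec"))
  set.seed(spec$seed)
  dil <- spec$dilutions
  sd0 <- spec$readout_noise_sd
  cutoff <- spec$cutoff_readout

  ## ---- ELISA titration plates ----
  tt <- spec$true_titers
  rows <- list()
  for (i in seq_len(nrow(tt))) {
    t_i <- tt$titer[i]
    extrap <- !is.na(t_i) && (t_i <= min(dil) / 4 || t_i >= max(dil) * 4)
    mu <- if (is.na(t_i)) rep(cutoff - 0.3, length(dil)) else
      cutoff + spec$slope_per_log10 * (log10(t_i) - log10(dil))
    rows[[i]] <- data.frame(
      sample = tt$sample[i], antigen = tt$antigen[i], dilution = dil,
      readout = mu + stats::rnorm(length(dil), 0, sd0),
      is_negative_control = FALSE, is_positive_control = FALSE,
      extrapolation_risk = extrap, stringsAsFactors = FALSE)
    if (extrap)
      warning(sprintf("true titer %g for (%s, %s) is outside the reliable ",
                      t_i, tt$sample[i], tt$antigen[i]),
              "titration range; curve flagged extrapolation_risk",
              call. = FALSE)
  }
  neg_mean <- cutoff - 3 * sd0
  for (ag in unique(tt$antigen)) {
    for (rep_i in 1:8) {
      rows[[length(rows) + 1]] <- data.frame(
        sample = sprintf("NEG_POOL_%d", rep_i), antigen = ag, dilution = dil,
        readout = neg_mean + stats::rnorm(length(dil), 0, sd0),
        is_negative_control = TRUE, is_positive_control = FALSE,
        extrapolation_risk = FALSE, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1]] <- data.frame(
      sample = "POS_POOL", antigen = ag, dilution = dil,
      readout = cutoff + spec$slope_per_log10 *
        (log10(max(dil) * 4) - log10(dil)) +
        stats::rnorm(length(dil), 0, sd0),
      is_negative_control = FALSE, is_positive_control = TRUE,
      extrapolation_risk = FALSE, stringsAsFactors = FALSE)
  }
  elisa <- do.call(rbind, rows); rownames(elisa) <- NULL

  ## ---- ELISpot wells (3 replicate wells per condition + background) ----
  conds <- names(spec$elispot_means)
  elispot <- data.frame(
    condition = rep(c(conds, "DMSO"), each = 3),
    well = rep(1:3, length(conds) + 1),
    spots = c(stats::rpois(3 * length(conds),
                           rep(spec$elispot_means, each = 3)),
              stats::rpois(3, spec$elispot_background_mean)),
    is_background = rep(c(FALSE, TRUE), c(3 * length(conds), 3)),
    stringsAsFactors = FALSE)

  ## ---- seromics duplicate-spot arrays ----
  classes <- rep(names(spec$n_antigens_by_class), spec$n_antigens_by_class)
  antigens <- sprintf("%s_%03d", classes, unlist(lapply(
    spec$n_antigens_by_class, seq_len)))
  neg_ids <- sprintf("NEGCTRL_%03d", seq_len(spec$n_neg_control_antigens))
  all_ag <- c(antigens, neg_ids)
  all_cls <- c(classes, rep("control", length(neg_ids)))
  is_neg <- c(rep(FALSE, length(antigens)), rep(TRUE, length(neg_ids)))

  samples <- c(sprintf("R%02d", seq_len(spec$n_samples_R)),
               sprintf("N%02d", seq_len(spec$n_samples_NR)))
  resp <- rep(c("R", "NR"), c(spec$n_samples_R, spec$n_samples_NR))
  sero <- list(); hit_reg <- list()
  for (ch in c("IgG", "IgA")) for (tp in TIMEPOINTS) {
    for (si in seq_along(samples)) {
      mean_hits <- if (resp[si] == "R") spec$hit_mean_R else spec$hit_mean_NR
      ## hits appear on-treatment; pretreatment arrays carry half the load
      scale_tp <- if (tp == "pre") 0.5 else 1
      hit_ag <- character(0)
      for (cl in names(spec$n_antigens_by_class)) {
        nh <- stats::rpois(1, mean_hits[[cl]] * scale_tp)
        nh <- min(nh, spec$n_antigens_by_class[[cl]])
        if (nh > 0)
          hit_ag <- c(hit_ag, sample(antigens[classes == cl], nh))
      }
      base <- stats::rlnorm(length(all_ag), log(1000), 0.3)
      base[match(hit_ag, all_ag)] <- base[match(hit_ag, all_ag)] * 8
      s1 <- base * stats::rlnorm(length(all_ag), 0, 0.05)
      s2 <- base * stats::rlnorm(length(all_ag), 0, 0.05)
      sero[[length(sero) + 1]] <- data.frame(
        antigen = all_ag, class = all_cls, is_negative_control = is_neg,
        sample = samples[si], response = resp[si], channel = ch,
        timepoint = tp, intensity_1 = s1, intensity_2 = s2,
        stringsAsFactors = FALSE)
      hit_reg[[length(hit_reg) + 1]] <- if (length(hit_ag)) data.frame(
        sample = samples[si], channel = ch, timepoint = tp,
        antigen = hit_ag, stringsAsFactors = FALSE) else NULL
    }
  }
  seromics <- do.call(rbind, sero); rownames(seromics) <- NULL
  hit_registry <- do.call(rbind, hit_reg)

  structure(list(elisa = elisa, elispot = elispot, seromics = seromics,
                 truth = list(titers = tt, hits = hit_registry)),
            class = "serology_data")
}
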