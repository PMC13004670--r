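#' Default ELISA cutoff rule: negative-control mean + 3 SD
#'
#' Pooled over dilutions; SD is 0 when only one control readout exists.
#' @param negative_readouts numeric vector of negative-control readouts.
#' @return cutoff value.
#' @export
cutoff_mean_3sd <- function(negative_readouts) {
  if (length(negative_readouts) == 0)
    stop("cutoff rule needs negative-control readouts", call. = FALSE)
  s <- if (length(negative_readouts) > 1) stats::sd(negative_readouts) else 0
  mean(negative_readouts) + 3 * s
}

#' Interpolate a reciprocal endpoint titer from a titration curve
#'
#' Fits `readout ~ a + b log10(reciprocal dilution)` by least squares and
#' reports the dilution at which the fitted line meets the cutoff:
#' `titer = 10^((cutoff - a) / b)`. Crossings outside
#' `[min(dilutions)/2, 2 max(dilutions)]` are clipped to the bound and
#' flagged `extrapolated_low` / `extrapolated_high`. If every readout is
#' below the cutoff the titer is 0 (`method = "none"`); a non-negative
#' slope also yields `"none"` with a diagnostic flag. A sample is
#' seropositive iff its reciprocal titer exceeds 100.
#'
#' @param dilutions reciprocal dilutions (>= 2 values).
#' @param readouts matched readouts.
#' @param negative_readouts negative-control readouts used by `cutoff_rule`
#'   (ignored when `cutoff` is given).
#' @param cutoff optional explicit cutoff value.
#' @param cutoff_rule function of the negative readouts (default
#'   [cutoff_mean_3sd()]).
#' @return list of class `titer_result`: `reciprocal_titer`, `method`
#'   (`interpolated`, `extrapolated_low`, `extrapolated_high`, `none`),
#'   `positive`, `cutoff`, `slope`, `intercept`, `flag`.
#' @export
reciprocal_titer <- function(dilutions, readouts, negative_readouts = NULL,
                             cutoff = NULL, cutoff_rule = cutoff_mean_3sd) {
  stopifnot(length(dilutions) >= 2, length(dilutions) == length(readouts),
            all(diff(dilutions) > 0))
  if (is.null(cutoff)) cutoff <- cutoff_rule(negative_readouts)
  lx <- log10(dilutions)
  b <- stats::cov(lx, readouts) / stats::var(lx)
  a <- mean(readouts) - b * mean(lx)
  lo <- min(dilutions) / 2; hi <- max(dilutions) * 2
  res <- function(titer, method, flag = NA_character_) {
    structure(list(reciprocal_titer = titer, method = method,
                   positive = titer > 100, cutoff = cutoff, slope = b,
                   intercept = a, flag = flag), class = "titer_result")
  }
  if (max(readouts) < cutoff) return(res(0, "none"))
  if (b >= 0) return(res(0, "none", "non-decreasing titration curve"))
  titer <- 10^((cutoff - a) / b)
  if (titer < lo) return(res(lo, "extrapolated_low"))
  if (titer > hi) return(res(hi, "extrapolated_high"))
  res(titer, "interpolated")
}

#' @export
print.titer_result <- function(x, ...) {
  cat(sprintf("<titer_result> reciprocal titer %.4g (%s), %s\n",
              x$reciprocal_titer, x$method,
              if (x$positive) "POSITIVE (> 100)" else "negative"))
  invisible(x)
}

#' Titers for every (sample, antigen) curve in a long ELISA table
#'
#' Negative-control rows (pooled per antigen, all dilutions) supply the
#' cutoff for that antigen's curves.
#'
#' @param elisa long data.frame: `sample`, `antigen`, `dilution`, `readout`,
#'   `is_negative_control` (logical).
#' @param cutoff_rule see [reciprocal_titer()].
#' @return data.frame: `sample`, `antigen`, `reciprocal_titer`, `method`,
#'   `positive`, `cutoff`.
#' @export
titer_table <- function(elisa, cutoff_rule = cutoff_mean_3sd) {
  need <- c("sample", "antigen", "dilution", "readout",
            "is_negative_control")
  stopifnot(all(need %in% names(elisa)))
  pos_flag <- if ("is_positive_control" %in% names(elisa))
    elisa$is_positive_control else rep(FALSE, nrow(elisa))
  out <- list()
  for (ag in unique(elisa$antigen)) {
    sub <- elisa[elisa$antigen == ag, , drop = FALSE]
    neg <- sub$readout[sub$is_negative_control]
    test <- sub[!sub$is_negative_control &
                  !(pos_flag[elisa$antigen == ag]), , drop = FALSE]
    for (s in unique(test$sample)) {
      cur <- test[test$sample == s, , drop = FALSE]
      cur <- cur[order(cur$dilution), ]
      tr <- reciprocal_titer(cur$dilution, cur$readout,
                             negative_readouts = neg,
                             cutoff_rule = cutoff_rule)
      out[[paste(s, ag)]] <- data.frame(
        sample = s, antigen = ag,
        reciprocal_titer = tr$reciprocal_titer, method = tr$method,
        positive = tr$positive, cutoff = tr$cutoff,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' ELISpot positivity rule
#'
#' Positive iff the mean test-well count exceeds `min_spots` (default 50)
#' AND is at least twice the mean background (non-pulsed/DMSO) count. A
#' sanity flag is raised when the background mean exceeds 3 spots per well
#' (background should be near-empty in a valid assay).
#'
#' @param well_counts integer spot counts of the test wells.
#' @param background_counts integer spot counts of the background wells
#'   (required).
#' @param min_spots threshold on the test mean (default 50).
#' @return list: `positive`, `mean_test`, `mean_background`,
#'   `background_flag`.
#' @export
elispot_positive <- function(well_counts, background_counts,
                             min_spots = 50) {
  if (length(background_counts) == 0)
    stop("ELISpot positivity is undefined without background wells",
         call. = FALSE)
  stopifnot(all(well_counts >= 0), all(background_counts >= 0))
  mt <- mean(well_counts); mb <- mean(background_counts)
  list(positive = (mt > min_spots) && (mt >= 2 * mb),
       mean_test = mt, mean_background = mb,
       background_flag = mb > 3)
}

#' Seromics autoantibody hit calling
#'
#' Per array (one `sample` x `channel` x `timepoint` combination):
#' duplicate spots are z-scored on the log-intensity scale against the
#' array's negative-control spot distribution (median / MAD; log-scale
#' scoring keeps a skewed, roughly log-normal baseline from flooding the
#' upper tail); an antigen is a hit iff BOTH duplicates reach
#' `z_threshold`. Duplicates are then collapsed by median and arrays
#' quantile-normalized within channel; the reported `z_score` is the
#' collapsed, normalized log signal against the normalized control null.
#' Arrays with fewer than 10 negative-control antigens are refused.
#'
#' @param seromics long data.frame: `antigen`, `class`,
#'   `is_negative_control`, `sample`, `channel`, `intensity_1`,
#'   `intensity_2`, optional `timepoint`, `response`.
#' @param z_threshold robust z cutoff (default 3).
#' @return data.frame of class `seromics_hits`: antigen/class/array keys,
#'   `normalized_signal`, `z_score`, `hit`.
#' @export
seromics_hits <- function(seromics, z_threshold = 3) {
  keys <- intersect(c("sample", "channel", "timepoint"), names(seromics))
  arr <- do.call(paste, c(seromics[keys], sep = "|"))
  antigens <- sort(unique(seromics$antigen))
  arrays <- unique(arr)

  ## per-array duplicate-level hit rule against the raw control null
  hit <- logical(nrow(seromics))
  for (a in arrays) {
    ix <- which(arr == a)
    neg <- seromics$is_negative_control[ix]
    if (sum(neg) < 10)
      stop("array ", a, " has fewer than 10 negative controls; ",
           "null distribution unstable", call. = FALSE)
    null_vals <- log(c(seromics$intensity_1[ix][neg],
                       seromics$intensity_2[ix][neg]))
    med <- stats::median(null_vals)
    mad0 <- stats::mad(null_vals)
    if (mad0 == 0) mad0 <- .Machine$double.eps
    z1 <- (log(seromics$intensity_1[ix]) - med) / mad0
    z2 <- (log(seromics$intensity_2[ix]) - med) / mad0
    hit[ix] <- z1 >= z_threshold & z2 >= z_threshold
  }

  ## collapsed matrix antigen x array, quantile-normalized within channel
  collapsed <- (pmin(seromics$intensity_1, seromics$intensity_2) +
                  pmax(seromics$intensity_1, seromics$intensity_2)) / 2
  mat <- matrix(NA_real_, length(antigens), length(arrays),
                dimnames = list(antigens, arrays))
  mat[cbind(match(seromics$antigen, antigens), match(arr, arrays))] <-
    collapsed
  ch_of_array <- seromics$channel[match(arrays, arr)]
  for (ch in unique(ch_of_array)) {
    cols <- which(ch_of_array == ch)
    mat[, cols] <- quantile_normalize(mat[, cols, drop = FALSE])
  }
  is_neg_ag <- seromics$is_negative_control[match(antigens,
                                                  seromics$antigen)]
  zmat <- log(mat)
  for (j in seq_len(ncol(mat))) {
    nv <- log(mat[is_neg_ag, j])
    md <- stats::median(nv); md_mad <- max(stats::mad(nv),
                                           .Machine$double.eps)
    zmat[, j] <- (log(mat[, j]) - md) / md_mad
  }

  flat_idx <- cbind(match(seromics$antigen, antigens), match(arr, arrays))
  out <- seromics[, c("antigen", "class", "is_negative_control", keys)]
  out$normalized_signal <- mat[flat_idx]
  out$z_score <- zmat[flat_idx]
  out$hit <- hit & !seromics$is_negative_control
  if ("response" %in% names(seromics)) out$response <- seromics$response
  ## order-invariant output
  out <- out[order(do.call(paste, c(out[keys], list(out$antigen)))), ]
  rownames(out) <- NULL
  structure(out, class = c("seromics_hits", "data.frame"))
}

#' Per-patient per-class hit counts with group tests
#'
#' Counts hit antigens per sample / timepoint / channel / antigen class,
#' compares responders vs non-responders per class and channel with the
#' two-sided Wilcoxon rank-sum test, and reports post-minus-pre deltas per
#' sample (NA when a timepoint is missing).
#'
#' @param hits a [seromics_hits()] result carrying `response` and
#'   `timepoint` columns.
#' @param test_timepoint timepoint at which groups are compared
#'   (default `"post"`).
#' @return list: `counts` (long data.frame), `tests` (class x channel
#'   p-values), `deltas`.
#' @export
hit_class_summary <- function(hits, test_timepoint = "post") {
  stopifnot(all(c("response", "timepoint") %in% names(hits)))
  df <- hits[!hits$is_negative_control, , drop = FALSE]
  classes <- setdiff(unique(df$class), "control")
  grid <- unique(df[, c("sample", "response", "channel", "timepoint")])
  counts <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sel <- df$sample == g$sample & df$channel == g$channel &
      df$timepoint == g$timepoint
    data.frame(g, class = classes,
               n_hits = vapply(classes, function(cl)
                 sum(df$hit[sel & df$class == cl]), numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  tests <- do.call(rbind, lapply(unique(counts$channel), function(ch) {
    do.call(rbind, lapply(classes, function(cl) {
      sub <- counts[counts$channel == ch & counts$class == cl &
                      counts$timepoint == test_timepoint, ]
      xr <- sub$n_hits[sub$response == "R"]
      xn <- sub$n_hits[sub$response == "NR"]
      p <- if (length(xr) && length(xn)) {
        if (all(c(xr, xn) == c(xr, xn)[1])) 1 else
          stats::wilcox.test(xr, xn, exact = FALSE)$p.value
      } else NA_real_
      data.frame(channel = ch, class = cl, mean_R = mean(xr),
                 mean_NR = mean(xn), p_value = p, stringsAsFactors = FALSE)
    }))
  }))
  rownames(tests) <- NULL
  deltas <- do.call(rbind, lapply(
    split(counts, counts[, c("sample", "channel", "class")], drop = TRUE),
    function(s) {
      pre <- s$n_hits[s$timepoint == "pre"]
      post <- s$n_hits[s$timepoint == "post"]
      data.frame(sample = s$sample[1], channel = s$channel[1],
                 class = s$class[1],
                 delta = if (length(pre) == 1 && length(post) == 1)
                   post - pre else NA_real_, stringsAsFactors = FALSE)
    }))
  rownames(deltas) <- NULL
  list(counts = counts, tests = tests, deltas = deltas)
}
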