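#' Construct a composition table
#'
#' @param counts integer matrix, samples x categories, non-negative.
#' @param meta data.frame of per-sample metadata (`sample` plus any of
#'   `patient`, `tissue`, `timepoint`, `response`), rows aligned with
#'   `counts`.
#' @return `composition_table` object (the count matrix with a `meta`
#'   attribute).
#' @export
composition_table <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (nrow(counts) != nrow(meta))
    stop("meta must have one row per sample", call. = FALSE)
  structure(counts, meta = meta, class = c("composition_table", "matrix"))
}

#' Build a composition table from cell annotation
#'
#' @param annotation cell table with `sample`, `cluster` and per-sample
#'   metadata fields.
#' @param isotype_calls optional [assign_isotypes()] `calls`; when given,
#'   categories are cluster x isotype (ambiguous cells dropped).
#' @param by `"cluster"` or `"cluster_isotype"`.
#' @return a [composition_table()].
#' @export
composition_from_annotation <- function(annotation, isotype_calls = NULL,
                                        by = c("cluster",
                                               "cluster_isotype")) {
  by <- match.arg(by)
  df <- annotation
  if (by == "cluster_isotype") {
    stopifnot(!is.null(isotype_calls))
    df <- merge(df, isotype_calls[, c("cell_id", "isotype")], by = "cell_id")
    df <- df[df$isotype != "ambiguous", , drop = FALSE]
    df$category <- paste(df$cluster, df$isotype, sep = ".")
  } else df$category <- df$cluster
  tab <- table(df$sample, df$category)
  meta_fields <- intersect(c("sample", "patient", "tissue", "timepoint",
                             "response"), names(annotation))
  meta <- unique(annotation[, meta_fields, drop = FALSE])
  meta <- meta[match(rownames(tab), meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  composition_table(unclass(as.matrix(tab)), meta)
}

#' Smooth raw proportions away from the simplex boundary
#'
#' Applies `y* = (y (n - 1) + 1/K) / n` per sample, where `n` is the sample's
#' total cell count and `K` the number of categories, yielding strictly
#' interior proportions that still sum to 1 (required by the Dirichlet
#' likelihood). Zero-count samples are dropped with a message.
#'
#' @param composition a [composition_table()] or plain count matrix.
#' @return numeric matrix of smoothed proportions (same metadata attribute
#'   if present).
#' @export
proportions_from_counts <- function(composition) {
  counts <- unclass(composition)
  ns <- rowSums(counts)
  drop <- ns == 0
  if (any(drop)) {
    message(sum(drop), " zero-count samples dropped")
    counts <- counts[!drop, , drop = FALSE]; ns <- ns[!drop]
  }
  K <- ncol(counts)
  y <- sweep(counts, 1, ns, "/")
  ystar <- sweep(y, 1, (ns - 1) / ns, "*") + 1 / (K * ns)
  meta <- attr(composition, "meta")
  if (!is.null(meta)) attr(ystar, "meta") <- meta[!drop, , drop = FALSE]
  ystar
}

#' Dirichlet log-likelihood of interior proportions
#'
#' @param Y matrix of proportions (rows strictly interior, summing to 1).
#' @param alpha matrix of positive concentrations, same shape (or a single
#'   vector recycled across rows).
#' @return total log-likelihood.
#' @export
dirichlet_loglik <- function(Y, alpha) {
  if (is.vector(alpha))
    alpha <- matrix(alpha, nrow(Y), length(alpha), byrow = TRUE)
  sum(lgamma(rowSums(alpha)) - rowSums(lgamma(alpha)) +
        rowSums((alpha - 1) * log(Y)))
}

#' Fit a Dirichlet regression with log-linear concentrations
#'
#' Maximizes the Dirichlet likelihood with `log(alpha_ic) = sum_k beta_kc
#' x_ik` (common parameterization, log link on every concentration) by BFGS
#' with the analytic digamma gradient. Intercepts are initialized by method
#' of moments; all other coefficients start at zero.
#'
#' @param Y strictly interior proportion matrix (n x K).
#' @param X design matrix (n x P) including an intercept column.
#' @param max_iter,gtol optimizer budget and gradient tolerance.
#' @return object of class `dirichlet_fit`: `beta` (P x K), `loglik`,
#'   `converged`, `n_iter`, `vcov` (for Wald tests), `covariate_names`,
#'   `categories`.
#' @export
fit_dirichlet_regression <- function(Y, X, max_iter = 500, gtol = 1e-8) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  stopifnot(nrow(Y) == nrow(X), all(Y > 0), all(Y < 1))
  ## all-zero columns are allowed (their coefficients stay pinned at 0);
  ## any other collinearity is refused
  nz <- colSums(X != 0) > 0
  if (qr(X[, nz, drop = FALSE])$rank < sum(nz))
    stop("design matrix is rank deficient", call. = FALSE)
  n <- nrow(Y); K <- ncol(Y); P <- ncol(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(P - 1)))[seq_len(P)]
  if (is.null(colnames(Y))) colnames(Y) <- paste0("cat", seq_len(K))
  logY <- log(Y)

  negll <- function(par) {
    beta <- matrix(par, P, K)
    alpha <- exp(X %*% beta)
    -(sum(lgamma(rowSums(alpha))) - sum(lgamma(alpha)) +
        sum((alpha - 1) * logY))
  }
  neggr <- function(par) {
    beta <- matrix(par, P, K)
    alpha <- exp(X %*% beta)
    dl_dalpha <- digamma(rowSums(alpha)) - digamma(alpha) + logY
    -as.vector(crossprod(X, dl_dalpha * alpha))
  }

  ## method-of-moments start for the intercepts
  m <- colMeans(Y)
  v <- apply(Y, 2, stats::var)
  a0 <- m * (1 - m) / pmax(v, 1e-8) - 1
  a0 <- stats::median(a0[a0 > 0])
  if (!is.finite(a0) || a0 <= 0) a0 <- 10
  beta0 <- matrix(0, P, K)
  icol <- which(apply(X, 2, function(col) all(col == 1)))[1]
  if (is.na(icol)) icol <- 1L
  beta0[icol, ] <- log(m * a0)

  opt <- stats::optim(as.vector(beta0), negll, neggr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  grad_norm <- max(abs(neggr(opt$par)))
  hess <- stats::optimHess(opt$par, negll, neggr)
  vc <- tryCatch(solve(hess), error = function(e) matrix(NA_real_,
                                                         length(opt$par),
                                                         length(opt$par)))
  beta <- matrix(opt$par, P, K,
                 dimnames = list(colnames(X), colnames(Y)))
  structure(list(beta = beta, loglik = -opt$value,
                 converged = opt$convergence == 0 && is.finite(opt$value),
                 n_iter = opt$counts[["function"]],
                 grad_norm = grad_norm, gtol = gtol,
                 vcov = vc, covariate_names = colnames(X),
                 categories = colnames(Y)), class = "dirichlet_fit")
}

#' @export
print.dirichlet_fit <- function(x, ...) {
  cat(sprintf("<dirichlet_fit> %d categories, covariates: %s\n  loglik = %.3f, converged = %s (%d evals)\n",
              length(x$categories), paste(x$covariate_names, collapse = ", "),
              x$loglik, x$converged, x$n_iter))
  invisible(x)
}

## fitted mean proportions at a covariate vector
fitted_props <- function(fit, x) {
  alpha <- exp(as.vector(x %*% fit$beta))
  alpha / sum(alpha)
}

#' Likelihood-ratio test and per-category effects for a covariate
#'
#' Global significance comes from the likelihood-ratio statistic
#' `2 (ll_full - ll_null)` on K degrees of freedom (one coefficient per
#' category). Per-category `log2fc` compares fitted mean proportions at
#' `tested = 1` vs `tested = 0` (all other non-intercept covariates at 0);
#' per-category p-values are Wald tests on the covariate's coefficients,
#' Benjamini-Hochberg adjusted across categories.
#'
#' @param full,null converged [fit_dirichlet_regression()] fits; `null` must
#'   be `full` without the tested covariate.
#' @param tested_covariate name of the covariate column being tested.
#' @return data.frame of class `abundance_result` (one row per category:
#'   `category`, `log2fc`, `lrt_stat`, `df`, `lrt_p`, `p_value`, `fdr`), with
#'   the global test in attributes `lrt_stat` / `lrt_p`.
#' @export
lrt_and_fdr <- function(full, null, tested_covariate) {
  stopifnot(inherits(full, "dirichlet_fit"), inherits(null, "dirichlet_fit"))
  if (!full$converged || !null$converged)
    stop("refusing to test non-converged fits", call. = FALSE)
  if (!(tested_covariate %in% full$covariate_names))
    stop("tested covariate not in the full model", call. = FALSE)
  if (!setequal(null$covariate_names,
                setdiff(full$covariate_names, tested_covariate)))
    stop("null model must equal the full model minus the tested covariate",
         call. = FALSE)
  ll_diff <- full$loglik - null$loglik
  if (ll_diff < -1e-6)
    stop("optimizer failure: nested null model has higher likelihood",
         call. = FALSE)
  K <- length(full$categories)
  stat <- max(0, 2 * ll_diff)
  p_global <- stats::pchisq(stat, df = K, lower.tail = FALSE)

  P <- length(full$covariate_names)
  ti <- match(tested_covariate, full$covariate_names)
  ii <- match("(Intercept)", full$covariate_names)
  if (is.na(ii)) ii <- 1L
  x0 <- numeric(P); x0[ii] <- 1
  x1 <- x0; x1[ti] <- 1
  p1 <- fitted_props(full, x1); p0 <- fitted_props(full, x0)
  log2fc <- log2(p1 / p0)

  idx <- (seq_len(K) - 1) * P + ti  # beta stored column-major P x K
  se <- sqrt(diag(full$vcov)[idx])
  z <- full$beta[ti, ] / se
  wald_p <- 2 * stats::pnorm(-abs(z))
  fdr <- stats::p.adjust(wald_p, method = "BH")
  res <- data.frame(category = full$categories, log2fc = log2fc,
                    lrt_stat = stat, df = K, lrt_p = p_global,
                    p_value = wald_p, fdr = fdr, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, lrt_stat = stat, lrt_p = p_global,
            class = c("abundance_result", "data.frame"))
}

#' Compare a composition between two groups with Dirichlet regression
#'
#' Convenience wrapper: smooths counts, fits full (intercept + group) and
#' null (intercept-only) models and runs [lrt_and_fdr()].
#'
#' @param composition a [composition_table()].
#' @param group_field metadata field with exactly two levels.
#' @param ref_level level coded 0 (default: the second sorted level).
#' @return an `abundance_result` (see [lrt_and_fdr()]).
#' @export
differential_abundance <- function(composition, group_field = "response",
                                   ref_level = NULL) {
  Y <- proportions_from_counts(composition)
  meta <- attr(Y, "meta")
  g <- meta[[group_field]]
  lv <- sort(unique(g))
  if (length(lv) != 2) stop("group field must have two levels", call. = FALSE)
  if (is.null(ref_level)) ref_level <- lv[2]
  x <- as.numeric(g != ref_level)
  X_full <- cbind("(Intercept)" = 1, group = x)
  X_null <- cbind("(Intercept)" = rep(1, length(x)))
  full <- fit_dirichlet_regression(Y, X_full)
  null <- fit_dirichlet_regression(Y, X_null)
  lrt_and_fdr(full, null, "group")
}

#' Exact/approximate two-sided Wilcoxon signed-rank test
#'
#' Mid-ranks of |x| after dropping zeros; the null distribution of the
#' positive-rank sum is computed exactly by dynamic programming over sign
#' patterns (tie-aware) for `n <= exact_max`, otherwise by normal
#' approximation with continuity and tie corrections.
#'
#' @param x numeric vector of paired differences / scores.
#' @param exact_max exact-enumeration limit (default 25).
#' @return list with `statistic` (positive-rank sum), `p_value`, `n`,
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(x, exact_max = 25) {
  x <- x[!is.na(x) & x != 0]
  n <- length(x)
  if (n == 0) return(list(statistic = NA_real_, p_value = 1, n = 0L,
                          method = "degenerate"))
  r <- rank(abs(x))
  W <- sum(r[x > 0])
  if (n <= exact_max) {
    ## DP over doubled ranks keeps everything integer despite midranks
    w2 <- round(2 * r)
    tot <- sum(w2)
    f <- numeric(tot + 1); f[1] <- 1
    for (v in w2) {
      g <- f
      g[(v + 1):(tot + 1)] <- g[(v + 1):(tot + 1)] + f[1:(tot + 1 - v)]
      f <- g
    }
    f <- f / 2^n
    w2obs <- round(2 * W)
    p_le <- sum(f[1:(w2obs + 1)])
    p_ge <- sum(f[(w2obs + 1):(tot + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(statistic = W, p_value = p, n = n, method = method)
}

#' Tumor vs adjacent-tissue enrichment per cluster
#'
#' For each patient with both tumor and adjacent samples, computes
#' `log2((p_tumor + eps) / (p_adjacent + eps))` per cluster (proportions
#' averaged across a patient's samples per tissue; `eps` defaults to
#' 1 / median total cell count), then tests the per-cluster scores against 0
#' with the two-sided Wilcoxon signed-rank test (exact for n <= 25) and
#' adjusts across clusters with Benjamini-Hochberg.
#'
#' @param composition a [composition_table()] whose metadata has `patient`
#'   and `tissue`.
#' @param eps pseudocount; default scales with sampling depth.
#' @param min_pairs minimum paired patients for a p-value (default 3; below
#'   it the score is reported with `p_value = NA`).
#' @return data.frame: `category`, `n_pairs`, `mean_score`, `p_value`, `fdr`;
#'   per-patient scores in `attr(, "scores")`.
#' @export
tumor_enrichment <- function(composition, eps = NULL, min_pairs = 3) {
  counts <- unclass(composition)
  meta <- attr(composition, "meta")
  stopifnot(all(c("patient", "tissue") %in% names(meta)))
  if (is.null(eps)) eps <- 1 / stats::median(rowSums(counts))
  props <- sweep(counts, 1, rowSums(counts), "/")
  pats <- unique(meta$patient)
  score_rows <- list()
  for (p in pats) {
    it <- meta$patient == p & meta$tissue == "tumor"
    ia <- meta$patient == p & meta$tissue == "adjacent"
    if (!any(it) || !any(ia)) next
    pt <- colMeans(props[it, , drop = FALSE])
    pa <- colMeans(props[ia, , drop = FALSE])
    score_rows[[p]] <- log2((pt + eps) / (pa + eps))
  }
  if (length(score_rows) == 0)
    stop("no patient has both tumor and adjacent samples", call. = FALSE)
  scores <- do.call(rbind, score_rows)
  n_pairs <- nrow(scores)
  pv <- apply(scores, 2, function(s) {
    if (n_pairs < min_pairs) return(NA_real_)
    wilcoxon_signed_rank(s)$p_value
  })
  res <- data.frame(category = colnames(scores), n_pairs = n_pairs,
                    mean_score = colMeans(scores), p_value = pv,
                    fdr = stats::p.adjust(pv, method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, scores = scores, eps = eps, class = c("data.frame"))
}
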