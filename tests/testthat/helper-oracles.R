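## Independent brute-force oracles. These deliberately avoid the package's
## data structures and algorithms: plain loops, full distance matrices,
## direct definitions.

## clonotype partition by (patient, key), as a canonical string signature:
## sorted "cell,cell,..." groups, sorted
bf_clone_signature <- function(airr, annotation, key = "junction_aa") {
  m <- merge(airr, annotation[, c("cell_id", "patient")], by = "cell_id")
  grp <- split(m$cell_id, paste(m$patient, m[[key]]))
  sort(unname(vapply(grp, function(g) paste(sort(g), collapse = ","),
                     character(1))))
}

## per-cell expansion flag by direct recount
bf_expansion_flags <- function(airr, annotation, key = "junction_aa") {
  m <- merge(airr, annotation[, c("cell_id", "patient")], by = "cell_id")
  k <- paste(m$patient, m[[key]])
  n <- table(k)
  stats::setNames(as.integer(n[k]) >= 2, m$cell_id)
}

## connected components under <= r linkage by BFS over the full
## pairwise distance matrix
bf_components <- function(x, y, r) {
  n <- length(x)
  if (n == 0) return(integer(0))
  d <- as.matrix(stats::dist(cbind(x, y)))
  lab <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(lab[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(lab[v])) next
      lab[v] <- cur
      nb <- which(d[v, ] <= r & is.na(lab))
      queue <- c(queue, nb)
    }
  }
  lab
}

## canonical partition signature from a label vector over item names
bf_partition_signature <- function(labels, items) {
  grp <- split(items, labels)
  sort(unname(vapply(grp, function(g) paste(sort(g), collapse = ","),
                     character(1))))
}

## Benjamini-Hochberg by the literal step-up definition
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

## exact two-sided signed-rank p by full sign-pattern enumeration (n <= 12)
bf_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  W <- sum(r[x > 0])
  ws <- vapply(0:(2^n - 1), function(m) {
    signs <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
    sum(r[signs])
  }, numeric(1))
  p_le <- mean(ws <= W + 1e-9)
  p_ge <- mean(ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

## deterministic grid quadrature for a union-of-disks area
bf_disk_union_grid <- function(x, y, r, h = 0.05) {
  xs <- seq(min(x) - r, max(x) + r, by = h)
  ys <- seq(min(y) - r, max(y) + r, by = h)
  inside <- matrix(FALSE, length(xs), length(ys))
  for (i in seq_along(x)) {
    dx2 <- (xs - x[i])^2
    dy2 <- (ys - y[i])^2
    inside <- inside | outer(dx2, dy2, "+") <= r^2
  }
  sum(inside) * h^2
}

## small cohort spec for fast repertoire tests
tiny_cohort <- function(seed, cells = 40L) {
  cohort_spec(n_patients_R = 1L, n_patients_NR = 1L,
              cells_per_sample = cells,
              tissues = c("tumor", "lymph_node"), seed = seed)
}
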