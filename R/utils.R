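#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## closed vocabularies used across modules
TISSUES    <- c("tumor", "adjacent", "lymph_node", "blood")
TIMEPOINTS <- c("pre", "post")
RESPONSES  <- c("R", "NR")
CLUSTERS   <- c("naive_B", "memory_B", "activated_B", "switched_B",
                "unswitched_B", "atypical_B", "plasmablast",
                "PC1", "PC2", "PC3")
ISOTYPES   <- c("IGHM", "IGHD", "IGHG1", "IGHG2", "IGHG3", "IGHG4",
                "IGHA1", "IGHA2", "IGHE")
SPATIAL_MARKERS <- c("CD3", "CD8", "CD20", "CD68", "FOXP3", "MZB1")

stop_field <- function(field, msg) {
  stop(sprintf("invalid spec field '%s': %s", field, msg), call. = FALSE)
}

check_count <- function(x, field) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x <= 0 || x != round(x))
    stop_field(field, "must be a single positive integer")
  as.integer(x)
}

check_positive <- function(x, field) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x <= 0)
    stop_field(field, "must be a single positive number")
  as.numeric(x)
}

check_prob <- function(x, field) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
    stop_field(field, "must be a probability in [0, 1]")
  as.numeric(x)
}

check_prob_vector <- function(x, field, n = NULL, tol = 1e-9) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0))
    stop_field(field, "must be a non-negative numeric vector")
  if (!is.null(n) && length(x) != n)
    stop_field(field, sprintf("must have length %d", n))
  if (abs(sum(x) - 1) > tol)
    stop_field(field, sprintf("must sum to 1 (got %.12f)", sum(x)))
  x
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to score recovery of ground-truth spatial communities.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number; 1 for identical partitions, ~0 for random ones.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2) return(1)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

## quantile normalization across columns (arrays); ties share means,
## NA not supported (array data are complete by construction)
quantile_normalize <- function(mat) {
  if (ncol(mat) < 2) return(mat)
  ranks <- apply(mat, 2, rank, ties.method = "first")
  sorted <- apply(mat, 2, sort)
  means <- rowMeans(sorted)
  out <- matrix(means[ranks], nrow = nrow(mat), dimnames = dimnames(mat))
  out
}

## standard genetic code; stop codons "*"
GENETIC_CODE_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

#' Translate in-frame nucleotide junctions to amino acids
#' @param nt character vector of nucleotide strings, lengths multiples of 3.
#' @return character vector of amino-acid strings ("*" marks stops).
#' @export
translate_junction <- function(nt) {
  vapply(nt, function(s) {
    if (is.na(s) || nchar(s) %% 3 != 0) return(NA_character_)
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aa <- GENETIC_CODE_TABLE[codons]
    if (anyNA(aa)) return(NA_character_)
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## stable short hash for ids / config provenance
short_hash <- function(x) {
  digest::digest(x, algo = "xxhash64", serialize = !is.character(x) ||
                   length(x) != 1)
}

## derive a child RNG seed from a global seed and a stage tag (< 2^31)
derive_seed <- function(seed, tag) {
  h <- digest::digest(paste0(as.integer(seed), "/", tag), algo = "xxhash32",
                      serialize = FALSE)
  as.integer(strtoi(substr(h, 1, 7), base = 16L) %% 2147483647L)
}

## TSV writer with a provenance header comment (schema version + config hash)
write_tsv_header <- function(df, path, config_hash = NA_character_,
                             seed = NA_integer_) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# humoralkit schema=1 config=%s seed=%s",
                     config_hash, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_header <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
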