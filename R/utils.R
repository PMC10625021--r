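#' @keywords internal
"_PACKAGE"

# Half-up integer rounding for displayed percentages (base round() is
# round-half-even, which does not match how claims tables are printed).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# Deterministic per-patient substream seed: patient i always gets the same
# stream for a given root seed, whatever the generation order.  Kept below
# 2^31 because R seeds are 32-bit integers.
patient_seed <- function(root_seed, i) {
  as.integer((as.double(root_seed) * 48271 + i * 16807) %% 2147483647L)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to score recovery of generator archetypes by the fitted clustering.
#' Returns 1 for identical partitions (up to label permutation) and has
#' expected value 0 for independent random labelings.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Delimited text IO used by every pipeline stage; plain TSV, one header row.
write_stage_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_stage_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
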