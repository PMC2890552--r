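# Small in-code fixtures shared across test files.

# A 2-chips-per-cell (8 chip) balanced design, the smallest the reader
# accepts; handy when a test wants hand-placed values.
tiny_design <- function() {
  chip_design(data.frame(
    chip_id = sprintf("c%02d", 1:8),
    orientation = rep(c("C_on_Cy5", "B6a_on_Cy5"), each = 4),
    age_months = rep(c(4L, 8L, 4L, 8L), each = 2)))
}

# Ratio matrix with explicit values (genes x 8 chips), stage as requested.
tiny_matrix <- function(values, stage = "rescaled") {
  d <- tiny_design()
  colnames(values) <- d$chip_id
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  ratio_matrix(values, d, stage = stage)
}

# Canonical 16-chip design for missing-filter boundary tests.
canonical_design <- function() {
  chip_design(data.frame(
    chip_id = sprintf("c%02d", 1:16),
    orientation = rep(c("C_on_Cy5", "B6a_on_Cy5"), each = 8),
    age_months = rep(rep(c(4L, 8L), each = 4), 2)))
}

# Chip table file with given spot rows; returns the path.
write_tmp_chip <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Exact hypergeometric mean and SD of r for (N, R, n) by enumeration over
# the support -- the independent oracle for the Z score.
hyper_moments <- function(N, R, n) {
  r <- max(0, n - (N - R)):min(n, R)
  p <- choose(R, r) * choose(N - R, n - r) / choose(N, n)
  mu <- sum(r * p)
  list(mean = mu, sd = sqrt(sum((r - mu)^2 * p)))
}
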