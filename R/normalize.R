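# Normalization chain for balanced dye-swap two-colour arrays:
#   log ratios -> per-chip lowess vs intensity -> cross-chip SD rescale ->
#   per-gene dye-effect estimate & removal with orientation flip ->
#   missing-value gene filter.
# All stages operate on a `ratio_matrix`: probes/genes x chips with a
# missingness mask that is only ever extended, never shrunk.

#' Ratio matrix container
#'
#' Genes (or probes) by chips matrix of log2 ratios with the chip design
#' attached and a stage tag recording how far through the normalization
#' chain the values have progressed.
#'
#' @param values numeric matrix, rows = probes/genes, columns = chips; `NA`
#'   encodes missing.
#' @param design a [chip_design()] whose `chip_id`s match `colnames(values)`.
#' @param stage one of `"raw"`, `"lowess"`, `"rescaled"`,
#'   `"dye_corrected_oriented"`.
#' @return object of class `ratio_matrix`.
#' @export
ratio_matrix <- function(values, design,
                         stage = c("raw", "lowess", "rescaled",
                                   "dye_corrected_oriented")) {
  stage <- match.arg(stage)
  stopifnot(is.matrix(values), inherits(design, "chip_design"))
  if (is.null(colnames(values)) ||
      !setequal(colnames(values), design$chip_id)) {
    stop("column names of values must match design chip_ids")
  }
  values <- values[, design$chip_id, drop = FALSE]
  structure(list(values = values, design = design, stage = stage),
            class = "ratio_matrix")
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat(sprintf("<ratio_matrix> %d genes x %d chips  stage=%s  (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values), x$stage,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
summary.ratio_matrix <- function(object, ...) {
  sds <- apply(object$values, 2, stats::sd, na.rm = TRUE)
  cat(sprintf("ratio_matrix at stage '%s'\n", object$stage))
  cat(sprintf("  genes: %d   chips: %d   missing: %d values\n",
              nrow(object$values), ncol(object$values),
              sum(is.na(object$values))))
  cat("  per-chip SD of log2 ratios:\n")
  print(round(sds, 4))
  invisible(object)
}

orientation_cols <- function(mat, orientation) {
  mat$design$chip_id[mat$design$orientation == orientation]
}

#' Per-spot M and A values for one chip
#'
#' M = log2(ch2/ch1) (Cy5/Cy3) and A = log2(sqrt(ch1*ch2)).  Both are
#' defined only where the spot is unflagged and both channels are strictly
#' positive; elsewhere they are `NA` — zero intensities make the log
#' undefined and are treated as missing, never imputed.
#'
#' @param chip a [two_color_chip()].
#' @return data frame `probe_id`, `gene_id`, `M`, `A`.
#' @export
compute_log_ratios <- function(chip) {
  stopifnot(inherits(chip, "two_color_chip"))
  s <- chip$spots
  ok <- !s$flagged & s$ch1 > 0 & s$ch2 > 0
  M <- A <- rep(NA_real_, nrow(s))
  M[ok] <- log2(s$ch2[ok] / s$ch1[ok])
  A[ok] <- log2(sqrt(s$ch1[ok] * s$ch2[ok]))
  data.frame(probe_id = s$probe_id, gene_id = s$gene_id, M = M, A = A,
             stringsAsFactors = FALSE)
}

#' Intensity-dependent lowess correction of log ratios
#'
#' Subtracts a lowess fit of M on A (tricube-weighted local linear
#' regression with robustifying iterations, evaluated at the observed A),
#' removing the intensity-dependent dye bias of a chip.  Missing values pass
#' through untouched.
#'
#' @param M,A numeric vectors of equal length; `NA` allowed.
#' @param span lowess span `f`, the fraction of the data in each local
#'   window.  Default 0.33.
#' @param iter robustifying iterations (default 3).
#' @return corrected M values, same length and missingness as `M`.
#' @export
lowess_correct <- function(M, A, span = 0.33, iter = 3) {
  stopifnot(length(M) == length(A))
  ok <- !is.na(M) & !is.na(A)
  n_ok <- sum(ok)
  if (n_ok < 10) {
    stop("lowess_correct needs >= 10 non-missing (M, A) pairs, got ", n_ok,
         "; supply more data or a larger span")
  }
  if (floor(n_ok * span) < 2) {
    stop("span ", span, " gives a local window of fewer than 2 points for ",
         n_ok, " pairs; increase span")
  }
  fit <- stats::lowess(A[ok], M[ok], f = span, iter = iter)
  # lowess returns the curve at sorted unique-ish x; interpolate back to the
  # observed A (constant extrapolation at the range ends).
  ghat <- stats::approx(fit$x, fit$y, xout = A[ok], rule = 2,
                        ties = mean)$y
  out <- M
  out[ok] <- M[ok] - ghat
  out
}

#' Build a probe-level ratio matrix from chips
#'
#' Computes M/A per chip, applies [lowess_correct()] per chip, and assembles
#' the probes x chips matrix (stage `"lowess"`).  All chips must share the
#' same probe set.
#'
#' @param chips list of [two_color_chip()] objects.
#' @param design matching [chip_design()].
#' @param span lowess span, passed through; `NULL` skips the intensity
#'   correction entirely (for data known to carry no intensity-dependent
#'   bias, e.g. idealized simulations).
#' @return a `ratio_matrix` at stage `"lowess"` carrying the probe-to-gene
#'   map as attribute `"probe_genes"`.
#' @export
build_ratio_matrix <- function(chips, design, span = 0.33) {
  stopifnot(length(chips) > 0)
  ids <- vapply(chips, function(ch) ch$chip_id, character(1))
  if (!setequal(ids, design$chip_id)) {
    stop("chips do not match design sheet")
  }
  probes <- chips[[1]]$spots$probe_id
  genes <- chips[[1]]$spots$gene_id
  vals <- matrix(NA_real_, length(probes), length(chips),
                 dimnames = list(probes, ids))
  for (ch in chips) {
    if (!identical(ch$spots$probe_id, probes)) {
      stop("chip '", ch$chip_id, "' has a different probe set")
    }
    ma <- compute_log_ratios(ch)
    vals[, ch$chip_id] <- if (is.null(span)) ma$M
                          else lowess_correct(ma$M, ma$A, span = span)
  }
  out <- ratio_matrix(vals, design, stage = "lowess")
  attr(out, "probe_genes") <- stats::setNames(genes, probes)
  out
}

#' Rescale chips to a common log-ratio spread
#'
#' Linearly rescales each chip so that the standard deviation of its log2
#' ratios (over non-missing values, denominator n-1) equals the median of
#' the per-chip standard deviations before scaling.
#'
#' @param mat a `ratio_matrix` at stage `"lowess"`.
#' @return a `ratio_matrix` at stage `"rescaled"`; per-chip scale factors are
#'   attached as attribute `"scale_factors"`.
#' @export
rescale_chips <- function(mat) {
  stopifnot(inherits(mat, "ratio_matrix"))
  if (mat$stage != "lowess") {
    stop("rescale_chips expects stage 'lowess', got '", mat$stage, "'")
  }
  sds <- apply(mat$values, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds)) || any(sds == 0)) {
    stop("degenerate chip with zero or undefined SD: ",
         paste(names(sds)[!is.finite(sds) | sds == 0], collapse = ", "))
  }
  target <- stats::median(sds)
  fac <- target / sds
  vals <- sweep(mat$values, 2, fac, `*`)
  out <- ratio_matrix(vals, mat$design, stage = "rescaled")
  attr(out, "probe_genes") <- attr(mat, "probe_genes")
  attr(out, "scale_factors") <- fac
  out
}

#' Estimate the per-gene dye effect from a balanced dye swap
#'
#' In a dye swap the strain effect changes sign with orientation while a
#' sequence-specific Cy5/Cy3 dye preference does not, so the sum of the two
#' orientation means is twice the dye effect: D = (mean over C-on-Cy5 chips
#' + mean over B6a-on-Cy5 chips) / 2, with means taken over non-missing
#' values.  D is `NA` for genes with no value in one orientation.
#'
#' @param mat a `ratio_matrix` at stage `"rescaled"`.
#' @return named numeric vector D, one entry per row of `mat`.
#' @export
estimate_dye_effect <- function(mat) {
  stopifnot(inherits(mat, "ratio_matrix"))
  if (mat$stage != "rescaled") {
    stop("estimate_dye_effect expects stage 'rescaled', got '", mat$stage, "'")
  }
  c1 <- orientation_cols(mat, "C_on_Cy5")
  c2 <- orientation_cols(mat, "B6a_on_Cy5")
  if (!length(c1) || !length(c2)) stop("both orientations must be present")
  m1 <- rowMeans(mat$values[, c1, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(mat$values[, c2, drop = FALSE], na.rm = TRUE)
  d <- (m1 + m2) / 2
  d[is.nan(d)] <- NA_real_
  d
}

#' Remove the dye effect and orient all chips to C/B6a
#'
#' C-on-Cy5 chips already measure log2(C/B6a) up to the dye effect: subtract
#' D.  B6a-on-Cy5 chips measure log2(B6a/C) plus the dye effect: negate and
#' add D.  After this step every chip estimates log2(C/B6a).
#'
#' @param mat a `ratio_matrix` at stage `"rescaled"`.
#' @param dye per-gene dye effect from [estimate_dye_effect()].
#' @return a `ratio_matrix` at stage `"dye_corrected_oriented"`.
#' @export
remove_dye_and_orient <- function(mat, dye) {
  stopifnot(inherits(mat, "ratio_matrix"))
  if (mat$stage != "rescaled") {
    stop("remove_dye_and_orient expects stage 'rescaled', got '",
         mat$stage, "'")
  }
  stopifnot(length(dye) == nrow(mat$values))
  vals <- mat$values
  c1 <- orientation_cols(mat, "C_on_Cy5")
  c2 <- orientation_cols(mat, "B6a_on_Cy5")
  vals[, c1] <- vals[, c1, drop = FALSE] - dye
  vals[, c2] <- -vals[, c2, drop = FALSE] + dye
  out <- ratio_matrix(vals, mat$design, stage = "dye_corrected_oriented")
  attr(out, "probe_genes") <- attr(mat, "probe_genes")
  out
}

#' Collapse probe-level rows to gene level
#'
#' Multiple cDNA clones can interrogate the same gene; rows are collapsed to
#' one per gene by the median of probe values within each chip (robust to a
#' single bad clone).  A gene's value on a chip is `NA` only when all its
#' probes are missing there.
#'
#' @param mat a probe-level `ratio_matrix` carrying a `"probe_genes"`
#'   attribute (as built by [build_ratio_matrix()]).
#' @return a gene-level `ratio_matrix`, same stage.
#' @export
collapse_probes <- function(mat) {
  stopifnot(inherits(mat, "ratio_matrix"))
  genes <- attr(mat, "probe_genes")
  if (is.null(genes)) stop("no probe-to-gene map attached")
  genes <- genes[rownames(mat$values)]
  glev <- sort(unique(genes))
  vals <- matrix(NA_real_, length(glev), ncol(mat$values),
                 dimnames = list(glev, colnames(mat$values)))
  idx <- split(seq_along(genes), genes)
  for (g in glev) {
    rows <- mat$values[idx[[g]], , drop = FALSE]
    vals[g, ] <- apply(rows, 2, stats::median, na.rm = TRUE)
  }
  vals[is.nan(vals)] <- NA_real_
  ratio_matrix(vals, mat$design, stage = mat$stage)
}

#' Missing-value gene filter
#'
#' Drops genes with too many missing chips in either dye orientation.  In
#' the canonical 8+8 design the rule is "missing four or more values among
#' the eight chips of either orientation"; for other balanced designs the
#' threshold generalizes to `ceiling(n_orientation / 2)`.
#'
#' @param mat a `ratio_matrix`.
#' @return list with `matrix` (filtered `ratio_matrix`) and `n_removed`.
#' @export
filter_missing <- function(mat) {
  stopifnot(inherits(mat, "ratio_matrix"))
  c1 <- orientation_cols(mat, "C_on_Cy5")
  c2 <- orientation_cols(mat, "B6a_on_Cy5")
  thr1 <- ceiling(length(c1) / 2)
  thr2 <- ceiling(length(c2) / 2)
  miss1 <- rowSums(is.na(mat$values[, c1, drop = FALSE]))
  miss2 <- rowSums(is.na(mat$values[, c2, drop = FALSE]))
  drop <- miss1 >= thr1 | miss2 >= thr2
  out <- ratio_matrix(mat$values[!drop, , drop = FALSE], mat$design,
                      stage = mat$stage)
  if (any(drop)) {
    message(sum(drop), " gene(s) removed by the missing-value filter")
  }
  list(matrix = out, n_removed = sum(drop))
}

#' Full normalization chain
#'
#' Convenience wrapper running [build_ratio_matrix()] (log ratios + lowess),
#' [rescale_chips()], [estimate_dye_effect()], [remove_dye_and_orient()],
#' [collapse_probes()] and [filter_missing()] in the study's order.
#'
#' @inheritParams build_ratio_matrix
#' @return list with `matrix` (gene-level, dye-corrected, filtered
#'   `ratio_matrix`), `dye_effect` (probe-level D), and `n_removed`.
#' @export
normalize_chips <- function(chips, design, span = 0.33) {
  m <- build_ratio_matrix(chips, design, span = span)
  m <- rescale_chips(m)
  d <- estimate_dye_effect(m)
  m <- remove_dye_and_orient(m, d)
  g <- collapse_probes(m)
  f <- filter_missing(g)
  list(matrix = f$matrix, dye_effect = d, n_removed = f$n_removed)
}
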