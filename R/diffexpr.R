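# Strain/age contrasts on the dye-corrected C/B6a matrix with SAM-style
# permutation FDR.  Four comparisons: all chips, 4-month chips, 8-month
# chips (one-group t against zero), and the age dependency of the strain
# difference (Welch two-sample t, 4 m vs 8 m).

.comparisons <- c("all16", "m4", "m8", "age_dependency")

#' One-group t test summary for one gene
#'
#' Plain one-sample t of the adjusted log2(C/B6a) values against zero:
#' t = mean / (sd / sqrt(n)), two-sided p from the t distribution with n-1
#' degrees of freedom.  A gene with zero spread is degenerate: t and p are
#' returned `NA` and the caller excludes it from FDR ranking.
#'
#' @param values numeric vector; `NA`s are dropped.
#' @return list with `mean`, `t`, `p`, `n`.
#' @export
one_group_t <- function(values) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n < 3) stop("one_group_t needs >= 3 non-missing values, got ", n)
  m <- mean(v)
  s <- stats::sd(v)
  if (s == 0) {
    warning("zero spread; t undefined for this gene")
    return(list(mean = m, t = NA_real_, p = NA_real_, n = n))
  }
  t <- m / (s / sqrt(n))
  list(mean = m, t = t, p = 2 * stats::pt(-abs(t), df = n - 1), n = n)
}

welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) {
    return(list(mean = NA_real_, t = NA_real_, p = NA_real_,
                n = length(a) + length(b)))
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(mean = 0, t = 0, p = 1, n = length(a) + length(b)))
    }
    return(list(mean = mean(b) - mean(a), t = NA_real_, p = NA_real_,
                n = length(a) + length(b)))
  }
  ht <- stats::t.test(b, a, var.equal = FALSE)
  list(mean = mean(b) - mean(a), t = unname(ht$statistic), p = ht$p.value,
       n = length(a) + length(b))
}

comparison_chips <- function(design, comparison) {
  switch(comparison,
    all16 = design$chip_id,
    m4 = design$chip_id[design$age_months == 4L],
    m8 = design$chip_id[design$age_months == 8L],
    age_dependency = design$chip_id,
    stop("unknown comparison '", comparison, "'"))
}

gene_stats <- function(vals, design, comparison) {
  if (comparison == "age_dependency") {
    a4 <- design$chip_id[design$age_months == 4L]
    a8 <- design$chip_id[design$age_months == 8L]
    res <- apply(vals, 1, function(v) {
      unlist(welch_t(v[a4], v[a8]))
    })
  } else {
    cols <- comparison_chips(design, comparison)
    res <- apply(vals[, cols, drop = FALSE], 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 3) {
        return(c(mean = NA_real_, t = NA_real_, p = NA_real_,
                 n = length(v)))
      }
      unlist(one_group_t(v))
    })
  }
  as.data.frame(t(res))
}

#' Run the four strain/age comparisons
#'
#' Comparisons 1-3 (`all16`, `m4`, `m8`) test whether the mean adjusted
#' log2(C/B6a) over the relevant chips is non-zero (one-group t);
#' comparison 4 (`age_dependency`) tests whether the strain difference
#' changes with age (Welch two-sample t, 8 m minus 4 m).  Fold change is
#' `2^mean` (for `age_dependency`, the mean is the 8m-4m difference).
#' SAM-style permutation q values are attached per comparison.
#'
#' @param mat a `ratio_matrix` at stage `"dye_corrected_oriented"`,
#'   missing-value filtered.
#' @param n_perm permutations for the FDR (default 1000).
#' @param seed RNG seed recorded in the output attributes.
#' @return named list of four data frames (one per comparison) with columns
#'   `gene_id`, `comparison`, `mean_log2_C_over_B6a`, `FC`, `t_stat`,
#'   `p_value`, `q_value`, `n_used`.
#' @export
run_comparisons <- function(mat, n_perm = 1000, seed = 1L) {
  stopifnot(inherits(mat, "ratio_matrix"))
  if (mat$stage != "dye_corrected_oriented") {
    stop("run_comparisons expects stage 'dye_corrected_oriented', got '",
         mat$stage, "'")
  }
  out <- list()
  for (cmp in .comparisons) {
    suppressWarnings(st <- gene_stats(mat$values, mat$design, cmp))
    q <- permutation_fdr(st$t, mat, cmp, n_perm = n_perm,
                         seed = seed + match(cmp, .comparisons))
    out[[cmp]] <- data.frame(
      gene_id = rownames(mat$values), comparison = cmp,
      mean_log2_C_over_B6a = st$mean, FC = 2^st$mean,
      t_stat = st$t, p_value = st$p, q_value = q, n_used = st$n,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  attr(out, "seed") <- seed
  attr(out, "n_perm") <- n_perm
  out
}

null_t_matrix <- function(vals, design, comparison, n_perm) {
  # one column of null t statistics per permutation; permutations act on
  # chips (sign flips or age-label shuffles), preserving gene correlation
  if (comparison == "age_dependency") {
    a4 <- design$chip_id[design$age_months == 4L]
    a8 <- design$chip_id[design$age_months == 8L]
    cols <- c(a4, a8)
    v <- vals[, cols, drop = FALSE]
    n4 <- length(a4)
    sapply(seq_len(n_perm), function(i) {
      perm <- sample(ncol(v))
      g1 <- v[, perm[seq_len(n4)], drop = FALSE]
      g2 <- v[, perm[-seq_len(n4)], drop = FALSE]
      welch_t_rows(g1, g2)
    })
  } else {
    cols <- comparison_chips(design, comparison)
    v <- vals[, cols, drop = FALSE]
    sapply(seq_len(n_perm), function(i) {
      signs <- sample(c(-1, 1), ncol(v), replace = TRUE)
      one_t_rows(sweep(v, 2, signs, `*`))
    })
  }
}

one_t_rows <- function(v) {
  n <- rowSums(!is.na(v))
  m <- rowMeans(v, na.rm = TRUE)
  ss <- rowSums(v^2, na.rm = TRUE) - n * m^2
  s2 <- ss / pmax(n - 1, 1)
  s2[s2 < 0] <- 0
  t <- m / sqrt(s2 / n)
  t[n < 3 | s2 == 0] <- NA_real_
  t
}

welch_t_rows <- function(g1, g2) {
  n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
  m1 <- rowMeans(g1, na.rm = TRUE); m2 <- rowMeans(g2, na.rm = TRUE)
  v1 <- (rowSums(g1^2, na.rm = TRUE) - n1 * m1^2) / pmax(n1 - 1, 1)
  v2 <- (rowSums(g2^2, na.rm = TRUE) - n2 * m2^2) / pmax(n2 - 1, 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  t[n1 < 3 | n2 < 3 | se2 == 0] <- NA_real_
  t
}

#' SAM-style permutation false discovery rate
#'
#' Null t statistics are generated by random chip sign flips (one-group
#' comparisons: flipping a chip's sign is exchangeable under the null of no
#' strain difference) or age-label shuffles (`age_dependency`).  For a
#' threshold c the FDR estimate is the median over permutations of the
#' number of null |t| >= c, divided by the observed count at that
#' threshold.  Each gene receives q at its own |t|, monotonized so q never
#' increases with |t|, and capped at 1.  Genes with undefined t get `NA`.
#'
#' @param observed_t vector of observed t statistics (one per gene).
#' @param mat the `ratio_matrix` the statistics came from.
#' @param comparison one of `"all16"`, `"m4"`, `"m8"`, `"age_dependency"`.
#' @param n_perm number of permutations, at least 100.
#' @param seed RNG seed.
#' @return q values in `[0, 1]`, same order as `observed_t`.
#' @export
permutation_fdr <- function(observed_t, mat, comparison, n_perm = 1000,
                            seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100, got ", n_perm)
  comparison <- match.arg(comparison, .comparisons)
  ok <- !is.na(observed_t)
  q <- rep(NA_real_, length(observed_t))
  if (!any(ok)) return(q)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  nulls <- withr_seed(null_t_matrix(mat$values, mat$design, comparison, n_perm))
  nulls <- matrix(nulls, ncol = n_perm)  # sapply drops dims for 1 gene
  abs_obs <- abs(observed_t[ok])
  abs_null <- abs(nulls)
  # counts of null |t| >= c per permutation, evaluated at each observed |t|
  ord <- order(abs_obs)
  sorted <- abs_obs[ord]
  null_counts <- matrix(0, length(sorted), ncol(abs_null))
  for (j in seq_len(ncol(abs_null))) {
    col <- abs_null[, j]
    col <- col[!is.na(col)]
    # number of null values >= each sorted threshold
    null_counts[, j] <- length(col) - findInterval(sorted, sort(col),
                                                   left.open = TRUE)
  }
  med_null <- apply(null_counts, 1, stats::median)
  # observed count at threshold |t_i|: number of observed |t| >= |t_i|
  # (ties share the count of genes at or above the tied value)
  obs_count <- length(sorted) - findInterval(sorted, sorted, left.open = TRUE)
  raw <- pmin(med_null / obs_count, 1)
  # monotone: a larger |t| never has a larger q.  With `sorted` ascending in
  # |t|, q_i = min of raw estimates over genes with |t| <= |t_i|.
  mono <- cummin(raw)
  qq <- numeric(length(sorted))
  qq[ord] <- mono
  q[ok] <- qq
  q
}

#' Regulated-gene call
#'
#' A gene is regulated when its fold change passes the inclusive thresholds
#' (FC >= 1.2 or FC <= 0.8) and its FDR q is below 0.05.
#'
#' @param FC linear fold change(s), C relative to B6a.
#' @param q_value FDR q value(s).
#' @param fc_up,fc_down,fdr thresholds; defaults 1.2, 0.8, 0.05.
#' @return logical vector; `NA` inputs give `FALSE` (a gene without a
#'   measurement cannot be called regulated).
#' @export
call_regulated <- function(FC, q_value, fc_up = 1.2, fc_down = 0.8,
                           fdr = 0.05) {
  out <- (FC >= fc_up | FC <= fc_down) & q_value < fdr
  out[is.na(out)] <- FALSE
  out
}
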