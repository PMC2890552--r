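# Comparative-Ct relative quantification and the ANOVA / Holm-Sidak
# statistics used to test strain-by-age expression differences.

#' Relative expression by the comparative-Ct method
#'
#' Technical replicate wells are averaged to one Ct per biological
#' replicate; `dCt = mean(ct_target) - mean(ct_reference)` per replicate
#' (reference is beta-actin in the study); the per-group fold is
#' `(1 + AE)^(dCt_calibrator - dCt_group)`, so a target more abundant than
#' in the calibrator group gives fold > 1 (standard Livak orientation; with
#' AE = 1 one cycle equals a doubling).  The calibrator group has fold 1
#' exactly.
#'
#' @param measurements data frame with columns `strain`, `age_months`,
#'   `replicate_id`, `ct_target`, `ct_reference` (one row per well;
#'   technical triplicates share a `replicate_id`).
#' @param AE amplification efficiency, default 1.0.
#' @param calibrator list/vector `(strain, age_months)` of the reference
#'   group; default B6a at 4 months.
#' @return data frame per group: `strain`, `age_months`, `delta_ct`
#'   (mean over biological replicates), `fold`, plus per-replicate dCt as
#'   attribute `"replicates"` for downstream testing.
#' @export
relative_expression <- function(measurements, AE = 1.0,
                                calibrator = list(strain = "B6a",
                                                  age_months = 4)) {
  need <- c("strain", "age_months", "replicate_id", "ct_target",
            "ct_reference")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) {
    stop("Ct table lacks column(s): ", paste(miss, collapse = ", "))
  }
  m <- measurements
  bad <- is.na(m$ct_reference) | is.na(m$ct_target)
  if (any(bad)) {
    warning(sum(bad), " well(s) with missing Ct dropped")
    m <- m[!bad, , drop = FALSE]
  }
  if (any(m$ct_target <= 0 | m$ct_target >= 45 |
          m$ct_reference <= 0 | m$ct_reference >= 45)) {
    stop("Ct values must lie in (0, 45) cycles")
  }
  key <- interaction(m$strain, m$age_months, m$replicate_id, drop = TRUE)
  dct <- tapply(m$ct_target, key, mean) - tapply(m$ct_reference, key, mean)
  meta <- m[!duplicated(key), c("strain", "age_months", "replicate_id")]
  meta <- meta[match(names(dct), as.character(
    interaction(meta$strain, meta$age_months, meta$replicate_id,
                drop = TRUE))), ]
  reps <- data.frame(meta, delta_ct = as.numeric(dct), row.names = NULL)
  grp <- interaction(reps$strain, reps$age_months, drop = TRUE)
  gmean <- tapply(reps$delta_ct, grp, mean)
  gmeta <- reps[!duplicated(grp), c("strain", "age_months")]
  gmeta <- gmeta[match(names(gmean), as.character(
    interaction(gmeta$strain, gmeta$age_months, drop = TRUE))), ]
  cal <- gmeta$strain == calibrator$strain &
    gmeta$age_months == calibrator$age_months
  if (!any(cal)) stop("calibrator group absent from the Ct table")
  dct_cal <- gmean[cal]
  out <- data.frame(gmeta, delta_ct = as.numeric(gmean),
                    fold = (1 + AE)^(dct_cal - as.numeric(gmean)),
                    row.names = NULL)
  attr(out, "replicates") <- reps
  out
}

#' Holm-Sidak stepdown adjustment
#'
#' Orders the m raw p values ascending and adjusts
#' `p_(k) -> max_{j<=k} (1 - (1 - p_(j))^(m-j+1))`, clipped at 1: the
#' Sidak correction applied stepwise with monotonization.
#'
#' @param p numeric vector of raw p values.
#' @return adjusted p values in the original order.
#' @export
holm_sidak <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' One-way ANOVA with Holm-Sidak pairwise comparisons
#'
#' One-way ANOVA across groups; if requested or significant, all pairwise
#' pooled-SD t tests with Holm-Sidak adjustment.  Performed on whatever
#' scale `values` is supplied on (the qPCR module calls it on per-replicate
#' dCt by default; pass fold values to switch scales).
#'
#' @param values numeric vector.
#' @param group factor/vector of group labels, >= 2 groups with >= 2 values
#'   each.
#' @return list with `anova_F`, `anova_p`, `pairwise` (matrix of adjusted p
#'   values) and `pairwise_raw`.
#' @export
anova_holm_sidak <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups")
  counts <- table(group)
  if (any(counts < 2)) {
    stop("every group needs >= 2 values; offending group(s): ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  wvar <- tapply(values, group, stats::var)
  if (all(wvar == 0)) stop("zero within-group variance in every group")
  fit <- stats::aov(values ~ group)
  an <- stats::anova(fit)
  pw <- stats::pairwise.t.test(values, group, p.adjust.method = "none",
                               pool.sd = TRUE)$p.value
  flat <- which(!is.na(pw))
  adj <- pw
  adj[flat] <- holm_sidak(pw[flat])
  list(anova_F = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
       pairwise = adj, pairwise_raw = pw)
}
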