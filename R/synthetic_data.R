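# Seeded generators for every input type the pipeline consumes, each
# returning its inputs together with a ground-truth record so downstream
# recovery tests never rely on hard-coded constants.

#' Simulate a balanced dye-swap two-colour experiment
#'
#' Emulates the study design: a balanced dye swap over two ages
#' (`n_chips_per_cell` chips per orientation-by-age cell; 4 gives the
#' canonical 16-chip experiment).  Per-gene abundance A is uniform on
#' `[6, 14]` log2 units (a typical spotted-array range, with a small
#' per-spot jitter).  The spot log ratio is built as
#' `M = scale_j * (sign * s_g(age) + dye_gene_g + eps) + dye_curve(A)`
#' where `sign` is +1 on C-on-Cy5 chips and -1 on dye-swapped chips,
#' `s_g` is the planted strain effect, `dye_gene_g ~ N(0, dye_gene_sd)` a
#' sequence-specific dye preference (removed only by the dye-swap
#' correction), `dye_curve(A) = dye_curve_amp * sin((A - 6) / 2.5)` the
#' intensity-dependent bias (removed by lowess), `scale_j` a per-chip
#' spread factor and `eps ~ N(0, sigma)` spot noise.  Channel intensities
#' are reconstructed as `ch2 = 2^(A + M/2)`, `ch1 = 2^(A - M/2)`.
#' Missingness is applied independently per spot through the flag column.
#'
#' @param n_genes number of genes (one probe each).
#' @param n_chips_per_cell chips per orientation x age cell (default 4).
#' @param effect_frac fraction of genes with a strain effect, in `[0, 1]`.
#' @param effect_size absolute planted strain effect, log2 units.
#' @param effect_age `"both"`, `"4m"` or `"8m"`: ages at which the planted
#'   effect is active.
#' @param dye_curve_amp amplitude of the intensity-dependent dye bias.
#' @param dye_gene_sd SD of the gene-specific dye preference.
#' @param sigma spot-level noise SD, log2 units.
#' @param missing_rate per-spot flag probability.
#' @param scale_range range of per-chip scale factors.
#' @param seed RNG seed; fixed seed reproduces the dataset exactly.
#' @return list with `chips` (list of [two_color_chip()]), `design`
#'   ([chip_design()]) and `truth` (per-gene effects, dye components,
#'   chip scales, parameters, seed).
#' @export
gen_two_color_experiment <- function(n_genes = 500, n_chips_per_cell = 4,
                                     effect_frac = 0.2, effect_size = 0.5,
                                     effect_age = c("both", "4m", "8m"),
                                     dye_curve_amp = 0.4, dye_gene_sd = 0.3,
                                     sigma = 0.2, missing_rate = 0.05,
                                     scale_range = c(0.9, 1.1), seed = 1L) {
  effect_age <- match.arg(effect_age)
  if (effect_frac < 0 || effect_frac > 1) {
    stop("effect_frac must be in [0, 1]")
  }
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  A0 <- stats::runif(n_genes, 6, 14)
  n_eff <- round(effect_frac * n_genes)
  s <- numeric(n_genes)
  if (n_eff > 0) {
    idx <- sample(n_genes, n_eff)
    s[idx] <- sample(c(-1, 1), n_eff, replace = TRUE) * effect_size
  }
  s4 <- if (effect_age %in% c("both", "4m")) s else numeric(n_genes)
  s8 <- if (effect_age %in% c("both", "8m")) s else numeric(n_genes)
  dye_gene <- if (dye_gene_sd > 0) stats::rnorm(n_genes, 0, dye_gene_sd)
              else numeric(n_genes)
  cells <- expand.grid(orientation = c("C_on_Cy5", "B6a_on_Cy5"),
                       age_months = c(4L, 8L), rep = seq_len(n_chips_per_cell),
                       stringsAsFactors = FALSE)
  n_chips <- nrow(cells)
  design <- chip_design(data.frame(
    chip_id = sprintf("chip%02d", seq_len(n_chips)),
    orientation = cells$orientation, age_months = cells$age_months))
  scales <- stats::runif(n_chips, scale_range[1], scale_range[2])
  dye_curve <- function(A) dye_curve_amp * sin((A - 6) / 2.5)
  chips <- vector("list", n_chips)
  for (j in seq_len(n_chips)) {
    sgn <- if (design$orientation[j] == "C_on_Cy5") 1 else -1
    sg <- if (design$age_months[j] == 4L) s4 else s8
    A <- A0 + stats::rnorm(n_genes, 0, 0.1)
    eps <- if (sigma > 0) stats::rnorm(n_genes, 0, sigma) else 0
    M <- scales[j] * (sgn * sg + dye_gene + eps) + dye_curve(A)
    flagged <- stats::runif(n_genes) < missing_rate
    chips[[j]] <- two_color_chip(
      design$chip_id[j], design$orientation[j], design$age_months[j],
      data.frame(probe_id = genes, gene_id = genes,
                 ch1 = 2^(A - M / 2), ch2 = 2^(A + M / 2),
                 flagged = flagged, stringsAsFactors = FALSE))
  }
  truth <- list(gene_id = genes, strain_effect_4m = s4,
                strain_effect_8m = s8, dye_gene = dye_gene,
                chip_scales = stats::setNames(scales, design$chip_id),
                dye_curve = list(id = "sine", amplitude = dye_curve_amp,
                                 origin = 6, period = 2.5),
                params = list(n_genes = n_genes,
                              n_chips_per_cell = n_chips_per_cell,
                              effect_frac = effect_frac,
                              effect_size = effect_size,
                              effect_age = effect_age,
                              dye_gene_sd = dye_gene_sd, sigma = sigma,
                              missing_rate = missing_rate),
                seed = seed)
  list(chips = chips, design = design, truth = truth)
}

#' Simulate a strain SNP table with a planted haplotype-pass set
#'
#' A planted fraction of genes receives at least one SNP satisfying the
#' haplotype rule (B6 != C and A != C); the remaining genes receive only
#' failing SNPs (allele shared with C, or an unknown A allele).
#'
#' @param n_genes number of genes.
#' @param pass_frac fraction of genes planted as haplotype passes.
#' @param seed RNG seed.
#' @return list with `snps` (data frame) and `truth` (named logical vector
#'   of planted passes, plus the seed).
#' @export
gen_snp_table <- function(n_genes = 200, pass_frac = 0.3, seed = 1L) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  pass <- rep(FALSE, n_genes)
  n_pass <- round(pass_frac * n_genes)
  if (n_pass > 0) pass[sample(n_genes, n_pass)] <- TRUE
  bases <- c("A", "C", "G", "T")
  rows <- lapply(seq_len(n_genes), function(i) {
    n_snp <- 1 + stats::rpois(1, 1)
    rc <- sample(.snp_region_classes, n_snp, replace = TRUE)
    mk_fail <- function() {
      mode <- sample(c("b6_eq_c", "a_eq_c", "a_unknown"), 1)
      cC <- sample(bases, 1)
      other <- sample(setdiff(bases, cC), 1)
      switch(mode,
        b6_eq_c = c(cC, cC, sample(bases, 1)),
        a_eq_c = c(other, cC, cC),
        a_unknown = c(other, cC, "?"))
    }
    al <- t(vapply(seq_len(n_snp), function(k) mk_fail(), character(3)))
    if (pass[i]) {
      cC <- sample(bases, 1)
      b6 <- sample(setdiff(bases, cC), 1)
      aa <- sample(setdiff(bases, cC), 1)
      al[sample(n_snp, 1), ] <- c(b6, cC, aa)
    }
    data.frame(gene_id = genes[i], region_class = rc,
               allele_B6 = al[, 1], allele_C = al[, 2], allele_A = al[, 3],
               stringsAsFactors = FALSE)
  })
  snps <- do.call(rbind, rows)
  rownames(snps) <- NULL
  list(snps = validate_snp_table(snps),
       truth = list(pass = stats::setNames(pass, genes), seed = seed))
}

#' Simulate a GO annotation with one planted enriched term
#'
#' Background genes change at `background_rate`; the planted term's genes
#' change at `planted_rate` (defaults 10% vs 80%).  Term sizes are drawn
#' uniformly from `term_size` and genes are assigned at random, so terms
#' overlap as real GO terms do.
#'
#' @param n_genes measured annotated genes.
#' @param n_terms number of terms, the first of which is planted.
#' @param term_size range of term sizes.
#' @param planted_rate,background_rate per-gene change probabilities.
#' @param seed RNG seed.
#' @return list with `annotation` (data frame), `changed` (character
#'   vector) and `truth` (planted term id and parameters).
#' @export
gen_go_annotation <- function(n_genes = 500, n_terms = 30,
                              term_size = c(10, 40), planted_rate = 0.8,
                              background_rate = 0.1, seed = 1L) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  terms <- sprintf("T%03d", seq_len(n_terms))
  sizes <- sample(term_size[1]:term_size[2], n_terms, replace = TRUE)
  ann <- do.call(rbind, lapply(seq_len(n_terms), function(k) {
    data.frame(gene_id = sample(genes, sizes[k]), term_id = terms[k],
               stringsAsFactors = FALSE)
  }))
  planted_genes <- ann$gene_id[ann$term_id == terms[1]]
  p_change <- rep(background_rate, n_genes)
  p_change[genes %in% planted_genes] <- planted_rate
  changed <- genes[stats::runif(n_genes) < p_change]
  list(annotation = ann, changed = changed,
       truth = list(planted_term = terms[1], planted_rate = planted_rate,
                    background_rate = background_rate, seed = seed))
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' For each strain-by-age group a planted fold (relative to the calibrator,
#' B6a at 4 months) is converted to a group dCt via
#' `dCt = dCt_cal - log2(fold) / log2(1 + AE)`.  Each biological replicate
#' (an animal pool, 3 by default as in a triplicate-pool design) draws its
#' dCt with SD `sigma_ct`; each of its technical wells adds smaller
#' well-level noise to both target and reference Ct.
#'
#' @param folds named numeric vector of planted folds; names `"strain.age"`
#'   (e.g. `"C.8"`).  Default plants a 2-fold increase in C at 8 months.
#' @param n_bio biological replicates per group.
#' @param n_tech technical wells per replicate.
#' @param sigma_ct biological dCt SD, cycles.
#' @param sigma_tech technical well SD, cycles.
#' @param AE amplification efficiency.
#' @param dct_cal calibrator group's true dCt (cycles).
#' @param seed RNG seed.
#' @return list with `measurements` (well-level data frame) and `truth`.
#' @export
gen_qpcr <- function(folds = c(B6a.4 = 1, C.4 = 1, B6a.8 = 1, C.8 = 2),
                     n_bio = 3, n_tech = 3, sigma_ct = 0.2,
                     sigma_tech = 0.1, AE = 1.0, dct_cal = 5, seed = 1L) {
  set.seed(seed)
  grp <- do.call(rbind, strsplit(names(folds), ".", fixed = TRUE))
  rows <- list()
  for (i in seq_along(folds)) {
    dct_true <- dct_cal - log2(folds[i]) / log2(1 + AE)
    for (b in seq_len(n_bio)) {
      dct_b <- dct_true + stats::rnorm(1, 0, sigma_ct)
      ct_ref <- 16 + stats::rnorm(1, 0, 0.3)
      for (w in seq_len(n_tech)) {
        rows[[length(rows) + 1L]] <- data.frame(
          strain = grp[i, 1], age_months = as.integer(grp[i, 2]),
          replicate_id = b, well = w,
          ct_target = ct_ref + dct_b + stats::rnorm(1, 0, sigma_tech),
          ct_reference = ct_ref + stats::rnorm(1, 0, sigma_tech),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(measurements = do.call(rbind, rows),
       truth = list(folds = folds, AE = AE, sigma_ct = sigma_ct,
                    n_bio = n_bio, seed = seed))
}

#' Simulate ONL thickness profiles with planted genotype means
#'
#' Each animal's section-level mean thickness is drawn from
#' `N(mean_genotype, sigma_animal)`; the 54 measurement slots add
#' within-section noise.  The default means (44, 40, 36 um) plant an
#' additive allele effect with the protective homozygote thickest.
#'
#' @param means named numeric vector of genotype mean thicknesses (um).
#' @param sigma_animal between-animal SD (um).
#' @param sigma_slot within-section slot SD (um).
#' @param n_per_group animals per genotype.
#' @param seed RNG seed.
#' @return list with `profiles` (list of [onl_profile()]) and `truth`.
#' @export
gen_onl <- function(means = c("B6a/B6a" = 44, "HET" = 40, "C/C" = 36),
                    sigma_animal = 2, sigma_slot = 1.5, n_per_group = 20,
                    seed = 1L) {
  set.seed(seed)
  profiles <- list()
  k <- 0L
  for (g in names(means)) {
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      mu <- stats::rnorm(1, means[g], sigma_animal)
      slots <- array(pmax(stats::rnorm(54, mu, sigma_slot), 1), c(2, 9, 3))
      profiles[[k]] <- onl_profile(sprintf("a%03d", k), g, slots)
    }
  }
  list(profiles = profiles,
       truth = list(means = means, sigma_animal = sigma_animal,
                    sigma_slot = sigma_slot, n_per_group = n_per_group,
                    seed = seed))
}

#' Write a simulation truth record as JSON
#'
#' Serializes a generator's `truth` list so a generated dataset directory is
#' reproducible from `(truth, seed)` alone.
#'
#' @param truth list as returned in a generator's `truth` element.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
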