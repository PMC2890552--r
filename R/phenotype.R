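# Outer nuclear layer (ONL) thickness summarization and genotype
# association.  The sampling protocol measures each retinal section in two
# hemispheres x nine 250-um sets x three positions = 54 slots; the animal-
# level mean is the unit of analysis (slots within an eye are not
# independent).

#' ONL profile constructor
#'
#' @param animal_id animal label.
#' @param genotype genotype at the marker SNP, e.g. `"B6a/B6a"`, `"HET"`,
#'   `"C/C"` (or `"+/+"`, `"+/-"` for knockout tests).
#' @param measurements numeric array `2 x 9 x 3` (hemisphere x set x
#'   position) of thicknesses in micrometres; `NA` marks unmeasurable slots
#'   (e.g. retinal tears).
#' @return object of class `onl_profile`.
#' @export
onl_profile <- function(animal_id, genotype, measurements) {
  if (!is.array(measurements) ||
      !identical(dim(measurements), c(2L, 9L, 3L))) {
    stop("measurements must be a 2 x 9 x 3 array ",
         "(hemisphere x set x position)")
  }
  if (any(measurements <= 0, na.rm = TRUE)) {
    stop("thickness values must be positive")
  }
  structure(list(animal_id = as.character(animal_id),
                 genotype = as.character(genotype),
                 measurements = measurements),
            class = "onl_profile")
}

#' Mean ONL thickness of one section
#'
#' Arithmetic mean over the non-missing measurement slots (54 when the
#' section is complete).
#'
#' @param profile an [onl_profile()].
#' @return mean thickness in micrometres.
#' @export
onl_mean <- function(profile) {
  stopifnot(inherits(profile, "onl_profile"))
  v <- profile$measurements
  if (all(is.na(v))) stop("profile has no non-missing measurement")
  mean(v, na.rm = TRUE)
}

#' Read long-format ONL measurement tables
#'
#' CSV columns: `animal`, `genotype`, `hemisphere` (1/2), `set` (1-9),
#' `position` (1-3), `thickness_um`.  Unlisted slots are missing.
#'
#' @param path CSV path.
#' @return list of [onl_profile()] objects.
#' @export
read_onl_profiles <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal", "genotype", "hemisphere", "set", "position",
            "thickness_um")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("ONL table lacks column(s): ", paste(miss, collapse = ", "))
  }
  lapply(split(tab, tab$animal), function(a) {
    m <- array(NA_real_, c(2, 9, 3))
    m[cbind(a$hemisphere, a$set, a$position)] <- a$thickness_um
    onl_profile(a$animal[1], a$genotype[1], m)
  })
}

#' Genotype association of ONL thickness
#'
#' One-way ANOVA of per-animal mean thickness across genotype groups with
#' Holm-Sidak pairwise comparisons (via [anova_holm_sidak()]).  For the
#' three-genotype case the additivity gap
#' `mean(HET) - (mean(hom1) + mean(hom2)) / 2` quantifies departure from an
#' additive allele effect (near zero under additivity).  Groups with fewer
#' than 2 animals are excluded with a warning.
#'
#' @param profiles list of [onl_profile()]s.
#' @param het_label genotype label of the heterozygote (default `"HET"`).
#' @return list with `anova_p`, `anova_F`, `pairwise` (Holm-Sidak adjusted),
#'   `group_means`, and `additivity_gap` (`NA` unless exactly 3 groups
#'   including `het_label`).
#' @export
genotype_association <- function(profiles, het_label = "HET") {
  means <- vapply(profiles, onl_mean, numeric(1))
  geno <- vapply(profiles, function(p) p$genotype, character(1))
  counts <- table(geno)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("genotype group(s) with n < 2 excluded: ",
            paste(small, collapse = ", "))
    keep <- !geno %in% small
    means <- means[keep]; geno <- geno[keep]
  }
  if (length(unique(geno)) < 2) stop("need >= 2 genotype groups")
  res <- anova_holm_sidak(means, geno)
  gm <- tapply(means, geno, mean)
  gap <- NA_real_
  if (length(gm) == 3 && het_label %in% names(gm)) {
    hom <- gm[names(gm) != het_label]
    gap <- unname(gm[het_label] - mean(hom))
  }
  list(anova_p = res$anova_p, anova_F = res$anova_F,
       pairwise = res$pairwise, group_means = gm, additivity_gap = gap)
}
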