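# MAPPFinder-style overrepresentation for GO terms (or any gene set, e.g.
# pathway MAPPs): standardized hypergeometric Z per term, label-permutation
# p value, and the ranked/filtered term list.

#' Standardized hypergeometric Z score
#'
#' With N measured annotated genes of which R changed, a term containing n
#' measured genes with r changed has, under random draws without
#' replacement, mean `n*R/N` and variance
#' `n*(R/N)*(1-R/N)*(1-(n-1)/(N-1))`.  The Z score standardizes r against
#' this hypergeometric null.  Degenerate nulls (R = 0, R = N or n = N)
#' have zero variance; Z is defined as 0 there, with a warning.
#'
#' @param r changed genes in the term.
#' @param n measured genes in the term.
#' @param R changed genes among all measured annotated genes.
#' @param N all measured annotated genes.
#' @return numeric Z (vectorized over `r`, `n`).
#' @export
z_score <- function(r, n, R, N) {
  stopifnot(all(r >= 0), all(r <= n), all(n <= N), R >= 0, R <= N)
  p <- R / N
  v <- n * p * (1 - p) * (1 - (n - 1) / (N - 1))
  z <- rep(0, length(v))
  degen <- v <= 0
  if (any(degen)) {
    warning("zero-variance null for ", sum(degen),
            " term(s) (R=0, R=N or n=N); Z set to 0")
  }
  z[!degen] <- (r[!degen] - n[!degen] * p) / sqrt(v[!degen])
  z
}

term_membership_matrix <- function(annotation, genes) {
  terms <- sort(unique(annotation$term_id))
  m <- matrix(0L, length(terms), length(genes),
              dimnames = list(terms, genes))
  keep <- annotation$gene_id %in% genes
  m[cbind(match(annotation$term_id[keep], terms),
          match(annotation$gene_id[keep], genes))] <- 1L
  m
}

#' Permutation p values for term Z scores
#'
#' Permutes the changed/unchanged labels over the measured annotated genes
#' `n_perm` times, recomputes each term's Z, and reports
#' `p = (1 + #(null Z >= observed Z)) / (1 + n_perm)` — never exactly zero.
#'
#' @param annotation data frame `gene_id`, `term_id` (measured annotated
#'   genes only).
#' @param changed character vector of changed gene ids.
#' @param n_perm permutations, at least 1000 for the p < 0.01 filter to be
#'   meaningful.
#' @param seed RNG seed; a fixed seed gives an identical p vector.
#' @return data frame `term_id`, `n_changed`, `n_measured`, `z_score`,
#'   `permute_p`.
#' @export
permutation_p <- function(annotation, changed, n_perm = 2000, seed = 1L) {
  if (n_perm < 1000) {
    warning("n_perm below 1000; the p<0.01 criterion is poorly resolved")
  }
  genes <- sort(unique(annotation$gene_id))
  N <- length(genes)
  flags <- as.integer(genes %in% changed)
  R <- sum(flags)
  memb <- term_membership_matrix(annotation, genes)
  n <- as.integer(memb %*% rep(1L, N))
  r <- as.integer(memb %*% flags)
  suppressWarnings(z_obs <- z_score(r, n, R, N))
  set.seed(seed)
  # all permutations at once: genes x n_perm matrix of shuffled flags
  perm_flags <- replicate(n_perm, sample(flags))
  r_null <- memb %*% perm_flags                 # terms x n_perm
  p <- R / N
  v <- n * p * (1 - p) * (1 - (n - 1) / (N - 1))
  z_null <- (r_null - n * p) / sqrt(pmax(v, .Machine$double.eps))
  z_null[v <= 0, ] <- 0
  exceed <- rowSums(z_null >= z_obs)
  data.frame(term_id = rownames(memb), n_changed = r, n_measured = n,
             z_score = z_obs, permute_p = (1 + exceed) / (1 + n_perm),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank and filter enrichment rows
#'
#' Keeps terms with permutation p < 0.01, Z >= 2, percent changed > 10
#' (strict) and at least 2 changed genes, sorted by permutation p ascending
#' with ties broken by Z descending.
#'
#' @param rows data frame as returned by [permutation_p()] (a `term_name`
#'   column, if present, is carried along).
#' @return the filtered, ranked subset with a `percent_changed` column.
#' @export
rank_and_filter <- function(rows) {
  rows$percent_changed <- 100 * rows$n_changed / rows$n_measured
  keep <- rows$permute_p < 0.01 & rows$z_score >= 2 &
    rows$percent_changed > 10 & rows$n_changed >= 2
  out <- rows[keep, , drop = FALSE]
  out <- out[order(out$permute_p, -out$z_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Propagate annotations up the term hierarchy
#'
#' Each gene annotated to a term becomes annotated to all the term's
#' ancestors (is_a/part_of rollup).  Idempotent; a cycle in the parent
#' edges is an error.
#'
#' @param annotation data frame `gene_id`, `term_id`.
#' @param edges data frame `child`, `parent`.
#' @return annotation data frame including ancestor memberships (set
#'   semantics: one row per gene-term pair).
#' @export
rollup_annotations <- function(annotation, edges) {
  if (nrow(edges) == 0) return(unique(annotation))
  parents <- split(edges$parent, edges$child)
  # validate the whole hierarchy up front: every node must reach a root
  check_cache <- new.env(parent = emptyenv())
  for (start in unique(edges$child)) {
    visit <- function(term, path) {
      if (term %in% path) {
        stop("cycle in term hierarchy involving '", term, "'")
      }
      if (isTRUE(check_cache[[term]])) return(invisible())
      for (p in parents[[term]]) visit(p, c(path, term))
      check_cache[[term]] <- TRUE
    }
    visit(start, character())
  }
  anc_cache <- new.env(parent = emptyenv())
  ancestors <- function(term, path = character()) {
    if (term %in% path) {
      stop("cycle in term hierarchy involving '", term, "'")
    }
    if (!is.null(anc_cache[[term]])) return(anc_cache[[term]])
    ps <- parents[[term]]
    if (is.null(ps)) {
      anc_cache[[term]] <- character()
      return(character())
    }
    out <- unique(c(ps, unlist(lapply(ps, ancestors,
                                      path = c(path, term)))))
    anc_cache[[term]] <- out
    out
  }
  res <- lapply(unique(annotation$term_id), function(tm) {
    anc <- ancestors(tm)
    genes <- annotation$gene_id[annotation$term_id == tm]
    data.frame(gene_id = rep(genes, times = 1 + length(anc)),
               term_id = rep(c(tm, anc), each = length(genes)),
               stringsAsFactors = FALSE)
  })
  out <- unique(do.call(rbind, res))
  out <- out[order(out$term_id, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Full enrichment run for one gene list
#'
#' Restricts the annotation to measured genes, scores every term, and
#' applies the ranked filter.  Direction-specific lists (up in one strain,
#' per age) are handled by calling this once per list, mirroring the
#' four-block presentation of the study's GO table.
#'
#' @param annotation data frame `gene_id`, `term_id`.
#' @param measured character vector of genes measured on the array.
#' @param changed character vector of changed genes (subset of `measured`).
#' @param term_names optional named character vector term_id -> name.
#' @inheritParams permutation_p
#' @return list with `scored` (all terms) and `ranked` (filtered list).
#' @export
go_enrichment <- function(annotation, measured, changed, n_perm = 2000,
                          seed = 1L, term_names = NULL) {
  ann <- annotation[annotation$gene_id %in% measured, , drop = FALSE]
  if (nrow(ann) == 0) stop("no measured gene carries an annotation")
  changed <- intersect(changed, unique(ann$gene_id))
  scored <- permutation_p(ann, changed, n_perm = n_perm, seed = seed)
  if (!is.null(term_names)) {
    scored$term_name <- unname(term_names[scored$term_id])
  }
  list(scored = scored, ranked = rank_and_filter(scored))
}
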