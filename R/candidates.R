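# QTL-interval candidate gene prioritization: interval mapping, the
# strain-haplotype SNP filter (B6 != C and A != C), and the 0/1/2 evidence
# score combining keyword-evidence (PosMed) membership with microarray
# regulation.

#' QTL interval constructor
#'
#' Closed interval in megabases on one chromosome, e.g. the refined loci on
#' Chr 6 (77.5-93.0 Mb) and Chr 10 (15.4-20.8 Mb).
#'
#' @param chromosome chromosome name ("6" or "chr6" both work).
#' @param start_mb,end_mb interval bounds in Mb, start < end.
#' @param name label for the interval.
#' @return list of class `qtl_interval`.
#' @export
qtl_interval <- function(chromosome, start_mb, end_mb, name = NULL) {
  if (!(start_mb < end_mb)) stop("start_mb must be < end_mb")
  structure(list(chromosome = normalize_chrom(chromosome),
                 start_mb = start_mb, end_mb = end_mb,
                 name = name %||% paste0("chr", normalize_chrom(chromosome))),
            class = "qtl_interval")
}

#' Genes overlapping a QTL interval
#'
#' A gene is included iff its locus overlaps the closed interval
#' `[start_mb, end_mb]` on the same chromosome; boundary-touching genes are
#' in.  Chromosome naming conventions ("chr10" vs "10") are normalized.
#'
#' @param loci data frame from [read_gene_loci()] (`gene_id`, `chromosome`,
#'   `start_mb`, `end_mb`).
#' @param interval a [qtl_interval()].
#' @return character vector of gene ids.
#' @export
map_genes_to_interval <- function(loci, interval) {
  stopifnot(inherits(interval, "qtl_interval"))
  chrom <- normalize_chrom(loci$chromosome)
  hit <- chrom == interval$chromosome &
    loci$start_mb <= interval$end_mb &
    loci$end_mb >= interval$start_mb
  unique(loci$gene_id[hit])
}

#' Strain-haplotype SNP filter
#'
#' A gene passes when at least one of its SNPs has `allele_B6 != allele_C`
#' and `allele_A != allele_C`: the allele differs between the contrasted
#' strains and is absent from the strain pair that showed no matching QTL.
#' An unknown A allele (`"?"`) cannot establish a pass.
#'
#' @param snps validated SNP data frame (see [read_snp_table()]).
#' @return named logical vector, one entry per gene present in `snps`.
#' @export
haplotype_filter <- function(snps) {
  if (nrow(snps) == 0) {
    return(stats::setNames(logical(0), character(0)))
  }
  snp_pass <- snps$allele_B6 != snps$allele_C &
    snps$allele_A != snps$allele_C &
    snps$allele_A != "?"
  genes <- unique(snps$gene_id)
  vapply(split(snp_pass, factor(snps$gene_id, levels = genes)), any,
         logical(1))
}

#' Two-criterion candidate evidence score
#'
#' Score 2 when the gene is both in the keyword-evidence (PosMed) list and
#' regulated in the microarray analysis at either age, 1 when exactly one
#' criterion holds, 0 when neither does.  Genes not present on the array
#' carry `FALSE` regulation flags.
#'
#' @param posmed logical, keyword-evidence membership.
#' @param regulated_4m,regulated_8m logical, regulated at 4 or 8 months.
#' @return integer score in 0:2 (vectorized).
#' @export
score_candidate <- function(posmed, regulated_4m, regulated_8m) {
  as.integer(posmed) + as.integer(regulated_4m | regulated_8m)
}

#' Assemble the candidate evidence table
#'
#' One row per haplotype-passing gene inside any of the QTL intervals,
#' carrying the interval, the evidence flags and the 0/1/2 score; sorted by
#' interval, then score descending, then gene id.  Genes in the SNP table
#' without a locus are dropped with a warning.
#'
#' @param loci gene locus data frame.
#' @param intervals list of [qtl_interval()]s.
#' @param snps SNP data frame.
#' @param posmed_genes character vector of keyword-evidence gene ids.
#' @param regulated_4m,regulated_8m character vectors of gene ids regulated
#'   at each age (from [call_regulated()] applied to the m4/m8 contrasts).
#' @return data frame with columns `gene_id`, `interval`, `in_qtl`,
#'   `haplotype_pass`, `posmed`, `regulated_4m`, `regulated_8m`, `score`.
#' @export
build_candidate_table <- function(loci, intervals, snps, posmed_genes,
                                  regulated_4m, regulated_8m) {
  if (inherits(intervals, "qtl_interval")) intervals <- list(intervals)
  if (nrow(snps) == 0) {
    return(data.frame(gene_id = character(), interval = character(),
                      in_qtl = logical(), haplotype_pass = logical(),
                      posmed = logical(), regulated_4m = logical(),
                      regulated_8m = logical(), score = integer(),
                      stringsAsFactors = FALSE))
  }
  orphan <- setdiff(unique(snps$gene_id), loci$gene_id)
  if (length(orphan)) {
    warning("SNP-table gene(s) absent from locus table, excluded: ",
            paste(orphan, collapse = ", "))
    snps <- snps[!snps$gene_id %in% orphan, , drop = FALSE]
  }
  hap <- haplotype_filter(snps)
  rows <- list()
  for (iv in intervals) {
    in_iv <- map_genes_to_interval(loci, iv)
    genes <- intersect(names(hap)[hap], in_iv)
    if (!length(genes)) next
    r4 <- genes %in% regulated_4m
    r8 <- genes %in% regulated_8m
    pm <- genes %in% posmed_genes
    rows[[iv$name]] <- data.frame(
      gene_id = genes, interval = iv$name, in_qtl = TRUE,
      haplotype_pass = TRUE, posmed = pm,
      regulated_4m = r4, regulated_8m = r8,
      score = score_candidate(pm, r4, r8),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(build_candidate_table(loci, intervals,
                                 snps[0, , drop = FALSE],
                                 posmed_genes, regulated_4m, regulated_8m))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$interval, -out$score, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Score a transcribed candidate table fixture
#'
#' Re-derives the "N criteria" score for a published candidate table from
#' its own printed inputs: PosMed membership plus per-age microarray fold
#' changes (`NP` marks genes not present on the array).  Regulation is the
#' inclusive fold-change rule (FC >= 1.2 or FC <= 0.8); the `de_listed`
#' column marks genes the study's differential-expression analysis flagged
#' in another contrast, which also count as regulated.
#'
#' @param path TSV with columns `gene`, `posmed` (Yes/No), `fc_4m`, `fc_8m`
#'   (numeric or `NP`), `de_listed` (Yes/No), `n_criteria` (the printed
#'   score, carried for comparison).
#' @return the table with logical evidence flags and a recomputed `score`
#'   column.
#' @export
score_candidate_fixture <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "posmed", "fc_4m", "fc_8m", "de_listed", "n_criteria")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("fixture lacks column(s): ", paste(miss, collapse = ", "))
  }
  fc_flag <- function(fc) {
    v <- suppressWarnings(as.numeric(fc))
    out <- !is.na(v) & (v >= 1.2 | v <= 0.8)
    out
  }
  tab$posmed_flag <- tab$posmed == "Yes"
  tab$regulated_4m <- fc_flag(tab$fc_4m)
  tab$regulated_8m <- fc_flag(tab$fc_8m)
  regulated_any <- tab$regulated_4m | tab$regulated_8m |
    tab$de_listed == "Yes"
  tab$score <- as.integer(tab$posmed_flag) + as.integer(regulated_any)
  tab
}
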