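# ---- two-colour chip ---------------------------------------------------

#' Construct a two-colour chip object
#'
#' One spotted array's raw spot intensities in two channels together with its
#' dye orientation and animal age.  `ch1` is the Cy3 channel and `ch2` the Cy5
#' channel, so downstream log ratios `log2(ch2/ch1)` are Cy5/Cy3.
#'
#' @param chip_id single character id.
#' @param orientation `"C_on_Cy5"` (strain C labelled with Cy5) or
#'   `"B6a_on_Cy5"` (dye-swapped).
#' @param age_months age of the animals hybridized on this chip, 4 or 8.
#' @param spots data frame with columns `probe_id`, `gene_id`, `ch1`, `ch2`
#'   and logical `flagged`.  Flagged or non-positive spots yield missing
#'   ratios downstream; they are never imputed.
#' @return object of class `two_color_chip`.
#' @export
two_color_chip <- function(chip_id, orientation, age_months, spots) {
  orientation <- match.arg(orientation, c("C_on_Cy5", "B6a_on_Cy5"))
  age_months <- as.integer(age_months)
  if (!age_months %in% c(4L, 8L)) {
    stop("age_months must be 4 or 8, got ", age_months)
  }
  need <- c("probe_id", "gene_id", "ch1", "ch2", "flagged")
  miss <- setdiff(need, names(spots))
  if (length(miss)) {
    stop("spot table is missing column(s): ", paste(miss, collapse = ", "))
  }
  spots <- spots[need]
  spots$probe_id <- as.character(spots$probe_id)
  spots$gene_id <- as.character(spots$gene_id)
  spots$flagged <- as.logical(spots$flagged)
  dup <- unique(spots$probe_id[duplicated(spots$probe_id)])
  if (length(dup)) {
    stop("duplicate probe_id within chip '", chip_id, "': ",
         paste(utils::head(dup, 10), collapse = ", "))
  }
  if (any(!is.finite(spots$ch1)) || any(!is.finite(spots$ch2))) {
    stop("non-finite intensity in chip '", chip_id, "'")
  }
  if (any(spots$ch1 < 0) || any(spots$ch2 < 0)) {
    stop("negative intensity in chip '", chip_id, "'")
  }
  structure(
    list(chip_id = as.character(chip_id), orientation = orientation,
         age_months = age_months, spots = spots),
    class = "two_color_chip")
}

#' @export
print.two_color_chip <- function(x, ...) {
  cat(sprintf("<two_color_chip> %s  orientation=%s  age=%d m  %d spots (%d flagged)\n",
              x$chip_id, x$orientation, x$age_months,
              nrow(x$spots), sum(x$spots$flagged)))
  invisible(x)
}

#' Read a chip intensity table
#'
#' Canonical dialect: tab-delimited with a header naming `probe`, `gene`,
#' `ch1`, `ch2` and an optional 0/1 `flag` column.  Spots that are flagged or
#' have a non-positive intensity are kept but marked, so they become missing
#' ratios later; no row is silently dropped.  Counts of accepted and flagged
#' rows are attached as the `"counts"` attribute.
#'
#' @param path file path.
#' @param chip_id id to assign.
#' @param orientation,age_months design entry for this chip (see
#'   [two_color_chip()]).
#' @return a `two_color_chip`.
#' @export
read_chip_table <- function(path, chip_id, orientation, age_months) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("probe", "gene", "ch1", "ch2")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("chip table '", path, "' lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  flagged <- if ("flag" %in% names(tab)) as.integer(tab$flag) != 0L
             else rep(FALSE, nrow(tab))
  spots <- data.frame(
    probe_id = as.character(tab$probe), gene_id = as.character(tab$gene),
    ch1 = as.numeric(tab$ch1), ch2 = as.numeric(tab$ch2),
    flagged = flagged, stringsAsFactors = FALSE)
  chip <- two_color_chip(chip_id, orientation, age_months, spots)
  attr(chip, "counts") <- c(accepted = nrow(spots), flagged = sum(flagged),
                            rejected = 0L)
  chip
}

#' Read a GenePix-style chip export
#'
#' Alternate reader for a GPR-subset dialect: tab-delimited with columns
#' `ID` (probe), `Name` (gene), `F532 Mean` (Cy3, mapped to ch1), `F635 Mean`
#' (Cy5, mapped to ch2) and `Flags` (negative values mark bad spots).  Mapped
#' onto the same [two_color_chip()] container as the canonical dialect.
#'
#' @inheritParams read_chip_table
#' @export
read_gpr_chip <- function(path, chip_id, orientation, age_months) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("ID", "Name", "F532 Mean", "F635 Mean")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("GPR table '", path, "' lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  flagged <- if ("Flags" %in% names(tab)) as.numeric(tab$Flags) < 0
             else rep(FALSE, nrow(tab))
  spots <- data.frame(
    probe_id = as.character(tab$ID), gene_id = as.character(tab$Name),
    ch1 = as.numeric(tab[["F532 Mean"]]), ch2 = as.numeric(tab[["F635 Mean"]]),
    flagged = flagged, stringsAsFactors = FALSE)
  chip <- two_color_chip(chip_id, orientation, age_months, spots)
  attr(chip, "counts") <- c(accepted = nrow(spots), flagged = sum(flagged),
                            rejected = 0L)
  chip
}

#' @rdname read_chip_table
#' @param chip a `two_color_chip` to serialize.
#' @export
write_chip_table <- function(chip, path) {
  stopifnot(inherits(chip, "two_color_chip"))
  out <- data.frame(probe = chip$spots$probe_id, gene = chip$spots$gene_id,
                    ch1 = chip$spots$ch1, ch2 = chip$spots$ch2,
                    flag = as.integer(chip$spots$flagged))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- chip design sheet -------------------------------------------------

#' Read or validate a chip design sheet
#'
#' CSV with columns `chip_id`, `orientation`, `age_months`.  The canonical
#' study design is 4 chips per orientation-by-age cell (16 chips); any
#' balanced design with at least 2 chips per cell is accepted.
#'
#' @param path CSV path, or for [chip_design()] a data frame.
#' @return data frame of class `chip_design`.
#' @export
read_design <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  chip_design(tab)
}

#' @rdname read_design
#' @param design data frame with `chip_id`, `orientation`, `age_months`.
#' @export
chip_design <- function(design) {
  need <- c("chip_id", "orientation", "age_months")
  miss <- setdiff(need, names(design))
  if (length(miss)) {
    stop("design sheet lacks column(s): ", paste(miss, collapse = ", "))
  }
  design <- design[need]
  design$chip_id <- as.character(design$chip_id)
  design$age_months <- as.integer(design$age_months)
  bad <- setdiff(unique(design$orientation), c("C_on_Cy5", "B6a_on_Cy5"))
  if (length(bad)) {
    stop("unknown orientation value(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(design$chip_id)) stop("duplicate chip_id in design sheet")
  cell <- table(design$orientation, design$age_months)
  if (nrow(cell) < 2 || any(cell < 2)) {
    stop("design must be a balanced dye swap with >= 2 chips per ",
         "orientation x age cell; got cells: ",
         paste(as.vector(cell), collapse = ", "))
  }
  if (length(unique(as.vector(cell))) != 1) {
    stop("design is unbalanced across orientation x age cells")
  }
  class(design) <- c("chip_design", "data.frame")
  design
}

#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- gene loci ---------------------------------------------------------

#' Read a BED-like gene locus table
#'
#' Tab-delimited `chrom`, `start`, `end`, `gene` with base-pair coordinates;
#' converted to megabases on read.  Downstream interval logic treats loci as
#' closed Mb intervals to match the printed "77.5-93.0 Mb" style.  Chromosome
#' names are normalized by stripping a leading "chr".
#'
#' @param path file path.
#' @return data frame with `gene_id`, `chromosome`, `start_mb`, `end_mb`.
#' @export
read_gene_loci <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("locus file needs 4 columns: chrom, start, end, gene")
  loci <- data.frame(
    gene_id = as.character(tab[[4]]),
    chromosome = normalize_chrom(tab[[1]]),
    start_mb = as.numeric(tab[[2]]) / 1e6,
    end_mb = as.numeric(tab[[3]]) / 1e6,
    stringsAsFactors = FALSE)
  bad <- which(loci$start_mb > loci$end_mb | loci$start_mb < 0)
  if (length(bad)) {
    stop("invalid locus coordinates on row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  loci
}

#' @export
write_gene_loci <- function(loci, path) {
  out <- data.frame(chrom = loci$chromosome,
                    start = formatC(loci$start_mb * 1e6, format = "d"),
                    end = formatC(loci$end_mb * 1e6, format = "d"),
                    gene = loci$gene_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

normalize_chrom <- function(x) sub("^[Cc]hr", "", as.character(x))

# ---- SNP table ---------------------------------------------------------

.snp_region_classes <- c("nonsyn", "syn", "utr5", "utr3", "intron", "flanking")

#' Read a strain SNP table
#'
#' CSV with one SNP per row: `gene_id`, `region_class`, `allele_B6`,
#' `allele_C`, `allele_A`.  Alleles are base or indel tokens over
#' `A/C/G/T/-`; `"?"` marks an unknown A-strain allele and is preserved as
#' unknown, never guessed.  Region classes outside the vocabulary
#' (`r paste(.snp_region_classes, collapse = ", ")`) are an error.
#'
#' @param path CSV path.
#' @return data frame of validated SNP records; an empty file yields an empty
#'   data frame with a warning.
#' @export
read_snp_table <- function(path) {
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) NULL)
  if (is.null(tab) || nrow(tab) == 0) {
    warning("SNP table '", path, "' is empty")
    return(data.frame(gene_id = character(), region_class = character(),
                      allele_B6 = character(), allele_C = character(),
                      allele_A = character(), stringsAsFactors = FALSE))
  }
  validate_snp_table(tab)
}

validate_snp_table <- function(tab) {
  need <- c("gene_id", "region_class", "allele_B6", "allele_C", "allele_A")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("SNP table lacks column(s): ", paste(miss, collapse = ", "))
  }
  tab <- tab[need]
  for (nm in need) tab[[nm]] <- as.character(tab[[nm]])
  bad <- setdiff(unique(tab$region_class), .snp_region_classes)
  if (length(bad)) {
    stop("region_class outside vocabulary: ", paste(bad, collapse = ", "))
  }
  ok_allele <- function(a, allow_unknown = FALSE) {
    grepl("^[ACGT-]+$", a) | (allow_unknown & a == "?")
  }
  bad_row <- which(!ok_allele(tab$allele_B6) | !ok_allele(tab$allele_C) |
                   !ok_allele(tab$allele_A, allow_unknown = TRUE))
  if (length(bad_row)) {
    stop("invalid allele token on row(s): ",
         paste(utils::head(bad_row, 10), collapse = ", "))
  }
  tab
}

#' @export
write_snp_table <- function(snps, path) {
  utils::write.csv(snps, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- evidence list -----------------------------------------------------

#' Read a keyword-evidence gene list
#'
#' Plain text, one gene id per line (PosMed-style precomputed candidate
#' list).  Duplicates are collapsed: the result has set semantics.
#'
#' @param path file path.
#' @param source tag recording where the list came from.
#' @return character vector of unique gene ids with a `"source"` attribute.
#' @export
read_evidence_list <- function(path, source = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  genes <- unique(lines[nzchar(lines)])
  attr(genes, "source") <- source
  genes
}

#' @export
write_evidence_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

# ---- GO annotation -----------------------------------------------------

#' Read gene-to-GO-term annotation
#'
#' Two-column tab-delimited file `gene`, `term_id`; duplicate pairs are
#' collapsed.
#'
#' @param path TSV path.
#' @return data frame with columns `gene_id`, `term_id`.
#' @export
read_go_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "term_id")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("annotation file lacks column(s): ", paste(miss, collapse = ", "))
  }
  unique(data.frame(gene_id = as.character(tab$gene),
                    term_id = as.character(tab$term_id),
                    stringsAsFactors = FALSE))
}

#' Read term parent edges from a minimal OBO subset
#'
#' Understands only `[Term]` stanzas with `id:`, `name:`, `is_a:` and
#' `relationship: part_of` lines — enough to recover the parent edges used
#' for annotation rollup.  Full OBO semantics are out of scope.
#'
#' @param path OBO file path.
#' @return list with `terms` (data frame `term_id`, `name`) and `edges`
#'   (data frame `child`, `parent`).
#' @export
read_obo_subset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- list(); edges <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) {
      terms[[length(terms) + 1L]] <<- data.frame(
        term_id = cur$id, name = cur$name %||% NA_character_,
        stringsAsFactors = FALSE)
      for (p in cur$parents) {
        edges[[length(edges) + 1L]] <<- data.frame(
          child = cur$id, parent = p, stringsAsFactors = FALSE)
      }
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- list(parents = character()) }
    else if (is.null(cur)) next
    else if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
    else if (startsWith(ln, "is_a:")) {
      cur$parents <- c(cur$parents,
                       trimws(sub("!.*$", "", sub("^is_a:", "", ln))))
    } else if (startsWith(ln, "relationship: part_of")) {
      cur$parents <- c(cur$parents,
                       trimws(sub("!.*$", "", sub("^relationship: part_of", "", ln))))
    }
  }
  flush()
  list(terms = if (length(terms)) do.call(rbind, terms) else
         data.frame(term_id = character(), name = character()),
       edges = if (length(edges)) do.call(rbind, edges) else
         data.frame(child = character(), parent = character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
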