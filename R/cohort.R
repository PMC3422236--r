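#' Trio cohort container
#'
#' A `trio_cohort` holds biallelic autosomal SNP genotypes for a set of
#' mother/father/child trios. Genotypes are stored as the count of the
#' B allele (`allele_b`) per individual and SNP: 0, 1, 2 or `NA` (missing).
#' Genotypes are unordered; phase, where present in the input, is discarded
#' because parental origin is derived from the trio structure itself.
#'
#' @param snps data.frame with columns `snp_id`, `chrom` (autosome number,
#'   1-22), `pos` (1-based bp), `allele_a`, `allele_b`.
#' @param families data.frame with columns `family_id`, `mother_id`,
#'   `father_id`, `child_id`, `population`.
#' @param geno integer matrix, individuals x SNPs, entries in `c(0, 1, 2, NA)`
#'   giving the B-allele count; rownames are individual ids, colnames match
#'   `snps$snp_id`.
#'
#' @return An object of class `trio_cohort`: a list with elements `snps`,
#'   `families` and `geno`.
#' @export
trio_cohort <- function(snps, families, geno) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  families <- as.data.frame(families, stringsAsFactors = FALSE)
  need_s <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  if (!all(need_s %in% names(snps)))
    stop("snps must have columns: ", paste(need_s, collapse = ", "))
  need_f <- c("family_id", "mother_id", "father_id", "child_id", "population")
  if (!all(need_f %in% names(families)))
    stop("families must have columns: ", paste(need_f, collapse = ", "))
  snps$chrom <- as.integer(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  if (any(is.na(snps$chrom)) || any(snps$chrom < 1L) || any(snps$chrom > 22L))
    stop("all SNPs must be autosomal (chrom 1-22)")
  if (any(snps$pos < 1L)) stop("SNP positions must be >= 1")
  if (any(snps$allele_a == snps$allele_b))
    stop("allele_a and allele_b must differ (biallelic SNPs only)")
  dup <- unique(snps$snp_id[duplicated(snps$snp_id)])
  if (length(dup))
    stop("duplicate snp_id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  ids <- c(families$mother_id, families$father_id, families$child_id)
  if (anyDuplicated(ids))
    stop("individual ids must be unique across all roles")
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(rownames(geno)) || (ncol(geno) > 0L && is.null(colnames(geno))))
    stop("geno must have individual ids as rownames and snp ids as colnames")
  missing_ids <- setdiff(ids, rownames(geno))
  if (length(missing_ids))
    stop("individual(s) absent from genotype matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  if (ncol(geno) > 0L && !identical(colnames(geno), snps$snp_id))
    stop("geno column names must match snps$snp_id in order")
  if (ncol(geno) != nrow(snps))
    stop("geno must have one column per SNP")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotypes must be allele counts 0/1/2 or NA")
  structure(list(snps = snps, families = families,
                 geno = geno[ids, , drop = FALSE]),
            class = "trio_cohort")
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf("trio_cohort: %d trios (%s), %d SNPs on %d autosome(s)\n",
              nrow(x$families),
              paste(sprintf("%s: %d", names(table(x$families$population)),
                            as.integer(table(x$families$population))),
                    collapse = ", "),
              nrow(x$snps), length(unique(x$snps$chrom))))
  invisible(x)
}

#' Child ids of a cohort, in family order
#' @param cohort a `trio_cohort`
#' @return character vector of child ids
#' @export
children <- function(cohort) cohort$families$child_id

#' Founder (parent) ids of a cohort
#' @param cohort a `trio_cohort`
#' @return character vector of mother and father ids
#' @export
founders <- function(cohort) c(cohort$families$mother_id,
                               cohort$families$father_id)

#' Per-individual sample table (id, role, family, population)
#' @param cohort a `trio_cohort`
#' @return data.frame with one row per individual
#' @export
cohort_samples <- function(cohort) {
  f <- cohort$families
  data.frame(
    id = c(f$mother_id, f$father_id, f$child_id),
    role = rep(c("mother", "father", "child"), each = nrow(f)),
    family_id = rep(f$family_id, 3),
    population = rep(f$population, 3),
    stringsAsFactors = FALSE)
}

#' Restrict a cohort to a subset of SNPs
#' @param cohort a `trio_cohort`
#' @param keep logical or index vector over SNPs
#' @return a `trio_cohort` with the selected SNPs
#' @export
subset_snps <- function(cohort, keep) {
  trio_cohort(cohort$snps[keep, , drop = FALSE], cohort$families,
              cohort$geno[, keep, drop = FALSE])
}

#' Which allele is the minor allele, per SNP
#'
#' The minor allele is fixed once over the combined cohort (all genotyped
#' individuals) so that dosage coding is consistent across populations and
#' association regimes. Ties (frequency exactly 0.5) take allele B as minor.
#'
#' @param cohort a `trio_cohort`
#' @return logical vector per SNP: `TRUE` when `allele_b` is the minor allele
#' @export
minor_is_b <- function(cohort) {
  fb <- colMeans(cohort$geno, na.rm = TRUE) / 2
  fb[is.nan(fb)] <- 0.5
  fb <= 0.5
}

#' Minor allele frequency per SNP over a set of individuals
#' @param cohort a `trio_cohort`
#' @param ids individual ids to use (default: everyone)
#' @return numeric vector of MAFs (NaN where fully missing)
#' @export
snp_maf <- function(cohort, ids = rownames(cohort$geno)) {
  fb <- colMeans(cohort$geno[ids, , drop = FALSE], na.rm = TRUE) / 2
  pmin(fb, 1 - fb)
}

#' Expression matrix container
#'
#' Log2-scale expression values for probe sets measured in the cohort's
#' children, with probe genomic coordinates and (after gene mapping) gene
#' assignment. Columns are ordered as the cohort's children.
#'
#' @param values numeric matrix, probes x children; rownames are probe ids.
#' @param probes data.frame with columns `probe_id`, `chrom`, `start`, `end`
#'   and optionally `gene` (comma-separated when a probe overlaps several
#'   genes; `NA` before mapping).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, probes) {
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "start", "end")
  if (!all(need %in% names(probes)))
    stop("probes must have columns: ", paste(need, collapse = ", "))
  if (!("gene" %in% names(probes))) probes$gene <- NA_character_
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!identical(rownames(values), probes$probe_id))
    stop("values rownames must match probes$probe_id in order")
  probes$chrom <- as.integer(probes$chrom)
  probes$start <- as.integer(probes$start)
  probes$end <- as.integer(probes$end)
  if (any(probes$start > probes$end)) stop("probe start must be <= end")
  if (any(!is.finite(values)))
    stop("expression values must all be finite")
  structure(list(values = values, probes = probes),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probes x %d children (log2 scale)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Restrict an expression matrix to a subset of probes
#' @param expr an `expression_matrix`
#' @param keep logical or index vector over probes
#' @return an `expression_matrix`
#' @export
subset_probes <- function(expr, keep) {
  expression_matrix(expr$values[keep, , drop = FALSE],
                    expr$probes[keep, , drop = FALSE])
}

#' Probe midpoints (floor of the coordinate mean)
#' @param probes probe data.frame with `start` and `end`
#' @return integer vector of midpoints
#' @export
probe_midpoint <- function(probes) {
  as.integer((as.numeric(probes$start) + as.numeric(probes$end)) %/% 2)
}
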