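# Readers and writers for the formats the pipeline consumes and emits:
# VCF + pedigree (FAM), PLINK text PED/MAP, expression TSV + probe
# annotation, gene BED, imprinted-gene lists, and result tables.

.normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  suppressWarnings(as.integer(x))  # X/Y/MT and friends become NA
}

.read_pedigree <- function(pedigree_path) {
  lines <- readLines(pedigree_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop("malformed pedigree line ", which(nf < 6L)[1], " in ", pedigree_path,
         ": expected 6 whitespace-delimited columns")
  ped <- data.frame(
    family_id = vapply(fields, `[`, "", 1L),
    id = vapply(fields, `[`, "", 2L),
    father_id = vapply(fields, `[`, "", 3L),
    mother_id = vapply(fields, `[`, "", 4L),
    sex = vapply(fields, `[`, "", 5L),
    phenotype = vapply(fields, `[`, "", 6L),
    stringsAsFactors = FALSE)
  if (anyDuplicated(ped$id))
    stop("duplicate individual id in pedigree: ",
         ped$id[duplicated(ped$id)][1])
  ped
}

# Trio rows (child with both parents named) from a 6-column pedigree table.
.pedigree_trios <- function(ped, population = NULL) {
  is_child <- ped$father_id != "0" & ped$mother_id != "0"
  kids <- ped[is_child, , drop = FALSE]
  if (!nrow(kids)) stop("pedigree defines no complete trios")
  absent <- setdiff(c(kids$father_id, kids$mother_id), ped$id)
  if (length(absent))
    stop("parent id(s) named in pedigree but not listed: ",
         paste(absent, collapse = ", "))
  fam <- data.frame(family_id = kids$family_id,
                    mother_id = kids$mother_id,
                    father_id = kids$father_id,
                    child_id = kids$id,
                    stringsAsFactors = FALSE)
  fam$population <- if (is.null(population)) "POP1" else
    unname(population[fam$family_id])
  if (any(is.na(fam$population)))
    stop("population label missing for family ",
         fam$family_id[is.na(fam$population)][1])
  fam
}

#' Read trio genotypes from a VCF and a pedigree file
#'
#' Parses GT fields for all pedigree individuals. Only biallelic autosomal
#' SNP records are retained; multi-allelic and non-autosomal records are
#' dropped with a message. Phase separators (`|`) in the input are ignored:
#' genotypes are treated as unordered allele pairs and parental origin is
#' re-derived from the trio structure.
#'
#' @param vcf_path path to a VCF 4.x file (plain text or gzipped).
#' @param pedigree_path path to a 6-column FAM-style pedigree file
#'   (family, individual, father, mother, sex, phenotype); individuals with
#'   both parents named form the trios.
#' @param population optional named character vector mapping `family_id` to a
#'   population label; defaults to a single population `"POP1"`.
#' @return a [trio_cohort()]
#' @export
read_trio_vcf <- function(vcf_path, pedigree_path, population = NULL) {
  ped <- .read_pedigree(pedigree_path)
  fam <- .pedigree_trios(ped, population)
  ids <- c(fam$mother_id, fam$father_id, fam$child_id)

  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  absent <- setdiff(ids, colnames(gt))
  if (length(absent))
    stop("pedigree individual(s) absent from VCF: ",
         paste(absent, collapse = ", "))

  chrom <- .normalize_chrom(fix$CHROM)
  biallelic <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nzchar(fix$REF) & nzchar(fix$ALT) & fix$REF != fix$ALT
  autosomal <- !is.na(chrom) & chrom >= 1L & chrom <= 22L
  keep <- biallelic & autosomal
  if (any(!keep))
    message(sum(!keep), " VCF record(s) dropped (",
            sum(!biallelic), " multi-allelic/invalid, ",
            sum(biallelic & !autosomal), " non-autosomal)")
  if (!any(keep)) stop("no biallelic autosomal SNPs in ", vcf_path)

  snp_id <- fix$ID
  no_id <- is.na(snp_id) | snp_id == "." | !nzchar(snp_id)
  snp_id[no_id] <- paste0(fix$CHROM[no_id], ":", fix$POS[no_id])
  snps <- data.frame(snp_id = snp_id[keep], chrom = chrom[keep],
                     pos = as.integer(fix$POS[keep]),
                     allele_a = fix$REF[keep], allele_b = fix$ALT[keep],
                     stringsAsFactors = FALSE)

  gt <- gt[keep, ids, drop = FALSE]
  # Count of ALT alleles; any separator accepted, phase ignored.
  code <- function(g) {
    out <- rep(NA_integer_, length(g))
    known <- !is.na(g) & !grepl("\\.", g)
    alleles <- strsplit(g[known], "[/|]")
    if (any(lengths(alleles) != 2L))
      stop("non-diploid GT encountered in ", vcf_path)
    a <- vapply(alleles, function(p) sum(as.integer(p)), 0L)
    out[known] <- a
    out
  }
  geno <- t(apply(gt, 2, code))  # individuals x snps
  colnames(geno) <- snps$snp_id
  rownames(geno) <- ids
  trio_cohort(snps, fam, geno)
}

#' Read trio genotypes from PLINK text PED/MAP files
#'
#' PED columns 1-6 are family, individual, father, mother, sex, phenotype,
#' followed by two allele columns per SNP; `0 0` codes a missing genotype.
#' MAP rows (chrom, snp id, genetic distance, position) align with the PED
#' allele-pair columns. Non-autosomal MAP rows are dropped.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @param population optional named character vector mapping `family_id` to a
#'   population label.
#' @return a [trio_cohort()]
#' @export
read_ped_map <- function(ped_path, map_path, population = NULL) {
  map <- utils::read.table(map_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos"))
  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  fields <- strsplit(trimws(ped_lines), "[ \t]+")
  nf <- unique(lengths(fields))
  if (length(nf) != 1L)
    stop("PED rows have inconsistent column counts: ",
         paste(nf, collapse = ", "))
  n_snp <- (nf - 6L) / 2L
  if (n_snp != nrow(map) || (nf - 6L) %% 2L != 0L)
    stop("PED/MAP mismatch: PED has ", n_snp, " genotype pair(s) but MAP has ",
         nrow(map), " row(s)")

  ped_tab <- data.frame(
    family_id = vapply(fields, `[`, "", 1L),
    id = vapply(fields, `[`, "", 2L),
    father_id = vapply(fields, `[`, "", 3L),
    mother_id = vapply(fields, `[`, "", 4L),
    sex = vapply(fields, `[`, "", 5L),
    phenotype = vapply(fields, `[`, "", 6L),
    stringsAsFactors = FALSE)
  fam <- .pedigree_trios(ped_tab, population)
  ids <- c(fam$mother_id, fam$father_id, fam$child_id)

  al <- t(vapply(fields, function(f) f[-(1:6)], character(nf - 6L)))
  rownames(al) <- ped_tab$id
  a1 <- al[, seq(1L, by = 2L, length.out = n_snp), drop = FALSE]
  a2 <- al[, seq(2L, by = 2L, length.out = n_snp), drop = FALSE]

  chrom <- .normalize_chrom(map$chrom)
  auto <- !is.na(chrom) & chrom >= 1L & chrom <= 22L
  if (any(!auto)) message(sum(!auto), " non-autosomal MAP row(s) dropped")
  geno <- matrix(NA_integer_, nrow(al), sum(auto),
                 dimnames = list(rownames(al), map$snp_id[auto]))
  allele_a <- allele_b <- character(sum(auto))
  jj <- 0L
  for (j in which(auto)) {
    jj <- jj + 1L
    x1 <- a1[, j]; x2 <- a2[, j]
    called <- x1 != "0" & x2 != "0"
    if (any((x1 == "0") != (x2 == "0")))
      stop("half-missing genotype at SNP ", map$snp_id[j])
    obs <- sort(unique(c(x1[called], x2[called])))
    if (length(obs) > 2L)
      stop("SNP ", map$snp_id[j], " has >2 alleles in PED")
    if (length(obs) == 0L) obs <- c("A", "B")
    if (length(obs) == 1L) obs <- c(obs, setdiff(c("A", "B", "C"), obs)[1])
    allele_a[jj] <- obs[1]; allele_b[jj] <- obs[2]
    geno[called, jj] <- (x1[called] == obs[2]) + (x2[called] == obs[2])
  }
  snps <- data.frame(snp_id = map$snp_id[auto], chrom = chrom[auto],
                     pos = as.integer(map$pos[auto]),
                     allele_a = allele_a, allele_b = allele_b,
                     stringsAsFactors = FALSE)
  trio_cohort(snps, fam, geno[ids, , drop = FALSE])
}

#' Write a cohort as PLINK text PED/MAP
#'
#' Inverse of [read_ped_map()]; round-trips genotypes, ids and SNP order.
#'
#' @param cohort a [trio_cohort()]
#' @param ped_path,map_path output paths
#' @return invisibly, the two paths
#' @export
write_ped_map <- function(cohort, ped_path, map_path) {
  s <- cohort$snps
  utils::write.table(
    data.frame(s$chrom, s$snp_id, 0L, s$pos),
    map_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  samp <- cohort_samples(cohort)
  fam <- cohort$families
  mother_of <- stats::setNames(fam$mother_id, fam$child_id)
  father_of <- stats::setNames(fam$father_id, fam$child_id)
  lines <- vapply(seq_len(nrow(samp)), function(i) {
    id <- samp$id[i]
    g <- cohort$geno[id, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, s$allele_b, s$allele_a))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, s$allele_b, s$allele_a))
    paste(samp$family_id[i], id,
          if (samp$role[i] == "child") father_of[[id]] else "0",
          if (samp$role[i] == "child") mother_of[[id]] else "0",
          if (samp$role[i] == "mother") "2" else
            if (samp$role[i] == "father") "1" else "0",
          "-9",
          paste(rbind(a1, a2), collapse = " "))
  }, "")
  writeLines(lines, ped_path)
  invisible(c(ped_path, map_path))
}

#' Write a cohort as VCF + FAM
#'
#' Emits an unphased VCF 4.2 with GT-only genotype fields plus a 6-column
#' pedigree file, the pair [read_trio_vcf()] consumes.
#'
#' @param cohort a [trio_cohort()]
#' @param vcf_path,fam_path output paths
#' @return invisibly, the two paths
#' @export
write_trio_vcf <- function(cohort, vcf_path, fam_path) {
  samp <- cohort_samples(cohort)
  s <- cohort$snps
  gt <- matrix("./.", nrow(s), nrow(samp))
  g <- t(cohort$geno[samp$id, , drop = FALSE])  # snps x individuals
  gt[!is.na(g) & g == 0L] <- "0/0"
  gt[!is.na(g) & g == 1L] <- "0/1"
  gt[!is.na(g) & g == 2L] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", sort(unique(s$chrom)), ">"),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samp$id), collapse = "\t"))
  body <- paste(s$chrom, s$pos, s$snp_id, s$allele_a, s$allele_b, ".",
                "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), vcf_path)
  fam <- cohort$families
  sex <- c(mother = "2", father = "1", child = "0")
  mother_of <- stats::setNames(fam$mother_id, fam$child_id)
  father_of <- stats::setNames(fam$father_id, fam$child_id)
  fam_lines <- vapply(seq_len(nrow(samp)), function(i) {
    id <- samp$id[i]
    paste(samp$family_id[i], id,
          if (samp$role[i] == "child") father_of[[id]] else "0",
          if (samp$role[i] == "child") mother_of[[id]] else "0",
          sex[[samp$role[i]]], "-9")
  }, "")
  writeLines(fam_lines, fam_path)
  invisible(c(vcf_path, fam_path))
}

#' Read a probe expression matrix and its annotation
#'
#' The matrix TSV has probe ids in the first column and child ids as the
#' remaining column headers; values are log2-scale intensities. Parsing is
#' strict: any non-numeric or missing cell is a hard error naming the cell,
#' since upstream preprocessing is expected to have produced a complete
#' matrix. Probes without an annotation row are dropped with a message, and
#' columns are re-ordered to the cohort's child order.
#'
#' @param matrix_path path to the expression TSV.
#' @param probe_annotation_path path to a TSV with columns
#'   `probe_id`, `chrom`, `start`, `end` (1-based inclusive).
#' @param cohort the [trio_cohort()] whose children the columns must match.
#' @return an [expression_matrix()]
#' @export
read_expression <- function(matrix_path, probe_annotation_path, cohort) {
  tab <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  probe_id <- tab[[1]]
  kids <- colnames(tab)[-1]
  extra <- setdiff(kids, children(cohort))
  if (length(extra))
    stop("expression column(s) not children of the cohort: ",
         paste(extra, collapse = ", "))
  raw <- as.matrix(tab[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric expression value '%s' at (%s, %s)",
                 raw[bad[1, 1], bad[1, 2]], probe_id[bad[1, 1]],
                 kids[bad[1, 2]]))
  dimnames(vals) <- list(probe_id, kids)

  ann <- utils::read.table(probe_annotation_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "start", "end")
  if (!all(need %in% names(ann)))
    stop("probe annotation must have columns: ", paste(need, collapse = ", "))
  ann$chrom <- .normalize_chrom(ann$chrom)
  ann <- ann[!is.na(ann$chrom) & ann$chrom >= 1L & ann$chrom <= 22L, ,
             drop = FALSE]
  unann <- setdiff(probe_id, ann$probe_id)
  if (length(unann))
    message(length(unann), " probe(s) without autosomal annotation dropped")
  keep <- probe_id %in% ann$probe_id
  if (!any(keep)) stop("no annotated probes remain")
  vals <- vals[keep, , drop = FALSE]
  probes <- ann[match(rownames(vals), ann$probe_id),
                c("probe_id", "chrom", "start", "end"), drop = FALSE]
  present <- intersect(children(cohort), colnames(vals))
  if (!length(present)) stop("no cohort children found in expression matrix")
  expression_matrix(vals[, present, drop = FALSE], probes)
}

#' Write an expression matrix and annotation as TSV
#' @param expr an [expression_matrix()]
#' @param matrix_path,annotation_path output paths
#' @return invisibly, the two paths
#' @export
write_expression <- function(expr, matrix_path, annotation_path) {
  tab <- data.frame(probe_id = rownames(expr$values), expr$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(expr$probes[, c("probe_id", "chrom", "start", "end")],
                     annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, annotation_path))
}

#' Read gene intervals from a BED file
#'
#' BED half-open 0-based coordinates are converted to the 1-based inclusive
#' convention used internally (`start + 1`). Non-autosomal rows are dropped.
#'
#' @param bed_path path to a BED file (chrom, start, end, name).
#' @return data.frame with columns `chrom`, `start`, `end`, `gene`
#' @export
read_gene_bed <- function(bed_path) {
  bed <- utils::read.table(bed_path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stop("BED file needs at least 4 columns (incl. name)")
  chrom <- .normalize_chrom(bed[[1]])
  keep <- !is.na(chrom) & chrom >= 1L & chrom <= 22L
  data.frame(chrom = chrom[keep],
             start = as.integer(bed[[2]][keep]) + 1L,
             end = as.integer(bed[[3]][keep]),
             gene = as.character(bed[[4]][keep]),
             stringsAsFactors = FALSE)
}

#' Write gene intervals as BED (1-based inclusive in, 0-based half-open out)
#' @param genes data.frame with `chrom`, `start`, `end`, `gene`
#' @param bed_path output path
#' @return invisibly, the path
#' @export
write_gene_bed <- function(genes, bed_path) {
  utils::write.table(
    data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene),
    bed_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(bed_path)
}

#' Read an imprinted-gene list (one gene symbol per line)
#' @param path path to a plain-text file; blank lines and `#` comments skipped
#' @return character vector of unique gene symbols
#' @export
read_imprinted_genes <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Write a result table as TSV
#'
#' Rows are ordered by chromosome, position and probe id where those columns
#' exist; p-value columns are printed in scientific notation. All records
#' must share one schema.
#'
#' @param records a data.frame of association results, LRT results or ieQTL
#'   calls, or a list of such data.frames with identical columns.
#' @param out_path output path
#' @return invisibly, the path
#' @export
write_results_table <- function(records, out_path) {
  if (is.list(records) && !is.data.frame(records)) {
    schemas <- unique(lapply(records, names))
    if (length(schemas) > 1L)
      stop("records have mixed schemas; cannot write one table")
    records <- do.call(rbind, records)
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  ord_cols <- intersect(c("chrom", "pos", "probe_id"), names(records))
  if (length(ord_cols) && nrow(records))
    records <- records[do.call(order, records[ord_cols]), , drop = FALSE]
  pcols <- grep("^(p_|lrt_p|het_support_p|conventional_p|bonferroni_)",
                names(records))
  for (j in pcols)
    records[[j]] <- ifelse(is.na(records[[j]]), NA,
                           sprintf("%.6e", records[[j]]))
  con <- tryCatch(file(out_path, "w"),
                  error = function(e) stop("cannot write ", out_path))
  on.exit(close(con))
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out_path)
}
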