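# Parental-origin assignment from unphased trio genotypes.
#
# At a biallelic SNP, the child's two alleles can be traced to the parents
# whenever at least one trio member is homozygous: a homozygous mother can
# only have transmitted her allele, which pins the child's other allele to
# the father, and symmetrically. When mother, father and child are all
# heterozygous the origin is undeterminable without external phase and the
# site is flagged rather than guessed.

.PHASE_ASSIGNED <- 1L
.PHASE_TRIPLE_HET <- 2L
.PHASE_ERROR <- 3L
.PHASE_MISSING <- 4L

.phase_status_labels <- c("assigned", "unassigned_triple_het",
                          "mendelian_error", "missing")

# Resolve one (mother, father, child) B-allele-count combination by the
# transmission rules. Returns c(status, maternal_allele, paternal_allele)
# with alleles NA unless assigned.
.phase_one <- function(gm, gf, gc) {
  if (gc == 0L) {
    if (gm == 2L || gf == 2L) return(c(.PHASE_ERROR, NA, NA))
    return(c(.PHASE_ASSIGNED, 0L, 0L))
  }
  if (gc == 2L) {
    if (gm == 0L || gf == 0L) return(c(.PHASE_ERROR, NA, NA))
    return(c(.PHASE_ASSIGNED, 1L, 1L))
  }
  # heterozygous child: mother gave A and father B, or mother B and father A
  mo_a_fa_b <- gm < 2L && gf > 0L
  mo_b_fa_a <- gm > 0L && gf < 2L
  if (!mo_a_fa_b && !mo_b_fa_a) return(c(.PHASE_ERROR, NA, NA))
  if (mo_a_fa_b && mo_b_fa_a) {
    # both orderings consistent; possible only when both parents are het
    stopifnot(gm == 1L, gf == 1L)
    return(c(.PHASE_TRIPLE_HET, NA, NA))
  }
  if (mo_a_fa_b) c(.PHASE_ASSIGNED, 0L, 1L) else c(.PHASE_ASSIGNED, 1L, 0L)
}

# Lookup over the 27 ordered trio combinations, indexed by 9*gm + 3*gf + gc + 1.
.phase_table <- local({
  tab <- matrix(NA_integer_, 27L, 3L)
  for (gm in 0:2) for (gf in 0:2) for (gc in 0:2) {
    res <- .phase_one(gm, gf, gc)
    # when both parents are homozygous for different alleles, resolution via
    # either parent must agree; cross-check the two single-parent deductions
    if (gc == 1L && gm != 1L && gf != 1L && res[1] == .PHASE_ASSIGNED)
      stopifnot(res[2] == gm / 2L, res[3] == gf / 2L)
    tab[9L * gm + 3L * gf + gc + 1L, ] <- res
  }
  tab
})

#' Assign parental origin of each child allele by Mendelian inheritance
#'
#' For every (child, SNP) cell, the unphased genotypes of mother, father and
#' child determine the maternally and paternally inherited alleles whenever
#' the trio contains at least one homozygote. Cells where any trio member is
#' ungenotyped are `missing`; cells whose genotypes admit no Mendelian
#' transmission are `mendelian_error`; all-heterozygous trios are
#' `unassigned_triple_het`. Statuses are data, not errors: downstream
#' association excludes every non-`assigned` cell.
#'
#' @param cohort a [trio_cohort()]
#' @return an object of class `phased_genotypes`: a list with integer
#'   matrices `mat` and `pat` (children x SNPs, B-allele 0/1, `NA` unless
#'   assigned) and a `status` matrix with values
#'   `"assigned"`, `"unassigned_triple_het"`, `"mendelian_error"`,
#'   `"missing"`.
#' @export
assign_parental_origin <- function(cohort) {
  fam <- cohort$families
  gm <- cohort$geno[fam$mother_id, , drop = FALSE]
  gf <- cohort$geno[fam$father_id, , drop = FALSE]
  gc <- cohort$geno[fam$child_id, , drop = FALSE]
  idx <- 9L * gm + 3L * gf + gc + 1L  # NA propagates from any missing member
  dims <- dim(gc)
  dn <- list(fam$child_id, cohort$snps$snp_id)
  status <- matrix(.PHASE_MISSING, dims[1], dims[2], dimnames = dn)
  mat <- matrix(NA_integer_, dims[1], dims[2], dimnames = dn)
  pat <- matrix(NA_integer_, dims[1], dims[2], dimnames = dn)
  ok <- !is.na(idx)
  status[ok] <- .phase_table[idx[ok], 1L]
  mat[ok] <- .phase_table[idx[ok], 2L]
  pat[ok] <- .phase_table[idx[ok], 3L]
  structure(list(mat = mat, pat = pat,
                 status = matrix(.phase_status_labels[status], dims[1],
                                 dims[2], dimnames = dn)),
            class = "phased_genotypes")
}

#' @export
print.phased_genotypes <- function(x, ...) {
  tab <- table(factor(x$status, levels = .phase_status_labels))
  cat(sprintf("phased_genotypes: %d children x %d SNPs (%s)\n",
              nrow(x$status), ncol(x$status),
              paste(sprintf("%s %d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

#' Per-child phasing summary
#'
#' Counts each assignment status per child and reports the assignability
#' fraction, assigned / (assigned + triple-het): the fraction of sites with
#' genotypes in all three trio members at which Mendelian logic determines
#' parental origin. `NaN` when no such site exists.
#'
#' @param phased a `phased_genotypes` object
#' @return data.frame with one row per child: status counts and
#'   `assignability`
#' @export
summarize_phasing <- function(phased) {
  counts <- vapply(.phase_status_labels, function(s)
    rowSums(phased$status == s), numeric(nrow(phased$status)))
  counts <- matrix(counts, nrow = nrow(phased$status),
                   dimnames = list(NULL, .phase_status_labels))
  out <- data.frame(child_id = rownames(phased$status), counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  denom <- out$assigned + out$unassigned_triple_het
  out$assignability <- ifelse(denom > 0, out$assigned / denom, NaN)
  out
}

#' Export phased genotypes as a long TSV
#' @param phased a `phased_genotypes` object
#' @param out_path output path
#' @return invisibly, the path
#' @export
write_phasing <- function(phased, out_path) {
  long <- data.frame(
    child_id = rep(rownames(phased$status), ncol(phased$status)),
    snp_id = rep(colnames(phased$status), each = nrow(phased$status)),
    maternal_allele = as.vector(phased$mat),
    paternal_allele = as.vector(phased$pat),
    status = as.vector(phased$status),
    stringsAsFactors = FALSE)
  utils::write.table(long, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out_path)
}
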