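# Shared fixtures and independent oracles.

# Brute-force transmission enumerator: all ordered (maternal, paternal)
# allele pairs consistent with the trio's unphased B-allele counts.
enumerate_transmissions <- function(gm, gf, gc) {
  mats <- if (gm == 1L) 0:1 else gm %/% 2L
  pats <- if (gf == 1L) 0:1 else gf %/% 2L
  out <- list()
  for (a in mats) for (b in pats)
    if (a + b == gc) out[[length(out) + 1L]] <- c(mat = a, pat = b)
  unique(out)
}

# Oracle status/alleles from the enumerator alone.
oracle_phase <- function(gm, gf, gc) {
  cons <- enumerate_transmissions(gm, gf, gc)
  if (length(cons) == 0L)
    list(status = "mendelian_error", mat = NA_integer_, pat = NA_integer_)
  else if (length(cons) == 1L)
    list(status = "assigned", mat = cons[[1]]["mat"],
         pat = cons[[1]]["pat"])
  else
    list(status = "unassigned_triple_het", mat = NA_integer_,
         pat = NA_integer_)
}

# Cohort of n_fam trios from explicit B-allele-count matrices
# (families x snps). Positions spaced 1 bp apart on chr1 unless given.
toy_cohort <- function(gm, gf, gc, pos = NULL, chrom = NULL,
                       population = NULL) {
  gm <- rbind(gm); gf <- rbind(gf); gc <- rbind(gc)
  nf <- nrow(gm); ns <- ncol(gm)
  fam_id <- sprintf("T%02d", seq_len(nf))
  fam <- data.frame(family_id = fam_id,
                    mother_id = paste0(fam_id, "_M"),
                    father_id = paste0(fam_id, "_F"),
                    child_id = paste0(fam_id, "_C"),
                    population = if (is.null(population)) "POP1"
                    else population,
                    stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = sprintf("s%02d", seq_len(ns)),
                     chrom = if (is.null(chrom)) 1L else chrom,
                     pos = if (is.null(pos)) 1000L + seq_len(ns) else pos,
                     allele_a = "A", allele_b = "G",
                     stringsAsFactors = FALSE)
  geno <- rbind(gm, gf, gc)
  rownames(geno) <- c(fam$mother_id, fam$father_id, fam$child_id)
  colnames(geno) <- snps$snp_id
  trio_cohort(snps, fam, geno)
}

# Expression matrix over a cohort's children from a probes x children
# value matrix; probes placed at synthetic chr1 positions unless given.
toy_expr <- function(cohort, values, chrom = 1L, start = NULL,
                     end = NULL, gene = NA_character_) {
  values <- rbind(values)
  np <- nrow(values)
  rownames(values) <- sprintf("p%02d", seq_len(np))
  colnames(values) <- children(cohort)
  if (is.null(start)) start <- 1000L * seq_len(np)
  if (is.null(end)) end <- start + 50L
  probes <- data.frame(probe_id = rownames(values),
                       chrom = chrom, start = start, end = end,
                       gene = gene, stringsAsFactors = FALSE)
  expression_matrix(values, probes)
}

# Two-sided Fisher's exact p by direct hypergeometric enumeration:
# the sum of probabilities of all tables (with the observed margins) whose
# point probability does not exceed the observed one.
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric by direct summation.
hyper_upper_oracle <- function(x, K, N, n) {
  ks <- x:min(K, n)
  if (x > min(K, n)) return(0)
  sum(stats::dhyper(ks, K, N - K, n))
}

# 99% binomial CI half-width check around p0.
within_binom_ci99 <- function(frac, p0, n) {
  abs(frac - p0) <= stats::qnorm(0.995) * sqrt(p0 * (1 - p0) / n)
}
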