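# Cis SNP-probe pairing and the four association regimes.
#
# The parental regimes regress expression on the haploid minor-allele
# indicator of one parental haplotype (0/1). This is the same regression a
# diploid association tool performs on those haplotypes recoded as
# artificial homozygotes (0/2 dosage): the slope halves, the t statistic
# and p-value are identical. Betas are reported on the 0/1 haploid scale.

#' Build cis SNP-probe pairs
#'
#' A SNP is paired with a probe when both lie on the same chromosome and
#' the SNP is within `window` bp of the probe midpoint
#' (`floor((start + end) / 2)`), boundary inclusive.
#'
#' @param snps SNP table (`snp_id`, `chrom`, `pos`)
#' @param probes probe table (`probe_id`, `chrom`, `start`, `end`, optional
#'   `gene`)
#' @param window half-width of the cis window in bp (default 1e6, i.e. a
#'   2 Mb window centred on the probe midpoint)
#' @return data.frame with columns `snp_id`, `probe_id`, `gene`, `chrom`,
#'   `pos`, `distance` (signed, SNP pos minus probe midpoint)
#' @export
build_cis_pairs <- function(snps, probes, window = 1e6) {
  stopifnot(nrow(snps) > 0, nrow(probes) > 0)
  mid <- probe_midpoint(probes)
  if (is.null(probes$gene)) probes$gene <- NA_character_
  out <- vector("list", nrow(probes))
  for (i in seq_len(nrow(probes))) {
    j <- which(snps$chrom == probes$chrom[i] &
                 abs(snps$pos - mid[i]) <= window)
    if (!length(j)) next
    out[[i]] <- data.frame(snp_id = snps$snp_id[j],
                           probe_id = probes$probe_id[i],
                           gene = probes$gene[i],
                           chrom = snps$chrom[j], pos = snps$pos[j],
                           distance = snps$pos[j] - mid[i],
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(snp_id = character(), probe_id = character(),
                      gene = character(), chrom = integer(), pos = integer(),
                      distance = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Simple quantitative-trait regression
#'
#' Ordinary least squares of expression on a numeric dosage with an
#' intercept; the slope's Wald t statistic is referred to a t distribution
#' with n - 2 degrees of freedom, two-sided. Pairs with missing dosage or
#' response are dropped first. The test is not run (`tested = FALSE`) when
#' fewer than `min_n` complete observations remain or the dosage is
#' constant.
#'
#' @param dosage numeric predictor per child (`NA` = excluded)
#' @param expr numeric response per child
#' @param min_n minimum complete observations (default 20)
#' @return list: `tested`, `reason` (when untested), `n`, `beta`, `tstat`,
#'   `p`
#' @export
regress_qt <- function(dosage, expr, min_n = 20L) {
  keep <- !is.na(dosage) & !is.na(expr)
  x <- dosage[keep]; y <- expr[keep]
  n <- length(x)
  untested <- function(reason)
    list(tested = FALSE, reason = reason, n = n,
         beta = NA_real_, tstat = NA_real_, p = NA_real_)
  if (n < min_n) return(untested("too_few_individuals"))
  sxx <- sum(x * x) - sum(x)^2 / n
  if (sxx == 0) return(untested("constant_dosage"))
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  syy <- sum(y * y) - sum(y)^2 / n
  beta <- sxy / sxx
  rss <- max(0, syy - beta * sxy)
  if (rss == 0) {
    if (beta == 0)  # constant response: nothing to explain
      return(list(tested = TRUE, reason = NA_character_, n = n, beta = 0,
                  tstat = 0, p = 1))
    return(list(tested = TRUE, reason = NA_character_, n = n, beta = beta,
                tstat = sign(beta) * Inf, p = 0))
  }
  se <- sqrt(rss / (n - 2L) / sxx)
  tstat <- beta / se
  list(tested = TRUE, reason = NA_character_, n = n, beta = beta,
       tstat = tstat, p = 2 * stats::pt(-abs(tstat), n - 2L))
}

# Run one regime given a children x SNPs dosage matrix. Bonferroni is per
# probe within the regime, with the multiplier equal to the number of
# *tested* cis SNPs for that probe.
.run_regime <- function(dosage, expr, pairs, regime, min_n) {
  np <- nrow(pairs)
  res <- data.frame(pairs, regime = rep(regime, np),
                    n = integer(np), beta = rep(NA_real_, np),
                    tstat = rep(NA_real_, np),
                    p_nominal = rep(NA_real_, np),
                    p_bonferroni = rep(NA_real_, np),
                    tested = logical(np), reason = rep(NA_character_, np),
                    stringsAsFactors = FALSE)
  if (!np) return(res)
  v <- expr$values
  for (k in seq_len(np)) {
    x <- dosage[, pairs$snp_id[k]]
    y <- v[pairs$probe_id[k], ]
    r <- regress_qt(x, y, min_n = min_n)
    res$n[k] <- r$n; res$beta[k] <- r$beta; res$tstat[k] <- r$tstat
    res$p_nominal[k] <- r$p; res$tested[k] <- r$tested
    res$reason[k] <- r$reason
  }
  m <- stats::ave(as.numeric(res$tested), res$probe_id, FUN = sum)
  res$p_bonferroni <- pmin(1, res$p_nominal * m)
  res
}

# Children x SNPs dosage of the minor allele on one parental haplotype;
# non-assigned cells are NA.
.parental_dosage <- function(phased, cohort, parent = c("mat", "pat")) {
  parent <- match.arg(parent)
  hap <- phased[[parent]]
  mb <- matrix(minor_is_b(cohort), nrow(hap), ncol(hap), byrow = TRUE)
  dos <- ifelse(mb, hap, 1L - hap)
  dos[phased$status != "assigned"] <- NA_integer_
  dimnames(dos) <- dimnames(hap)
  dos
}

#' Association with maternally inherited alleles
#'
#' For each cis pair, expression is regressed on the count (0/1) of the
#' minor allele on the maternally inherited haplotype; children without an
#' assigned parental origin at the SNP are excluded.
#'
#' @param phased `phased_genotypes` from [assign_parental_origin()]
#' @param expr an [expression_matrix()]
#' @param pairs cis pairs from [build_cis_pairs()]
#' @param cohort the [trio_cohort()] (fixes the minor-allele coding)
#' @param min_n minimum informative children per test (default 20)
#' @return data.frame of association results, one row per cis pair, with
#'   `beta`, `tstat`, `p_nominal` and per-probe `p_bonferroni`
#' @export
run_maternal <- function(phased, expr, pairs, cohort, min_n = 20L) {
  .run_regime(.parental_dosage(phased, cohort, "mat"), expr, pairs,
              "maternal", min_n)
}

#' Association with paternally inherited alleles
#' @inheritParams run_maternal
#' @return data.frame of association results (regime `"paternal"`)
#' @export
run_paternal <- function(phased, expr, pairs, cohort, min_n = 20L) {
  .run_regime(.parental_dosage(phased, cohort, "pat"), expr, pairs,
              "paternal", min_n)
}

#' Reciprocal-heterozygote comparison
#'
#' Children are restricted to assigned heterozygotes at the SNP and split
#' by parental origin: group 0 carries the minor allele maternally, group 1
#' paternally. Expression is regressed on the group indicator, which is
#' exactly the pooled-variance two-sample t-test. The pair is untested when
#' fewer than `min_het` heterozygotes are available (or either class is
#' empty, which makes the indicator constant).
#'
#' @inheritParams run_maternal
#' @param min_het minimum total heterozygotes (default 8)
#' @return data.frame of association results (regime `"heterozygote"`)
#' @export
run_heterozygote <- function(phased, expr, pairs, cohort, min_het = 8L) {
  mb <- matrix(minor_is_b(cohort), nrow(phased$mat), ncol(phased$mat),
               byrow = TRUE)
  het <- phased$status == "assigned" & (phased$mat != phased$pat)
  minor_mat <- ifelse(mb, phased$mat == 1L, phased$mat == 0L)
  grp <- ifelse(het, 1L - as.integer(minor_mat), NA_integer_)
  dimnames(grp) <- dimnames(phased$mat)
  .run_regime(grp, expr, pairs, "heterozygote", min_n = min_het)
}

#' Conventional diploid association
#'
#' Expression regressed on the diploid minor-allele count (0/1/2), ignoring
#' parental origin; children with missing genotypes are excluded.
#'
#' @inheritParams run_maternal
#' @return data.frame of association results (regime `"conventional"`)
#' @export
run_conventional <- function(cohort, expr, pairs, min_n = 20L) {
  g <- cohort$geno[children(cohort), , drop = FALSE]
  mb <- matrix(minor_is_b(cohort), nrow(g), ncol(g), byrow = TRUE)
  dos <- ifelse(mb, g, 2L - g)
  dimnames(dos) <- dimnames(g)
  .run_regime(dos, expr, pairs, "conventional", min_n)
}
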