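# Imprinting likelihood ratio test: a full linear model with separate
# maternal and paternal minor-allele effects,
#   Y = b0 + bM * X_MAT + bP * X_PAT + e,
# against the reduced (non-imprinting) model on the combined dosage,
#   Y = b0' + bB' * (X_MAT + X_PAT) + e.
# The models are nested (bM = bP recovers the reduced model), so under
# Gaussian errors the maximum-likelihood ratio statistic is
# n * ln(RSS_reduced / RSS_full), referred to chi-square with 1 df.

#' Fit the imprinting LRT for one SNP-probe pair
#'
#' @param x_mat 0/1 minor-allele count on the maternal haplotype per child
#'   (`NA` = excluded)
#' @param x_pat 0/1 minor-allele count on the paternal haplotype per child
#' @param expr expression per child
#' @param min_n minimum complete observations (default 20)
#' @param method `"chisq"` (default): n*ln(RSS ratio) against chi-square(1);
#'   `"ftest"`: the equivalent extra-sum-of-squares F test with
#'   (1, n - 3) df, available for sensitivity analysis.
#' @return list with `tested`, `reason`, `n`, full-model coefficients
#'   (`beta0`, `beta_m`, `beta_p`), reduced-model coefficients (`beta0_b`,
#'   `beta_b`), `rss_full`, `rss_reduced`, `lrt_stat`, `p`
#' @export
fit_lrt <- function(x_mat, x_pat, expr, min_n = 20L,
                    method = c("chisq", "ftest")) {
  method <- match.arg(method)
  keep <- !is.na(x_mat) & !is.na(x_pat) & !is.na(expr)
  xm <- as.numeric(x_mat[keep]); xp <- as.numeric(x_pat[keep])
  y <- as.numeric(expr[keep])
  n <- length(y)
  untested <- function(reason)
    list(tested = FALSE, reason = reason, n = n,
         beta0 = NA_real_, beta_m = NA_real_, beta_p = NA_real_,
         beta0_b = NA_real_, beta_b = NA_real_,
         rss_full = NA_real_, rss_reduced = NA_real_,
         lrt_stat = NA_real_, p = NA_real_)
  if (n < min_n) return(untested("too_few_individuals"))
  X <- cbind(1, xm, xp)
  if (qr(X)$rank < 3L) return(untested("not_identifiable"))
  fit_f <- stats::lm.fit(X, y)
  rss_f <- sum(fit_f$residuals^2)
  fit_r <- stats::lm.fit(cbind(1, xm + xp), y)
  rss_r <- sum(fit_r$residuals^2)
  if (rss_f <= 1e-12 * max(1, sum(y^2)))
    return(untested("degenerate_perfect_fit"))
  stat <- max(0, n * log(rss_r / rss_f))
  p <- if (method == "chisq") {
    stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  } else {
    f <- (rss_r - rss_f) / (rss_f / (n - 3L))
    stats::pf(max(0, f), 1L, n - 3L, lower.tail = FALSE)
  }
  list(tested = TRUE, reason = NA_character_, n = n,
       beta0 = unname(fit_f$coefficients[1]),
       beta_m = unname(fit_f$coefficients[2]),
       beta_p = unname(fit_f$coefficients[3]),
       beta0_b = unname(fit_r$coefficients[1]),
       beta_b = unname(fit_r$coefficients[2]),
       rss_full = rss_f, rss_reduced = rss_r,
       lrt_stat = if (method == "chisq") stat else
         (rss_r - rss_f) / (rss_f / (n - 3L)),
       p = p)
}

#' Genome-wide imprinting LRT screen
#'
#' Runs [fit_lrt()] over every cis pair, using exactly the children with
#' assigned parental origin at the SNP (the same exclusion set as the
#' parental regimes, so all tests see identical samples). Bonferroni
#' correction is per probe over the tested cis SNPs, as in the association
#' regimes.
#'
#' @param phased `phased_genotypes` from [assign_parental_origin()]
#' @param expr an [expression_matrix()]
#' @param pairs cis pairs from [build_cis_pairs()]
#' @param cohort the [trio_cohort()] (fixes the minor-allele coding)
#' @param min_n minimum informative children per test (default 20)
#' @param method passed to [fit_lrt()]
#' @return data.frame with one row per cis pair: `beta_m`, `beta_p`,
#'   `beta_b`, `lrt_stat`, `p_lrt`, `p_bonferroni`, `tested`, `reason`
#' @export
run_lrt_screen <- function(phased, expr, pairs, cohort, min_n = 20L,
                           method = c("chisq", "ftest")) {
  method <- match.arg(method)
  dm <- .parental_dosage(phased, cohort, "mat")
  dp <- .parental_dosage(phased, cohort, "pat")
  np <- nrow(pairs)
  res <- data.frame(pairs, n = integer(np),
                    beta_m = rep(NA_real_, np), beta_p = rep(NA_real_, np),
                    beta_b = rep(NA_real_, np),
                    lrt_stat = rep(NA_real_, np),
                    p_lrt = rep(NA_real_, np),
                    p_bonferroni = rep(NA_real_, np),
                    tested = logical(np),
                    reason = rep(NA_character_, np),
                    stringsAsFactors = FALSE)
  if (!np) return(res)
  for (k in seq_len(np)) {
    r <- fit_lrt(dm[, pairs$snp_id[k]], dp[, pairs$snp_id[k]],
                 expr$values[pairs$probe_id[k], ], min_n = min_n,
                 method = method)
    res$n[k] <- r$n; res$beta_m[k] <- r$beta_m; res$beta_p[k] <- r$beta_p
    res$beta_b[k] <- r$beta_b; res$lrt_stat[k] <- r$lrt_stat
    res$p_lrt[k] <- r$p; res$tested[k] <- r$tested; res$reason[k] <- r$reason
  }
  m <- stats::ave(as.numeric(res$tested), res$probe_id, FUN = sum)
  res$p_bonferroni <- pmin(1, res$p_lrt * m)
  res
}
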