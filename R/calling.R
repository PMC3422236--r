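# ieQTL calling: best-SNP selection per probe, the parent-of-origin
# decision rules, and imprinted-gene enrichment.

#' Most significant SNP for one probe in one regime
#'
#' Among tested results, the row with the smallest nominal p; ties are
#' broken by smaller absolute distance to the probe midpoint, then
#' lexicographic snp id, for determinism under LD-duplicated SNPs.
#'
#' @param results association-result rows for a single probe and regime
#' @return the selected row (or NULL when nothing was tested)
#' @export
select_best_snp <- function(results) {
  stopifnot(nrow(results) > 0)
  res <- results[results$tested, , drop = FALSE]
  if (!nrow(res)) return(NULL)
  res[order(res$p_nominal, abs(res$distance), res$snp_id)[1], , drop = FALSE]
}

#' Call imprinted eQTLs from the association regimes
#'
#' For each probe and each parental regime, the best cis SNP is taken; a
#' call is emitted when its nominal p in that regime is below the
#' suggestive threshold while the *same SNP* shows no evidence of
#' association in the other parental regime (p above `other_max`). Calls
#' with p below `sig` are tiered `"significant"`, the rest `"suggestive"`.
#' The chosen SNP's heterozygote-comparison, conventional and LRT p-values
#' are attached as supporting evidence where those tests ran. Multi-gene
#' probes yield one row per overlapping gene; a probe called in both
#' parental directions (via different SNPs) has both rows flagged.
#'
#' @param maternal,paternal association results from [run_maternal()] /
#'   [run_paternal()]
#' @param het,conventional,lrt optional supporting results ([run_heterozygote()],
#'   [run_conventional()], [run_lrt_screen()])
#' @param sig significant-tier nominal p threshold (default 1e-7)
#' @param sug suggestive-tier nominal p threshold (default 1e-6)
#' @param other_max other-parent screen: same-SNP p in the other parental
#'   regime must exceed this (default 0.05)
#' @return data.frame of calls: probe, gene, SNP, parent, tier, same- and
#'   other-parent nominal and Bonferroni p, supporting p-values, and a flag
#'   for probes called in both parental directions
#' @export
call_ieqtls <- function(maternal, paternal, het = NULL, conventional = NULL,
                        lrt = NULL, sig = 1e-7, sug = 1e-6,
                        other_max = 0.05) {
  stopifnot(sig < sug, sug <= other_max)
  key <- function(d) paste(d$snp_id, d$probe_id)
  lookup <- function(d, col, k) {
    if (is.null(d)) return(NA_real_)
    i <- match(k, key(d))
    if (is.na(i) || !d$tested[i]) return(NA_real_)
    d[[col]][i]
  }
  calls <- list()
  for (parent in c("maternal", "paternal")) {
    same <- if (parent == "maternal") maternal else paternal
    other <- if (parent == "maternal") paternal else maternal
    for (pb in unique(same$probe_id)) {
      best <- select_best_snp(same[same$probe_id == pb, , drop = FALSE])
      if (is.null(best) || !(best$p_nominal < sug)) next
      k <- key(best)
      p_other <- lookup(other, "p_nominal", k)
      if (is.na(p_other) || !(p_other > other_max)) next
      genes <- if (is.na(best$gene)) NA_character_ else
        strsplit(best$gene, ",", fixed = TRUE)[[1]]
      calls[[length(calls) + 1L]] <- data.frame(
        probe_id = pb, gene = genes, best_snp_id = best$snp_id,
        chrom = best$chrom, pos = best$pos, parent = parent,
        tier = if (best$p_nominal < sig) "significant" else "suggestive",
        n = best$n, beta = best$beta,
        p_same_parent = best$p_nominal,
        bonferroni_same = best$p_bonferroni,
        p_other_parent = p_other,
        bonferroni_other = lookup(other, "p_bonferroni", k),
        het_support_p = lookup(het, "p_nominal", k),
        conventional_p = lookup(conventional, "p_nominal", k),
        lrt_p = lookup(lrt, "p_lrt", k),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls))
    return(data.frame(probe_id = character(), gene = character(),
                      best_snp_id = character(), chrom = integer(),
                      pos = integer(), parent = character(),
                      tier = character(), n = integer(), beta = numeric(),
                      p_same_parent = numeric(), bonferroni_same = numeric(),
                      p_other_parent = numeric(),
                      bonferroni_other = numeric(),
                      het_support_p = numeric(), conventional_p = numeric(),
                      lrt_p = numeric(), both_parents_flag = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  dirs <- tapply(out$parent, out$probe_id,
                 function(x) length(unique(x)))
  out$both_parents_flag <- unname(dirs[out$probe_id] > 1L)
  rownames(out) <- NULL
  out
}

#' Imprinted-gene enrichment of the called set
#'
#' Tests whether the genes carrying ieQTL calls are enriched for known
#' imprinted genes, by the upper-tail hypergeometric probability of drawing
#' at least the observed number of imprinted genes when `called_genes` genes
#' are drawn from the tested universe. Fold enrichment is observed over
#' expected count under random draws.
#'
#' @param calls data.frame from [call_ieqtls()] (unique genes are counted)
#' @param universe character vector: all genes with at least one tested
#'   probe
#' @param imprinted character vector of known imprinted gene symbols
#' @return one-row data.frame: `universe_genes`, `imprinted_in_universe`,
#'   `called_genes`, `imprinted_called`, `fold_enrichment`,
#'   `p_hypergeometric`
#' @export
enrichment_test <- function(calls, universe, imprinted) {
  universe <- unique(universe)
  stopifnot(length(universe) > 0)
  called <- unique(calls$gene[!is.na(calls$gene)])
  if (!all(called %in% universe))
    stop("called gene(s) outside the tested universe: ",
         paste(setdiff(called, universe), collapse = ", "))
  N <- length(universe)
  K <- sum(universe %in% imprinted)
  n <- length(called)
  x <- sum(called %in% imprinted)
  expected <- n * K / N
  fold <- if (K == 0) NA_real_ else if (x == 0) 0 else x / expected
  p <- if (x == 0) 1 else
    stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(universe_genes = N, imprinted_in_universe = K,
             called_genes = n, imprinted_called = x,
             fold_enrichment = fold, p_hypergeometric = p)
}
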