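# SNP and expression quality filters, including the cross-population
# stratification screens used when two populations are pooled in one
# association analysis, and probe-to-gene interval mapping.

#' Filter configuration
#'
#' Thresholds for the SNP and expression quality filters. Boundary behaviour:
#' SNPs with MAF below `maf_min` or call rate below `callrate_min` are
#' removed (values exactly at the threshold are retained); probes with mean
#' log2 intensity below `expr_intensity_min` or sample SD below
#' `expr_sd_min` are removed.
#'
#' @param maf_min minimum per-population minor allele frequency (default
#'   0.10).
#' @param callrate_min minimum per-population genotyped fraction (default
#'   0.90).
#' @param strat_snp_alpha Fisher's-exact p below which a SNP is removed for
#'   cross-population allele-frequency difference (default 0.05).
#' @param expr_intensity_min minimum mean log2 intensity (default 6).
#' @param expr_sd_min minimum across-children sample SD, log2 units
#'   (default 0.2).
#' @param strat_expr_alpha two-sample t-test p below which a probe is
#'   removed for cross-population expression difference (default 0.05).
#' @param strat_founders_only use founders only (not children) for the
#'   stratification allele counts, so each transmitted allele is counted
#'   once (default TRUE).
#' @param intensity_stat `"mean"` (default) or `"median"`: the per-probe
#'   location statistic compared against `expr_intensity_min`.
#' @return a `filter_config` list
#' @export
filter_config <- function(maf_min = 0.10, callrate_min = 0.90,
                          strat_snp_alpha = 0.05,
                          expr_intensity_min = 6, expr_sd_min = 0.2,
                          strat_expr_alpha = 0.05,
                          strat_founders_only = TRUE,
                          intensity_stat = c("mean", "median")) {
  stopifnot(maf_min >= 0, maf_min <= 0.5,
            callrate_min >= 0, callrate_min <= 1,
            strat_snp_alpha > 0, strat_snp_alpha < 1,
            expr_sd_min >= 0,
            strat_expr_alpha > 0, strat_expr_alpha < 1)
  structure(list(maf_min = maf_min, callrate_min = callrate_min,
                 strat_snp_alpha = strat_snp_alpha,
                 expr_intensity_min = expr_intensity_min,
                 expr_sd_min = expr_sd_min,
                 strat_expr_alpha = strat_expr_alpha,
                 strat_founders_only = strat_founders_only,
                 intensity_stat = match.arg(intensity_stat)),
            class = "filter_config")
}

.report_row <- function(stage, input, removed) {
  data.frame(stage = stage, input = input, removed = removed,
             retained = input - removed, stringsAsFactors = FALSE)
}

#' Per-population MAF and call-rate filter
#'
#' A SNP is retained only if, within every population separately, its minor
#' allele frequency is at least `maf_min` and the fraction of genotyped trio
#' members is at least `callrate_min`. Both statistics are computed over all
#' trio members (parents and children) of that population.
#'
#' @param cohort a [trio_cohort()]
#' @param config a [filter_config()]
#' @return list with elements `cohort` (filtered) and `report` (per-stage
#'   counts)
#' @export
filter_snps <- function(cohort, config = filter_config()) {
  samp <- cohort_samples(cohort)
  pops <- unique(samp$population)
  keep <- rep(TRUE, nrow(cohort$snps))
  for (p in pops) {
    ids <- samp$id[samp$population == p]
    if (!length(ids)) stop("population ", p, " has zero individuals")
    g <- cohort$geno[ids, , drop = FALSE]
    callrate <- colMeans(!is.na(g))
    fb <- colMeans(g, na.rm = TRUE) / 2
    maf <- pmin(fb, 1 - fb)
    maf[is.nan(maf)] <- 0
    keep <- keep & callrate >= config$callrate_min & maf >= config$maf_min
  }
  list(cohort = subset_snps(cohort, keep),
       report = .report_row("snp_maf_callrate", length(keep), sum(!keep)))
}

#' Cross-population allele-frequency stratification screen
#'
#' With exactly two populations, each SNP's minor/major allele counts are
#' tabulated per population (founders only by default) and SNPs whose
#' frequencies differ at `strat_snp_alpha` by a two-sided Fisher's exact
#' test are removed, so that frequency differences between the pooled
#' populations cannot masquerade as expression associations. With any other
#' number of populations the cohort is returned unchanged with a message.
#'
#' @param cohort a [trio_cohort()]
#' @param config a [filter_config()]
#' @return list with elements `cohort` and `report`
#' @export
filter_snp_stratification <- function(cohort, config = filter_config()) {
  samp <- cohort_samples(cohort)
  pops <- sort(unique(samp$population))
  n <- nrow(cohort$snps)
  if (length(pops) != 2L) {
    message("stratification screen skipped: ", length(pops),
            " population(s) present")
    return(list(cohort = cohort,
                report = .report_row("snp_stratification", n, 0L)))
  }
  use <- if (config$strat_founders_only) samp$role != "child" else TRUE
  minor_b <- minor_is_b(cohort)
  counts <- lapply(pops, function(p) {
    ids <- samp$id[samp$population == p & use]
    g <- cohort$geno[ids, , drop = FALSE]
    nb <- colSums(g, na.rm = TRUE)            # B alleles
    tot <- 2 * colSums(!is.na(g))
    minor <- ifelse(minor_b, nb, tot - nb)
    cbind(minor = minor, major = tot - minor)
  })
  pvals <- vapply(seq_len(n), function(j) {
    tab <- rbind(counts[[1]][j, ], counts[[2]][j, ])
    if (any(rowSums(tab) == 0)) return(1)
    stats::fisher.test(tab)$p.value
  }, 0)
  keep <- pvals >= config$strat_snp_alpha
  list(cohort = subset_snps(cohort, keep),
       report = .report_row("snp_stratification", n, sum(!keep)))
}

# Pooled-variance (Student) two-sample t-test, two-sided. Zero pooled
# variance is handled deterministically: equal means give t = 0, p = 1;
# unequal means give t = +-Inf, p = 0.
.pooled_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2L
  d <- mean(x) - mean(y)
  s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
  se <- sqrt(s2 * (1 / nx + 1 / ny))
  tstat <- if (se == 0) ifelse(d == 0, 0, sign(d) * Inf) else d / se
  p <- if (is.infinite(tstat)) 0 else 2 * stats::pt(-abs(tstat), df)
  list(tstat = tstat, df = df, p = p)
}

#' Expression intensity, variability and stratification filters
#'
#' A probe is removed when its location statistic (mean log2 intensity by
#' default) is below `expr_intensity_min` or its sample SD (n-1 denominator)
#' across children is below `expr_sd_min`. When the cohort has exactly two
#' populations, a second stage removes probes whose expression differs
#' between the populations by a two-sided pooled-variance (Student) t-test
#' at `strat_expr_alpha`.
#'
#' @param expr an [expression_matrix()]
#' @param cohort the matching [trio_cohort()] (supplies per-child population
#'   labels)
#' @param config a [filter_config()]
#' @return list with elements `expr` and `report` (one row per stage)
#' @export
filter_expression <- function(expr, cohort, config = filter_config()) {
  v <- expr$values
  loc <- if (config$intensity_stat == "mean") rowMeans(v)
         else apply(v, 1, stats::median)
  sds <- apply(v, 1, stats::sd)
  keep1 <- loc >= config$expr_intensity_min & sds >= config$expr_sd_min
  report <- .report_row("expr_intensity_sd", nrow(v), sum(!keep1))
  expr <- subset_probes(expr, keep1)

  fam <- cohort$families
  pop_of_child <- stats::setNames(fam$population, fam$child_id)
  pops <- sort(unique(pop_of_child[colnames(expr$values)]))
  if (length(pops) == 2L) {
    grp <- pop_of_child[colnames(expr$values)]
    if (any(table(factor(grp, levels = pops)) < 2L))
      stop("each population needs >= 2 children for the expression t-test")
    i1 <- grp == pops[1]; i2 <- grp == pops[2]
    p <- vapply(seq_len(nrow(expr$values)), function(r)
      .pooled_t_test(expr$values[r, i1], expr$values[r, i2])$p, 0)
    keep2 <- p >= config$strat_expr_alpha
    report <- rbind(report, .report_row("expr_stratification",
                                        length(keep2), sum(!keep2)))
    expr <- subset_probes(expr, keep2)
  } else {
    report <- rbind(report, .report_row("expr_stratification",
                                        nrow(expr$values), 0L))
  }
  list(expr = expr, report = report)
}

#' Map probes to genes by genomic overlap
#'
#' A probe is annotated with every gene interval it overlaps by at least
#' 1 bp (both in 1-based inclusive coordinates); probes overlapping no gene
#' are dropped. Probes overlapping several genes keep all labels,
#' comma-separated; downstream calling emits one row per gene.
#'
#' @param expr an [expression_matrix()]
#' @param genes data.frame with `chrom`, `start`, `end`, `gene` (1-based
#'   inclusive, as from [read_gene_bed()])
#' @return list with elements `expr` (gene-annotated, unmapped probes
#'   dropped) and `report`
#' @export
map_probes_to_genes <- function(expr, genes) {
  pr <- GenomicRanges::GRanges(
    seqnames = expr$probes$chrom,
    ranges = IRanges::IRanges(expr$probes$start, expr$probes$end))
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(pr, gr, minoverlap = 1L)
  lab <- tapply(genes$gene[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits),
                function(g) paste(sort(unique(g)), collapse = ","))
  gene <- rep(NA_character_, nrow(expr$probes))
  gene[as.integer(names(lab))] <- unname(lab)
  n <- nrow(expr$probes)
  keep <- !is.na(gene)
  probes <- expr$probes
  probes$gene <- gene
  out <- expression_matrix(expr$values, probes)
  list(expr = subset_probes(out, keep),
       report = .report_row("probe_gene_overlap", n, sum(!keep)))
}
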