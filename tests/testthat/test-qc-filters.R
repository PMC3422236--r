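# SNP and expression QC filters and the stratification screens.

test_that("MAF and call-rate thresholds apply per population, boundaries inclusive", {
  # 10 trios, 2 populations of 5; genotypes built per SNP to hit boundaries
  nf <- 10L
  pop <- rep(c("CEU", "YRI"), each = 5)
  # s1: MAF 0.09 (below) in CEU via founders+children; easier: one pop low
  # build with explicit columns: 30 individuals per SNP
  mk <- function(bcounts) matrix(bcounts, nrow = nf)
  # s1: CEU all hom major except tiny; YRI common
  gm <- cbind(c(1L, rep(0L, 4), rep(1L, 5)),   # s1
              c(rep(1L, 10)),                  # s2 MAF 0.5-ish everywhere
              c(rep(1L, 10)))                  # s3 callrate case
  gf <- cbind(c(rep(0L, 5), rep(1L, 5)),
              c(rep(1L, 10)),
              c(rep(1L, 10)))
  gc <- cbind(c(rep(0L, 5), rep(1L, 5)),
              c(rep(0L, 10)),
              c(rep(1L, 10)))
  gc[1:2, 3] <- NA_integer_  # s3: 2 of 15 CEU members missing -> 86.7% < 90%
  cohort <- toy_cohort(gm, gf, gc, population = pop)
  out <- filter_snps(cohort, filter_config())
  # s1: CEU B-allele count 1/30 = MAF 0.033 -> removed
  expect_false("s01" %in% out$cohort$snps$snp_id)
  expect_true("s02" %in% out$cohort$snps$snp_id)
  expect_false("s03" %in% out$cohort$snps$snp_id)
  expect_identical(out$report$input, 3L)
  expect_identical(out$report$removed + out$report$retained,
                   out$report$input)

  # boundary: MAF exactly 0.10 and callrate exactly 0.90 are retained
  nf2 <- 10L  # one population, 30 individuals, 60 alleles
  gm2 <- cbind(c(rep(1L, 3), rep(0L, 7)))  # 3 B among mothers
  gf2 <- cbind(c(rep(1L, 3), rep(0L, 7)))
  gc2 <- cbind(rep(0L, 10))
  # B count 6/60 = 0.10 exactly
  c2 <- toy_cohort(gm2, gf2, gc2)
  expect_true("s01" %in% filter_snps(c2)$cohort$snps$snp_id)
  gc2[1:3, 1] <- NA_integer_  # 27/30 genotyped = 0.90 exactly
  c3 <- toy_cohort(gm2, gf2, gc2)
  # MAF now 6/54 = 0.111 >= 0.1, callrate exactly 0.9 -> retained
  expect_true("s01" %in% filter_snps(c3)$cohort$snps$snp_id)
})

test_that("Fisher stratification screen matches the exact enumeration oracle", {
  # random 2x2 allele-count tables with margins <= 40
  set.seed(42)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(3:9, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(stats::fisher.test(tab)$p.value, fisher_oracle(tab),
                 tolerance = 1e-10)
  }
})

test_that("stratification removes frequency-divergent SNPs and skips single populations", {
  # founders engineered: POP1 mostly A, POP2 mostly B at s1; identical at s2
  nf <- 20L
  pop <- rep(c("P1", "P2"), each = 10)
  gm <- cbind(c(rep(0L, 10), rep(2L, 10)), rep(1L, nf))
  gf <- cbind(c(rep(0L, 10), rep(2L, 10)), rep(1L, nf))
  gc <- cbind(c(rep(0L, 10), rep(2L, 10)), rep(1L, nf))
  cohort <- toy_cohort(gm, gf, gc, population = pop)
  out <- filter_snp_stratification(cohort, filter_config())
  expect_false("s01" %in% out$cohort$snps$snp_id)
  expect_true("s02" %in% out$cohort$snps$snp_id)  # identical counts, p = 1

  single <- toy_cohort(gm, gf, gc)  # one population
  expect_message(res <- filter_snp_stratification(single), "skipped")
  expect_identical(res$cohort$snps, single$snps)
  expect_identical(res$report$removed, 0L)
})

test_that("under the null the SNP stratification screen removes about alpha", {
  cfg <- sim_config(n_trios = 40, n_units = 800, maf = 0.3,
                    populations = 2, pop_maf_delta = 0, seed = 19)
  sim <- simulate_trios(cfg)
  out <- filter_snp_stratification(sim$cohort)
  frac <- out$report$removed / out$report$input
  # Fisher is conservative on discrete tables: removal rate at or below
  # alpha, but clearly nonzero
  expect_lt(frac, 0.05 + 2.576 * sqrt(0.05 * 0.95 / 800))
  # with genuinely different MAFs the screen removes far more than alpha
  cfg2 <- sim_config(n_trios = 40, n_units = 400, maf = 0.3,
                     populations = 2, pop_maf_delta = 0.35, seed = 20)
  out2 <- filter_snp_stratification(simulate_trios(cfg2)$cohort)
  expect_gt(out2$report$removed / out2$report$input, 0.5)
})

test_that("expression filters remove low, invariant and stratified probes", {
  nf <- 6L
  pop <- rep(c("P1", "P2"), each = 3)
  cohort <- toy_cohort(matrix(1L, nf, 1), matrix(1L, nf, 1),
                       matrix(1L, nf, 1), population = pop)
  vals <- rbind(rep(7, 6),                     # SD 0 -> removed
                c(5.0, 5.5, 6.0, 5.5, 6.5, 6.0),  # mean 5.75 -> removed
                c(8, 8.4, 8.2, 10, 10.4, 10.2),   # pop-different -> removed
                c(8, 9, 7.5, 8.2, 9.1, 7.4))      # kept
  out <- filter_expression(toy_expr(cohort, vals), cohort, filter_config())
  expect_identical(rownames(out$expr$values), "p04")
  expect_identical(out$report$stage,
                   c("expr_intensity_sd", "expr_stratification"))
  expect_identical(out$report$removed, c(2L, 1L))
  # stage counts reconcile: retained of stage k = input of stage k+1
  expect_identical(out$report$retained[1], out$report$input[2])
})

test_that("zero-variance cross-population difference is removed deterministically", {
  nf <- 8L
  pop <- rep(c("P1", "P2"), each = 4)
  cohort <- toy_cohort(matrix(1L, nf, 1), matrix(1L, nf, 1),
                       matrix(1L, nf, 1), population = pop)
  # constant within group, different between: infinite t, p = 0
  vals <- rbind(c(8, 8, 8, 8, 10, 10, 10, 10),
                c(8, 9, 7, 8.5, 8.2, 9.1, 7.3, 8.6))
  # give row 1 nonzero overall SD so it survives stage 1 (SD ~ 1.07)
  out <- filter_expression(toy_expr(cohort, vals), cohort)
  expect_identical(rownames(out$expr$values), "p02")
})

test_that("equal-variance t-test p matches t.test(var.equal = TRUE)", {
  set.seed(9)
  for (i in 1:50) {
    x <- rnorm(sample(3:10, 1)); y <- rnorm(sample(3:10, 1), mean = 0.3)
    got <- pofoqtl:::.pooled_t_test(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    expect_equal(got$tstat, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("probe-gene mapping keeps >= 1 bp overlaps and multi-gene labels", {
  cohort <- toy_cohort(cbind(c(0L, 1L)), cbind(c(1L, 1L)), cbind(c(1L, 1L)))
  vals <- rbind(c(8, 9), c(8, 9), c(8, 9))
  expr <- toy_expr(cohort, vals, chrom = 1L,
                   start = c(100L, 100L, 500L), end = c(200L, 200L, 600L))
  genes <- data.frame(chrom = 1L, start = c(200L, 201L, 150L),
                      end = c(300L, 300L, 250L),
                      gene = c("G1", "G2", "G3"), stringsAsFactors = FALSE)
  # p1/p2 [100,200]: gene G1 [200,300] overlaps exactly 1 bp; G2 [201,300]
  # does not; G3 [150,250] overlaps
  out <- map_probes_to_genes(expr, genes[1:2, ])
  expect_identical(out$expr$probes$gene, c("G1", "G1"))
  expect_identical(out$report$removed, 1L)  # p3 overlaps nothing
  multi <- map_probes_to_genes(expr, genes)
  expect_identical(multi$expr$probes$gene[1], "G1,G3")
})
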