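# Cis pairing, the regression core and the four regimes.

test_that("cis pairing is boundary-inclusive on the probe midpoint", {
  snps <- data.frame(snp_id = c("a", "b", "c"), chrom = c(1L, 1L, 2L),
                     pos = c(4000000L, 6000001L, 5000000L),
                     stringsAsFactors = FALSE)
  probes <- data.frame(probe_id = "p", chrom = 1L,
                       start = 4999000L, end = 5001000L,
                       stringsAsFactors = FALSE)
  pairs <- build_cis_pairs(snps, probes, window = 1e6)
  # midpoint 5,000,000: SNP a at exactly 1 Mb included; b at 1,000,001
  # excluded; c on another chromosome excluded
  expect_identical(pairs$snp_id, "a")
  expect_identical(pairs$distance, -1000000L)
  # odd span: midpoint floors
  probes2 <- data.frame(probe_id = "q", chrom = 1L, start = 10L, end = 13L,
                        stringsAsFactors = FALSE)
  expect_identical(probe_midpoint(probes2), 11L)
})

test_that("regress_qt matches the closed-form OLS oracle on the worked example", {
  r <- regress_qt(c(0, 0, 0, 1, 1, 1), c(1.0, 1.2, 0.9, 2.1, 1.9, 2.0),
                  min_n = 4)
  expect_true(r$tested)
  expect_equal(r$beta, 0.966666666666667, tolerance = 1e-12)
  expect_equal(r$tstat, 9.17060521448831, tolerance = 1e-10)
  expect_equal(r$p, 0.000785043001832899, tolerance = 1e-10)
  expect_identical(r$n, 6L)
})

test_that("regress_qt agrees with lm() across random datasets", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(5:30, 1)
    x <- sample(0:2, n, replace = TRUE)
    y <- 0.3 * x + rnorm(n)
    if (length(unique(x)) < 2) next
    r <- regress_qt(x, y, min_n = 5)
    s <- summary(lm(y ~ x))$coefficients
    expect_equal(r$beta, s["x", "Estimate"], tolerance = 1e-8)
    expect_equal(r$tstat, s["x", "t value"], tolerance = 1e-8)
    expect_equal(r$p, s["x", "Pr(>|t|)"], tolerance = 1e-8)
  }
})

test_that("regress_qt degenerate inputs behave as documented", {
  # constant response: nothing to explain
  r <- regress_qt(c(0, 1, 0, 1, 0, 1), rep(2.5, 6), min_n = 4)
  expect_identical(r$beta, 0)
  expect_identical(r$tstat, 0)
  expect_identical(r$p, 1)
  # monomorphic dosage: untested
  r <- regress_qt(rep(0, 10), rnorm(10), min_n = 4)
  expect_false(r$tested)
  expect_identical(r$reason, "constant_dosage")
  # too few observations: untested
  r <- regress_qt(c(0, 1, NA), c(1, 2, 3), min_n = 3)
  expect_false(r$tested)
  expect_identical(r$reason, "too_few_individuals")
})

make_assoc_fixture <- function(seed = 33, model = "maternal", beta = 1,
                               n_trios = 60, n_units = 6, noise_sd = 0.5) {
  eff <- plant_effects(n_units, model, beta)
  st <- simulate_study(sim_config(n_trios = n_trios, n_units = n_units,
                                  maf = 0.3, effects = eff,
                                  noise_sd = noise_sd, seed = seed))
  st$phased <- assign_parental_origin(st$cohort)
  st$pairs <- build_cis_pairs(st$cohort$snps, st$expr$probes)
  st
}

test_that("parental dosage codes the minor allele on the stated haplotype", {
  st <- make_assoc_fixture()
  dos <- pofoqtl:::.parental_dosage(st$phased, st$cohort, "mat")
  a <- st$phased$status == "assigned"
  # B is minor at MAF 0.3, so the maternal dosage is the transmitted B allele
  expect_true(all(minor_is_b(st$cohort)))
  expect_identical(dos[a], st$truth$mat[a])
  expect_true(all(is.na(dos[!a])))  # triple-het children excluded
})

test_that("maternal-only effects light up the maternal regime, not the paternal", {
  st <- make_assoc_fixture(seed = 71)
  mm <- run_maternal(st$phased, st$expr, st$pairs, st$cohort)
  pp <- run_paternal(st$phased, st$expr, st$pairs, st$cohort)
  expect_true(all(mm$p_nominal < 1e-4))
  expect_true(all(pp$p_nominal > 1e-4))
  expect_gt(median(pp$p_nominal), 0.05)
})

test_that("relabeling mothers as fathers swaps the parental regimes exactly", {
  st <- make_assoc_fixture(seed = 13)
  sw <- st$cohort
  sw$families[, c("mother_id", "father_id")] <-
    sw$families[, c("father_id", "mother_id")]
  ph_sw <- assign_parental_origin(sw)
  mm <- run_maternal(st$phased, st$expr, st$pairs, st$cohort)
  pp_sw <- run_paternal(ph_sw, st$expr, st$pairs, sw)
  expect_equal(mm$beta, pp_sw$beta, tolerance = 1e-12)
  expect_equal(mm$p_nominal, pp_sw$p_nominal, tolerance = 1e-12)
})

test_that("heterozygote regime equals the pooled two-sample t-test", {
  # frozen worked example: reciprocal groups of four
  g0 <- c(1.0, 1.1, 0.9, 1.0); g1 <- c(2.0, 2.1, 1.9, 2.0)
  r <- regress_qt(c(rep(0, 4), rep(1, 4)), c(g0, g1), min_n = 8)
  expect_equal(r$p, 2.373334543896e-06, tolerance = 1e-10)
  expect_equal(abs(r$tstat), 17.320508075689, tolerance = 1e-9)

  st <- make_assoc_fixture(seed = 5, n_units = 8)
  hh <- run_heterozygote(st$phased, st$expr, st$pairs, st$cohort)
  for (k in which(hh$tested)) {
    snp <- hh$snp_id[k]; probe <- hh$probe_id[k]
    a <- st$phased$status[, snp] == "assigned" &
      st$phased$mat[, snp] != st$phased$pat[, snp]
    grp <- st$phased$mat[, snp] == 1L  # B maternal
    y <- st$expr$values[probe, ]
    ref <- t.test(y[a & grp], y[a & !grp], var.equal = TRUE)
    expect_equal(hh$p_nominal[k], ref$p.value, tolerance = 1e-10)
  }
})

test_that("heterozygote test refuses fewer than min_het informative children", {
  st <- make_assoc_fixture(seed = 5, n_units = 2)
  # count assigned heterozygotes at snp 1, then set the bar just above it
  snp <- st$pairs$snp_id[1]
  n_het <- sum(st$phased$status[, snp] == "assigned" &
                 st$phased$mat[, snp] != st$phased$pat[, snp])
  hh <- run_heterozygote(st$phased, st$expr, st$pairs, st$cohort,
                         min_het = n_het + 1L)
  expect_false(hh$tested[1])
  expect_identical(hh$reason[1], "too_few_individuals")
  hh2 <- run_heterozygote(st$phased, st$expr, st$pairs, st$cohort,
                          min_het = n_het)
  expect_true(hh2$tested[1])
})

test_that("conventional dosage ignores parental origin", {
  st <- make_assoc_fixture(seed = 23, n_units = 3)
  cc <- run_conventional(st$cohort, st$expr, st$pairs)
  g <- st$cohort$geno[children(st$cohort), st$pairs$snp_id[1]]
  y <- st$expr$values[st$pairs$probe_id[1], ]
  ref <- summary(lm(y ~ g))$coefficients
  expect_equal(cc$beta[1], ref["g", "Estimate"], tolerance = 1e-10)
  expect_equal(cc$p_nominal[1], ref["g", "Pr(>|t|)"], tolerance = 1e-10)
})

test_that("a maternal-only effect is diluted in the conventional test", {
  # the diploid dosage regression sees about half the haploid slope
  betas_m <- betas_c <- numeric(30)
  for (r in seq_len(30)) {
    st <- make_assoc_fixture(seed = 400 + r, n_units = 1)
    mm <- run_maternal(st$phased, st$expr, st$pairs, st$cohort)
    cc <- run_conventional(st$cohort, st$expr, st$pairs)
    betas_m[r] <- mm$beta[1]; betas_c[r] <- cc$beta[1]
  }
  expect_equal(mean(betas_m), 1, tolerance = 0.1)
  expect_equal(mean(betas_c), 0.5, tolerance = 0.1)
})

test_that("Bonferroni multiplier is the tested cis-SNP count per probe", {
  # put several SNPs near one probe: simulate then stack extra pairs
  st <- make_assoc_fixture(seed = 55, n_units = 5)
  pairs <- st$pairs
  pairs$probe_id <- pairs$probe_id[1]  # pretend all SNPs are cis to probe 1
  pairs$gene <- pairs$gene[1]
  mm <- run_maternal(st$phased, st$expr, pairs, st$cohort)
  m <- sum(mm$tested)
  expect_gt(m, 1)
  ratio <- mm$p_bonferroni[mm$tested] / mm$p_nominal[mm$tested]
  expect_equal(ratio[mm$p_bonferroni[mm$tested] < 1], rep(m,
    sum(mm$p_bonferroni[mm$tested] < 1)), tolerance = 1e-9)
  expect_true(all(mm$p_bonferroni <= 1, na.rm = TRUE))
})
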