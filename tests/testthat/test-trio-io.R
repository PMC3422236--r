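# Readers, writers and round trips.

write_mini_vcf <- function(path, records,
                           samples = c("M1", "F1", "C1")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
}

write_mini_fam <- function(path) {
  writeLines(c("FAM1 M1 0 0 2 -9",
               "FAM1 F1 0 0 1 -9",
               "FAM1 C1 F1 M1 0 -9"), path)
}

test_that("VCF + pedigree parse into a trio cohort, dropping bad records", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  fam <- withr::local_tempfile(fileext = ".fam")
  write_mini_fam(fam)
  write_mini_vcf(vcf, c(
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t0/1",
    "1\t200\trs2\tA\tG\t.\tPASS\t.\tGT\t1|1\t0|0\t0|1",  # phased input
    "2\t300\trs3\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/0\t0/0",  # multiallelic
    "X\t400\trs4\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/0\t0/0",    # non-autosomal
    "3\t500\trs5\tC\tT\t.\tPASS\t.\tGT\t./.\t0/1\t1/1"))
  expect_message(cohort <- read_trio_vcf(vcf, fam), "dropped")
  expect_identical(cohort$snps$snp_id, c("rs1", "rs2", "rs5"))
  expect_identical(nrow(cohort$families), 1L)
  # phase separators ignored; genotype is the unordered ALT count
  expect_identical(unname(cohort$geno["M1", "rs2"]), 2L)
  expect_identical(unname(cohort$geno["C1", "rs2"]), 1L)
  expect_true(is.na(cohort$geno["M1", "rs5"]))
})

test_that("pedigree individual missing from the VCF is a named error", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  fam <- withr::local_tempfile(fileext = ".fam")
  write_mini_vcf(vcf, "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
                 samples = c("M1", "F1"))
  write_mini_fam(fam)
  expect_error(read_trio_vcf(vcf, fam), "C1")
})

test_that("malformed pedigree line reports its line number", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  fam <- withr::local_tempfile(fileext = ".fam")
  write_mini_vcf(vcf, "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t0/1")
  writeLines(c("FAM1 M1 0 0 2 -9", "FAM1 F1 0 0"), fam)
  expect_error(read_trio_vcf(vcf, fam), "line 2")
})

test_that("PED/MAP parse, code 0 0 as missing, and reject misaligned files", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines(c("1\ts1\t0\t1000", "1\ts2\t0\t2000"), map)
  writeLines(c("FAM1 M1 0 0 2 -9 A A A G",
               "FAM1 F1 0 0 1 -9 A G G G",
               "FAM1 C1 F1 M1 0 -9 0 0 A G"), ped)
  cohort <- read_ped_map(ped, map)
  expect_identical(nrow(cohort$snps), 2L)
  expect_true(is.na(cohort$geno["C1", "s1"]))
  expect_identical(unname(cohort$geno["F1", "s2"]), 2L)
  expect_identical(unname(cohort$geno["C1", "s2"]), 1L)
  # MAP with an extra row no longer matches the PED genotype pairs
  writeLines(c("1\ts1\t0\t1000", "1\ts2\t0\t2000", "1\ts3\t0\t3000"), map)
  expect_error(read_ped_map(ped, map), "mismatch")
})

test_that("PED/MAP round trip preserves genotypes, ids and SNP order", {
  st <- simulate_study(sim_config(n_trios = 8, n_units = 12,
                                  maf = c(0.1, 0.5), missing_rate = 0.05,
                                  seed = 3))
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  write_ped_map(st$cohort, ped, map)
  back <- read_ped_map(ped, map)
  expect_identical(back$snps$snp_id, st$cohort$snps$snp_id)
  expect_identical(back$families, st$cohort$families)
  expect_identical(back$geno, st$cohort$geno)
})

test_that("VCF round trip preserves genotypes and parsing is deterministic", {
  st <- simulate_study(sim_config(n_trios = 6, n_units = 10,
                                  missing_rate = 0.1, seed = 5))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  fam <- withr::local_tempfile(fileext = ".fam")
  write_trio_vcf(st$cohort, vcf, fam)
  b1 <- read_trio_vcf(vcf, fam)
  b2 <- read_trio_vcf(vcf, fam)
  expect_identical(b1$geno, st$cohort$geno)
  expect_identical(b1, b2)
})

test_that("expression reader is strict and aligns children to the cohort", {
  cohort <- toy_cohort(cbind(c(0L, 1L)), cbind(c(1L, 1L)), cbind(c(1L, 1L)))
  mtx <- withr::local_tempfile(fileext = ".tsv")
  ann <- withr::local_tempfile(fileext = ".tsv")
  kids <- children(cohort)
  writeLines(c(paste(c("probe_id", rev(kids)), collapse = "\t"),
               paste(c("p1", "7.1", "7.9"), collapse = "\t"),
               paste(c("p2", "6.2", "6.4"), collapse = "\t"),
               paste(c("p3", "5.0", "5.5"), collapse = "\t")), mtx)
  writeLines(c("probe_id\tchrom\tstart\tend",
               "p1\t1\t100\t200",
               "p2\t1\t300\t400"), ann)
  expect_message(expr <- read_expression(mtx, ann, cohort), "dropped")
  expect_identical(rownames(expr$values), c("p1", "p2"))  # p3 unannotated
  expect_identical(colnames(expr$values), kids)           # cohort order
  expect_equal(unname(expr$values["p1", kids[1]]), 7.9)

  writeLines(c(paste(c("probe_id", kids), collapse = "\t"),
               "p1\t7.1\tNA"), mtx)
  expect_error(read_expression(mtx, ann, cohort), "p1")
  writeLines(c(paste(c("probe_id", kids[1], "STRANGER"), collapse = "\t"),
               "p1\t7.1\t7.2"), mtx)
  expect_error(read_expression(mtx, ann, cohort), "STRANGER")
})

test_that("BED genes convert to 1-based inclusive coordinates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t200\tG1", "2\t0\t50\tG2", "chrX\t5\t10\tG3"), bed)
  g <- read_gene_bed(bed)
  expect_identical(g$start, c(100L, 1L))
  expect_identical(g$end, c(200L, 50L))
  expect_identical(g$gene, c("G1", "G2"))  # X dropped
})

test_that("result tables are written sorted with scientific p-values", {
  f <- withr::local_tempfile(fileext = ".tsv")
  rec <- data.frame(snp_id = c("b", "a"), chrom = c(2L, 1L),
                    pos = c(5L, 9L), probe_id = c("p2", "p1"),
                    p_nominal = c(0.02, 3e-9), stringsAsFactors = FALSE)
  write_results_table(rec, f)
  lines <- readLines(f)
  expect_identical(length(lines), 3L)
  expect_match(lines[2], "^a\t1\t9\tp1\t3\\.0*e-09")
  # empty input -> header only
  write_results_table(rec[0, ], f)
  expect_identical(length(readLines(f)), 1L)
  # mixed schemas refuse to combine
  expect_error(write_results_table(list(rec, data.frame(x = 1)), f),
               "mixed schemas")
})
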