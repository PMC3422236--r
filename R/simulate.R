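# Synthetic trio-cohort generator with known ground truth.
#
# Each simulated "unit" is one SNP plus one expression probe placed next to
# it, with units spaced far enough apart (default 3 Mb, wider than twice
# the 1 Mb cis half-window) that every probe pairs only with its own SNP.
# Founder genotypes are drawn under Hardy-Weinberg equilibrium at the
# configured MAF and each child inherits one uniformly random allele from
# each parent; the transmitted haplotypes are recorded as ground truth.
# Expression is baseline + beta_M * X_MAT + beta_P * X_PAT + Gaussian noise
# on the log2 scale, with (beta_M, beta_P) set by the unit's effect model.

#' Simulation configuration
#'
#' @param n_trios number of mother/father/child trios (default 60, the
#'   scale of a pooled two-population trio panel).
#' @param n_units number of SNP-probe units (default 200).
#' @param maf either a single minor allele frequency applied to every SNP,
#'   or a length-2 range from which per-SNP MAFs are drawn uniformly
#'   (default `c(0.1, 0.5)`, a post-filter common-variant spectrum).
#' @param effects data.frame with columns `unit` (1-based index), `model`
#'   (one of `"maternal"`, `"paternal"`, `"biallelic"`, `"reciprocal"`),
#'   `beta_m`, `beta_p`; units not listed are null. See [plant_effects()].
#'   Effect sizes are log2 expression units per minor-allele copy.
#' @param noise_sd residual SD of log2 expression (default 0.5).
#' @param baseline mean log2 expression (default 8).
#' @param populations 1 or 2; with 2, trios are split evenly and labelled
#'   `POP1`/`POP2`.
#' @param pop_maf_delta with 2 populations, total MAF offset between them
#'   (each population sits at maf -/+ delta/2, clamped to \[0.01, 0.99\]).
#' @param pop_expr_delta with 2 populations, log2 expression offset added
#'   to the second population's children for every probe.
#' @param missing_rate per-cell genotype missingness probability.
#' @param mendel_error_rate probability that a child's observed genotype is
#'   corrupted by flipping one allele (truth is unchanged).
#' @param window_bp cis half-window the layout must respect (default 1e6).
#' @param unit_spacing_bp genomic spacing between adjacent units on a
#'   chromosome (default 3e6, > 2 * `window_bp`).
#' @param seed master seed; genotype and expression draws use separate
#'   streams derived from it, so adding probes never perturbs genotypes.
#' @return a `sim_config` list
#' @export
sim_config <- function(n_trios = 60L, n_units = 200L, maf = c(0.1, 0.5),
                       effects = NULL, noise_sd = 0.5, baseline = 8,
                       populations = 1L, pop_maf_delta = 0,
                       pop_expr_delta = 0, missing_rate = 0,
                       mendel_error_rate = 0, window_bp = 1e6,
                       unit_spacing_bp = 3e6, seed = 1L) {
  stopifnot(n_trios >= 1, n_units >= 1,
            all(maf >= 0), all(maf <= 0.5), length(maf) %in% 1:2,
            noise_sd >= 0, populations %in% 1:2,
            missing_rate >= 0, missing_rate <= 1,
            mendel_error_rate >= 0, mendel_error_rate <= 1,
            unit_spacing_bp > 2 * window_bp,
            is.finite(seed), abs(seed) < 2^31)
  if (is.null(effects))
    effects <- data.frame(unit = integer(), model = character(),
                          beta_m = numeric(), beta_p = numeric(),
                          stringsAsFactors = FALSE)
  stopifnot(all(c("unit", "model", "beta_m", "beta_p") %in% names(effects)),
            all(effects$unit >= 1), all(effects$unit <= n_units),
            !anyDuplicated(effects$unit),
            all(effects$model %in%
                  c("maternal", "paternal", "biallelic", "reciprocal")),
            all(is.finite(effects$beta_m)), all(is.finite(effects$beta_p)))
  structure(list(n_trios = as.integer(n_trios),
                 n_units = as.integer(n_units), maf = maf,
                 effects = effects, noise_sd = noise_sd,
                 baseline = baseline, populations = as.integer(populations),
                 pop_maf_delta = pop_maf_delta,
                 pop_expr_delta = pop_expr_delta,
                 missing_rate = missing_rate,
                 mendel_error_rate = mendel_error_rate,
                 window_bp = window_bp, unit_spacing_bp = unit_spacing_bp,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Effect table for planted loci
#'
#' Convenience constructor for [sim_config()]'s `effects` argument: plants
#' `n_planted` loci of one effect model at the first units.
#'
#' @param n_planted number of planted units
#' @param model `"maternal"`, `"paternal"`, `"biallelic"` or `"reciprocal"`
#' @param beta effect size (for `"reciprocal"`, the maternal effect)
#' @param beta_p paternal effect for `"reciprocal"` (default `-beta`)
#' @param units which unit indices to plant (default `1:n_planted`)
#' @return data.frame suitable for `sim_config(effects = ...)`
#' @export
plant_effects <- function(n_planted, model = "maternal", beta = 1,
                          beta_p = NULL, units = seq_len(n_planted)) {
  bm <- switch(model, maternal = beta, biallelic = beta,
               reciprocal = beta, paternal = 0)
  bp <- switch(model, maternal = 0, biallelic = beta, paternal = beta,
               reciprocal = if (is.null(beta_p)) -beta else beta_p)
  data.frame(unit = units, model = model, beta_m = bm, beta_p = bp,
             stringsAsFactors = FALSE)
}

# Deterministic unit layout: unit i sits on chromosome ((i-1) mod 22) + 1 at
# position 1e6 + slot * spacing; its probe starts 5 kb downstream.
.unit_layout <- function(config) {
  i <- seq_len(config$n_units)
  chrom <- (i - 1L) %% 22L + 1L
  slot <- (i - 1L) %/% 22L
  pos <- as.integer(1e6 + slot * config$unit_spacing_bp)
  data.frame(unit = i, chrom = chrom, snp_pos = pos,
             probe_start = pos + 5000L, probe_end = pos + 5999L,
             stringsAsFactors = FALSE)
}

#' Simulate a trio cohort with recorded transmissions
#'
#' Founder genotypes are drawn under HWE at each SNP's MAF (per population
#' when a MAF offset is configured); each child inherits one uniformly
#' random allele from each parent. The true transmitted haplotypes are
#' recorded before missingness or Mendelian-error corruption is applied to
#' the observed genotypes, so phasing and association can be checked
#' against the truth.
#'
#' @param config a [sim_config()]
#' @return list with elements `cohort` (a [trio_cohort()]) and `truth`
#'   (list: `mat`/`pat` children x SNPs transmitted B-allele matrices,
#'   `effects` per-probe effect table with causal SNP, `maf` realized
#'   per-SNP configured MAF, `layout`)
#' @export
simulate_trios <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lay <- .unit_layout(config)
  nt <- config$n_trios; ns <- config$n_units
  set.seed(config$seed)
  maf <- if (length(config$maf) == 1L) rep(config$maf, ns) else
    stats::runif(ns, config$maf[1], config$maf[2])

  fam_id <- sprintf("FAM%03d", seq_len(nt))
  pop <- if (config$populations == 2L)
    rep(c("POP1", "POP2"), length.out = nt) else rep("POP1", nt)
  fam <- data.frame(family_id = fam_id,
                    mother_id = paste0(fam_id, "_M"),
                    father_id = paste0(fam_id, "_F"),
                    child_id = paste0(fam_id, "_C"),
                    population = pop, stringsAsFactors = FALSE)

  # per-trio, per-SNP MAF (population offset applied on top of the base MAF)
  offset <- if (config$populations == 2L)
    ifelse(pop == "POP1", -config$pop_maf_delta / 2,
           config$pop_maf_delta / 2) else rep(0, nt)
  m <- pmin(pmax(outer(offset, maf, `+`), 0.01), 0.99)  # trios x snps

  gm <- matrix(stats::rbinom(nt * ns, 2L, m), nt, ns)
  gf <- matrix(stats::rbinom(nt * ns, 2L, m), nt, ns)
  transmit <- function(g)
    ifelse(g == 1L, matrix(stats::rbinom(nt * ns, 1L, 0.5), nt, ns), g %/% 2L)
  hm <- transmit(gm)  # maternal transmitted B-allele
  hp <- transmit(gf)
  gc <- hm + hp

  snp_id <- sprintf("snp%04d", lay$unit)
  dn_kids <- list(fam$child_id, snp_id)
  dimnames(hm) <- dn_kids; dimnames(hp) <- dn_kids

  geno <- rbind(gm, gf, gc)
  rownames(geno) <- c(fam$mother_id, fam$father_id, fam$child_id)
  colnames(geno) <- snp_id

  if (config$mendel_error_rate > 0) {
    flip <- matrix(stats::runif(nt * ns) < config$mendel_error_rate, nt, ns)
    obs <- geno[fam$child_id, , drop = FALSE]
    up <- flip & obs < 2L & matrix(stats::runif(nt * ns) < 0.5, nt, ns)
    dn <- flip & !up & obs > 0L
    up2 <- flip & !up & !dn  # obs == 0 forced upward
    obs[up | up2] <- obs[up | up2] + 1L
    obs[dn] <- obs[dn] - 1L
    geno[fam$child_id, ] <- obs
  }
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(geno)) < config$missing_rate,
                   nrow(geno), ncol(geno))
    geno[drop] <- NA_integer_
  }

  snps <- data.frame(snp_id = snp_id, chrom = lay$chrom, pos = lay$snp_pos,
                     allele_a = "A", allele_b = "G",
                     stringsAsFactors = FALSE)
  eff <- data.frame(unit = lay$unit,
                    probe_id = sprintf("probe%04d", lay$unit),
                    causal_snp = snp_id, model = "null",
                    beta_m = 0, beta_p = 0, stringsAsFactors = FALSE)
  if (nrow(config$effects)) {
    i <- match(config$effects$unit, eff$unit)
    eff$model[i] <- config$effects$model
    eff$beta_m[i] <- config$effects$beta_m
    eff$beta_p[i] <- config$effects$beta_p
  }
  list(cohort = trio_cohort(snps, fam, geno),
       truth = list(mat = hm, pat = hp, effects = eff, maf = maf,
                    layout = lay))
}

#' Simulate expression from recorded transmissions
#'
#' Per probe, child expression is
#' `baseline + beta_m * x_mat + beta_p * x_pat + N(0, noise_sd^2)` where
#' `x_mat`/`x_pat` are the true transmitted minor(B)-allele indicators at
#' the probe's causal SNP. Each probe uses its own RNG substream derived
#' from the master seed, so probes can be added without perturbing earlier
#' draws; a configured population offset is added to the second
#' population's children.
#'
#' @param truth the `truth` element of [simulate_trios()]'s result
#' @param config the same [sim_config()]
#' @param cohort the cohort from the same call (supplies child order and
#'   populations)
#' @return an [expression_matrix()] (probes x children, log2 scale)
#' @export
simulate_expression <- function(truth, config, cohort) {
  stopifnot(inherits(config, "sim_config"))
  eff <- truth$effects
  lay <- truth$layout
  nt <- config$n_trios
  pop2 <- cohort$families$population == "POP2"
  vals <- matrix(0, nrow(eff), nt,
                 dimnames = list(eff$probe_id, children(cohort)))
  for (r in seq_len(nrow(eff))) {
    set.seed((config$seed + 104729L + 7919L * r) %% .Machine$integer.max)
    mu <- config$baseline +
      eff$beta_m[r] * truth$mat[, eff$causal_snp[r]] +
      eff$beta_p[r] * truth$pat[, eff$causal_snp[r]] +
      ifelse(pop2, config$pop_expr_delta, 0)
    vals[r, ] <- mu + stats::rnorm(nt, 0, config$noise_sd)
  }
  probes <- data.frame(probe_id = eff$probe_id, chrom = lay$chrom,
                       start = lay$probe_start, end = lay$probe_end,
                       gene = paste0("GENE", lay$unit),
                       stringsAsFactors = FALSE)
  expression_matrix(vals, probes)
}

#' Simulate a full study (cohort + truth + expression)
#'
#' @param config a [sim_config()]
#' @return list with `cohort`, `truth`, `expr` and `genes` (one gene
#'   interval per unit, spanning its probe)
#' @export
simulate_study <- function(config) {
  sim <- simulate_trios(config)
  expr <- simulate_expression(sim$truth, config, sim$cohort)
  lay <- sim$truth$layout
  genes <- data.frame(chrom = lay$chrom, start = lay$probe_start - 500L,
                      end = lay$probe_end + 500L,
                      gene = paste0("GENE", lay$unit),
                      stringsAsFactors = FALSE)
  list(cohort = sim$cohort, truth = sim$truth, expr = expr, genes = genes)
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Emits VCF + FAM, PED/MAP, expression matrix and probe annotation TSVs,
#' a gene BED, and a ground-truth TSV (probe, causal SNP, effect model and
#' sizes), so the pipeline can be exercised end to end from files.
#'
#' @param study result of [simulate_study()]
#' @param dir output directory (created if absent)
#' @return invisibly, a named character vector of the files written
#' @export
write_study_files <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             fam = file.path(dir, "cohort.fam"),
             ped = file.path(dir, "cohort.ped"),
             map = file.path(dir, "cohort.map"),
             expression = file.path(dir, "expression.tsv"),
             probe_annotation = file.path(dir, "probes.tsv"),
             genes_bed = file.path(dir, "genes.bed"),
             truth = file.path(dir, "truth.tsv"))
  write_trio_vcf(study$cohort, paths["vcf"], paths["fam"])
  write_ped_map(study$cohort, paths["ped"], paths["map"])
  write_expression(study$expr, paths["expression"],
                   paths["probe_annotation"])
  write_gene_bed(study$genes, paths["genes_bed"])
  utils::write.table(study$truth$effects, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Power and type-I error study over a parameter grid
#'
#' For every combination of effect model, effect size, trio count and
#' significance level, simulates single-unit cohorts and reports the
#' fraction of replicates in which each test (maternal, paternal,
#' heterozygote, conventional, LRT) rejects. Rows with `beta = 0` are
#' type-I error rows and should sit near their alpha.
#'
#' @param models character vector of effect models (including `"null"`)
#' @param betas numeric vector of effect sizes
#' @param n_trios_grid integer vector of cohort sizes
#' @param alphas significance levels
#' @param n_replicates replicates per combination (default 200)
#' @param maf minor allele frequency (default 0.3)
#' @param noise_sd residual SD (default 0.5)
#' @param min_n,min_het test thresholds as in the association regimes
#' @param seed master seed
#' @return data.frame: one row per (model, beta, n_trios, alpha, regime)
#'   with the rejection fraction `power` and `n_replicates`
#' @export
power_study <- function(models = c("null", "maternal"), betas = 1,
                        n_trios_grid = 60L, alphas = 0.05,
                        n_replicates = 200L, maf = 0.3, noise_sd = 0.5,
                        min_n = 20L, min_het = 8L, seed = 1L) {
  regimes <- c("maternal", "paternal", "heterozygote", "conventional", "lrt")
  grid <- expand.grid(model = models, beta = betas, n_trios = n_trios_grid,
                      stringsAsFactors = FALSE)
  out <- list()
  for (g in seq_len(nrow(grid))) {
    model <- grid$model[g]; beta <- grid$beta[g]; nt <- grid$n_trios[g]
    pm <- matrix(NA_real_, n_replicates, length(regimes),
                 dimnames = list(NULL, regimes))
    for (r in seq_len(n_replicates)) {
      eff <- if (model == "null") NULL else plant_effects(1, model, beta)
      cfg <- sim_config(n_trios = nt, n_units = 1L, maf = maf,
                        effects = eff, noise_sd = noise_sd,
                        seed = (seed + 7717L * g + r) %%
                          .Machine$integer.max)
      st <- simulate_study(cfg)
      ph <- assign_parental_origin(st$cohort)
      pairs <- build_cis_pairs(st$cohort$snps, st$expr$probes,
                               window = cfg$window_bp)
      pm[r, "maternal"] <- run_maternal(ph, st$expr, pairs, st$cohort,
                                        min_n)$p_nominal[1]
      pm[r, "paternal"] <- run_paternal(ph, st$expr, pairs, st$cohort,
                                        min_n)$p_nominal[1]
      pm[r, "heterozygote"] <- run_heterozygote(ph, st$expr, pairs,
                                                st$cohort,
                                                min_het)$p_nominal[1]
      pm[r, "conventional"] <- run_conventional(st$cohort, st$expr, pairs,
                                                min_n)$p_nominal[1]
      pm[r, "lrt"] <- run_lrt_screen(ph, st$expr, pairs, st$cohort,
                                     min_n)$p_lrt[1]
    }
    for (a in alphas) for (reg in regimes) {
      p <- pm[, reg]
      out[[length(out) + 1L]] <- data.frame(
        model = model, beta = beta, n_trios = nt, alpha = a, regime = reg,
        power = mean(p < a, na.rm = TRUE),
        n_tested = sum(!is.na(p)), n_replicates = n_replicates,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
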