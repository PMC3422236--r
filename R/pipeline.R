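# End-to-end pipeline: read -> phase -> QC -> cis association (four
# regimes) -> LRT -> ieQTL calling -> enrichment, with every stage writing
# its table and appending counts to a run log. Deterministic given
# identical inputs and configuration.

#' Pipeline configuration
#'
#' Build (or load from YAML) the configuration driving [run_pipeline()].
#' The YAML mirrors this function's arguments; flags set here override the
#' file. Input files may be VCF+FAM (`format: vcf`) or PED/MAP
#' (`format: pedmap`).
#'
#' @param yaml_path optional YAML file to load first.
#' @param ... overrides: `inputs` (list with `format`, `vcf`, `fam`, `ped`,
#'   `map`, `expression`, `probe_annotation`, `genes_bed`,
#'   `imprinted_genes`, optional `populations` named `family_id -> label`),
#'   `output_dir`, `filters` (arguments to [filter_config()]), `window_bp`,
#'   `min_n`, `min_het`, `sig`, `sug`, `other_max`, `stages` (list of
#'   logical toggles `qc`, `het`, `conventional`, `lrt`, `enrichment`),
#'   `seed`.
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(yaml_path = NULL, ...) {
  cfg <- list(inputs = list(format = "vcf"), output_dir = "pofoqtl_out",
              filters = list(), window_bp = 1e6, min_n = 20L, min_het = 8L,
              sig = 1e-7, sug = 1e-6, other_max = 0.05,
              stages = list(qc = TRUE, het = TRUE, conventional = TRUE,
                            lrt = TRUE, enrichment = TRUE),
              seed = 1L)
  modifyList2 <- function(a, b) {
    for (nm in names(b))
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        modifyList2(a[[nm]], b[[nm]]) else b[[nm]]
    a
  }
  if (!is.null(yaml_path)) cfg <- modifyList2(cfg, yaml::read_yaml(yaml_path))
  cfg <- modifyList2(cfg, list(...))
  stopifnot(cfg$sig < cfg$sug, cfg$sug <= cfg$other_max)
  structure(cfg, class = "pipeline_config")
}

.log_line <- function(con, ...) {
  line <- paste0(...)
  writeLines(line, con)
  message(line)
}

#' Run the full ieQTL pipeline
#'
#' Stages: read inputs, assign parental origin, SNP and expression QC
#' (toggleable), cis pairing, maternal/paternal association, heterozygote
#' comparison, conventional association, imprinting LRT, ieQTL calling,
#' imprinted-gene enrichment. Every stage writes a TSV under
#' `config$output_dir` and appends its counts to `run_log.txt`. A repeated
#' run on identical inputs produces byte-identical outputs.
#'
#' @param config a [pipeline_config()] (or a YAML path accepted by it)
#' @return invisibly, a list with all intermediate and final objects:
#'   `cohort`, `phased`, `expr`, `filter_report`, `pairs`, `maternal`,
#'   `paternal`, `het`, `conventional`, `lrt`, `calls`, `enrichment`
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(config$output_dir, "run_log.txt"), "w")
  on.exit(close(log_con))
  stage <- function(name, fn) {
    tryCatch(fn, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  inp <- config$inputs
  pops <- if (!is.null(inp$populations)) unlist(inp$populations)
  cohort <- stage("read_genotypes",
    if (identical(inp$format, "pedmap"))
      read_ped_map(inp$ped, inp$map, population = pops)
    else read_trio_vcf(inp$vcf, inp$fam, population = pops))
  .log_line(log_con, "read_genotypes: ", nrow(cohort$families), " trios, ",
            nrow(cohort$snps), " SNPs")

  fcfg <- do.call(filter_config, config$filters)
  report <- NULL
  if (isTRUE(config$stages$qc)) {
    fs <- stage("filter_snps", filter_snps(cohort, fcfg))
    st <- stage("filter_snp_stratification",
                filter_snp_stratification(fs$cohort, fcfg))
    cohort <- st$cohort
    report <- rbind(fs$report, st$report)
  }

  expr <- stage("read_expression",
                read_expression(inp$expression, inp$probe_annotation,
                                cohort))
  .log_line(log_con, "read_expression: ", nrow(expr$values), " probes, ",
            ncol(expr$values), " children")
  if (isTRUE(config$stages$qc)) {
    fe <- stage("filter_expression", filter_expression(expr, cohort, fcfg))
    expr <- fe$expr
    report <- rbind(report, fe$report)
  }
  if (!is.null(inp$genes_bed)) {
    genes <- stage("read_genes", read_gene_bed(inp$genes_bed))
    mg <- stage("map_probes_to_genes", map_probes_to_genes(expr, genes))
    expr <- mg$expr
    report <- rbind(report, mg$report)
  }
  if (!is.null(report)) {
    utils::write.table(report,
                       file.path(config$output_dir, "filter_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (i in seq_len(nrow(report)))
      .log_line(log_con, report$stage[i], ": ", report$input[i], " in, ",
                report$removed[i], " removed, ", report$retained[i],
                " retained")
  }

  phased <- stage("phase", assign_parental_origin(cohort))
  psum <- summarize_phasing(phased)
  utils::write.table(psum,
                     file.path(config$output_dir, "phasing_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .log_line(log_con, "phase: mean assignability ",
            sprintf("%.4f", mean(psum$assignability, na.rm = TRUE)))

  pairs <- stage("cis_pairs",
                 build_cis_pairs(cohort$snps, expr$probes,
                                 window = config$window_bp))
  .log_line(log_con, "cis_pairs: ", nrow(pairs), " SNP-probe pairs")

  out_tsv <- function(d, name) write_results_table(
    d, file.path(config$output_dir, paste0(name, ".tsv")))

  maternal <- stage("assoc_maternal",
                    run_maternal(phased, expr, pairs, cohort, config$min_n))
  paternal <- stage("assoc_paternal",
                    run_paternal(phased, expr, pairs, cohort, config$min_n))
  out_tsv(maternal, "assoc_maternal"); out_tsv(paternal, "assoc_paternal")
  .log_line(log_con, "assoc_maternal: ", sum(maternal$tested), " of ",
            nrow(maternal), " pairs tested")
  .log_line(log_con, "assoc_paternal: ", sum(paternal$tested), " of ",
            nrow(paternal), " pairs tested")

  het <- conventional <- lrt <- NULL
  if (isTRUE(config$stages$het)) {
    het <- stage("assoc_heterozygote",
                 run_heterozygote(phased, expr, pairs, cohort,
                                  config$min_het))
    out_tsv(het, "assoc_heterozygote")
    .log_line(log_con, "assoc_heterozygote: ", sum(het$tested), " of ",
              nrow(het), " pairs tested")
  }
  if (isTRUE(config$stages$conventional)) {
    conventional <- stage("assoc_conventional",
                          run_conventional(cohort, expr, pairs,
                                           config$min_n))
    out_tsv(conventional, "assoc_conventional")
    .log_line(log_con, "assoc_conventional: ", sum(conventional$tested),
              " of ", nrow(conventional), " pairs tested")
  }
  if (isTRUE(config$stages$lrt)) {
    lrt <- stage("lrt", run_lrt_screen(phased, expr, pairs, cohort,
                                       config$min_n))
    out_tsv(lrt, "lrt")
    .log_line(log_con, "lrt: ", sum(lrt$tested), " of ", nrow(lrt),
              " pairs tested")
  }

  calls <- stage("call_ieqtls",
                 call_ieqtls(maternal, paternal, het, conventional, lrt,
                             sig = config$sig, sug = config$sug,
                             other_max = config$other_max))
  out_tsv(calls, "ieqtl_calls")
  .log_line(log_con, "call_ieqtls: ", nrow(calls), " call row(s), ",
            length(unique(calls$probe_id)), " probe(s)")

  enrichment <- NULL
  if (isTRUE(config$stages$enrichment) && !is.null(inp$imprinted_genes)) {
    imprinted <- stage("read_imprinted",
                       read_imprinted_genes(inp$imprinted_genes))
    universe <- unique(unlist(strsplit(
      expr$probes$gene[!is.na(expr$probes$gene)], ",", fixed = TRUE)))
    enrichment <- stage("enrichment",
                        enrichment_test(calls, universe, imprinted))
    utils::write.table(enrichment,
                       file.path(config$output_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .log_line(log_con, "enrichment: ", enrichment$imprinted_called, " of ",
              enrichment$called_genes, " called genes imprinted (fold ",
              sprintf("%.2f", enrichment$fold_enrichment), ", p ",
              sprintf("%.3e", enrichment$p_hypergeometric), ")")
  }

  invisible(list(cohort = cohort, phased = phased, expr = expr,
                 filter_report = report, pairs = pairs, maternal = maternal,
                 paternal = paternal, het = het,
                 conventional = conventional, lrt = lrt, calls = calls,
                 enrichment = enrichment))
}

#' Three-panel locus plot
#'
#' Box plots of a probe's expression split by (1) the maternally inherited
#' allele, (2) the paternally inherited allele, and (3) the two reciprocal
#' heterozygote classes, the standard display for a parent-of-origin
#' association.
#'
#' @param probe_id probe to plot
#' @param snp_id SNP to plot
#' @param phased `phased_genotypes` from [assign_parental_origin()]
#' @param expr an [expression_matrix()]
#' @param cohort the [trio_cohort()]
#' @param file output image path (`.png` or `.svg`); `NULL` draws on the
#'   active device
#' @return invisibly, the per-panel group values
#' @export
plot_locus <- function(probe_id, snp_id, phased, expr, cohort,
                       file = NULL) {
  if (!probe_id %in% rownames(expr$values))
    stop("unknown probe id: ", probe_id)
  if (!snp_id %in% colnames(phased$mat)) stop("unknown snp id: ", snp_id)
  y <- expr$values[probe_id, ]
  assigned <- phased$status[, snp_id] == "assigned"
  if (!any(assigned)) stop("no assigned children at ", snp_id)
  minor_b <- minor_is_b(cohort)[snp_id]
  lab <- function(h) ifelse(xor(h == 1L, !minor_b), "minor", "major")
  mat <- ifelse(assigned, lab(phased$mat[, snp_id]), NA)
  pat <- ifelse(assigned, lab(phased$pat[, snp_id]), NA)
  het <- assigned & phased$mat[, snp_id] != phased$pat[, snp_id]
  hclass <- ifelse(het, ifelse(mat == "minor", "minor MAT", "minor PAT"), NA)
  groups <- list(maternal = split(y[!is.na(mat)], mat[!is.na(mat)]),
                 paternal = split(y[!is.na(pat)], pat[!is.na(pat)]),
                 heterozygote = split(y[!is.na(hclass)],
                                      hclass[!is.na(hclass)]))
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           png = grDevices::png(file, width = 1200, height = 420),
           svg = grDevices::svg(file, width = 12, height = 4.2),
           stop("unsupported plot format: .", ext))
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  titles <- c("Maternal allele", "Paternal allele",
              "Reciprocal heterozygotes")
  for (i in seq_along(groups)) {
    if (length(groups[[i]]) == 0) {
      graphics::plot.new(); graphics::title(main = titles[i])
    } else {
      graphics::boxplot(groups[[i]], main = titles[i],
                        ylab = sprintf("%s log2 expression", probe_id),
                        col = c("lightpink", "lightblue"))
    }
  }
  invisible(groups)
}
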