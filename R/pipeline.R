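# End-to-end analysis pipeline: HWE -> association -> LD matrix -> blocks
# (three rules) -> compound-genotype analysis -> epistasis, with TSV/JSON
# reports and a run log. Each stage failure aborts with the stage name.

#' Run the full two-SNP / five-SNP analysis pipeline
#'
#' Executes, over a genotype table (read from file or simulated from a
#' preset): per-SNP Hardy-Weinberg tests, case-control allelic and
#' genotypic association with Bonferroni control, the pairwise LD matrix,
#' haplotype blocks under all three rules, the compound-genotype
#' observed-vs-expected analysis for a SNP pair, and the SNP-SNP
#' interaction test. Reports are written as TSV (plus a JSON run log with
#' seeds and package version) when `out_dir` is given; all results are also
#' returned.
#'
#' @param genotypes A [genotype_table()], or a path.
#' @param labels A [cohort_labels()] or path to a labels CSV
#'   (sample,status,stratum), or NULL to skip case-control stages.
#' @param format Input format when `genotypes` is a path.
#' @param snp_defs SNP definitions for CSV input.
#' @param snp_pair SNP pair for the compound and epistasis stages (default
#'   rs2248374, rs2549782).
#' @param expectation_mode Null for the compound expectations.
#' @param freq_digits Rounding of allele frequencies before expectations
#'   (2 = published-table fidelity; NULL = full precision).
#' @param alpha Test level.
#' @param seed Seed for EM restarts.
#' @param out_dir Output directory, or NULL.
#' @return List of per-stage results.
#' @export
run_pipeline <- function(genotypes, labels = NULL, format = "csv",
                         snp_defs = erap2_snps(),
                         snp_pair = c("rs2248374", "rs2549782"),
                         expectation_mode = "naive_product",
                         freq_digits = 2, alpha = 0.05, seed = 1L,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  tab <- stage("input", {
    if (inherits(genotypes, "genotype_table")) genotypes
    else read_genotypes(genotypes, format = format, snp_defs = snp_defs)
  })
  labs <- stage("labels", {
    if (is.null(labels) || inherits(labels, "cohort_labels")) labels
    else {
      if (!file.exists(labels)) stop("phenotype file not found: ", labels)
      raw <- utils::read.csv(labels, stringsAsFactors = FALSE)
      cohort_labels(raw$sample, raw$status, raw$stratum, table = tab)
    }
  })
  snps <- tab$snps$id
  hwe <- stage("hwe", {
    do.call(rbind, lapply(snps, function(s) {
      r <- hwe_test(genotype_counts(tab, s))
      data.frame(snp = s, test = r$method, statistic = r$statistic,
                 df = r$df, p = r$p_value, stringsAsFactors = FALSE)
    }))
  })
  assoc <- NULL
  if (!is.null(labs)) {
    assoc <- stage("association", {
      case_ids <- labs$sample[labs$status == "case"]
      ctrl_ids <- labs$sample[labs$status == "control"]
      rows <- lapply(snps, function(s) {
        cc <- genotype_counts(tab, s, subset = case_ids)
        ct <- genotype_counts(tab, s, subset = ctrl_ids)
        al <- allelic_association(cc, ct)
        gt <- tryCatch(genotypic_association(cc, ct),
                       error = function(e) NULL)
        data.frame(snp = s, p_allelic = al$p_value,
                   odds_ratio = al$odds_ratio,
                   p_genotypic = if (is.null(gt)) NA_real_ else gt$p_value,
                   stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, rows)
      bf <- bonferroni(out$p_allelic, alpha)
      out$p_allelic_bonferroni <- bf$p_adjusted
      out
    })
  }
  ld <- blocks <- NULL
  if (length(snps) >= 2L) {
    ld <- stage("ld_matrix", ld_matrix(tab, snps, seed = seed))
    blocks <- stage("blocks", list(
      confidence_interval = blocks_confidence_interval(tab, snps),
      four_gamete = blocks_four_gamete(tab, snps),
      solid_spine = blocks_solid_spine(tab, snps)
    ))
  }
  compound <- NULL
  if (all(snp_pair %in% snps)) {
    compound <- stage("compound", {
      ct <- compound_table(tab, snp_pair[1], snp_pair[2], labels = labs)
      list(table = ct, report = compound_report(ct, digits = freq_digits))
    })
  }
  epistasis <- NULL
  if (!is.null(labs) && all(snp_pair %in% snps)) {
    epistasis <- stage("epistasis",
                       interaction_test(tab, snp_pair[1], snp_pair[2], labs))
  }
  results <- list(genotypes = tab, labels = labs, hwe = hwe,
                  association = assoc, ld = ld, blocks = blocks,
                  compound = compound, epistasis = epistasis)
  if (!is.null(out_dir)) {
    stage("report", write_pipeline_reports(results, out_dir, alpha, seed))
  }
  results
}

write_pipeline_reports <- function(results, out_dir, alpha, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  tsv(results$hwe, "hwe.tsv")
  if (!is.null(results$association)) tsv(results$association, "association.tsv")
  if (!is.null(results$ld)) tsv(ld_matrix_table(results$ld), "ld_matrix.tsv")
  if (!is.null(results$blocks)) {
    tsv(do.call(rbind, lapply(results$blocks, block_table)), "blocks.tsv")
  }
  if (!is.null(results$compound)) tsv(results$compound$report, "compound.tsv")
  if (!is.null(results$epistasis)) {
    e <- results$epistasis
    tsv(data.frame(coding = e$coding, beta_interaction = e$beta_interaction,
                   se = e$se_interaction, lrt_stat = e$statistic,
                   df = e$df, p = e$p_value, n_used = e$n_used),
        "epistasis.tsv")
  }
  log <- list(package = "erap2hap",
              version = as.character(utils::packageVersion("erap2hap")),
              r_version = R.version.string,
              alpha = alpha, seed = seed,
              n_samples = length(results$genotypes$samples),
              snps = results$genotypes$snps$id,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
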