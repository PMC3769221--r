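# Core data model: SNP definitions, unphased genotype tables, cohort labels.
#
# Genotype calls are stored as minor-allele dosage: 0 = homozygous major,
# 1 = heterozygous, 2 = homozygous minor, NA = missing. All downstream
# statistics (allele frequencies, LD, EM phasing) are defined on this coding.

VALID_BASES <- c("A", "C", "G", "T")

#' Define a biallelic SNP
#'
#' @param id SNP identifier, e.g. `"rs2248374"`.
#' @param major_allele,minor_allele Single-character bases (A/C/G/T); must
#'   differ. "Major"/"minor" is an assignment of roles, not a frequency
#'   claim about any particular cohort.
#' @return A one-row data frame with columns `id`, `major`, `minor`.
#' @examples
#' snp_def("rs2248374", major_allele = "G", minor_allele = "A")
#' @export
snp_def <- function(id, major_allele, minor_allele) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!(major_allele %in% VALID_BASES) || !(minor_allele %in% VALID_BASES)) {
    stop("alleles must be one of A, C, G, T", call. = FALSE)
  }
  if (major_allele == minor_allele) {
    stop("major and minor alleles must differ for SNP ", id, call. = FALSE)
  }
  data.frame(id = id, major = major_allele, minor = minor_allele,
             stringsAsFactors = FALSE)
}

#' The five ERAP2 tag SNPs
#'
#' SNP definitions for the five-SNP ERAP2 haplotype system, in locus order:
#' rs2549782 (major T / minor G; the N392K coding variant), rs2548538
#' (A/T), rs2248374 (G/A; the splice-site SNP whose G allele is a functional
#' null through nonsense-mediated decay), rs2287988 (A/G) and rs1056893
#' (T/C).
#'
#' @return A data frame of five [snp_def()] rows in locus order.
#' @export
erap2_snps <- function() {
  rbind(
    snp_def("rs2549782", "T", "G"),
    snp_def("rs2548538", "A", "T"),
    snp_def("rs2248374", "G", "A"),
    snp_def("rs2287988", "A", "G"),
    snp_def("rs1056893", "T", "C")
  )
}

#' Construct a genotype table
#'
#' @param samples Character vector of unique sample ids.
#' @param snp_defs Data frame of SNP definitions ([snp_def()] rows).
#' @param dosage Integer matrix, samples x SNPs, of minor-allele dosages
#'   (0, 1, 2 or NA).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(samples, snp_defs, dosage) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(snp_defs$id)) {
    stop("duplicate SNP id: ",
         paste(unique(snp_defs$id[duplicated(snp_defs$id)]), collapse = ", "),
         call. = FALSE)
  }
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != length(samples) || ncol(dosage) != nrow(snp_defs)) {
    stop("dosage matrix dimensions do not match samples/snps", call. = FALSE)
  }
  if (!all(dosage %in% c(0L, 1L, 2L, NA))) {
    stop("dosage values must be 0, 1, 2 or NA", call. = FALSE)
  }
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(samples, snp_defs$id)
  structure(list(samples = samples, snps = snp_defs, dosage = dosage),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$samples), "samples x", nrow(x$snps),
      "SNPs (", sum(is.na(x$dosage)), "missing calls )\n")
  cat("SNPs:", paste0(x$snps$id, "[", x$snps$major, "/", x$snps$minor, "]",
                      collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$dosage)

snp_index <- function(table, snp) {
  i <- match(snp, table$snps$id)
  if (is.na(i)) stop("unknown SNP id: ", snp, call. = FALSE)
  i
}

# Genotype string for a dosage at one SNP, alleles sorted alphabetically
# (cells are unphased, so "AG" and "GA" are the same genotype).
dosage_to_geno <- function(dos, major, minor) {
  out <- rep(NA_character_, length(dos))
  lab <- function(a, b) paste0(sort(c(a, b)), collapse = "")
  out[!is.na(dos) & dos == 0L] <- lab(major, major)
  out[!is.na(dos) & dos == 1L] <- lab(major, minor)
  out[!is.na(dos) & dos == 2L] <- lab(minor, minor)
  out
}

#' Cohort labels: case/control status and stratum
#'
#' @param sample Character vector of sample ids.
#' @param status `"case"` or `"control"` per sample.
#' @param stratum `"maternal"` or `"fetal"` per sample.
#' @param table Optional [genotype_table()]; if given, every labeled id must
#'   exist in it.
#' @return A data frame of class `cohort_labels`.
#' @export
cohort_labels <- function(sample, status, stratum, table = NULL) {
  sample <- as.character(sample)
  status <- as.character(status)
  stratum <- as.character(stratum)
  stopifnot(length(status) == length(sample), length(stratum) == length(sample))
  if (!all(status %in% c("case", "control"))) {
    stop("status must be 'case' or 'control'", call. = FALSE)
  }
  if (!all(stratum %in% c("maternal", "fetal"))) {
    stop("stratum must be 'maternal' or 'fetal'", call. = FALSE)
  }
  if (anyDuplicated(sample)) stop("duplicate sample ids in labels", call. = FALSE)
  if (!is.null(table) && !all(sample %in% table$samples)) {
    stop("labels refer to samples absent from the genotype table", call. = FALSE)
  }
  structure(data.frame(sample = sample, status = status, stratum = stratum,
                       stringsAsFactors = FALSE),
            class = c("cohort_labels", "data.frame"))
}

#' Genotype counts at one SNP
#'
#' Counts of the three genotype classes plus missing calls at one SNP,
#' optionally restricted to a sample subset. Missing calls are excluded
#' per SNP (pairwise deletion).
#'
#' @param table A [genotype_table()].
#' @param snp SNP id.
#' @param subset Optional character vector of sample ids.
#' @return Object of class `genotype_counts`: a named integer vector with
#'   elements `hom_major`, `het`, `hom_minor`, `missing`.
#' @export
genotype_counts <- function(table, snp, subset = NULL) {
  j <- snp_index(table, snp)
  dos <- table$dosage[, j]
  if (!is.null(subset)) {
    miss <- setdiff(subset, table$samples)
    if (length(miss)) stop("unknown samples in subset: ",
                           paste(utils::head(miss, 3), collapse = ", "),
                           call. = FALSE)
    if (!length(subset)) stop("empty subset", call. = FALSE)
    dos <- dos[subset]
  }
  n_missing <- sum(is.na(dos))
  if (n_missing == length(dos)) {
    stop("no non-missing calls at ", snp, " in the requested subset",
         call. = FALSE)
  }
  counts <- c(
    hom_major = sum(dos == 0L, na.rm = TRUE),
    het       = sum(dos == 1L, na.rm = TRUE),
    hom_minor = sum(dos == 2L, na.rm = TRUE),
    missing   = n_missing
  )
  structure(as.integer(counts), names = names(counts),
            snp = snp, class = "genotype_counts")
}

#' Build a genotype_counts object directly from counts
#'
#' Convenience constructor for published genotype count data.
#' @param hom_major,het,hom_minor,missing Non-negative integer counts.
#' @param snp Optional SNP id attached as an attribute.
#' @export
as_genotype_counts <- function(hom_major, het, hom_minor, missing = 0L,
                               snp = NULL) {
  counts <- c(hom_major = hom_major, het = het, hom_minor = hom_minor,
              missing = missing)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(as.integer(counts), names = names(counts),
            snp = snp, class = "genotype_counts")
}

#' Minor-allele frequency from genotype counts
#'
#' @param counts A `genotype_counts` object (or named vector with elements
#'   `hom_major`, `het`, `hom_minor`).
#' @return Minor-allele frequency `(2 * hom_minor + het) / (2 * n_typed)`.
#' @export
allele_frequency <- function(counts) {
  n_typed <- counts[["hom_major"]] + counts[["het"]] + counts[["hom_minor"]]
  if (n_typed == 0L) stop("no non-missing genotypes", call. = FALSE)
  (2 * counts[["hom_minor"]] + counts[["het"]]) / (2 * n_typed)
}

# ---- readers / writers -----------------------------------------------------

#' Read unphased genotypes from VCF or the two-letter genotype CSV dialect
#'
#' The CSV dialect has a header row `sample,<snp1>,<snp2>,...` and cells
#' holding two allele letters (order not meaningful; genotypes are
#' unphased) or `--` for a missing call. VCF input must be biallelic;
#' GT fields `0/0`, `0/1`, `1/1` and `./.` (or `|`-separated) are mapped to
#' the hom-major / het / hom-minor / missing call states with REF as the
#' major and ALT as the minor allele.
#'
#' @param path File path.
#' @param format `"vcf"` or `"csv"`.
#' @param snp_defs For CSV input, a data frame of [snp_def()] rows covering
#'   every SNP column (required: the dialect does not carry allele roles).
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, format = c("csv", "vcf"), snp_defs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         csv = read_genotypes_csv(path, snp_defs),
         vcf = read_genotypes_vcf(path))
}

read_genotypes_csv <- function(path, snp_defs) {
  if (is.null(snp_defs)) {
    stop("snp_defs is required for the CSV genotype dialect", call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!nrow(raw) || names(raw)[1] != "sample") {
    stop("parse error in ", path, " line 1: header must start with 'sample'",
         call. = FALSE)
  }
  snp_ids <- names(raw)[-1]
  missing_defs <- setdiff(snp_ids, snp_defs$id)
  if (length(missing_defs)) {
    stop("no SNP definition for column(s): ",
         paste(missing_defs, collapse = ", "), call. = FALSE)
  }
  defs <- snp_defs[match(snp_ids, snp_defs$id), , drop = FALSE]
  dosage <- matrix(NA_integer_, nrow(raw), length(snp_ids))
  for (j in seq_along(snp_ids)) {
    cell <- raw[[j + 1L]]
    dosage[, j] <- geno_cell_to_dosage(cell, defs$major[j], defs$minor[j],
                                       snp_ids[j], path)
  }
  genotype_table(raw$sample, defs, dosage)
}

geno_cell_to_dosage <- function(cell, major, minor, snp, path) {
  out <- rep(NA_integer_, length(cell))
  is_miss <- cell == "--"
  ok <- !is_miss
  if (any(nchar(cell[ok]) != 2L)) {
    bad <- which(ok & nchar(cell) != 2L)[1]
    stop("parse error in ", path, " line ", bad + 1L, ": bad genotype '",
         cell[bad], "' at ", snp, call. = FALSE)
  }
  a1 <- substr(cell, 1, 1); a2 <- substr(cell, 2, 2)
  legal <- c(major, minor)
  bad <- ok & (!(a1 %in% legal) | !(a2 %in% legal))
  if (any(bad)) {
    stop("parse error in ", path, " line ", which(bad)[1] + 1L,
         ": allele not in {", major, ",", minor, "} for ", snp, call. = FALSE)
  }
  out[ok] <- (a1[ok] == minor) + (a2[ok] == minor)
  out
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt))) {
    stop("multi-allelic record at ", fix[which(grepl(",", alt))[1], "ID"],
         ": only biallelic SNPs are supported", call. = FALSE)
  }
  ref <- fix[, "REF"]
  if (any(nchar(ref) != 1L | nchar(alt) != 1L)) {
    stop("non-SNP record (indel?) in ", path, call. = FALSE)
  }
  ids <- fix[, "ID"]
  if (anyDuplicated(ids)) stop("duplicate SNP id in VCF: ",
                               ids[duplicated(ids)][1], call. = FALSE)
  defs <- do.call(rbind, Map(snp_def, ids, ref, alt))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  gt_clean <- gsub("\\|", "/", gt)
  dosage <- matrix(NA_integer_, length(samples), length(ids))
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  for (i in seq_along(ids)) {
    g <- gt_clean[i, ]
    known <- g %in% c(names(map), "./.", ".", NA)
    if (!all(known)) {
      stop("parse error: unexpected GT '", g[!known][1], "' at ", ids[i],
           call. = FALSE)
    }
    dosage[, i] <- unname(map[g])
  }
  genotype_table(samples, defs, dosage)
}

#' Write a genotype table
#'
#' CSV output uses the two-letter dialect of [read_genotypes()]; VCF output
#' is bgzip-compressed VCF 4.x with REF = major and ALT = minor allele.
#'
#' @param table A [genotype_table()].
#' @param path Output path (use a `.vcf.gz` extension for VCF).
#' @param format `"csv"` or `"vcf"`.
#' @export
write_genotypes <- function(table, path, format = c("csv", "vcf")) {
  format <- match.arg(format)
  if (format == "csv") {
    cells <- vapply(seq_len(nrow(table$snps)), function(j) {
      g <- dosage_to_geno(table$dosage[, j], table$snps$major[j],
                          table$snps$minor[j])
      ifelse(is.na(g), "--", g)
    }, character(length(table$samples)))
    cells <- matrix(cells, nrow = length(table$samples))
    out <- data.frame(sample = table$samples, cells, stringsAsFactors = FALSE)
    names(out) <- c("sample", table$snps$id)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    write_genotypes_vcf(table, path)
  }
  invisible(path)
}

write_genotypes_vcf <- function(table, path) {
  n_snp <- nrow(table$snps)
  gt <- matrix("./.", n_snp, length(table$samples))
  for (j in seq_len(n_snp)) {
    dos <- table$dosage[, j]
    gt[j, !is.na(dos) & dos == 0L] <- "0/0"
    gt[j, !is.na(dos) & dos == 1L] <- "0/1"
    gt[j, !is.na(dos) & dos == 2L] <- "1/1"
  }
  gt <- cbind(FORMAT = "GT", gt)
  colnames(gt) <- c("FORMAT", table$samples)
  fix <- cbind(CHROM = "5", POS = as.character(seq_len(n_snp)),
               ID = table$snps$id, REF = table$snps$major,
               ALT = table$snps$minor, QUAL = ".", FILTER = "PASS", INFO = ".")
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  obj <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                      meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(obj, file = path)
  invisible(path)
}
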