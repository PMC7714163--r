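## Plain-text interchange: TSV tables, a minimal VCF export, optional VCF
## import via VariantAnnotation, and JSON reports.

#' Write / read a genotype matrix as TSV
#'
#' `write_genotypes_tsv` writes two files: `<prefix>_genotypes.tsv` (subjects
#' x SNPs, rsIDs as header, -2 for missing) and `<prefix>_snpmap.tsv`; a
#' `<prefix>_subjects.tsv` follows when subject metadata is present.
#'
#' @param g a [genotype_matrix].
#' @param prefix output path prefix.
#' @return (invisibly) the written paths.
#' @export
write_genotypes_tsv <- function(g, prefix) {
  paths <- c(genotypes = paste0(prefix, "_genotypes.tsv"),
             snpmap = paste0(prefix, "_snpmap.tsv"))
  gt <- data.frame(subject_id = rownames(g$genotypes) %||% seq_len(nrow(g$genotypes)),
                   g$genotypes, check.names = FALSE)
  utils::write.table(gt, paths["genotypes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(g$map, paths["snpmap"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(g$subjects)) {
    paths["subjects"] <- paste0(prefix, "_subjects.tsv")
    utils::write.table(g$subjects, paths["subjects"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(prefix) {
  gt <- utils::read.table(paste0(prefix, "_genotypes.tsv"), sep = "\t",
                          header = TRUE, check.names = FALSE)
  map <- utils::read.table(paste0(prefix, "_snpmap.tsv"), sep = "\t",
                           header = TRUE, colClasses = NA)
  subjects_path <- paste0(prefix, "_subjects.tsv")
  subjects <- if (file.exists(subjects_path)) {
    utils::read.table(subjects_path, sep = "\t", header = TRUE)
  } else {
    data.frame(subject_id = gt$subject_id)
  }
  G <- as.matrix(gt[, -1, drop = FALSE])
  rownames(G) <- gt$subject_id
  genotype_matrix(G, map, subjects)
}

#' Write / read a phenotype table as TSV
#' @param pheno data.frame of phenotype codes or values.
#' @param path output path.
#' @export
write_phenotypes_tsv <- function(pheno, path) {
  utils::write.table(data.frame(subject_id = rownames(pheno) %||% seq_len(nrow(pheno)),
                                pheno, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  out <- df[, -1, drop = FALSE]
  rownames(out) <- df[[1]]
  out
}

#' Write / read longitudinal growth observations as TSV
#'
#' Columns: `subject_id`, `time_weeks`, `head_circumference_cm`.
#' @param obs a `growth_observations` data.frame.
#' @param path output path.
#' @export
write_growth_tsv <- function(obs, path) {
  utils::write.table(
    data.frame(subject_id = obs$subject_id, time_weeks = obs$time_weeks,
               head_circumference_cm = obs$hc_cm),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_growth_tsv
#' @export
read_growth_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  out <- data.frame(subject_id = df$subject_id, time_weeks = df$time_weeks,
                    hc_cm = df$head_circumference_cm)
  class(out) <- c("growth_observations", "data.frame")
  out
}

#' Export a genotype matrix as VCF (GT field)
#'
#' Minimal VCFv4.2 with one sample column per subject; minor-allele counts
#' map to GT as 0 -> 0/0, 1 -> 0/1, 2 -> 1/1, missing -> ./.
#'
#' @param g a [genotype_matrix].
#' @param path output `.vcf` path (uncompressed).
#' @export
write_vcf <- function(g, path) {
  ids <- rownames(g$genotypes) %||% sprintf("S%04d", seq_len(nrow(g$genotypes)))
  gt_code <- c(`-2` = "./.", `0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=deltascan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  ), con)
  for (j in seq_len(ncol(g$genotypes))) {
    row <- c(g$map$chr[j], g$map$pos[j], g$map$rsid[j], g$map$major[j],
             g$map$minor[j], ".", "PASS", ".", "GT",
             gt_code[as.character(g$genotypes[, j])])
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

#' Import a VCF as a genotype matrix
#'
#' GT fields are converted to minor(ALT)-allele counts 0/1/2 with missing
#' calls as -2. Requires the optional \pkg{VariantAnnotation} package.
#'
#' @param path VCF path.
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("VCF import requires VariantAnnotation", call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  dose <- function(x) {
    ifelse(x %in% c("./.", ".", ".|."), -2L,
           vapply(strsplit(x, "[/|]"), function(a) sum(a == "1"), 1L))
  }
  G <- matrix(dose(as.vector(gt)), nrow = nrow(gt))  # variants x samples
  rr <- SummarizedExperiment::rowRanges(vcf)
  map <- data.frame(
    rsid = rownames(gt),
    chr = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    major = as.character(VariantAnnotation::ref(vcf)),
    minor = vapply(VariantAnnotation::alt(vcf), function(a) as.character(a)[1], ""),
    stringsAsFactors = FALSE
  )
  G <- t(G)  # subjects x SNPs
  genotype_matrix(G, map,
                  data.frame(subject_id = colnames(gt), stringsAsFactors = FALSE))
}

#' Write a preprocessing report as JSON
#' @param report a `preprocess_report`.
#' @param path output path.
#' @export
write_preprocess_report <- function(report, path) {
  jsonlite::write_json(
    list(steps = as.list(report$steps),
         collapsed_identical = report$collapsed_identical,
         collapsed_mi = report$collapsed_mi,
         removed = report$removed,
         retained_snps = report$retained_snps,
         xy_snps = report$xy_snps),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Write a scan result as TSV
#' @param result a `scan_result`.
#' @param path output path.
#' @export
write_scan_tsv <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
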