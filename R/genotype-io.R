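#' Write a genotype matrix in the pipeline's dosage TSV dialect
#'
#' SNPs as rows, subjects as columns, dosages in \{0,1,2\}, missing written as
#' `NA`. First column `snp_id`, header row carries subject ids.
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @export
write_genotype_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  df <- data.frame(snp_id = rownames(g$dosages), g$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write SNP panel metadata as TSV
#' @param snp_meta the `snp_meta` data.frame of a [genotype_matrix()].
#' @param path output file.
#' @export
write_panel_tsv <- function(snp_meta, path) {
  utils::write.table(snp_meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read SNP panel metadata TSV
#' @param path file written by [write_panel_tsv()].
#' @return data.frame.
#' @export
read_panel_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(snp_id = "character"),
                    stringsAsFactors = FALSE)
}

#' Write a phenotype table as TSV
#' @param pheno a [phenotype_table()].
#' @param path output file.
#' @export
write_phenotype_tsv <- function(pheno, path) {
  utils::write.table(as.data.frame(pheno), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate TSV
#'
#' Requires `subject_id`, `chd`, `t2d`, `age`, `sex`, `bmi`; the disease
#' pattern is recomputed from the statuses and checked against any provided
#' `pattern` column. Subjects missing either disease status are dropped with
#' a message.
#'
#' @param path TSV file.
#' @return a [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(subject_id = "character"),
                          stringsAsFactors = FALSE)
  phenotype_table(df)
}

#' Write genotypes as PLINK text .ped/.map
#'
#' Dosage 0 maps to `ref ref`, 1 to `ref alt`, 2 to `alt alt`; missing to
#' `0 0`. Disease status for the .ped phenotype column may be supplied,
#' otherwise it is written as missing (-9). Coordinates are 1-based.
#'
#' @param g a [genotype_matrix()] whose `snp_meta` carries `ref` and `alt`.
#' @param prefix path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @param phenotype optional 0/1 vector aligned to subjects.
#' @export
write_ped_map <- function(g, prefix, phenotype = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  sm <- g$snp_meta
  map <- data.frame(sm$chrom, sm$snp_id, 0, sm$pos)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  n <- ncol(g$dosages)
  ph <- if (is.null(phenotype)) rep(-9L, n) else phenotype + 1L  # PLINK 1/2 coding
  a1 <- sm$ref; a2 <- sm$alt
  lines <- vapply(seq_len(n), function(j) {
    d <- g$dosages[, j]
    al <- character(2 * length(d))
    al[seq_along(d) * 2 - 1] <- ifelse(is.na(d), "0", ifelse(d >= 1, a2, a1))
    al[seq_along(d) * 2]     <- ifelse(is.na(d), "0", ifelse(d == 2, a2, a1))
    paste(c(g$subject_ids[j], g$subject_ids[j], "0", "0", "1", ph[j], al),
          collapse = "\t")
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Write genotypes as a minimal VCFv4.2 file
#'
#' One biallelic SNV record per SNP with a `GT` field per subject
#' (unphased; dosage as alternate-allele count, missing as `./.`).
#'
#' @param g a [genotype_matrix()].
#' @param path output `.vcf` file (uncompressed).
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  sm <- g$snp_meta
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$subject_ids), collapse = "\t"))
  gt_of <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(g$dosages)), function(i) {
    d <- g$dosages[i, ]
    gt <- ifelse(is.na(d), "./.", gt_of[d + 1L])
    paste(c(sm$chrom[i], sm$pos[i], sm$snp_id[i], sm$ref[i], sm$alt[i],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genotypes from TSV, PLINK .ped/.map, or VCF
#'
#' All formats land in the same internal model: dosages oriented
#' SNPs x subjects as alternate-allele counts, half-missing genotypes treated
#' as missing. Non-biallelic VCF records are skipped with a logged count.
#'
#' @param path file path; for `ped_map`, the prefix without extension.
#' @param format one of `"tsv"`, `"ped_map"`, `"vcf"`.
#' @param snp_meta optional metadata data.frame (`snp_id`, `ref`, `alt`,
#'   `panel_label`, ...) used to orient alleles; for `ped_map` without it, the
#'   minor allele is taken as alternate.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "ped_map", "vcf"),
                           snp_meta = NULL) {
  format <- match.arg(format)
  switch(format,
         tsv = read_genotype_tsv(path, snp_meta),
         ped_map = read_ped_map(path, snp_meta),
         vcf = read_vcf(path, snp_meta))
}

read_genotype_tsv <- function(path, snp_meta = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character")
  snp_ids <- df[[1]]
  dos <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(dos) <- "integer")
  if (is.null(snp_meta))
    snp_meta <- data.frame(snp_id = snp_ids, chrom = "1",
                           pos = seq_along(snp_ids), ref = "A", alt = "G",
                           stringsAsFactors = FALSE)
  else snp_meta <- snp_meta[match(snp_ids, snp_meta$snp_id), , drop = FALSE]
  genotype_matrix(dos, snp_meta, colnames(df)[-1])
}

read_ped_map <- function(prefix, snp_meta = NULL) {
  map <- utils::read.table(paste0(prefix, ".map"), sep = "\t", header = FALSE,
                           colClasses = "character")
  snp_ids <- map[[2]]
  m <- nrow(map)
  ped_lines <- readLines(paste0(prefix, ".ped"))
  fields <- strsplit(ped_lines, "[ \t]+")
  n <- length(fields)
  expected <- 6 + 2 * m
  bad <- which(lengths(fields) != expected)
  if (length(bad)) stop("malformed .ped line ", bad[1], ": expected ",
                        expected, " fields, got ", lengths(fields)[bad[1]])
  subject_ids <- vapply(fields, `[`, character(1), 2)
  a1 <- t(vapply(fields, function(f) f[6 + seq_len(m) * 2 - 1], character(m)))
  a2 <- t(vapply(fields, function(f) f[6 + seq_len(m) * 2], character(m)))
  if (m == 1) { a1 <- matrix(a1, ncol = 1); a2 <- matrix(a2, ncol = 1) }
  # determine the counted (alternate) allele per SNP
  if (!is.null(snp_meta)) {
    alt <- snp_meta$alt[match(snp_ids, snp_meta$snp_id)]
    ref <- snp_meta$ref[match(snp_ids, snp_meta$snp_id)]
  } else {
    alt <- ref <- character(m)
    for (j in seq_len(m)) {
      al <- c(a1[, j], a2[, j]); al <- al[al != "0"]
      tab <- sort(table(al))
      alt[j] <- names(tab)[1]                       # minor allele
      ref[j] <- if (length(tab) > 1) names(tab)[length(tab)] else names(tab)[1]
    }
  }
  dos <- matrix(NA_integer_, m, n)
  for (j in seq_len(m)) {
    miss <- a1[, j] == "0" | a2[, j] == "0"         # half-missing -> missing
    dos[j, !miss] <- (a1[!miss, j] == alt[j]) + (a2[!miss, j] == alt[j])
  }
  meta <- if (is.null(snp_meta))
    data.frame(snp_id = snp_ids, chrom = map[[1]], pos = as.integer(map[[4]]),
               ref = ref, alt = alt, stringsAsFactors = FALSE)
  else snp_meta[match(snp_ids, snp_meta$snp_id), , drop = FALSE]
  genotype_matrix(dos, meta, subject_ids)
}

read_vcf <- function(path, snp_meta = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VCF input requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  biallelic <- lengths(VariantAnnotation::alt(vcf)) == 1L
  n_skip <- sum(!biallelic)
  if (n_skip) message("skipping ", n_skip, " non-biallelic VCF record(s)")
  vcf <- vcf[biallelic, ]
  gt <- VariantAnnotation::geno(vcf)$GT
  dose1 <- function(a) if (a %in% c(".", "")) NA_integer_ else as.integer(a != "0")
  dos <- apply(gt, c(1, 2), function(s) {
    al <- strsplit(s, "[/|]")[[1]]
    if (length(al) != 2) return(NA_integer_)
    d <- vapply(al, dose1, integer(1))
    if (anyNA(d)) NA_integer_ else sum(d)           # half-missing -> missing
  })
  rr <- SummarizedExperiment::rowRanges(vcf)
  meta <- data.frame(snp_id = names(rr),
                     chrom = as.character(GenomicRanges::seqnames(rr)),
                     pos = GenomicRanges::start(rr),
                     ref = as.character(VariantAnnotation::ref(vcf)),
                     alt = vapply(as.list(VariantAnnotation::alt(vcf)),
                                  function(a) as.character(a)[1], character(1)),
                     stringsAsFactors = FALSE)
  if (!is.null(snp_meta)) {
    idx <- match(meta$snp_id, snp_meta$snp_id)
    extra <- snp_meta[idx, setdiff(names(snp_meta), names(meta)), drop = FALSE]
    meta <- cbind(meta, extra)
  }
  genotype_matrix(dos, meta, colnames(gt))
}

#' Write a JSON manifest recording configuration and provenance
#'
#' @param path output `.json` file.
#' @param config any serializable list (e.g. a `cohort_config`).
#' @param seed integer seed used.
#' @param files named character vector of artifact paths.
#' @export
write_manifest <- function(path, config, seed, files = character()) {
  obj <- list(config = unclass_deep(config), seed = seed,
              files = as.list(files),
              package_version = as.character(utils::packageVersion("snpsetarch")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
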