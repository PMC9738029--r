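test_that("dosage TSV round-trips the internal model", {
  g <- tiny_genotypes(seed = 2)
  g$dosages[1, 3] <- NA_integer_  # exercise the missing path
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_tsv(g, path)
  g2 <- read_genotypes(path, "tsv", snp_meta = g$snp_meta)
  expect_identical(g2$dosages, g$dosages)
  expect_identical(g2$subject_ids, g$subject_ids)
  # write(read(x)) stability
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_tsv(g2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("ped/map round-trips and counts alternate alleles by tally", {
  g <- tiny_genotypes(m = 6, n = 25, seed = 5)
  g$dosages[2, 4] <- NA_integer_
  prefix <- file.path(withr::local_tempdir(), "cohort")
  write_ped_map(g, prefix)
  g2 <- read_genotypes(prefix, "ped_map", snp_meta = g$snp_meta)
  expect_identical(g2$dosages, g$dosages)

  # hand-written .ped: alleles A A at a SNP whose alternate allele is A -> dosage 2
  dir <- withr::local_tempdir()
  writeLines("1\trs1\t0\t100", file.path(dir, "toy.map"))
  writeLines(c("F1\tI1\t0\t0\t1\t-9\tA\tA",
               "F2\tI2\t0\t0\t1\t-9\tC\tA",
               "F3\tI3\t0\t0\t1\t-9\t0\t0"), file.path(dir, "toy.ped"))
  meta <- data.frame(snp_id = "rs1", chrom = "1", pos = 100L,
                     ref = "C", alt = "A", stringsAsFactors = FALSE)
  g3 <- read_genotypes(file.path(dir, "toy"), "ped_map", snp_meta = meta)
  expect_identical(as.integer(g3$dosages), c(2L, 1L, NA))

  # malformed line is reported with its number
  writeLines(c("F1\tI1\t0\t0\t1\t-9\tA\tA", "F2\tI2\t0\t0\t1\t-9\tA"),
             file.path(dir, "bad.ped"))
  writeLines("1\trs1\t0\t100", file.path(dir, "bad.map"))
  expect_error(read_genotypes(file.path(dir, "bad"), "ped_map"), "line 2")
})

test_that("VCF GT fields map to dosage with half-missing treated as missing", {
  g <- tiny_genotypes(m = 5, n = 10, seed = 7)
  g$dosages[1, 1] <- NA_integer_
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, path)
  g2 <- read_genotypes(path, "vcf", snp_meta = g$snp_meta)
  expect_equal(unname(g2$dosages), unname(g$dosages))
  # explicit coding conventions, including a skipped multiallelic record
  dir <- withr::local_tempdir()
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tX1\tX2\tX3",
           "1\t10\trsA\tA\tG\t.\tPASS\t.\tGT\t0/1\t./.\t1|1",
           "1\t20\trsB\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0",
           "1\t30\trsC\tA\tG\t.\tPASS\t.\tGT\t./1\t0/0\t0/0")
  vp <- file.path(dir, "toy.vcf")
  writeLines(vcf, vp)
  expect_message(g3 <- read_genotypes(vp, "vcf"), "1 non-biallelic")
  expect_equal(nrow(g3$dosages), 2)  # rsB skipped
  expect_identical(as.integer(g3$dosages["rsA", ]), c(1L, NA, 2L))
  expect_true(is.na(g3$dosages["rsC", 1]))  # half-missing
})

test_that("phenotype reader recomputes patterns and drops incomplete subjects", {
  df <- data.frame(subject_id = sprintf("P%d", 1:6),
                   chd = c(1, 1, 0, 0, 1, NA), t2d = c(1, 0, 1, 0, NA, 0),
                   age = 60, sex = 1, bmi = 25)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(ph <- read_phenotypes(path), "dropping 2")
  expect_equal(nrow(ph), 4)
  expect_equal(as.character(ph$pattern),
               c("comorbid", "chd_only", "t2d_only", "none"))
  # a contradictory provided pattern column is rejected
  df2 <- df[1:4, ]; df2$pattern <- "none"
  write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_phenotypes(path), "disagrees")
})

test_that("duplicate ids and malformed dosages are rejected", {
  dos <- matrix(0L, 2, 2)
  meta <- data.frame(snp_id = c("a", "a"), chrom = "1", pos = 1:2,
                     ref = "A", alt = "G")
  expect_error(genotype_matrix(dos, meta, c("x", "y")), "duplicate SNP")
  meta$snp_id <- c("a", "b")
  expect_error(genotype_matrix(dos, meta, c("x", "x")), "duplicate subject")
  dos[1, 1] <- 3L
  expect_error(genotype_matrix(dos, meta, c("x", "y")), "\\{0,1,2\\}")
})

test_that("align_subjects joins on id, never positionally", {
  g <- tiny_genotypes(n = 10, seed = 3)
  ph <- tiny_pheno(n = 10, seed = 3)
  ph <- ph[sample(nrow(ph)), ]  # scramble order
  al <- align_subjects(g, ph)
  expect_identical(al$genotypes$subject_ids, al$phenotypes$subject_id)
  expect_identical(al$genotypes$dosages, g$dosages[, al$phenotypes$subject_id])
})
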