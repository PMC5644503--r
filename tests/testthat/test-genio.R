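test_that("toy cohort loads with sample allele frequencies", {
  td <- withr::local_tempdir()
  geno <- genotype_matrix(matrix(c(0, 1, 2, 2, 1, 0), 3, 2,
                                 dimnames = list(c("a", "b", "c"), c("s1", "s2"))))
  write_genotypes(geno, file.path(td, "g.tsv"))
  ped <- pedigree(data.frame(family_id = "f1", person_id = c("a", "b", "c"),
                             father_id = NA, mother_id = NA,
                             sex = c("F", "M", "F"), generation = "parent"))
  write_pedigree(ped, file.path(td, "p.tsv"))
  write_phenotypes(data.frame(person_id = c("a", "b", "c"),
                              edu_years = c(12, 14, 16), age = 40,
                              sex = c("F", "M", "F"), survey_year = 2010),
                   file.path(td, "ph.tsv"))
  coh <- load_cohort(file.path(td, "g.tsv"), file.path(td, "p.tsv"),
                     file.path(td, "ph.tsv"))
  expect_equal(dim(coh$genotypes$dosage), c(3L, 2L))
  expect_equal(unname(coh$genotypes$panel$freq),
               unname(colMeans(geno$dosage) / 2))
  expect_false(any(coh$phenotypes$missing_genotype))
})

test_that("VCF genotypes decode GT allele counts", {
  td <- withr::local_tempdir()
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
           "1\t100\trs1\tG\tA\t.\tPASS\t.\tGT\t0/1\t1/1\t0/0",
           "1\t200\trs2\tT\tC\t.\tPASS\t.\tGT\t0|0\t0/1\t./.")
  writeLines(vcf, file.path(td, "toy.vcf"))
  gv <- read_genotypes_vcf(file.path(td, "toy.vcf"))
  expect_equal(unname(gv$dosage["S1", ]), c(1, 0))
  expect_equal(unname(gv$dosage["S2", ]), c(2, 1))
  expect_true(is.na(gv$dosage["S3", "rs2"]))
  expect_equal(gv$panel$effect_allele, c("A", "C"))
})

test_that("simulated cohort round-trips bit-identically through disk", {
  td <- withr::local_tempdir()
  b <- simulate_cohort(sim_config(n_families = 40, m_snps = 25,
                                  calibrate = FALSE, seed = 2))
  write_cohort(b, td)
  coh <- load_cohort(file.path(td, "genotypes.tsv"),
                     file.path(td, "pedigree.tsv"),
                     file.path(td, "phenotypes.tsv"))
  expect_identical(coh$genotypes$dosage, b$genotypes$dosage)
  expect_identical(coh$phenotypes$edu_years, b$phenotypes$edu_years)
  expect_identical(coh$pedigree$mother_id, b$pedigree$mother_id)
  w <- read_weights(file.path(td, "weights_noisy.tsv"))
  expect_identical(w$weight, b$noisy_weights$weight)
})

test_that("id and allele integrity is enforced", {
  expect_error(genotype_matrix(matrix(0, 2, 1), sample_id = c("x", "x")),
               "duplicate")
  expect_error(snp_panel(c("a", "a")), "duplicate")
  expect_error(snp_panel("a", freq = 1.0), "strictly")
  expect_error(pedigree(data.frame(family_id = "f", person_id = "a",
                                   father_id = "a", mother_id = NA,
                                   sex = "M", generation = "parent")),
               "own parent")
  geno <- toy_genotypes(3, 2)
  w <- data.frame(snp_id = "rs001", effect_allele = "T", weight = 0.1)
  td <- withr::local_tempdir()
  write_genotypes(geno, file.path(td, "g.tsv"))
  write_pedigree(pedigree(data.frame(family_id = "f", person_id = geno$sample_id,
                                     father_id = NA, mother_id = NA, sex = "F",
                                     generation = "parent")),
                 file.path(td, "p.tsv"))
  write_phenotypes(data.frame(person_id = geno$sample_id, edu_years = 12,
                              age = 40, sex = "F", survey_year = NA),
                   file.path(td, "ph.tsv"))
  expect_error(load_cohort(file.path(td, "g.tsv"), file.path(td, "p.tsv"),
                           file.path(td, "ph.tsv"), weights = w),
               "rs001")
})

test_that("missing dosage policy drops heavy missingness and mean-imputes", {
  X <- matrix(c(0, 1, 2, 2, NA, 0, 1, 1, NA, NA, NA, 2), 4, 3, byrow = TRUE)
  rownames(X) <- sprintf("i%d", 1:4)
  geno <- genotype_matrix(X)
  expect_message(out <- impute_dosages(geno, max_missing = 0.5), "dropping 1")
  expect_equal(nrow(out$dosage), 3L)
  expect_false(anyNA(out$dosage))
  miss_col <- out$panel$freq[2] * 2   # imputed value equals 2 p
  expect_equal(out$dosage["i2", 2], miss_col)
})

test_that("GCTA text GRM layout and round trip", {
  A <- matrix(c(1.01, 0.02, 0.02, 0.99), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  grm <- structure(list(sample_id = c("a", "b"), A = A, n_snps = 100L),
                   class = "grm")
  td <- withr::local_tempdir()
  pre <- file.path(td, "t")
  write_grm_gcta(grm, pre)
  tri <- read.table(paste0(pre, ".grm"))
  expect_equal(nrow(tri), 3L)                         # n(n+1)/2
  expect_equal(tri[, 1], c(1L, 2L, 2L))
  expect_equal(tri[, 2], c(1L, 1L, 2L))
  back <- read_grm_gcta(pre)
  expect_equal(back$A, A)

  g10 <- compute_grm(toy_genotypes(10, 40, seed = 3))
  write_grm_gcta(g10, file.path(td, "t10"))
  expect_equal(nrow(read.table(file.path(td, "t10.grm"))), 55L)
  expect_equal(read_grm_gcta(file.path(td, "t10"))$A, g10$A)

  grm$A[1, 2] <- NaN
  expect_error(write_grm_gcta(grm, file.path(td, "bad")), "non-finite")
  # truncate the triangle -> gap-listing error
  lines <- readLines(paste0(pre, ".grm"))
  writeLines(lines[-2], paste0(pre, ".grm"))
  expect_error(read_grm_gcta(pre), "incomplete")
})
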