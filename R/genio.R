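## Readers and writers for genotypes, weights, pedigrees, phenotypes and
## GCTA-style text GRMs. All downstream modules consume only the in-memory
## containers built here. Text formats are tab-delimited with a header row;
## ids are opaque strings.

#' SNP panel descriptor
#'
#' Holds the marker metadata attached to a genotype matrix: identifiers, the
#' effect allele whose copies the dosage counts, the other allele, and the
#' effect-allele frequency (estimated in-sample when not supplied).
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param effect_allele single-character allele codes (recycled).
#' @param other_allele single-character allele codes (recycled).
#' @param freq effect-allele frequencies in (0,1), or `NA` to fill later.
#' @return A `data.frame` with class `snp_panel`.
#' @export
snp_panel <- function(snp_id, effect_allele = "A", other_allele = "B",
                      freq = NA_real_) {
  snp_id <- as.character(snp_id)
  if (anyDuplicated(snp_id)) stop_poly("duplicate snp_id in panel")
  p <- data.frame(
    snp_id = snp_id,
    effect_allele = rep_len(as.character(effect_allele), length(snp_id)),
    other_allele = rep_len(as.character(other_allele), length(snp_id)),
    freq = rep_len(as.numeric(freq), length(snp_id)),
    stringsAsFactors = FALSE
  )
  bad <- !is.na(p$freq) & (p$freq <= 0 | p$freq >= 1)
  if (any(bad)) {
    stop_poly("allele frequencies must lie strictly in (0,1); offending SNP(s): %s",
              paste(head(p$snp_id[bad], 5), collapse = ", "))
  }
  class(p) <- c("snp_panel", "data.frame")
  p
}

#' Additive genotype dosage matrix
#'
#' @param dosage numeric N x M matrix of effect-allele counts in `[0,2]`
#'   (`NA` = missing). Row names are taken as sample ids when `sample_id` is
#'   not given.
#' @param panel an [snp_panel()]; a default panel is built from column names
#'   when absent.
#' @param sample_id character sample identifiers, length N.
#' @return An object of class `genotype_matrix` with fields `sample_id`,
#'   `dosage`, `panel`.
#' @export
genotype_matrix <- function(dosage, panel = NULL, sample_id = NULL) {
  dosage <- as.matrix(dosage)
  sample_id <- as.character(sample_id %||% rownames(dosage))
  if (is.null(sample_id) || !length(sample_id)) {
    sample_id <- sprintf("S%05d", seq_len(nrow(dosage)))
  }
  if (anyDuplicated(sample_id)) stop_poly("duplicate sample ids in genotype matrix")
  if (length(sample_id) != nrow(dosage)) {
    stop_poly("sample_id length (%d) != dosage rows (%d)",
              length(sample_id), nrow(dosage))
  }
  if (is.null(panel)) {
    ids <- colnames(dosage) %||% sprintf("snp%05d", seq_len(ncol(dosage)))
    panel <- snp_panel(ids)
  }
  if (nrow(panel) != ncol(dosage)) {
    stop_poly("panel has %d SNPs but dosage has %d columns",
              nrow(panel), ncol(dosage))
  }
  rng <- range(dosage, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    stop_poly("dosages must lie in [0,2]; observed range [%g, %g]", rng[1], rng[2])
  }
  rownames(dosage) <- sample_id
  colnames(dosage) <- panel$snp_id
  structure(list(sample_id = sample_id, dosage = dosage, panel = panel),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Estimate effect-allele frequencies from the sample
#'
#' Per-SNP frequency is `mean(dosage)/2` over non-missing entries.
#'
#' @param geno a [genotype_matrix()].
#' @return Numeric vector of frequencies, one per SNP.
#' @export
allele_freqs <- function(geno) {
  colMeans(geno$dosage, na.rm = TRUE) / 2
}

#' Fill missing panel frequencies from the sample
#' @param geno a [genotype_matrix()].
#' @return The genotype matrix with `panel$freq` completed.
#' @export
fill_panel_freqs <- function(geno) {
  est <- allele_freqs(geno)
  miss <- is.na(geno$panel$freq)
  geno$panel$freq[miss] <- est[miss]
  geno
}

#' Handle missing dosages before scoring / GRM work
#'
#' Persons missing more than `max_missing` of their SNPs are dropped (with a
#' message reporting the count); remaining missing dosages are imputed to the
#' SNP mean `2 p_i`.
#'
#' @param geno a [genotype_matrix()].
#' @param max_missing maximum tolerated per-person missing fraction.
#' @return A complete-data `genotype_matrix`.
#' @export
impute_dosages <- function(geno, max_missing = 0.1) {
  miss_frac <- rowMeans(is.na(geno$dosage))
  drop <- miss_frac > max_missing
  if (any(drop)) {
    message(sprintf("impute_dosages: dropping %d person(s) with > %.0f%% missing SNPs",
                    sum(drop), 100 * max_missing))
    geno <- genotype_matrix(geno$dosage[!drop, , drop = FALSE], geno$panel)
  }
  if (anyNA(geno$dosage)) {
    geno <- fill_panel_freqs(geno)
    mu <- 2 * geno$panel$freq
    idx <- which(is.na(geno$dosage), arr.ind = TRUE)
    geno$dosage[idx] <- mu[idx[, 2]]
  }
  geno
}

## ---------------------------------------------------------------------------
## delimited text I/O

#' Write / read a genotype matrix as TSV (rows = samples)
#'
#' The layout is one header line (`sample_id` then SNP ids) and one row per
#' sample. Panel metadata (alleles, frequencies) goes to `<path>.panel` so the
#' matrix file stays interoperable with plain spreadsheet tools.
#'
#' @param geno a [genotype_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  dt <- data.table(sample_id = geno$sample_id)
  dos <- as.data.table(geno$dosage)
  fwrite(cbind(dt, dos), path, sep = "\t", na = "NA", quote = FALSE)
  pf <- geno$panel
  pf$freq <- fmt_num(pf$freq)
  fwrite(pf, paste0(path, ".panel"), sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, na.strings = "NA",
              data.table = FALSE)
  if (anyDuplicated(dt$sample_id)) stop_poly("duplicate sample ids in %s", path)
  dos <- as.matrix(dt[, -1, drop = FALSE])
  rownames(dos) <- dt$sample_id
  panel_path <- paste0(path, ".panel")
  panel <- NULL
  if (file.exists(panel_path)) {
    pf <- fread(panel_path, sep = "\t", header = TRUE, na.strings = "NA",
                data.table = FALSE)
    panel <- snp_panel(pf$snp_id, pf$effect_allele, pf$other_allele, pf$freq)
  }
  genotype_matrix(dos, panel = panel, sample_id = dt$sample_id)
}

#' Read diploid genotypes from a VCF file
#'
#' Thin wrapper over `VariantAnnotation::readVcf()`: dosages count copies of
#' the ALT allele from the GT field (phased or unphased). Multi-allelic
#' records are rejected.
#'
#' @param path VCF path (uncompressed or bgzipped).
#' @return A [genotype_matrix()] with ALT as the effect allele.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop_poly("read_genotypes_vcf requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  if (any(lengths(alt) != 1L)) stop_poly("multi-allelic VCF records are not supported")
  gt <- VariantAnnotation::geno(vcf)$GT                 # variants x samples
  count_alt <- function(g) {
    if (g %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(strsplit(g, "[/|]")[[1]] == "1")
  }
  dos <- t(apply(gt, c(1, 2), count_alt))               # samples x variants
  panel <- snp_panel(rownames(gt),
                     effect_allele = as.character(unlist(alt)),
                     other_allele = as.character(VariantAnnotation::ref(vcf)))
  genotype_matrix(dos, panel = panel, sample_id = colnames(gt))
}

#' Pedigree table
#'
#' One row per person: family id, person id, parent ids (`NA` for founders or
#' parents outside the sample), sex (`"F"`/`"M"`), generation
#' (`"parent"`/`"offspring"`).
#'
#' @param df data.frame with columns `family_id`, `person_id`, `father_id`,
#'   `mother_id`, `sex`, `generation`.
#' @return The validated data.frame with class `pedigree`.
#' @export
pedigree <- function(df) {
  assert_cols(df, c("family_id", "person_id", "father_id", "mother_id",
                    "sex", "generation"), "pedigree")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (cc in c("family_id", "person_id", "father_id", "mother_id")) {
    df[[cc]] <- as.character(df[[cc]])
    df[[cc]][df[[cc]] %in% c("0", "")] <- NA_character_
  }
  if (anyDuplicated(df$person_id)) stop_poly("duplicate person_id in pedigree")
  if (any(!is.na(df$father_id) & df$father_id == df$person_id) ||
      any(!is.na(df$mother_id) & df$mother_id == df$person_id)) {
    stop_poly("pedigree lists a person as their own parent")
  }
  # two-generation check: a stated parent must either be present or flagged external
  present <- df$person_id
  for (cc in c("father_id", "mother_id")) {
    stated <- df[[cc]][!is.na(df[[cc]])]
    ext <- setdiff(stated, present)
    if (length(ext) && !isTRUE(attr(df, "allow_external_parents"))) {
      attr(df, "external_parents") <- ext
    }
  }
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Write / read a pedigree as a FAM-like TSV
#'
#' Columns `FID IID PAT MAT SEX GEN` with header; sex written as F/M and read
#' back from either F/M or PLINK 1/2 coding; missing parents written as 0.
#'
#' @param ped a [pedigree()].
#' @param path file path.
#' @return `path` (write) or a `pedigree` (read).
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(FID = ped$family_id, IID = ped$person_id,
                    PAT = ifelse(is.na(ped$father_id), "0", ped$father_id),
                    MAT = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                    SEX = ped$sex, GEN = ped$generation)
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, data.table = FALSE,
              colClasses = "character")
  sex <- dt$SEX
  sex[sex == "1"] <- "M"; sex[sex == "2"] <- "F"
  pedigree(data.frame(family_id = dt$FID, person_id = dt$IID,
                      father_id = dt$PAT, mother_id = dt$MAT,
                      sex = sex, generation = dt$GEN,
                      stringsAsFactors = FALSE))
}

#' Write / read a phenotype table
#'
#' Columns: `person_id`, `edu_years`, `age`, `sex`, `survey_year`.
#'
#' @param phen data.frame phenotype table.
#' @param path file path.
#' @return `path` (write) or the table (read).
#' @export
write_phenotypes <- function(phen, path) {
  assert_cols(phen, c("person_id", "edu_years", "age", "sex"), "phenotype table")
  out <- phen
  for (cc in c("edu_years", "age")) out[[cc]] <- fmt_num(out[[cc]])
  fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- fread(path, sep = "\t", header = TRUE, na.strings = "NA",
              data.table = FALSE)
  assert_cols(df, c("person_id", "edu_years", "age", "sex"), "phenotype table")
  df$person_id <- as.character(df$person_id)
  if (anyDuplicated(df$person_id)) stop_poly("duplicate person_id in %s", path)
  if (any(!is.finite(df$edu_years))) stop_poly("non-finite edu_years in %s", path)
  df
}

#' Write / read a GWAS weight table
#'
#' TSV with header `SNP A1 WEIGHT`: SNP id, effect allele, per-allele weight
#' in years of schooling.
#'
#' @param weights data.frame with columns `snp_id`, `effect_allele`, `weight`.
#' @param path file path.
#' @return `path` (write) or the weight table (read).
#' @export
write_weights <- function(weights, path) {
  assert_cols(weights, c("snp_id", "effect_allele", "weight"), "weight table")
  out <- data.frame(SNP = weights$snp_id, A1 = weights$effect_allele,
                    WEIGHT = fmt_num(weights$weight))
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  assert_cols(dt, c("SNP", "A1", "WEIGHT"), "weight file")
  w <- data.frame(snp_id = as.character(dt$SNP),
                  effect_allele = as.character(dt$A1),
                  weight = as.numeric(dt$WEIGHT), stringsAsFactors = FALSE)
  if (anyDuplicated(w$snp_id)) stop_poly("duplicate snp_id in weight file %s", path)
  if (any(!is.finite(w$weight))) stop_poly("non-finite weight in %s", path)
  w
}

#' Load a cohort from delimited files
#'
#' Reads genotypes (TSV or VCF), pedigree and phenotypes, cross-references
#' ids, and estimates allele frequencies from the sample when the panel does
#' not supply them. Persons present in the phenotype table but absent from the
#' genotype file are retained and flagged (`missing_genotype`). If a weight
#' table is supplied, its effect alleles are checked against the panel and a
#' mismatch is a hard error naming the SNP.
#'
#' @param genotype_path path to a genotype TSV (or VCF when `vcf = TRUE`).
#' @param pedigree_path path to a FAM-like pedigree TSV.
#' @param phenotype_path path to a phenotype TSV.
#' @param weights optional weight table (data.frame) for allele checking.
#' @param vcf logical; read genotypes as VCF.
#' @return List with elements `genotypes`, `pedigree`, `phenotypes` (the
#'   phenotype table gains a logical `missing_genotype` column).
#' @export
load_cohort <- function(genotype_path, pedigree_path, phenotype_path,
                        weights = NULL, vcf = FALSE) {
  for (p in c(genotype_path, pedigree_path, phenotype_path)) {
    if (!file.exists(p)) stop_poly("input file not found: %s", p)
  }
  geno <- if (vcf) read_genotypes_vcf(genotype_path) else read_genotypes(genotype_path)
  ped <- read_pedigree(pedigree_path)
  phen <- read_phenotypes(phenotype_path)
  geno <- fill_panel_freqs(geno)
  phen$missing_genotype <- !(phen$person_id %in% geno$sample_id)
  if (!is.null(weights)) {
    m <- match(weights$snp_id, geno$panel$snp_id)
    shared <- which(!is.na(m))
    ok <- weights$effect_allele[shared] == geno$panel$effect_allele[m[shared]] |
      weights$effect_allele[shared] == geno$panel$other_allele[m[shared]]
    if (any(!ok)) {
      stop_poly("allele code mismatch between genotype panel and weight table for SNP(s): %s",
                paste(head(weights$snp_id[shared[!ok]], 5), collapse = ", "))
    }
  }
  list(genotypes = geno, pedigree = ped, phenotypes = phen)
}

## ---------------------------------------------------------------------------
## GCTA-style text GRM

#' Write a GRM in the GCTA text layout
#'
#' Emits `<prefix>.grm` (tab-separated lower triangle: index j, index k <= j,
#' number of SNPs, relatedness A_jk) and `<prefix>.grm.id` (family id,
#' person id).
#'
#' @param grm a [compute_grm()] result.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_grm_gcta <- function(grm, prefix) {
  A <- grm$A
  if (any(!is.finite(A))) stop_poly("GRM contains non-finite entries")
  n <- nrow(A)
  j <- rep(seq_len(n), seq_len(n))
  k <- unlist(lapply(seq_len(n), seq_len))
  vals <- A[cbind(j, k)]
  dt <- data.table(j = j, k = k, n_snps = grm$n_snps, a = fmt_num(vals))
  fwrite(dt, paste0(prefix, ".grm"), sep = "\t", col.names = FALSE, quote = FALSE)
  fam <- grm$family_id %||% grm$sample_id
  fwrite(data.table(fid = fam, iid = grm$sample_id),
         paste0(prefix, ".grm.id"), sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' Read a GCTA text GRM
#'
#' @param prefix path prefix of a `<prefix>.grm` / `<prefix>.grm.id` pair.
#' @return A `grm` object (see [compute_grm()]).
#' @export
read_grm_gcta <- function(prefix) {
  gp <- paste0(prefix, ".grm"); ip <- paste0(prefix, ".grm.id")
  if (!file.exists(gp) || !file.exists(ip)) {
    stop_poly("GRM files not found at prefix %s", prefix)
  }
  ids <- fread(ip, sep = "\t", header = FALSE, data.table = FALSE,
               colClasses = "character")
  tri <- fread(gp, sep = "\t", header = FALSE, data.table = FALSE)
  n <- nrow(ids)
  need <- n * (n + 1) / 2
  if (nrow(tri) != need) {
    have <- paste(tri[[1]], tri[[2]])
    all_jk <- paste(rep(seq_len(n), seq_len(n)),
                    unlist(lapply(seq_len(n), seq_len)))
    gaps <- setdiff(all_jk, have)
    stop_poly("GRM lower triangle incomplete: expected %d entries, found %d; missing (j k): %s%s",
              need, nrow(tri), paste(head(gaps, 10), collapse = "; "),
              if (length(gaps) > 10) " ..." else "")
  }
  A <- matrix(0, n, n)
  A[cbind(tri[[1]], tri[[2]])] <- tri[[4]]
  A[cbind(tri[[2]], tri[[1]])] <- tri[[4]]
  dimnames(A) <- list(ids[[2]], ids[[2]])
  structure(list(sample_id = ids[[2]], family_id = ids[[1]], A = A,
                 n_snps = tri[[3]][1]),
            class = "grm")
}
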