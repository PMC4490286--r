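# PLINK BED/BIM/FAM input/output ---------------------------------------------
#
# SNP-major .bed with the standard magic bytes 0x6c 0x1b 0x01; two bits per
# genotype, samples packed little-endian within each byte. Allele A1 is the
# minor (B) allele, so the stored codes map to minor-allele dosage as
# 00 -> 2, 10 -> 1, 11 -> 0, 01 -> missing.

#' Write a genotype table as PLINK BED/BIM/FAM
#'
#' Also writes `<prefix>.subjects.tsv` carrying the subject metadata that
#' FAM cannot hold (group, age, sex, site, ethnicity, clinical scores).
#'
#' @param gt a `genotype_table`.
#' @param prefix output path prefix (no extension).
#' @return invisibly, the paths written.
#' @export
write_plink <- function(gt, prefix) {
  stopifnot(inherits(gt, "genotype_table"))
  n <- nrow(gt$dosage); m <- ncol(gt$dosage)
  # .fam: FID IID PAT MAT SEX PHENO (1=control, 2=case)
  sex_code <- ifelse(is.na(gt$subjects$sex), 0L,
                     ifelse(gt$subjects$sex == "male", 1L, 2L))
  pheno <- ifelse(gt$subjects$group == "control", 1L, 2L)
  fam <- data.frame(gt$subjects$id, gt$subjects$id, 0L, 0L, sex_code, pheno)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bim <- data.frame(gt$snps$chromosome, gt$snps$id, 0L, gt$snps$position,
                    gt$snps$allele_b, gt$snps$allele_a)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  # .bed
  code <- matrix(1L, n, m)                    # 01 = missing
  code[!is.na(gt$dosage) & gt$dosage == 2L] <- 0L
  code[!is.na(gt$dosage) & gt$dosage == 1L] <- 2L
  code[!is.na(gt$dosage) & gt$dosage == 0L] <- 3L
  bytes_per_snp <- ceiling(n / 4)
  pad <- bytes_per_snp * 4L - n
  if (pad > 0L) code <- rbind(code, matrix(0L, pad, m))
  shifts <- rep(c(1L, 4L, 16L, 64L), bytes_per_snp)
  packed <- code * shifts
  dim(packed) <- c(4L, bytes_per_snp * m)
  bytes <- as.raw(colSums(packed))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  utils::write.table(gt$subjects, paste0(prefix, ".subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam", ".subjects.tsv")))
}

#' Read PLINK BED/BIM/FAM into a genotype table
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` triplet. When a
#'   `<prefix>.subjects.tsv` metadata table is present it supplies the
#'   subject columns; otherwise group/sex are decoded from FAM.
#' @return a `genotype_table`.
#' @export
read_plink <- function(prefix) {
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE)
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3L + ceiling(n / 4) * m)
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK .bed file", call. = FALSE)
  body <- as.integer(raw[-(1:3)])
  bytes_per_snp <- ceiling(n / 4)
  codes <- matrix(0L, 4L * bytes_per_snp, m)
  b <- matrix(body, bytes_per_snp, m)
  codes[seq(1, by = 4, length.out = bytes_per_snp), ] <- b %% 4L
  codes[seq(2, by = 4, length.out = bytes_per_snp), ] <- (b %/% 4L) %% 4L
  codes[seq(3, by = 4, length.out = bytes_per_snp), ] <- (b %/% 16L) %% 4L
  codes[seq(4, by = 4, length.out = bytes_per_snp), ] <- (b %/% 64L) %% 4L
  codes <- codes[seq_len(n), , drop = FALSE]
  dosage <- matrix(NA_integer_, n, m)
  dosage[codes == 0L] <- 2L
  dosage[codes == 2L] <- 1L
  dosage[codes == 3L] <- 0L
  meta_path <- paste0(prefix, ".subjects.tsv")
  subjects <- if (file.exists(meta_path)) {
    utils::read.delim(meta_path, stringsAsFactors = FALSE)
  } else {
    data.frame(id = as.character(fam$V2),
               group = ifelse(fam$V6 == 1, "control", "case1"),
               sex = c("male", "female", NA)[ifelse(fam$V5 %in% 1:2,
                                                    fam$V5, 3L)],
               stringsAsFactors = FALSE)
  }
  snps <- data.frame(id = as.character(bim$V2), chromosome = bim$V1,
                     position = bim$V4, allele_a = as.character(bim$V6),
                     allele_b = as.character(bim$V5),
                     stringsAsFactors = FALSE)
  rownames(dosage) <- subjects$id; colnames(dosage) <- snps$id
  genotype_table(dosage, snps, subjects)
}
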