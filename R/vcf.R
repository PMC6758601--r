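#' Read biallelic SNPs from a VCF file
#'
#' Parses a VCF 4.x file with vcfR and converts GT fields to alternate-allele
#' dosages.  Only biallelic SNP records are retained (multiallelic records
#' are dropped, not decomposed — the five-taxon D framework is defined on
#' biallelic sites).  `CHROM` becomes the locus id, positions stay 1-based as
#' in the VCF.  Half-calls and `./.` become missing.  Phasing is ignored:
#' downstream statistics use allele frequencies only.
#'
#' @param path VCF file path (plain or gzipped).
#' @return A [snp_matrix()].  Ploidy per sample is inferred from the GT
#'   fields (a sample with any two-allele call is diploid).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) abort(sprintf("cannot parse VCF %s: %s",
                                                  path, conditionMessage(e))))
  fix <- v@fix
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L) abort("VCF has no genotype columns")
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  bases <- c("A", "C", "G", "T")
  biallelic <- ref %in% bases & alt %in% bases
  if (!any(biallelic)) abort("no biallelic SNP records in VCF")
  fix <- fix[biallelic, , drop = FALSE]
  gtf <- gt[biallelic, -1L, drop = FALSE]  # drop FORMAT column
  samples <- colnames(gtf)
  # GT is the first colon-separated field
  gt_only <- sub(":.*$", "", gtf)
  alleles <- strsplit(gt_only, "[/|]")
  dose1 <- function(a) {
    a <- a[a != "."]
    if (length(a) == 0L) NA_integer_ else sum(a == "1")
  }
  dos <- matrix(vapply(alleles, dose1, integer(1L)),
                nrow = nrow(gtf), ncol = ncol(gtf))
  n_all <- matrix(vapply(alleles, length, integer(1L)),
                  nrow = nrow(gtf), ncol = ncol(gtf))
  # half calls (e.g. "./1") -> missing
  half <- matrix(vapply(alleles, function(a) any(a == ".") && !all(a == "."),
                        logical(1L)), nrow = nrow(gtf))
  dos[half] <- NA_integer_
  if (all(is.na(dos))) abort("VCF genotypes are all missing: empty matrix")
  ploidy <- apply(n_all, 2L, max)
  dos <- t(dos)
  rownames(dos) <- samples
  snp_matrix(
    dos,
    tibble(locus_id = fix[, "CHROM"],
           position = as.integer(fix[, "POS"]),
           ref = fix[, "REF"], alt = fix[, "ALT"]),
    ploidy = as.integer(ploidy)
  )
}

#' Write a SNP matrix as a plain-text VCF 4.2 file
#'
#' @param m a [snp_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pentad",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(m)), collapse = "\t")
  ), con)
  if (n_sites(m) > 0L) {
    gt_string <- function(d, p) {
      if (is.na(d)) return(if (p == 2L) "./." else ".")
      if (p == 1L) as.character(d) else c("0/0", "0/1", "1/1")[d + 1L]
    }
    pl <- unname(m$ploidy)
    rows <- vapply(seq_len(n_sites(m)), function(j) {
      gts <- vapply(seq_len(n_samples(m)),
                    function(i) gt_string(m$dosage[i, j], pl[i]), "")
      paste(c(m$sites$locus_id[j], m$sites$position[j], ".",
              m$sites$ref[j], m$sites$alt[j], ".", "PASS", ".", "GT", gts),
            collapse = "\t")
    }, "")
    writeLines(rows, con)
  }
  invisible(path)
}
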