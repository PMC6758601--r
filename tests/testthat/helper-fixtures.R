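# Shared fixture builders.  Everything is generated in code; no binary data.

# minimal VCF text for toy genotype tables: `gt` is a samples x sites matrix
# of GT strings, `chrom`/`pos`/`ref`/`alt` per site
write_toy_vcf <- function(path, gt, chrom, pos, ref, alt) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(gt)), collapse = "\t")
  )
  for (j in seq_along(pos)) {
    lines <- c(lines, paste(c(chrom[j], pos[j], ".", ref[j], alt[j], ".",
                              "PASS", ".", "GT", gt[, j]), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# haploid snp_matrix with every lineage fixed (dosage 0/1 per clade), built
# from per-site clade patterns; `patterns` is a sites x 5 matrix over {0,1}
# with columns P1, P2, P3a, P3b, O
fixed_difference_matrix <- function(patterns, n_per_clade = 2L,
                                    loci_per_site = TRUE) {
  n_sites <- nrow(patterns)
  clades <- c("P1", "P2", "P3a", "P3b", "O")
  ids <- unlist(lapply(clades, function(cl) paste0(cl, "_", seq_len(n_per_clade))))
  dos <- matrix(0L, nrow = length(ids), ncol = n_sites,
                dimnames = list(ids, NULL))
  for (k in seq_along(clades)) {
    rows <- ((k - 1L) * n_per_clade + 1L):(k * n_per_clade)
    dos[rows, ] <- matrix(rep(patterns[, k], each = n_per_clade),
                          nrow = n_per_clade, byrow = FALSE)
  }
  locus <- if (loci_per_site) sprintf("L%03d", seq_len(n_sites)) else
    rep("L001", n_sites)
  snp_matrix(dos,
             tibble::tibble(locus_id = locus, position = seq_len(n_sites),
                            ref = "A", alt = "T"),
             ploidy = 1L)
}

fixed_difference_map <- function(n_per_clade = 2L) {
  clades <- c("P1", "P2", "P3a", "P3b", "O")
  ids <- unlist(lapply(clades, function(cl) paste0(cl, "_", seq_len(n_per_clade))))
  clade_map(setNames(rep(clades, each = n_per_clade), ids), outgroup = "O")
}

fixed_difference_roles <- function() {
  role_assignment("P1", "P2", "P3a", "P3b", "O")
}

# literal per-site classifier for fixed (0/1) five-taxon patterns, the
# independent oracle for the frequency-weighted counts
classify_fixed_patterns <- function(patterns) {
  stopifnot(all(patterns %in% c(0, 1)))
  key <- apply(patterns, 1L, paste, collapse = "")
  c(ABBAA = sum(key == "01100"), BABAA = sum(key == "10100"),
    ABABA = sum(key == "01010"), BAABA = sum(key == "10010"),
    ABBBA = sum(key == "01110"), BABBA = sum(key == "10110"))
}

# quick small null-model config for pipeline-level tests
tiny_config <- function(seed, ...) {
  five_clade_config(seed = seed, n_loci = 40L, n_per_clade = 2L, ...)
}
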