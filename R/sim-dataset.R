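#' Generate a complete synthetic RAD-seq dataset
#'
#' Composes the simulation stages: multispecies-coalescent gene trees (with
#' any admixture pulses), Jukes-Cantor sequence evolution per locus, RAD-style
#' whole-locus dropout, and SNP extraction.  The returned dataset carries a
#' `truth` record with the config, per-locus retained-sample sets, and
#' (optionally) the gene trees, so downstream inferences can be checked
#' against known ground truth.  Identical configs (including seed) yield
#' byte-identical datasets.
#'
#' @param cfg a [sim_config()].
#' @param keep_gene_trees store the simulated gene trees in the truth record
#'   (default `FALSE`; they can be large).
#' @return An object of class `rad_dataset`: list with elements `alignment`
#'   (a [rad_alignment()] with locus bounds), `snp` (a [snp_matrix()]), and
#'   `truth` (config, pulses, retained matrix, seeds, optional gene trees).
#' @export
generate_dataset <- function(cfg, keep_gene_trees = FALSE) {
  gts <- simulate_gene_trees(cfg)
  L <- cfg$locus_length
  seqs <- with_seed_(stage_seed(cfg$seed, "sequences"), {
    lapply(gts, evolve_jc, L = L, mu = cfg$mu)
  })
  sample_ids <- rownames(seqs[[1L]])
  # align sample order across loci and concatenate
  mat <- do.call(cbind, lapply(seqs, function(s) s[sample_ids, , drop = FALSE]))
  bounds <- tibble(
    locus_id = sprintf("locus_%04d", seq_along(gts)),
    start = (seq_along(gts) - 1L) * L,
    end = seq_along(gts) * L
  )
  aln <- rad_alignment(mat, locus_bounds = bounds)
  ds <- structure(list(
    alignment = aln,
    snp = alignment_to_snps(aln),
    truth = list(
      config = cfg,
      pulses = cfg$pulses,
      retained = matrix(TRUE, nrow = length(sample_ids), ncol = nrow(bounds),
                        dimnames = list(sample_ids, bounds$locus_id)),
      seeds = list(master = cfg$seed,
                   gene_trees = stage_seed(cfg$seed, "gene_trees"),
                   sequences = stage_seed(cfg$seed, "sequences"),
                   dropout = stage_seed(cfg$seed, "dropout")),
      gene_trees = if (keep_gene_trees) gts
    )
  ), class = "rad_dataset")
  if (any(cfg$dropout > 0)) {
    ds <- apply_rad_missingness(ds, cfg$dropout,
                                seed = stage_seed(cfg$seed, "dropout"))
  }
  ds
}

#' @export
print.rad_dataset <- function(x, ...) {
  cat(sprintf("<rad_dataset> %d samples, %d loci, %d bp concatenated, %d SNPs\n",
              nrow(x$alignment$seqs), nrow(x$alignment$locus_bounds),
              aln_length(x$alignment), n_sites(x$snp)))
  invisible(x)
}

#' Apply RAD-style locus dropout
#'
#' Independently erases each (sample, locus) pair with its dropout
#' probability: the sample's stretch of that locus becomes all-`N` in the
#' alignment and all-missing in the SNP matrix.  Whole-locus dropout is the
#' RAD failure mode (restriction-site loss), as opposed to per-site missing
#' calls.
#'
#' @param ds a `rad_dataset`.
#' @param dropout scalar probability, or named per-clade probabilities keyed
#'   by species-tree tip label (each sample gets its clade's rate, the clade
#'   being the prefix of the sample id).
#' @param seed integer seed for the erasure draw.
#' @return The modified `rad_dataset`; its `truth$retained` matrix records
#'   which (sample, locus) pairs survived.
#' @export
apply_rad_missingness <- function(ds, dropout, seed = 1L) {
  aln <- ds$alignment
  lb <- aln$locus_bounds
  samples <- rownames(aln$seqs)
  n_s <- length(samples); n_l <- nrow(lb)
  if (is.null(names(dropout))) {
    rate <- rep_len(dropout, n_s)
  } else {
    clade <- sub("_[0-9]+$", "", samples)
    bad <- setdiff(unique(clade), names(dropout))
    assert_that_(length(bad) == 0L,
                 sprintf("no dropout rate for clade(s): %s", paste(bad, collapse = ", ")))
    rate <- unname(dropout[clade])
  }
  drop <- with_seed_(seed, {
    matrix(runif(n_s * n_l), nrow = n_s) < rate
  })
  dimnames(drop) <- list(samples, lb$locus_id)
  seqs <- aln$seqs
  for (j in seq_len(n_l)) {
    cols <- (lb$start[j] + 1L):lb$end[j]
    hit <- drop[, j]
    if (any(hit)) seqs[hit, cols] <- "N"
  }
  aln2 <- rad_alignment(seqs, locus_bounds = lb)
  ds$alignment <- aln2
  ds$snp <- alignment_to_snps(aln2)
  ds$truth$retained <- ds$truth$retained & !drop
  ds
}

#' Filter loci by minimum sample coverage
#'
#' Retains exactly the loci for which at least `min_n` samples have
#' non-missing data, the standard RAD assembly filter.  Locus coverage is
#' read from the alignment (a sample covers a locus when any of its columns
#' there is a called base).
#'
#' @param ds a `rad_dataset`.
#' @param min_n minimum number of covering samples per locus.
#' @return The filtered `rad_dataset`.
#' @seealso [rad_summary()] for the locus/length/SNP summary table.
#' @export
filter_min_samples <- function(ds, min_n) {
  assert_that_(min_n >= 0, "min_n must be >= 0")
  cov <- locus_coverage(ds$alignment)
  keep <- colSums(cov) >= min_n
  lb <- ds$alignment$locus_bounds[keep, , drop = FALSE]
  cols <- unlist(mapply(function(s, e) (s + 1L):e, lb$start, lb$end,
                        SIMPLIFY = FALSE))
  seqs <- ds$alignment$seqs[, cols, drop = FALSE]
  len <- lb$end - lb$start
  lb2 <- tibble(locus_id = lb$locus_id,
                start = cumsum(c(0L, head(len, -1L))),
                end = cumsum(len))
  ds$alignment <- rad_alignment(seqs, locus_bounds = lb2)
  ds$snp <- subset_sites(ds$snp, ds$snp$sites$locus_id %in% lb$locus_id)
  ds$truth$retained <- ds$truth$retained[, keep, drop = FALSE]
  ds
}

# samples x loci logical coverage matrix
locus_coverage <- function(aln) {
  lb <- aln$locus_bounds
  assert_that_(!is.null(lb), "alignment has no locus bounds")
  vapply(seq_len(nrow(lb)), function(j) {
    cols <- (lb$start[j] + 1L):lb$end[j]
    rowSums(aln$seqs[, cols, drop = FALSE] != "N") > 0L
  }, logical(nrow(aln$seqs)))
}

#' Locus / length / SNP summary of a dataset
#'
#' The per-dataset bookkeeping reported for RAD filter cascades: number of
#' retained loci, concatenated alignment length, and number of biallelic
#' SNPs.
#'
#' @param ds a `rad_dataset`.
#' @return A one-row tibble with `n_loci`, `concat_length`, `n_snps`.
#' @export
rad_summary <- function(ds) {
  tibble(n_loci = nrow(ds$alignment$locus_bounds),
         concat_length = aln_length(ds$alignment),
         n_snps = n_sites(ds$snp))
}

#' Filter-cascade summary over several thresholds
#'
#' Applies [filter_min_samples()] at each threshold and tabulates the
#' summaries, emulating a min-samples filter series.
#'
#' @param ds a `rad_dataset`.
#' @param thresholds integer vector of `min_n` values.
#' @return A tibble with one row per threshold.
#' @export
filter_cascade <- function(ds, thresholds) {
  purrr::map_dfr(thresholds, function(m) {
    dplyr::bind_cols(tibble(min_n = m), rad_summary(filter_min_samples(ds, m)))
  })
}
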