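#' SNP matrix container
#'
#' A `snp_matrix` holds biallelic single-nucleotide variants as an integer
#' dosage matrix (samples in rows, sites in columns) together with per-site
#' records and per-sample ploidy.  Dosage counts copies of the alternate
#' allele: `{0, 1}` for haploids, `{0, 1, 2}` for diploids, `NA` for missing.
#' Every site carries a `locus_id`; sites of a locus occupy contiguous
#' columns, mirroring the structure of assembled RAD loci.
#'
#' @param dosage integer matrix, samples x sites, rownames are sample ids,
#'   `NA` marks missing genotypes.
#' @param sites data frame with one row per site and columns `locus_id`,
#'   `position` (1-based within its source), `ref`, `alt`.
#' @param ploidy integer vector (1 or 2), one per sample; recycled if
#'   length 1.
#'
#' @return An object of class `snp_matrix`.
#' @export
snp_matrix <- function(dosage, sites, ploidy = 1L) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage))) abort("`dosage` must have sample ids as rownames")
  sites <- as_tibble(sites)
  needed <- c("locus_id", "position", "ref", "alt")
  assert_that_(all(needed %in% names(sites)),
               "`sites` needs columns locus_id, position, ref, alt")
  assert_that_(nrow(sites) == ncol(dosage),
               "one site record per dosage column required")
  ploidy <- rep_len(as.integer(ploidy), nrow(dosage))
  assert_that_(all(ploidy %in% c(1L, 2L)), "ploidy must be 1 or 2")
  bad <- sweep(dosage, 1L, ploidy, ">")
  assert_that_(!any(bad, na.rm = TRUE), "dosage exceeds ploidy")
  # loci must label contiguous runs of columns
  if (nrow(sites) > 0L) {
    r <- rle(as.character(sites$locus_id))
    assert_that_(!anyDuplicated(r$values),
                 "sites of one locus_id must be contiguous")
  }
  structure(
    list(dosage = dosage, sites = sites, ploidy = setNames(ploidy, rownames(dosage))),
    class = "snp_matrix"
  )
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf(
    "<snp_matrix> %d samples x %d biallelic sites (%d loci, %.1f%% missing)\n",
    n_samples(x), n_sites(x), n_loci(x),
    100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' @rdname snp_matrix
#' @param x a `snp_matrix`.
#' @export
n_samples <- function(x) nrow(x$dosage)

#' @rdname snp_matrix
#' @export
n_sites <- function(x) ncol(x$dosage)

#' @rdname snp_matrix
#' @export
n_loci <- function(x) length(unique(x$sites$locus_id))

#' @rdname snp_matrix
#' @export
sample_ids <- function(x) rownames(x$dosage)

#' Tidy a SNP matrix into long format
#'
#' One row per (sample, site) genotype call, suitable for dplyr workflows.
#'
#' @param x a [snp_matrix()].
#' @param ... unused.
#' @return A tibble with columns `sample_id`, `locus_id`, `position`,
#'   `ref`, `alt`, `dosage`, `ploidy`.
#' @method tidy snp_matrix
#' @export
tidy.snp_matrix <- function(x, ...) {
  if (n_sites(x) == 0L) {
    return(tibble(sample_id = character(), locus_id = character(),
                  position = integer(), ref = character(), alt = character(),
                  dosage = integer(), ploidy = integer()))
  }
  tibble(
    sample_id = rep(sample_ids(x), times = n_sites(x)),
    locus_id = rep(x$sites$locus_id, each = n_samples(x)),
    position = rep(x$sites$position, each = n_samples(x)),
    ref = rep(x$sites$ref, each = n_samples(x)),
    alt = rep(x$sites$alt, each = n_samples(x)),
    dosage = as.integer(x$dosage),
    ploidy = rep(unname(x$ploidy), times = n_sites(x))
  )
}

#' @method glance snp_matrix
#' @export
glance.snp_matrix <- function(x, ...) {
  tibble(
    n_samples = n_samples(x), n_sites = n_sites(x), n_loci = n_loci(x),
    prop_missing = mean(is.na(x$dosage))
  )
}

# subset sites (logical or integer index over columns), keeping structure
subset_sites <- function(x, idx) {
  snp_matrix(x$dosage[, idx, drop = FALSE], x$sites[idx, , drop = FALSE],
             unname(x$ploidy))
}
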