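#' Role assignment for the five-taxon D test
#'
#' Assigns clades to the five roles of the symmetric topology
#' `(((P1, P2), (P3a, P3b)), O)`.  `P1`/`P2` are the putative recipients,
#' `P3a`/`P3b` the two sub-lineages of the putative donor, and `O` the
#' outgroup, which may pool several clades.  Roles must be disjoint.
#'
#' @param P1,P2,P3a,P3b character: one clade id each.
#' @param O character vector: one or more outgroup clade ids.
#' @return An object of class `role_assignment` (named list of clade id
#'   vectors).
#' @export
role_assignment <- function(P1, P2, P3a, P3b, O) {
  roles <- list(P1 = P1, P2 = P2, P3a = P3a, P3b = P3b, O = O)
  assert_that_(all(lengths(roles[1:4]) == 1L),
               "P1, P2, P3a, P3b take exactly one clade each")
  assert_that_(length(O) >= 1L, "O needs at least one clade")
  all_cl <- unlist(roles)
  assert_that_(!anyDuplicated(all_cl), "roles must be disjoint")
  structure(roles, class = "role_assignment")
}

#' @export
print.role_assignment <- function(x, ...) {
  cat(format_config_label(x), "\n")
  invisible(x)
}

format_config_label <- function(roles) {
  sprintf("((%s, %s), (%s, %s), %s)",
          roles$P1, roles$P2, roles$P3a, roles$P3b,
          paste(roles$O, collapse = "&"))
}

#' Pooled per-site allele frequencies for each D-test role
#'
#' Pools the samples of each role's clade(s) into one population and computes
#' the per-site alternate-allele frequency from non-missing dosages.  A
#' site is *usable* only if, at its locus, every clade involved in the test
#' retains at least `min_clade_cov` of its samples (the locus-coverage rule;
#' default one third), and every role has at least one called genotype at
#' the site.
#'
#' @param m a [snp_matrix()].
#' @param map a [clade_map()] covering every sample in `m`.
#' @param roles a [role_assignment()].
#' @param min_clade_cov minimum fraction of a clade's samples that must cover
#'   a locus (default 1/3).
#' @return A tibble of class `site_freqs` with one row per site: `locus_id`,
#'   `site`, frequencies `p1, p2, p3a, p3b, pO`, and `usable`.  Frequencies
#'   are of the alternate allele until [polarize()] re-orients them to the
#'   derived allele.
#' @export
lineage_frequencies <- function(m, map, roles, min_clade_cov = 1 / 3) {
  unmapped <- setdiff(sample_ids(m), map$assignment$sample_id)
  assert_that_(length(unmapped) == 0L,
               sprintf("samples absent from clade map: %s",
                       paste(head(unmapped, 5L), collapse = ", ")))
  clades <- unique(unlist(roles))
  idx_of <- lapply(setNames(clades, clades), function(cl) {
    idx <- which(sample_ids(m) %in% samples_in_clade(map, cl))
    if (length(idx) == 0L) abort(sprintf("clade '%s' has no samples in the matrix", cl))
    idx
  })
  d <- m$dosage
  called <- !is.na(d)
  # locus-level coverage per clade: a sample covers a locus when it has >= 1
  # called site there
  loci <- unique(m$sites$locus_id)
  site_locus <- match(m$sites$locus_id, loci)
  locus_ok <- rep(TRUE, length(loci))
  for (cl in clades) {
    idx <- idx_of[[cl]]
    cov <- vapply(seq_along(loci), function(l) {
      cols <- which(site_locus == l)
      mean(rowSums(called[idx, cols, drop = FALSE]) > 0L)
    }, numeric(1L))
    locus_ok <- locus_ok & cov >= min_clade_cov
  }
  freq_role <- function(cl_set) {
    idx <- unlist(idx_of[cl_set], use.names = FALSE)
    dd <- d[idx, , drop = FALSE]
    cc <- called[idx, , drop = FALSE]
    num <- colSums(dd, na.rm = TRUE)
    den <- colSums(cc * m$ploidy[idx])
    ifelse(den > 0, num / den, NA_real_)
  }
  fr <- tibble(
    locus_id = m$sites$locus_id,
    site = seq_len(n_sites(m)),
    p1 = freq_role(roles$P1), p2 = freq_role(roles$P2),
    p3a = freq_role(roles$P3a), p3b = freq_role(roles$P3b),
    pO = freq_role(roles$O)
  )
  fr$usable <- locus_ok[site_locus] &
    !is.na(fr$p1) & !is.na(fr$p2) & !is.na(fr$p3a) & !is.na(fr$p3b) & !is.na(fr$pO)
  attr(fr, "polarized") <- FALSE
  attr(fr, "roles") <- roles
  attr(fr, "min_clade_cov") <- min_clade_cov
  class(fr) <- c("site_freqs", class(fr))
  fr
}

#' Polarize site frequencies by the outgroup
#'
#' Re-orients every site so that the outgroup's minor allele is the derived
#' allele (`B`): wherever the pooled outgroup frequency exceeds 0.5, all five
#' frequencies are flipped to their complements, leaving `pO <= 0.5`.
#' Residual outgroup polymorphism is down-weighted downstream by the
#' `(1 - pO)` factor in the pattern weights.  Exact ties (`pO == 0.5`) leave
#' the site unusable: the outgroup carries no orientation information there.
#'
#' @param freqs a `site_freqs` tibble from [lineage_frequencies()].
#' @return The polarized `site_freqs`.
#' @export
polarize <- function(freqs) {
  assert_that_(inherits(freqs, "site_freqs"), "need a site_freqs object")
  flip <- !is.na(freqs$pO) & freqs$pO > 0.5
  tie <- !is.na(freqs$pO) & freqs$pO == 0.5
  for (col in c("p1", "p2", "p3a", "p3b", "pO")) {
    freqs[[col]][flip] <- 1 - freqs[[col]][flip]
  }
  freqs$usable <- freqs$usable & !tie
  attr(freqs, "polarized") <- TRUE
  freqs
}

#' Frequency-weighted five-taxon site-pattern counts
#'
#' For each usable, polarized site with derived-allele frequencies
#' `(p1, p2, p3a, p3b, pO)`, accumulates the probability weight of each of
#' the six discordant five-taxon patterns:
#' \deqn{w_{ABBAA} = (1-p_1) p_2 p_{3a} (1-p_{3b}) (1-p_O)}
#' and analogously for BABAA, ABABA, BAABA, ABBBA, BABBA.  When every
#' lineage is fixed (frequencies 0 or 1) these weights reduce to the literal
#' 0/1 pattern tally; with polymorphic lineages the totals are fractional.
#'
#' @param freqs a polarized `site_freqs`.
#' @param snps `"all"` (default) accumulates every usable SNP per locus;
#'   `"one_per_locus"` keeps only the first usable SNP of each locus,
#'   trading information for strict between-site independence.
#' @return A tibble of class `pattern_counts` with one row per locus that has
#'   usable sites: six weight columns plus `n_sites`.  Attributes
#'   `n_sites_used` and `n_loci_used` carry the bookkeeping totals; grand
#'   totals via [pattern_totals()].
#' @export
pattern_counts <- function(freqs, snps = c("all", "one_per_locus")) {
  assert_that_(isTRUE(attr(freqs, "polarized")),
               "frequencies must be polarized first (see polarize())")
  snps <- match.arg(snps)
  u <- freqs[freqs$usable, , drop = FALSE]
  if (snps == "one_per_locus" && nrow(u) > 0L) {
    u <- u[!duplicated(u$locus_id), , drop = FALSE]
  }
  w <- with(u, tibble(
    locus_id = locus_id,
    ABBAA = (1 - p1) * p2 * p3a * (1 - p3b) * (1 - pO),
    BABAA = p1 * (1 - p2) * p3a * (1 - p3b) * (1 - pO),
    ABABA = (1 - p1) * p2 * (1 - p3a) * p3b * (1 - pO),
    BAABA = p1 * (1 - p2) * (1 - p3a) * p3b * (1 - pO),
    ABBBA = (1 - p1) * p2 * p3a * p3b * (1 - pO),
    BABBA = p1 * (1 - p2) * p3a * p3b * (1 - pO)
  ))
  out <- w |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(dplyr::across(ABBAA:BABBA, sum), n_sites = dplyr::n(),
                     .groups = "drop")
  attr(out, "n_sites_used") <- nrow(u)
  attr(out, "n_loci_used") <- nrow(out)
  class(out) <- c("pattern_counts", class(out))
  out
}

#' @rdname pattern_counts
#' @param counts a `pattern_counts` tibble.
#' @return `pattern_totals()` returns a named numeric vector of the six
#'   grand totals plus `n_sites_used` and `n_loci_used`.
#' @export
pattern_totals <- function(counts) {
  pats <- c("ABBAA", "BABAA", "ABABA", "BAABA", "ABBBA", "BABBA")
  tot <- vapply(pats, function(p) sum(counts[[p]]), numeric(1L))
  c(tot,
    n_sites_used = as.numeric(attr(counts, "n_sites_used") %||% sum(counts$n_sites)),
    n_loci_used = as.numeric(attr(counts, "n_loci_used") %||% nrow(counts)))
}
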