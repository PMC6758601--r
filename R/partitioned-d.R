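#' Partitioned D-statistics from pattern totals
#'
#' Each statistic is the normalized difference of two frequency-weighted
#' pattern totals:
#' \deqn{D_1 = \frac{n_{ABBAA} - n_{BABAA}}{n_{ABBAA} + n_{BABAA}}, \quad
#'       D_2 = \frac{n_{ABABA} - n_{BAABA}}{n_{ABABA} + n_{BAABA}}, \quad
#'       D_{12} = \frac{n_{ABBBA} - n_{BABBA}}{n_{ABBBA} + n_{BABBA}}.}
#' `D1` attributes introgression signal to the `P3a` sub-lineage, `D2` to
#' `P3b`, and `D12` to their common ancestor; positive values implicate `P2`
#' as the partner, negative values `P1`.  A statistic whose denominator is
#' zero is reported as 0 with its `zero_denom` flag set, keeping result
#' tables total.
#'
#' @param counts a [pattern_counts()] tibble, or a named numeric vector with
#'   elements `ABBAA`, `BABAA`, `ABABA`, `BAABA`, `ABBBA`, `BABBA`.
#' @return A one-row tibble: `D1`, `D2`, `D12` and logical
#'   `zero_denom_D1/D2/D12`.
#' @export
compute_d <- function(counts) {
  if (inherits(counts, "pattern_counts")) counts <- pattern_totals(counts)
  pats <- c("ABBAA", "BABAA", "ABABA", "BAABA", "ABBBA", "BABBA")
  assert_that_(all(pats %in% names(counts)),
               sprintf("counts must be named with %s", paste(pats, collapse = ", ")))
  x <- as.numeric(counts[pats])
  assert_that_(all(is.finite(x)), "pattern totals must be finite")
  assert_that_(all(x >= 0), "pattern totals must be non-negative")
  ratio <- function(a, b) {
    if (a + b == 0) list(d = 0, zero = TRUE) else list(d = (a - b) / (a + b), zero = FALSE)
  }
  d1 <- ratio(x[1L], x[2L]); d2 <- ratio(x[3L], x[4L]); d12 <- ratio(x[5L], x[6L])
  tibble(D1 = d1$d, D2 = d2$d, D12 = d12$d,
         zero_denom_D1 = d1$zero, zero_denom_D2 = d2$zero,
         zero_denom_D12 = d12$zero)
}

#' Bootstrap settings for D-statistic significance
#'
#' Significance is assessed by a nonparametric bootstrap over loci (the
#' resampling unit): loci are resampled with replacement, the pattern totals
#' and D recomputed per replicate, and `Z = |D_observed| / SD(D_replicates)`.
#'
#' @param n_replicates bootstrap replicates (default 1000).
#' @param z_threshold significance threshold on Z (default 2.55).
#' @param seed integer seed.
#' @return An object of class `bootstrap_spec`.
#' @export
bootstrap_spec <- function(n_replicates = 1000L, z_threshold = 2.55, seed = 1L) {
  assert_that_(n_replicates >= 1L, "n_replicates must be >= 1")
  structure(list(n_replicates = as.integer(n_replicates),
                 z_threshold = z_threshold, seed = as.integer(seed)),
            class = "bootstrap_spec")
}

#' Locus-bootstrap Z-scores for the partitioned D-statistics
#'
#' Resamples loci with replacement `n_replicates` times and recomputes each D
#' from the resampled per-locus pattern totals (numerically identical to
#' re-running the whole site-pattern pipeline on the resampled loci, since
#' the totals are sums over sites and usability is decided per locus).
#' `Z = |D_obs| / SD(D_boot)`; when the bootstrap SD is exactly 0 the Z is
#' reported as `Inf` with a degeneracy flag.  Deterministic for a fixed seed.
#'
#' @param counts a [pattern_counts()] per-locus tibble with at least 2 loci.
#' @param spec a [bootstrap_spec()].
#' @return A one-row tibble: `Z1`, `Z2`, `Z12`, bootstrap SDs, and
#'   `degenerate_Z1/Z2/Z12` flags.
#' @export
bootstrap_z <- function(counts, spec = bootstrap_spec()) {
  n_loci <- nrow(counts)
  if (n_loci < 2L) abort("bootstrap needs at least 2 usable loci")
  pats <- c("ABBAA", "BABAA", "ABABA", "BAABA", "ABBBA", "BABBA")
  mat <- as.matrix(counts[, pats])
  obs <- compute_d(pattern_totals(counts))
  reps <- with_seed_(spec$seed, {
    vapply(seq_len(spec$n_replicates), function(r) {
      tot <- colSums(mat[sample.int(n_loci, n_loci, replace = TRUE), ,
                         drop = FALSE])
      d <- compute_d(tot)
      c(d$D1, d$D2, d$D12)
    }, numeric(3L))
  })
  sds <- apply(reps, 1L, sd)
  z <- ifelse(sds == 0, Inf, abs(c(obs$D1, obs$D2, obs$D12)) / sds)
  tibble(Z1 = z[1L], Z2 = z[2L], Z12 = z[3L],
         sd_D1 = sds[1L], sd_D2 = sds[2L], sd_D12 = sds[3L],
         degenerate_Z1 = sds[1L] == 0, degenerate_Z2 = sds[2L] == 0,
         degenerate_Z12 = sds[3L] == 0)
}

#' Enumerate clade-role configurations compatible with a species tree
#'
#' Finds every assignment of clades to the five D-test roles that obeys the
#' symmetric topology: `{P1, P2}` a sister pair of clades in the tree,
#' `{P3a, P3b}` another sister pair, the two pairs themselves sisters, and
#' everything else (plus the declared outgroup clades) pooled into `O`.
#' Both within-pair orders and the pair-role swap are enumerated, giving 8
#' assignments per balanced quartet of clades; `canonical = TRUE` collapses
#' sign/swap-equivalent rows to 4.
#'
#' @param tree an [ape::phylo] whose tips are clade ids, or a Newick string.
#' @param outgroup_clades clade ids always pooled into the `O` role (they
#'   need not be tips of `tree`).
#' @param canonical collapse within-pair order swaps of `(P1, P2)`.
#' @return A list of [role_assignment()] objects; empty (with a warning)
#'   when the tree contains no symmetric quartet.
#' @export
enumerate_configurations <- function(tree, outgroup_clades, canonical = FALSE) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  ntip <- ape::Ntip(tree)
  cherries <- function(tr) {
    # internal nodes whose two children are both tips
    int <- unique(tr$edge[, 1L])
    Filter(function(v) {
      ch <- tr$edge[tr$edge[, 1L] == v, 2L]
      length(ch) == 2L && all(ch <= ntip)
    }, int)
  }
  out <- list()
  for (v in cherries(tree)) {
    # sister of v must itself be a cherry
    par <- tree$edge[tree$edge[, 2L] == v, 1L]
    if (length(par) != 1L) next
    sibs <- setdiff(tree$edge[tree$edge[, 1L] == par, 2L], v)
    for (w in sibs) {
      if (w <= ntip || w <= v) next
      chw <- tree$edge[tree$edge[, 1L] == w, 2L]
      if (length(chw) != 2L || !all(chw <= ntip)) next
      pair1 <- tree$tip.label[tree$edge[tree$edge[, 1L] == v, 2L]]
      pair2 <- tree$tip.label[chw]
      rest <- setdiff(tree$tip.label, c(pair1, pair2))
      O <- unique(c(rest, outgroup_clades))
      if (length(O) == 0L) next
      for (pp in list(list(pair1, pair2), list(pair2, pair1))) {
        p12 <- pp[[1L]]; p34 <- pp[[2L]]
        orders12 <- if (canonical) list(p12) else list(p12, rev(p12))
        for (o12 in orders12) {
          for (o34 in list(p34, rev(p34))) {
            out[[length(out) + 1L]] <- role_assignment(
              P1 = o12[1L], P2 = o12[2L], P3a = o34[1L], P3b = o34[2L], O = O)
          }
        }
      }
    }
  }
  if (length(out) == 0L) {
    warn("no symmetric quartet of clades in the tree; nothing to test")
  }
  out
}

#' Run the full partitioned D analysis
#'
#' For every clade-role configuration compatible with the clade tree, pools
#' allele frequencies, polarizes by the outgroup, accumulates the six
#' discordant pattern weights, computes `D1`, `D2`, `D12`, and attaches
#' locus-bootstrap Z-scores and significance flags.
#'
#' @param m a [snp_matrix()].
#' @param map a [clade_map()].
#' @param tree clade-level species tree ([ape::phylo] or Newick string) whose
#'   tips are clade ids; non-quartet clades and `map$outgroup` pool into `O`.
#' @param spec a [bootstrap_spec()].
#' @param min_clade_cov locus-coverage rule (default 1/3).
#' @param snps `"all"` or `"one_per_locus"`, see [pattern_counts()].
#' @param canonical collapse sign-equivalent configurations.
#' @return A tibble of class `d_table`, one row per configuration, shaped
#'   like a partitioned-D result table: `config`, `D12`, `Z12`, `D1`, `Z1`,
#'   `D2`, `Z2`, significance flags, the six weighted pattern totals,
#'   `n_sites`, `n_loci`.
#' @export
run_partitioned_tests <- function(m, map, tree, spec = bootstrap_spec(),
                                  min_clade_cov = 1 / 3,
                                  snps = "all", canonical = FALSE) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  ingroup_tree <- tree
  # drop declared outgroup clades from the tree before looking for the quartet
  og_tips <- intersect(map$outgroup, tree$tip.label)
  if (length(og_tips) > 0L && length(og_tips) < ape::Ntip(tree)) {
    keep <- setdiff(tree$tip.label, og_tips)
    if (length(keep) >= 4L) {
      ingroup_tree <- ape::keep.tip(tree, keep)
    }
  }
  configs <- enumerate_configurations(ingroup_tree, map$outgroup,
                                      canonical = canonical)
  rows <- purrr::imap(configs, function(roles, i) {
    fr <- polarize(lineage_frequencies(m, map, roles,
                                       min_clade_cov = min_clade_cov))
    pc <- pattern_counts(fr, snps = snps)
    tot <- pattern_totals(pc)
    d <- compute_d(tot)
    z <- bootstrap_z(pc, bootstrap_spec(spec$n_replicates, spec$z_threshold,
                                        seed = stage_seed(spec$seed, "bootstrap", i)))
    dplyr::bind_cols(
      tibble(config = format_config_label(roles)),
      d[, c("D12", "D1", "D2")], z[, c("Z12", "Z1", "Z2")],
      tibble(
        sig_D12 = z$Z12 >= spec$z_threshold,
        sig_D1 = z$Z1 >= spec$z_threshold,
        sig_D2 = z$Z2 >= spec$z_threshold,
        n_ABBBA = tot[["ABBBA"]], n_BABBA = tot[["BABBA"]],
        n_ABBAA = tot[["ABBAA"]], n_BABAA = tot[["BABAA"]],
        n_ABABA = tot[["ABABA"]], n_BAABA = tot[["BAABA"]],
        n_sites = tot[["n_sites_used"]], n_loci = tot[["n_loci_used"]]
      )
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "z_threshold") <- spec$z_threshold
  attr(out, "roles") <- configs
  class(out) <- c("d_table", class(out))
  out
}

#' Interpret partitioned D signs as donor/recipient statements
#'
#' Positive `D1` indicates introgression between `P2` and `P3a`, negative
#' between `P1` and `P3a`; `D2` reads the same way for `P3b`, and `D12` for
#' the common ancestor of `P3a` and `P3b`.  Only significant statistics are
#' interpreted.  Note that D tests over nested configurations are not
#' phylogenetically independent; interpret overlapping signals cautiously.
#'
#' @param d a `d_table` from [run_partitioned_tests()].
#' @return A tibble with `config`, `statistic`, and `interpretation`.
#' @export
interpret_d <- function(d) {
  roles <- attr(d, "roles")
  purrr::imap_dfr(roles, function(r, i) {
    row <- d[i, ]
    one <- function(stat, val, sig, donor) {
      if (!sig) return(NULL)
      partner <- if (val >= 0) r$P2 else r$P1
      tibble(config = row$config, statistic = stat,
             interpretation = sprintf("introgression between %s and %s",
                                      partner, donor))
    }
    dplyr::bind_rows(
      one("D1", row$D1, row$sig_D1, r$P3a),
      one("D2", row$D2, row$sig_D2, r$P3b),
      one("D12", row$D12, row$sig_D12,
          sprintf("the ancestor of (%s, %s)", r$P3a, r$P3b))
    )
  })
}

#' @method glance d_table
#' @export
glance.d_table <- function(x, ...) {
  tibble(n_configs = nrow(x),
         n_sig_D1 = sum(x$sig_D1), n_sig_D2 = sum(x$sig_D2),
         n_sig_D12 = sum(x$sig_D12),
         z_threshold = attr(x, "z_threshold") %||% NA_real_)
}

#' @method tidy d_table
#' @export
tidy.d_table <- function(x, ...) {
  x |>
    tidyr::pivot_longer(c("D12", "D1", "D2"), names_to = "statistic",
                        values_to = "estimate") |>
    dplyr::mutate(
      z = dplyr::case_when(statistic == "D1" ~ .data$Z1,
                           statistic == "D2" ~ .data$Z2,
                           TRUE ~ .data$Z12),
      significant = dplyr::case_when(statistic == "D1" ~ .data$sig_D1,
                                     statistic == "D2" ~ .data$sig_D2,
                                     TRUE ~ .data$sig_D12)
    ) |>
    dplyr::select("config", "statistic", "estimate", "z", "significant")
}

#' Write a partitioned-D result table as TSV
#'
#' @param d a `d_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_d_table <- function(d, path) {
  write.table(as.data.frame(d), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @method autoplot d_table
#' @export
autoplot.d_table <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$config,
                                   colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~statistic, nrow = 1) +
    ggplot2::labs(x = "partitioned D", y = NULL, colour = "significant") +
    ggplot2::theme_minimal()
}
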