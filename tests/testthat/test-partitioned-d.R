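test_that("compute_d reproduces published worked examples from count pairs", {
  # internally consistent count -> value pairs from the clade I-IV analysis
  pairs <- list(
    list(a = 809.84, b = 778.10, d = 0.020),
    list(a = 1273.58, b = 1115.49, d = 0.066),
    list(a = 505.48, b = 286.73, d = 0.276),
    list(a = 271.16, b = 444.45, d = -0.242),
    list(a = 403.07, b = 222.05, d = 0.290)
  )
  for (p in pairs) {
    counts <- c(ABBAA = p$a, BABAA = p$b, ABABA = p$a, BAABA = p$b,
                ABBBA = p$a, BABBA = p$b)
    d <- compute_d(counts)
    expect_equal(round(d$D1, 3), p$d)
    expect_equal(round(d$D2, 3), p$d)
    expect_equal(round(d$D12, 3), p$d)
  }
})

test_that("compute_d handles boundaries and degenerate denominators", {
  eq <- compute_d(c(ABBAA = 3, BABAA = 3, ABABA = 3, BAABA = 3,
                    ABBBA = 3, BABBA = 3))
  expect_equal(c(eq$D1, eq$D2, eq$D12), c(0, 0, 0))
  expect_false(any(c(eq$zero_denom_D1, eq$zero_denom_D2, eq$zero_denom_D12)))
  b <- compute_d(c(ABBAA = 2, BABAA = 0, ABABA = 0, BAABA = 0,
                   ABBBA = 1, BABBA = 1))
  expect_equal(b$D1, 1)
  expect_equal(b$D2, 0)
  expect_true(b$zero_denom_D2)
  expect_error(compute_d(c(ABBAA = -1, BABAA = 0, ABABA = 0, BAABA = 0,
                           ABBBA = 0, BABBA = 0)), "non-negative")
})

test_that("D is associative over merged pattern counts", {
  set.seed(3)
  pat1 <- matrix(rbinom(40 * 5, 1L, 0.5), ncol = 5L)
  pat2 <- matrix(rbinom(25 * 5, 1L, 0.5), ncol = 5L)
  tot <- function(pat) {
    m <- fixed_difference_matrix(pat)
    pattern_totals(pattern_counts(polarize(lineage_frequencies(
      m, fixed_difference_map(), fixed_difference_roles()))))
  }
  t1 <- tot(pat1); t2 <- tot(pat2); t12 <- tot(rbind(pat1, pat2))
  expect_equal(t12[1:6], t1[1:6] + t2[1:6])
  expect_equal(compute_d(t12), compute_d(t1[1:6] + t2[1:6]))
})

test_that("exchanging roles transforms D as the definitions require", {
  cfg <- five_clade_config(seed = 31L, n_loci = 150L, n_per_clade = 3L)
  ds <- generate_dataset(cfg)
  map <- sim_clade_map(cfg)
  d_for <- function(roles) {
    compute_d(pattern_counts(polarize(lineage_frequencies(ds$snp, map, roles))))
  }
  base <- d_for(role_assignment("I", "II", "III", "IV", c("V", "OG")))
  swapped <- d_for(role_assignment("II", "I", "III", "IV", c("V", "OG")))
  expect_equal(swapped$D1, -base$D1)
  expect_equal(swapped$D2, -base$D2)
  expect_equal(swapped$D12, -base$D12)
  p3swap <- d_for(role_assignment("I", "II", "IV", "III", c("V", "OG")))
  expect_equal(p3swap$D1, base$D2)
  expect_equal(p3swap$D2, base$D1)
  expect_equal(p3swap$D12, base$D12)
  expect_true(all(abs(c(base$D1, base$D2, base$D12)) <= 1))
})

test_that("bootstrap Z is deterministic, bounded and flags degeneracy", {
  cfg <- tiny_config(seed = 17L)
  ds <- generate_dataset(cfg)
  map <- sim_clade_map(cfg)
  roles <- role_assignment("I", "II", "III", "IV", c("V", "OG"))
  pc <- pattern_counts(polarize(lineage_frequencies(ds$snp, map, roles)))
  z1 <- bootstrap_z(pc, bootstrap_spec(200, seed = 5))
  z2 <- bootstrap_z(pc, bootstrap_spec(200, seed = 5))
  expect_identical(z1, z2)
  z3 <- bootstrap_z(pc, bootstrap_spec(200, seed = 6))
  expect_false(identical(z1$sd_D12, z3$sd_D12))

  # duplicated identical loci: every resample gives the same D -> SD 0
  dup <- pc[rep(1L, 5L), ]
  attr(dup, "n_sites_used") <- attr(pc, "n_sites_used")
  class(dup) <- class(pc)
  zd <- bootstrap_z(dup, bootstrap_spec(50, seed = 1))
  expect_true(zd$degenerate_Z1 || zd$Z1 == Inf)

  expect_error(bootstrap_z(pc[1L, ], bootstrap_spec(10, seed = 1)),
               "at least 2")
})

test_that("configuration enumeration matches the exhaustive predicate", {
  tree <- "(((I,II),(III,IV)),V);"
  configs <- enumerate_configurations(tree, c("V", "OG"))
  expect_length(configs, 8L)
  labels <- vapply(configs, format_config_label, "")
  expect_true("((I, II), (III, IV), V&OG)" %in% labels)
  expect_true("((IV, III), (I, II), V&OG)" %in% labels)
  expect_length(enumerate_configurations(tree, c("V", "OG"),
                                         canonical = TRUE), 4L)

  # exhaustive oracle: all ordered assignments of the 4 quartet clades to
  # (P1,P2,P3a,P3b), filtered by the sister-pair predicate on the tree
  tr <- ape::read.tree(text = tree)
  is_sister_pair <- function(x, y) {
    mrca <- ape::getMRCA(tr, c(x, y))
    setequal(ape::extract.clade(tr, mrca)$tip.label, c(x, y))
  }
  perms <- gtools_permutations <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  valid <- Filter(function(p) {
    is_sister_pair(p[1L], p[2L]) && is_sister_pair(p[3L], p[4L])
  }, perms(c("I", "II", "III", "IV")))
  oracle_labels <- vapply(valid, function(p)
    format_config_label(role_assignment(p[1L], p[2L], p[3L], p[4L],
                                        c("V", "OG"))), "")
  expect_setequal(labels, oracle_labels)

  expect_warning(out <- enumerate_configurations("((((I,II),III),IV),V);",
                                                 "V"), "no symmetric")
  expect_length(out, 0L)
})

test_that("the full test table has the expected shape and symmetries", {
  cfg <- five_clade_config(seed = 23L, n_loci = 120L, n_per_clade = 3L)
  ds <- generate_dataset(cfg)
  map <- sim_clade_map(cfg)
  d <- run_partitioned_tests(ds$snp, map, "(((I,II),(III,IV)),V);",
                             spec = bootstrap_spec(100, seed = 2))
  expect_s3_class(d, "d_table")
  expect_equal(nrow(d), 8L)
  expect_true(all(c("config", "D12", "Z12", "D1", "Z1", "D2", "Z2",
                    "n_ABBAA", "n_BABAA", "n_loci") %in% names(d)))
  i <- match("((I, II), (III, IV), V&OG)", d$config)
  j <- match("((II, I), (III, IV), V&OG)", d$config)
  expect_equal(d$D1[i], -d$D1[j])
  expect_equal(d$D12[i], -d$D12[j])
  expect_true(all(abs(c(d$D1, d$D2, d$D12)) <= 1))
  # tidy/glance accessors
  td <- tidy(d)
  expect_equal(nrow(td), 24L)
  expect_equal(glance(d)$n_configs, 8L)
})

test_that("interpretation maps signs to donor/recipient statements", {
  d <- tibble::tibble(config = "((I, II), (III, IV), V&OG)",
                      D1 = 0.3, D2 = -0.2, D12 = 0.1,
                      sig_D1 = TRUE, sig_D2 = TRUE, sig_D12 = FALSE)
  attr(d, "roles") <- list(role_assignment("I", "II", "III", "IV",
                                           c("V", "OG")))
  class(d) <- c("d_table", class(d))
  out <- interpret_d(d)
  expect_equal(nrow(out), 2L)
  expect_match(out$interpretation[out$statistic == "D1"],
               "between II and III")
  expect_match(out$interpretation[out$statistic == "D2"],
               "between I and IV")
})
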