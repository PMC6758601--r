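complete_alignment <- function(seqs) rad_alignment(seqs)

test_that("branch partitions cover the leaves disjointly", {
  tr <- ape::read.tree(text = "((a,b),(c,d),o);")
  ie <- which(tr$edge[, 1L] > ape::Ntip(tr) & tr$edge[, 2L] > ape::Ntip(tr))
  expect_length(ie, 2L)
  parts <- branch_partitions(tr, ie[1L])
  expect_length(parts, 4L)
  expect_setequal(unlist(parts), tr$tip.label)
  expect_equal(sum(lengths(parts)), 5L)

  # balanced 8-leaf tree: central branch gives four subsets of two
  tr8 <- ape::unroot(ape::read.tree(
    text = "(((a,b),(c,d)),((e,f),(g,h)));"))
  ie8 <- which(tr8$edge[, 1L] > 8L & tr8$edge[, 2L] > 8L)
  sizes <- lapply(ie8, function(e) sort(lengths(branch_partitions(tr8, e))))
  expect_true(any(vapply(sizes, function(s) all(s == 2L), logical(1L))))

  expect_error(branch_partitions(tr, which(tr$edge[, 2L] <= 5L)[1L]),
               "terminal")
})

test_that("branch partitions agree with an independent graph-cut oracle", {
  skip_if_not_installed("igraph")
  set.seed(5)
  for (r in 1:5) {
    tr <- ape::unroot(ape::rtree(12))
    ntip <- ape::Ntip(tr)
    g <- igraph::graph_from_edgelist(tr$edge, directed = FALSE)
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    ie <- which(tr$edge[, 1L] > ntip & tr$edge[, 2L] > ntip)
    for (e in ie) {
      parts <- branch_partitions(tr, e)
      u <- tr$edge[e, 1L]; v <- tr$edge[e, 2L]
      # delete u and v; each remaining component holds exactly one subset
      g2 <- igraph::delete_vertices(g, as.character(c(u, v)))
      comp <- igraph::components(g2)$membership
      verts <- as.integer(names(comp))
      groups <- split(verts[verts <= ntip], comp[verts <= ntip])
      oracle <- vapply(groups, function(ix)
        paste(sort(tr$tip.label[ix]), collapse = ","), "")
      got <- vapply(parts, function(p) paste(sort(p), collapse = ","), "")
      expect_setequal(got, unname(oracle))
    }
  }
})

test_that("quartet draws respect the overlap rule", {
  subsets <- list("a", "b", "c", "d")
  ov <- matrix(100, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  cfg <- qs_config(min_overlap = 0, seed = 1)
  set.seed(1)
  expect_equal(sort(draw_quartet(subsets, ov, cfg)), c("a", "b", "c", "d"))
  # taxon with no data blocks any quartet containing it
  ov2 <- ov; ov2["d", ] <- 0; ov2[, "d"] <- 0
  cfg2 <- qs_config(min_overlap = 50, max_attempts = 5, seed = 1)
  set.seed(1)
  expect_null(draw_quartet(subsets, ov2, cfg2))
  expect_error(draw_quartet(list(character(), "b", "c", "d"), ov, cfg),
               "empty")
})

test_that("identical sequences are uninformative with zero support difference", {
  seqs <- matrix("A", nrow = 4L, ncol = 50L,
                 dimnames = list(paste0("t", 1:4), NULL))
  res <- resolve_quartet(seqs)
  expect_equal(res$outcome, "uninformative")
  expect_equal(res$delta, 0)
  expect_error(resolve_quartet(matrix("N", 4, 10)), "non-missing")
})

test_that("clean synapomorphies resolve the expected topology decisively", {
  set.seed(2)
  base <- matrix(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                 nrow = 1L)[rep(1L, 4L), ]
  rownames(base) <- paste0("t", 1:4)
  syn <- sample(1000L, 30L)
  base[c(1L, 2L), syn] <- "A"
  base[c(3L, 4L), syn] <- "T"
  res <- resolve_quartet(base, cutoff = 2, engine = "ml")
  expect_equal(res$outcome, 1L)
  expect_gt(res$delta, 2)
  # parsimony oracle agrees
  resp <- resolve_quartet(base, engine = "parsimony")
  expect_equal(resp$outcome, 1L)
  expect_equal(resp$delta, 30)  # 30 steps separate best from alternatives
})

test_that("balanced conflict yields an uninformative tie", {
  base <- matrix("C", nrow = 4L, ncol = 40L,
                 dimnames = list(paste0("t", 1:4), NULL))
  base[c(1L, 2L), 1:10] <- "A"; base[c(3L, 4L), 1:10] <- "G"
  base[c(1L, 3L), 11:20] <- "T"; base[c(2L, 4L), 11:20] <- "G"
  res <- resolve_quartet(base)
  expect_equal(res$outcome, "uninformative")
  expect_lt(res$delta, 1e-6)
})

test_that("the ML engine matches phangorn likelihoods on a random quartet", {
  skip_if_not_installed("phangorn")
  set.seed(8)
  tr <- ape::read.tree(text = "((t1:0.1,t2:0.2):0.15,(t3:0.25,t4:0.1):0.15);")
  seqs <- evolve_sequences(ape::unroot(tr), 400L, mu = 1, seed = 3L)
  pat <- quartet_patterns(seqs)
  ours <- optimize_quartet(pat)
  pd <- phangorn::phyDat(seqs, type = "DNA")
  fit <- phangorn::pml(ape::unroot(tr), pd)
  fit <- phangorn::optim.pml(fit, optEdge = TRUE, control =
                               phangorn::pml.control(trace = 0))
  expect_lt(abs(ours - fit$logLik), 0.01)
})

test_that("branch and taxon scores follow the QC/QD/QI/QF formulas", {
  mk <- function(t0, t1, t2, n_un = 0L) {
    tibble::tibble(
      branch = 1L,
      taxon1 = "a", taxon2 = "b", taxon3 = "c", taxon4 = "d",
      outcome = c(rep("concordant", t0), rep("discordant1", t1),
                  rep("discordant2", t2), rep("uninformative", n_un)),
      delta = 1
    )
  }
  s1 <- branch_and_taxon_scores(mk(30L, 0L, 0L))$branches
  expect_equal(s1$QC, 1)
  expect_true(is.na(s1$QD))
  expect_equal(s1$QI, 1)

  s2 <- branch_and_taxon_scores(mk(10L, 10L, 10L))$branches
  expect_equal(s2$QC, 0)
  expect_equal(s2$QD, 1)

  s3 <- branch_and_taxon_scores(mk(0L, 20L, 0L))$branches
  expect_equal(s3$QC, -1)
  expect_equal(s3$QD, 0)

  # direct arithmetic oracle for (150, 75, 25)
  s4 <- branch_and_taxon_scores(mk(150L, 75L, 25L, n_un = 50L))$branches
  p <- c(150, 75, 25) / 250
  qc_oracle <- 1 + sum(p * log(p, base = 3))
  expect_equal(s4$QC, qc_oracle)
  expect_equal(s4$QD, 1 - abs(75 - 25) / 100)
  expect_equal(s4$QI, 250 / 300)

  # QF: every replicate contains all four taxa here
  taxa <- branch_and_taxon_scores(mk(150L, 75L, 25L))$taxa
  expect_equal(unique(taxa$QF), 150 / 250)
})

test_that("QF bookkeeping conserves concordant counts", {
  cfg <- five_clade_config(seed = 41L, n_loci = 40L, n_per_clade = 2L,
                           dropout = 0)
  ds <- generate_dataset(cfg)
  tree <- expand_species_tree(cfg$model)
  qs <- run_quartet_sampling(ds$alignment, tree,
                             qs_config(n_replicates = 20L, min_overlap = 0,
                                       seed = 2L))
  lhs <- sum(qs$taxa$n_informative * qs$taxa$QF)
  rhs <- 4 * sum(qs$branches$t0)
  expect_equal(lhs, rhs)
  expect_true(all(qs$branches$QC >= -1 & qs$branches$QC <= 1, na.rm = TRUE))
  expect_true(all(qs$branches$QD >= 0 & qs$branches$QD <= 1, na.rm = TRUE))
  expect_true(all(qs$branches$QI >= 0 & qs$branches$QI <= 1, na.rm = TRUE))
  expect_true(all(qs$taxa$QF >= 0 & qs$taxa$QF <= 1))
})

test_that("quartet sampling is deterministic and annotates the tree", {
  cfg <- five_clade_config(seed = 43L, n_loci = 30L, n_per_clade = 2L,
                           dropout = 0)
  ds <- generate_dataset(cfg)
  tree <- expand_species_tree(cfg$model)
  cfgq <- qs_config(n_replicates = 10L, min_overlap = 0, seed = 7L)
  qs1 <- run_quartet_sampling(ds$alignment, tree, cfgq)
  qs2 <- run_quartet_sampling(ds$alignment, tree, cfgq)
  expect_identical(qs1$branches, qs2$branches)
  expect_identical(qs1$replicates, qs2$replicates)
  labs <- qs1$tree$node.label
  expect_true(any(grepl("^-?[0-9.]+/", labs)))
  expect_error(run_quartet_sampling(ds$alignment,
                                    ape::read.tree(text = "(a,b,c);")),
               "at least 4")
})
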