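#' Quartet Sampling configuration
#'
#' @param n_replicates quartet draws per internal branch (default 500).
#' @param min_overlap minimum pairwise overlap, in aligned columns called in
#'   both taxa, for a drawn quartet to be accepted (default 300000, the
#'   setting used for large sparse RAD alignments; lower it for small or
#'   complete alignments).
#' @param lnl_cutoff log-likelihood difference below which a quartet is
#'   uninformative (default 2).
#' @param max_attempts resampling attempts per replicate before recording a
#'   failed-overlap draw (default 10).
#' @param engine quartet resolution engine, `"ml"` or `"parsimony"`.
#' @param seed integer seed.
#' @return An object of class `qs_config`.
#' @export
qs_config <- function(n_replicates = 500L, min_overlap = 300000L,
                      lnl_cutoff = 2, max_attempts = 10L,
                      engine = c("ml", "parsimony"), seed = 1L) {
  assert_that_(n_replicates >= 1L, "n_replicates must be >= 1")
  assert_that_(min_overlap >= 0L, "min_overlap must be >= 0")
  assert_that_(lnl_cutoff >= 0, "lnl_cutoff must be >= 0")
  structure(list(n_replicates = as.integer(n_replicates),
                 min_overlap = as.numeric(min_overlap),
                 lnl_cutoff = lnl_cutoff,
                 max_attempts = as.integer(max_attempts),
                 engine = match.arg(engine), seed = as.integer(seed)),
            class = "qs_config")
}

# adjacency list of an unrooted phylo
tree_adjacency <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  adj <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1L]; b <- tree$edge[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# leaves reachable from `start` without crossing `block`
leaves_beyond <- function(adj, ntip, start, block) {
  seen <- c(block, start)
  stack <- start
  leaves <- integer()
  while (length(stack) > 0L) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v <= ntip) leaves <- c(leaves, v)
    nxt <- setdiff(adj[[v]], seen)
    seen <- c(seen, nxt)
    stack <- c(stack, nxt)
  }
  leaves
}

#' Four taxon subsets induced by an internal branch
#'
#' An internal branch of an unrooted binary tree divides the leaves into four
#' non-overlapping subsets, one per edge adjacent to the branch's two
#' endpoints.  Subsets 1 and 2 attach at one endpoint, 3 and 4 at the other;
#' the concordant quartet topology is therefore `(1,2 | 3,4)`.
#'
#' @param tree an unrooted [ape::phylo].
#' @param edge_id row index into `tree$edge` of an internal branch (both
#'   endpoints internal nodes).
#' @return A list of four character vectors of tip labels.
#' @export
branch_partitions <- function(tree, edge_id) {
  ntip <- ape::Ntip(tree)
  u <- tree$edge[edge_id, 1L]; v <- tree$edge[edge_id, 2L]
  if (u <= ntip || v <= ntip) abort("terminal branch: no quartet partition")
  adj <- tree_adjacency(tree)
  nu <- setdiff(adj[[u]], v); nv <- setdiff(adj[[v]], u)
  if (length(nu) != 2L || length(nv) != 2L) {
    abort("branch endpoints must be binary (degree 3) for quartet partitioning")
  }
  subsets <- c(
    lapply(nu, function(s) leaves_beyond(adj, ntip, s, u)),
    lapply(nv, function(s) leaves_beyond(adj, ntip, s, v))
  )
  lapply(subsets, function(ix) tree$tip.label[sort(ix)])
}

#' Draw one quartet replicate
#'
#' Samples one taxon uniformly from each subset and accepts the draw only if
#' all six pairwise overlaps meet `cfg$min_overlap`, retrying up to
#' `cfg$max_attempts` times before recording a failed-overlap replicate.
#'
#' @param subsets list of four tip-label vectors from [branch_partitions()].
#' @param overlap named square matrix of pairwise called-column counts.
#' @param cfg a [qs_config()].
#' @return A character vector of four taxa, or `NULL` on overlap failure.
#' @export
draw_quartet <- function(subsets, overlap, cfg) {
  if (any(lengths(subsets) == 0L)) abort("empty branch subset")
  for (a in seq_len(cfg$max_attempts)) {
    q <- vapply(subsets, function(s) s[sample.int(length(s), 1L)], "")
    ov <- overlap[q, q]
    if (min(ov[upper.tri(ov)]) >= cfg$min_overlap) return(q)
  }
  NULL
}

#' Branch and taxon scores from quartet replicates
#'
#' With `t0` concordant and `t1`, `t2` discordant informative counts,
#' `s = t0 + t1 + t2` and `p_i = t_i / s`:
#' * `QC = 1 + sum(p_i log3 p_i)` when the concordant topology has the
#'   plurality, and the negative of that quantity otherwise; undefined
#'   (`NA`) when `s = 0`.
#' * `QD = 1 - |t1 - t2| / (t1 + t2)`; undefined when `t1 + t2 = 0`.
#' * `QI = s / n` over the `n` successfully drawn (resolved) replicates.
#' * `QF(taxon)` = concordant replicates containing the taxon / informative
#'   replicates containing it, pooled over all branches.
#'
#' @param replicates tibble with columns `branch`, `taxon1..taxon4`,
#'   `outcome` (`"concordant"`, `"discordant1"`, `"discordant2"`,
#'   `"uninformative"`, `"failed_overlap"`).
#' @return A list with `branches` and `taxa` tibbles.
#' @export
branch_and_taxon_scores <- function(replicates) {
  qc_entropy <- function(t0, t1, t2) {
    s <- t0 + t1 + t2
    if (s == 0) return(NA_real_)
    p <- c(t0, t1, t2) / s
    ent <- sum(p[p > 0] * log(p[p > 0], base = 3))
    if (t0 == max(t0, t1, t2)) 1 + ent else -(1 + ent)
  }
  branches <- replicates |>
    dplyr::group_by(.data$branch) |>
    dplyr::summarise(
      t0 = sum(.data$outcome == "concordant"),
      t1 = sum(.data$outcome == "discordant1"),
      t2 = sum(.data$outcome == "discordant2"),
      n_uninformative = sum(.data$outcome == "uninformative"),
      n_failed = sum(.data$outcome == "failed_overlap"),
      .groups = "drop"
    ) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      QC = qc_entropy(.data$t0, .data$t1, .data$t2),
      QD = if (.data$t1 + .data$t2 > 0)
        1 - abs(.data$t1 - .data$t2) / (.data$t1 + .data$t2) else NA_real_,
      QI = {
        n_success <- .data$t0 + .data$t1 + .data$t2 + .data$n_uninformative
        if (n_success > 0)
          (.data$t0 + .data$t1 + .data$t2) / n_success else NA_real_
      }
    ) |>
    dplyr::ungroup()
  inf <- replicates[replicates$outcome %in%
                      c("concordant", "discordant1", "discordant2"), ]
  long <- tidyr::pivot_longer(inf, dplyr::starts_with("taxon"),
                              values_to = "taxon")
  taxa <- long |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(
      n_informative = dplyr::n(),
      n_concordant = sum(.data$outcome == "concordant"),
      .groups = "drop"
    ) |>
    dplyr::mutate(QF = .data$n_concordant / .data$n_informative)
  list(branches = branches, taxa = taxa)
}

#' Run Quartet Sampling on an alignment and focal tree
#'
#' For every internal branch of the (unrooted) focal tree, repeatedly samples
#' one taxon from each of the four branch-induced subsets, resolves each
#' quartet from the alignment, and summarises concordance as QC/QD/QI per
#' branch and QF per taxon.  Deterministic for a fixed config seed.
#'
#' @param aln a [rad_alignment()] whose rows include every tree tip.
#' @param tree an [ape::phylo] (rooted trees are unrooted internally).
#' @param cfg a [qs_config()].
#' @return An object of class `quartet_sampling`: list with `branches`
#'   (tibble: branch id, split sizes, tallies, QC, QD, QI), `taxa` (tibble
#'   with QF), `replicates` (the raw draw records), `tree` (the unrooted
#'   input tree with `QC/QD/QI` node labels), and `config`.
#' @export
run_quartet_sampling <- function(aln, tree, cfg = qs_config()) {
  if (ape::Ntip(tree) < 4L) abort("Quartet Sampling needs at least 4 taxa")
  missing_tips <- setdiff(tree$tip.label, rownames(aln$seqs))
  assert_that_(length(missing_tips) == 0L,
               sprintf("tree tips absent from alignment: %s",
                       paste(head(missing_tips, 5L), collapse = ", ")))
  utree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  ntip <- ape::Ntip(utree)
  seqs <- aln$seqs[utree$tip.label, , drop = FALSE]
  valid <- matrix(seqs %in% BASES, nrow = nrow(seqs),
                  dimnames = list(rownames(seqs), NULL))
  overlap <- tcrossprod(valid * 1)
  internal_edges <- which(utree$edge[, 1L] > ntip & utree$edge[, 2L] > ntip)
  reps <- with_seed_(stage_seed(cfg$seed, "quartet"), {
    purrr::map_dfr(internal_edges, function(ei) {
      subsets <- branch_partitions(utree, ei)
      purrr::map_dfr(seq_len(cfg$n_replicates), function(r) {
        q <- draw_quartet(subsets, overlap, cfg)
        if (is.null(q)) {
          return(tibble(branch = ei, taxon1 = NA_character_,
                        taxon2 = NA_character_, taxon3 = NA_character_,
                        taxon4 = NA_character_, outcome = "failed_overlap",
                        delta = NA_real_))
        }
        res <- resolve_quartet(seqs[q, , drop = FALSE],
                               cutoff = cfg$lnl_cutoff, engine = cfg$engine)
        outcome <- switch(as.character(res$outcome),
                          "1" = "concordant", "2" = "discordant1",
                          "3" = "discordant2", "uninformative")
        tibble(branch = ei, taxon1 = q[1L], taxon2 = q[2L], taxon3 = q[3L],
               taxon4 = q[4L], outcome = outcome, delta = res$delta)
      })
    })
  })
  scores <- branch_and_taxon_scores(reps)
  branches <- scores$branches
  # readable split description: leaves on the child side of the branch
  branches$node <- utree$edge[branches$branch, 2L]
  branches$split <- vapply(branches$branch, function(ei) {
    parts <- branch_partitions(utree, ei)
    paste(paste(parts[[3L]], collapse = ","), "|",
          paste(parts[[4L]], collapse = ","))
  }, "")
  ann <- tibble(
    node = branches$node,
    label = vapply(seq_len(nrow(branches)), function(i)
      format_qs_label(branches$QC[i], branches$QD[i], branches$QI[i]), "")
  )
  n_int <- utree$Nnode
  labs <- rep("", n_int)
  labs[ann$node - ntip] <- ann$label
  utree$node.label <- labs
  structure(list(branches = branches, taxa = scores$taxa, replicates = reps,
                 tree = utree, config = cfg),
            class = "quartet_sampling")
}

#' @export
print.quartet_sampling <- function(x, ...) {
  cat(sprintf("<quartet_sampling> %d internal branches, %d replicates each (%s engine)\n",
              nrow(x$branches), x$config$n_replicates, x$config$engine))
  print(x$branches[, c("split", "QC", "QD", "QI")])
  invisible(x)
}

#' @method tidy quartet_sampling
#' @export
tidy.quartet_sampling <- function(x, ...) x$branches

#' @method glance quartet_sampling
#' @export
glance.quartet_sampling <- function(x, ...) {
  tibble(
    n_branches = nrow(x$branches),
    median_QC = stats::median(x$branches$QC, na.rm = TRUE),
    median_QD = stats::median(x$branches$QD, na.rm = TRUE),
    median_QI = stats::median(x$branches$QI, na.rm = TRUE),
    mean_QF = mean(x$taxa$QF)
  )
}

#' Write Quartet Sampling outputs
#'
#' Writes the per-branch and per-taxon score tables as TSV and the annotated
#' Newick tree.
#'
#' @param x a `quartet_sampling` result.
#' @param branches_path,taxa_path,tree_path output paths (`NULL` to skip).
#' @return `x`, invisibly.
#' @export
write_quartet_sampling <- function(x, branches_path = NULL, taxa_path = NULL,
                                   tree_path = NULL) {
  if (!is.null(branches_path)) {
    write.table(as.data.frame(x$branches), branches_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(taxa_path)) {
    write.table(as.data.frame(x$taxa), taxa_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(tree_path)) ape::write.tree(x$tree, file = tree_path)
  invisible(x)
}

#' @method autoplot quartet_sampling
#' @export
autoplot.quartet_sampling <- function(object, ...) {
  ggplot2::ggplot(object$branches,
                  ggplot2::aes(x = .data$QC, y = .data$QD, size = .data$QI)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::xlim(-1, 1) + ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "quartet concordance (QC)",
                  y = "quartet differential (QD)",
                  size = "QI") +
    ggplot2::theme_minimal()
}
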