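#' Species model for the multispecies coalescent
#'
#' A rooted, ultrametric species tree with branch lengths in coalescent units
#' (time scaled by 2N generations), per-branch relative population sizes, and
#' per-tip sample counts.  Tips sit at time 0; node times increase root-ward.
#' Branches are addressed by the label of the node *below* them: tip labels
#' for terminal branches, node labels (assigned `anc_<tip>.<tip>...` when
#' absent) for internal ones.
#'
#' @param tree an [ape::phylo] object or Newick string; must be rooted and
#'   binary with branch lengths in coalescent units.
#' @param n_samples named integer vector of haploid samples per tip; unnamed
#'   scalar recycled to all tips.
#' @param pop_size named numeric vector of relative population sizes per
#'   branch label (default 1 everywhere); unnamed scalar recycled.
#' @return An object of class `species_model`.
#' @export
species_model <- function(tree, n_samples = 2L, pop_size = 1) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  assert_that_(inherits(tree, "phylo"), "`tree` must be a phylo or Newick string")
  assert_that_(ape::is.rooted(tree) && ape::is.binary(tree),
               "species tree must be rooted and binary")
  assert_that_(!is.null(tree$edge.length), "species tree needs branch lengths")
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  # node times from tip depths (tips at 0)
  depth <- ape::node.depth.edgelength(tree)
  times <- max(depth) - depth
  assert_that_(all(abs(times[seq_len(ntip)]) < 1e-9),
               "species tree must be ultrametric (all tips at time 0)")
  times[seq_len(ntip)] <- 0
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label))) {
    lab <- tree$node.label %||% rep("", nnode)
    for (i in which(!nzchar(lab))) {
      node <- ntip + i
      tips <- ape::extract.clade(tree, node)$tip.label
      lab[i] <- paste0("anc_", paste(tips, collapse = "."))
    }
    tree$node.label <- lab
  }
  labels <- c(tree$tip.label, tree$node.label)
  assert_that_(!anyDuplicated(labels), "tip/node labels must be unique")
  if (is.null(names(n_samples))) {
    n_samples <- setNames(rep_len(as.integer(n_samples), ntip), tree$tip.label)
  }
  assert_that_(all(tree$tip.label %in% names(n_samples)),
               "n_samples must cover every tip")
  n_samples <- as.integer(n_samples[tree$tip.label])
  names(n_samples) <- tree$tip.label
  if (is.null(names(pop_size))) {
    pop_size <- setNames(rep_len(pop_size, length(labels)), labels)
  } else {
    ps <- setNames(rep(1, length(labels)), labels)
    bad <- setdiff(names(pop_size), labels)
    assert_that_(length(bad) == 0L,
                 sprintf("pop_size names not in tree: %s", paste(bad, collapse = ", ")))
    ps[names(pop_size)] <- pop_size
    pop_size <- ps
  }
  assert_that_(all(pop_size > 0), "population sizes must be positive")
  parent <- rep(NA_integer_, ntip + nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  structure(list(
    tree = tree, labels = labels, times = times, parent = parent,
    n_samples = n_samples, pop_size = pop_size, root = ntip + 1L
  ), class = "species_model")
}

#' @export
print.species_model <- function(x, ...) {
  cat(sprintf("<species_model> %d tips, %d samples, root age %.3g coalescent units\n",
              ape::Ntip(x$tree), sum(x$n_samples), max(x$times)))
  invisible(x)
}

# existence interval of the branch above node labelled `lab`
branch_interval <- function(model, lab) {
  node <- match(lab, model$labels)
  if (is.na(node)) abort(sprintf("unknown branch label: %s", lab))
  lo <- model$times[node]
  hi <- if (node == model$root) Inf else model$times[model$parent[node]]
  c(lo, hi)
}

#' Admixture pulse specification
#'
#' A pulse is a single instantaneous admixture event: at `time` (coalescent
#' units before present), each lineage then tracing through the recipient
#' branch independently derives from the donor branch with probability
#' `fraction`.  Forward in time this is a pulse of migration from donor to
#' recipient; it is simulated backward as lineage reassignment.
#'
#' @param donor,recipient branch labels in the species model.
#' @param time event time in coalescent units.
#' @param fraction admixture proportion in `[0, 1]`.
#' @return A one-row tibble; rows can be bound to form a pulse table.
#' @export
admixture_pulse <- function(donor, recipient, time, fraction) {
  assert_that_(is_scalar_number(fraction) && fraction >= 0 && fraction <= 1,
               "fraction must be in [0, 1]")
  assert_that_(is_scalar_number(time) && time >= 0, "time must be >= 0")
  tibble(donor = donor, recipient = recipient, time = time, fraction = fraction)
}

validate_pulses <- function(model, pulses) {
  if (is.null(pulses) || nrow(pulses) == 0L) return(invisible(TRUE))
  for (i in seq_len(nrow(pulses))) {
    p <- pulses[i, ]
    for (lab in c(p$donor, p$recipient)) {
      iv <- branch_interval(model, lab)
      if (p$time < iv[1] - 1e-12 || p$time > iv[2] + 1e-12) {
        abort(sprintf(
          "pulse at time %g outside existence interval [%g, %g] of branch '%s'",
          p$time, iv[1], iv[2], lab))
      }
    }
  }
  invisible(TRUE)
}

#' Simulation configuration
#'
#' Bundles a species model, admixture pulses, and the locus/mutation/dropout
#' parameters of a synthetic RAD-seq experiment.
#'
#' @param model a [species_model()].
#' @param pulses a pulse table from [admixture_pulse()] rows, or `NULL`.
#' @param n_loci number of unlinked loci (independent gene trees).
#' @param locus_length locus length in bp.
#' @param mu per-site mutation rate per coalescent unit (theta-scaled).
#' @param dropout probability that a given sample misses a given locus
#'   entirely; either a scalar or a named vector of per-clade rates (names =
#'   species-tree tip labels).
#' @param seed master seed; per-stage substreams are derived from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(model, pulses = NULL, n_loci = 500L, locus_length = 64L,
                       mu = 0.0055, dropout = 0.2, seed = 1L) {
  assert_that_(n_loci >= 1L, "n_loci must be >= 1")
  assert_that_(locus_length >= 1L, "locus_length must be >= 1")
  assert_that_(mu >= 0, "mu must be >= 0")
  assert_that_(all(dropout >= 0 & dropout <= 1), "dropout must be in [0, 1]")
  validate_pulses(model, pulses)
  structure(list(model = model, pulses = pulses, n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length), mu = mu,
                 dropout = dropout, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default five-clade study design
#'
#' A ready-made [sim_config()] emulating the structure the partitioned D
#' analysis assumes: five ingroup clades `I`, `II`, `III`, `IV`, `V` plus an
#' outgroup `OG` on the topology `((((I,II),(III,IV)),V),OG)`, with the
#' `(I,II)` split deeper than the `(III,IV)` split so that a tip branch of
#' the first pair coexists in time with the ancestor branch of the second
#' pair (making ancestral-introgression scenarios expressible).  Four haploid
#' samples per clade; 500 loci of 64 bp; mutation rate chosen to give RAD-like
#' SNP densities (~10 SNPs per locus); 20% random locus dropout.
#'
#' @inheritParams sim_config
#' @param n_per_clade haploid samples per clade tip.
#' @param ... overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
five_clade_config <- function(seed = 1L, n_per_clade = 4L, pulses = NULL, ...) {
  nwk <- "((((I:1.5,II:1.5)A12:1.0,(III:1.0,IV:1.0)A34:1.5)A1234:1.0,V:3.5)AING:1.5,OG:5.0)AROOT;"
  model <- species_model(nwk, n_samples = n_per_clade)
  sim_config(model, pulses = pulses, seed = seed, ...)
}

#' Sample-level focal tree for a species model
#'
#' Expands each species-tree tip into a pectinate subtree of its samples,
#' producing the binary sample-level topology implied by the model (the
#' within-clade arrangement is arbitrary, which is immaterial for clade-level
#' questions but keeps every branch quartet-partitionable).
#'
#' @param model a [species_model()].
#' @return An [ape::phylo] with tips `<tip>_<k>`.
#' @export
expand_species_tree <- function(model) {
  tree <- model$tree
  ntip <- ape::Ntip(tree)
  expand_tip <- function(ids) {
    if (length(ids) == 1L) return(ids)
    paste0("(", ids[1L], ",", expand_tip(ids[-1L]), ")")
  }
  rec <- function(node) {
    if (node <= ntip) {
      tp <- tree$tip.label[node]
      return(expand_tip(paste0(tp, "_", seq_len(model$n_samples[[tp]]))))
    }
    ch <- tree$edge[tree$edge[, 1L] == node, 2L]
    paste0("(", paste(vapply(ch, rec, ""), collapse = ","), ")")
  }
  ape::read.tree(text = paste0(rec(ntip + 1L), ";"))
}

#' Clade map matching a simulated dataset
#'
#' @param cfg a [sim_config()].
#' @param outgroup clade ids to declare as outgroup (default: `"OG"` plus
#'   `"V"` when present, mirroring pooled-outgroup usage).
#' @return A [clade_map()] whose sample ids are those produced by
#'   [generate_dataset()] (`<tip>_<k>`).
#' @export
sim_clade_map <- function(cfg, outgroup = NULL) {
  tips <- names(cfg$model$n_samples)
  ids <- unlist(lapply(tips, function(tp)
    paste0(tp, "_", seq_len(cfg$model$n_samples[[tp]]))))
  cl <- rep(tips, times = cfg$model$n_samples)
  if (is.null(outgroup)) outgroup <- intersect(c("V", "OG"), tips)
  clade_map(setNames(cl, ids), outgroup = outgroup)
}
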