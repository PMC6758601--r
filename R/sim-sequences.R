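#' Evolve sequences along a gene tree under Jukes-Cantor
#'
#' Sites evolve independently under JC69: starting from a uniform root state,
#' a site at the end of a branch of length `t` differs from its parent state
#' with probability `(3/4)(1 - exp(-4 mu t / 3))`, the substituted base being
#' uniform over the three alternatives.  No rate heterogeneity and no indels.
#'
#' @param tree an [ape::phylo] gene tree with branch lengths in coalescent
#'   units.
#' @param locus_length number of sites.
#' @param mu per-site substitution rate per coalescent unit.
#' @param seed optional integer; when given the simulation runs in its own
#'   RNG stream, otherwise it draws from the current stream.
#' @return A character matrix (tips x sites) of bases, rownames = tip labels.
#' @export
evolve_sequences <- function(tree, locus_length, mu, seed = NULL) {
  if (any(tree$edge.length < 0)) abort("negative branch length in gene tree")
  run <- function() evolve_jc(tree, locus_length, mu)
  if (is.null(seed)) run() else with_seed_(seed, run())
}

evolve_jc <- function(tree, L, mu) {
  bases <- c("A", "C", "G", "T")
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  seqs <- matrix(NA_integer_, nrow = nnode, ncol = L)
  root <- ntip + 1L
  seqs[root, ] <- sample.int(4L, L, replace = TRUE)
  ord <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  p_change <- 0.75 * (1 - exp(-4 * mu * ord$edge.length / 3))
  for (i in seq_len(nrow(ord$edge))) {
    par <- ord$edge[i, 1L]; ch <- ord$edge[i, 2L]
    x <- seqs[par, ]
    hit <- which(runif(L) < p_change[i])
    if (length(hit) > 0L) {
      # uniform over the three other bases
      x[hit] <- (x[hit] - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L
    }
    seqs[ch, ] <- x
  }
  out <- matrix(bases[seqs[seq_len(ntip), , drop = FALSE]], nrow = ntip)
  rownames(out) <- tree$tip.label
  out
}
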