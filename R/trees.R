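#' Read and write Newick trees, with per-branch score annotations
#'
#' Thin wrappers around ape's Newick parser/writer.  `write_annotated_newick()`
#' serialises per-branch score triplets as `QC/QD/QI` strings in internal node
#' labels, the display convention used for Quartet Sampling results; undefined
#' scores are rendered `-`.
#'
#' @param path file path.
#' @return `read_newick()` returns an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(sprintf("tree file not found: %s", path))
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) abort(sprintf("cannot parse Newick in %s: %s",
                                                   path, conditionMessage(e))))
  if (is.null(tr)) abort(sprintf("cannot parse Newick in %s", path))
  tr
}

#' @rdname read_newick
#' @param tree an [ape::phylo] object.
#' @param annotations optional data frame with columns `node` (internal node
#'   number) and `label` (the annotation string), e.g. from
#'   [run_quartet_sampling()]; when absent the tree is written as is.
#' @return `write_annotated_newick()` returns `path`, invisibly.
#' @export
write_annotated_newick <- function(tree, path, annotations = NULL) {
  if (!is.null(annotations)) {
    n_int <- tree$Nnode
    labs <- rep("", n_int)
    idx <- annotations$node - ape::Ntip(tree)
    ok <- idx >= 1 & idx <= n_int
    labs[idx[ok]] <- annotations$label[ok]
    tree$node.label <- labs
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

format_qs_label <- function(qc, qd, qi, digits = 2) {
  fmt1 <- function(v) {
    if (is.na(v)) "-" else format(round(v, digits), trim = TRUE)
  }
  paste(fmt1(qc), fmt1(qd), fmt1(qi), sep = "/")
}
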