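#' Simulate gene trees under the multispecies coalescent with pulses
#'
#' Runs a backward-in-time coalescent within the species model: within each
#' population (species-tree branch) holding `k` lineages of relative size
#' `N`, lineage pairs coalesce at total rate `k(k-1)/2 / N` per coalescent
#' unit.  At a species-tree node the two child populations merge; at an
#' admixture pulse every lineage then in the recipient branch independently
#' reassigns to the donor branch with probability `fraction`.  One gene tree
#' is returned per locus; the whole list is deterministic for a fixed
#' config seed.
#'
#' @param cfg a [sim_config()].
#' @return A list of `cfg$n_loci` [ape::phylo] gene trees whose tip labels
#'   are the sample ids `<tip>_<k>`, with branch lengths in coalescent units.
#' @export
simulate_gene_trees <- function(cfg) {
  model <- cfg$model
  validate_pulses(model, cfg$pulses)
  events <- fixed_event_table(model, cfg$pulses)
  tips <- names(model$n_samples)
  sample_pop <- rep(match(tips, model$labels), times = model$n_samples)
  sample_ids <- unlist(lapply(tips, function(tp)
    paste0(tp, "_", seq_len(model$n_samples[[tp]]))))
  with_seed_(stage_seed(cfg$seed, "gene_trees"), {
    lapply(seq_len(cfg$n_loci), function(l)
      sim_one_gene_tree(model, events, sample_pop, sample_ids))
  })
}

fixed_event_table <- function(model, pulses) {
  ntip <- ape::Ntip(model$tree)
  internal <- (ntip + 1L):(ntip + model$tree$Nnode)
  ev <- data.frame(time = model$times[internal], type = "merge",
                   node = internal, donor = NA_integer_,
                   recipient = NA_integer_, fraction = NA_real_)
  if (!is.null(pulses) && nrow(pulses) > 0L) {
    pv <- data.frame(
      time = pulses$time, type = "pulse", node = NA_integer_,
      donor = match(pulses$donor, model$labels),
      recipient = match(pulses$recipient, model$labels),
      fraction = pulses$fraction
    )
    ev <- rbind(ev, pv)
  }
  # pulses fire before a merge at the same instant
  ev[order(ev$time, ev$type != "pulse"), ]
}

sim_one_gene_tree <- function(model, events, sample_pop, sample_ids) {
  n <- length(sample_pop)
  pop <- sample_pop                      # current population per active lineage
  gnode <- seq_len(n)                    # gene-tree node id per active lineage
  node_time <- numeric(2L * n - 1L)
  kids <- matrix(NA_integer_, nrow = 2L * n - 1L, ncol = 2L)
  next_internal <- n
  t <- 0
  ei <- 1L
  n_events <- nrow(events)
  repeat {
    t_next <- if (ei <= n_events) events$time[ei] else Inf
    # stochastic coalescence until the next fixed event
    repeat {
      if (length(gnode) <= 1L) break
      tb <- tabulate(pop, nbins = length(model$labels))
      rates <- tb * (tb - 1) / 2 / model$pop_size
      total <- sum(rates)
      if (total == 0) { t <- t_next; break }
      dt <- rexp(1L, total)
      if (t + dt >= t_next) { t <- t_next; break }
      t <- t + dt
      p <- sample.int(length(rates), 1L, prob = rates)
      pair <- sample(which(pop == p), 2L)
      next_internal <- next_internal + 1L
      node_time[next_internal] <- t
      kids[next_internal, ] <- gnode[pair]
      gnode <- c(gnode[-pair], next_internal)
      pop <- c(pop[-pair], p)
    }
    if (length(gnode) <= 1L && ei > n_events) break
    if (ei > n_events) next  # keep coalescing in the root population
    e <- events[ei, ]
    ei <- ei + 1L
    if (e$type == "merge") {
      ch <- model$tree$edge[model$tree$edge[, 1L] == e$node, 2L]
      pop[pop %in% ch] <- e$node
    } else {
      hit <- pop == e$recipient & runif(length(pop)) < e$fraction
      pop[hit] <- e$donor
    }
  }
  build_phylo(n, node_time, kids, sample_ids)
}

# assemble an ape phylo from coalescence records; internal ids are renumbered
# so the last-created node (the root) becomes ntip+1 as ape requires
build_phylo <- function(n, node_time, kids, sample_ids) {
  n_int <- n - 1L
  old <- (n + 1L):(n + n_int)
  new_id <- c(seq_len(n), rev(old))      # old internal s -> 2n - (s - n)
  edge <- matrix(NA_integer_, nrow = 2L * n_int, ncol = 2L)
  elen <- numeric(2L * n_int)
  r <- 0L
  for (s in old) {
    for (ch in kids[s, ]) {
      r <- r + 1L
      edge[r, ] <- c(new_id[s], new_id[ch])
      elen[r] <- node_time[s] - node_time[ch]
    }
  }
  tr <- structure(list(edge = edge, edge.length = elen, Nnode = n_int,
                       tip.label = sample_ids), class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}
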