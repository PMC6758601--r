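config_defaults <- function() {
  list(
    # global
    seed = 1L, out_dir = ".",
    # simulate
    n_loci = 500L, locus_length = 64L, mu = 0.0055, dropout = 0.2,
    n_per_clade = 4L, pulses = NULL,
    # filter
    min_n = 0L,
    # baba
    vcf = NULL, clades = NULL, tree = NULL, min_clade_cov = 1 / 3,
    boots = 1000L, z_threshold = 2.55, snps = "all", canonical = FALSE,
    # qsample
    alignment = NULL, reps = 500L, min_overlap = 300000, lnl_cutoff = 2,
    max_attempts = 10L, engine = "ml"
  )
}

#' Resolve a run configuration from a YAML file and/or flags
#'
#' Every parameter has a default; values from a YAML config file override the
#' defaults, and command-line style flags override the file.  Unknown keys
#' raise an error naming the nearest valid key.
#'
#' @param path optional YAML config file.
#' @param overrides named list of parameter overrides (flag values).
#' @return A named list of class `run_config` with all parameters resolved.
#' @export
parse_run_config <- function(path = NULL, overrides = list()) {
  cfg <- config_defaults()
  apply_kv <- function(cfg, kv, origin) {
    for (k in names(kv)) {
      if (!k %in% names(config_defaults())) {
        abort(sprintf("unknown %s key '%s'; did you mean '%s'? valid keys: %s",
                      origin, k, nearest_key(k, names(config_defaults())),
                      paste(names(config_defaults()), collapse = ", ")))
      }
      cfg[[k]] <- kv[[k]]
    }
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
    file_cfg <- yaml::read_yaml(path)
    if (length(file_cfg) > 0L) cfg <- apply_kv(cfg, file_cfg, "config")
  }
  provided <- union(if (!is.null(path)) names(yaml::read_yaml(path)),
                    names(overrides))
  if (length(overrides) > 0L) cfg <- apply_kv(cfg, overrides, "flag")
  # coerce numerics that may arrive as strings from flags
  for (k in c("seed", "n_loci", "locus_length", "n_per_clade", "min_n",
              "boots", "reps", "max_attempts")) {
    cfg[[k]] <- as.integer(cfg[[k]])
  }
  for (k in c("mu", "dropout", "min_clade_cov", "z_threshold", "min_overlap",
              "lnl_cutoff")) {
    cfg[[k]] <- as.numeric(cfg[[k]])
  }
  cfg$canonical <- isTRUE(cfg$canonical) || identical(cfg$canonical, "true")
  structure(cfg, provided = provided, class = "run_config")
}

parse_pulse_spec <- function(pulses) {
  if (is.null(pulses)) return(NULL)
  if (is.character(pulses) && length(pulses) == 1L) {
    # "donor:recipient:time:fraction[;donor:recipient:time:fraction...]"
    parts <- strsplit(strsplit(pulses, ";")[[1L]], ":")
    pulses <- lapply(parts, function(p) {
      assert_that_(length(p) == 4L,
                   "pulse flag format is donor:recipient:time:fraction")
      list(donor = p[1L], recipient = p[2L],
           time = as.numeric(p[3L]), fraction = as.numeric(p[4L]))
    })
  }
  dplyr::bind_rows(lapply(pulses, function(p)
    admixture_pulse(p$donor, p$recipient, p$time, p$fraction)))
}

write_run_log <- function(cfg, out_dir, subcommand) {
  scalars <- cfg[!vapply(cfg, is.null, logical(1L))]
  scalars$pulses <- NULL
  yaml::write_yaml(scalars, file.path(out_dir, "run_config.yaml"))
  log_lines <- c(
    sprintf("pentad %s run", subcommand),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("R version: %s", R.version.string),
    sprintf("pentad version: %s",
            as.character(utils::packageVersion("pentad"))),
    "resolved config:",
    vapply(names(scalars), function(k)
      sprintf("  %s: %s", k, paste(format(scalars[[k]]), collapse = ",")), "")
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
}

run_simulate <- function(cfg) {
  pulses <- parse_pulse_spec(cfg$pulses)
  sim <- five_clade_config(seed = cfg$seed, n_per_clade = cfg$n_per_clade,
                           pulses = pulses, n_loci = cfg$n_loci,
                           locus_length = cfg$locus_length, mu = cfg$mu,
                           dropout = cfg$dropout)
  ds <- generate_dataset(sim)
  map <- sim_clade_map(sim)
  out <- cfg$out_dir
  write_alignment(ds$alignment, file.path(out, "alignment.fasta"))
  write.table(as.data.frame(ds$alignment$locus_bounds),
              file.path(out, "locus_bounds.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_vcf(ds$snp, file.path(out, "snps.vcf"))
  write_clade_map(map, file.path(out, "clades.tsv"))
  truth <- list(
    seed = cfg$seed, n_loci = cfg$n_loci, locus_length = cfg$locus_length,
    mu = cfg$mu, dropout = cfg$dropout,
    tree = ape::write.tree(sim$model$tree),
    pulses = if (!is.null(pulses)) lapply(seq_len(nrow(pulses)), function(i)
      as.list(pulses[i, ])),
    retained_per_locus = unname(colSums(ds$truth$retained))
  )
  yaml::write_yaml(truth, file.path(out, "truth.yaml"))
  ds
}

read_dataset_dir <- function(dir) {
  aln_path <- file.path(dir, "alignment.fasta")
  lb_path <- file.path(dir, "locus_bounds.tsv")
  for (p in c(aln_path, lb_path)) {
    if (!file.exists(p)) abort(sprintf("missing input file: %s", p))
  }
  aln <- read_alignment(aln_path)
  lb <- as_tibble(read.table(lb_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE))
  aln <- rad_alignment(aln$seqs, locus_bounds = lb)
  structure(list(alignment = aln, snp = alignment_to_snps(aln),
                 truth = list(retained = locus_coverage(aln))),
            class = "rad_dataset")
}

run_filter <- function(cfg) {
  ds <- read_dataset_dir(cfg$out_dir)
  f <- filter_min_samples(ds, cfg$min_n)
  out <- cfg$out_dir
  write_alignment(f$alignment, file.path(out, "alignment_filtered.fasta"))
  write_vcf(f$snp, file.path(out, "snps_filtered.vcf"))
  write.table(as.data.frame(rad_summary(f)), file.path(out, "filter_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

run_baba <- function(cfg) {
  vcf <- cfg$vcf %||% file.path(cfg$out_dir, "snps.vcf")
  clades <- cfg$clades %||% file.path(cfg$out_dir, "clades.tsv")
  for (p in c(vcf, clades)) {
    if (!file.exists(p)) abort(sprintf("missing input file: %s", p))
  }
  m <- read_vcf(vcf)
  map <- read_clade_map(clades)
  tree <- if (is.null(cfg$tree)) {
    "(((I,II),(III,IV)),V);"
  } else if (file.exists(cfg$tree)) {
    read_newick(cfg$tree)
  } else {
    cfg$tree
  }
  d <- run_partitioned_tests(
    m, map, tree,
    spec = bootstrap_spec(cfg$boots, cfg$z_threshold, seed = cfg$seed),
    min_clade_cov = cfg$min_clade_cov, snps = cfg$snps,
    canonical = cfg$canonical
  )
  write_d_table(d, file.path(cfg$out_dir, "d_statistics.tsv"))
  interp <- interpret_d(d)
  write.table(as.data.frame(interp), file.path(cfg$out_dir, "d_interpretation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  d
}

run_qsample <- function(cfg) {
  aln_path <- cfg$alignment %||% file.path(cfg$out_dir, "alignment.fasta")
  if (!file.exists(aln_path)) abort(sprintf("missing input file: %s", aln_path))
  aln <- read_alignment(aln_path)
  tree <- if (is.null(cfg$tree)) {
    abort("qsample needs a focal tree (tree: path or Newick string)")
  } else if (file.exists(cfg$tree)) {
    read_newick(cfg$tree)
  } else {
    ape::read.tree(text = cfg$tree)
  }
  qs <- run_quartet_sampling(
    aln, tree,
    qs_config(n_replicates = cfg$reps, min_overlap = cfg$min_overlap,
              lnl_cutoff = cfg$lnl_cutoff, max_attempts = cfg$max_attempts,
              engine = cfg$engine, seed = cfg$seed)
  )
  write_quartet_sampling(qs,
                         branches_path = file.path(cfg$out_dir, "qs_branches.tsv"),
                         taxa_path = file.path(cfg$out_dir, "qs_taxa.tsv"),
                         tree_path = file.path(cfg$out_dir, "qs_annotated.nwk"))
  qs
}

#' Pipeline entry point
#'
#' Dispatches the subcommands `simulate`, `filter`, `baba`, `qsample`, and
#' `all` (simulate, then filter, then both analyses on the simulated data).
#' Arguments are `--key value` flags plus an optional `--config file.yaml`;
#' flags override file values.  A resolved-config sidecar
#' (`run_config.yaml`) and a plain-text run log are written to the output
#' directory, so any result table can be regenerated from its logged config
#' and seed alone.  A thin executable wrapper suitable for
#' `Rscript` lives at `system.file("cli", "pentad", package = "pentad")`.
#'
#' @param argv character vector of command-line arguments (subcommand first).
#' @return Exit status, invisibly: 0 on success, 1 on error (with the
#'   diagnostic written to stderr).
#' @export
pentad_main <- function(argv) {
  status <- tryCatch({
    if (length(argv) == 0L) abort(
      "usage: pentad <simulate|filter|baba|qsample|all> [--config file.yaml] [--key value ...]")
    sub <- argv[[1L]]
    assert_that_(sub %in% c("simulate", "filter", "baba", "qsample", "all"),
                 sprintf("unknown subcommand '%s'", sub))
    rest <- argv[-1L]
    flags <- list(); config_path <- NULL
    i <- 1L
    while (i <= length(rest)) {
      a <- rest[[i]]
      assert_that_(startsWith(a, "--"), sprintf("expected a --flag, got '%s'", a))
      key <- sub("^--", "", a)
      assert_that_(i + 1L <= length(rest), sprintf("flag --%s needs a value", key))
      val <- rest[[i + 1L]]
      if (key == "config") config_path <- val else flags[[key]] <- val
      i <- i + 2L
    }
    cfg <- parse_run_config(config_path, flags)
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_log(cfg, cfg$out_dir, sub)
    switch(sub,
           simulate = run_simulate(cfg),
           filter = { run_simulate(cfg); run_filter(cfg) },
           baba = run_baba(cfg),
           qsample = run_qsample(cfg),
           all = {
             run_simulate(cfg)
             if (cfg$min_n > 0L) run_filter(cfg)
             run_baba(cfg)
             cfg_q <- cfg
             sim <- five_clade_config(seed = cfg$seed,
                                      n_per_clade = cfg$n_per_clade)
             cfg_q$tree <- cfg$tree %||%
               ape::write.tree(expand_species_tree(sim$model))
             provided <- attr(cfg, "provided") %||% character()
             if (!"min_overlap" %in% provided) cfg_q$min_overlap <- 0
             run_qsample(cfg_q)
           })
    0L
  }, error = function(e) {
    message("pentad error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
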