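#' Multiple sequence alignment container
#'
#' Sequences are stored as a character matrix (samples x columns) over
#' `{A,C,G,T,N,-}`.  `locus_bounds` optionally maps columns to loci as
#' half-open 0-based intervals `[start, end)`, tiling the columns without
#' overlap — the natural bookkeeping for a concatenated RAD alignment.
#'
#' @param seqs character matrix of single characters with sample ids as
#'   rownames, or a named character vector of equal-length strings.
#' @param locus_bounds optional data frame with columns `locus_id`, `start`,
#'   `end` (0-based, half-open).
#' @return An object of class `rad_alignment`.
#' @export
rad_alignment <- function(seqs, locus_bounds = NULL) {
  if (!is.matrix(seqs)) {
    assert_that_(!is.null(names(seqs)), "sequences must be named")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) abort("sequences have unequal lengths")
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
  }
  seqs <- toupper(seqs)
  seqs[!(seqs %in% c("A", "C", "G", "T", "-"))] <- "N"
  if (!is.null(locus_bounds)) {
    locus_bounds <- as_tibble(locus_bounds)
    assert_that_(all(c("locus_id", "start", "end") %in% names(locus_bounds)),
                 "locus_bounds needs locus_id, start, end")
    lb <- locus_bounds[order(locus_bounds$start), ]
    ok <- nrow(lb) == 0L ||
      (lb$start[1] == 0L && lb$end[nrow(lb)] == ncol(seqs) &&
         all(lb$start[-1] == lb$end[-nrow(lb)]))
    assert_that_(ok, "locus_bounds must tile the columns without overlap")
    locus_bounds <- lb
  }
  structure(list(seqs = seqs, locus_bounds = locus_bounds),
            class = "rad_alignment")
}

#' @export
print.rad_alignment <- function(x, ...) {
  nl <- if (is.null(x$locus_bounds)) "no locus map" else
    sprintf("%d loci", nrow(x$locus_bounds))
  cat(sprintf("<rad_alignment> %d sequences x %d columns (%s)\n",
              nrow(x$seqs), ncol(x$seqs), nl))
  invisible(x)
}

aln_samples <- function(a) rownames(a$seqs)
aln_length <- function(a) ncol(a$seqs)

#' Read an alignment from FASTA or relaxed PHYLIP
#'
#' FASTA parsing is delegated to [ape::read.FASTA()].  Relaxed sequential
#' PHYLIP (whitespace-separated name and sequence, names of any length) is
#' parsed directly.  Sequences are upper-cased and any ambiguity code other
#' than `N` is mapped to `N`.
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"`; guessed from the first character
#'   when `NULL`.
#' @return A [rad_alignment()].
#' @export
read_alignment <- function(path, format = NULL) {
  if (!file.exists(path)) abort(sprintf("alignment file not found: %s", path))
  if (is.null(format)) {
    first <- substr(trimws(readLines(path, n = 1L)), 1, 1)
    format <- if (first == ">") "fasta" else "phylip"
  }
  format <- match.arg(format, c("fasta", "phylip"))
  if (format == "fasta") {
    dna <- ape::read.FASTA(path)
    if (length(dna) == 0L) abort(sprintf("no sequences in %s", path))
    chr <- toupper(sapply(as.character(dna), paste, collapse = ""))
    lens <- nchar(chr)
    if (length(unique(lens)) > 1L) {
      abort(sprintf("ragged FASTA: lengths %s", paste(unique(lens), collapse = ", ")))
    }
    return(rad_alignment(chr))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 2L || anyNA(suppressWarnings(as.integer(hdr[1:2])))) {
    abort("malformed PHYLIP header")
  }
  ntax <- as.integer(hdr[1]); nchar_ <- as.integer(hdr[2])
  body <- lines[-1]
  if (length(body) != ntax) {
    abort(sprintf("PHYLIP header promises %d sequences, found %d records",
                  ntax, length(body)))
  }
  parts <- strsplit(trimws(body), "\\s+")
  nm <- vapply(parts, `[[`, "", 1L)
  sq <- vapply(parts, function(p) paste(p[-1], collapse = ""), "")
  if (any(nchar(sq) != nchar_)) {
    abort(sprintf("PHYLIP sequences do not all have stated length %d", nchar_))
  }
  rad_alignment(setNames(sq, nm))
}

#' Write an alignment to FASTA or relaxed PHYLIP
#'
#' @param aln a [rad_alignment()].
#' @param path output file path.
#' @inheritParams read_alignment
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  sq <- apply(aln$seqs, 1L, paste, collapse = "")
  if (format == "fasta") {
    out <- as.vector(rbind(paste0(">", names(sq)), sq))
  } else {
    out <- c(sprintf("%d %d", length(sq), aln_length(aln)),
             paste(names(sq), sq))
  }
  writeLines(out, path)
  invisible(path)
}

#' Extract biallelic SNPs from a haploid alignment
#'
#' Scans alignment columns and retains exactly those that are biallelic among
#' non-missing states (`N` and `-` are missing and excluded from the allele
#' tally).  The column's majority allele among non-missing sequences becomes
#' the reference (dosage 0), the minority allele the alternate (dosage 1);
#' ties are broken by alphabetical order, the earlier allele becoming the
#' reference.  Columns with three or more alleles, or fewer than two, are
#' dropped.
#'
#' @param aln a [rad_alignment()] of haploid sequences.
#' @return A [snp_matrix()]; empty (zero sites) when the alignment has no
#'   biallelic column.  `locus_id` and `position` come from the alignment's
#'   `locus_bounds` when present (positions 1-based within each locus),
#'   otherwise all sites belong to locus `"L1"` with global positions.
#' @export
alignment_to_snps <- function(aln) {
  s <- aln$seqs
  nseq <- nrow(s); ncol_ <- ncol(s)
  sample_names <- rownames(s)
  # per-column allele bookkeeping, vectorised over the four bases
  counts <- vapply(c("A", "C", "G", "T"),
                   function(b) colSums(s == b), numeric(ncol_))
  if (ncol_ == 1L) counts <- matrix(counts, nrow = 1L,
                                    dimnames = list(NULL, c("A", "C", "G", "T")))
  n_alleles <- rowSums(counts > 0)
  keep <- which(n_alleles == 2L)
  locus_of <- function(cols) {
    if (is.null(aln$locus_bounds)) {
      list(locus = rep("L1", length(cols)), pos = cols)
    } else {
      lb <- aln$locus_bounds
      i <- findInterval(cols - 1L, lb$start)  # cols 1-based, bounds 0-based
      list(locus = as.character(lb$locus_id[i]), pos = cols - lb$start[i])
    }
  }
  if (length(keep) == 0L) {
    return(snp_matrix(
      matrix(integer(), nrow = nseq, ncol = 0L,
             dimnames = list(sample_names, NULL)),
      tibble(locus_id = character(), position = integer(),
             ref = character(), alt = character()),
      ploidy = 1L
    ))
  }
  bases <- c("A", "C", "G", "T")
  dos <- matrix(NA_integer_, nrow = nseq, ncol = length(keep),
                dimnames = list(sample_names, NULL))
  ref <- alt <- character(length(keep))
  for (j in seq_along(keep)) {
    col <- keep[j]
    present <- bases[counts[col, ] > 0]
    cnt <- counts[col, present]
    # majority -> ref; alphabetical tie-break (bases are already sorted)
    ref_j <- present[which.max(cnt)]
    alt_j <- setdiff(present, ref_j)
    ref[j] <- ref_j; alt[j] <- alt_j
    obs <- s[, col]
    dos[obs == ref_j, j] <- 0L
    dos[obs == alt_j, j] <- 1L
  }
  lp <- locus_of(keep)
  snp_matrix(dos,
             tibble(locus_id = lp$locus, position = as.integer(lp$pos),
                    ref = ref, alt = alt),
             ploidy = 1L)
}
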