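#' Sample-to-clade assignment
#'
#' Maps every sample to exactly one clade and declares which clades form the
#' outgroup.  Pooling all samples of a clade into one population is what
#' turns per-sample genotypes into clade-level allele frequencies for the
#' D-statistics.
#'
#' @param assignment data frame with columns `sample_id`, `clade_id` (or a
#'   named character vector sample -> clade).
#' @param outgroup character vector of clade ids declared as outgroup; must
#'   be non-empty and present in the assignment.
#' @return An object of class `clade_map`.
#' @export
clade_map <- function(assignment, outgroup) {
  if (!is.data.frame(assignment)) {
    assignment <- tibble(sample_id = names(assignment),
                         clade_id = unname(assignment))
  }
  assignment <- as_tibble(assignment)[, c("sample_id", "clade_id")]
  dup <- assignment$sample_id[duplicated(assignment$sample_id)]
  if (length(dup) > 0L) {
    abort(sprintf("duplicated sample ids in clade map: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  assert_that_(length(outgroup) >= 1L, "outgroup clade set must be non-empty")
  missing_og <- setdiff(outgroup, assignment$clade_id)
  assert_that_(length(missing_og) == 0L,
               sprintf("outgroup clade(s) with no samples: %s",
                       paste(missing_og, collapse = ", ")))
  structure(list(assignment = assignment, outgroup = outgroup),
            class = "clade_map")
}

#' @export
print.clade_map <- function(x, ...) {
  tab <- table(x$assignment$clade_id)
  cat(sprintf("<clade_map> %d samples in %d clades (outgroup: %s)\n",
              nrow(x$assignment), length(tab),
              paste(x$outgroup, collapse = ", ")))
  invisible(x)
}

clades_of <- function(map) sort(unique(map$assignment$clade_id))

samples_in_clade <- function(map, clade) {
  map$assignment$sample_id[map$assignment$clade_id %in% clade]
}

#' Read a clade map from a TSV file
#'
#' Expects two or three tab-separated columns: `sample_id`, `clade_id`, and
#' optionally `outgroup` (logical flag or 0/1).  Alternatively the outgroup
#' clades can be declared in a header comment line `#outgroup: <id>,<id>`.
#'
#' @param path TSV file path.
#' @return A [clade_map()].
#' @export
read_clade_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("clade map not found: %s", path))
  lines <- readLines(path)
  og_hdr <- grep("^#\\s*outgroup\\s*:", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  df <- read.table(text = body, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  assert_that_(all(c("sample_id", "clade_id") %in% names(df)),
               "clade map needs sample_id and clade_id columns")
  if (length(og_hdr) > 0L) {
    og <- trimws(strsplit(sub("^#\\s*outgroup\\s*:", "", og_hdr[1]), ",")[[1]])
  } else if ("outgroup" %in% names(df)) {
    flag <- df$outgroup %in% c(TRUE, "TRUE", "true", 1, "1", "yes")
    og <- unique(df$clade_id[flag])
  } else {
    abort("no outgroup declared (use an 'outgroup' column or '#outgroup:' header)")
  }
  clade_map(df[, c("sample_id", "clade_id")], outgroup = og)
}

#' Write a clade map as TSV
#'
#' @param map a [clade_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clade_map <- function(map, path) {
  df <- map$assignment
  df$outgroup <- df$clade_id %in% map$outgroup
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
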