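# Quartet resolution engines.
#
# The ML engine scores the three unrooted quartet topologies under JC69 by
# Felsenstein pruning on site-pattern counts, optimizing the five branch
# lengths by cyclic one-dimensional search.  A parsimony engine is provided
# as a fast, independent alternative (used mainly to cross-check the ML
# engine on clean synthetic quartets).

BASES <- c("A", "C", "G", "T")

# encode a 4 x L character matrix into pattern counts over complete columns
quartet_patterns <- function(seqs) {
  ok <- matrix(seqs %in% BASES, nrow = 4L)
  keep <- colSums(ok) == 4L
  if (!any(keep)) return(NULL)
  s <- matrix(match(seqs[, keep, drop = FALSE], BASES), nrow = 4L)
  code <- (s[1L, ] - 1L) + 4L * (s[2L, ] - 1L) + 16L * (s[3L, ] - 1L) +
    64L * (s[4L, ] - 1L)
  cnt <- tabulate(code + 1L, nbins = 256L)
  idx <- which(cnt > 0L)
  list(
    counts = cnt[idx],
    states = rbind((idx - 1L) %% 4L + 1L,
                   ((idx - 1L) %/% 4L) %% 4L + 1L,
                   ((idx - 1L) %/% 16L) %% 4L + 1L,
                   ((idx - 1L) %/% 64L) %% 4L + 1L)
  )
}

# JC69 log-likelihood of topology ((a,b),(c,d)) given branch lengths
# t = (ta, tb, tc, td, t_internal); pat from quartet_patterns(), with rows of
# pat$states permuted so that taxa order is (a, b, c, d)
quartet_lnl <- function(t, pat) {
  e <- exp(-4 * t / 3)
  m <- 0.25 + 0.75 * e   # P(same)
  x <- 0.25 - 0.25 * e   # P(diff)
  P <- length(pat$counts)
  tip_lik <- function(k) {
    # 4 x P: P_tk(state_x -> observed state)
    obs <- pat$states[k, ]
    out <- matrix(x[k], nrow = 4L, ncol = P)
    out[cbind(obs, seq_len(P))] <- m[k]
    out
  }
  Lx <- tip_lik(1L) * tip_lik(2L)
  Ly <- tip_lik(3L) * tip_lik(4L)
  # sum over internal states with P5(x,y) = x5 + (m5 - x5) I(x == y)
  Sy <- colSums(Ly)
  inner <- x[5L] * matrix(Sy, nrow = 4L, ncol = P, byrow = TRUE) +
    (m[5L] - x[5L]) * Ly
  lik <- 0.25 * colSums(Lx * inner)
  sum(pat$counts * log(pmax(lik, 1e-300)))
}

# maximize quartet_lnl over branch lengths by cyclic 1-D search
optimize_quartet <- function(pat, tol = 1e-6, max_sweeps = 25L) {
  t <- rep(0.05, 5L)
  last <- quartet_lnl(t, pat)
  for (s in seq_len(max_sweeps)) {
    for (i in 1:5) {
      opt <- optimize(function(ti) {
        tt <- t; tt[i] <- ti
        quartet_lnl(tt, pat)
      }, interval = c(0, 10), maximum = TRUE, tol = tol)
      t[i] <- opt$maximum
    }
    cur <- quartet_lnl(t, pat)
    if (cur - last < tol) break
    last <- cur
  }
  quartet_lnl(t, pat)
}

# Fitch parsimony length of ((a,b),(c,d)) per pattern, vectorised
quartet_parsimony <- function(pat) {
  st <- pat$states
  # bitmask state sets
  b <- 2L^(st - 1L)
  f2 <- function(i, j) {
    inter <- bitwAnd(b[i, ], b[j, ])
    cost <- as.integer(inter == 0L)
    set <- ifelse(inter == 0L, bitwOr(b[i, ], b[j, ]), inter)
    list(set = set, cost = cost)
  }
  l <- f2(1L, 2L); r <- f2(3L, 4L)
  inter <- bitwAnd(l$set, r$set)
  total <- l$cost + r$cost + as.integer(inter == 0L)
  sum(pat$counts * total)
}

# taxa permutations putting each unrooted topology into ((a,b),(c,d)) form:
# topology 1 = (q1,q2 | q3,q4), 2 = (q1,q3 | q2,q4), 3 = (q1,q4 | q2,q3)
TOPOLOGY_PERMS <- list(c(1L, 2L, 3L, 4L), c(1L, 3L, 2L, 4L), c(1L, 4L, 2L, 3L))

#' Resolve a quartet from aligned sequences
#'
#' Evaluates the three unrooted topologies of four sequences and reports the
#' best-supported one.  The default engine computes maximum likelihood under
#' JC69 (Felsenstein pruning over site-pattern counts; five branch lengths
#' optimized by cyclic one-dimensional search, tolerance `1e-6`, at most 25
#' sweeps).  The quartet is *informative* when the best topology beats the
#' second-best by at least `cutoff` log-likelihood units (exact ties are
#' uninformative).  The parsimony engine scores topologies by Fitch length;
#' there a difference of at least one step is required.
#'
#' @param seqs 4 x L character matrix (rows = the four sampled taxa); only
#'   columns where all four carry a called base are used.
#' @param cutoff log-likelihood difference threshold (default 2).
#' @param engine `"ml"` (JC69 likelihood) or `"parsimony"`.
#' @return A list: `outcome` (1, 2, 3 for topology `(q1,q2|q3,q4)`,
#'   `(q1,q3|q2,q4)`, `(q1,q4|q2,q3)`, or `"uninformative"`), `delta` (the
#'   support difference), `n_columns` used.
#' @export
resolve_quartet <- function(seqs, cutoff = 2, engine = c("ml", "parsimony")) {
  engine <- match.arg(engine)
  pat <- quartet_patterns(seqs)
  if (is.null(pat)) abort("no shared non-missing columns among the four taxa")
  score <- vapply(TOPOLOGY_PERMS, function(perm) {
    p <- list(counts = pat$counts, states = pat$states[perm, , drop = FALSE])
    if (engine == "ml") optimize_quartet(p) else -quartet_parsimony(p)
  }, numeric(1L))
  ord <- order(score, decreasing = TRUE)
  delta <- score[ord[1L]] - score[ord[2L]]
  min_delta <- if (engine == "ml") cutoff else max(1, cutoff)
  outcome <- if (delta >= min_delta && delta > 1e-9) ord[1L] else "uninformative"
  list(outcome = outcome, delta = delta, n_columns = sum(pat$counts))
}
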