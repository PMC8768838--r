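#' Test whether two alignment columns are genealogically compatible
#'
#' Two polymorphic sites are compatible when a single genealogy can explain
#' both without homoplasy.  The check builds the bipartite graph joining
#' each state of site i to each state of site j observed together in some
#' sequence; the sites are compatible iff that graph is acyclic.  For two
#' biallelic sites this reduces to the four-gamete test.
#'
#' @param column_i,column_j Equal-length character vectors (one base per
#'   sequence).
#' @return `TRUE` if compatible, `FALSE` otherwise.
#' @export
site_compatibility <- function(column_i, column_j) {
  stopifnot(length(column_i) == length(column_j))
  joint <- unique(paste(column_i, column_j, sep = "\r"))
  states_i <- unique(column_i); states_j <- unique(column_j)
  n_i <- length(states_i)
  parent <- .uf_new(n_i + length(states_j))
  for (pair in strsplit(joint, "\r", fixed = TRUE)) {
    a <- match(pair[1L], states_i)
    b <- n_i + match(pair[2L], states_j)
    ra <- .uf_find(parent, a); rb <- .uf_find(parent, b)
    if (ra == rb) return(FALSE)  # edge closes a cycle
    parent[rb] <- ra
  }
  TRUE
}

# Parsimony-informative columns: >= 2 states each carried by >= 2 sequences.
.informative_columns <- function(m) {
  which(apply(m, 2L, function(col) {
    tab <- table(col)
    sum(tab >= 2L) >= 2L
  }))
}

#' PHI-style permutation test for recombination
#'
#' The statistic is the mean 0/1 incompatibility (see
#' [site_compatibility()]) over all pairs of parsimony-informative sites
#' whose alignment positions lie within `w` bp of each other.  Significance
#' is assessed by permuting the assignment of informative sites to their
#' observed positions, which destroys spatial clustering of incompatibility
#' while preserving its overall amount; the p-value uses the add-one
#' estimator.
#'
#' @param alignment Character vector of equal-length ACGT sequences.
#' @param w Window width in alignment positions (bp), default 100.
#' @param n_permutations Number of site-position permutations (default
#'   1000).
#' @param seed Optional integer seed making the permutation draw
#'   reproducible.
#' @return An object of class `phi_result`: `phi_statistic`,
#'   `n_informative_sites`, `w`, `n_permutations`, `seed`, `p_value`.
#' @export
phi_test <- function(alignment, w = 100L, n_permutations = 1000L,
                     seed = NULL) {
  stopifnot(length(alignment) >= 2L, n_permutations >= 1L, w >= 1L)
  alignment <- toupper(alignment)
  .check_dna(alignment)
  m <- seq_matrix(alignment)
  inf <- .informative_columns(m)
  k <- length(inf)
  if (k < 2L)
    stop("insufficient informative sites (need >= 2)", call. = FALSE)

  M <- matrix(0L, k, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    M[i, j] <- M[j, i] <- 1L - site_compatibility(m[, inf[i]], m[, inf[j]])

  pair_idx <- which(outer(inf, inf, function(a, b) b - a) >= 1L &
                    outer(inf, inf, function(a, b) abs(b - a)) <= w,
                    arr.ind = TRUE)
  if (nrow(pair_idx) == 0L)
    stop("no informative site pairs within window w = ", w, call. = FALSE)
  a <- pair_idx[, 1L]; b <- pair_idx[, 2L]
  observed <- mean(M[cbind(a, b)])

  if (!is.null(seed)) set.seed(seed)
  perm_ge <- 0L
  for (r in seq_len(n_permutations)) {
    s <- sample.int(k)
    if (mean(M[cbind(s[a], s[b])]) >= observed) perm_ge <- perm_ge + 1L
  }
  structure(list(phi_statistic = observed, n_informative_sites = k,
                 w = as.integer(w),
                 n_permutations = as.integer(n_permutations),
                 seed = seed,
                 p_value = (1 + perm_ge) / (1 + n_permutations)),
            class = "phi_result")
}

#' @export
print.phi_result <- function(x, ...) {
  cat(sprintf(
    "PHI test: statistic = %.4f over %d informative sites (w = %d bp), p = %.4g (%d permutations)\n",
    x$phi_statistic, x$n_informative_sites, x$w, x$p_value,
    x$n_permutations))
  invisible(x)
}

# Per-column base counts (4 x L matrix, rows A, C, G, T).
.base_counts <- function(m) {
  L <- ncol(m)
  cnt <- matrix(0L, 4L, L)
  for (b in 1:4)
    cnt[b, ] <- colSums(m == c("A", "C", "G", "T")[b])
  cnt
}

# Majority consensus (alphabetical tie-break) from a base-count matrix.
.consensus_from_counts <- function(cnt) {
  c("A", "C", "G", "T")[max.col(t(cnt), ties.method = "first")]
}

# Subgroup SNP positions: columns where the subgroup consensus differs from
# the complement consensus (majority rule, alphabetical tie-break).
# `total_counts` lets callers that sweep many labels reuse one count pass.
.subgroup_snps <- function(m, in_group, total_counts = NULL) {
  if (is.null(total_counts)) total_counts <- .base_counts(m)
  cnt_in <- .base_counts(m[in_group, , drop = FALSE])
  which(.consensus_from_counts(cnt_in) !=
        .consensus_from_counts(total_counts - cnt_in))
}

#' Scan a labeled alignment for clustered-SNP recombinant segments
#'
#' For each label, SNPs are the columns where the subgroup consensus
#' disagrees with the consensus of all other sequences.  Sliding windows
#' whose SNP count is improbably high under a binomial model at the
#' subgroup's genome-wide SNP rate (upper tail below `score_cutoff`) are
#' merged and trimmed to their outermost SNPs; each maximal segment is
#' reported with 0-based half-open coordinates.
#'
#' @param alignment Character vector of equal-length sequences (typically
#'   concatenated profiles).
#' @param group_labels Vector of labels, one per sequence; a label whose
#'   complement is empty is skipped.
#' @param window_bp Sliding window width in bp (default 200); a window
#'   wider than the alignment degrades to one whole-length window.
#' @param score_cutoff Binomial tail probability below which a window is
#'   called significant (default 1e-6).
#' @return Data frame with columns `label`, `start`, `end`, `snps_in`,
#'   `background_rate`, `score` (zero rows when nothing is found).
#' @export
scan_recombinant_segments <- function(alignment, group_labels,
                                      window_bp = 200L,
                                      score_cutoff = 1e-6) {
  if (length(alignment) == 0L) stop("empty alignment", call. = FALSE)
  stopifnot(length(group_labels) == length(alignment), window_bp >= 1L)
  alignment <- toupper(alignment)
  m <- seq_matrix(alignment)
  L <- ncol(m)
  win <- min(as.integer(window_bp), L)
  tot <- .base_counts(m)
  out <- list()
  for (lab in unique(group_labels)) {
    in_group <- group_labels == lab
    if (all(in_group)) next
    snps <- .subgroup_snps(m, in_group, tot)
    if (length(snps) == 0L) next
    rate <- length(snps) / L
    starts <- unique(c(seq(0L, L - win, by = max(1L, win %/% 4L)), L - win))
    hit <- logical(length(starts))
    for (i in seq_along(starts)) {
      kin <- sum(snps > starts[i] & snps <= starts[i] + win)
      hit[i] <- stats::pbinom(kin - 1L, win, rate,
                              lower.tail = FALSE) < score_cutoff
    }
    if (!any(hit)) next
    # merge overlapping significant windows into maximal runs
    sig <- starts[hit]
    runs <- split(sig, cumsum(c(TRUE, diff(sig) > win)))
    for (r in runs) {
      s0 <- min(r); e0 <- max(r) + win
      inside <- snps[snps > s0 & snps <= e0]
      if (length(inside) == 0L) next
      start <- inside[1L] - 1L; end <- inside[length(inside)]
      kin <- length(inside)
      score <- stats::pbinom(kin - 1L, end - start, rate,
                             lower.tail = FALSE)
      out[[length(out) + 1L]] <-
        data.frame(label = as.character(lab), start = start, end = end,
                   snps_in = kin, background_rate = rate, score = score,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(label = character(), start = integer(),
                      end = integer(), snps_in = integer(),
                      background_rate = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Simple r/m summary from scanned segments
#'
#' Partitions every subgroup SNP (as called by
#' [scan_recombinant_segments()]'s consensus rule) by inclusion in any
#' reported segment and returns the inside/outside ratio — a transparent
#' SNP-count analogue of the recombination-to-mutation ratio, labelled
#' `r_over_m_simple` to avoid conflation with model-based estimators.
#'
#' @param alignment,group_labels As in [scan_recombinant_segments()].
#' @param segments Data frame returned by [scan_recombinant_segments()].
#' @return List of class `rm_estimate`: `n_snps_in_segments`,
#'   `n_snps_outside`, `r_over_m_simple` (`Inf` when every SNP lies in a
#'   segment; 0 when no segment was found).
#' @export
estimate_r_over_m <- function(alignment, group_labels, segments) {
  stopifnot(length(group_labels) == length(alignment))
  m <- seq_matrix(toupper(alignment))
  tot <- .base_counts(m)
  n_in <- 0L; n_out <- 0L
  for (lab in unique(group_labels)) {
    in_group <- group_labels == lab
    if (all(in_group)) next
    snps <- .subgroup_snps(m, in_group, tot)
    if (!length(snps)) next
    inside <- rep(FALSE, length(snps))
    if (nrow(segments))
      for (r in seq_len(nrow(segments)))
        inside <- inside | (snps > segments$start[r] &
                            snps <= segments$end[r])
    n_in <- n_in + sum(inside)
    n_out <- n_out + sum(!inside)
  }
  ratio <- if (n_in == 0L) 0 else if (n_out == 0L) Inf else n_in / n_out
  structure(list(n_snps_in_segments = n_in, n_snps_outside = n_out,
                 r_over_m_simple = ratio),
            class = "rm_estimate")
}

#' @export
print.rm_estimate <- function(x, ...) {
  cat(sprintf("r/m (simple SNP partition): %s  (%d SNPs in segments, %d outside)\n",
              format(x$r_over_m_simple), x$n_snps_in_segments,
              x$n_snps_outside))
  invisible(x)
}
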