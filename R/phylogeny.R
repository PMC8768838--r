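#' Kimura two-parameter distance between two sequences
#'
#' Separates transition (A/G, C/T) from transversion differences:
#' with P and Q their per-site fractions, d = -(1/2) ln((1 - 2P - Q)
#' sqrt(1 - 2Q)).  Saturated pairs (log argument non-positive) return an
#' `NA` distance with a warning.
#'
#' @param seq_a,seq_b Equal-length uppercase ACGT strings.
#' @return An object of class `k2p` with fields `p_transition`,
#'   `q_transversion`, `distance`.
#' @examples
#' k2p_distance("AAAA", "GAAA")$distance  # -(1/2) log(0.5)
#' @export
k2p_distance <- function(seq_a, seq_b) {
  stopifnot(nchar(seq_a) == nchar(seq_b))
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  .check_dna(c(seq_a, seq_b))
  a <- strsplit(seq_a, "", fixed = TRUE)[[1L]]
  b <- strsplit(seq_b, "", fixed = TRUE)[[1L]]
  L <- length(a)
  neq <- a != b
  purine_a <- a %in% c("A", "G"); purine_b <- b %in% c("A", "G")
  ts <- neq & (purine_a == purine_b)   # A<->G or C<->T
  P <- sum(ts) / L
  Q <- sum(neq & !ts) / L
  arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
  d <- if (arg1 <= 0 || arg2 <= 0) {
    warning("K2P distance saturated; returning NA", call. = FALSE)
    NA_real_
  } else -0.5 * log(arg1 * sqrt(arg2))
  structure(list(p_transition = P, q_transversion = Q, distance = d),
            class = "k2p")
}

#' @export
print.k2p <- function(x, ...) {
  cat(sprintf("K2P: P = %.4f, Q = %.4f, d = %s\n", x$p_transition,
              x$q_transversion,
              ifelse(is.na(x$distance), "NA (saturated)",
                     sprintf("%.6f", x$distance))))
  invisible(x)
}

#' Pairwise K2P distance matrix
#'
#' @param sequences Named character vector of equal-length ACGT sequences.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
k2p_matrix <- function(sequences) {
  stopifnot(length(sequences) >= 2L)
  sequences <- toupper(sequences)
  .check_dna(sequences)
  m <- seq_matrix(sequences)
  n <- nrow(m)
  L <- ncol(m)
  # one-hot indicator per base; pairwise match/transition counts by
  # cross-products so large collections stay fast
  X <- lapply(c("A", "C", "G", "T"), function(b) (m == b) * 1)
  same <- Reduce(`+`, lapply(X, function(x) tcrossprod(x)))
  ts_n <- tcrossprod(X[[1]], X[[3]]); ts_n <- ts_n + t(ts_n)
  ct <- tcrossprod(X[[2]], X[[4]]); ts_n <- ts_n + ct + t(ct)
  P <- ts_n / L
  Q <- (L - same - ts_n) / L
  arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
  D <- matrix(NA_real_, n, n,
              dimnames = list(names(sequences), names(sequences)))
  ok <- arg1 > 0 & arg2 > 0
  D[ok] <- -0.5 * log(arg1[ok] * sqrt(arg2[ok]))
  diag(D) <- 0
  if (anyNA(D)) warning("saturated (NA) K2P distances present",
                        call. = FALSE)
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via [ape::nj()]).  Negative branch
#' lengths, an occasional artifact of NJ on non-additive matrices, are by
#' default clamped to zero with the deficit transferred to the adjacent
#' branch so path lengths are preserved as far as possible.
#'
#' @param distance_matrix Symmetric numeric matrix, zero diagonal, >= 3
#'   taxa, with dimnames giving taxon labels.
#' @param negative `"clamp_transfer"` (default) or `"keep"` raw NJ branch
#'   lengths.
#' @return An unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(distance_matrix,
                             negative = c("clamp_transfer", "keep")) {
  negative <- match.arg(negative)
  D <- as.matrix(distance_matrix)
  if (nrow(D) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (anyNA(D)) stop("distance matrix contains NA", call. = FALSE)
  if (any(abs(D - t(D)) > 1e-12) || any(diag(D) != 0))
    stop("matrix must be symmetric with zero diagonal", call. = FALSE)
  if (is.null(rownames(D)))
    dimnames(D) <- list(paste0("t", seq_len(nrow(D))),
                        paste0("t", seq_len(nrow(D))))
  tree <- ape::nj(D)
  if (negative == "clamp_transfer" && any(tree$edge.length < 0)) {
    repeat {
      neg <- which(tree$edge.length < 0)
      if (!length(neg)) break
      e <- neg[1L]
      parent <- tree$edge[e, 1L]
      deficit <- tree$edge.length[e]
      tree$edge.length[e] <- 0
      adj <- setdiff(which(tree$edge[, 1L] == parent |
                           tree$edge[, 2L] == parent), e)
      if (length(adj)) {
        tree$edge.length[adj[1L]] <- tree$edge.length[adj[1L]] + deficit
        if (tree$edge.length[adj[1L]] < 0) tree$edge.length[adj[1L]] <- 0
      }
    }
  }
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the K2P + NJ tree
#' per replicate, and reports for each internal bipartition of the
#' point-estimate tree the percentage of replicates containing it
#' (attached as `node.label`).  Replicates whose resampled alignment is
#' degenerate (all sequences identical, or saturated distances) are skipped
#' but still counted in the denominator, and reported via a message.
#'
#' @param alignment Named character vector of equal-length ACGT sequences
#'   (>= 4 taxa).
#' @param n_replicates Number of bootstrap replicates (conventionally
#'   1,000).
#' @param seed Optional integer seed.
#' @return The point-estimate tree with `node.label` support percentages.
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000L,
                              seed = NULL) {
  stopifnot(length(alignment) >= 4L, n_replicates >= 1L)
  if (is.null(names(alignment)))
    names(alignment) <- paste0("t", seq_along(alignment))
  point <- neighbor_joining(k2p_matrix(alignment))
  m <- seq_matrix(alignment)
  if (!is.null(seed)) set.seed(seed)
  reps <- list(); skipped <- 0L
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    rm_ <- m[, cols, drop = FALSE]
    seqs <- stats::setNames(collapse_rows(rm_), names(alignment))
    if (length(unique(seqs)) == 1L) { skipped <- skipped + 1L; next }
    D <- suppressWarnings(k2p_matrix(seqs))
    if (anyNA(D)) { skipped <- skipped + 1L; next }
    reps[[length(reps) + 1L]] <- neighbor_joining(D)
  }
  if (skipped)
    message(skipped, " degenerate bootstrap replicate(s) skipped")
  counts <- if (length(reps))
    ape::prop.clades(point, reps, rooted = FALSE) else
    rep(0L, point$Nnode)
  counts[is.na(counts)] <- 0L
  point$node.label <- round(100 * counts / n_replicates, 1)
  point
}

#' Which leaf labels form monophyletic groups on an unrooted tree?
#'
#' A label is monophyletic iff some edge of the unrooted tree bipartitions
#' exactly that label's leaves from all others (labels covering a single
#' leaf, or every leaf, are trivially monophyletic).
#'
#' @param tree An [ape::phylo] tree.
#' @param label_map Named character vector: `names()` are tip labels of
#'   `tree`, values are group labels; every tip must be covered.
#' @return Named logical vector, one entry per group label.
#' @export
check_group_monophyly <- function(tree, label_map) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!all(tips %in% names(label_map)))
    stop("unlabeled leaves: ",
         paste(setdiff(tips, names(label_map)), collapse = ", "),
         call. = FALSE)
  lab <- label_map[tips]
  n <- length(tips)
  parts <- lapply(ape::prop.part(tree), sort)
  vapply(stats::setNames(unique(lab), unique(lab)), function(g) {
    set <- sort(unname(which(lab == g)))
    k <- length(set)
    if (k <= 1L || k >= n - 1L) return(TRUE)  # pendant edge always exists
    comp <- sort(setdiff(seq_len(n), set))
    any(vapply(parts, function(p)
      identical(p, set) || identical(p, comp), TRUE))
  }, TRUE)
}

#' NJ tree over one representative sequence per ST
#'
#' Convenience wrapper reproducing the concatenated-ST phylogeny: takes one
#' isolate per sequence type, concatenates its loci, computes K2P distances
#' and returns the NJ tree with tips labelled `ST<k>` (optionally with
#' bootstrap support).
#'
#' @param fit An [mlst()] fit.
#' @param bootstrap Number of bootstrap replicates (0 = none).
#' @param seed Optional seed for the bootstrap.
#' @return An [ape::phylo] tree.
#' @export
st_tree <- function(fit, bootstrap = 0L, seed = NULL) {
  stopifnot(inherits(fit, "mlst"))
  if (nrow(fit$st_table$profiles) < 3L)
    stop("need at least 3 STs", call. = FALSE)
  reps <- vapply(fit$st_table$isolates, `[[`, "", 1L)
  seqs <- stats::setNames(concat_sequences(fit$dataset)[reps],
                          paste0("ST", names(fit$st_table$isolates)))
  if (bootstrap > 0L) bootstrap_support(seqs, bootstrap, seed)
  else neighbor_joining(k2p_matrix(seqs))
}
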