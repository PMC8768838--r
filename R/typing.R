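#' Trim a raw locus sequence to the scheme frame
#'
#' Finds the ungapped window of the scheme's trimmed length with minimum
#' Hamming distance to the locus reference allele (leftmost window on ties)
#' and returns it.  A sequence already at the trimmed length is returned
#' unchanged.
#'
#' @param raw_seq Raw uppercase ACGT sequence, at least as long as the
#'   scheme trimmed length.
#' @param scheme A [locus_scheme()] carrying reference alleles.
#' @param locus Locus name.
#' @param min_identity Identity floor for the best window (default 0.80);
#'   below it the sequence is rejected as not matching the locus.
#' @return The trimmed sequence of exactly the scheme length.
#' @export
trim_to_scheme <- function(raw_seq, scheme, locus, min_identity = 0.80) {
  stopifnot(inherits(scheme, "locus_scheme"))
  if (is.null(scheme$reference) || !locus %in% names(scheme$reference))
    stop("scheme has no reference allele for locus ", locus, call. = FALSE)
  raw_seq <- toupper(raw_seq)
  .check_dna(raw_seq, paste("locus", locus))
  L <- scheme_lengths(scheme)[[locus]]
  R <- nchar(raw_seq)
  if (R < L)
    stop(sprintf("locus %s: raw sequence (%d bp) shorter than trimmed length %d",
                 locus, R, L), call. = FALSE)
  if (R == L) return(raw_seq)
  ref <- strsplit(scheme$reference[[locus]], "", fixed = TRUE)[[1L]]
  raw <- strsplit(raw_seq, "", fixed = TRUE)[[1L]]
  n_win <- R - L + 1L
  mism <- vapply(seq_len(n_win), function(s)
    sum(raw[s:(s + L - 1L)] != ref), 0L)
  best <- which.min(mism)  # leftmost on ties
  if (1 - mism[best] / L < min_identity)
    stop(sprintf("locus %s: best window identity %.3f below floor %.2f",
                 locus, 1 - mism[best] / L, min_identity), call. = FALSE)
  substr(raw_seq, best, best + L - 1L)
}

#' Create an empty allele catalog
#'
#' An allele catalog maps each distinct trimmed sequence of a locus to a
#' positive integer allele number, contiguous from 1 in first-seen order.
#' Numbers are arbitrary labels; every downstream statistic is invariant
#' under their permutation.
#'
#' @param scheme A [locus_scheme()].
#' @return An object of class `allele_catalog` (per-locus ordered sequence
#'   vectors; the index of a sequence is its allele number).
#' @export
allele_catalog <- function(scheme = default_scheme()) {
  structure(stats::setNames(rep(list(character()), nrow(scheme$loci)),
                            scheme_loci(scheme)),
            class = "allele_catalog")
}

#' Assign (or look up) one allele number
#'
#' A known sequence returns its existing number; a novel sequence is
#' appended with number `max + 1`.
#'
#' @param catalog An [allele_catalog()].
#' @param locus Locus name.
#' @param seq Trimmed sequence (lowercase accepted; ambiguity codes are an
#'   error — no allele is called on ambiguous sequence).
#' @return List with elements `catalog` (possibly extended) and `allele`
#'   (integer).
#' @export
assign_allele <- function(catalog, locus, seq) {
  stopifnot(inherits(catalog, "allele_catalog"),
            locus %in% names(catalog))
  seq <- toupper(seq)
  .check_dna(seq, paste("locus", locus))
  known <- catalog[[locus]]
  if (length(known) && nchar(known[1L]) != nchar(seq))
    stop(sprintf("locus %s: sequence length %d != catalog allele length %d",
                 locus, nchar(seq), nchar(known[1L])), call. = FALSE)
  i <- match(seq, known)
  if (is.na(i)) {
    catalog[[locus]] <- c(known, seq)
    i <- length(known) + 1L
  }
  list(catalog = catalog, allele = as.integer(i))
}

#' Assign sequence types to allelic profiles
#'
#' Distinct six-allele profiles get distinct ST numbers, contiguous from 1
#' in order of first appearance.
#'
#' @param profiles Integer matrix of allele numbers, one row per isolate
#'   (rownames = isolate ids), one column per locus in scheme order.
#' @return An object of class `st_table`: list with `profiles` (one row per
#'   ST), `st_of_isolate` (named integer) and `isolates` (list of isolate
#'   ids per ST).
#' @export
assign_sts <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (anyNA(profiles) || any(profiles < 1))
    stop("incomplete allelic profile", call. = FALSE)
  storage.mode(profiles) <- "integer"
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("iso", seq_len(nrow(profiles)))
  key <- apply(profiles, 1L, paste, collapse = "_")
  st <- match(key, unique(key))
  st_profiles <- profiles[!duplicated(key), , drop = FALSE]
  rownames(st_profiles) <- seq_len(nrow(st_profiles))
  structure(list(profiles = st_profiles,
                 st_of_isolate = stats::setNames(st, rownames(profiles)),
                 isolates = split(rownames(profiles), st)),
            class = "st_table")
}

#' @export
print.st_table <- function(x, ...) {
  cat("ST table:", nrow(x$profiles), "STs over",
      length(x$st_of_isolate), "isolates\n")
  invisible(x)
}

# Isolate count per ST, named by ST number.
st_counts <- function(st_table) {
  stats::setNames(lengths(st_table$isolates), names(st_table$isolates))
}

#' Number of loci at which two allelic profiles differ
#'
#' The edge weight of the MST and the variant level of goeBURST: 0 for
#' identical profiles, 1 for a single-locus variant (SLV), up to the number
#' of scheme loci.
#'
#' @param p1,p2 Complete allele-number vectors of equal length.
#' @return Integer distance.
#' @export
profile_distance <- function(p1, p2) {
  stopifnot(length(p1) == length(p2), !anyNA(p1), !anyNA(p2))
  sum(p1 != p2)
}

#' Type an isolate collection: alleles, profiles and sequence types
#'
#' The central fitting-style entry point.  Takes a dataset whose sequences
#' are already at the scheme lengths (or raw sequences together with
#' `trim = TRUE` and a reference-bearing scheme), builds or extends an
#' allele catalog, assigns allelic profiles and STs, and returns a classed
#' fit with `print`, `summary` and `plot` methods.
#'
#' @param dataset An [mlst_dataset()].
#' @param catalog Optional preloaded [allele_catalog()] (e.g. from an
#'   earlier run) to keep allele numbering stable across datasets.
#' @param trim If `TRUE`, raw sequences are first passed through
#'   [trim_to_scheme()].
#' @param min_identity Identity floor forwarded to [trim_to_scheme()].
#' @return An object of class `mlst`: list with `profiles` (data frame:
#'   `isolate`, `ST`, one allele column per locus), `catalog`, `st_table`,
#'   `dataset`, `scheme`.
#' @examples
#' sim <- simulate_mlst(sim_config(isolates_per_lineage = c(4, 4, 4), seed = 1))
#' fit <- mlst(sim$dataset)
#' fit
#' @export
mlst <- function(dataset, catalog = NULL, trim = FALSE, min_identity = 0.80) {
  stopifnot(inherits(dataset, "mlst_dataset"))
  scheme <- dataset$scheme
  loci <- scheme_loci(scheme)
  if (trim) {
    for (lc in loci)
      dataset$sequences[[lc]] <- vapply(
        dataset$sequences[[lc]], trim_to_scheme, "", scheme = scheme,
        locus = lc, min_identity = min_identity)
    dataset <- mlst_dataset(dataset$sequences, dataset$metadata, scheme)
  }
  lens <- scheme_lengths(scheme)
  for (lc in loci)
    if (!all(nchar(dataset$sequences[[lc]]) == lens[[lc]]))
      stop("sequences not at scheme lengths; run with trim = TRUE",
           call. = FALSE)
  if (is.null(catalog)) catalog <- allele_catalog(scheme)
  stopifnot(inherits(catalog, "allele_catalog"))
  ids <- dataset$metadata$isolate_id
  prof <- matrix(NA_integer_, nrow = length(ids), ncol = length(loci),
                 dimnames = list(ids, loci))
  for (lc in loci) {
    seqs <- dataset$sequences[[lc]]
    # first-seen numbering, vectorized against the (possibly preloaded) catalog
    for (id in ids) {
      res <- assign_allele(catalog, lc, seqs[[id]])
      catalog <- res$catalog
      prof[id, lc] <- res$allele
    }
  }
  st_table <- assign_sts(prof)
  profiles <- data.frame(isolate = ids,
                         ST = unname(st_table$st_of_isolate[ids]),
                         prof, stringsAsFactors = FALSE, row.names = NULL)
  structure(list(profiles = profiles, catalog = catalog,
                 st_table = st_table, dataset = dataset, scheme = scheme),
            class = "mlst")
}

#' @export
print.mlst <- function(x, ...) {
  n <- nrow(x$profiles)
  n_st <- nrow(x$st_table$profiles)
  cat("MLST typing of", n, "isolates on",
      length(scheme_loci(x$scheme)), "loci\n")
  cat("  distinct STs:", n_st, "\n")
  cat("  alleles per locus:",
      paste(sprintf("%s=%d", scheme_loci(x$scheme),
                    lengths(x$catalog)[scheme_loci(x$scheme)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Summarize an MLST fit
#'
#' Reports ST richness, the largest STs, and the clonal-complex (SLV-level)
#' and BURST-group (DLV-level) partitions from [goeburst_groups()].
#'
#' @param object An [mlst()] fit.
#' @param ... Unused.
#' @return An object of class `summary.mlst`.
#' @export
summary.mlst <- function(object, ...) {
  counts <- sort(st_counts(object$st_table), decreasing = TRUE)
  cc <- goeburst_groups(object$st_table, level = 1L)
  bg <- goeburst_groups(object$st_table, level = 2L)
  out <- list(n_isolates = nrow(object$profiles),
              n_sts = nrow(object$st_table$profiles),
              largest_sts = utils::head(counts, 5L),
              cc = summarize_complexes(cc, object$st_table),
              bg = summarize_complexes(bg, object$st_table),
              n_singleton_cc = sum(vapply(cc, function(g)
                length(g$members) == 1L, TRUE)),
              n_singleton_bg = sum(vapply(bg, function(g)
                length(g$members) == 1L, TRUE)))
  class(out) <- "summary.mlst"
  out
}

#' @export
print.summary.mlst <- function(x, ...) {
  cat(x$n_isolates, "isolates typed into", x$n_sts, "STs\n")
  cat("Largest STs (isolate counts):",
      paste(sprintf("ST%s=%d", names(x$largest_sts), x$largest_sts),
            collapse = ", "), "\n")
  cc_multi <- x$cc[x$cc$n_STs > 1L, , drop = FALSE]
  cat("Clonal complexes (SLV level):", nrow(cc_multi), "multi-ST complexes,",
      x$n_singleton_cc, "singleton STs\n")
  if (nrow(cc_multi))
    print(utils::head(cc_multi[, c("group_id", "founder", "n_STs",
                                   "n_isolates")], 10L), row.names = FALSE)
  bg_multi <- x$bg[x$bg$n_STs > 1L, , drop = FALSE]
  cat("BURST groups (DLV level):", nrow(bg_multi), "multi-ST groups,",
      x$n_singleton_bg, "singleton STs\n")
  invisible(x)
}

#' Plot the minimum spanning tree of an MLST fit
#'
#' Draws the [build_mst()] tree with vertex size proportional to the square
#' root of each ST's isolate count, the classic MST population snapshot.
#'
#' @param x An [mlst()] fit.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.mlst <- function(x, ...) {
  mst <- build_mst(x$st_table)
  counts <- st_counts(x$st_table)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(mst$st_a), to = as.character(mst$st_b)),
    directed = FALSE,
    vertices = data.frame(name = names(counts)))
  igraph::plot.igraph(
    g, vertex.size = 4 + 3 * sqrt(counts[igraph::V(g)$name]),
    vertex.label.cex = 0.6, edge.label = mst$weight,
    edge.label.cex = 0.6, ...)
  invisible(x)
}
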