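# Internal helpers shared across modules.

.check_dna <- function(seqs, what = "sequence") {
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    s <- seqs[bad][1L]
    pos <- regexpr("[^ACGT]", s)
    stop(sprintf("%s contains non-ACGT character '%s' at position %d",
                 what, substr(s, pos, pos), pos), call. = FALSE)
  }
  invisible(TRUE)
}

# Character matrix with one row per sequence (all equal length).
seq_matrix <- function(seqs) {
  n <- unique(nchar(seqs))
  if (length(n) != 1L)
    stop("sequences must have equal length", call. = FALSE)
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

collapse_rows <- function(m) apply(m, 1L, paste, collapse = "")

# Majority-rule consensus of a character matrix; ties broken alphabetically.
consensus_seq <- function(m) {
  apply(m, 2L, function(col) {
    tab <- table(col)
    names(tab)[which.max(tab)]  # which.max: first of ties, names sorted
  })
}

#' Concatenate per-locus sequences in canonical scheme order
#'
#' @param dataset An `mlst_dataset` (see [mlst_dataset()]).
#' @return Named character vector, one concatenated sequence per isolate.
#' @export
concat_sequences <- function(dataset) {
  stopifnot(inherits(dataset, "mlst_dataset"))
  ids <- dataset$metadata$isolate_id
  out <- vapply(ids, function(id) {
    paste(vapply(scheme_loci(dataset$scheme),
                 function(lc) dataset$sequences[[lc]][[id]], ""),
          collapse = "")
  }, "")
  names(out) <- ids
  out
}

#' Bundle per-locus sequences and isolate metadata into a dataset
#'
#' The canonical in-memory container consumed by the typing, diversity,
#' recombination and phylogeny stages: one aligned-length sequence per
#' isolate per scheme locus, plus an isolate metadata table.
#'
#' @param sequences Named list, one element per scheme locus, each a named
#'   character vector of uppercase ACGT sequences keyed by isolate id.
#' @param metadata Data frame with at least a column `isolate_id`; `region`
#'   and `source` columns are added (as `"unknown"`) when absent.
#' @param scheme A [locus_scheme()].
#' @param check_lengths If `TRUE` (default), require every sequence to match
#'   the scheme trimmed length; set `FALSE` for raw, untrimmed input destined
#'   for [trim_to_scheme()].
#' @return An object of class `mlst_dataset`.
#' @export
mlst_dataset <- function(sequences, metadata, scheme = default_scheme(),
                         check_lengths = TRUE) {
  stopifnot(inherits(scheme, "locus_scheme"), is.list(sequences))
  loci <- scheme_loci(scheme)
  missing <- setdiff(loci, names(sequences))
  if (length(missing))
    stop("missing loci: ", paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(sequences), loci)
  if (length(extra))
    stop("unknown loci: ", paste(extra, collapse = ", "), call. = FALSE)
  if (!is.data.frame(metadata) || !"isolate_id" %in% names(metadata))
    stop("metadata must be a data.frame with an isolate_id column",
         call. = FALSE)
  metadata$isolate_id <- as.character(metadata$isolate_id)
  if (anyDuplicated(metadata$isolate_id))
    stop("duplicate isolate ids in metadata", call. = FALSE)
  for (col in c("region", "source"))
    if (!col %in% names(metadata)) metadata[[col]] <- "unknown"
  ids <- metadata$isolate_id
  lens <- scheme_lengths(scheme)
  for (lc in loci) {
    s <- sequences[[lc]]
    if (!all(ids %in% names(s)))
      stop(sprintf("locus %s missing sequences for isolates: %s", lc,
                   paste(setdiff(ids, names(s)), collapse = ", ")),
           call. = FALSE)
    s <- toupper(s[ids])
    .check_dna(s, paste("locus", lc))
    if (check_lengths && !all(nchar(s) == lens[[lc]]))
      stop(sprintf("locus %s: sequence length != scheme length %d", lc,
                   lens[[lc]]), call. = FALSE)
    sequences[[lc]] <- s
  }
  structure(list(sequences = sequences[loci], metadata = metadata,
                 scheme = scheme),
            class = "mlst_dataset")
}

#' @export
print.mlst_dataset <- function(x, ...) {
  cat("MLST dataset:", nrow(x$metadata), "isolates,",
      length(x$sequences), "loci (",
      paste(scheme_loci(x$scheme), collapse = ", "), ")\n")
  invisible(x)
}
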