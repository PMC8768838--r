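# Canonical locus order (alphabetical, matching the scheme table row order).
.mlst_loci <- c("clpC", "fusA", "ileS", "purF", "rplB", "rpoB")
.mlst_lengths <- c(clpC = 600L, fusA = 664L, ileS = 487L, purF = 574L,
                   rplB = 355L, rpoB = 497L)

#' Define a multilocus typing scheme
#'
#' A locus scheme fixes the locus names, the trimmed fragment length of each
#' locus, the reading-frame offset used for codon-based statistics, and
#' (optionally) one reference allele per locus used to anchor trimming of raw
#' sequences.
#'
#' @param names Character vector of locus names.
#' @param lengths Integer vector of trimmed fragment lengths (bp), one per
#'   locus.
#' @param frame_offsets Integer vector in \{0, 1, 2\}: number of leading bases
#'   to skip before the first complete codon.  Defaults to 0 for every locus.
#' @param reference_alleles Optional named character vector of reference
#'   allele sequences (names must match `names`, lengths must match
#'   `lengths`).  Required only by [trim_to_scheme()].
#' @return An object of class `locus_scheme`.
#' @seealso [default_scheme()]
#' @export
locus_scheme <- function(names, lengths, frame_offsets = NULL,
                         reference_alleles = NULL) {
  stopifnot(is.character(names), length(names) >= 1L,
            !anyDuplicated(names), length(lengths) == length(names))
  lengths <- as.integer(lengths)
  if (any(lengths < 3L)) stop("locus lengths must be >= 3 bp")
  if (is.null(frame_offsets)) frame_offsets <- rep(0L, length(names))
  frame_offsets <- as.integer(frame_offsets)
  stopifnot(length(frame_offsets) == length(names),
            all(frame_offsets %in% 0:2))
  if (!is.null(reference_alleles)) {
    stopifnot(is.character(reference_alleles),
              all(names %in% base::names(reference_alleles)))
    reference_alleles <- toupper(reference_alleles[names])
    if (!all(nchar(reference_alleles) == lengths))
      stop("reference allele lengths must equal the scheme trimmed lengths")
    .check_dna(reference_alleles, "reference allele")
  }
  structure(list(loci = data.frame(name = names, length = lengths,
                                   frame_offset = frame_offsets,
                                   stringsAsFactors = FALSE),
                 reference = reference_alleles),
            class = "locus_scheme")
}

#' The default six-locus B. longum scheme
#'
#' Six housekeeping loci (`clpC`, `fusA`, `ileS`, `purF`, `rplB`, `rpoB`) with
#' trimmed lengths 600, 664, 487, 574, 355 and 497 bp; the concatenated
#' profile sequence is 3,177 bp.
#'
#' @param reference_alleles Optional named character vector of reference
#'   alleles (see [locus_scheme()]).
#' @return A `locus_scheme` object.
#' @examples
#' sc <- default_scheme()
#' sum(sc$loci$length)  # 3177
#' @export
default_scheme <- function(reference_alleles = NULL) {
  locus_scheme(.mlst_loci, unname(.mlst_lengths),
               reference_alleles = reference_alleles)
}

#' @export
print.locus_scheme <- function(x, ...) {
  cat("Locus scheme:", nrow(x$loci), "loci,",
      sum(x$loci$length), "bp concatenated\n")
  df <- x$loci
  df$reference <- if (is.null(x$reference)) "-" else "yes"
  print(df, row.names = FALSE)
  invisible(x)
}

scheme_loci <- function(scheme) scheme$loci$name
scheme_lengths <- function(scheme) {
  stats::setNames(scheme$loci$length, scheme$loci$name)
}

# Locus boundaries on the concatenated sequence, 0-based half-open.
scheme_offsets <- function(scheme) {
  len <- scheme$loci$length
  start <- cumsum(c(0L, len[-length(len)]))
  data.frame(name = scheme$loci$name, start = start, end = start + len)
}
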