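#' Read per-locus multi-FASTA sequences
#'
#' Reads FASTA records whose headers follow the `isolateID|locus` convention
#' (one record per isolate per locus) and groups them by isolate.  A file
#' holding a single locus without `|` separators can be read by naming that
#' locus via `locus`.
#'
#' @param path One or more FASTA file paths.
#' @param scheme A [locus_scheme()]; loci found in headers must belong to it.
#' @param locus Optional locus name: treat every record in `path` as this
#'   locus and use the full header as the isolate id.
#' @return A named list, one element per scheme locus present, each a named
#'   character vector keyed by isolate id.  Isolates missing one or more
#'   loci are reported in a warning and listed in the `"incomplete"`
#'   attribute.
#' @export
read_locus_fasta <- function(path, scheme = default_scheme(), locus = NULL) {
  recs <- list()
  for (p in path) {
    set <- Biostrings::readDNAStringSet(p)
    if (length(set) == 0L) {
      warning("empty FASTA file: ", p, call. = FALSE)
      next
    }
    hdr <- sub("\\s.*$", "", names(set))
    if (is.null(locus)) {
      if (any(!grepl("|", hdr, fixed = TRUE)))
        stop("FASTA header lacks the 'isolateID|locus' separator: ",
             hdr[!grepl("|", hdr, fixed = TRUE)][1L], call. = FALSE)
      iso <- sub("\\|[^|]*$", "", hdr)
      lc <- sub("^.*\\|", "", hdr)
    } else {
      iso <- hdr
      lc <- rep(locus, length(hdr))
    }
    bad <- setdiff(unique(lc), scheme_loci(scheme))
    if (length(bad))
      stop("unknown locus in FASTA headers: ", paste(bad, collapse = ", "),
           call. = FALSE)
    seqs <- toupper(as.character(set))
    for (i in seq_along(seqs)) {
      if (grepl("[^ACGT]", seqs[i])) {
        pos <- regexpr("[^ACGT]", seqs[i])
        stop(sprintf("non-ACGT character at position %d in record %s",
                     pos, hdr[i]), call. = FALSE)
      }
      if (iso[i] %in% names(recs[[lc[i]]]))
        stop(sprintf("duplicate record for isolate %s, locus %s",
                     iso[i], lc[i]), call. = FALSE)
      recs[[lc[i]]] <- c(recs[[lc[i]]],
                         stats::setNames(seqs[i], iso[i]))
    }
  }
  if (!length(recs)) return(structure(list(), incomplete = character()))
  ids <- unique(unlist(lapply(recs, names)))
  complete <- vapply(ids, function(id)
    all(vapply(recs, function(s) id %in% names(s), TRUE)), TRUE)
  incomplete <- ids[!complete]
  if (length(incomplete))
    warning("isolates missing one or more loci: ",
            paste(incomplete, collapse = ", "), call. = FALSE)
  structure(recs, incomplete = incomplete)
}

#' Write a dataset as `isolateID|locus` multi-FASTA
#'
#' @param dataset An [mlst_dataset()].
#' @param path Output FASTA path.
#' @export
write_locus_fasta <- function(dataset, path) {
  stopifnot(inherits(dataset, "mlst_dataset"))
  ids <- dataset$metadata$isolate_id
  seqs <- unlist(lapply(scheme_loci(dataset$scheme), function(lc)
    stats::setNames(dataset$sequences[[lc]][ids], paste0(ids, "|", lc))))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write and read PubMLST-style allelic profile tables
#'
#' Tab-separated with header
#' `isolate<TAB>ST<TAB>clpC<TAB>fusA<TAB>ileS<TAB>purF<TAB>rplB<TAB>rpoB`
#' (locus columns follow the scheme order), one row per isolate.  The pair
#' round-trips losslessly.
#'
#' @param profiles Data frame as found in the `profiles` element of an
#'   [mlst()] fit: columns `isolate`, `ST`, then one allele column per locus.
#' @param path Output (input) TSV path.
#' @return `write_profiles_tsv` returns `path` invisibly;
#'   `read_profiles_tsv` returns the profiles data frame.
#' @export
write_profiles_tsv <- function(profiles, path) {
  stopifnot(is.data.frame(profiles),
            all(c("isolate", "ST") %in% names(profiles)))
  if (anyNA(profiles))
    stop("profile table contains unassigned entries", call. = FALSE)
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_profiles_tsv
#' @export
read_profiles_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(isolate = "character"))
  df
}

#' Write a dataset metadata table
#'
#' @param dataset An [mlst_dataset()].
#' @param path Output TSV path.
#' @export
write_metadata_tsv <- function(dataset, path) {
  utils::write.table(dataset$metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write a phylogenetic tree as Newick
#'
#' Branch lengths are serialized to 6 decimals; bootstrap supports (if
#' present as `node.label`) become internal node labels.
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' Write minimum-spanning-tree edges as TSV
#'
#' Columns `st_a`, `st_b`, `weight` (profile distance), and the isolate
#' counts of the two endpoint STs — the quantities a graph viewer needs to
#' reproduce the classic MST figure (circle per ST, size proportional to
#' isolate count).
#'
#' @param mst Edge table from [build_mst()].
#' @param st_table ST table from [assign_sts()] (or an [mlst()] fit's
#'   `st_table`).
#' @param path Output TSV path.
#' @export
write_mst_edges <- function(mst, st_table, path) {
  counts <- st_counts(st_table)
  df <- data.frame(st_a = mst$st_a, st_b = mst$st_b, weight = mst$weight,
                   isolates_a = counts[as.character(mst$st_a)],
                   isolates_b = counts[as.character(mst$st_b)])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write goeBURST groups as TSV
#'
#' Columns `group_id`, `level`, `founder`, `n_STs`, `n_isolates`, `members`
#' (comma-separated ST list).
#'
#' @param groups Result of [goeburst_groups()].
#' @param path Output TSV path.
#' @export
write_groups_tsv <- function(groups, path) {
  df <- summarize_complexes(groups)
  df$members <- vapply(df$members, paste, "", collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write the per-locus statistics table as TSV
#'
#' @param stats Data frame from [stats_table()].
#' @param path Output TSV path.
#' @export
write_stats_tsv <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", na = "NA")
  invisible(path)
}

#' Serialize simulation truth to JSON
#'
#' @param sim An `mlst_sim` object from [simulate_mlst()].
#' @param path Output JSON path.
#' @export
write_truth_json <- function(sim, path) {
  stopifnot(inherits(sim, "mlst_sim"))
  jsonlite::write_json(
    list(lineage_of_isolate = as.list(sim$truth$lineage_of_isolate),
         ancestral_sequences = as.list(sim$truth$ancestral_sequences),
         implanted_segments = sim$truth$implanted_segments,
         n_mutations = as.list(sim$truth$n_mutations)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
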