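#' Configuration for the multi-lineage isolate simulator
#'
#' The simulator emulates a worldwide collection of B. longum-like isolates:
#' a handful of deeply diverged lineages (the three subspecies), point
#' mutation on top of each lineage ancestor, and rare single-fragment
#' homologous recombination imports from another lineage.  Defaults mirror a
#' 437-isolate, three-lineage collection typed on the six-locus scheme:
#' a per-isolate mutation load below one substitution (so sequence types are
#' shared and single-locus-variant complexes form), subspecies-scale
#' lineage divergence, and about 2% of isolates carrying one imported
#' 213-bp fragment.
#'
#' @param n_lineages Number of diverged lineages (default 3).
#' @param isolates_per_lineage Integer vector of length `n_lineages`; default
#'   `c(380, 35, 22)`, dominated by the first lineage as human-derived
#'   collections are by subsp. longum.
#' @param per_site_mutation_rate Probability that any one site of an isolate
#'   differs from its lineage ancestor by point mutation (theta).
#' @param lineage_divergence Approximate probability per site that two
#'   lineage ancestors differ (delta); each ancestor is derived from a
#'   shared center sequence at delta/2 per site.
#' @param recombination_prob Probability that an isolate carries one imported
#'   donor fragment from another lineage.
#' @param fragment_length Length (bp) of the imported fragment; default 213.
#' @param gc_target Expected G+C fraction of ancestral sequence; default
#'   0.625, the concatenated-scheme value for B. longum.
#' @param locus_lengths Six locus lengths; default the scheme lengths
#'   600, 664, 487, 574, 355, 497.
#' @param seed Optional integer; when given, the full run is reproducible
#'   from it alone.
#' @return An object of class `mlst_sim_config`.
#' @export
sim_config <- function(n_lineages = 3L,
                       isolates_per_lineage = c(380L, 35L, 22L),
                       per_site_mutation_rate = 4e-4,
                       lineage_divergence = 0.05,
                       recombination_prob = 0.02,
                       fragment_length = 213L,
                       gc_target = 0.625,
                       locus_lengths = unname(.mlst_lengths),
                       seed = NULL) {
  n_lineages <- as.integer(n_lineages)
  if (length(isolates_per_lineage) == 1L)
    isolates_per_lineage <- rep(isolates_per_lineage, n_lineages)
  isolates_per_lineage <- as.integer(isolates_per_lineage)
  if (n_lineages < 1L || length(isolates_per_lineage) != n_lineages ||
      any(isolates_per_lineage < 1L))
    stop("invalid lineage/isolate counts", call. = FALSE)
  for (p in c(per_site_mutation_rate, lineage_divergence,
              recombination_prob, gc_target))
    if (!is.numeric(p) || is.na(p) || p < 0 || p > 1)
      stop("probabilities must lie in [0, 1]", call. = FALSE)
  locus_lengths <- as.integer(locus_lengths)
  if (length(locus_lengths) != 6L || any(locus_lengths < 3L))
    stop("locus_lengths must be six positive lengths", call. = FALSE)
  fragment_length <- as.integer(fragment_length)
  if (fragment_length < 0L || fragment_length > sum(locus_lengths))
    stop("fragment_length must lie in [0, total concatenated length]",
         call. = FALSE)
  structure(list(n_lineages = n_lineages,
                 isolates_per_lineage = isolates_per_lineage,
                 per_site_mutation_rate = per_site_mutation_rate,
                 lineage_divergence = lineage_divergence,
                 recombination_prob = recombination_prob,
                 fragment_length = fragment_length,
                 gc_target = gc_target,
                 locus_lengths = locus_lengths,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "mlst_sim_config")
}

.bases <- c("A", "C", "G", "T")

# Draw an i.i.d. ancestral sequence with P(G or C) = gc.
.draw_ancestor <- function(len, gc) {
  paste(sample(.bases, len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Substitute sites of a sequence independently at a fixed rate
#'
#' Each site is replaced, with probability `rate`, by a base drawn uniformly
#' from the three alternatives (Jukes-Cantor-like), so the expected Hamming
#' distance to the input is `rate * nchar(seq)`.
#'
#' @param seq Uppercase ACGT string.
#' @param rate Per-site substitution probability in [0, 1].
#' @return The mutated sequence (same length).
#' @export
mutate_sequence <- function(seq, rate) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  .check_dna(seq)
  if (!is.numeric(rate) || rate < 0 || rate > 1)
    stop("rate must lie in [0, 1]", call. = FALSE)
  if (rate == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    cur <- match(chars[hit], .bases)
    step <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- .bases[(cur + step - 1L) %% 4L + 1L]
  }
  paste(chars, collapse = "")
}

#' Copy a donor fragment into a recipient sequence
#'
#' Models one homologous recombination (gene-conversion-like) import: the
#' recipient is returned unchanged outside the 0-based half-open interval
#' `[start, start + length)` and carries the donor's bases inside it.
#'
#' @param recipient,donor Equal-length uppercase ACGT strings.
#' @param start 0-based offset of the imported fragment.
#' @param length Fragment length in bp (0 allowed).
#' @return The chimeric sequence.
#' @export
implant_recombination <- function(recipient, donor, start, length) {
  stopifnot(is.character(recipient), is.character(donor),
            nchar(recipient) == nchar(donor))
  start <- as.integer(start); length <- as.integer(length)
  if (start < 0L || length < 0L || start + length > nchar(recipient))
    stop("fragment interval out of range", call. = FALSE)
  if (length == 0L) return(recipient)
  paste0(substr(recipient, 1L, start),
         substr(donor, start + 1L, start + length),
         substr(recipient, start + length + 1L, nchar(recipient)))
}

#' Simulate a multi-lineage six-locus isolate collection
#'
#' Draws one unobserved center sequence (i.i.d. sites at the target GC),
#' derives each lineage ancestor from it by flipping each site with
#' probability `lineage_divergence / 2` (so two lineage ancestors differ at
#' about `lineage_divergence` per site and every lineage is a clade of the
#' true genealogy), mutates each isolate's
#' copy of its lineage ancestor site-wise at `per_site_mutation_rate`, and,
#' with probability `recombination_prob` per isolate, implants one
#' `fragment_length`-bp fragment of a uniformly chosen other lineage's
#' ancestor at a uniform position.
#'
#' @param config An [sim_config()] object.
#' @return A list of class `mlst_sim` with elements `dataset` (an
#'   [mlst_dataset()] whose metadata carries the true `lineage`) and `truth`
#'   (lineage map, ancestral sequences, implanted segment table with 0-based
#'   half-open concatenated coordinates, realized mutation counts).
#' @examples
#' sim <- simulate_mlst(sim_config(isolates_per_lineage = c(5, 5, 5), seed = 1))
#' sim$dataset
#' @export
simulate_mlst <- function(config = sim_config()) {
  stopifnot(inherits(config, "mlst_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  scheme <- locus_scheme(.mlst_loci, config$locus_lengths)
  total <- sum(config$locus_lengths)
  k <- config$n_lineages

  # Lineage ancestors radiate from an unobserved center sequence, each at
  # delta/2, so any two ancestors differ at ~delta per site and every
  # lineage has a positive-length stem in the true genealogy.
  center <- .draw_ancestor(total, config$gc_target)
  anc <- character(k)
  if (k == 1L) anc[1L] <- center
  else for (l in 1:k)
    anc[l] <- mutate_sequence(center, config$lineage_divergence / 2)

  ids <- unlist(lapply(seq_len(k), function(l)
    sprintf("L%d_i%03d", l, seq_len(config$isolates_per_lineage[l]))))
  lineage <- rep(seq_len(k), config$isolates_per_lineage)

  seqs <- character(length(ids))
  n_mut <- integer(length(ids))
  seg <- list()
  for (i in seq_along(ids)) {
    s <- mutate_sequence(anc[lineage[i]], config$per_site_mutation_rate)
    n_mut[i] <- sum(strsplit(s, "")[[1L]] !=
                    strsplit(anc[lineage[i]], "")[[1L]])
    if (k > 1L && config$fragment_length > 0L &&
        stats::runif(1L) < config$recombination_prob) {
      donor <- sample(setdiff(seq_len(k), lineage[i]), 1L)
      start <- sample.int(total - config$fragment_length + 1L, 1L) - 1L
      s <- implant_recombination(s, anc[donor], start, config$fragment_length)
      seg[[length(seg) + 1L]] <-
        data.frame(isolate_id = ids[i], start = start,
                   end = start + config$fragment_length,
                   donor_lineage = donor, stringsAsFactors = FALSE)
    }
    seqs[i] <- s
  }
  segments <- if (length(seg)) do.call(rbind, seg) else
    data.frame(isolate_id = character(), start = integer(),
               end = integer(), donor_lineage = integer(),
               stringsAsFactors = FALSE)

  off <- scheme_offsets(scheme)
  sequences <- lapply(seq_len(nrow(off)), function(j)
    stats::setNames(substr(seqs, off$start[j] + 1L, off$end[j]), ids))
  names(sequences) <- off$name

  metadata <- data.frame(isolate_id = ids, region = "simulated",
                         source = "simulated", lineage = lineage,
                         stringsAsFactors = FALSE)
  dataset <- mlst_dataset(sequences, metadata, scheme)
  truth <- list(lineage_of_isolate = stats::setNames(lineage, ids),
                ancestral_sequences = stats::setNames(anc, paste0("L", 1:k)),
                implanted_segments = segments,
                n_mutations = stats::setNames(n_mut, ids))
  structure(list(dataset = dataset, truth = truth, config = config),
            class = "mlst_sim")
}

#' @export
print.mlst_sim <- function(x, ...) {
  cat("Simulated MLST collection:", nrow(x$dataset$metadata), "isolates,",
      x$config$n_lineages, "lineages,",
      nrow(x$truth$implanted_segments), "implanted fragment(s)\n")
  invisible(x)
}
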