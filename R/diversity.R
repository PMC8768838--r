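#' Pooled G+C content of a set of sequences
#'
#' @param sequences Character vector of ACGT sequences (lengths may differ).
#' @return Fraction of G and C bases pooled over all sequences.
#' @export
gc_content <- function(sequences) {
  if (length(sequences) == 0L || all(nchar(sequences) == 0L))
    stop("empty input", call. = FALSE)
  sequences <- toupper(sequences)
  .check_dna(sequences)
  gc <- sum(nchar(gsub("[AT]", "", sequences)))
  gc / sum(nchar(sequences))
}

#' Number of segregating (polymorphic) sites in an alignment
#'
#' @param alignment Character vector of equal-length ACGT sequences, n >= 2.
#' @return Count of columns with more than one distinct base.
#' @export
segregating_sites <- function(alignment) {
  stopifnot(length(alignment) >= 2L)
  alignment <- toupper(alignment)
  .check_dna(alignment)
  m <- seq_matrix(alignment)
  sum(apply(m, 2L, function(col) length(unique(col))) > 1L)
}

# Per-column pairwise-difference counts: sum over columns of the number of
# differing sequence pairs.  O(sites x n), avoids the n^2 pair loop.
.pairwise_diff_total <- function(m) {
  n <- nrow(m)
  sum(apply(m, 2L, function(col) {
    cnt <- tabulate(match(col, c("A", "C", "G", "T")), 4L)
    (n * n - sum(cnt * cnt)) / 2
  }))
}

#' Nucleotide diversity (pi) per site
#'
#' Mean over all sequence pairs of the Hamming distance divided by the
#' alignment length.
#'
#' @param alignment Character vector of equal-length ACGT sequences, n >= 2.
#' @return Numeric pi in [0, 1].
#' @export
nucleotide_diversity <- function(alignment) {
  stopifnot(length(alignment) >= 2L)
  alignment <- toupper(alignment)
  .check_dna(alignment)
  m <- seq_matrix(alignment)
  n <- nrow(m)
  .pairwise_diff_total(m) / (n * (n - 1) / 2) / ncol(m)
}

#' Tajima's D with its full constant breakdown
#'
#' Contrasts mean pairwise diversity with the segregating-sites estimate of
#' the mutation parameter, normalized by the Tajima (1989) variance
#' constants.  Negative values indicate an excess of rare variants.
#'
#' @param alignment Character vector of equal-length ACGT sequences, n >= 4.
#' @return An object of class `tajima_d`: `n`, `S`, `pi_total` (mean
#'   pairwise differences per pair, not per site), constants `a1`, `a2`,
#'   `b1`, `b2`, `c1`, `c2`, `e1`, `e2`, and `D` (`NA` when `S` = 0).
#' @examples
#' tajimas_d(c("AAAA", "AAAA", "AAAA", "AAAT"))$D  # about -0.61
#' @export
tajimas_d <- function(alignment) {
  if (length(alignment) < 4L)
    stop("insufficient sequences (need n >= 4)", call. = FALSE)
  alignment <- toupper(alignment)
  .check_dna(alignment)
  m <- seq_matrix(alignment)
  n <- nrow(m)
  S <- sum(apply(m, 2L, function(col) length(unique(col))) > 1L)
  pi_total <- .pairwise_diff_total(m) / (n * (n - 1) / 2)

  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- if (S == 0L) NA_real_ else
    (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  structure(list(n = n, S = S, pi_total = pi_total, a1 = a1, a2 = a2,
                 b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2,
                 D = D),
            class = "tajima_d")
}

#' @export
print.tajima_d <- function(x, ...) {
  cat(sprintf("Tajima's D = %s  (n = %d, S = %d, mean pairwise diff = %.4f)\n",
              ifelse(is.na(x$D), "NA (no segregating sites)",
                     sprintf("%.5f", x$D)),
              x$n, x$S, x$pi_total))
  invisible(x)
}

## ---- Nei-Gojobori (1986) dN/dS -------------------------------------------

.ng_env <- new.env(parent = emptyenv())

.codon_table <- function() {
  if (is.null(.ng_env$code)) {
    code <- Biostrings::GENETIC_CODE
    .ng_env$code <- stats::setNames(as.character(code), names(code))
  }
  .ng_env$code
}

# Synonymous site count of one codon: per position, the fraction of the 3
# possible changes that preserve the amino acid.  Changes to stop codons
# count as nonsynonymous; stop codons themselves return NA.
.syn_sites <- function(codon) {
  key <- paste0("s_", codon)
  if (!is.null(.ng_env[[key]])) return(.ng_env[[key]])
  code <- .codon_table()
  aa <- code[[codon]]
  if (aa == "*") return(.ng_env[[key]] <- NA_real_)
  chars <- strsplit(codon, "")[[1L]]
  s <- 0
  for (pos in 1:3) for (b in setdiff(.bases, chars[pos])) {
    alt <- chars; alt[pos] <- b
    alt <- paste(alt, collapse = "")
    if (code[[alt]] == aa) s <- s + 1 / 3
  }
  .ng_env[[key]] <- s
}

# Average (nonsynonymous, synonymous) difference counts between two codons
# over all minimal substitution pathways; pathways passing through a stop
# codon are excluded unless every pathway is blocked.
.ng_codon_pair <- function(ca, cb) {
  key <- paste0("p_", ca, cb)
  if (!is.null(.ng_env[[key]])) return(.ng_env[[key]])
  code <- .codon_table()
  da <- strsplit(ca, "")[[1L]]; db <- strsplit(cb, "")[[1L]]
  diff <- which(da != db)
  k <- length(diff)
  if (k == 0L) return(.ng_env[[key]] <- c(0, 0))
  perms <- switch(k, list(1L), list(1:2, 2:1),
                  list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
                       c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L)))
  paths <- list(); paths_stop <- list()
  for (p in perms) {
    cur <- da; nd <- 0; sd <- 0; blocked <- FALSE
    for (step in diff[p]) {
      nxt <- cur; nxt[step] <- db[step]
      aa1 <- code[[paste(cur, collapse = "")]]
      aa2 <- code[[paste(nxt, collapse = "")]]
      if (aa2 == "*" && !identical(nxt, db)) blocked <- TRUE
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (blocked) paths_stop[[length(paths_stop) + 1L]] <- c(nd, sd)
    else paths[[length(paths) + 1L]] <- c(nd, sd)
  }
  use <- if (length(paths)) paths else paths_stop
  .ng_env[[key]] <- Reduce(`+`, use) / length(use)
}

#' Nei-Gojobori (1986) dN/dS with Jukes-Cantor correction
#'
#' Counts synonymous and nonsynonymous sites and differences averaged over
#' all sequence pairs (equal-weight enumeration of minimal substitution
#' pathways between differing codons), converts the proportions with the
#' Jukes-Cantor correction d = -(3/4) ln(1 - (4/3) p), and reports the
#' dN/dS ratio.
#'
#' @param alignment Character vector of equal-length coding ACGT sequences,
#'   n >= 2.
#' @param frame_offset 0, 1 or 2 leading bases skipped before the first
#'   complete codon; a trailing partial codon is truncated.
#' @param on_stop `"warn"` (default) excludes codon columns containing an
#'   internal stop codon with a warning; `"error"` aborts.
#' @return An object of class `nei_gojobori`: `N_sites`, `S_sites`, `Nd`,
#'   `Sd`, `pN`, `pS`, `dN`, `dS`, `ratio` (`NA` sentinel when `dS` is 0 or
#'   a correction saturates).
#' @export
nei_gojobori <- function(alignment, frame_offset = 0L,
                         on_stop = c("warn", "error")) {
  on_stop <- match.arg(on_stop)
  stopifnot(length(alignment) >= 2L, frame_offset %in% 0:2)
  alignment <- toupper(alignment)
  .check_dna(alignment)
  len <- unique(nchar(alignment))
  if (length(len) != 1L) stop("unequal sequence lengths", call. = FALSE)
  eff <- len - frame_offset
  n_codon <- eff %/% 3L
  if (n_codon < 1L) stop("fewer than one complete codon", call. = FALSE)
  n <- length(alignment)
  code <- .codon_table()

  # codon matrix: n sequences x n_codon columns
  starts <- frame_offset + 3L * (seq_len(n_codon) - 1L) + 1L
  cod <- vapply(starts, function(s) substr(alignment, s, s + 2L),
                character(n))
  if (n == 1L) cod <- matrix(cod, nrow = 1L)

  has_stop <- apply(cod, 2L, function(col) any(code[col] == "*"))
  if (any(has_stop)) {
    msg <- sprintf("%d codon column(s) contain internal stop codons",
                   sum(has_stop))
    if (on_stop == "error") stop(msg, call. = FALSE)
    warning(msg, "; excluded", call. = FALSE)
    cod <- cod[, !has_stop, drop = FALSE]
    if (ncol(cod) == 0L) stop("no codons left after stop exclusion",
                              call. = FALSE)
  }

  # site counts: mean over sequences (equals the mean over pairs of the
  # two-sequence average)
  syn_per_seq <- rowSums(apply(cod, 2L, function(col)
    vapply(col, .syn_sites, 0)))
  S_sites <- mean(syn_per_seq)
  N_sites <- 3 * ncol(cod) - S_sites

  # differences: per codon column, weighted sum over distinct codon pairs
  n_pairs <- n * (n - 1) / 2
  Nd <- 0; Sd <- 0
  for (j in seq_len(ncol(cod))) {
    tab <- table(cod[, j])
    if (length(tab) < 2L) next
    u <- names(tab); cnt <- as.numeric(tab)
    for (x in seq_len(length(u) - 1L)) for (y in (x + 1L):length(u)) {
      w <- cnt[x] * cnt[y]
      ns <- .ng_codon_pair(u[x], u[y])
      Nd <- Nd + w * ns[1L]; Sd <- Sd + w * ns[2L]
    }
  }
  Nd <- Nd / n_pairs; Sd <- Sd / n_pairs
  pN <- Nd / N_sites; pS <- Sd / S_sites
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dN <- jc(pN); dS <- jc(pS)
  # dN = 0 with any synonymous divergence pins the ratio at 0, even when
  # the synonymous correction saturates
  ratio <- if (!is.na(dN) && dN == 0 && Sd > 0) 0
  else if (is.na(dN) || is.na(dS) || dS == 0) NA_real_ else dN / dS
  structure(list(N_sites = N_sites, S_sites = S_sites, Nd = Nd, Sd = Sd,
                 pN = pN, pS = pS, dN = dN, dS = dS, ratio = ratio),
            class = "nei_gojobori")
}

#' @export
print.nei_gojobori <- function(x, ...) {
  cat(sprintf("Nei-Gojobori: dN = %.5g, dS = %.5g, dN/dS = %s\n",
              x$dN, x$dS,
              ifelse(is.na(x$ratio), "NA (undefined)",
                     sprintf("%.5g", x$ratio))))
  invisible(x)
}

#' Per-locus and concatenated diversity statistics table
#'
#' Computes, for every scheme locus and for the concatenated sequences, the
#' classic MLST descriptive row: length, number of alleles (STs for the
#' concatenated row), segregating sites, GC content, Tajima's D, optional
#' PHI-test p-value, nucleotide diversity and Nei-Gojobori dN/dS.
#'
#' @param fit An [mlst()] fit.
#' @param mode `"isolates"` (default) computes pi, D, dN/dS and the PHI test
#'   over all isolate sequences; `"alleles"` uses one sequence per distinct
#'   allele (per distinct ST for the concatenated row).
#' @param phi If `TRUE`, run [phi_test()] per row and fill `phi_p`.
#' @param n_permutations,w,seed Forwarded to [phi_test()].
#' @return Data frame with columns `locus`, `length`, `n_alleles`,
#'   `polymorphic_sites`, `gc`, `tajima_D`, `phi_p`, `pi`, `dn_ds`;
#'   undefined statistics are `NA`.
#' @export
stats_table <- function(fit, mode = c("isolates", "alleles"), phi = FALSE,
                        n_permutations = 1000L, w = 100L, seed = NULL) {
  stopifnot(inherits(fit, "mlst"))
  mode <- match.arg(mode)
  scheme <- fit$scheme
  loci <- scheme_loci(scheme)
  ids <- fit$dataset$metadata$isolate_id

  concat_all <- concat_sequences(fit$dataset)
  st_first <- vapply(fit$st_table$isolates, `[[`, "", 1L)
  rows <- vector("list", length(loci) + 1L)
  for (i in seq_along(loci)) {
    lc <- loci[i]
    seqs_all <- fit$dataset$sequences[[lc]][ids]
    seqs <- if (mode == "alleles") fit$catalog[[lc]] else unname(seqs_all)
    rows[[i]] <- .stats_row(lc, seqs, n_alleles = length(fit$catalog[[lc]]),
                            frame = scheme$loci$frame_offset[i],
                            phi, n_permutations, w, seed)
  }
  seqs <- if (mode == "alleles") unname(concat_all[st_first]) else
    unname(concat_all)
  rows[[length(loci) + 1L]] <-
    .stats_row("Concatenated", seqs,
               n_alleles = nrow(fit$st_table$profiles), frame = 0L,
               phi, n_permutations, w, seed)
  do.call(rbind, rows)
}

.stats_row <- function(label, seqs, n_alleles, frame, phi,
                       n_permutations, w, seed) {
  len <- nchar(seqs[1L])
  S <- segregating_sites(seqs)
  pi <- nucleotide_diversity(seqs)
  D <- if (length(seqs) >= 4L) tajimas_d(seqs)$D else NA_real_
  ng <- tryCatch(nei_gojobori(seqs, frame)$ratio,
                 error = function(e) NA_real_)
  p <- NA_real_
  if (isTRUE(phi)) {
    p <- tryCatch(phi_test(seqs, w = w, n_permutations = n_permutations,
                           seed = seed)$p_value,
                  error = function(e) NA_real_)
  }
  data.frame(locus = label, length = len, n_alleles = n_alleles,
             polymorphic_sites = S, gc = gc_content(seqs),
             tajima_D = D, phi_p = p, pi = pi, dn_ds = ng,
             stringsAsFactors = FALSE)
}
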