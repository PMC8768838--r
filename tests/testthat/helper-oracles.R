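# Independent oracle implementations used to cross-check the package.
# These deliberately use different code paths (explicit pair loops,
# recursion, igraph) from the implementations they verify.

# Random allelic profile matrix: n isolates x 6 loci, alleles 1..max_allele.
random_profiles <- function(n, max_allele = 3L) {
  m <- matrix(sample.int(max_allele, n * 6L, replace = TRUE), nrow = n)
  rownames(m) <- paste0("iso", seq_len(n))
  colnames(m) <- c("clpC", "fusA", "ileS", "purF", "rplB", "rpoB")
  m
}

# Brute-force pairwise profile-distance matrix by explicit double loop.
oracle_profile_dist <- function(profiles) {
  n <- nrow(profiles)
  D <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sum(profiles[i, ] != profiles[j, ])
  D
}

# Connected components of the <= level threshold graph, via igraph.
oracle_components <- function(D, level) {
  g <- igraph::graph_from_adjacency_matrix(D <= level & D >= 0,
                                           mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

# Minimum spanning tree total weight, via igraph.
oracle_mst_weight <- function(D) {
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  sum(igraph::E(igraph::mst(g))$weight)
}

# Exhaustive minimum spanning-tree weight over all edge subsets of size
# n - 1 (feasible for n <= 6).
oracle_mst_weight_exhaustive <- function(D) {
  n <- nrow(D)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  best <- Inf
  for (subset in utils::combn(nrow(pairs), n - 1L, simplify = FALSE)) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (e in subset) {
      a <- find(pairs[e, 1L]); b <- find(pairs[e, 2L])
      if (a == b) { ok <- FALSE; break }
      parent[b] <- a
    }
    if (ok) best <- min(best, sum(D[pairs[subset, , drop = FALSE]]))
  }
  best
}

# Tajima's D recomputed from first principles with an explicit pair loop.
oracle_tajima_d <- function(seqs) {
  n <- length(seqs)
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1L]])
  L <- length(chars[[1L]])
  S <- 0L
  for (site in seq_len(L))
    if (length(unique(vapply(chars, `[[`, "", site))) > 1L) S <- S + 1L
  diffs <- 0
  for (i in 1:(n - 1L)) for (j in (i + 1L):n)
    diffs <- diffs + sum(chars[[i]] != chars[[j]])
  pi_total <- diffs / (n * (n - 1) / 2)
  a1 <- sum(1 / seq_len(n - 1L)); a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  if (S == 0L) return(NA_real_)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Independent NG86 for ONE sequence pair: recursive pathway enumeration
# (the package uses permutation loops and column-wise weighting).
oracle_ng86_pair <- function(sa, sb, frame_offset = 0L) {
  code <- Biostrings::GENETIC_CODE
  syn_sites_codon <- function(codon) {
    aa <- code[[codon]]
    ch <- strsplit(codon, "")[[1L]]
    s <- 0
    for (pos in 1:3) for (b in setdiff(c("A","C","G","T"), ch[pos])) {
      alt <- ch; alt[pos] <- b
      if (code[[paste(alt, collapse = "")]] == aa) s <- s + 1/3
    }
    s
  }
  # recursive enumeration of all orders of introducing the differences
  paths <- function(cur, target) {
    diff <- which(cur != target)
    if (!length(diff))
      return(list(list(nd = 0, sd = 0, blocked = FALSE)))
    out <- list()
    for (pos in diff) {
      nxt <- cur; nxt[pos] <- target[pos]
      aa1 <- code[[paste(cur, collapse = "")]]
      aa2 <- code[[paste(nxt, collapse = "")]]
      step_blocked <- aa2 == "*" && any(nxt != target)
      syn <- aa1 == aa2
      for (rest in paths(nxt, target)) {
        out[[length(out) + 1L]] <- list(
          nd = rest$nd + !syn, sd = rest$sd + syn,
          blocked = rest$blocked || step_blocked)
      }
    }
    out
  }
  eff <- nchar(sa) - frame_offset
  nc <- eff %/% 3L
  Nd <- 0; Sd <- 0; Ssites_a <- 0; Ssites_b <- 0
  used_codons <- 0L
  for (k in seq_len(nc)) {
    from <- frame_offset + 3L * (k - 1L) + 1L
    ca <- substr(sa, from, from + 2L); cb <- substr(sb, from, from + 2L)
    if (code[[ca]] == "*" || code[[cb]] == "*") next
    used_codons <- used_codons + 1L
    Ssites_a <- Ssites_a + syn_sites_codon(ca)
    Ssites_b <- Ssites_b + syn_sites_codon(cb)
    if (ca != cb) {
      pl <- paths(strsplit(ca, "")[[1L]], strsplit(cb, "")[[1L]])
      open <- Filter(function(p) !p$blocked, pl)
      if (!length(open)) open <- pl
      Nd <- Nd + mean(vapply(open, `[[`, 0, "nd"))
      Sd <- Sd + mean(vapply(open, `[[`, 0, "sd"))
    }
  }
  S <- (Ssites_a + Ssites_b) / 2
  N <- 3 * used_codons - S
  pN <- Nd / N; pS <- Sd / S
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(N_sites = N, S_sites = S, Nd = Nd, Sd = Sd,
       dN = jc(pN), dS = jc(pS))
}

# Random stop-free coding sequence of n_codon codons.
random_coding_seq <- function(n_codon) {
  code <- Biostrings::GENETIC_CODE
  ok <- names(code)[code != "*"]
  paste(sample(ok, n_codon, replace = TRUE), collapse = "")
}

# Does a frame-0 coding sequence contain a stop codon?
has_stop_codon <- function(s) {
  any(Biostrings::GENETIC_CODE[substring(s, seq(1, nchar(s) - 2, 3),
                                         seq(3, nchar(s), 3))] == "*")
}

# Random ACGT alignment (n sequences derived from one ancestor).
random_alignment <- function(n, len, rate = 0.05) {
  anc <- paste(sample(c("A","C","G","T"), len, replace = TRUE),
               collapse = "")
  vapply(seq_len(n), function(i) mutate_sequence(anc, rate), "")
}

# Site compatibility via igraph: bipartite state-intersection graph is a
# forest.
oracle_compatible <- function(ci, cj) {
  si <- unique(ci); sj <- unique(cj)
  joint <- unique(paste(match(ci, si), length(si) + match(cj, sj)))
  el <- do.call(rbind, lapply(strsplit(joint, " "), as.integer))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::is_forest(g)
}

# Jaccard overlap of two 0-based half-open intervals.
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  if (inter == 0) return(0)
  inter / (max(e1, e2) - min(s1, s2))
}
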