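# Pairwise profile-distance matrix between STs (rows of st_table$profiles).
st_distance_matrix <- function(st_table) {
  p <- st_table$profiles
  m <- nrow(p)
  D <- matrix(0L, m, m)
  for (j in seq_len(ncol(p)))
    D <- D + outer(p[, j], p[, j], "!=")
  dimnames(D) <- list(rownames(p), rownames(p))
  D
}

#' Count single-, double- and triple-locus variants of an ST
#'
#' @param st ST number (integer) present in the table.
#' @param st_table An [assign_sts()] table.
#' @return Named integer vector `c(slv, dlv, tlv)`: number of other STs at
#'   profile distance exactly 1, 2 and 3.
#' @export
variant_counts <- function(st, st_table) {
  stopifnot(inherits(st_table, "st_table"))
  m <- nrow(st_table$profiles)
  if (st < 1L || st > m) stop("unknown ST: ", st, call. = FALSE)
  d <- .profile_dist_to(st_table$profiles, st)
  c(slv = sum(d == 1L, na.rm = TRUE), dlv = sum(d == 2L, na.rm = TRUE),
    tlv = sum(d == 3L, na.rm = TRUE))
}

.profile_dist_to <- function(profiles, st) {
  d <- integer(nrow(profiles))
  for (j in seq_len(ncol(profiles)))
    d <- d + (profiles[, j] != profiles[st, j])
  d[st] <- NA_integer_
  d
}

# Union-find for component and spanning-tree construction.
.uf_new <- function(n) seq_len(n)
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' goeBURST clustering of STs into clonal complexes / BURST groups
#'
#' Groups are the connected components of the graph whose edges join ST
#' pairs at profile distance at most `level` (1 = single-locus variants,
#' giving clonal complexes; 2 = double-locus variants, giving BURST groups).
#' Within each group the founder is the member maximizing the canonical
#' goeBURST tie-break chain: most SLV neighbors, then most DLV neighbors,
#' then highest isolate frequency, then the smaller ST number.  Neighbor
#' counts are computed over the whole dataset, not within the group.
#'
#' @param st_table An [assign_sts()] table.
#' @param level Variant threshold, 1 (SLV) or 2 (DLV); 3 also accepted.
#' @return A list of class `goeburst_groups` (attribute `level`); each
#'   element has `members`, `founder`, `n_isolates`, and per-member `slv`,
#'   `dlv`, `tlv`, `freq`.
#' @export
goeburst_groups <- function(st_table, level = 1L) {
  stopifnot(inherits(st_table, "st_table"), level %in% 1:3)
  D <- st_distance_matrix(st_table)
  m <- nrow(D)
  counts <- st_counts(st_table)
  slv <- rowSums(D == 1L); dlv <- rowSums(D == 2L); tlv <- rowSums(D == 3L)

  parent <- .uf_new(m)
  if (m > 1L) for (i in 1:(m - 1L)) for (j in (i + 1L):m)
    if (D[i, j] <= level) {
      ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
      if (ri != rj) parent[rj] <- ri
    }
  root <- vapply(seq_len(m), function(i) .uf_find(parent, i), 0L)
  comp <- split(seq_len(m), root)

  groups <- lapply(comp, function(members) {
    # founder election: (slv, dlv, frequency) maximized, smaller ST on ties
    key <- order(-slv[members], -dlv[members], -counts[members], members)
    list(members = members, founder = members[key[1L]],
         n_isolates = sum(counts[members]),
         slv = stats::setNames(slv[members], members),
         dlv = stats::setNames(dlv[members], members),
         tlv = stats::setNames(tlv[members], members),
         freq = stats::setNames(unname(counts[members]), members))
  })
  ord <- order(-vapply(groups, `[[`, 0, "n_isolates"),
               vapply(groups, `[[`, 0L, "founder"))
  structure(unname(groups[ord]), level = as.integer(level),
            class = "goeburst_groups")
}

#' @export
print.goeburst_groups <- function(x, ...) {
  multi <- sum(vapply(x, function(g) length(g$members) > 1L, TRUE))
  cat("goeBURST groups at level", attr(x, "level"), ":", multi,
      "multi-ST groups,", length(x) - multi, "singleton STs\n")
  invisible(x)
}

#' Tabulate goeBURST groups
#'
#' One row per group (multi-ST complexes and singletons alike), sorted by
#' descending isolate count then founder ST.
#'
#' @param groups Result of [goeburst_groups()].
#' @param st_table Unused; accepted for call-site symmetry.
#' @return Data frame with columns `group_id`, `level`, `founder`, `n_STs`,
#'   `n_isolates` and a list column `members`.
#' @export
summarize_complexes <- function(groups, st_table = NULL) {
  stopifnot(inherits(groups, "goeburst_groups"))
  df <- data.frame(group_id = seq_along(groups),
                   level = attr(groups, "level"),
                   founder = vapply(groups, `[[`, 0L, "founder"),
                   n_STs = vapply(groups, function(g) length(g$members), 0L),
                   n_isolates = vapply(groups, function(g)
                     as.integer(g$n_isolates), 0L))
  df$members <- lapply(groups, `[[`, "members")
  df
}

#' Minimum spanning tree over allelic profiles
#'
#' Builds a spanning tree of the STs minimizing total profile distance.
#' Edges are selected Kruskal-style after sorting by the goeBURST comparison
#' chain: weight ascending, then higher maximum endpoint SLV count, then DLV
#' count, then higher maximum endpoint isolate frequency, then the
#' lexicographically smaller ST pair.  The sort key of each kept edge is
#' returned, so the rule that admitted it can be read off.
#'
#' @param st_table An [assign_sts()] table.
#' @return Data frame of `nrow(profiles) - 1` edges with columns `st_a`,
#'   `st_b`, `weight`, `max_slv`, `max_dlv`, `max_freq`, in deterministic
#'   inclusion order.
#' @export
build_mst <- function(st_table) {
  stopifnot(inherits(st_table, "st_table"))
  m <- nrow(st_table$profiles)
  empty <- data.frame(st_a = integer(), st_b = integer(), weight = integer(),
                      max_slv = integer(), max_dlv = integer(),
                      max_freq = integer())
  if (m <= 1L) return(empty)
  D <- st_distance_matrix(st_table)
  counts <- st_counts(st_table)
  slv <- rowSums(D == 1L); dlv <- rowSums(D == 2L)

  idx <- which(upper.tri(D), arr.ind = TRUE)
  a <- idx[, 1L]; b <- idx[, 2L]
  w <- D[idx]
  mslv <- pmax(slv[a], slv[b]); mdlv <- pmax(dlv[a], dlv[b])
  mfreq <- pmax(counts[a], counts[b])
  ord <- order(w, -mslv, -mdlv, -mfreq, a, b)

  parent <- .uf_new(m)
  keep <- integer(m - 1L); k <- 0L
  for (e in ord) {
    ra <- .uf_find(parent, a[e]); rb <- .uf_find(parent, b[e])
    if (ra != rb) {
      parent[rb] <- ra
      k <- k + 1L
      keep[k] <- e
      if (k == m - 1L) break
    }
  }
  data.frame(st_a = a[keep], st_b = b[keep], weight = as.integer(w[keep]),
             max_slv = as.integer(mslv[keep]),
             max_dlv = as.integer(mdlv[keep]),
             max_freq = as.integer(unname(mfreq[keep])))
}
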