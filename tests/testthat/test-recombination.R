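test_that("site compatibility implements the four-gamete / forest criterion", {
  expect_true(site_compatibility(c("A", "A", "T", "T"),
                                 c("C", "C", "G", "G")))
  expect_false(site_compatibility(c("A", "A", "T", "T"),
                                  c("C", "G", "C", "G")))
  # symmetric by construction
  set.seed(89)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    ci <- sample(c("A", "C", "T"), n, replace = TRUE)
    cj <- sample(c("G", "T", "A"), n, replace = TRUE)
    expect_equal(site_compatibility(ci, cj), site_compatibility(cj, ci))
    # independent forest-criterion oracle (igraph), incl. tri-allelic sites
    expect_equal(site_compatibility(ci, cj), oracle_compatible(ci, cj))
  }
})

test_that("phi statistic and p-value behave at the degenerate extremes", {
  # informative sites pairwise compatible: statistic 0, p = 1
  al <- c("AACC", "AACC", "TTGG", "TTGG")
  r <- phi_test(al, w = 10, n_permutations = 50, seed = 1)
  expect_equal(r$phi_statistic, 0)
  expect_equal(r$p_value, 1)

  # exactly two mutually incompatible informative sites: statistic 1,
  # permutation-invariant, p = 1
  al2 <- c("AC", "AG", "TC", "TG")
  r2 <- phi_test(al2, w = 10, n_permutations = 50, seed = 1)
  expect_equal(r2$phi_statistic, 1)
  expect_equal(r2$p_value, 1)

  expect_error(phi_test(c("AAAA", "AAAT", "AAAA", "AAAA")),
               "insufficient informative")
})

test_that("sampled permutation p matches exhaustive enumeration at tiny size", {
  # 5 informative sites at controlled positions: one adjacent incompatible
  # pair, the rest compatible
  inc_a <- c("A", "A", "T", "T", "A", "T")
  inc_b <- c("C", "G", "C", "G", "C", "G")   # incompatible with inc_a
  comp <- c("A", "A", "A", "T", "T", "T")    # compatible with both? no -
  # build columns explicitly and verify incompatibilities with the oracle
  cols <- list(inc_a, inc_b, comp, comp, comp)
  positions <- c(1L, 3L, 40L, 45L, 50L)
  L <- 60L
  m <- matrix("A", nrow = 6, ncol = L)
  for (k in seq_along(cols)) m[, positions[k]] <- cols[[k]]
  # pad a second state nowhere else so only these 5 are informative
  al <- apply(m, 1, paste, collapse = "")

  w <- 10L
  r <- phi_test(al, w = w, n_permutations = 2000, seed = 5)
  expect_equal(r$n_informative_sites, 5L)

  # exhaustive: all 120 permutations of sites over the fixed positions
  M <- matrix(0L, 5, 5)
  for (i in 1:4) for (j in (i + 1):5)
    M[i, j] <- M[j, i] <- 1L - site_compatibility(cols[[i]], cols[[j]])
  pairs <- which(outer(positions, positions, function(a, b) b - a) >= 1 &
                 abs(outer(positions, positions, "-")) <= w,
                 arr.ind = TRUE)
  # enumerate all 5! permutations recursively, no extra packages
  all_perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in all_perms(v[-i]))
        out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  obs <- mean(M[pairs])
  exact <- vapply(all_perms(1:5), function(s)
    mean(M[cbind(s[pairs[, 1]], s[pairs[, 2]])]), 0)
  p_exact <- mean(exact >= obs)
  tol <- 3 * sqrt(p_exact * (1 - p_exact) / 2000) + 1 / 2000
  expect_lt(abs(r$p_value - p_exact), tol + 1e-9)
})

test_that("phi permutation draw is reproducible from its seed", {
  sim <- simulate_mlst(sim_config(n_lineages = 1, isolates_per_lineage = 12,
                                  per_site_mutation_rate = 0.015,
                                  recombination_prob = 0, seed = 97))
  al <- unname(concat_sequences(sim$dataset))
  r1 <- phi_test(al, n_permutations = 200, seed = 7)
  r2 <- phi_test(al, n_permutations = 200, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("segment scanner finds implanted fragments and respects boundaries", {
  set.seed(101)
  sim <- simulate_mlst(sim_config(isolates_per_lineage = c(6, 6, 6),
                                  per_site_mutation_rate = 0.002,
                                  lineage_divergence = 0.1,
                                  recombination_prob = 0, seed = 103))
  cs <- concat_sequences(sim$dataset)
  anc <- sim$truth$ancestral_sequences
  start <- 1500L
  sub <- cs[1:6]
  sub[[1]] <- implant_recombination(sub[[1]], anc[["L2"]], start, 213L)
  labels <- c("rec", rep("bg", 5))
  segs <- scan_recombinant_segments(unname(sub), labels)
  segs <- segs[segs$label == "rec", , drop = FALSE]
  expect_equal(nrow(segs), 1L)
  expect_gte(interval_jaccard(segs$start, segs$end, start, start + 213L),
             0.5)

  # no recombination: nothing reported at the default cutoff
  segs0 <- scan_recombinant_segments(unname(cs[1:6]), labels)
  expect_equal(nrow(segs0[segs0$label == "rec", , drop = FALSE]), 0L)

  # window larger than the alignment: single whole-length window, no crash
  short <- c("AAAAAAAAAA", "AAAATTAAAA", "AAAAAAAAAA")
  expect_silent(scan_recombinant_segments(short, c("a", "b", "b"),
                                          window_bp = 100))
  expect_error(scan_recombinant_segments(character(), character()),
               "empty")

  # invariant under isolate reordering within labels
  perm <- c(1L, sample(2:6))
  segs_p <- scan_recombinant_segments(unname(sub[perm]), labels[perm])
  segs_p <- segs_p[segs_p$label == "rec", , drop = FALSE]
  expect_equal(segs_p$start, segs$start)
  expect_equal(segs_p$end, segs$end)
})

test_that("r/m partition ratio covers its sentinel and monotone behaviour", {
  al <- c("AAAAAAAAAA", "AAAATTAAAA", "AAAATTAAAA")
  labels <- c("a", "b", "b")
  none <- data.frame(label = character(), start = integer(),
                     end = integer(), snps_in = integer(),
                     background_rate = numeric(), score = numeric())
  expect_equal(estimate_r_over_m(al, labels, none)$r_over_m_simple, 0)

  allin <- data.frame(label = "b", start = 0L, end = 10L, snps_in = 2L,
                      background_rate = 0.2, score = 0)
  expect_equal(estimate_r_over_m(al, labels, allin)$r_over_m_simple, Inf)

  # sweeping recombination upward (theta fixed) never decreases the ratio
  # in rank correlation across seeds
  ratios <- c(); precs <- c()
  for (p_rec in c(0, 0.3, 0.6)) for (s in 1:4) {
    sim <- simulate_mlst(sim_config(isolates_per_lineage = c(5, 5, 5),
                                    per_site_mutation_rate = 0.002,
                                    lineage_divergence = 0.1,
                                    recombination_prob = p_rec,
                                    seed = 200 + 10 * s + round(10 * p_rec)))
    cs <- concat_sequences(sim$dataset)
    lab <- names(cs)
    keep <- sim$truth$lineage_of_isolate == 1
    segs <- scan_recombinant_segments(unname(cs[keep]), lab[keep])
    rm_ <- estimate_r_over_m(unname(cs[keep]), lab[keep], segs)
    ratios <- c(ratios, min(rm_$r_over_m_simple, 100))
    precs <- c(precs, p_rec)
  }
  expect_gt(suppressWarnings(cor(precs, ratios, method = "spearman")), 0)
})
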