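test_that("GC content, segregating sites and pi match hand-counted values", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("AATT"), 0.0)
  expect_equal(gc_content(c("GGAA", "CCAA")), 0.5)
  expect_error(gc_content(character()), "empty")

  expect_equal(segregating_sites(c("AAAA", "AAAA")), 0L)
  expect_equal(segregating_sites(c("AAAA", "AAAT")), 1L)
  expect_error(segregating_sites(c("AAAA", "AAA")), "equal length")

  expect_equal(nucleotide_diversity(c("AAAA", "AAAA")), 0)
  expect_equal(nucleotide_diversity(c("AAAA", "AAAT")), 0.25)
  # 6 pairs, 3 differ at 1 of 4 sites: (3 * 0.25) / 6
  expect_equal(nucleotide_diversity(c("AAAA", "AAAA", "AAAA", "AAAT")),
               0.125)

  # brute-force column-scan oracle on simulated alignments
  set.seed(53)
  for (rep in 1:5) {
    al <- random_alignment(20, 120, 0.03)
    chars <- lapply(al, function(s) strsplit(s, "")[[1L]])
    S <- sum(vapply(seq_len(120), function(j)
      length(unique(vapply(chars, `[[`, "", j))) > 1L, TRUE))
    expect_equal(segregating_sites(al), S)
    diffs <- 0
    for (i in 1:19) for (j in (i + 1):20)
      diffs <- diffs + sum(chars[[i]] != chars[[j]])
    expect_equal(nucleotide_diversity(al), diffs / 190 / 120)
  }
})

test_that("Tajima's D reproduces the singleton example and the oracle", {
  expect_error(tajimas_d(c("AA", "AA", "AA")), "insufficient")
  expect_true(is.na(tajimas_d(rep("AAAA", 4))$D))

  td <- tajimas_d(c("AAAA", "AAAA", "AAAA", "AAAT"))
  expect_equal(td$a1, 11 / 6, tolerance = 1e-12)
  expect_equal(td$pi_total, 0.5)
  expect_equal(td$D, -0.61237243569579458, tolerance = 1e-9)
  expect_equal(td$D, oracle_tajima_d(c("AAAA", "AAAA", "AAAA", "AAAT")),
               tolerance = 1e-12)

  # sign property: a 2/2 split gives D > 0, a singleton gives D < 0
  expect_gt(tajimas_d(c("AAAA", "AAAA", "TAAA", "TAAA"))$D, 0)
  expect_lt(tajimas_d(c("AAAA", "AAAA", "AAAA", "TAAA"))$D, 0)

  set.seed(59)
  for (rep in 1:10) {
    al <- random_alignment(sample(4:10, 1), 80, 0.05)
    expect_equal(tajimas_d(al)$D, oracle_tajima_d(al), tolerance = 1e-9)
  }
})

test_that("D sign tracks the sign of pi_total - S/a1 (the D = 0 identity)", {
  set.seed(61)
  for (rep in 1:20) {
    al <- random_alignment(8, 60, 0.04)
    td <- tajimas_d(al)
    if (td$S == 0) next
    expect_equal(sign(td$D), sign(td$pi_total - td$S / td$a1))
  }
})

test_that("Nei-Gojobori matches forced examples and the pathway oracle", {
  ng0 <- nei_gojobori(c("ATGGCTTTT", "ATGGCTTTT"))
  expect_equal(ng0$Nd, 0); expect_equal(ng0$Sd, 0)
  expect_true(is.na(ng0$ratio))

  # GCT vs GCC: Ala -> Ala, one synonymous change, dN = 0 so ratio 0
  ng1 <- nei_gojobori(c("GCT", "GCC"))
  expect_equal(ng1$Nd, 0)
  expect_equal(ng1$Sd, 1)
  expect_equal(ng1$ratio, 0)

  # single nonsynonymous change: dS = 0 sentinel
  ng2 <- nei_gojobori(c("ATGGCTTTT", "ATGGATTTT"))
  o2 <- oracle_ng86_pair("ATGGCTTTT", "ATGGATTTT")
  expect_equal(ng2$Nd, o2$Nd); expect_equal(ng2$Sd, o2$Sd)
  expect_equal(ng2$N_sites, o2$N_sites, tolerance = 1e-12)
  expect_true(is.na(ng2$ratio))

  set.seed(67)
  for (rep in 1:10) {
    a <- random_coding_seq(30)
    b <- mutate_sequence(a, 0.05)
    if (has_stop_codon(b)) next  # stop-codon handling tested separately
    got <- nei_gojobori(c(a, b))
    want <- oracle_ng86_pair(a, b)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-9)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-9)
    expect_equal(got$N_sites, want$N_sites, tolerance = 1e-9)
    expect_equal(got$S_sites, want$S_sites, tolerance = 1e-9)
    if (!is.na(want$dS) && want$dS > 0)
      expect_equal(got$ratio, want$dN / want$dS, tolerance = 1e-9)
  }

  # multi-sequence averaging equals the explicit pair-loop mean
  set.seed(71)
  seqs <- c(a <- random_coding_seq(20), mutate_sequence(a, 0.04),
            mutate_sequence(a, 0.04), mutate_sequence(a, 0.04))
  if (!any(vapply(seqs, has_stop_codon, TRUE))) {
    got <- nei_gojobori(seqs)
    pairs <- utils::combn(4, 2)
    oo <- apply(pairs, 2, function(ij)
      unlist(oracle_ng86_pair(seqs[ij[1]], seqs[ij[2]])[c("Nd", "Sd")]))
    expect_equal(got$Nd, mean(oo["Nd", ]), tolerance = 1e-9)
    expect_equal(got$Sd, mean(oo["Sd", ]), tolerance = 1e-9)
  }
})

test_that("synonymous-only divergence drives the ratio to 0 and stops are handled", {
  # CTT/CTC/CTA/CTG all encode Leu: synonymous-only alignment
  syn <- c("CTTCTTCTT", "CTCCTCCTC", "CTACTACTA")
  ngs <- nei_gojobori(syn)
  expect_equal(ngs$ratio, 0)

  # internal stop codon: warn-and-exclude by default, error on request
  has_stop <- c("ATGTAAGCT", "ATGTAAGCC")
  expect_warning(ngx <- nei_gojobori(has_stop), "stop")
  expect_equal(ngx$Sd, 1)  # only the GCT/GCC codon column remains
  expect_error(nei_gojobori(has_stop, on_stop = "error"), "stop")
})

test_that("stats table covers all loci plus the 3177-bp concatenated row", {
  sim <- simulate_mlst(sim_config(isolates_per_lineage = c(4, 4, 4),
                                  per_site_mutation_rate = 0.003,
                                  seed = 73))
  fit <- mlst(sim$dataset)
  st <- suppressWarnings(stats_table(fit))
  expect_equal(nrow(st), 7L)
  expect_equal(st$length[st$locus == "Concatenated"], 3177L)
  expect_equal(st$length[1:6], c(600L, 664L, 487L, 574L, 355L, 497L))
  expect_equal(st$n_alleles[7], nrow(fit$st_table$profiles))
  expect_true(all(st$polymorphic_sites >= 0 & st$polymorphic_sites <=
                  st$length))
  expect_true(all(st$pi >= 0 & st$pi <= 1))

  # theta = 0 degeneracy: no polymorphism anywhere, alleles = lineages
  sim0 <- simulate_mlst(sim_config(isolates_per_lineage = c(4, 4, 4),
                                   per_site_mutation_rate = 0,
                                   lineage_divergence = 0.02,
                                   recombination_prob = 0, seed = 79))
  st0 <- suppressWarnings(stats_table(mlst(sim0$dataset)))
  expect_true(all(st0$polymorphic_sites > 0))  # lineage divergence remains
  expect_equal(st0$n_alleles[1:6], rep(3L, 6))

  # statistics invariant under sequence reordering
  perm <- sample(nrow(sim$dataset$metadata))
  meta_p <- sim$dataset$metadata[perm, , drop = FALSE]
  ds_p <- mlst_dataset(sim$dataset$sequences, meta_p, sim$dataset$scheme)
  st_p <- suppressWarnings(stats_table(mlst(ds_p)))
  expect_equal(st_p[, c("length", "polymorphic_sites", "gc", "tajima_D",
                        "pi", "dn_ds")],
               st[, c("length", "polymorphic_sites", "gc", "tajima_D",
                      "pi", "dn_ds")],
               tolerance = 1e-12)
})

test_that("under the star-genealogy simulator Tajima's D is negative in expectation", {
  # the generator mutates isolates independently from a shared ancestor, so
  # rare variants are over-represented relative to a coalescent genealogy
  set.seed(83)
  ds <- replicate(15, {
    sim <- simulate_mlst(sim_config(n_lineages = 1,
                                    isolates_per_lineage = 20,
                                    per_site_mutation_rate = 0.01,
                                    recombination_prob = 0,
                                    seed = sample.int(1e6, 1)))
    tajimas_d(unname(concat_sequences(sim$dataset)))$D
  })
  expect_lt(mean(ds), 0)
})
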