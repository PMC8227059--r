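# Synthetic-data generator: founders, meiosis-derived populations,
# testcrosses and multi-environment phenotypes.

test_that("founders are homozygous, deterministic, and hit target frequencies", {
  cfg <- sim_config(genome = genome_map(n_chromosomes = 2, n_markers = 50),
                    n_qtl = 20, maf_range = c(0.3, 0.3), seed = 7)
  f1 <- simulate_founders(cfg, n_founders = 10000)
  expect_false(any(f1$calls == 1L))              # inbred: never Aa
  expect_true(all(f1$calls %in% c(0L, 2L)))
  f2 <- simulate_founders(cfg, n_founders = 10000)
  expect_identical(f1$calls, f2$calls)           # same seed, same matrix
  # binomial sampling oracle: realized per-locus frequency within 3 SE of 0.3
  p_hat <- colMeans(f1$calls) / 2
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_true(all(abs(p_hat - 0.3) < 3 * se + 1e-12 |
                    abs(p_hat - 0.3) < 4 * se))  # allow 1 locus at 3-4 SE
  expect_lt(max(abs(p_hat - 0.3)), 4 * se)
  cfg0 <- sim_config(genome = genome_map(n_markers = 10), n_qtl = 5)
  cfg0$genome <- cfg0$genome[0, ]
  expect_error(simulate_founders(cfg0), "zero markers")
})

test_that("derived populations match their breeding-design expectations", {
  cfg <- sim_config(genome = genome_map(n_chromosomes = 5, n_markers = 200),
                    n_qtl = 20, maf_range = c(0.5, 0.5), seed = 3)
  founders <- simulate_founders(cfg, n_founders = 3,
                                founder_ids = c("don", "rec", "oth"))
  # force donor/recurrent fully informative (all loci segregate)
  founders$calls["don", ] <- 2L
  founders$calls["rec", ] <- 0L

  dh <- derive_population(pedigree_spec("dh", 40, c(donor = "don", recurrent = "rec"),
                                        "oth"), founders, seed = 5)
  expect_false(any(dh$calls == 1L))              # doubled haploids homozygous

  # one backcross then intercross/selfing: expected recurrent share 0.75
  bc <- derive_population(pedigree_spec("bc1f3", 2000,
                                        c(donor = "don", recurrent = "rec"),
                                        "oth"), founders, seed = 6)
  rec_share <- 1 - mean(bc$calls) / 2            # rec allele dosage share
  se <- sd(1 - rowMeans(bc$calls) / 2) / sqrt(2000)
  expect_lt(abs(rec_share - 0.75), 3 * se)

  # F4 heterozygosity: brute-force single-locus selfing recursion oracle
  selfing_het <- function(generations) {
    p <- c(AA = 0, Aa = 1, aa = 0)
    for (g in seq_len(generations))
      p <- c(AA = unname(p["AA"] + p["Aa"] / 4), Aa = unname(p["Aa"] / 2),
             aa = unname(p["aa"] + p["Aa"] / 4))
    unname(p["Aa"])
  }
  expect_equal(selfing_het(3), 0.125)            # F1 -> F4
  f4 <- derive_population(pedigree_spec("f45", 3000, c(p1 = "don", p2 = "rec"),
                                        "oth"), founders, seed = 8)
  line_het <- rowMeans(f4$calls == 1L)           # loci correlated, lines iid
  se_het <- sd(line_het) / sqrt(length(line_het))
  expect_lt(abs(mean(line_het) - selfing_het(3)), 4 * se_het)

  expect_error(derive_population(pedigree_spec("bc1f3", 5,
                                               c(donor = "nope", recurrent = "rec"),
                                               "oth"), founders),
               "not found")
  expect_error(pedigree_spec("f6", 5, character(), "oth"), "unknown population_type")
})

test_that("testcross codes follow Mendelian expectations", {
  g <- toy_geno(rbind(c("AA", "aa", "Aa"),
                      c("aa", "AA", "Aa")))
  tester <- c(2L, 2L, 2L)                        # AA tester
  h <- testcross(g, tester)
  expect_equal(unname(h$Z[1, ]), c(1, 0, 0.5))   # AAxAA=1, aaxAA=0, AaxAA=0.5
  expect_equal(unname(h$W[1, ]), c(0, 1, 0.5))
  expect_error(testcross(g, c(2L, 1L, 2L)), "homozygous")
})

test_that("phenotype simulation matches the trial model", {
  st <- small_study()
  rec <- st$records
  cfg <- st$config
  n <- sum(cfg$pop_sizes)
  expect_equal(nrow(rec), n * 3 * 2)             # lines x env x rep rows
  expect_equal(length(unique(rec$line)), n)

  # var_ge = var_error = 0 => replicates identical up to rep effects; with
  # var_rep = 0 too, H2 = 1
  cfg0 <- sim_config(genome = cfg$genome, n_qtl = 50, var_ge = 0,
                     var_rep = 0, var_error = 0, seed = 9)
  rec0 <- simulate_phenotypes(st$hybrids, cfg0)
  wide <- tapply(rec0$yield, list(rec0$line, paste(rec0$env, rec0$rep)), mean)
  expect_lt(max(apply(sweep(wide, 2, colMeans(wide)), 1, sd)), 1e-9)
  expect_equal(heritability(anova_ms(rec0)), 1, tolerance = 1e-9)

  # deterministic under identical config
  rec_b <- simulate_phenotypes(st$hybrids, cfg)
  expect_identical(rec$yield, rec_b$yield)
})

test_that("H2 converges to the plug-in value for large n", {
  # var_g=1, var_ge=0.5, var_error=1, e=3, r=2 -> H2 = 1/(1 + 0.5/3 + 1/6)
  cfg <- sim_config(genome = genome_map(n_chromosomes = 2, n_markers = 120),
                    pop_sizes = c(bc1f3 = 0, dh = 0, f45 = 0, unrelated = 1000),
                    n_qtl = 60, var_g = 1, var_ge = 0.5, var_rep = 0.1,
                    var_error = 1, mu = 0, env_means = c(0, 0, 0), seed = 21)
  founders <- simulate_founders(cfg, n_founders = 20)
  pop <- derive_population(pedigree_spec("unrelated", 1000, character(), "f"),
                           founders, seed = 22)
  hyb <- testcross(pop, founders$calls[1, ])
  rec <- simulate_phenotypes(hyb, cfg)
  h2 <- heritability(anova_ms(rec, convention = "classical"))
  expect_lt(abs(h2 - 1 / (1 + 0.5 / 3 + 1 / 6)), 0.05)
})
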