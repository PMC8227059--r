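# SNP QC, imputation, allele coding and hybrid genotype inference.

test_that("filter_snps applies the four rules in order and is idempotent", {
  calls <- matrix(2L, 100, 5,
                  dimnames = list(paste0("L", 1:100), paste0("m", 1:5)))
  calls[, 2] <- c(rep(0L, 50), rep(2L, 50))      # polymorphic, clean
  calls[1:2, 3] <- NA                            # missing rate 0.02 -> removed
  calls[, 4] <- c(rep(0L, 2), rep(2L, 98))       # MAF 0.02 -> removed
  calls[, 5] <- c(rep(0L, 40), rep(2L, 60))
  g <- toy_geno(matrix("AA", 1, 5))              # template for map
  g <- geno_matrix(calls, data.frame(marker = paste0("m", 1:5),
                                     chrom = c(1, 1, 1, 1, NA),
                                     pos = c(10, 20, 30, 40, NA),
                                     a1 = "A", a2 = "B"))
  filt <- filter_snps(g, maf_min = 0.05, missing_rate_max = 0.01)
  expect_identical(colnames(filt$calls), c("m2"))  # m1 monomorphic (MAF 0)
  rem <- attr(filt, "removed")
  expect_equal(unname(rem["position"]), 1L)
  expect_equal(unname(rem["missing"]), 1L)
  expect_equal(unname(rem["maf"]), 2L)           # m1 and m4

  # already-clean matrix is unchanged; reapplication is identity
  again <- filter_snps(filt)
  expect_identical(again$calls, filt$calls)

  strict <- function() filter_snps(g, maf_min = 0.6)
  expect_error(strict(), "no markers survive")
})

test_that("imputation fills missing calls as documented", {
  s <- matrix("AA", 11, 2)
  s[1:10, 1] <- "AA"; s[11, 1] <- NA; s[10, 1] <- "aa"
  g <- toy_geno(s)
  imp <- impute_missing(g)
  expect_false(anyNA(imp$calls))
  expect_equal(imp$calls[11, 1], 2L)             # major call is AA
  # no missing -> untouched
  expect_identical(impute_missing(imp)$calls, imp$calls)
  # freq_sample deterministic under a fixed seed
  a <- impute_missing(g, "freq_sample", seed = 5)
  b <- impute_missing(g, "freq_sample", seed = 5)
  expect_identical(a$calls, b$calls)
  # all-missing marker errors
  s2 <- matrix(c(NA, NA, "AA", "aa"), 2, 2)
  expect_error(impute_missing(toy_geno(s2)), "no observed calls")
})

test_that("code_alleles orients the minor allele as A with lexicographic ties", {
  # a1 frequency 0.7 -> flip so minor becomes a1
  s <- rbind(c("AA"), c("AA"), c("AA"), c("aa"), c("aa"),
             c("AA"), c("AA"), c("AA"), c("aa"), c("AA"))
  g <- toy_geno(s, a1 = "G", a2 = "C")
  coded <- code_alleles(g)
  expect_equal(coded$map$a1, "C")                # minor now first
  expect_equal(unname(additive_codes(coded)[, 1]),
               ifelse(s[, 1] == "AA", -1, 1))    # old AA is now aa = -1
  # exact tie: lexicographically smaller label becomes minor
  s_tie <- rbind("AA", "aa")
  tie <- code_alleles(toy_geno(s_tie, a1 = "T", a2 = "C"))
  expect_equal(tie$map$a1, "C")
  # monomorphic marker warns
  expect_warning(code_alleles(toy_geno(rbind("AA", "AA"))), "monomorphic")
})

test_that("hybrid codes equal parental means and expected heterozygosity", {
  # all six mating types against both tester homozygotes
  lines <- toy_geno(rbind(c("AA"), c("Aa"), c("aa")))
  # brute-force Mendelian enumeration oracle
  enumerate <- function(line_dose, tester_dose) {
    la <- c(rep(1, line_dose), rep(0, 2 - line_dose))     # line alleles
    ta <- c(rep(1, tester_dose), rep(0, 2 - tester_dose))
    off <- expand.grid(l = la, t = ta)
    c(add = mean(off$l + off$t - 1), het = mean(off$l != off$t))
  }
  for (td in c(0L, 2L)) {
    h <- infer_hybrid_genotypes(lines, rep(td, 1))
    for (i in 1:3) {
      ex <- enumerate(lines$calls[i, 1], td)
      expect_equal(unname(h$Z[i, 1]), unname(ex["add"]))
      expect_equal(unname(h$W[i, 1]), unname(ex["het"]))
    }
  }
  # headline codings: Aa x AA -> 0.5 / 0.5 ; Aa x aa -> -0.5 / 0.5
  hAA <- infer_hybrid_genotypes(lines, 2L)
  expect_equal(unname(hAA$Z[2, 1]), 0.5)
  expect_equal(unname(hAA$W[2, 1]), 0.5)
  haa <- infer_hybrid_genotypes(lines, 0L)
  expect_equal(unname(haa$Z[2, 1]), -0.5)
  expect_equal(unname(haa$W[2, 1]), 0.5)
  # W is zero wherever parents share a homozygous genotype
  expect_equal(unname(hAA$W[1, 1]), 0)
  expect_equal(unname(haa$W[3, 1]), 0)
  expect_error(infer_hybrid_genotypes(lines, 1L), "homozygous")
})

test_that("genotype TSV and VCF round-trips preserve calls", {
  st <- small_study()
  g <- st$founders
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_geno_tsv(g, tmp)
  back <- read_geno_tsv(tmp)
  expect_identical(back$calls, g$calls)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##contig=<ID=1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t100\tsnp1\tA\tG\t.\t.\t.\tGT\t0/0\t1/1",
    "1\t200\tsnp2\tC\tT\t.\t.\t.\tGT\t0/1\t./.",
    "1\t300\tindel\tC\tTT\t.\t.\t.\tGT\t0/0\t0/0"), vcf)
  suppressWarnings(suppressMessages({
    gv <- read_vcf_genotypes(vcf)
  }))
  expect_equal(dim(gv$calls), c(2L, 2L))
  expect_equal(unname(gv$calls["S1", ]), c(0L, 1L))
  expect_equal(unname(gv$calls["S2", ]), c(2L, NA))
})
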