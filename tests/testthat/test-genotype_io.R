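# PLINK text and binary genotype IO.

test_that("PED/MAP parsing codes homozygotes, missing and drops non-autosomes", {
  d <- withr::local_tempdir()
  writeLines(c("1\tm1\t0\t1000",
               "1\tm2\t0\t2000",
               "19\tm3\t0\t3000"), file.path(d, "x.map"))
  writeLines(c("F1 S1 0 0 0 -9 A A A C G G",
               "F1 S2 0 0 0 -9 C C 0 0 G G"), file.path(d, "x.ped"))
  res <- suppressMessages(read_ped_map(file.path(d, "x.ped"),
                                       file.path(d, "x.map")))
  # chromosome-19 marker absent from the map
  expect_equal(res$map$snp, c("m1", "m2"))
  expect_equal(ncol(res$geno), 2L)
  # homozygote codes are 0 or 2, never 1; first-seen allele is A1
  expect_equal(res$geno["S1", "m1"], 0L)   # A A, A first seen
  expect_equal(res$geno["S2", "m1"], 2L)   # C C, other homozygote
  expect_equal(res$geno["S1", "m2"], 1L)   # A C heterozygote
  expect_true(is.na(res$geno["S2", "m2"])) # 0 0 -> missing
})

test_that("PED parse errors name the offending line", {
  d <- withr::local_tempdir()
  writeLines("1\tm1\t0\t1000", file.path(d, "x.map"))
  writeLines(c("F1 S1 0 0 0 -9 A A",
               "F1 S2 0 0 0 -9 A"), file.path(d, "x.ped"))
  expect_error(read_ped_map(file.path(d, "x.ped"), file.path(d, "x.map")),
               "line 2")
  writeLines(c("F1 S1 0 0 0 -9 X A"), file.path(d, "y.ped"))
  expect_error(read_ped_map(file.path(d, "y.ped"), file.path(d, "x.map")),
               "allele symbol")
  writeLines(c("F1 S1 0 0 0 -9 A 0"), file.path(d, "z.ped"))
  expect_error(read_ped_map(file.path(d, "z.ped"), file.path(d, "x.map")),
               "half-missing")
})

test_that("BED 2-bit decoding follows the PLINK bit spec", {
  d <- withr::local_tempdir()
  pre <- file.path(d, "one")
  writeLines("1\tm1\t0\t1000\t1\t2", paste0(pre, ".bim"))
  writeLines("F1 S1 0 0 0 -9", paste0(pre, ".fam"))
  for (case in list(list(byte = 0x03, code = 2L),   # 11 -> hom A2
                    list(byte = 0x00, code = 0L),   # 00 -> hom A1
                    list(byte = 0x02, code = 1L))) {# 10 -> het
    writeBin(as.raw(c(0x6c, 0x1b, 0x01, case$byte)), paste0(pre, ".bed"))
    res <- read_bed_bim_fam(pre)
    expect_equal(res$geno[1, 1], case$code)
  }
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x01)), paste0(pre, ".bed")) # 01
  expect_true(is.na(read_bed_bim_fam(pre)$geno[1, 1]))
  # bad magic is refused
  writeBin(as.raw(c(0x6c, 0x00, 0x01, 0x00)), paste0(pre, ".bed"))
  expect_error(read_bed_bim_fam(pre), "magic")
})

test_that("binary round trip reproduces a random matrix exactly", {
  set.seed(11)
  map <- make_map(20, spacing = 5e4)
  g <- matrix(sample(c(0:2, NA), 200, replace = TRUE), nrow = 10)
  rownames(g) <- sprintf("S%02d", 1:10)
  colnames(g) <- map$snp
  storage.mode(g) <- "integer"
  pre <- file.path(withr::local_tempdir(), "rt")
  write_bed_bim_fam(g, map, pre)
  back <- read_bed_bim_fam(pre)
  expect_identical(back$geno, g)
  expect_equal(back$map, map)
})

test_that("text and binary loaders agree on equivalent inputs", {
  set.seed(12)
  map <- make_map(30, spacing = 4e4)
  # first sample carries code 0 everywhere so the PED first-seen allele
  # matches the BIM A1 and codes align across dialects
  g <- rbind(rep(0L, 30),
             matrix(sample(c(0:2, NA), 150, replace = TRUE,
                           prob = c(0.3, 0.3, 0.3, 0.1)), nrow = 5))
  rownames(g) <- sprintf("S%d", 1:6)
  colnames(g) <- map$snp
  storage.mode(g) <- "integer"
  d <- withr::local_tempdir()
  write_ped_map(g, map, file.path(d, "t"))
  write_bed_bim_fam(g, map, file.path(d, "b"))
  ped <- read_ped_map(file.path(d, "t.ped"), file.path(d, "t.map"))
  bed <- read_bed_bim_fam(file.path(d, "b"))
  expect_identical(ped$geno, bed$geno)
  expect_identical(ped$geno, g)
})

test_that("ROH tables are written .hom-style, sorted, with KB arithmetic", {
  d <- withr::local_tempdir()
  f <- file.path(d, "empty.tsv")
  write_roh_table(empty <- data.frame(sample = character(), chr = integer(),
                                      start = numeric(), end = numeric(),
                                      n_snps = integer()), f)
  expect_equal(readLines(f),
               "FID\tIID\tCHR\tSNP1\tSNP2\tPOS1\tPOS2\tKB\tNSNP")

  seg <- data.frame(sample = c("S1", "S1"), chr = c(1L, 1L),
                    start = c(5e6, 1e6), end = c(8e6, 3499999),
                    n_snps = c(60L, 55L), stringsAsFactors = FALSE)
  f2 <- file.path(d, "two.tsv")
  write_roh_table(seg, f2)
  tab <- read.delim(f2)
  expect_equal(tab$POS1, c(1e6, 5e6))        # sorted by start
  expect_equal(tab$KB[1], 2500.0)            # (end - start + 1) / 1000
})
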