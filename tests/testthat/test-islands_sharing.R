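# Per-SNP incidence, hotspot calling, island construction and sharing.

test_that("incidence counts individuals, not segments", {
  map <- make_map(200, spacing = 1e4)
  pop <- sprintf("P_%02d", 1:10)
  seg <- data.frame(sample = pop[1:9], chr = 1L,
                    start = map$pos[100], end = map$pos[150],
                    n_snps = 51L, length_bp = map$pos[150] - map$pos[100] + 1)
  tr <- snp_incidence(seg, map, pop)
  expect_equal(unique(tr$incidence[100:150]), 0.9)
  expect_true(all(tr$incidence[c(1:99, 151:200)] == 0))
  # no ROH at all -> all-zero track; empty population -> error
  expect_true(all(snp_incidence(seg[0, ], map, pop)$incidence == 0))
  expect_error(snp_incidence(seg, map, character()), "empty population")
})

test_that("hotspots are the top tail with ties included, zeros never", {
  map <- make_map(1000, spacing = 5e4)
  tr <- data.frame(snp = map$snp, chr = map$chr, pos = map$pos,
                   incidence = rep(0.1, 1000))
  tr$incidence[c(37, 101:109)] <- 0.9
  hs <- call_hotspots(tr, top_fraction = 0.01)
  expect_equal(sort(hs$pos), sort(tr$pos[c(37, 101:109)]))

  # all values tied at the threshold: everything returned, with a warning
  tr2 <- tr; tr2$incidence <- 0.5
  expect_warning(hs2 <- call_hotspots(tr2, 0.01), "tie")
  expect_equal(nrow(hs2), 1000L)

  # all-zero track: empty set with a warning
  tr3 <- tr; tr3$incidence <- 0
  expect_warning(hs3 <- call_hotspots(tr3, 0.01), "zero")
  expect_equal(nrow(hs3), 0L)

  # zero-incidence markers never qualify even when the quantile is zero
  tr4 <- tr; tr4$incidence <- 0; tr4$incidence[5] <- 0.2
  hs4 <- suppressWarnings(call_hotspots(tr4, 0.5))
  expect_equal(hs4$pos, tr4$pos[5])
})

test_that("hotspot calling equals a rank-and-cut oracle on random tracks", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(200:800, 1)
    map <- make_map(n, spacing = 5e4)
    inc <- runif(n)                      # continuous: ties improbable
    tr <- data.frame(snp = map$snp, chr = map$chr, pos = map$pos,
                     incidence = inc)
    hs <- call_hotspots(tr, 0.01)
    k <- ceiling(0.01 * n)
    cut <- sort(inc, decreasing = TRUE)[k]
    expect_setequal(hs$snp, tr$snp[inc >= cut])
  }
})

test_that("hotspot count is at least the tail share of nonzero markers", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(100:600, 1)
    map <- make_map(n, spacing = 5e4)
    inc <- ifelse(runif(n) < 0.7, 0, runif(n))
    if (all(inc == 0)) inc[1] <- 0.5
    tr <- data.frame(snp = map$snp, chr = map$chr, pos = map$pos,
                     incidence = inc)
    hs <- suppressWarnings(call_hotspots(tr, 0.01))
    expect_gte(nrow(hs), ceiling(0.01 * sum(inc > 0)))
  }
})

test_that("islands are gap-bounded runs of hotspot markers", {
  hs <- data.frame(snp = c("a", "b", "c"), chr = 8L,
                   pos = c(1e6, 1.1e6, 1.2e6), incidence = c(0.4, 0.5, 0.45))
  isl <- build_islands(hs, population = "X")
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$start, 1e6)
  expect_equal(isl$end, 1.2e6)
  expect_equal(isl$n_hotspot_snps, 3L)
  expect_equal(isl$peak_incidence, 0.5)

  # an 800 kb gap splits
  hs2 <- data.frame(snp = c("a", "b"), chr = 1L, pos = c(1e6, 1.8e6),
                    incidence = 0.3)
  expect_equal(nrow(build_islands(hs2)), 2L)

  # isolated hotspot: zero-length span retained
  isl3 <- build_islands(hs2[1, ])
  expect_equal(isl3$start, isl3$end)

  # islands within a population never overlap
  set.seed(42)
  hs4 <- data.frame(snp = sprintf("s%d", 1:50), chr = 1L,
                    pos = sort(sample(1e7, 50)), incidence = runif(50))
  isl4 <- build_islands(hs4)
  if (nrow(isl4) > 1) {
    expect_true(all(isl4$start[-1] > isl4$end[-nrow(isl4)]))
  }
})

isl <- function(chr, start, end, pop = "g") {
  data.frame(population = pop, chr = chr, start = start, end = end,
             n_hotspot_snps = 1L, peak_incidence = 0.5,
             stringsAsFactors = FALSE)
}

test_that("three-set sharing counts follow the overlap definition", {
  A <- isl(1L, 1e6, 2e6, "A")
  B <- isl(1L, 1.5e6, 2.5e6, "B")
  C0 <- isl(1L, 1, 1)[0, ]
  v <- venn_segments(list(A = A, B = B, C = C0))
  expect_equal(unname(v$counts["AB"]), 1)
  expect_equal(unname(v$counts["ABC"]), 0)
  expect_equal(unname(v$counts["only_A"]), 0)

  # identical lists: everything is in the triple region
  X <- rbind(isl(1L, 1e6, 2e6), isl(2L, 5e6, 9e6))
  v2 <- venn_segments(list(A = X, B = X, C = X))
  expect_equal(unname(v2$counts["ABC"]), 2)
  expect_true(all(v2$counts[c("only_A", "only_B", "only_C", "AB", "AC",
                              "BC")] == 0))

  # disjoint lists: only the exclusive regions fill
  v3 <- venn_segments(list(A = isl(1L, 1e6, 2e6),
                           B = isl(1L, 5e6, 6e6),
                           C = rbind(isl(2L, 1e6, 2e6), isl(2L, 4e6, 5e6))))
  expect_equal(unname(v3$counts[c("only_A", "only_B", "only_C")]), c(1, 1, 2))
  expect_true(all(v3$counts[c("AB", "AC", "BC", "ABC")] == 0))
})

test_that("each group's islands partition into its four sharing regions", {
  set.seed(43)
  rand_islands <- function(n, pop) {
    start <- sort(sample(seq(1e6, 9e7, by = 1e6), n))
    do.call(rbind, lapply(seq_len(n), function(i) {
      isl(sample(1:2, 1), start[i], start[i] + sample(5e5:3e6, 1), pop)
    }))
  }
  g <- list(A = rand_islands(8, "A"), B = rand_islands(10, "B"),
            C = rand_islands(6, "C"))
  v <- venn_segments(g)
  sums <- rowSums(v$regions[, c("exclusive", "with_first_other",
                                "with_second_other", "with_both")])
  expect_equal(unname(sums), unname(v$regions$total))
  expect_equal(unname(v$regions$total), vapply(g, nrow, numeric(1),
                                               USE.NAMES = FALSE))
})

test_that("reference sharing keeps exactly the overlapping islands", {
  ref <- rbind(isl(1L, 1e6, 2e6, "R"), isl(2L, 5e6, 8e6, "R"))
  pop <- rbind(isl(1L, 1.9e6, 3e6, "P"),   # overlaps reference
               isl(1L, 4e6, 5e6, "P"),     # disjoint
               isl(2L, 5e6, 8e6, "P"))     # identical to a reference island
  out <- shared_with_reference(list(R = ref, P = pop), "R")
  expect_equal(nrow(out), 2L)
  expect_equal(out$start, c(1.9e6, 5e6))
  expect_error(shared_with_reference(list(P = pop), "R"), "not present")
})
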