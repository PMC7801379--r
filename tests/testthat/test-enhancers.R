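# Stitching, super-enhancer calling, typical enhancers, TSS assignment,
# eRNA windows and the SE-vs-TE rank-sum comparison.

# brute-force tangent-rule oracle, written independently of the caller
brute_se_flags <- function(s) {
  n <- length(s)
  if (max(s) == min(s)) return(rep(FALSE, n))
  o <- order(s)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s[o] - min(s)) / (max(s) - min(s))
  best <- 1L
  for (i in seq_len(n)) if (y[i] - x[i] <= y[best] - x[best]) best <- i
  fl <- logical(n)
  fl[o[seq_len(n) > best]] <- TRUE
  fl
}

# exact rank-sum oracle over all C(N, n1) rank splits
enum_rank_sum <- function(a, b) {
  N <- length(a) + length(b)
  rk <- rank(c(a, b))
  W <- sum(rk[seq_along(a)])
  combos <- utils::combn(N, length(a))
  Ws <- apply(combos, 2, function(ix) sum(rk[ix]))
  min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
}

test_that("stitch_peaks merges by edge-to-edge gap", {
  pk <- data.table(chrom = "chr1",
                   start = c(0, 5000, 30000), end = c(1000, 6000, 31000),
                   signal = c(1, 2, 4))
  st <- stitch_peaks(pk, min_dist = 12500)
  expect_equal(st$start, c(0, 30000))
  expect_equal(st$end, c(6000, 31000))
  expect_equal(st$signal, c(3, 4))
  expect_equal(st$n_constituents, c(2L, 1L))
  # single peak: unchanged
  st1 <- stitch_peaks(pk[3], min_dist = 12500)
  expect_equal(st1[, .(start, end, signal)], pk[3, .(start, end, signal)])
  # overlapping peaks always merge
  ov <- data.table(chrom = "c", start = c(0, 500), end = c(1000, 1500),
                   signal = c(1, 1))
  expect_equal(nrow(stitch_peaks(ov, min_dist = 0)), 1L)
})

test_that("stitching is idempotent with pairwise gaps above min_dist", {
  set.seed(5)
  for (i in 1:20) {
    pk <- data.table(chrom = sample(c("c1", "c2"), 40, replace = TRUE),
                     start = sample.int(5e5, 40))
    pk[, end := start + sample(200:2000, 40, replace = TRUE)]
    pk[, signal := runif(40)]
    st <- stitch_peaks(pk, min_dist = 12500)
    st2 <- stitch_peaks(st[, .(chrom, start, end, signal)], min_dist = 12500)
    expect_equal(st2[, .(chrom, start, end, signal)],
                 st[, .(chrom, start, end, signal)])
    gaps <- st[, start[-1] - end[-.N], by = chrom]$V1
    expect_true(all(gaps > 12500))
  }
})

test_that("call_super_enhancers places the cutoff on the scaled hockey-stick", {
  mk <- function(s) data.table(region_id = as.character(seq_along(s)),
                               chrom = "c", start = seq_along(s) * 1e5,
                               end = seq_along(s) * 1e5 + 1000, signal = s)
  # 98 low / 2 high: exactly the two high regions
  r <- call_super_enhancers(mk(c(rep(1, 98), 100, 100)))
  expect_equal(sum(r$is_super), 2L)
  expect_true(all(r[signal == 100, is_super]))
  # all equal: degenerate, none flagged
  r0 <- call_super_enhancers(mk(rep(7, 50)))
  expect_equal(sum(r0$is_super), 0L)
  expect_true(is.na(attr(r0, "cutoff_signal")))
  # monotone geometric signals match the brute-force slope/tangent oracle
  g <- 2^(0:15)
  rg <- call_super_enhancers(mk(g))
  expect_equal(rg$is_super, brute_se_flags(g))
  expect_error(call_super_enhancers(mk(1)), "insufficient data")
})

test_that("SE calling equals the brute-force oracle on random signal vectors", {
  set.seed(11)
  mk <- function(s) data.table(region_id = as.character(seq_along(s)),
                               chrom = "c", start = seq_along(s) * 1e5,
                               end = seq_along(s) * 1e5 + 1000, signal = s)
  for (i in 1:200) {
    n <- sample(2:80, 1)
    s <- rlnorm(n, sdlog = sample(c(0.3, 1, 2), 1))
    expect_identical(call_super_enhancers(mk(s))$is_super, brute_se_flags(s))
  }
})

test_that("typical enhancers require K4me1 overlap, TSS distance and SE exclusion", {
  k27 <- data.table(chrom = "chr1",
                    start = c(20000, 40000, 60000, 80000),
                    end = c(21000, 41000, 61000, 81000),
                    name = c("a", "b", "c", "d"), signal = 1)
  k4 <- data.table(chrom = "chr1", start = c(20500, 40500, 80500),
                   end = c(21500, 41500, 81500))  # peak "c" has no overlap
  tss <- data.table(gene = c("g1", "g2"), chrom = "chr1",
                    tss = c(41500, 120000))       # 500 bp from peak "b" edge
  ses <- data.table(chrom = "chr1", start = 80999, end = 90000,
                    is_super = TRUE)              # 1 bp overlap with "d"
  te <- define_typical_enhancers(k27, k4, tss, ses)
  expect_equal(te$name, "a")
  # TE set disjoint from SEs and TSS-proximal zones by construction
  expect_false(any(caploop:::.overlaps_any(te, ses)))
})

test_that("nearest_tss_assignment uses edge distance with low-coordinate ties", {
  tss <- data.table(gene = c("near", "far", "inside"), chrom = "chr1",
                    tss = c(11500, 20000, 10500))
  r1 <- nearest_tss_assignment(
    data.table(chrom = "chr1", start = 10000, end = 11000), tss[1:2])
  expect_equal(r1$gene, "near")
  expect_equal(r1$tss_distance, 500)
  # TSS inside the region: distance 0
  r2 <- nearest_tss_assignment(
    data.table(chrom = "chr1", start = 10000, end = 11000), tss)
  expect_equal(r2$gene, "inside")
  expect_equal(r2$tss_distance, 0)
  # equidistant: the lower-coordinate gene wins
  tss3 <- data.table(gene = c("hi", "lo"), chrom = "chr1", tss = c(1500, 500))
  r3 <- nearest_tss_assignment(
    data.table(chrom = "chr1", start = 900, end = 1100), tss3)
  expect_equal(r3$gene, "lo")
  # no TSS on the chromosome: unassigned
  r4 <- nearest_tss_assignment(
    data.table(chrom = "chr9", start = 0, end = 10), tss)
  expect_true(is.na(r4$gene))
})

test_that("erna_windows keeps intergenic enhancer-overlapping ATAC peaks", {
  atac <- data.table(chrom = "chr1",
                     start = c(10000, 30000, 50000, 70000),
                     end = c(10400, 30400, 50400, 70400))
  ses <- data.table(chrom = "chr1", start = 9000, end = 12000, is_super = TRUE)
  tes <- data.table(chrom = "chr1", start = c(9900, 30100), end = c(10100, 30300))
  genes <- data.table(chrom = "chr1", start = 49000, end = 55000)
  w <- erna_windows(atac, ses, tes, genes)
  # peak 1: SE (wins over TE overlap); peak 2: TE; peak 3: in a gene body;
  # peak 4: overlaps neither class
  expect_equal(nrow(w), 2L)
  expect_equal(w$class, c("SE", "TE"))
  expect_equal(w$end - w$start, c(1000, 1000))
  expect_equal(w$start[1], 10200 - 500)
})

test_that("rank-sum comparison is exact for small groups and handles ties", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  r <- class_response_compare(a, b)
  expect_equal(r$p, 0.1)       # 2 / C(6,3)
  expect_equal(r$median_a, 2)
  expect_equal(r$median_b, 5)
  # identical sets: p = 1 under the exact midrank test
  expect_equal(class_response_compare(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(class_response_compare(numeric(0), 1), "invalid input")
  # random small cases against exhaustive enumeration
  set.seed(13)
  for (i in 1:40) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(1:20, n1); y <- sample(1:20, n2)
    expect_equal(rank_sum_test(x, y)$p, enum_rank_sum(x, y))
  }
})
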