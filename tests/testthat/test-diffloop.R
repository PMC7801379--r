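# Windowed paired-rank differential testing: window construction, filters,
# the signed-rank test against exhaustive enumeration, Holm adjustment,
# logFC, summaries and the feature-association ratio.

# exhaustive 2^n two-sided signed-rank oracle (distinct |d|)
enum_signed_rank <- function(d) {
  d <- d[d != 0]
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  Ws <- as.vector(signs %*% rk)
  min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
}

test_that("build_windows centers and clips", {
  w <- build_windows(data.table(chrom = "chr1",
                                start = c(45000, 2000, 0),
                                end = c(55000, 4000, 1000)))
  expect_equal(w$start, c(45000, 0, 0))
  expect_equal(w$end, c(55000, 8000, 5500))
  # clipped at the chromosome end too
  w2 <- build_windows(data.table(chrom = "chr1", start = 9000, end = 9800),
                      chrom_lengths = c(chr1 = 10000))
  expect_equal(c(w2$start, w2$end), c(4400, 10000))
})

test_that("filter_windows applies the trans / domain / probe-proximity rules", {
  vp <- viewpoint("v", "chr1", 100000, 100500)
  dom <- data.table(chrom = "chr1", start = 50000, end = 200000)
  w <- build_windows(data.table(
    chrom = c("chr2", "chr1", "chr1", "chr1"),
    start = c(60000, 300000, 110499, 145000),
    end = c(70000, 310000, 120499, 155000)))
  f <- filter_windows(w, vp, dom)
  expect_equal(f$trans, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(f$outside_domain, c(TRUE, TRUE, FALSE, FALSE))
  # window 3's nearest edge is 9,999 bp from the probe -> excluded
  expect_equal(f$near_probe, c(FALSE, FALSE, TRUE, FALSE))
  # cis window inside the domain, ~50 kb away -> retained by all filters
  expect_false(any(unlist(f[4, .(trans, outside_domain, near_probe)])))
  expect_error(filter_windows(w, vp, NULL), "configuration error")
})

test_that("exact signed-rank p equals exhaustive enumeration for n <= 8", {
  set.seed(42)
  for (n in 1:8) {
    for (i in 1:25) {
      d <- runif(n, -1, 1)
      while (anyDuplicated(abs(d)) || any(d == 0)) d <- runif(n, -1, 1)
      expect_identical(signed_rank_test(d)$p, enum_signed_rank(d))
    }
  }
  # all-positive six pairs: p = 2 / 2^6
  expect_equal(signed_rank_test(c(1, 2, 3, 4, 5, 6))$p, 0.03125)
})

test_that("signed-rank handles zeros, ties and the approximation crossover", {
  expect_equal(signed_rank_test(rep(0, 10))$n, 0L)
  expect_true(is.na(signed_rank_test(rep(0, 10))$p))
  # tied |d| still exact via doubled midranks, and symmetric under negation
  d <- c(1, 1, -1, 2, 2, 3)
  expect_equal(signed_rank_test(d)$p, signed_rank_test(-d)$p)
  # large n: normal approximation close to the exact path near the boundary
  set.seed(7)
  d <- rnorm(25) + 0.3
  p_exact <- signed_rank_test(d, exact_max = 25)$p
  p_norm <- signed_rank_test(d, exact_max = 10)$p
  expect_equal(p_exact, p_norm, tolerance = 0.08)
})

test_that("holm_adjust matches hand-applied step-down and validates input", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.3), 0.3)
  expect_equal(holm_adjust(c(0.03, 0.02, 0.01)), c(0.04, 0.04, 0.03))
  expect_error(holm_adjust(c(0.1, 0)), "invalid input")
  expect_error(holm_adjust(c(0.1, 1.2)), "invalid input")
  # brute-force oracle on random vectors
  brute <- function(p) {
    m <- length(p); o <- order(p); run <- 0; out <- numeric(m)
    for (i in seq_len(m)) {
      run <- max(run, (m - i + 1) * p[o[i]]); out[o[i]] <- min(1, run)
    }
    out
  }
  set.seed(9)
  for (i in 1:100) {
    p <- runif(sample(1:30, 1))
    a <- holm_adjust(p)
    expect_equal(a, brute(p))
    expect_true(all(a >= p))
    expect_true(all(a <= pmin(1, length(p) * p) + 1e-12))
  }
})

test_that("window_logfc reproduces closed-form values", {
  map <- make_tiling_map(n = 10, step = 1000)
  win <- data.table(window_id = "w", chrom = "chr1", start = 0, end = 10000)
  tab <- make_norm_table(map, "v", list(
    ctrl = list(r1 = rep(100, 10), r2 = rep(100, 10)),
    trt = list(r1 = rep(200, 10), r2 = rep(100, 10))))
  lf <- window_logfc(win, tab, map, "ctrl", "trt", psi = 1)
  expect_equal(unname(lf$logfc_per_replicate["r1"]), log2(201 / 101))
  expect_equal(unname(lf$logfc_per_replicate["r2"]), 0)
  expect_equal(lf$mean_logfc, log2(201 / 101) / 2)
  # label swap negates every replicate logFC
  lf_swap <- window_logfc(win, tab, map, "trt", "ctrl", psi = 1)
  expect_equal(lf_swap$logfc_per_replicate, -lf$logfc_per_replicate)
})

test_that("paired_window_test pairs (fragment, replicate) units", {
  map <- make_tiling_map(n = 10, step = 1000)
  win <- data.table(window_id = "w", chrom = "chr1", start = 0, end = 6000)
  # identical counts: all differences zero -> too few pairs, no p
  tab0 <- make_norm_table(map, "v", list(
    ctrl = list(r1 = rep(5, 6)), trt = list(r1 = rep(5, 6))))
  r0 <- paired_window_test(win, tab0, map, "ctrl", "trt")
  expect_true(r0$too_few_pairs)
  expect_equal(r0$n_pairs, 0L)
  expect_true(is.na(r0$p_raw))
  # six positive pairs across 2 replicates x 3 fragments
  win2 <- data.table(window_id = "w", chrom = "chr1", start = 0, end = 3000)
  tab2 <- make_norm_table(map, "v", list(
    ctrl = list(r1 = c(1, 2, 3), r2 = c(4, 5, 6)),
    trt = list(r1 = c(11, 22, 33), r2 = c(14, 15, 16))))
  r2 <- paired_window_test(win2, tab2, map, "ctrl", "trt")
  expect_equal(r2$n_pairs, 6L)
  expect_equal(r2$p_raw, 0.03125)
  # condition swap leaves p unchanged
  expect_equal(paired_window_test(win2, tab2, map, "trt", "ctrl")$p_raw,
               r2$p_raw)
  # mismatched replicate labels
  tab3 <- make_norm_table(map, "v", list(
    ctrl = list(r1 = c(1, 2, 3)), trt = list(rX = c(2, 3, 4))))
  expect_error(paired_window_test(win2, tab3, map, "ctrl", "trt"),
               "pairing error")
  expect_error(paired_window_test(win2, tab2, map, "ctrl", "nope"),
               "lookup error")
})

test_that("differential_summary counts and averages significant windows", {
  r <- data.table(tested = c(TRUE, TRUE, TRUE, FALSE),
                  p_adj = c(0.01, 0.02, 0.8, NA),
                  mean_logfc = c(0.2, 0.4, -1, NA))
  s <- differential_summary(r, alpha = 0.05, label = "x")
  expect_equal(s$n_tested, 3L)
  expect_equal(s$n_significant, 2L)
  expect_equal(s$n_increased, 2L)
  expect_equal(s$n_decreased, 0L)
  expect_equal(s$mean_logfc_significant, 0.3)
  s0 <- differential_summary(r[3], alpha = 0.05)
  expect_equal(s0$n_significant, 0L)
  expect_true(is.na(s0$mean_logfc_significant))
})

test_that("association_enrichment computes the in-domain contact ratio", {
  map <- make_tiling_map(n = 100, step = 1000)
  vp <- viewpoint("v", "chr1", 100, 200)
  dom <- data.table(chrom = "chr1", start = 40000, end = 80000)
  # 40 in-domain fragments (indices 41..80), all far from the probe
  v <- rep(0, 100); v[41:80] <- 1; v[41:50] <- 2   # 10 at 2c, 30 at c
  tab <- make_norm_table(map, "v", list(ctrl = list(r1 = v)))
  feat <- data.table(chrom = "chr1", start = 40000, end = 50000)
  expect_equal(association_enrichment(feat, tab, map, vp, dom), 1.6)
  # uniform profile -> ratio 1
  tabu <- make_norm_table(map, "v", list(ctrl = list(r1 = rep(3, 100))))
  expect_equal(association_enrichment(feat, tabu, map, vp, dom), 1)
  # feature entirely outside the domain -> missing, not an error
  feat2 <- data.table(chrom = "chr1", start = 90000, end = 95000)
  expect_true(is.na(association_enrichment(feat2, tab, map, vp, dom)))
})

test_that("diff_windows agrees with single-window calls and excludes flagged windows", {
  design <- small_design(seed = 3, effect_log2 = 1, n_affected = 5L)
  map <- simulate_fragment_map(design)
  sim <- simulate_capture_experiment(design, map)
  norm <- normalize_interactions(sim$table, map, sim$viewpoints)
  res <- diff_windows(norm, map, sim$viewpoints, sim$peaks, sim$domains,
                      "control", "treated")
  # no flagged window enters the tested family
  expect_false(any(res[trans | outside_domain | near_probe, tested]))
  expect_true(all(res[tested == TRUE, p_adj] >= res[tested == TRUE, p_raw]))
  # direction is consistent with alpha and sign
  sig <- res[tested == TRUE & p_adj < 0.05]
  expect_true(all(sig[mean_logfc > 0, direction] == "increased"))
  expect_true(all(sig[mean_logfc < 0, direction] == "decreased"))
  # spot-check three windows against the single-window API
  vtab <- norm[viewpoint == "vp1" & trans == FALSE]
  for (wid in res[viewpoint == "vp1" & tested == TRUE, window_id][1:3]) {
    w <- res[viewpoint == "vp1" & window_id == wid]
    single <- paired_window_test(w[, .(window_id, chrom, start, end)],
                                 vtab, map, "control", "treated")
    expect_equal(w$p_raw, single$p_raw)
    expect_equal(w$n_pairs, single$n_pairs)
    lf <- window_logfc(w[, .(window_id, chrom, start, end)],
                       vtab, map, "control", "treated")
    expect_equal(w$mean_logfc, lf$mean_logfc)
  }
  # label antisymmetry on the full result
  res_swap <- diff_windows(norm, map, sim$viewpoints, sim$peaks, sim$domains,
                           "treated", "control")
  expect_equal(res_swap[tested == TRUE, p_raw], res[tested == TRUE, p_raw])
  expect_equal(res_swap[tested == TRUE, mean_logfc],
               -res[tested == TRUE, mean_logfc])
})
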