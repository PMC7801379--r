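# In-silico digestion, fragment lookup and interaction normalization.

test_that("digest_sequence applies the cut-before-motif rule", {
  d <- digest_sequence("AAGATCCGATCA", "GATC")
  expect_equal(d$start, c(0, 2, 7))
  expect_equal(d$end, c(2, 7, 12))

  d1 <- digest_sequence("AAAAAA", "GATC")
  expect_equal(nrow(d1), 1L)
  expect_equal(c(d1$start, d1$end), c(0, 6))

  # cut at position 0: leading empty fragment dropped
  d2 <- digest_sequence("GATCGATC", "GATC")
  expect_equal(d2$start, c(0, 4))
  expect_equal(d2$end, c(4, 8))
})

test_that("digest_sequence validates its inputs", {
  expect_error(digest_sequence("", "GATC"), "invalid input")
  expect_error(digest_sequence("ACGT", ""), "invalid input")
  expect_error(digest_sequence("ACGTX", "GATC"), "invalid input")
  expect_error(digest_sequence("ACGT", "GANC"), "invalid input")
  # motif longer than sequence: one fragment, not an error
  expect_equal(nrow(digest_sequence("ACG", "GATC")), 1L)
})

test_that("digestion matches a naive scan oracle and tiles the sequence", {
  set.seed(71)
  naive <- function(seq, motif) {
    n <- nchar(seq); k <- nchar(motif)
    cuts <- if (k <= n)
      which(vapply(1:(n - k + 1), function(i)
        substr(seq, i, i + k - 1) == motif, logical(1))) - 1L
    else integer(0)
    sort(unique(c(0L, cuts, n)))
  }
  for (i in 1:200) {
    len <- sample(100:2000, 1)
    seq <- random_dna(len)
    d <- digest_sequence(seq, "GATC")
    bounds <- naive(seq, "GATC")
    expect_identical(as.integer(d$start), head(bounds, -1L))
    expect_identical(as.integer(d$end), tail(bounds, -1L))
    expect_equal(sum(d$end - d$start), len)   # exact partition
    expect_true(all(d$end > d$start))
  }
})

test_that("fragments_in_interval returns overlaps in order and errors on bad lookups", {
  map <- make_tiling_map(n = 10, step = 1000)
  expect_equal(fragments_in_interval(map, "chr1", 2000, 3000), "chr1_3")
  # 1 bp on either side of a boundary picks up both fragments
  expect_equal(fragments_in_interval(map, "chr1", 2999, 3001),
               c("chr1_3", "chr1_4"))
  expect_error(fragments_in_interval(map, "chrX", 0, 10), "lookup error")
  expect_error(fragments_in_interval(map, "chr1", 20000, 21000), "lookup error")
})

test_that("fragment_map rejects non-tiling input", {
  expect_error(fragment_map(data.table(chrom = "c", start = c(0, 20), end = c(10, 30))),
               "tile")
  expect_error(fragment_map(data.table(chrom = "c", start = 0, end = 0)),
               "zero")
})

test_that("viewpoints must sit inside a single fragment", {
  map <- make_tiling_map(n = 10, step = 1000)
  vp_bad <- viewpoint("v", "chr1", 900, 1100)
  expect_error(caploop:::validate_viewpoint(vp_bad, map), "one restriction fragment")
  expect_silent(caploop:::validate_viewpoint(viewpoint("v", "chr1", 100, 500), map))
})

test_that("normalization rescales each library to the scale constant", {
  map <- make_tiling_map(n = 100, step = 1000)
  vp <- viewpoint("v", "chr1", 50100, 50200)
  # uniform 2500 raw per fragment; exclusion zone ~ [49100, 51200) touches
  # fragments 50, 51, 52 -> cis total outside = 2500 * 97
  tab <- interaction_table(data.table(
    viewpoint = "v", fragment_id = map$fragment_id, replicate = "r1",
    condition = "ctrl", raw_count = 2500))
  norm <- normalize_interactions(tab, map, vp, scale = 1e5)
  kept <- norm[excluded == FALSE]
  expect_equal(sum(kept$norm_count), 1e5, tolerance = 1e-9)
  expect_equal(unique(kept$norm_count), 2500 * 1e5 / (2500 * 97))
  expect_true(all(norm[excluded == TRUE, norm_count] == 0))
  expect_equal(sum(norm$excluded), 3L)
})

test_that("normalization hand ratio, identity and scale equivariance", {
  map <- make_tiling_map(n = 20, step = 1000)
  vp <- viewpoint("v", "chr1", 100, 200)
  base <- data.table(viewpoint = "v", fragment_id = map$fragment_id,
                     replicate = "r1", condition = "ctrl",
                     raw_count = c(rep(0, 2), rep(10101, 18)))
  # fragments 1-2 are inside the 1 kb exclusion zone; T = 18 * 10101
  n1 <- normalize_interactions(interaction_table(base), map, vp, scale = 1e5)
  expect_equal(n1[excluded == FALSE, unique(norm_count)],
               10101 * 1e5 / (18 * 10101))
  # cis total equal to scale: identity
  b2 <- copy(base)[, raw_count := c(rep(0, 2), rep(1e5 / 18, 18))]
  n2 <- normalize_interactions(interaction_table(b2), map, vp, scale = 1e5)
  expect_equal(n2[excluded == FALSE, norm_count],
               b2[3:20, raw_count], tolerance = 1e-12)
  # multiplying all raw counts leaves normalized counts unchanged
  b3 <- copy(base)[, raw_count := raw_count * 7]
  n3 <- normalize_interactions(interaction_table(b3), map, vp, scale = 1e5)
  expect_equal(n3$norm_count, n1$norm_count, tolerance = 1e-12)
})

test_that("degenerate libraries are rejected by name", {
  map <- make_tiling_map(n = 20, step = 1000)
  vp <- viewpoint("v", "chr1", 100, 200)
  tab <- interaction_table(rbindlist(list(
    data.table(viewpoint = "v", fragment_id = map$fragment_id,
               replicate = "r1", condition = "ctrl", raw_count = 5),
    data.table(viewpoint = "v", fragment_id = map$fragment_id,
               replicate = "r2", condition = "ctrl", raw_count = 0))))
  expect_error(normalize_interactions(tab, map, vp),
               "degenerate library.*r2", perl = TRUE)
})

test_that("trans fragments are flagged and kept, normalized by the cis total", {
  map <- make_tiling_map(c("chr1", "chr2"), n = 20, step = 1000)
  vp <- viewpoint("v", "chr1", 5100, 5200)
  tab <- interaction_table(rbindlist(list(
    data.table(viewpoint = "v", fragment_id = map[chrom == "chr1", fragment_id],
               replicate = "r1", condition = "ctrl", raw_count = 100),
    data.table(viewpoint = "v", fragment_id = map[chrom == "chr2", fragment_id][1],
               replicate = "r1", condition = "ctrl", raw_count = 50))))
  norm <- normalize_interactions(tab, map, vp, scale = 1e5)
  tr <- norm[trans == TRUE]
  expect_equal(nrow(tr), 1L)
  n_cis_kept <- norm[trans == FALSE & excluded == FALSE, .N]
  expect_equal(tr$norm_count, 50 * 1e5 / (100 * n_cis_kept))
})
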