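# Property-based validation runners. Each runner regenerates its inputs from
# a seed, runs the package implementation against an independent oracle or a
# planted truth, and returns summary metrics. They back both the acceptance
# test suite and scripts/acceptance.R.

# --- independent oracles (deliberately naive implementations) ---------------

# naive character-scan digestion oracle
oracle_digest <- function(seq, motif) {
  n <- nchar(seq)
  cuts <- integer(0)
  k <- nchar(motif)
  if (k <= n) {
    for (i in 1:(n - k + 1)) {
      if (substr(seq, i, i + k - 1) == motif) cuts <- c(cuts, i - 1L)
    }
  }
  bounds <- sort(unique(c(0L, cuts, n)))
  data.table(start = head(bounds, -1L), end = tail(bounds, -1L))
}

# exhaustive 2^n signed-rank oracle (distinct |d| assumed)
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% rk)
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# brute-force step-down Holm oracle
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, run)
  }
  adj
}

# brute-force tangent-rule SE-calling oracle on a signal vector: returns
# logical flags in input order
oracle_se_flags <- function(s) {
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

# --- criterion runners ------------------------------------------------------

#' Acceptance runners
#'
#' Each `run_*` function regenerates inputs from `seed`, exercises the
#' package and returns summary metrics for one validation criterion. See the
#' package vignette for what each establishes.
#'
#' @param seed integer seed.
#' @param n_seqs,n_vectors,n_runs problem sizes (defaults are the reference
#'   sizes).
#' @name acceptance-runners
NULL

#' @describeIn acceptance-runners random-sequence digestion vs a naive-scan
#'   oracle plus the partition invariant. Returns `fraction_matching` and
#'   `n`.
#' @export
run_digestion_oracle <- function(seed = 1L, n_seqs = 1000L) {
  set.seed(seed)
  ok <- logical(n_seqs)
  for (i in seq_len(n_seqs)) {
    len <- sample(100:10000, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    got <- digest_sequence(seq, "GATC")
    exp <- oracle_digest(seq, "GATC")
    ok[i] <- identical(as.numeric(got$start), as.numeric(exp$start)) &&
      identical(as.numeric(got$end), as.numeric(exp$end)) &&
      got$start[1] == 0 && got$end[nrow(got)] == len &&
      all(got$start[-1] == got$end[-nrow(got)]) &&
      sum(got$end - got$start) == len
  }
  list(fraction_matching = mean(ok), n = n_seqs)
}

#' @describeIn acceptance-runners exact signed-rank p vs exhaustive 2^n
#'   enumeration for n = 1..8 with distinct differences. Returns
#'   `max_abs_diff` and `n` (vectors checked).
#' @export
run_signed_rank_oracle <- function(seed = 1L, n_vectors = 200L) {
  set.seed(seed)
  worst <- 0
  total <- 0L
  for (n in 1:8) {
    for (j in seq_len(n_vectors)) {
      d <- runif(n, -1, 1)
      while (anyDuplicated(abs(d)) || any(d == 0)) d <- runif(n, -1, 1)
      p_impl <- signed_rank_test(d)$p
      p_or <- oracle_signed_rank(d)
      worst <- max(worst, abs(p_impl - p_or))
      total <- total + 1L
    }
  }
  list(max_abs_diff = worst, n = total)
}

#' @describeIn acceptance-runners Holm adjustment vs brute-force step-down on
#'   random p-vectors; also checks `adj >= raw`, `adj <= Bonferroni`, and
#'   monotonicity along the sorted order. Returns `max_abs_diff`,
#'   `fraction_valid`, `n`.
#' @export
run_holm_oracle <- function(seed = 1L, n_vectors = 1000L) {
  set.seed(seed)
  worst <- 0
  valid <- logical(n_vectors)
  for (i in seq_len(n_vectors)) {
    m <- sample(1:50, 1)
    p <- runif(m, .Machine$double.eps, 1)
    a <- holm_adjust(p)
    b <- oracle_holm(p)
    worst <- max(worst, max(abs(a - b)))
    o <- order(p)
    valid[i] <- all(a >= p - 1e-12) && all(a <= pmin(1, m * p) + 1e-12) &&
      !is.unsorted(a[o])
  }
  list(max_abs_diff = worst, fraction_valid = mean(valid), n = n_vectors)
}

# one full null/effect capture simulation -> diff_windows result
.run_capture_comparison <- function(seed, effect_log2 = 0, n_affected = 0L,
                                    ...) {
  design <- sim_design(seed = seed, effect_log2 = effect_log2,
                       n_affected = n_affected, ...)
  map <- simulate_fragment_map(design)
  sim <- simulate_capture_experiment(design, map)
  norm <- normalize_interactions(sim$table, map, sim$viewpoints)
  res <- diff_windows(norm, map, sim$viewpoints, sim$peaks, sim$domains,
                      cond_a = design$conditions[1],
                      cond_b = design$conditions[2],
                      width = design$window_width)
  list(result = res, truth = sim$truth)
}

#' @describeIn acceptance-runners family-wise error rate under the null: the
#'   share of simulated null comparisons (500 windows, 3+3 replicates) with
#'   any window at Holm-adjusted p < alpha. Returns `fwer`, `bound`
#'   (alpha + 2 SE), `n`.
#' @export
run_fwer <- function(seed = 1L, n_runs = 200L, alpha = 0.05) {
  seeds <- .sub_seed(seed, 1000L + seq_len(n_runs))
  any_sig <- vapply(seeds, function(s) {
    r <- .run_capture_comparison(s)$result
    any(r$tested & r$p_adj < alpha, na.rm = TRUE)
  }, logical(1))
  list(fwer = mean(any_sig),
       bound = alpha + 2 * sqrt(alpha * (1 - alpha) / n_runs),
       n = n_runs)
}

#' @describeIn acceptance-runners effect recovery: log2 effect 0.5 injected
#'   at 50/500 windows; mean estimated `mean_logfc` over truly affected,
#'   significant windows and the sign-agreement fraction. Returns
#'   `mean_logfc_at_affected`, `injected`, `sign_agreement`, `n`
#'   (significant affected windows).
#' @export
run_effect_recovery <- function(seed = 1L, n_runs = 10L, effect_log2 = 0.5,
                                n_affected = 50L, alpha = 0.05) {
  seeds <- .sub_seed(seed, 2000L + seq_len(n_runs))
  vals <- list()
  for (s in seeds) {
    rr <- .run_capture_comparison(s, effect_log2 = effect_log2,
                                  n_affected = n_affected)
    r <- merge(rr$result, rr$truth[, .(window_id, affected)],
               by = "window_id")
    vals[[length(vals) + 1L]] <-
      r[affected == TRUE & tested == TRUE & p_adj < alpha, mean_logfc]
  }
  v <- unlist(vals)
  list(mean_logfc_at_affected = mean(v), injected = effect_log2,
       sign_agreement = mean(sign(v) == sign(effect_log2)), n = length(v))
}

#' @describeIn acceptance-runners spike-in factor recovery for true factors
#'   0.25/0.5/1.0 at 1e6 reads. Returns `max_rel_error` and `n` (reads).
#' @export
run_spikein_recovery <- function(seed = 1L, factors = c(0.25, 0.5, 1.0),
                                 depth = 1e6) {
  design <- sim_design(seed = seed, spike_depth = depth,
                       spike_factors = c(reference = 1,
                                         setNames(factors, paste0("s", seq_along(factors)))))
  sp <- simulate_spikein_counts(design)
  est <- vapply(names(design$spike_factors), function(nm)
    spike_in_factor(sp$pairs[[nm]], sp$pairs[["reference"]]), numeric(1))
  rel <- abs(est - design$spike_factors) / design$spike_factors
  list(max_rel_error = max(rel), n = depth)
}

#' @describeIn acceptance-runners planted super-enhancer recovery: fraction
#'   of seeded runs in which the flagged set equals the planted set (5% SE at
#'   a 50x mean). Also cross-checks the caller against the brute-force
#'   tangent oracle on every run. Returns `fraction_recovered`,
#'   `fraction_oracle_match`, `n`.
#' @export
run_se_recovery <- function(seed = 1L, n_runs = 100L) {
  seeds <- .sub_seed(seed, 3000L + seq_len(n_runs))
  rec <- logical(n_runs); om <- logical(n_runs)
  for (i in seq_len(n_runs)) {
    design <- sim_design(seed = seeds[i])
    sig <- simulate_signal_and_nascent(design)
    st <- stitch_peaks(sig$peaks)
    called <- call_super_enhancers(st)
    # stitched regions map 1:1 to planted regions (50 kb spacing)
    truth_by_pos <- sig$truth$is_super[match(called$start, sig$peaks$start)]
    rec[i] <- identical(called$is_super, truth_by_pos)
    om[i] <- identical(called$is_super, oracle_se_flags(called$signal))
  }
  list(fraction_recovered = mean(rec), fraction_oracle_match = mean(om),
       n = n_runs)
}

#' @describeIn acceptance-runners pipeline determinism: two runs with the
#'   same config and seed produce byte-identical outputs. Returns
#'   `identical` (0/1) and `n` (files compared).
#' @export
run_determinism <- function(seed = 1L) {
  cfg <- list(seed = seed,
              design = list(n_viewpoints = 2L, chrom_length = 4e5,
                            domain_halfwidth = 1.8e5,
                            n_peaks_per_viewpoint = 20L,
                            depth = 2e5, n_enhancer_regions = 60L),
              comparisons = list(c("control", "treated")))
  d1 <- tempfile("det1_"); d2 <- tempfile("det2_")
  run_pipeline(cfg, d1)
  run_pipeline(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  same <- identical(f1, f2) && all(vapply(f1, function(f)
    unname(tools::md5sum(file.path(d1, f))) ==
      unname(tools::md5sum(file.path(d2, f))), logical(1)))
  unlink(c(d1, d2), recursive = TRUE)
  list(identical = as.numeric(same), n = length(f1))
}
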