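# Truth-tagged synthetic data with the statistical structure the analysis
# assumes: viewpoint contact profiles with power-law distance decay,
# domain-bounded contrast and localized enhancer contact windows;
# negative-binomial replicate noise; multiplicative treatment effects at
# chosen windows; two-genome spike-in mixtures; bimodal (SE vs TE) enhancer
# signal; and class-dependent eRNA responses.
#
# A single integer seed drives everything; each generator derives its own
# sub-stream with a fixed offset so outputs do not depend on generation
# order. Identical designs give byte-identical outputs.

.sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

#' Synthetic experiment design
#'
#' Bundles every parameter of the generators, with defaults emulating the
#' published experimental setting: DpnII-scale fragments (mean 256 bp),
#' 10 kb peak windows inside visually-bounded interaction domains, three
#' biological replicates per condition, ~1e6 reported cis reads per
#' viewpoint, negative-binomial counts, and a 1:4 spike:target chromatin
#' mixture.
#'
#' @param seed integer master seed.
#' @param n_viewpoints number of viewpoints, one per simulated chromosome.
#' @param chrom_length chromosome length (bp).
#' @param mean_fragment_length mean restriction-fragment length (bp, >= 50).
#' @param domain_halfwidth interaction-domain half-width around the
#'   viewpoint (bp).
#' @param n_peaks_per_viewpoint binding peaks (test windows) per viewpoint.
#' @param peak_halfwidth peak half-width (bp).
#' @param peak_spacing distance between consecutive peak centers (bp).
#' @param first_peak_offset distance from the viewpoint to the nearest peak
#'   center (bp; beyond the 10 kb probe exclusion).
#' @param decay_exponent power-law contact decay exponent (alpha).
#' @param decay_offset bp offset avoiding the distance-zero singularity.
#' @param outside_domain_factor intensity multiplier outside domains.
#' @param enhancer_fold contact fold (epsilon >= 1) inside peak windows.
#' @param effect_log2 log2 treatment effect injected at affected windows.
#' @param n_affected number of affected windows (chosen by seeded sampling
#'   over all windows; the rest have multiplier 1).
#' @param replicates replicates per condition.
#' @param depth reported cis reads per (viewpoint, replicate, condition).
#' @param nb_dispersion negative-binomial dispersion `k`
#'   (variance = mu + mu^2/k).
#' @param trans_rate fraction of each library's reads scattered on other
#'   chromosomes.
#' @param conditions two condition labels (control first).
#' @param window_width test-window width (bp).
#' @param spike_mix spike fraction of the chromatin mixture (1:4 ratio =
#'   0.2).
#' @param spike_depth reads per spike-in library.
#' @param spike_factors named vector of true global IP-efficiency factors per
#'   sample (reference first, factor 1).
#' @param n_enhancer_regions number of enhancer regions for the signal
#'   generator.
#' @param se_fraction fraction of regions planted as super-enhancers.
#' @param te_signal_mean,se_signal_mean lognormal mean per-mark signal of the
#'   two classes.
#' @param signal_sdlog lognormal sd (log scale) of per-mark signals.
#' @param erna_mean mean eRNA nascent count per window (control).
#' @param erna_se_logfc,erna_te_logfc class-dependent log2 treatment effect
#'   on eRNA windows.
#' @return A `sim_design` list.
#' @export
sim_design <- function(seed = 1L,
                       n_viewpoints = 5L,
                       chrom_length = 1.3e6,
                       mean_fragment_length = 256,
                       domain_halfwidth = 6e5,
                       n_peaks_per_viewpoint = 100L,
                       peak_halfwidth = 1000,
                       peak_spacing = 11000,
                       first_peak_offset = 20000,
                       decay_exponent = 1,
                       decay_offset = 1000,
                       outside_domain_factor = 0.1,
                       enhancer_fold = 3,
                       effect_log2 = 0,
                       n_affected = 0L,
                       replicates = 3L,
                       depth = 1e6,
                       nb_dispersion = 10,
                       trans_rate = 0.01,
                       conditions = c("control", "treated"),
                       window_width = 10000,
                       spike_mix = 0.2,
                       spike_depth = 1e6,
                       spike_factors = c(reference = 1, treated = 0.5),
                       n_enhancer_regions = 200L,
                       se_fraction = 0.05,
                       te_signal_mean = 1,
                       se_signal_mean = 50,
                       signal_sdlog = 0.5,
                       erna_mean = 100,
                       erna_se_logfc = -1,
                       erna_te_logfc = 0) {
  d <- as.list(environment())
  stopifnot(d$mean_fragment_length >= 50, d$depth > 0, d$nb_dispersion > 0,
            d$enhancer_fold >= 1, d$outside_domain_factor > 0,
            d$se_fraction > 0, d$se_fraction < 1,
            length(d$conditions) == 2, all(d$spike_factors > 0),
            d$spike_mix > 0, d$spike_mix < 1)
  structure(d, class = "sim_design")
}

#' Simulate a restriction-fragment map
#'
#' Fragment lengths are geometric with the design mean (floor 20 bp), tiling
#' each chromosome exactly. Optionally emits chromosome sequences with the
#' digestion motif planted exactly at the internal fragment boundaries (and
#' nowhere else), so [digest_sequence()] reproduces the map.
#'
#' @param design a [sim_design()].
#' @param emit_sequence also return sequences (slow for large genomes; meant
#'   for round-trip tests).
#' @param motif motif planted when `emit_sequence = TRUE`.
#' @return A [fragment_map()]; with `emit_sequence`, a list
#'   `(map, sequences)`.
#' @export
simulate_fragment_map <- function(design, emit_sequence = FALSE,
                                  motif = "GATC") {
  set.seed(.sub_seed(design$seed, 11L))
  m <- design$mean_fragment_length
  p <- 1 / (m - 19)
  chroms <- paste0("chr", seq_len(design$n_viewpoints))
  L <- design$chrom_length
  frag <- rbindlist(lapply(chroms, function(cc) {
    n_guess <- ceiling(L / m * 1.3) + 50
    lens <- 20 + rgeom(n_guess, p)
    while (sum(lens) < L) lens <- c(lens, 20 + rgeom(n_guess, p))
    ends <- cumsum(lens)
    ends <- c(ends[ends < L], L)
    data.table(chrom = cc, start = c(0, head(ends, -1)), end = ends)
  }))
  map <- fragment_map(frag)
  if (!emit_sequence) return(map)
  k <- nchar(motif)
  seqs <- lapply(chroms, function(cc) {
    sub <- map[chrom == cc]
    # non-G alphabet outside planted motifs: the motif cannot occur by chance
    s <- sample(c("A", "C", "T"), L, replace = TRUE)
    for (b in sub$start[-1]) s[(b + 1):(b + k)] <- strsplit(motif, "")[[1]]
    paste(s, collapse = "")
  })
  names(seqs) <- chroms
  list(map = map, sequences = seqs)
}

# expected (unnormalized) contact intensity per fragment for one viewpoint
.capture_lambda <- function(frag, vp_pos, design, windows, deltas,
                            treated = FALSE) {
  d <- abs((frag$start + frag$end) / 2 - vp_pos)
  lam <- (d + design$decay_offset)^(-design$decay_exponent)
  in_dom <- interval_gap(frag$start, frag$end,
                         vp_pos - design$domain_halfwidth,
                         vp_pos + design$domain_halfwidth) == 0
  lam[!in_dom] <- lam[!in_dom] * design$outside_domain_factor
  if (nrow(windows)) {
    for (i in seq_len(nrow(windows))) {
      hit <- frag$start < windows$end[i] & frag$end > windows$start[i]
      lam[hit] <- lam[hit] * design$enhancer_fold *
        (if (treated) deltas[i] else 1)
    }
  }
  lam
}

#' Simulate a Capture-C experiment
#'
#' Places peaks at fixed spacing on both sides of each viewpoint inside its
#' interaction domain, injects the design's multiplicative treatment effect
#' at a seeded sample of windows, and draws per-(viewpoint, replicate,
#' condition) fragment counts from a negative binomial around a power-law
#' decay profile scaled to the library depth. A `trans_rate` share of each
#' library is scattered uniformly over other chromosomes.
#'
#' @param design a [sim_design()].
#' @param map a [fragment_map()] from [simulate_fragment_map()].
#' @return list with `table` (raw [interaction_table()]), `peaks`, `domains`
#'   (both with a `viewpoint` column), `viewpoints` (named list) and `truth`
#'   (per-window `delta`, `log2_delta`, `affected`).
#' @export
simulate_capture_experiment <- function(design, map) {
  set.seed(.sub_seed(design$seed, 23L))
  chroms <- paste0("chr", seq_len(design$n_viewpoints))
  lens <- attr(map, "chrom_lengths")
  vp_pos <- floor(design$chrom_length / 2)
  half <- design$n_peaks_per_viewpoint / 2
  offs <- design$first_peak_offset + (seq_len(ceiling(half)) - 1) * design$peak_spacing
  peaks_l <- list(); dom_l <- list(); vps <- list()
  for (i in seq_along(chroms)) {
    cc <- chroms[i]
    ctrs <- sort(c(vp_pos - offs[seq_len(floor(half))],
                   vp_pos + offs[seq_len(ceiling(half))]))
    peaks_l[[i]] <- data.table(
      viewpoint = paste0("vp", i), chrom = cc,
      start = ctrs - design$peak_halfwidth, end = ctrs + design$peak_halfwidth,
      name = sprintf("vp%d_peak%03d", i, seq_along(ctrs)))
    dom_l[[i]] <- data.table(viewpoint = paste0("vp", i), chrom = cc,
                             start = max(0, vp_pos - design$domain_halfwidth),
                             end = min(lens[[cc]], vp_pos + design$domain_halfwidth))
    host <- map[chrom == cc & start <= vp_pos & end > vp_pos]
    vps[[paste0("vp", i)]] <- viewpoint(paste0("vp", i), cc,
                                        host$start, host$end)
  }
  peaks <- rbindlist(peaks_l)
  domains <- rbindlist(dom_l)
  windows <- build_windows(peaks, width = design$window_width,
                           chrom_lengths = lens)
  windows[, viewpoint := peaks$viewpoint]
  # seeded choice of affected windows, multiplier 2^effect_log2
  n_aff <- min(design$n_affected, nrow(windows))
  aff_idx <- if (n_aff > 0) sort(sample.int(nrow(windows), n_aff)) else integer(0)
  deltas <- rep(1, nrow(windows))
  deltas[aff_idx] <- 2^design$effect_log2
  truth <- data.table(viewpoint = windows$viewpoint,
                      window_id = windows$window_id,
                      delta = deltas, log2_delta = log2(deltas),
                      affected = seq_len(nrow(windows)) %in% aff_idx)
  reps <- paste0("rep", seq_len(design$replicates))
  k <- design$nb_dispersion
  rows <- list()
  for (i in seq_along(chroms)) {
    cc <- chroms[i]
    vname <- paste0("vp", i)
    frag <- map[chrom == cc]
    w_i <- windows[viewpoint == vname]
    d_i <- truth[viewpoint == vname, delta]
    other <- map[chrom != cc]
    for (cond_j in 1:2) {
      cond <- design$conditions[cond_j]
      lam <- .capture_lambda(frag, vp_pos, design, w_i, d_i,
                             treated = cond_j == 2)
      mu_cis <- lam / sum(lam) * design$depth * (1 - design$trans_rate)
      n_trans_reads <- round(design$depth * design$trans_rate)
      for (r in reps) {
        cnt <- rnbinom(length(mu_cis), mu = mu_cis, size = k)
        rows[[length(rows) + 1L]] <- data.table(
          viewpoint = vname, fragment_id = frag$fragment_id,
          replicate = r, condition = cond, raw_count = cnt)
        if (n_trans_reads > 0 && nrow(other)) {
          tc <- as.vector(rmultinom(1, n_trans_reads,
                                    rep(1 / nrow(other), nrow(other))))
          nz <- tc > 0
          rows[[length(rows) + 1L]] <- data.table(
            viewpoint = vname, fragment_id = other$fragment_id[nz],
            replicate = r, condition = cond, raw_count = tc[nz])
        }
      }
    }
  }
  list(table = interaction_table(rbindlist(rows), validate = FALSE),
       peaks = peaks, domains = domains, viewpoints = vps,
       truth = truth)
}

#' Simulate spike-in read-count pairs
#'
#' Input libraries are multinomial over (spike, target) at the design mixing
#' fraction; IP libraries have the target share multiplied by each sample's
#' true global factor `f` (then renormalized), so the estimator in
#' [spike_in_factor()] is consistent for `f`.
#'
#' @param design a [sim_design()]; samples and true factors come from
#'   `design$spike_factors` (first entry is the reference).
#' @return list with `pairs` (named list of [spikein_pair()]) and `truth`
#'   (`sample`, `true_factor`).
#' @export
simulate_spikein_counts <- function(design) {
  set.seed(.sub_seed(design$seed, 37L))
  fs <- design$spike_factors
  mix <- design$spike_mix
  pairs <- list()
  for (nm in names(fs)) {
    f <- fs[[nm]]
    inp <- as.vector(rmultinom(1, design$spike_depth, c(mix, 1 - mix)))
    p_ip <- c(mix, (1 - mix) * f)
    ip <- as.vector(rmultinom(1, design$spike_depth, p_ip / sum(p_ip)))
    pairs[[nm]] <- spikein_pair(nm, nm,
                                input_target = inp[2], input_spike = inp[1],
                                ip_target = ip[2], ip_spike = ip[1])
  }
  list(pairs = pairs,
       truth = data.table(sample = names(fs), true_factor = unname(fs)))
}

#' Simulate bimodal enhancer signal, coverage tracks and eRNA counts
#'
#' Plants `n_enhancer_regions` well-separated enhancer regions on a dedicated
#' chromosome; a seeded `se_fraction` share are super-enhancers whose
#' per-mark signals (H3K27ac, H3K4me1, BRD4, MED1) are lognormal with a
#' `se_signal_mean / te_signal_mean` mean ratio. Gene bodies are placed
#' between regions (so region-centered ATAC peaks are intergenic), and eRNA
#' nascent counts at 1 kb ATAC windows are negative binomial with the
#' class-dependent log2 treatment effect.
#'
#' @param design a [sim_design()].
#' @return list with `peaks` (per-region intervals with per-mark and combined
#'   `signal`), `tracks` (named list of [signal_track()], one per mark),
#'   `atac`, `genes`, `tss`, `erna` (per window and replicate counts for both
#'   conditions), and `truth` (planted class and eRNA effect per region).
#' @export
simulate_signal_and_nascent <- function(design) {
  set.seed(.sub_seed(design$seed, 53L))
  n <- design$n_enhancer_regions
  spacing <- 50000
  cc <- "chrE"
  ctrs <- spacing * seq_len(n)
  halfw <- 2000
  n_se <- max(1L, round(n * design$se_fraction))
  se_idx <- sort(sample.int(n, n_se))
  is_se <- seq_len(n) %in% se_idx
  marks <- c("H3K27ac", "H3K4me1", "BRD4", "MED1")
  sdl <- design$signal_sdlog
  mlog <- function(m) log(m) - sdl^2 / 2
  sig <- sapply(marks, function(mk)
    rlnorm(n, meanlog = ifelse(is_se, mlog(design$se_signal_mean),
                               mlog(design$te_signal_mean)), sdlog = sdl))
  peaks <- data.table(name = sprintf("enh%03d", seq_len(n)), chrom = cc,
                      start = ctrs - halfw, end = ctrs + halfw)
  for (mk in marks) set(peaks, j = mk, value = sig[, mk])
  set(peaks, j = "signal", value = rowSums(sig))
  tracks <- lapply(marks, function(mk)
    signal_track(data.table(chrom = cc, start = peaks$start, end = peaks$end,
                            value = sig[, mk]),
                 depth = 1e7, scale_state = "per1e7"))
  names(tracks) <- marks
  atac <- data.table(chrom = cc, start = ctrs - 200, end = ctrs + 200,
                     name = sprintf("atac%03d", seq_len(n)))
  gb_ctr <- ctrs + spacing / 2
  genes <- data.table(gene = sprintf("gene%03d", seq_len(n)), chrom = cc,
                      strand = "+", start = gb_ctr - 2500, end = gb_ctr + 2500)
  tss <- genes[, .(gene, chrom, tss = start)]
  effect <- ifelse(is_se, design$erna_se_logfc, design$erna_te_logfc)
  reps <- paste0("rep", seq_len(design$replicates))
  k <- design$nb_dispersion
  erna <- CJ(region = seq_len(n), replicate = reps,
             condition = design$conditions, sorted = FALSE)
  mu <- design$erna_mean *
    ifelse(erna$condition == design$conditions[2], 2^effect[erna$region], 1)
  erna[, count := rnbinom(.N, mu = mu, size = k)]
  erna[, window_id := sprintf("%s:%d", cc, as.integer(ctrs[region]))]
  list(peaks = peaks, tracks = tracks, atac = atac, genes = genes, tss = tss,
       erna = erna[, .(window_id, region, replicate, condition, count)],
       truth = data.table(name = peaks$name, region = seq_len(n),
                          is_super = is_se, erna_log2_effect = effect))
}

#' Estimated eRNA log2 fold-changes per window
#'
#' Convenience summary of the eRNA counts from
#' [simulate_signal_and_nascent()]: per window,
#' `log2((mean treated + psi) / (mean control + psi))`.
#'
#' @param erna the `erna` table.
#' @param conditions two condition labels (control first).
#' @param psi pseudocount (count units).
#' @return `data.table` with `window_id`, `region`, `logfc`.
#' @export
erna_logfc <- function(erna, conditions, psi = 1) {
  e <- as.data.table(erna)
  wide <- e[, .(m = mean(count)), by = .(window_id, region, condition)]
  wide <- dcast(wide, window_id + region ~ condition, value.var = "m")
  wide[, logfc := log2((get(conditions[2]) + psi) / (get(conditions[1]) + psi))]
  wide[, .(window_id, region, logfc)]
}
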