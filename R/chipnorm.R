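# Spike-in (ChIP-Rx) reference normalization and ChIP signal utilities.
#
# A foreign-genome spike-in (Drosophila chromatin mixed with the target
# chromatin at a nominal 1:4 ratio before IP) acts as an internal standard:
# the spike:target read ratio of the IP library, corrected by the same ratio
# in the input library (which absorbs mixing variation), is inversely
# proportional to global IP efficiency for the target genome. Tracks are
# first depth-normalized to tags per 1e7 target reads, then multiplied by the
# reference-anchored spike-in factor.

#' Two-genome read counts for one ChIP sample
#'
#' @param label sample label.
#' @param condition condition label.
#' @param input_target,input_spike target-/spike-genome read counts of the
#'   input library.
#' @param ip_target,ip_spike read counts of the IP library.
#' @return A `spikein_pair` object.
#' @export
spikein_pair <- function(label, condition,
                         input_target, input_spike, ip_target, ip_spike) {
  structure(list(label = label, condition = condition,
                 input_target = input_target, input_spike = input_spike,
                 ip_target = ip_target, ip_spike = ip_spike),
            class = "spikein_pair")
}

.spike_ratio <- function(pair, input_corrected = TRUE) {
  cts <- unlist(pair[c("input_target", "input_spike", "ip_target", "ip_spike")])
  if (any(cts <= 0))
    stop("undefined factor: zero read count in library '", pair$label, "'")
  r_ip <- pair$ip_spike / pair$ip_target
  if (input_corrected) (pair$input_spike / pair$input_target) / r_ip else 1 / r_ip
}

#' Spike-in reference-normalization factor
#'
#' `factor(sample) = [(input_spike/input_target) / (ip_spike/ip_target)]`
#' of the sample, rescaled so the reference sample's factor equals 1. A
#' sample with globally depleted target IP material (relatively more spike
#' reads in the IP) yields a factor below 1, shrinking its track.
#'
#' @param sample,reference [spikein_pair()] objects.
#' @param input_corrected correct the IP spike:target ratio by the input
#'   ratio (default), absorbing deviations from the nominal mixing ratio.
#' @return positive scalar factor.
#' @export
spike_in_factor <- function(sample, reference, input_corrected = TRUE) {
  .spike_ratio(sample, input_corrected) / .spike_ratio(reference, input_corrected)
}

#' Construct a coverage signal track
#'
#' A step function of coverage over the genome: per chromosome, sorted
#' non-overlapping intervals with non-negative values (bedGraph semantics;
#' uncovered positions are 0).
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `value`.
#' @param depth total target-genome read count of the library (needed for
#'   per-1e7 scaling).
#' @param scale_state one of `"raw"`, `"per1e7"`, `"refnorm"`.
#' @return A `signal_track` (`data.table` with attributes).
#' @export
signal_track <- function(df, depth = NA_real_, scale_state = "raw") {
  dt <- as.data.table(df)[, .(chrom = as.character(chrom),
                              start = as.numeric(start),
                              end = as.numeric(end),
                              value = as.numeric(value))]
  if (any(dt$value < 0)) stop("signal values must be non-negative")
  setorder(dt, chrom, start)
  if (dt[, any(start[-1] < end[-.N]), by = chrom][, any(V1)])
    stop("signal track intervals overlap")
  setattr(dt, "depth", depth)
  setattr(dt, "scale_state", scale_state)
  setattr(dt, "class", c("signal_track", class(data.table())))
  dt[]
}

#' Reference-normalize a set of ChIP signal tracks
#'
#' Each track is scaled to tags per 1e7 target reads, then multiplied by its
#' spike-in factor relative to the reference sample.
#'
#' @param tracks named list of [signal_track()]s (raw scale, with `depth`).
#' @param pairs named list of [spikein_pair()]s, one per track (matched by
#'   name).
#' @param reference name of the reference sample (factor anchored to 1).
#' @param input_corrected see [spike_in_factor()].
#' @return named list of reference-normalized tracks; spike-in factors in
#'   attribute `factors`.
#' @export
normalize_chip_tracks <- function(tracks, pairs, reference,
                                  input_corrected = TRUE) {
  miss <- setdiff(names(tracks), names(pairs))
  if (length(miss))
    stop("configuration error: no spike-in counts for track(s): ",
         paste(miss, collapse = ", "))
  if (!reference %in% names(pairs))
    stop("configuration error: reference sample '", reference, "' not found")
  ref <- pairs[[reference]]
  factors <- vapply(names(tracks), function(nm)
    spike_in_factor(pairs[[nm]], ref, input_corrected), numeric(1))
  out <- lapply(names(tracks), function(nm) {
    tr <- tracks[[nm]]
    depth <- attr(tr, "depth")
    if (is.na(depth) || depth <= 0)
      stop("track '", nm, "' has no positive depth for per-1e7 scaling")
    dt <- copy(as.data.table(tr))
    dt[, value := value * 1e7 / depth * factors[[nm]]]
    signal_track(dt, depth = depth, scale_state = "refnorm")
  })
  names(out) <- names(tracks)
  attr(out, "factors") <- factors
  out
}

#' Length-weighted mean signal over intervals
#'
#' @param track a [signal_track()].
#' @param intervals data.frame of query intervals (`chrom`, `start`, `end`).
#' @return numeric vector, one entry per interval: the length-weighted mean
#'   of the step function over the interval (uncovered bases contribute 0).
#' @export
quantify_windows <- function(track, intervals) {
  iv <- as.data.table(intervals)
  stopifnot(all(iv$start < iv$end))
  unknown <- setdiff(unique(iv$chrom), unique(track$chrom))
  if (length(unknown))
    stop("lookup error: chromosome(s) absent from track: ",
         paste(unknown, collapse = ", "))
  res <- numeric(nrow(iv))
  for (cc in unique(iv$chrom)) {
    ti <- track[chrom == cc]
    qi <- which(iv$chrom == cc)
    ir_t <- IRanges::IRanges(start = ti$start + 1, end = ti$end)
    ir_q <- IRanges::IRanges(start = iv$start[qi] + 1, end = iv$end[qi])
    hits <- IRanges::findOverlaps(ir_q, ir_t)
    if (length(hits)) {
      ovl <- IRanges::width(IRanges::pintersect(
        ir_q[S4Vectors::queryHits(hits)], ir_t[S4Vectors::subjectHits(hits)]))
      sums <- tapply(ovl * ti$value[S4Vectors::subjectHits(hits)],
                     S4Vectors::queryHits(hits), sum)
      res[qi[as.integer(names(sums))]] <- sums / IRanges::width(ir_q)[as.integer(names(sums))]
    }
  }
  res
}

#' Mean signal metaprofile around peak centers
#'
#' Bins the track over `[center - flank, center + flank)` for every peak and
#' averages per bin over peaks. Bins falling off the chromosome start count
#' as zero coverage.
#'
#' @param track a [signal_track()].
#' @param peaks data.frame of peak intervals.
#' @param flank half-width of the profiled region (bp; default 5000).
#' @param bin bin size (bp; default 100); must satisfy `flank >= bin > 0`.
#' @param rescale_to optional positive scalar to divide the profile by
#'   (e.g. the peak value of a control profile, reproducing
#'   "normalized to the peak DMSO read count").
#' @return `data.table` with `offset_start`, `offset_end` (bp relative to
#'   peak center) and `mean_value`.
#' @export
metaprofile <- function(track, peaks, flank = 5000, bin = 100,
                        rescale_to = NULL) {
  pk <- as.data.table(peaks)
  if (!nrow(pk)) stop("invalid input: empty peak set")
  stopifnot(bin > 0, flank >= bin)
  nb <- as.integer(2 * flank / bin)
  ctr <- floor((pk$start + pk$end) / 2)
  grid <- CJ(peak = seq_len(nrow(pk)), bin_i = seq_len(nb))
  bs <- ctr[grid$peak] - flank + (grid$bin_i - 1) * bin
  iv <- data.table(chrom = pk$chrom[grid$peak],
                   start = pmax(bs, 0), end = pmax(bs + bin, 1))
  vals <- quantify_windows(track, iv)
  vals[bs + bin <= 0] <- 0
  prof <- data.table(bin_i = grid$bin_i, v = vals)[, .(mean_value = mean(v)),
                                                   by = bin_i]
  setorder(prof, bin_i)
  out <- data.table(offset_start = -flank + (prof$bin_i - 1) * bin,
                    offset_end = -flank + prof$bin_i * bin,
                    mean_value = prof$mean_value)
  if (!is.null(rescale_to)) {
    stopifnot(rescale_to > 0)
    out[, mean_value := mean_value / rescale_to]
  }
  out[]
}

#' Rank peaks by relative promoter-like signal
#'
#' Scores each interval by `log2((H3K4me3 + psi) / (H3K4me1 + psi))` and
#' orders descending, so promoter-like peaks (high H3K4me3) come first and
#' enhancer-like peaks (high H3K4me1) last. Ties are broken by genomic
#' coordinate.
#'
#' @param intervals data.frame of peaks (`chrom`, `start`, `end`).
#' @param m3,m1 numeric vectors: mean H3K4me3 / H3K4me1 signal per interval
#'   (same order as `intervals`).
#' @param psi pseudocount in signal units (default 1).
#' @return `data.table` of the intervals with a `score` column, sorted.
#' @export
rank_by_promoter_score <- function(intervals, m3, m1, psi = 1) {
  iv <- as.data.table(intervals)
  if (length(m3) != nrow(iv) || length(m1) != nrow(iv))
    stop("alignment error: signal columns do not match the interval set")
  iv[, score := log2((m3 + psi) / (m1 + psi))]
  setorder(iv, -score, chrom, start)
  iv[]
}

#' Pairwise Pearson correlation and hierarchical clustering of datasets
#'
#' @param mat numeric matrix: rows are intervals (e.g. ATAC peaks), columns
#'   are datasets.
#' @return list with `correlation` (symmetric, unit diagonal), `order`
#'   (dendrogram leaf order, column names) and the `hclust` object (average
#'   linkage on distance `1 - r`).
#' @export
correlate_datasets <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2 || nrow(mat) < 3)
    stop("need at least 2 datasets and 3 intervals")
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0))
    stop("undefined correlation: zero-variance dataset(s): ",
         paste(colnames(mat)[sds == 0], collapse = ", "))
  r <- cor(mat, method = "pearson")
  hc <- hclust(as.dist(1 - r), method = "average")
  list(correlation = r, order = colnames(mat)[hc$order], hclust = hc)
}
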