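# Super-enhancer stitching and calling, typical-enhancer definition,
# nearest-TSS assignment and eRNA response windows.
#
# Super-enhancer calling follows the rank-curve convention: stitched regions
# are sorted by aggregate coactivator signal, rank and signal are rescaled to
# [0, 1], and the cutoff sits where a line of slope 1 is tangent to the
# hockey-stick curve (the rightmost point where the discrete slope of the
# scaled curve first exceeds 1, equivalently the rightmost minimum of
# scaled_signal - scaled_rank). Regions above the cutoff are super-enhancers.

#' Stitch nearby peaks into candidate enhancer regions
#'
#' Peaks on the same chromosome whose edge-to-edge gap is at most `min_dist`
#' are merged transitively; each stitched region spans the minimum start to
#' maximum end of its constituents and carries the sum of their signals.
#'
#' @param peaks data.frame with `chrom`, `start`, `end`, `signal` and
#'   optionally `name` (constituent ids).
#' @param min_dist maximum edge-to-edge gap to merge (bp; default 12500).
#' @return `data.table` of stitched regions: `region_id`, `chrom`, `start`,
#'   `end`, `n_constituents`, `constituents` (comma-separated), `signal`.
#' @export
stitch_peaks <- function(peaks, min_dist = 12500) {
  stopifnot(min_dist >= 0)
  pk <- as.data.table(peaks)
  if (!"signal" %in% names(pk)) pk[, signal := NA_real_]
  if (!"name" %in% names(pk))
    pk[, name := sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))]
  setorder(pk, chrom, start, end)
  pk[, grp := {
    gap <- start - shift(cummax(end))
    cumsum(is.na(gap) | gap > min_dist)   # NA: first peak opens a region
  }, by = chrom]
  out <- pk[, .(start = min(start), end = max(end),
                n_constituents = .N,
                constituents = paste(name, collapse = ","),
                signal = sum(signal)),
            by = .(chrom, grp)]
  out[, grp := NULL]
  setorder(out, chrom, start)
  out[, region_id := sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))]
  setcolorder(out, c("region_id", "chrom", "start", "end"))
  out[]
}

#' Call super-enhancers from stitched regions
#'
#' Sorts regions ascending by aggregate signal, rescales rank and signal to
#' `[0, 1]` and places the cutoff at the rightmost minimum of
#' `scaled_signal - scaled_rank` (the tangent point of a slope-1 line on the
#' hockey-stick curve). Regions strictly above the cutoff point are flagged
#' `is_super`. When all signals are equal the curve is flat and no region is
#' flagged.
#'
#' @param stitched output of [stitch_peaks()] (at least 2 regions with finite
#'   signal).
#' @return `stitched` with logical `is_super`, plus attributes
#'   `cutoff_signal` (signal at the tangent point; `NA` when degenerate) and
#'   `n_super`.
#' @export
call_super_enhancers <- function(stitched) {
  st <- copy(as.data.table(stitched))
  if (nrow(st) < 2 || any(!is.finite(st$signal)))
    stop("insufficient data: need >= 2 stitched regions with finite signal")
  o <- order(st$signal)
  s <- st$signal[o]
  n <- length(s)
  if (max(s) == min(s)) {
    st[, is_super := FALSE]
    setattr(st, "cutoff_signal", NA_real_)
    setattr(st, "n_super", 0L)
    return(st[])
  }
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / (max(s) - min(s))
  f <- y - x
  i_star <- max(which(f == min(f)))
  flagged <- logical(n)
  if (i_star < n) flagged[(i_star + 1L):n] <- TRUE
  st[o, is_super := flagged]
  setattr(st, "cutoff_signal", s[i_star])
  setattr(st, "n_super", sum(flagged))
  st[]
}

# >=1 bp overlap of each interval in a with any interval in b (both 0-based
# half-open data.frames with chrom/start/end)
.overlaps_any <- function(a, b) {
  a <- as.data.table(a); b <- as.data.table(b)
  if (!nrow(b)) return(rep(FALSE, nrow(a)))
  vapply(seq_len(nrow(a)), function(i)
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i]),
    logical(1))
}

# minimum distance from a region to any TSS on its chromosome (0 if inside)
.min_tss_dist <- function(chrom_, start_, end_, tss) {
  p <- tss[["tss"]][tss[["chrom"]] == chrom_]
  if (!length(p)) return(NA_real_)
  min(pmax(start_ - p, p - end_, 0))
}

#' Define typical enhancers
#'
#' Typical enhancers are H3K27ac peaks that overlap an H3K4me1 peak by at
#' least 1 bp, lie more than `min_tss_dist` from every annotated TSS, and do
#' not overlap any super-enhancer region.
#'
#' @param k27ac,k4me1 data.frames of peak intervals.
#' @param tss data.frame of TSS annotation with columns `gene`, `chrom`,
#'   `tss` (0-based position).
#' @param ses output of [call_super_enhancers()] (only `is_super` regions are
#'   used).
#' @param min_tss_dist minimum distance from any TSS (bp; default 1000).
#' @return `data.table` of retained H3K27ac peaks.
#' @export
define_typical_enhancers <- function(k27ac, k4me1, tss, ses,
                                     min_tss_dist = 1000) {
  pk <- as.data.table(k27ac)
  se <- as.data.table(ses)
  se <- if ("is_super" %in% names(se)) se[is_super == TRUE] else se
  keep_me1 <- .overlaps_any(pk, k4me1)
  dist_tss <- vapply(seq_len(nrow(pk)), function(i)
    .min_tss_dist(pk$chrom[i], pk$start[i], pk$end[i], tss), numeric(1))
  keep_tss <- is.na(dist_tss) | dist_tss > min_tss_dist
  keep_se <- !.overlaps_any(pk, se)
  pk[keep_me1 & keep_tss & keep_se]
}

#' Assign regions to the gene with the nearest TSS
#'
#' Distance is the minimum distance from the region edges to the TSS (0 when
#' the TSS falls inside the region); ties are broken by the smaller TSS
#' coordinate. Regions on chromosomes without any TSS are left unassigned
#' (`NA`).
#'
#' @param regions data.frame of intervals.
#' @param tss data.frame with `gene`, `chrom`, `tss`.
#' @return `data.table`: the regions with `gene` and `tss_distance` columns.
#' @export
nearest_tss_assignment <- function(regions, tss) {
  rg <- copy(as.data.table(regions))
  tt <- as.data.table(tss)
  res <- lapply(seq_len(nrow(rg)), function(i) {
    cand <- tt[chrom == rg$chrom[i]]
    if (!nrow(cand)) return(list(gene = NA_character_, dist = NA_real_))
    d <- pmax(rg$start[i] - cand$tss, cand$tss - rg$end[i], 0)
    j <- which(d == min(d))
    j <- j[which.min(cand$tss[j])]
    list(gene = cand$gene[j], dist = d[j])
  })
  rg[, gene := vapply(res, `[[`, character(1), "gene")]
  rg[, tss_distance := vapply(res, `[[`, numeric(1), "dist")]
  rg[]
}

#' Build eRNA quantification windows at intergenic accessible sites
#'
#' Keeps ATAC peaks with no gene-body overlap that overlap a super-enhancer
#' or a typical enhancer and emits a fixed 1 kb window centered on each
#' (class `"SE"` wins when a peak overlaps both).
#'
#' @param atac data.frame of ATAC peak intervals.
#' @param ses super-enhancer regions (rows with `is_super == TRUE` if the
#'   column is present).
#' @param tes typical-enhancer intervals.
#' @param genes data.frame of gene bodies (`chrom`, `start`, `end`).
#' @param width window width (bp, default 1000).
#' @return `data.table` of windows: `window_id`, `chrom`, `start`, `end`,
#'   `class`.
#' @export
erna_windows <- function(atac, ses, tes, genes, width = 1000) {
  pk <- as.data.table(atac)
  se <- as.data.table(ses)
  se <- if ("is_super" %in% names(se)) se[is_super == TRUE] else se
  intergenic <- !.overlaps_any(pk, genes)
  in_se <- .overlaps_any(pk, se)
  in_te <- .overlaps_any(pk, tes)
  keep <- intergenic & (in_se | in_te)
  pk <- pk[keep]
  cls <- ifelse(in_se[keep], "SE", "TE")
  ctr <- floor((pk$start + pk$end) / 2)
  data.table(window_id = sprintf("%s:%d", pk$chrom, as.integer(ctr)),
             chrom = pk$chrom,
             start = ctr - floor(width / 2),
             end = ctr + ceiling(width / 2),
             class = cls)
}

#' Compare treatment response between two classes
#'
#' Two-sided Mann-Whitney rank-sum test between two sets of per-element
#' values (e.g. SE vs TE log fold-changes of BRD4, MED1, eRNA or gene
#' expression); see [rank_sum_test()].
#'
#' @param values_a,values_b numeric vectors (non-empty).
#' @return list with `p`, `median_a`, `median_b`, `method`.
#' @export
class_response_compare <- function(values_a, values_b) {
  r <- rank_sum_test(values_a, values_b)
  r[c("p", "median_a", "median_b", "method")]
}
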