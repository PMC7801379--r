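# Windowed differential interaction testing at binding peaks: the analysis
# asks, for each ChIP/ATAC peak inside a viewpoint's interaction domain,
# whether promoter contact frequency changes between two treatment
# conditions. Pairs are (fragment, replicate) units of normalized counts; the
# paired Wilcoxon signed-rank test gives a raw p per window, Holm-Bonferroni
# controls the family-wise error over all tested windows of a comparison, and
# effect size is the mean over replicates of the log2 ratio of window mean
# counts.

#' Build fixed-width test windows centered on peaks
#'
#' @param peaks data.frame of peak intervals with columns `chrom`, `start`,
#'   `end` and optionally `name` (used as `window_id`).
#' @param width window width in bp (default 10000, the published choice).
#' @param chrom_lengths optional named vector used to clip windows at
#'   chromosome ends; windows are always clipped at 0.
#' @return `data.table` of windows: `window_id`, `chrom`, `start`, `end`,
#'   `peak_start`, `peak_end`.
#' @export
build_windows <- function(peaks, width = 10000, chrom_lengths = NULL) {
  stopifnot(width > 0)
  pk <- as.data.table(peaks)
  stopifnot(all(pk$start < pk$end))
  ctr <- floor((pk$start + pk$end) / 2)
  ws <- pmax(0, ctr - floor(width / 2))
  we <- ctr + ceiling(width / 2)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[pk$chrom]
    we <- pmin(we, ifelse(is.na(lim), we, lim))
  }
  id <- if ("name" %in% names(pk)) as.character(pk$name) else
    sprintf("%s:%d-%d", pk$chrom, as.integer(pk$start), as.integer(pk$end))
  data.table(window_id = id, chrom = as.character(pk$chrom),
             start = ws, end = we,
             peak_start = as.numeric(pk$start), peak_end = as.numeric(pk$end))
}

#' Flag windows excluded from differential testing
#'
#' Windows on a different chromosome than the viewpoint (`trans`), with no
#' overlap with any interaction-domain interval (`outside_domain`), or coming
#' within the analysis exclusion radius (10 kb) of the capture probe
#' (`near_probe`) are flagged; only unflagged windows proceed to testing.
#'
#' @param windows output of [build_windows()].
#' @param vp a [viewpoint()].
#' @param domains data.frame of interaction-domain intervals for this
#'   viewpoint (`chrom`, `start`, `end`).
#' @return `windows` with logical columns `trans`, `outside_domain`,
#'   `near_probe`.
#' @export
filter_windows <- function(windows, vp, domains) {
  if (is.null(domains) || !nrow(as.data.table(domains)))
    stop("configuration error: no interaction domains supplied for viewpoint '",
         vp$name, "'")
  dom <- as.data.table(domains)
  w <- copy(as.data.table(windows))
  w[, trans := chrom != vp$chrom]
  ov <- function(ws, we, wc) {
    any(dom$chrom == wc & dom$start < we & dom$end > ws)
  }
  w[, outside_domain := !mapply(ov, start, end, chrom)]
  w[, near_probe := !trans &
      interval_gap(start, end, vp$start, vp$end) < vp$analysis_exclusion_radius]
  w[]
}

# long (window_id, fragment_id) membership. Exploits the tiling property of
# the fragment map: binary search on fragment starts per chromosome.
window_members <- function(windows, map) {
  w <- as.data.table(windows)
  lens <- attr(map, "chrom_lengths")
  out <- vector("list", 0L)
  for (cc in unique(w$chrom)) {
    if (!cc %in% names(lens)) next
    sub <- map[chrom == cc]
    ws <- w[chrom == cc]
    clen <- lens[[cc]]
    qs <- pmax(0, pmin(ws$start, clen - 1))
    qe <- pmin(ws$end, clen)
    first <- findInterval(qs, sub$start)
    last <- findInterval(pmax(qe - 1, qs), sub$start)
    keep <- ws$start < clen & qe > qs
    if (!any(keep)) next
    idx <- which(keep)
    out[[length(out) + 1L]] <- rbindlist(lapply(idx, function(i)
      data.table(window_id = ws$window_id[i],
                 fragment_id = sub$fragment_id[first[i]:last[i]])))
  }
  if (!length(out)) return(data.table(window_id = character(), fragment_id = character()))
  rbindlist(out)
}

# paired (fragment, replicate) differences for one viewpoint comparison;
# missing table rows count as zero
paired_differences <- function(table, members, cond_a, cond_b) {
  dt <- as.data.table(table)
  conds <- unique(dt$condition)
  if (!cond_a %in% conds) stop("lookup error: unknown condition '", cond_a, "'")
  if (!cond_b %in% conds) stop("lookup error: unknown condition '", cond_b, "'")
  rep_a <- sort(unique(dt[condition == cond_a, replicate]))
  rep_b <- sort(unique(dt[condition == cond_b, replicate]))
  if (!identical(rep_a, rep_b))
    stop("pairing error: replicate labels differ between conditions (",
         paste(rep_a, collapse = ","), " vs ", paste(rep_b, collapse = ","), ")")
  sub <- dt[condition %in% c(cond_a, cond_b) & fragment_id %in% unique(members$fragment_id)]
  wide <- dcast(sub, fragment_id + replicate ~ condition,
                value.var = "norm_count", fill = 0)
  # complete the grid: fragments with no reads in either condition are zeros
  grid <- CJ(fragment_id = unique(members$fragment_id), replicate = rep_a)
  wide <- wide[grid, on = c("fragment_id", "replicate")]
  for (cc in c(cond_a, cond_b)) set(wide, which(is.na(wide[[cc]])), cc, 0)
  members[wide, on = "fragment_id", allow.cartesian = TRUE
          ][, .(window_id, fragment_id, replicate,
                a = get(cond_a), b = get(cond_b), d = get(cond_b) - get(cond_a))]
}

#' Paired rank test for one window
#'
#' Pairs the normalized counts of every member fragment and replicate across
#' the two conditions and applies the two-sided Wilcoxon signed-rank test
#' (see [signed_rank_test()]). Windows with fewer than `min_pairs` nonzero
#' paired differences are flagged `too_few_pairs` and return no p-value (an
#' exact two-sided signed-rank p cannot reach 0.05 below 5 pairs).
#'
#' @param window one row of [build_windows()] output (or anything with
#'   `window_id`, `chrom`, `start`, `end`).
#' @param table a normalized [interaction_table()] for the window's viewpoint.
#' @param map the [fragment_map()].
#' @param cond_a,cond_b condition labels (control, treated).
#' @param min_pairs minimum nonzero pairs to test (default 5).
#' @param exact_max exact-distribution size limit (default 25).
#' @return list with `p_raw`, `n_pairs`, `too_few_pairs`.
#' @export
paired_window_test <- function(window, table, map, cond_a, cond_b,
                               min_pairs = 5L, exact_max = 25L) {
  members <- window_members(window, map)
  if (!nrow(members)) stop("empty window: no member fragments")
  pd <- paired_differences(table, members, cond_a, cond_b)
  res <- signed_rank_test(pd$d, exact_max = exact_max)
  too_few <- res$n < min_pairs
  list(p_raw = if (too_few) NA_real_ else res$p,
       n_pairs = res$n, too_few_pairs = too_few)
}

#' Per-replicate and mean log2 fold-change of window interaction frequency
#'
#' For each replicate, the log2 ratio of window mean normalized counts
#' (treated over control) with pseudocount `psi` on both means; `mean_logfc`
#' averages the per-replicate values.
#'
#' @inheritParams paired_window_test
#' @param psi pseudocount in normalized-count units (default 1).
#' @return list with `logfc_per_replicate` (named) and `mean_logfc`.
#' @export
window_logfc <- function(window, table, map, cond_a, cond_b, psi = 1) {
  members <- window_members(window, map)
  if (!nrow(members)) stop("empty window: no member fragments")
  pd <- paired_differences(table, members, cond_a, cond_b)
  lf <- pd[, .(logfc = log2((mean(b) + psi) / (mean(a) + psi))), by = replicate]
  list(logfc_per_replicate = setNames(lf$logfc, lf$replicate),
       mean_logfc = mean(lf$logfc))
}

#' Differential interaction testing over all windows of a comparison
#'
#' Runs the full windowed analysis for one condition pair: attaches member
#' fragments, forms (fragment, replicate) pairs, tests every unflagged window
#' with enough nonzero pairs, Holm-adjusts the p-values over the pooled
#' family of tested windows, and computes per-replicate and mean logFC.
#'
#' @param table normalized [interaction_table()] (may hold several
#'   viewpoints).
#' @param map the [fragment_map()].
#' @param viewpoints named list of [viewpoint()]s.
#' @param peaks data.frame of peak intervals (see [build_windows()]).
#' @param domains data.frame of domain intervals with a `viewpoint` column,
#'   or a named list of per-viewpoint domain data.frames.
#' @param cond_a,cond_b condition labels (control, treated).
#' @param width window width (bp).
#' @param alpha significance level on adjusted p (default 0.05).
#' @param psi logFC pseudocount (normalized-count units).
#' @param min_pairs minimum nonzero pairs per tested window.
#' @param exact_max exact signed-rank size limit.
#' @return `data.table`, one row per (viewpoint, window): coordinates, filter
#'   flags, `n_pairs`, `p_raw`, `p_adj`, per-replicate logFC columns
#'   (`logfc_<rep>`), `mean_logfc`, `direction`
#'   (increased/decreased/unchanged) and `tested`.
#' @export
diff_windows <- function(table, map, viewpoints, peaks, domains,
                         cond_a, cond_b, width = 10000, alpha = 0.05,
                         psi = 1, min_pairs = 5L, exact_max = 25L) {
  if (inherits(viewpoints, "viewpoint"))
    viewpoints <- setNames(list(viewpoints), viewpoints$name)
  dt <- as.data.table(table)
  dom_for <- function(vname) {
    if (is.data.frame(domains)) {
      d <- as.data.table(domains)
      if ("viewpoint" %in% names(d)) d <- d[viewpoint == vname]
      d
    } else domains[[vname]]
  }
  out <- list()
  for (vname in names(viewpoints)) {
    if (!vname %in% dt$viewpoint) next
    vp <- viewpoints[[vname]]
    w <- build_windows(peaks, width = width,
                       chrom_lengths = attr(map, "chrom_lengths"))
    w <- filter_windows(w, vp, dom_for(vname))
    w[, viewpoint := vname]
    keep <- w[!(trans | outside_domain | near_probe)]
    res <- w[, .(viewpoint, window_id, chrom, start, end,
                 trans, outside_domain, near_probe)]
    res[, `:=`(n_pairs = NA_integer_, p_raw = NA_real_, mean_logfc = NA_real_)]
    if (nrow(keep)) {
      members <- window_members(keep, map)
      vtab <- dt[viewpoint == vname & trans == FALSE]
      pd <- paired_differences(vtab, members, cond_a, cond_b)
      stat <- pd[d != 0, .(n_pairs = .N,
                           p_raw = signed_rank_test(d, exact_max = exact_max)$p),
                 by = window_id]
      lf <- pd[, .(logfc = log2((mean(b) + psi) / (mean(a) + psi))),
               by = .(window_id, replicate)]
      lfw <- dcast(lf, window_id ~ replicate, value.var = "logfc")
      setnames(lfw, setdiff(names(lfw), "window_id"),
               paste0("logfc_", setdiff(names(lfw), "window_id")))
      mlf <- lf[, .(mean_logfc = mean(logfc)), by = window_id]
      res[stat, `:=`(n_pairs = i.n_pairs, p_raw = i.p_raw), on = "window_id"]
      res[mlf, mean_logfc := i.mean_logfc, on = "window_id"]
      res <- merge(res, lfw, by = "window_id", all.x = TRUE, sort = FALSE)
      setcolorder(res, c("viewpoint", "window_id"))
    }
    res[is.na(n_pairs) & !(trans | outside_domain | near_probe), n_pairs := 0L]
    out[[vname]] <- res
  }
  res <- rbindlist(out, fill = TRUE)
  res[, too_few_pairs := !(trans | outside_domain | near_probe) & n_pairs < min_pairs]
  res[too_few_pairs == TRUE, p_raw := NA_real_]
  res[, tested := !(trans | outside_domain | near_probe | too_few_pairs)]
  res[, p_adj := NA_real_]
  if (any(res$tested)) res[tested == TRUE, p_adj := holm_adjust(p_raw)]
  res[, direction := fifelse(tested & p_adj < alpha & mean_logfc > 0, "increased",
                      fifelse(tested & p_adj < alpha & mean_logfc < 0, "decreased",
                              "unchanged"))]
  setattr(res, "comparison", c(cond_a = cond_a, cond_b = cond_b))
  setattr(res, "alpha", alpha)
  res[]
}

#' Summarize a differential comparison
#'
#' @param results output of [diff_windows()] for one comparison family.
#' @param alpha significance level on Holm-adjusted p (default 0.05).
#' @param label comparison label carried into the summary.
#' @return one-row `data.table`: `comparison`, `n_tested`, `n_significant`,
#'   `n_increased`, `n_decreased`, `mean_logfc_significant` (NA when nothing
#'   is significant).
#' @export
differential_summary <- function(results, alpha = 0.05, label = NA_character_) {
  r <- as.data.table(results)
  tested <- r[tested == TRUE]
  sig <- tested[p_adj < alpha]
  data.table(comparison = label,
             n_tested = nrow(tested),
             n_significant = nrow(sig),
             n_increased = sum(sig$mean_logfc > 0),
             n_decreased = sum(sig$mean_logfc < 0),
             mean_logfc_significant = if (nrow(sig)) mean(sig$mean_logfc) else NA_real_)
}

#' Enrichment of promoter contact at chromatin-feature peaks
#'
#' Ratio of the mean normalized interaction frequency of in-domain fragments
#' overlapping a set of feature peaks (e.g. H3K27ac, BRD4) to the mean over
#' all in-domain fragments, per viewpoint. Fragments within the probe
#' analysis exclusion radius are removed from numerator and denominator;
#' counts are averaged over replicates (and conditions present in `table`).
#'
#' @param feature_peaks data.frame of feature peak intervals.
#' @param table normalized [interaction_table()].
#' @param map the [fragment_map()].
#' @param vp a [viewpoint()].
#' @param domains data.frame of domain intervals for this viewpoint.
#' @return ratio (numeric), or `NA` when no in-domain fragment overlaps a
#'   feature peak.
#' @export
association_enrichment <- function(feature_peaks, table, map, vp, domains) {
  dom <- as.data.table(domains)
  if (!nrow(dom)) stop("configuration error: no domains for viewpoint '", vp$name, "'")
  dom_frag <- unique(unlist(lapply(seq_len(nrow(dom)), function(i)
    fragments_in_interval(map, dom$chrom[i], dom$start[i], dom$end[i]))))
  coords <- map[fragment_id %in% dom_frag]
  near <- coords[interval_gap(start, end, vp$start, vp$end) <
                   vp$analysis_exclusion_radius, fragment_id]
  dom_frag <- setdiff(dom_frag, near)
  if (!length(dom_frag)) return(NA_real_)
  fp <- as.data.table(feature_peaks)
  feat_frag <- unique(unlist(lapply(seq_len(nrow(fp)), function(i)
    tryCatch(fragments_in_interval(map, fp$chrom[i], fp$start[i], fp$end[i]),
             error = function(e) character(0)))))
  feat_frag <- intersect(feat_frag, dom_frag)
  if (!length(feat_frag)) return(NA_real_)
  dt <- as.data.table(table)[viewpoint == vp$name & fragment_id %in% dom_frag]
  per_frag <- dt[, .(m = mean(norm_count)), by = fragment_id]
  # fragments with no table rows have zero contact
  allm <- per_frag[J(dom_frag), on = "fragment_id"][is.na(m), m := 0][]
  num <- mean(allm[fragment_id %in% feat_frag, m])
  den <- mean(allm$m)
  if (den == 0) return(NA_real_)
  num / den
}
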