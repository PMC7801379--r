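# Per-viewpoint interaction count tables and cis normalization.
#
# An interaction table holds one row per (viewpoint, fragment, replicate,
# condition) with raw and normalized contact counts plus the exclusion and
# trans flags used downstream. Normalization scales each library so the sum
# of normalized counts over cis, non-excluded fragments equals a common
# constant (counts per `scale` reported cis reads; the downstream paired test
# is invariant to the constant).

#' Construct an interaction table
#'
#' @param df data.frame with columns `viewpoint`, `fragment_id`, `replicate`,
#'   `condition`, `raw_count` and optionally `norm_count`, `excluded`,
#'   `trans`.
#' @param validate check key uniqueness (skipped by internal callers whose
#'   construction guarantees it).
#' @return An `interaction_table` (keyed `data.table`).
#' @export
interaction_table <- function(df, validate = TRUE) {
  dt <- as.data.table(df)
  need <- c("viewpoint", "fragment_id", "replicate", "condition", "raw_count")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("interaction table missing columns: ", paste(miss, collapse = ", "))
  if (any(dt$raw_count < 0)) stop("raw_count must be non-negative")
  if (!"norm_count" %in% names(dt)) dt[, norm_count := NA_real_]
  if (!"excluded" %in% names(dt)) dt[, excluded := FALSE]
  if (!"trans" %in% names(dt)) dt[, trans := NA]
  key <- c("viewpoint", "fragment_id", "replicate", "condition")
  if (validate) {
    if (anyDuplicated(dt, by = key))
      stop("(viewpoint, fragment_id, replicate, condition) must be unique")
    setkeyv(dt, key)
  }
  setattr(dt, "class", c("interaction_table", class(data.table())))
  dt[]
}

#' Normalize fragment-level interaction counts per library
#'
#' For every (viewpoint, replicate, condition) library, counts are scaled to
#' `norm_count = raw_count * scale / T`, where `T` is the sum of raw counts
#' over cis fragments lying outside the viewpoint exclusion radius. Fragments
#' inside the exclusion zone get `norm_count = 0` and are flagged `excluded`;
#' trans fragments are scaled by the same `T` and flagged `trans` (they are
#' kept in the table but removed from window testing downstream).
#'
#' @param table an [interaction_table()] with raw counts.
#' @param map the [fragment_map()] the fragment ids refer to.
#' @param viewpoints a single [viewpoint()] or a named list of viewpoints
#'   covering every viewpoint label in `table`.
#' @param scale positive normalization constant (default `1e5`: counts per
#'   100,000 reported cis reads).
#' @return The table with `norm_count`, `excluded` and `trans` filled in.
#' @export
normalize_interactions <- function(table, map, viewpoints, scale = 1e5) {
  stopifnot(scale > 0)
  if (inherits(viewpoints, "viewpoint")) {
    viewpoints <- setNames(list(viewpoints), viewpoints$name)
  }
  dt <- copy(as.data.table(table))
  bad <- setdiff(unique(dt$fragment_id), map$fragment_id)
  if (length(bad)) stop("fragment ids absent from map: ", paste(head(bad, 3), collapse = ", "),
                        if (length(bad) > 3) " ...")
  dt[map, `:=`(chrom = i.chrom, start = i.start, end = i.end),
     on = "fragment_id"]
  vps <- unique(dt$viewpoint)
  miss <- setdiff(vps, names(viewpoints))
  if (length(miss)) stop("no viewpoint definition for: ", paste(miss, collapse = ", "))
  out <- vector("list", length(vps))
  for (i in seq_along(vps)) {
    vp <- viewpoints[[vps[i]]]
    validate_viewpoint(vp, map)
    sub <- dt[viewpoint == vps[i]]
    sub[, trans := chrom != vp$chrom]
    sub[, excluded := !trans &
          interval_gap(start, end, vp$start, vp$end) < vp$exclusion_radius]
    totals <- sub[!trans & !excluded,
                  .(T_ = sum(raw_count)), by = .(replicate, condition)]
    bad <- totals[T_ == 0]
    if (nrow(bad))
      stop("degenerate library: no cis reads outside the exclusion zone for ",
           "viewpoint=", vps[i], " replicate=", bad$replicate[1],
           " condition=", bad$condition[1])
    sub[totals, T_ := i.T_, on = c("replicate", "condition")]
    sub[, norm_count := fifelse(excluded, 0, raw_count * scale / T_)]
    sub[, T_ := NULL]
    out[[i]] <- sub
  }
  res <- rbindlist(out)
  res[, c("chrom", "start", "end") := NULL]
  interaction_table(res, validate = FALSE)
}
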