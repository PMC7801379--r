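# Restriction-fragment coordinate maps: in-silico digestion and interval
# lookup. Fragments tile each chromosome exactly in 0-based half-open
# coordinates; fragment ids are "<chrom>_<ordinal>".

#' Construct a fragment map
#'
#' A fragment map is the genome partition produced by restriction digestion:
#' per chromosome an ordered set of non-overlapping fragments tiling
#' `[0, chrom_length)` with no gaps and no zero-length fragments.
#'
#' @param df data.frame with columns `chrom`, `start`, `end` and optionally
#'   `fragment_id` (generated as `<chrom>_<i>` when absent).
#' @return A `fragment_map` (a `data.table` with columns `chrom`, `start`,
#'   `end`, `fragment_id`), with chromosome lengths in attribute
#'   `chrom_lengths`.
#' @export
fragment_map <- function(df) {
  dt <- as.data.table(df)[, .(chrom = as.character(chrom),
                              start = as.numeric(start),
                              end = as.numeric(end))]
  setorder(dt, chrom, start)
  if (!"fragment_id" %in% names(df)) {
    dt[, fragment_id := paste0(chrom, "_", seq_len(.N)), by = chrom]
  } else {
    dt[, fragment_id := as.character(as.data.table(df)[order(chrom, start), fragment_id])]
  }
  validate_fragment_map(dt)
  setattr(dt, "chrom_lengths", dt[, .(len = max(end)), by = chrom][, setNames(len, chrom)])
  setattr(dt, "class", c("fragment_map", class(data.table())))
  dt[]
}

validate_fragment_map <- function(dt) {
  if (any(dt$end <= dt$start)) stop("fragment map contains zero/negative-length fragments")
  bad <- dt[, {
    ok <- start[1] == 0 && all(start[-1] == end[-.N])
    !ok
  }, by = chrom][V1 == TRUE]
  if (nrow(bad)) {
    stop("fragments do not tile [0, chrom_length) on: ",
         paste(bad$chrom, collapse = ", "))
  }
  if (anyDuplicated(dt$fragment_id)) stop("duplicated fragment_id in map")
  invisible(dt)
}

#' In-silico restriction digestion of one chromosome sequence
#'
#' Cuts at the start of every motif occurrence (the 4-cutter convention for
#' DpnII, which cleaves 5' of GATC), so fragments are the intervals between
#' consecutive cut sites plus the sequence ends. Zero-length terminal
#' fragments (motif at position 0 or abutting the ends) are dropped.
#'
#' @param seq single DNA string over `{A,C,G,T,N}` (case-insensitive).
#' @param motif recognition motif over `{A,C,G,T}`, e.g. `"GATC"` for DpnII.
#' @param chrom chromosome name for the emitted fragments.
#' @return A [fragment_map()] for the single chromosome.
#' @examples
#' digest_sequence("AAGATCCGATCA", "GATC")
#' @export
digest_sequence <- function(seq, motif = "GATC", chrom = "chr1") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop("invalid input: sequence must be a non-empty DNA string")
  if (length(motif) != 1L || is.na(motif) || !nzchar(motif))
    stop("invalid input: motif must be a non-empty DNA string")
  seq <- toupper(seq); motif <- toupper(motif)
  if (grepl("[^ACGTN]", seq)) stop("invalid input: sequence has characters outside {A,C,G,T,N}")
  if (grepl("[^ACGT]", motif)) stop("invalid input: motif has characters outside {A,C,G,T}")
  n <- nchar(seq)
  cuts <- if (nchar(motif) > n) integer(0) else {
    m <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq))
    BiocGenerics::start(m) - 1L  # 0-based cut positions
  }
  bounds <- sort(unique(c(0, cuts, n)))
  fragment_map(data.frame(chrom = chrom,
                          start = head(bounds, -1L),
                          end = tail(bounds, -1L)))
}

#' Fragments overlapping a genomic interval
#'
#' @param map a [fragment_map()].
#' @param chrom,start,end query interval, 0-based half-open; must satisfy
#'   `start < end` and lie on a chromosome present in the map.
#' @return Character vector of fragment ids with at least 1 bp overlap, in
#'   coordinate order.
#' @export
fragments_in_interval <- function(map, chrom, start, end) {
  stopifnot(start < end)
  qc <- chrom; qs <- start; qe <- end
  lens <- attr(map, "chrom_lengths")
  if (!qc %in% names(lens)) stop("lookup error: unknown chromosome '", qc, "'")
  if (qs >= lens[[qc]]) stop("lookup error: interval beyond end of ", qc)
  map[chrom == qc & start < qe & end > qs, fragment_id]
}

#' Define a Capture-C viewpoint
#'
#' @param name viewpoint (captured gene/element) name.
#' @param chrom chromosome of the capture probe.
#' @param start,end probe interval (0-based half-open); must lie within a
#'   single restriction fragment.
#' @param exclusion_radius bp around the probe removed from normalization
#'   (proximity artifacts); default 1000.
#' @param analysis_exclusion_radius bp around the probe within which peak
#'   windows are removed from differential testing; fixed at 10000 in the
#'   published analysis.
#' @return A `viewpoint` object (list).
#' @export
viewpoint <- function(name, chrom, start, end,
                      exclusion_radius = 1000,
                      analysis_exclusion_radius = 10000) {
  stopifnot(start < end, exclusion_radius >= 0, analysis_exclusion_radius >= 0)
  structure(list(name = name, chrom = chrom, start = start, end = end,
                 exclusion_radius = exclusion_radius,
                 analysis_exclusion_radius = analysis_exclusion_radius),
            class = "viewpoint")
}

#' @export
print.viewpoint <- function(x, ...) {
  cat(sprintf("<viewpoint %s> %s:%d-%d (excl %d bp, analysis excl %d bp)\n",
              x$name, x$chrom, x$start, x$end,
              x$exclusion_radius, x$analysis_exclusion_radius))
  invisible(x)
}

validate_viewpoint <- function(vp, map) {
  host <- fragments_in_interval(map, vp$chrom, vp$start, vp$end)
  if (length(host) != 1L)
    stop("viewpoint '", vp$name, "' probe interval spans ", length(host),
         " fragments; it must lie within one restriction fragment")
  invisible(host)
}

# gap between two half-open intervals; 0 when they overlap or abut
interval_gap <- function(s1, e1, s2, e2) {
  pmax(s2 - e1, s1 - e2, 0)
}
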