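# File formats: BED and bedGraph via rtracklayer (converted to the package's
# 0-based half-open data.frames), tab-separated tables with '#'-prefixed
# header lines for everything else, and JSON run configuration.

granges_to_df <- function(gr, value_col = NULL) {
  df <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1,
                   end = BiocGenerics::end(gr))
  md <- S4Vectors::mcols(gr)
  if ("name" %in% names(md)) df[, name := md$name]
  if (!is.null(value_col) && "score" %in% names(md)) df[[value_col]] <- md$score
  df[]
}

df_to_granges <- function(df, value_col = NULL) {
  df <- as.data.table(df)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
  if ("name" %in% names(df)) S4Vectors::mcols(gr)$name <- df$name
  if (!is.null(value_col)) S4Vectors::mcols(gr)$score <- df[[value_col]]
  gr
}

#' Read/write interval sets as BED
#'
#' BED is parsed as 0-based half-open; column 4 becomes `name`, column 5
#' `score`. Writers round-trip losslessly through [read_bed()].
#'
#' @param path file path.
#' @param df data.frame with `chrom`, `start`, `end` and optional `name`,
#'   `score`.
#' @return `read_bed`: a `data.table`; `write_bed`: the path, invisibly.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- granges_to_df(gr, value_col = "score")
  df[]
}

#' @rdname read_bed
#' @export
write_bed <- function(df, path) {
  df <- as.data.table(df)
  if (any(df$start < 0)) stop("parse error: negative coordinates")
  gr <- df_to_granges(df, value_col = if ("score" %in% names(df)) "score")
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read/write coverage tracks as bedGraph
#'
#' @param path file path.
#' @param track a [signal_track()].
#' @param depth,scale_state metadata attached to the track on read.
#' @return `read_bedgraph`: a [signal_track()]; `write_bedgraph`: the path.
#' @export
read_bedgraph <- function(path, depth = NA_real_, scale_state = "raw") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- granges_to_df(gr, value_col = "value")
  signal_track(df, depth = depth, scale_state = scale_state)
}

#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(track, path) {
  gr <- df_to_granges(as.data.table(track), value_col = "value")
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read/write tab-separated tables with a '#'-prefixed header
#'
#' UTF-8, no quoting; the first line is `#col1<TAB>col2...`.
#'
#' @param dt data.frame to write.
#' @param path file path.
#' @return `read_table_tsv`: a `data.table`; `write_table_tsv`: the path.
#' @export
write_table_tsv <- function(dt, path) {
  dt <- as.data.table(dt)
  header <- paste0("#", paste(names(dt), collapse = "\t"))
  con <- file(path, open = "wb")  # binary: stable bytes across platforms
  writeLines(header, con, sep = "\n")
  close(con)
  fwrite(dt, path, sep = "\t", append = TRUE, col.names = FALSE, quote = FALSE,
         eol = "\n")
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#")) stop("parse error: missing '#' header in ", path)
  cols <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
  dt <- fread(path, sep = "\t", skip = 1L, header = FALSE)
  if (nrow(dt) && ncol(dt) != length(cols))
    stop("parse error: column count mismatch in ", path)
  if (!nrow(dt)) dt <- as.data.table(setNames(rep(list(logical(0)), length(cols)), cols))
  else setnames(dt, cols)
  dt[]
}

#' Write/read an interaction table
#'
#' Tab-separated with columns `viewpoint`, `fragment_id`, `chrom`, `start`,
#' `end`, `replicate`, `condition`, `raw_count`, `norm_count`, `flags`
#' (comma-separated among `excluded`, `trans`).
#'
#' @param table an [interaction_table()].
#' @param map a [fragment_map()] supplying coordinates (write) / validating
#'   ids (read).
#' @param path file path.
#' @return `read_interactions`: an [interaction_table()];
#'   `write_interactions`: the path.
#' @export
write_interactions <- function(table, map, path) {
  dt <- copy(as.data.table(table))
  dt[map, `:=`(chrom = i.chrom, start = i.start, end = i.end), on = "fragment_id"]
  dt[, flags := paste0(ifelse(excluded %in% TRUE, "excluded", ""),
                       ifelse(excluded %in% TRUE & trans %in% TRUE, ",", ""),
                       ifelse(trans %in% TRUE, "trans", ""))]
  out <- dt[, .(viewpoint, fragment_id, chrom, start, end, replicate,
                condition, raw_count,
                norm_count = fifelse(is.na(norm_count), NA_real_, norm_count),
                flags)]
  write_table_tsv(out, path)
}

#' @rdname write_interactions
#' @export
read_interactions <- function(path) {
  dt <- read_table_tsv(path)
  dt[, flags := as.character(flags)]
  dt[is.na(flags), flags := ""]
  dt[, excluded := grepl("excluded", flags)]
  dt[, trans := grepl("trans", flags)]
  interaction_table(dt[, .(viewpoint, fragment_id, replicate, condition,
                           raw_count, norm_count, excluded, trans)])
}

#' Read a run configuration
#'
#' JSON with blocks `seed`, `design` (overrides for [sim_design()]),
#' `params` (window width, `min_pairs`, `psi`, `alpha`, `scale`, `min_dist`,
#' `flank`, `bin`) and `comparisons` (list of `[condition_a, condition_b]`
#' pairs, which must reference declared conditions).
#'
#' @param path JSON file path.
#' @return validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) config_error("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg a config list (as parsed from JSON).
#' @export
validate_config <- function(cfg) {
  if (is.null(cfg$seed)) config_error("config must declare a seed")
  design_args <- cfg$design %||% list()
  conditions <- design_args$conditions %||% c("control", "treated")
  cmp <- cfg$comparisons %||% list(conditions)
  if (is.matrix(cmp)) cmp <- split(cmp, seq_len(nrow(cmp)))
  for (pair in cmp) {
    if (length(pair) != 2) config_error("each comparison must be a pair of conditions")
    und <- setdiff(unlist(pair), conditions)
    if (length(und))
      config_error("comparison references undeclared condition(s): ",
                   paste(und, collapse = ", "))
  }
  cfg$comparisons <- cmp
  cfg
}

config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("caploop_config_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
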