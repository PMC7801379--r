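# End-to-end pipeline: simulate -> normalize -> window/filter/test/adjust ->
# summarize, with optional spike-in ChIP, enhancer-classification, eRNA and
# feature-association stages. Deterministic given (config, seed); every
# output file is checksummed into the run report.

#' Run the full analysis pipeline from a configuration
#'
#' Stages (selected via `stages`): `"simulate"` writes the synthetic inputs
#' (fragment map, peaks, domains, raw interaction table); `"normalize"` the
#' normalized table; `"diff"` per-window differential results and a summary
#' per comparison; `"chipnorm"` spike-in counts and factors; `"enhancers"`
#' stitched regions with SE calls and typical enhancers; `"erna"` eRNA
#' windows, logFC and the SE-vs-TE comparison; `"associate"` the
#' feature-vs-interaction enrichment per viewpoint. Later stages pull in the
#' earlier ones they need.
#'
#' @param config path to a JSON config or a config list (see
#'   [read_config()]).
#' @param outdir output directory (created).
#' @param stages character vector of stages to run.
#' @return The run report (list), invisibly; also written as
#'   `run_report.json`.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "normalize", "diff",
                                    "chipnorm", "enhancers", "erna",
                                    "associate")) {
  cfg <- if (is.character(config)) read_config(config) else validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- cfg$params %||% list()
  width <- p$window_width %||% 10000
  alpha <- p$alpha %||% 0.05
  psi <- p$psi %||% 1
  min_pairs <- p$min_pairs %||% 5L
  scale <- p$scale %||% 1e5
  min_dist <- p$min_dist %||% 12500
  design <- do.call(sim_design, c(list(seed = cfg$seed), cfg$design %||% list()))
  report <- list(seed = cfg$seed,
                 params = list(window_width = width, alpha = alpha, psi = psi,
                               min_pairs = min_pairs, scale = scale,
                               min_dist = min_dist),
                 stages = list(), outputs = list())
  outfile <- function(name) file.path(outdir, name)
  log_stage <- function(stage, files, rows) {
    # basenames only: reports must be byte-identical across output locations
    report$stages[[stage]] <<- list(outputs = basename(files), rows = rows)
    for (f in files)
      report$outputs[[basename(f)]] <<- unname(tools::md5sum(f))
  }

  need <- function(s) s %in% stages ||
    (s == "simulate") ||
    (s == "normalize" && any(c("diff", "associate") %in% stages))

  map <- simulate_fragment_map(design)
  sim <- simulate_capture_experiment(design, map)
  if ("simulate" %in% stages) {
    write_bed(map[, .(chrom, start, end, name = fragment_id)],
              outfile("fragment_map.bed"))
    write_bed(sim$peaks[, .(chrom, start, end, name)], outfile("peaks.bed"))
    write_bed(sim$domains[, .(chrom, start, end, name = viewpoint)],
              outfile("domains.bed"))
    write_interactions(sim$table, map, outfile("interactions_raw.tsv"))
    write_table_tsv(sim$truth, outfile("truth_windows.tsv"))
    log_stage("simulate",
              outfile(c("fragment_map.bed", "peaks.bed", "domains.bed",
                        "interactions_raw.tsv", "truth_windows.tsv")),
              nrow(sim$table))
  }

  norm <- NULL
  if (need("normalize")) {
    norm <- normalize_interactions(sim$table, map, sim$viewpoints, scale = scale)
    if ("normalize" %in% stages) {
      write_interactions(norm, map, outfile("interactions_norm.tsv"))
      log_stage("normalize", outfile("interactions_norm.tsv"), nrow(norm))
    }
  }

  if ("diff" %in% stages) {
    for (i in seq_along(cfg$comparisons)) {
      pair <- unlist(cfg$comparisons[[i]])
      lab <- paste(pair, collapse = "_vs_")
      res <- diff_windows(norm, map, sim$viewpoints, sim$peaks, sim$domains,
                          cond_a = pair[1], cond_b = pair[2], width = width,
                          alpha = alpha, psi = psi, min_pairs = min_pairs)
      smy <- differential_summary(res, alpha = alpha, label = lab)
      f1 <- outfile(sprintf("diff_%s.tsv", lab))
      f2 <- outfile(sprintf("diff_summary_%s.tsv", lab))
      write_table_tsv(res, f1)
      write_table_tsv(smy, f2)
      log_stage(paste0("diff:", lab), c(f1, f2), nrow(res))
    }
  }

  if ("chipnorm" %in% stages) {
    sp <- simulate_spikein_counts(design)
    tab <- rbindlist(lapply(sp$pairs, function(x) as.data.table(unclass(x))))
    f1 <- outfile("spikein_counts.tsv")
    write_table_tsv(tab, f1)
    ref <- names(design$spike_factors)[1]
    fac <- vapply(sp$pairs, function(x)
      spike_in_factor(x, sp$pairs[[ref]]), numeric(1))
    f2 <- outfile("spikein_factors.tsv")
    write_table_tsv(data.table(sample = names(fac), factor = unname(fac),
                               true_factor = sp$truth$true_factor), f2)
    log_stage("chipnorm", c(f1, f2), length(fac))
  }

  sig <- NULL
  if (any(c("enhancers", "erna") %in% stages)) {
    sig <- simulate_signal_and_nascent(design)
  }

  ses <- tes <- NULL
  if ("enhancers" %in% stages) {
    st <- stitch_peaks(sig$peaks, min_dist = min_dist)
    ses <- call_super_enhancers(st)
    tes <- define_typical_enhancers(
      k27ac = sig$peaks, k4me1 = sig$peaks, tss = sig$tss, ses = ses)
    f1 <- outfile("super_enhancers.bed")
    se_only <- ses[is_super == TRUE]
    write_bed(se_only[, .(chrom, start, end, name = region_id, score = signal)], f1)
    f2 <- outfile("typical_enhancers.bed")
    write_bed(tes[, .(chrom, start, end, name, score = signal)], f2)
    assigned <- nearest_tss_assignment(ses, sig$tss)
    f3 <- outfile("stitched_enhancers.tsv")
    write_table_tsv(assigned, f3)
    log_stage("enhancers", c(f1, f2, f3), nrow(ses))
  }

  if ("erna" %in% stages) {
    if (is.null(ses)) {
      st <- stitch_peaks(sig$peaks, min_dist = min_dist)
      ses <- call_super_enhancers(st)
      tes <- define_typical_enhancers(sig$peaks, sig$peaks, sig$tss, ses)
    }
    ew <- erna_windows(sig$atac, ses, tes, sig$genes)
    lfc <- erna_logfc(sig$erna, design$conditions, psi = psi)
    ew[lfc, logfc := i.logfc, on = "window_id"]
    f1 <- outfile("erna_windows.tsv")
    write_table_tsv(ew, f1)
    cmp <- if (all(c("SE", "TE") %in% ew$class)) {
      class_response_compare(ew[class == "SE", logfc], ew[class == "TE", logfc])
    } else list(p = NA_real_, median_a = NA_real_, median_b = NA_real_)
    f2 <- outfile("erna_class_compare.tsv")
    write_table_tsv(data.table(p = cmp$p, median_se = cmp$median_a,
                               median_te = cmp$median_b), f2)
    log_stage("erna", c(f1, f2), nrow(ew))
  }

  if ("associate" %in% stages) {
    enr <- rbindlist(lapply(names(sim$viewpoints), function(vn) {
      vp <- sim$viewpoints[[vn]]
      dom <- sim$domains[viewpoint == vn]
      fp <- sim$peaks[viewpoint == vn]
      data.table(viewpoint = vn,
                 enrichment = association_enrichment(fp, norm, map, vp, dom))
    }))
    f1 <- outfile("feature_association.tsv")
    write_table_tsv(enr, f1)
    log_stage("associate", f1, nrow(enr))
  }

  report_path <- outfile("run_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(report)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `digest`, `normalize`, `diff`, `chip-norm`,
#' `enhancers`, `erna`, `associate`, `report`. All except `digest` take
#' `--config <json>` and `--outdir <dir>`; `digest` takes `--fasta`,
#' `--motif` and `--out` (BED4 fragment map). Exit status: 0 success, 2
#' configuration error, 1 computation error.
#'
#' @param args character vector of CLI arguments (default: the process
#'   command line).
#' @return integer exit status, invisibly.
#' @export
caploop_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    message("usage: caploop <simulate|digest|normalize|diff|chip-norm|enhancers|erna|associate|report> [options]")
    2L
  }
  if (!length(args)) return(invisible(usage()))
  cmd <- args[1]
  opts <- args[-1]
  getopt <- function(flag) {
    i <- which(opts == flag)
    if (!length(i) || i == length(opts)) NULL else opts[i + 1]
  }
  status <- tryCatch({
    if (cmd == "digest") {
      fa <- getopt("--fasta"); out <- getopt("--out")
      motif <- getopt("--motif") %||% "GATC"
      if (is.null(fa) || is.null(out)) config_error("digest needs --fasta and --out")
      seqs <- Biostrings::readDNAStringSet(fa)
      maps <- rbindlist(lapply(seq_along(seqs), function(i)
        digest_sequence(as.character(seqs[[i]]), motif,
                        chrom = names(seqs)[i])))
      write_bed(maps[, .(chrom, start, end, name = fragment_id)], out)
      0L
    } else if (cmd %in% c("simulate", "normalize", "diff", "chip-norm",
                          "enhancers", "erna", "associate", "report")) {
      cfgp <- getopt("--config"); outdir <- getopt("--outdir")
      if (is.null(cfgp) || is.null(outdir))
        config_error(cmd, " needs --config and --outdir")
      stages <- switch(cmd,
        simulate = "simulate",
        normalize = c("simulate", "normalize"),
        diff = c("simulate", "normalize", "diff"),
        `chip-norm` = "chipnorm",
        enhancers = "enhancers",
        erna = "enhancers",
        associate = "associate",
        report = c("simulate", "normalize", "diff", "chipnorm",
                   "enhancers", "erna", "associate"))
      if (cmd == "erna") stages <- c(stages, "erna")
      run_pipeline(cfgp, outdir, stages = stages)
      0L
    } else {
      usage()
    }
  },
  caploop_config_error = function(e) { message("config error: ", conditionMessage(e)); 2L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
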