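# In-code fixtures shared across test files.

library(data.table)

# regular tiling map: `n` fragments of `step` bp on each chromosome
make_tiling_map <- function(chroms = "chr1", n = 100, step = 1000) {
  fragment_map(rbindlist(lapply(chroms, function(cc)
    data.table(chrom = cc, start = step * (seq_len(n) - 1),
               end = step * seq_len(n)))))
}

# interaction table with given per-fragment norm counts for one viewpoint;
# counts: named list condition -> replicate -> numeric vector over fragments
make_norm_table <- function(map, vp_name, counts) {
  rows <- list()
  for (cond in names(counts)) {
    for (rep_ in names(counts[[cond]])) {
      v <- counts[[cond]][[rep_]]
      rows[[length(rows) + 1L]] <- data.table(
        viewpoint = vp_name, fragment_id = map$fragment_id[seq_along(v)],
        replicate = rep_, condition = cond,
        raw_count = v, norm_count = as.numeric(v),
        excluded = FALSE, trans = FALSE)
    }
  }
  interaction_table(rbindlist(rows))
}

small_design <- function(seed = 1L, ...) {
  sim_design(seed = seed, n_viewpoints = 2L, chrom_length = 4e5,
             domain_halfwidth = 1.8e5, n_peaks_per_viewpoint = 20L,
             depth = 2e5, n_enhancer_regions = 60L, ...)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
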