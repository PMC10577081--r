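# End-to-end drivers: simulate a complete tiled selection experiment and
# score it, mirroring the full count -> enrich -> rescale -> combine chain.

#' Simulate a complete tiled selection experiment
#'
#' For each biological replicate, draws a fresh clone pool from the library
#' model, applies in-silico selection, and sequences four pools with the
#' same tiling design: the variant pool before (`nonselect`) and after
#' (`select`) selection, and a wild-type control pool under both conditions
#' (`wt_nonselect`, `wt_select`). All four are tabulated with the duplex
#' posterior rule.
#'
#' @param truth a [generate_ground_truth()] map.
#' @param lib a [library_model()].
#' @param seqm a [sequencing_model()].
#' @param sel a [selection_model()].
#' @param n_rep number of biological replicates (default 2).
#' @param seed integer seed.
#' @param posterior_threshold duplex calling threshold (default 0.9).
#' @return list with `counts` (one long data.frame: all count tables with
#'   `condition` and `replicate` columns), `pools` (per replicate, the
#'   post-selection pool for inspection), `region_bounds`.
#' @export
run_tile_experiment <- function(truth, lib, seqm, sel, n_rep = 2, seed = 1,
                                posterior_threshold = 0.9) {
  counts <- list()
  pools <- list()
  bounds <- NULL
  for (r in seq_len(n_rep)) {
    s0 <- child_seed(seed, 1000 + r)
    pool <- simulate_clone_pool(truth, lib, s0)
    bounds <- pool$region_bounds
    pool_sel <- simulate_selection(pool, truth, sel, child_seed(s0, 2))
    wt <- wt_control_pool(truth)
    runs <- list(nonselect = pool, select = pool_sel,
                 wt_nonselect = wt, wt_select = wt)
    for (cond in names(runs)) {
      rps <- simulate_read_pairs(runs[[cond]], seqm, truth,
                                 child_seed(s0, 10 + match(cond, names(runs))))
      ct <- tabulate_pairs(rps, posterior_threshold,
                           condition = cond, replicate = r)
      ct[["condition"]] <- rep(cond, nrow(ct))
      ct[["replicate"]] <- rep(r, nrow(ct))
      counts[[paste(cond, r)]] <- ct
    }
    pools[[r]] <- pool_sel
  }
  list(counts = do.call(rbind, counts), pools = pools,
       region_bounds = bounds)
}

#' Score a tiled selection experiment
#'
#' Runs the full scoring chain on a long count table: per replicate, filter
#' both conditions against count and WT-percentile thresholds, subtract the
#' WT control, form enrichment ratios, compute per-region nonsense and
#' synonymous medians and rescale to functional impact scores; across
#' replicates, average the scores, regularize the errors against the
#' frequency trend and apply the quality filters.
#'
#' @param counts long count data.frame from [run_tile_experiment()] (or
#'   equivalent) with `condition` in
#'   `nonselect`/`select`/`wt_nonselect`/`wt_select` and `replicate`.
#' @param protein_length protein length in residues.
#' @param region_bounds list of mutagenesis-region intervals (default: one
#'   region).
#' @param config a [score_config()].
#' @return data.frame: one row per variant with `key`, `pos`, `ref_aa`,
#'   `alt_aa`, `class`, `region`, `fs`, `sigma`, `n_rep`, `f_ns`,
#'   `pass_sigma`, `pass_f_ns`, `passed_filters`; attributes `scales` (per
#'   replicate) and `config`.
#' @export
score_tile_experiment <- function(counts, protein_length,
                                  region_bounds = NULL,
                                  config = score_config()) {
  region_bounds <- region_bounds %||% list(c(1L, protein_length))
  reps <- sort(unique(counts$replicate))
  rep_scores <- list()
  scales_log <- list()
  for (r in reps) {
    tab <- function(cond) {
      t <- counts[counts$condition == cond & counts$replicate == r, ,
                  drop = FALSE]
      finish_count_table(t, cond, r)
    }
    nsel <- tab("nonselect"); sel <- tab("select")
    wt_ns <- tab("wt_nonselect"); wt_s <- tab("wt_select")
    # empty WT tables are legitimate when sequencing is error-free: the
    # percentile threshold is then zero and no background is subtracted
    f_ns <- if (nrow(wt_ns)) {
      filter_counts(nsel, wt_ns, config$min_count, config$min_cpm,
                    config$wt_percentile)
    } else nsel
    f_s <- if (nrow(wt_s)) {
      filter_counts(sel, wt_s, config$min_count, config$min_cpm,
                    config$wt_percentile)
    } else sel
    if (nrow(wt_ns) == 0L) {
      f_ns <- f_ns[f_ns$count >= config$min_count, , drop = FALSE]
    }
    if (nrow(wt_s) == 0L) {
      f_s <- f_s[f_s$count >= config$min_count, , drop = FALSE]
    }
    # a variant must survive filtering in BOTH conditions
    keep <- intersect(f_ns$key, f_s$key)
    f_ns <- f_ns[f_ns$key %in% keep, , drop = FALSE]
    f_s <- f_s[f_s$key %in% keep, , drop = FALSE]

    enr <- adjust_and_enrich(f_s, f_ns, wt_s, wt_ns, config$pseudo_n)
    scales <- compute_scales(enr, protein_length, config$c_term_exclusion,
                             region_bounds)
    scored <- functional_score(enr, scales, region_bounds)
    scales_log[[as.character(r)]] <- scales
    rep_scores[[as.character(r)]] <-
      data.frame(key = scored$key, replicate = r, fs = scored$fs,
                 f_ns = scored$f_ns, stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rep_scores)
  est <- estimate_error(long, m = config$m_prior, trend_k = config$trend_k)
  est <- quality_filter(est, config$max_sigma, config$min_f_ns)
  pk <- parse_key(est$key)
  est$pos <- pk$pos
  est$ref_aa <- pk$ref_aa
  est$alt_aa <- pk$alt_aa
  est$class <- pk$class
  est$region <- region_of(est$pos, region_bounds)
  attr(est, "scales") <- scales_log
  attr(est, "config") <- config
  est[order(est$pos, est$alt_aa), ]
}

#' Simulate and score a two-isoform experiment
#'
#' Runs [run_tile_experiment()] and [score_tile_experiment()] twice against
#' the same ground truth (independent library draws, selections and
#' sequencing — emulating maps of two protein isoforms sharing a common
#' region), rescales the first map onto the second and combines them by
#' inverse-variance weighting.
#'
#' @inheritParams run_tile_experiment
#' @param config a [score_config()].
#' @return list with `map_1`, `map_2` (per-isoform score tables, `map_1`
#'   rescaled), `combined` (from [combine_maps()]).
#' @export
run_two_isoform_experiment <- function(truth, lib, seqm, sel, n_rep = 2,
                                       seed = 1, config = score_config()) {
  maps <- lapply(1:2, function(i) {
    ex <- run_tile_experiment(truth, lib, seqm, sel, n_rep,
                              child_seed(seed, 7000 + i),
                              config$posterior_threshold)
    score_tile_experiment(ex$counts, truth$protein_length, ex$region_bounds,
                          config)
  })
  m1 <- rescale_isoform(maps[[1L]], maps[[2L]])
  list(map_1 = m1, map_2 = maps[[2L]],
       combined = combine_maps(m1, maps[[2L]]))
}
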