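# Enrichment-ratio scoring: count filters, WT-control subtraction, enrichment
# ratio phi, rescaled functional impact scores anchored on the nonsense and
# synonymous medians, regularized errors, isoform rescaling/combination and
# the hyper-complementation preference transforms.

#' Scoring configuration
#'
#' Collects every tunable threshold of the scoring pipeline in one versioned
#' object.
#'
#' @param min_count minimum raw read count in each of the selective and
#'   non-selective libraries (default 10).
#' @param min_cpm alternative reading of the count filter as counts per
#'   million sequenced; `NULL` (default) disables it and the raw-count rule
#'   is used.
#' @param wt_percentile percentile (0-100) of the WT-control frequency
#'   distribution below which variant frequencies are filtered (default 90).
#' @param pseudo_n pseudo-count (reads) used to floor non-positive adjusted
#'   selective frequencies (default 0.5).
#' @param c_term_exclusion nonsense variants within this many residues of the
#'   C terminus are excluded from the nonsense median (default 14).
#' @param max_sigma scores with regularized standard error strictly above
#'   this fail quality filtering (default 0.3).
#' @param min_f_ns scores with non-selective frequency strictly below this
#'   fail quality filtering (default 5e-5, i.e. 0.005%).
#' @param posterior_threshold duplex calling threshold (default 0.9).
#' @param m_prior pseudo-replicate weight of the frequency-conditional error
#'   trend (default 2).
#' @param trend_k window width (odd) of the running-median error trend
#'   (default 51).
#' @return a named list of class `score_config`.
#' @export
score_config <- function(min_count = 10, min_cpm = NULL, wt_percentile = 90,
                         pseudo_n = 0.5, c_term_exclusion = 14,
                         max_sigma = 0.3, min_f_ns = 5e-5,
                         posterior_threshold = 0.9, m_prior = 2,
                         trend_k = 51) {
  structure(list(version = "1", min_count = min_count, min_cpm = min_cpm,
                 wt_percentile = wt_percentile, pseudo_n = pseudo_n,
                 c_term_exclusion = c_term_exclusion, max_sigma = max_sigma,
                 min_f_ns = min_f_ns,
                 posterior_threshold = posterior_threshold,
                 m_prior = m_prior, trend_k = trend_k),
            class = "score_config")
}

#' Filter a count table against raw-count and WT-control thresholds
#'
#' Removes variants whose raw count falls below `min_count` (or, when
#' `min_cpm` is set, below `min_cpm` counts per million of tile depth) and
#' variants whose frequency falls strictly below the `wt_percentile`-th
#' percentile of the variant frequencies observed in the matched WT-control
#' library. When all WT-control frequencies are zero the percentile is zero
#' and the WT rule removes nothing.
#'
#' @param table a `count_table` for one condition/replicate.
#' @param wt_table the WT-control `count_table` from the same condition.
#' @param min_count,min_cpm,wt_percentile see [score_config()].
#' @return the filtered table; removed variants and their reasons are kept in
#'   the `"filter_log"` attribute.
#' @export
filter_counts <- function(table, wt_table, min_count = 10, min_cpm = NULL,
                          wt_percentile = 90) {
  if (is.null(wt_table) || nrow(wt_table) == 0L) {
    stop("calibration error: WT-control table is empty, percentile undefined")
  }
  wt_thresh <- unname(quantile(wt_table$frequency, wt_percentile / 100,
                               names = FALSE, type = 7))
  fail_count <- if (is.null(min_cpm)) {
    table$count < min_count
  } else {
    table$count / table$depth * 1e6 < min_cpm
  }
  fail_wt <- table$frequency < wt_thresh
  keep <- !(fail_count | fail_wt)
  log <- data.frame(key = table$key[!keep],
                    reason = ifelse(fail_count[!keep] & fail_wt[!keep],
                                    "count+wt_percentile",
                                    ifelse(fail_count[!keep], "count",
                                           "wt_percentile")),
                    stringsAsFactors = FALSE)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- log
  attr(out, "wt_threshold") <- wt_thresh
  attr(out, "condition") <- attr(table, "condition")
  attr(out, "replicate") <- attr(table, "replicate")
  class(out) <- class(table)
  out
}

#' WT-subtracted enrichment ratios
#'
#' Subtracts matched WT-control frequencies from the variant frequencies in
#' both conditions, then forms the enrichment ratio
#' `phi = f_s_adj / f_ns_adj`. A non-positive adjusted selective frequency is
#' floored at a pseudo-frequency of `pseudo_n` reads over the covering-tile
#' depth (the variant is then strongly null-like but scoreable); a
#' non-positive adjusted non-selective frequency makes the record unusable.
#' Variants absent from the non-selective table are unusable and logged.
#'
#' @param select,nonselect filtered `count_table`s for the selective and
#'   non-selective conditions.
#' @param wt_select,wt_nonselect matched WT-control tables (may have zero
#'   overlap; missing WT frequencies are treated as 0).
#' @param pseudo_n pseudo-count for the selective-side floor (default 0.5).
#' @return data.frame of class `enrichment_table`: `key`, `pos`, `ref_aa`,
#'   `alt_aa`, `class`, `tile`, `f_ns`, `f_s`, `f_wt_ns`, `f_wt_s`,
#'   `f_ns_adj`, `f_s_adj`, `phi`, `usable`.
#' @export
adjust_and_enrich <- function(select, nonselect, wt_select, wt_nonselect,
                              pseudo_n = 0.5) {
  ns <- data.table::as.data.table(nonselect)[
    , .(key, pos, ref_aa, alt_aa, class, tile, f_ns = frequency,
        count_ns = count, depth_ns = depth)]
  s <- data.table::as.data.table(select)[
    , .(key, f_s = frequency, count_s = count, depth_s = depth,
        tile_s = tile)]
  m <- merge(ns, s, by = "key", all = TRUE)

  # records only present in the selective table lack a non-selective
  # frequency: unusable, but keep them for the log
  orphan <- is.na(m$f_ns)
  if (any(orphan)) {
    pk <- parse_key(m$key[orphan])
    m$pos[orphan] <- pk$pos
    m$ref_aa[orphan] <- pk$ref_aa
    m$alt_aa[orphan] <- pk$alt_aa
    m$class[orphan] <- pk$class
    m$tile[orphan] <- m$tile_s[orphan]
  }
  wt_freq <- function(wt) {
    if (is.null(wt) || nrow(wt) == 0L) {
      return(data.table::as.data.table(list(key = character(), fwt = numeric())))
    }
    data.table::as.data.table(wt)[, .(key, fwt = frequency)]
  }
  m <- merge(m, wt_freq(wt_nonselect)[, .(key, f_wt_ns = fwt)],
             by = "key", all.x = TRUE)
  m <- merge(m, wt_freq(wt_select)[, .(key, f_wt_s = fwt)],
             by = "key", all.x = TRUE)
  m[is.na(f_wt_ns), f_wt_ns := 0]
  m[is.na(f_wt_s), f_wt_s := 0]
  m[is.na(f_s), f_s := 0]
  # depth of the covering tile in the selective run, for the floor
  if (any(is.na(m$depth_s))) {
    ds <- stats::na.omit(unique(
      data.table::data.table(tile = m$tile_s %||% m$tile, d = m$depth_s)))
    med_ds <- if (nrow(ds)) stats::median(ds$d) else stats::median(m$depth_ns, na.rm = TRUE)
    m[is.na(depth_s), depth_s := med_ds]
  }

  m[, f_ns_adj := f_ns - f_wt_ns]
  m[, f_s_adj := f_s - f_wt_s]
  m[, floored := f_s_adj <= 0]
  m[floored == TRUE, f_s_adj := pseudo_n / depth_s]
  m[, usable := !is.na(f_ns) & f_ns_adj > 0]
  m[, phi := ifelse(usable, f_s_adj / f_ns_adj, NA_real_)]

  out <- as.data.frame(m[, .(key, pos, ref_aa, alt_aa, class, tile,
                             f_ns, f_s, f_wt_ns, f_wt_s,
                             f_ns_adj, f_s_adj, phi, usable, floored)])
  class(out) <- c("enrichment_table", "data.frame")
  out
}

region_of <- function(pos, region_bounds) {
  r <- rep(NA_integer_, length(pos))
  for (i in seq_along(region_bounds)) {
    b <- region_bounds[[i]]
    r[pos >= b[1] & pos <= b[2]] <- i
  }
  r
}

#' Nonsense and synonymous enrichment medians per region
#'
#' `phi_stop` is the median enrichment ratio of usable nonsense variants —
#' excluding those within `c_term_exclusion` residues of the C terminus,
#' where truncation is unlikely to matter — and `phi_syn` the median over
#' usable synonymous variants, computed separately per mutagenesis region.
#'
#' @param records an `enrichment_table`.
#' @param protein_length protein length in residues.
#' @param c_term_exclusion C-terminal exclusion for the nonsense median
#'   (default 14).
#' @param region_bounds list of residue intervals; default one region
#'   spanning the protein.
#' @return data.frame with `region`, `phi_stop`, `phi_syn`, `n_stop`,
#'   `n_syn`.
#' @export
compute_scales <- function(records, protein_length, c_term_exclusion = 14,
                           region_bounds = NULL) {
  region_bounds <- region_bounds %||% list(c(1L, protein_length))
  rec <- records[records$usable & !is.na(records$phi), , drop = FALSE]
  rec$region <- region_of(rec$pos, region_bounds)
  out <- lapply(seq_along(region_bounds), function(r) {
    rr <- rec[rec$region == r, , drop = FALSE]
    stop_phi <- rr$phi[rr$class == "nonsense" &
                         rr$pos <= protein_length - c_term_exclusion]
    syn_phi <- rr$phi[rr$class == "synonymous"]
    if (length(stop_phi) < 3L || length(syn_phi) < 3L) {
      stop("need at least 3 usable nonsense and synonymous records in ",
           "region ", r)
    }
    data.frame(region = r, phi_stop = median(stop_phi),
               phi_syn = median(syn_phi),
               n_stop = length(stop_phi), n_syn = length(syn_phi))
  })
  out <- do.call(rbind, out)
  bad <- out$phi_syn <= out$phi_stop
  if (any(bad)) {
    stop("calibration failure: synonymous median does not exceed nonsense ",
         "median in region ", paste(out$region[bad], collapse = ", "))
  }
  out
}

#' Functional impact scores from enrichment ratios
#'
#' Rescales each usable enrichment ratio onto the scale where the nonsense
#' median maps to 0 and the synonymous median maps to 1:
#' \deqn{FS = \ln(\Phi/\Phi_{STOP}) / \ln(\Phi_{SYN}/\Phi_{STOP})}
#' computed with the scales of the variant's own mutagenesis region. Values
#' above 1 (hyper-complementation) and below 0 are permitted.
#'
#' @param records an `enrichment_table`.
#' @param scales output of [compute_scales()].
#' @param region_bounds the same region intervals used for `scales`.
#' @return `records` with columns `region` and `fs` added (`fs` is `NA` for
#'   unusable records).
#' @export
functional_score <- function(records, scales, region_bounds = NULL) {
  region_bounds <- region_bounds %||%
    list(c(1L, max(records$pos, na.rm = TRUE)))
  records$region <- region_of(records$pos, region_bounds)
  i <- match(records$region, scales$region)
  phi_stop <- scales$phi_stop[i]
  phi_syn <- scales$phi_syn[i]
  records$fs <- ifelse(records$usable & records$phi > 0,
                       log(records$phi / phi_stop) /
                         log(phi_syn / phi_stop),
                       NA_real_)
  records
}

#' Regularized per-variant error estimates
#'
#' The empirical replicate standard deviation of each variant's score is
#' shrunk toward a frequency-conditional expected deviation: variants are
#' ordered by log non-selective frequency and a running median of replicate
#' SDs (unbiased to the SD scale by `1/qnorm(0.75)`) provides the trend.
#' Shrinkage blends on the variance scale with `m` prior pseudo-replicates:
#' \deqn{\sigma^2_{shrunk} = \frac{m t^2 + n_{rep} s^2}{m + n_{rep}}}
#' and the reported `sigma` is the shrunk standard error of the replicate
#' mean, `sqrt(sigma2_shrunk / n_rep)`. With `m = 0` the estimate is the
#' ordinary empirical standard error. Variants measured in a single
#' replicate take their error from the trend alone and are flagged.
#'
#' @param rep_scores data.frame with columns `key`, `replicate`, `fs`,
#'   `f_ns` (one row per variant per replicate; `fs` may be `NA`).
#' @param m prior pseudo-replicate weight (default 2).
#' @param trend_k running-median window, odd (default 51).
#' @return data.frame: `key`, `fs` (replicate mean), `sigma`, `n_rep`,
#'   `f_ns` (mean), `sd_emp`, `sd_trend`, `single_rep`.
#' @export
estimate_error <- function(rep_scores, m = 2, trend_k = 51) {
  dt <- data.table::as.data.table(rep_scores)
  agg <- dt[, .(fs = mean(fs, na.rm = TRUE),
                n_rep = sum(!is.na(fs)),
                sd_emp = sd(fs, na.rm = TRUE),
                f_ns = mean(f_ns, na.rm = TRUE)), by = key]
  agg <- agg[n_rep > 0L]
  agg[is.na(sd_emp), sd_emp := 0]

  multi <- agg[n_rep >= 2L][order(log(f_ns))]
  if (nrow(multi) == 0L) {
    warning("no variant measured in >= 2 replicates; errors from trend only")
    agg[, sd_trend := NA_real_]
    agg[, sigma := NA_real_]
    agg[, single_rep := TRUE]
    return(as.data.frame(agg))
  }
  k <- min(trend_k, nrow(multi))
  if (k %% 2 == 0L) k <- k - 1L
  trend <- if (k >= 3L) {
    runmed(multi$sd_emp, k, endrule = "median") / qnorm(0.75)
  } else {
    rep(median(multi$sd_emp) / qnorm(0.75), nrow(multi))
  }
  multi[, sd_trend := trend]

  # interpolate the trend for everything (incl. single-replicate variants)
  if (nrow(multi) >= 2L) {
    f <- approx(log(multi$f_ns), multi$sd_trend, xout = log(agg$f_ns),
                rule = 2, ties = mean)$y
  } else {
    f <- rep(multi$sd_trend[1L], nrow(agg))
  }
  agg[, sd_trend := f]
  agg[, single_rep := n_rep < 2L]
  agg[, sigma := ifelse(single_rep,
                        sd_trend,
                        sqrt((m * sd_trend^2 + n_rep * sd_emp^2) /
                               (m + n_rep) / n_rep))]
  as.data.frame(agg)
}

#' Quality-filter scored variants
#'
#' Applies the two map-level quality rules: regularized standard error
#' strictly above `max_sigma` fails, and mean non-selective frequency
#' strictly below `min_f_ns` fails. Equality passes in both cases. Rows are
#' flagged, not deleted, so downstream analyses can audit exclusions.
#'
#' @param scores data.frame with `sigma` and `f_ns` columns (e.g. from
#'   [estimate_error()]).
#' @param max_sigma default 0.3.
#' @param min_f_ns default 5e-5 (0.005%).
#' @return `scores` with logical columns `pass_sigma`, `pass_f_ns`,
#'   `passed_filters`.
#' @export
quality_filter <- function(scores, max_sigma = 0.3, min_f_ns = 5e-5) {
  scores$pass_sigma <- !(scores$sigma > max_sigma) & !is.na(scores$sigma)
  scores$pass_f_ns <- !(scores$f_ns < min_f_ns) & !is.na(scores$f_ns)
  scores$passed_filters <- scores$pass_sigma & scores$pass_f_ns
  scores
}

#' Rescale one isoform map onto another
#'
#' Fits the affine transform `a * fs + b` minimizing the mean squared
#' distance between the two maps over shared well-measured variants
#' (ordinary least squares of map-b scores on map-a scores) and applies it to
#' every map-a score. Being monotone (for `a > 0`), the transform leaves
#' rank correlations between the maps unchanged. Errors are scaled by `|a|`.
#'
#' @param map_a,map_b score data.frames with `key`, `fs`, `sigma`,
#'   `passed_filters` columns; `map_a` is rescaled onto `map_b`'s scale.
#' @param min_shared minimum number of shared passing variants (default 50).
#' @return `map_a` with transformed `fs` (and `sigma`); the fitted
#'   coefficients are in the `"rescale_coef"` attribute.
#' @export
rescale_isoform <- function(map_a, map_b, min_shared = 50) {
  shared <- merge(map_a[map_a$passed_filters, c("key", "fs")],
                  map_b[map_b$passed_filters, c("key", "fs")],
                  by = "key", suffixes = c("_a", "_b"))
  if (nrow(shared) < min_shared) {
    stop("only ", nrow(shared), " shared well-measured variants (need >= ",
         min_shared, ")")
  }
  if (stats::var(shared$fs_a) < 1e-12) {
    stop("degenerate shared score set: zero variance")
  }
  fit <- lm(fs_b ~ fs_a, data = shared)
  a <- unname(coef(fit)[2L]); b <- unname(coef(fit)[1L])
  map_a$fs <- a * map_a$fs + b
  if ("sigma" %in% names(map_a)) map_a$sigma <- abs(a) * map_a$sigma
  attr(map_a, "rescale_coef") <- c(slope = a, intercept = b)
  map_a
}

#' Combine two isoform maps into one
#'
#' Where a variant passes quality filtering in both maps, the combined score
#' is the inverse-variance weighted mean
#' \deqn{FS_c = (FS_1/\sigma_1^2 + FS_2/\sigma_2^2) /
#'       (1/\sigma_1^2 + 1/\sigma_2^2)}
#' with combined variance `1 / (1/sigma_1^2 + 1/sigma_2^2)` (the standard
#' inverse-variance form). Where only one map has a passing score it is
#' passed through. The delta score is `fs_1 - fs_2` (first minus second map,
#' e.g. erythroid minus ubiquitous) where both are present.
#'
#' @param map_1,map_2 score data.frames with `key`, `fs`, `sigma`,
#'   `passed_filters` (rows failing filters are ignored).
#' @return data.frame: `key`, `fs_combined`, `sigma_combined`, `delta`,
#'   `sources` (`"both"`, `"map1"` or `"map2"`).
#' @export
combine_maps <- function(map_1, map_2) {
  m1 <- map_1[map_1$passed_filters, c("key", "fs", "sigma")]
  m2 <- map_2[map_2$passed_filters, c("key", "fs", "sigma")]
  if (any(c(m1$sigma, m2$sigma) <= 0, na.rm = TRUE)) {
    stop("sigma must be positive")
  }
  m <- merge(m1, m2, by = "key", all = TRUE, suffixes = c("_1", "_2"))
  w1 <- 1 / m$sigma_1^2
  w2 <- 1 / m$sigma_2^2
  both <- !is.na(m$fs_1) & !is.na(m$fs_2)
  fs <- ifelse(both, (m$fs_1 * w1 + m$fs_2 * w2) / (w1 + w2),
               ifelse(is.na(m$fs_1), m$fs_2, m$fs_1))
  sg <- ifelse(both, sqrt(1 / (w1 + w2)),
               ifelse(is.na(m$fs_1), m$sigma_2, m$sigma_1))
  data.frame(key = m$key, fs_combined = fs, sigma_combined = sg,
             delta = ifelse(both, m$fs_1 - m$fs_2, NA_real_),
             sources = ifelse(both, "both",
                              ifelse(is.na(m$fs_1), "map2", "map1")),
             stringsAsFactors = FALSE)
}

#' Amino-acid preference transforms for hyper-complementation models
#'
#' Converts a matrix of WT-normalized variant scores (rows = positions,
#' columns = residues; the wild-type residue scores 1 at each position) into
#' per-position amino-acid preferences under three hypotheses about
#' above-WT ("hyper-complementing") scores:
#' * `advantageous` — scores are used as-is;
#' * `neutral` — scores above 1 are capped at 1;
#' * `damaging` — scores above 1 are inverted to their reciprocal.
#' Each row is then normalized to sum to 1. Scores at or below 0 are clipped
#' to 1e-6 before normalization so preferences remain defined.
#'
#' @param score_matrix numeric matrix, positions x residues.
#' @return named list of three preference matrices (`advantageous`,
#'   `neutral`, `damaging`), each row summing to 1. Rows containing `NA`
#'   propagate `NA` and are flagged with a warning.
#' @export
preference_transforms <- function(score_matrix) {
  s <- as.matrix(score_matrix)
  if (any(!is.finite(s) & !is.na(s))) stop("scores must be finite or NA")
  if (any(is.na(s))) warning("rows with missing scores yield NA preferences")
  s[!is.na(s) & s <= 0] <- 1e-6
  norm_rows <- function(x) x / rowSums(x)
  list(
    advantageous = norm_rows(s),
    neutral = norm_rows(pmin(s, 1)),
    damaging = norm_rows(ifelse(!is.na(s) & s > 1, 1 / s, s))
  )
}
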