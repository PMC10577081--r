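# Map-performance evaluation: ROC/AUROC with DeLong comparison, balanced
# precision-recall with R90BP, distribution comparison, positional profiles
# and allele-frequency depletion. Orientation convention throughout: LOWER
# functional score = more damaging = positive (pathogenic) class.

check_labels <- function(label) {
  label <- as.character(label)
  if (!all(label %in% c("positive", "negative"))) {
    stop('labels must be "positive" or "negative"')
  }
  if (!any(label == "positive") || !any(label == "negative")) {
    stop("both classes must be nonempty")
  }
  label
}

#' Empirical ROC curve and AUROC
#'
#' Standard empirical ROC over all score thresholds. With the default
#' orientation, a variant is predicted positive when its score is at or
#' below the threshold. The AUROC is computed by the rank (Mann-Whitney)
#' formula, which equals the trapezoidal area under the empirical curve with
#' ties averaged.
#'
#' @param score numeric scores.
#' @param label `"positive"` / `"negative"` per score.
#' @param orientation `"lower_positive"` (default) or `"higher_positive"`.
#' @return list with `curve` (data.frame: threshold, fpr, tpr), `auroc`,
#'   `n_pos`, `n_neg`.
#' @export
roc_and_auroc <- function(score, label, orientation = "lower_positive") {
  label <- check_labels(label)
  pred <- if (orientation == "lower_positive") -score else score
  pos <- label == "positive"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  r <- rank(pred)
  auroc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  o <- order(pred, decreasing = TRUE)
  tp <- cumsum(pos[o]); fp <- cumsum(!pos[o])
  # one operating point per distinct predictor value
  last <- !duplicated(pred[o], fromLast = TRUE)
  curve <- data.frame(threshold = score[o][last],
                      fpr = fp[last] / n_neg, tpr = tp[last] / n_pos)
  list(curve = rbind(data.frame(threshold = NA_real_, fpr = 0, tpr = 0),
                     curve),
       auroc = auroc, n_pos = n_pos, n_neg = n_neg)
}

#' Paired AUROC comparison with the DeLong variance estimator
#'
#' Compares the AUROCs of two score sets over the same labeled variants.
#' The DeLong test itself is delegated to \pkg{pROC}.
#'
#' @param score_a,score_b paired scores.
#' @param label class labels shared by both.
#' @param orientation see [roc_and_auroc()].
#' @return list with `auroc_a`, `auroc_b`, `p`.
#' @export
compare_auroc <- function(score_a, score_b, label,
                          orientation = "lower_positive") {
  label <- check_labels(label)
  dir <- if (orientation == "lower_positive") ">" else "<"
  ra <- pROC::roc(response = label, predictor = score_a,
                  levels = c("negative", "positive"), direction = dir,
                  quiet = TRUE)
  rb <- pROC::roc(response = label, predictor = score_b,
                  levels = c("negative", "positive"), direction = dir,
                  quiet = TRUE)
  tt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  list(auroc_a = as.numeric(pROC::auc(ra)),
       auroc_b = as.numeric(pROC::auc(rb)),
       p = tt$p.value)
}

#' Balanced precision-recall curve, AUBPRC and R90BP
#'
#' At each threshold the balanced precision is `TPR / (TPR + FPR)` — the
#' precision that would be observed under equal class priors — so the curve
#' does not depend on the (often unrepresentative) class balance of the
#' reference sets. When the classes are balanced it equals the ordinary
#' empirical precision at every threshold. R90BP is the maximum recall over
#' thresholds at which balanced precision is at least `min_bp` (default
#' 90%); if no threshold qualifies, R90BP is 0 with a warning. The area
#' under the curve (AUBPRC) integrates step-wise over recall (no linear
#' interpolation between operating points): each recall increment
#' contributes its own balanced precision.
#'
#' @param score numeric scores.
#' @param label `"positive"` / `"negative"`.
#' @param orientation `"lower_positive"` (default): predicted positive when
#'   score <= threshold.
#' @param min_bp balanced-precision level defining the recall summary
#'   (default 0.9).
#' @return list with `curve` (data.frame: threshold, recall,
#'   balanced_precision, precision), `aubprc`, `r90bp`,
#'   `threshold_at_r90bp`, `n_pos`, `n_neg`.
#' @export
balanced_pr <- function(score, label, orientation = "lower_positive",
                        min_bp = 0.9) {
  label <- check_labels(label)
  pred <- if (orientation == "lower_positive") -score else score
  o <- order(pred, decreasing = TRUE)
  pos <- (label == "positive")[o]
  n_pos <- sum(pos); n_neg <- sum(!pos)
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- !duplicated(pred[o], fromLast = TRUE)
  tpr <- tp[last] / n_pos
  fpr <- fp[last] / n_neg
  prec <- tp[last] / (tp[last] + fp[last])
  bp <- ifelse(tpr + fpr == 0, NA_real_, tpr / (tpr + fpr))
  curve <- data.frame(threshold = score[o][last], recall = tpr,
                      balanced_precision = bp, precision = prec)
  ok <- which(!is.na(bp) & bp >= min_bp)
  if (length(ok)) {
    r90bp <- max(tpr[ok])
    thr <- curve$threshold[ok[which.max(tpr[ok])]]
  } else {
    warning("no threshold reaches balanced precision ", min_bp)
    r90bp <- 0
    thr <- NA_real_
  }
  dr <- diff(c(0, curve$recall))
  aubprc <- sum(dr * ifelse(is.na(curve$balanced_precision), 0,
                            curve$balanced_precision))
  list(curve = curve, aubprc = aubprc, r90bp = r90bp,
       threshold_at_r90bp = thr, n_pos = n_pos, n_neg = n_neg)
}

#' Summary of map performance against a reference set
#'
#' @inheritParams balanced_pr
#' @return list of class `perf_summary`: `auroc`, `aubprc`, `r90bp`,
#'   `threshold_at_r90bp`, `n_pos`, `n_neg`.
#' @export
perf_summary <- function(score, label, orientation = "lower_positive",
                         min_bp = 0.9) {
  roc <- roc_and_auroc(score, label, orientation)
  bpr <- balanced_pr(score, label, orientation, min_bp)
  structure(list(auroc = roc$auroc, aubprc = bpr$aubprc, r90bp = bpr$r90bp,
                 threshold_at_r90bp = bpr$threshold_at_r90bp,
                 n_pos = roc$n_pos, n_neg = roc$n_neg),
            class = "perf_summary")
}

#' @export
print.perf_summary <- function(x, ...) {
  cat(sprintf(
    "Map performance (%d positive / %d negative):\n", x$n_pos, x$n_neg))
  cat(sprintf("  AUROC  %.3f\n  AUBPRC %.3f\n  R90BP  %.3f\n",
              x$auroc, x$aubprc, x$r90bp))
  invisible(x)
}

#' Compare two score distributions
#'
#' Two-sided Mann-Whitney U test with tie correction. The reported delta
#' median is `median(set_b) - median(set_a)`: when `set_a` holds the
#' pathogenic/positive scores and `set_b` the benign/negative scores, a
#' positive delta means benign variants score higher.
#'
#' @param set_a,set_b numeric score vectors.
#' @return list with `delta_median`, `U` (number of (a, b) pairs with
#'   a > b, plus half the ties), `p`.
#' @export
compare_distributions <- function(set_a, set_b) {
  if (!length(set_a) || !length(set_b)) stop("score sets must be nonempty")
  wt <- suppressWarnings(wilcox.test(set_a, set_b))
  list(delta_median = median(set_b) - median(set_a),
       U = unname(wt$statistic), p = wt$p.value)
}

#' Moving-window positional profile
#'
#' Centered running mean of a per-position quantity over an odd window of
#' residues, truncated at the termini; positions absent from the input are
#' skipped from the mean.
#'
#' @param values named numeric vector (names = residue positions) or
#'   data.frame with `pos` and `value` columns.
#' @param window odd positive window width in residues (default 5).
#' @return data.frame with `position`, `windowed_value`, `window`.
#' @export
moving_window_profile <- function(values, window = 5) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (is.data.frame(values)) {
    pos <- values$pos
    val <- values$value
  } else {
    pos <- as.integer(names(values))
    val <- as.numeric(values)
  }
  if (!length(val)) {
    return(data.frame(position = integer(), windowed_value = numeric(),
                      window = integer()))
  }
  h <- (window - 1) / 2
  out <- vapply(pos, function(p) {
    mean(val[pos >= p - h & pos <= p + h], na.rm = TRUE)
  }, 0)
  data.frame(position = pos, windowed_value = out, window = window)
}

#' Classify residue positions by solvent accessibility and interface burial
#'
#' Relative accessible surface area below 20% is buried, above 40% exposed,
#' otherwise intermediate. Independently, a residue is interfacial when its
#' accessible surface area changes by strictly more than `interface_dasa`
#' (default 1 Å²) between the complexed and single-chain structures; when
#' the change is missing, the interface flag is `NA`, not `FALSE`.
#'
#' @param asa named numeric vector of relative surface area percentages.
#' @param delta_asa optional named vector of ASA changes (Å²).
#' @param buried_max,exposed_min class boundaries in percent (20 and 40).
#' @param interface_dasa interface threshold (strict `>`).
#' @return data.frame with `position`, `asa`, `asa_class`, `interface`.
#' @export
classify_positions <- function(asa, delta_asa = NULL, buried_max = 20,
                               exposed_min = 40, interface_dasa = 1) {
  stopifnot(all(asa >= 0, na.rm = TRUE))
  position <- as.integer(names(asa))
  asa_class <- ifelse(asa < buried_max, "buried",
                      ifelse(asa > exposed_min, "exposed", "intermediate"))
  interface <- rep(NA, length(asa))
  if (!is.null(delta_asa)) {
    stopifnot(all(delta_asa >= 0, na.rm = TRUE))
    i <- match(position, as.integer(names(delta_asa)))
    interface <- delta_asa[i] > interface_dasa
  }
  data.frame(position = position, asa = unname(asa),
             asa_class = asa_class, interface = unname(interface))
}

#' Unity-based normalization of predictor scores
#'
#' Rescales computational predictor scores onto `[0, 1]` with orientation
#' flipped: `1 - (s - min(s)) / (max(s) - min(s))`, so the minimum input
#' maps to 1 (neutral-like) and the maximum to 0 (null-like).
#'
#' @param scores numeric vector with at least two distinct values.
#' @return normalized scores in `[0, 1]`.
#' @export
normalize_predictor <- function(scores) {
  rng <- range(scores, na.rm = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    stop("normalization undefined for constant input")
  }
  1 - (scores - rng[1]) / (rng[2] - rng[1])
}

#' Allele-depletion odds ratio
#'
#' Odds ratio of a 2x2 table of map-damaging vs map-neutral variants against
#' observed vs not-observed in population cohorts, with a Haldane correction
#' (0.5 added to every cell) when any cell is zero; the two-sided p value is
#' the exact hypergeometric (Fisher) test on the uncorrected table.
#'
#' @param tab 2x2 matrix of nonnegative integer counts, rows = map class,
#'   columns = cohort observation.
#' @return list with `odds_ratio`, `p`, `table`.
#' @export
allele_depletion_or <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  if (sum(tab) == 0) stop("odds ratio undefined for an all-zero table")
  ct <- if (any(tab == 0)) tab + 0.5 else tab
  or <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
  p <- fisher.test(round(tab))$p.value
  list(odds_ratio = or, p = p, table = tab)
}

#' Flag residue positions excluded from clinical performance analysis
#'
#' Marks positions falling in the configured excluded ranges or singleton
#' positions (defaults: residues 160-215, 255 and 355 — regions where the
#' complementation assay is suspected not to reflect pathogenicity).
#'
#' @param positions integer residue positions.
#' @param ranges list of `c(start, end)` inclusive intervals.
#' @param singles individual positions.
#' @return logical vector, `TRUE` = excluded.
#' @export
flag_excluded_positions <- function(positions,
                                    ranges = list(c(160L, 215L)),
                                    singles = c(255L, 355L)) {
  out <- positions %in% singles
  for (b in ranges) out <- out | (positions >= b[1] & positions <= b[2])
  out
}
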