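# Clinical calibration: reference sets, kernel-density log likelihood ratios
# of pathogenicity (LLRp), and ACMG/AMP evidence-strength thresholds derived
# from the Bayesian points framework.

PATHOGENIC_LABELS <- c("pathogenic", "likely_pathogenic")
BENIGN_LABELS <- c("benign", "likely_benign")

#' Build positive and negative reference variant sets
#'
#' The positive set contains variants labeled pathogenic or likely
#' pathogenic. The negative set contains variants labeled benign or likely
#' benign (variants with conflicting interpretations are excluded), plus
#' "proxy-benign" variants: unannotated rare variants (minor allele
#' frequency < 0.0005) observed homozygous in at least one individual.
#'
#' @param annotated data.frame with columns `variant`, `clinical_label`
#'   (one of `pathogenic`, `likely_pathogenic`, `benign`, `likely_benign`,
#'   `VUS`, `conflicting`, `none`), `maf`, `n_homozygotes` and optionally
#'   `source`.
#' @param proxy_max_maf MAF bound for proxy-benign membership
#'   (default 5e-4, strict `<`).
#' @param proxy_min_hom minimum homozygote count (default 1).
#' @return list with `positive` and `negative` data.frames (the negative set
#'   carries a `proxy_benign` flag) and `log`, a data.frame of excluded
#'   variants with reasons.
#' @export
build_reference_sets <- function(annotated, proxy_max_maf = 5e-4,
                                 proxy_min_hom = 1L) {
  req <- c("variant", "clinical_label", "maf", "n_homozygotes")
  if (!all(req %in% names(annotated))) {
    stop("annotated table must have columns: ", paste(req, collapse = ", "))
  }
  lab <- annotated$clinical_label
  is_pos <- lab %in% PATHOGENIC_LABELS
  is_neg_lab <- lab %in% BENIGN_LABELS
  is_proxy <- lab == "none" &
    !is.na(annotated$maf) & annotated$maf < proxy_max_maf &
    !is.na(annotated$n_homozygotes) & annotated$n_homozygotes >= proxy_min_hom
  if (any(is_pos & (is_neg_lab | is_proxy))) {
    stop("variant qualifies for both reference sets: ",
         paste(annotated$variant[is_pos & (is_neg_lab | is_proxy)],
               collapse = ", "))
  }
  positive <- annotated[is_pos, , drop = FALSE]
  negative <- annotated[is_neg_lab | is_proxy, , drop = FALSE]
  negative$proxy_benign <- is_proxy[is_neg_lab | is_proxy]
  excl <- !(is_pos | is_neg_lab | is_proxy)
  reason <- ifelse(lab == "conflicting", "conflicting_interpretations",
            ifelse(lab == "VUS", "uncertain_significance",
            ifelse(lab == "none" & !is.na(annotated$maf) &
                     annotated$maf >= proxy_max_maf, "maf_too_high",
            ifelse(lab == "none", "no_homozygote_or_missing", "other"))))
  log <- data.frame(variant = annotated$variant[excl],
                    reason = reason[excl], stringsAsFactors = FALSE)
  rownames(positive) <- rownames(negative) <- NULL
  list(positive = positive, negative = negative, log = log)
}

gauss_kde <- function(points, bw) {
  force(points); force(bw)
  function(x) {
    vapply(x, function(xi) mean(dnorm(xi, mean = points, sd = bw)), 0)
  }
}

#' Estimate score densities and the log likelihood ratio of pathogenicity
#'
#' Gaussian kernel density estimates of the score distributions in the
#' positive (pathogenic) and negative (benign) reference sets; the LLRp of a
#' score `s` is `log10` of the ratio of the two densities at `s`. Each
#' density is floored at `floor_frac` of its own maximum before the ratio is
#' taken, keeping the LLR finite in the tails (no boundary reflection is
#' applied: functional scores are not strictly bounded).
#'
#' @param pos_scores,neg_scores numeric score vectors (>= 5 each).
#' @param bandwidth `"silverman"` (default, [stats::bw.nrd0()]), or a single
#'   number, or a length-2 numeric `c(pos, neg)`.
#' @param floor_frac density floor as a fraction of each density's maximum
#'   (default 1e-6).
#' @param min_bw fallback bandwidth when a set has zero variance
#'   (default 1e-3).
#' @return object of class `llr_calibration`: list with `pos_scores`,
#'   `neg_scores`, `bw` (named length-2), `density_pos`, `density_neg`
#'   (functions), `llr` (function of score, vectorized), `floor`.
#' @export
estimate_densities <- function(pos_scores, neg_scores,
                               bandwidth = "silverman",
                               floor_frac = 1e-6, min_bw = 1e-3) {
  pos_scores <- pos_scores[is.finite(pos_scores)]
  neg_scores <- neg_scores[is.finite(neg_scores)]
  if (length(pos_scores) < 5L || length(neg_scores) < 5L) {
    stop("need at least 5 scores in each reference set")
  }
  pick_bw <- function(x, b) {
    if (is.numeric(b)) return(b)
    if (sd(x) < 1e-12) {
      warning("zero-variance score set; falling back to minimum bandwidth")
      return(min_bw)
    }
    max(bw.nrd0(x), min_bw)
  }
  if (is.numeric(bandwidth)) {
    bws <- if (length(bandwidth) == 2L) bandwidth else rep(bandwidth, 2L)
  } else {
    bws <- c(pick_bw(pos_scores, bandwidth), pick_bw(neg_scores, bandwidth))
  }
  dpos <- gauss_kde(pos_scores, bws[1L])
  dneg <- gauss_kde(neg_scores, bws[2L])
  floor_pos <- floor_frac * max(dpos(pos_scores))
  floor_neg <- floor_frac * max(dneg(neg_scores))
  llr <- function(s) {
    log10(pmax(dpos(s), floor_pos) / pmax(dneg(s), floor_neg))
  }
  structure(list(pos_scores = pos_scores, neg_scores = neg_scores,
                 bw = c(pos = bws[1L], neg = bws[2L]),
                 density_pos = dpos, density_neg = dneg,
                 llr = llr, floor = c(pos = floor_pos, neg = floor_neg),
                 floor_frac = floor_frac),
            class = "llr_calibration")
}

#' Tabulate a calibration over a score grid
#'
#' @param calib an `llr_calibration`.
#' @param grid score grid; default 512 points spanning the observed scores
#'   padded by 3 bandwidths.
#' @return data.frame with `score`, `density_pos`, `density_neg`, `llr`.
#' @export
calibration_table <- function(calib, grid = NULL) {
  if (is.null(grid)) {
    rng <- range(c(calib$pos_scores, calib$neg_scores))
    pad <- 3 * max(calib$bw)
    grid <- seq(rng[1] - pad, rng[2] + pad, length.out = 512L)
  }
  data.frame(score = grid,
             density_pos = calib$density_pos(grid),
             density_neg = calib$density_neg(grid),
             llr = calib$llr(grid))
}

#' The ACMG/AMP evidence combining rules as data
#'
#' Each rule is the minimum-strength instantiation of one ACMG/AMP evidence
#' combination, expressed as its total exponent weight in "very strong"
#' units (very strong = 1, strong = 1/2, moderate = 1/4, supporting = 1/8;
#' benign evidence counts negatively). The combination of two strong
#' pathogenic criteria is flagged `exempt`: in the Bayesian points framework
#' at prior 0.1 it is the documented exception whose posterior (0.975) falls
#' in the likely-pathogenic range, so it is excluded from the >99%
#' constraint family.
#'
#' @return data.frame with `rule`, `category` (`P`, `LP`, `LB`, `B`),
#'   `weight`, `exempt`.
#' @export
acmg_rules <- function() {
  data.frame(
    rule = c("PVS+1PS", "PVS+2PM", "PVS+1PM+1PSu", "PVS+2PSu", "2PS",
             "1PS+3PM", "1PS+2PM+2PSu", "1PS+1PM+4PSu",
             "PVS+1PM", "1PS+1PM", "1PS+2PSu", "3PM", "2PM+2PSu",
             "1PM+4PSu",
             "1BSt+1BSu", "2BSu",
             "2BSt"),
    category = c(rep("P", 8L), rep("LP", 6L), rep("LB", 2L), "B"),
    weight = c(1 + 1 / 2, 1 + 2 / 4, 1 + 1 / 4 + 1 / 8, 1 + 2 / 8, 1,
               1 / 2 + 3 / 4, 1 / 2 + 2 / 4 + 2 / 8, 1 / 2 + 1 / 4 + 4 / 8,
               1 + 1 / 4, 1 / 2 + 1 / 4, 1 / 2 + 2 / 8, 3 / 4,
               2 / 4 + 2 / 8, 1 / 4 + 4 / 8,
               1 / 2 + 1 / 8, 2 / 8,
               1),
    exempt = c(rep(FALSE, 4L), TRUE, rep(FALSE, 12L)),
    stringsAsFactors = FALSE
  )
}

acmg_posterior <- function(X, weight, prior) {
  op <- X^weight * prior / (1 - prior)
  op / (1 + op)
}

#' Derive ACMG/AMP evidence-strength LLR thresholds
#'
#' Models the posterior odds of pathogenicity as
#' `prior_odds * X^w`, where `X` is the odds of pathogenicity conferred by
#' one "pathogenic very strong" item and `w` is the summed evidence weight
#' (very strong = 1, strong = 1/2, moderate = 1/4, supporting = 1/8; benign
#' items negative). The solver finds the most conservative (smallest) `X`
#' such that every non-exempt combining rule satisfies its posterior
#' constraint — pathogenic > 99%, likely pathogenic > 90%, likely benign
#' < 10%, benign < 1% — by scanning a log grid and bisecting the feasibility
#' boundary. LLR cut points then descend by a factor of 2 per evidence
#' level, mirrored for benign evidence:
#' `PVSt = log10(X)`, `PSt = PVSt/2`, `PM = PVSt/4`, `PSu = PVSt/8`,
#' `BSu = -PSu`, `BSt = -PSt`.
#'
#' At the default prior of 0.1 the six cuts are 2.54, 1.27, 0.64, 0.32,
#' -0.32, -1.27 (log10 units; X = 350.5).
#'
#' @param prior global prior probability of pathogenicity (default 0.1).
#' @param rules combining-rule table, see [acmg_rules()].
#' @param posterior_bounds named vector of posterior constraints
#'   (default `c(P = 0.99, LP = 0.90, LB = 0.10, B = 0.01)`).
#' @param grid log10 search grid for `X`.
#' @return object of class `evidence_thresholds`: list with `prior`,
#'   `odds_pvst` (X), `llr_cuts` (named: PVSt, PSt, PM, PSu, BSu, BSt),
#'   `rules`, `posterior_bounds`.
#' @export
solve_acmg_thresholds <- function(prior = 0.1, rules = acmg_rules(),
                                  posterior_bounds = c(P = 0.99, LP = 0.90,
                                                       LB = 0.10, B = 0.01),
                                  grid = seq(0, 6, by = 0.01)) {
  stopifnot(prior > 0, prior < 1)
  active <- rules[!rules$exempt, , drop = FALSE]
  feasible <- function(X) {
    post_p <- acmg_posterior(X, active$weight[active$category == "P"], prior)
    post_lp <- acmg_posterior(X, active$weight[active$category == "LP"], prior)
    post_lb <- acmg_posterior(X, -active$weight[active$category == "LB"], prior)
    post_b <- acmg_posterior(X, -active$weight[active$category == "B"], prior)
    all(post_p > posterior_bounds[["P"]]) &&
      all(post_lp > posterior_bounds[["LP"]]) &&
      all(post_lb < posterior_bounds[["LB"]]) &&
      all(post_b < posterior_bounds[["B"]])
  }
  ok <- vapply(10^grid, feasible, TRUE)
  if (!any(ok)) {
    stop("no feasible X in the scanned range [1, 10^", max(grid), "]; ",
         "constraints cannot be satisfied jointly")
  }
  first <- which(ok)[1L]
  if (first == 1L) {
    X <- 10^grid[1L]
  } else {
    lo <- 10^grid[first - 1L]
    hi <- 10^grid[first]
    for (i in 1:100) {
      mid <- sqrt(lo * hi)
      if (feasible(mid)) hi <- mid else lo <- mid
    }
    X <- hi
  }
  pvst <- log10(X)
  cuts <- c(PVSt = pvst, PSt = pvst / 2, PM = pvst / 4, PSu = pvst / 8,
            BSu = -pvst / 8, BSt = -pvst / 2)
  structure(list(prior = prior, odds_pvst = X, llr_cuts = cuts,
                 rules = rules, posterior_bounds = posterior_bounds),
            class = "evidence_thresholds")
}

#' @export
print.evidence_thresholds <- function(x, ...) {
  cat("ACMG/AMP evidence thresholds (prior", x$prior, ")\n")
  cat("  odds of pathogenicity per very-strong item:",
      format(x$odds_pvst, digits = 5), "\n")
  cat("  LLR cuts (log10):\n")
  print(round(x$llr_cuts, 4))
  invisible(x)
}

EVIDENCE_LEVELS <- c("pathogenic_very_strong", "pathogenic_strong",
                     "pathogenic_moderate", "pathogenic_supporting",
                     "indeterminate",
                     "benign_supporting", "benign_strong")

#' Assign ACMG/AMP evidence strength to scores
#'
#' Maps each score through the calibration's LLR function and assigns the
#' strongest pathogenic level whose cut is strictly exceeded, or the
#' strongest benign level whose cut strictly exceeds the LLR; an LLR exactly
#' at a cut receives the weaker category. Scores outside the range of the
#' calibration reference scores are flagged as extrapolated.
#'
#' @param score numeric scores (ignored when `llr` is supplied directly).
#' @param calib an `llr_calibration` (required unless `llr` given).
#' @param thresholds an `evidence_thresholds`.
#' @param llr optionally, precomputed LLR values.
#' @return data.frame with `score`, `llr`, `category` (ordered factor over
#'   the seven levels), `extrapolated`.
#' @export
assign_evidence <- function(score = NULL, calib = NULL, thresholds,
                            llr = NULL) {
  stopifnot(inherits(thresholds, "evidence_thresholds"))
  if (is.null(llr)) {
    stopifnot(inherits(calib, "llr_calibration"))
    llr <- calib$llr(score)
  } else if (is.null(score)) {
    score <- rep(NA_real_, length(llr))
  }
  cuts <- thresholds$llr_cuts
  category <- ifelse(llr > cuts[["PVSt"]], "pathogenic_very_strong",
              ifelse(llr > cuts[["PSt"]], "pathogenic_strong",
              ifelse(llr > cuts[["PM"]], "pathogenic_moderate",
              ifelse(llr > cuts[["PSu"]], "pathogenic_supporting",
              ifelse(llr < cuts[["BSt"]], "benign_strong",
              ifelse(llr < cuts[["BSu"]], "benign_supporting",
                     "indeterminate"))))))
  extrapolated <- if (!is.null(calib)) {
    rng <- range(c(calib$pos_scores, calib$neg_scores))
    !is.na(score) & (score < rng[1] | score > rng[2])
  } else {
    rep(NA, length(llr))
  }
  data.frame(score = score, llr = llr,
             category = factor(category, levels = EVIDENCE_LEVELS,
                               ordered = TRUE),
             extrapolated = extrapolated)
}
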