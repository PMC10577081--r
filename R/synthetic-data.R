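# Synthetic experiment generator: ground-truth fitness maps, codon-randomized
# clone libraries, pooled selection and tiled duplex sequencing. Stands in for
# the wet-lab complementation assay so every downstream stage is testable and
# parameter recovery can be asserted.

#' Generate a ground-truth variant fitness map
#'
#' Enumerates every amino-acid substitution of a random coding sequence —
#' 19 missense changes, one nonsense change and one synonymous codon change
#' per position — and assigns each a true functional score on the scale where
#' 0 is null (nonsense-like) and 1 is wild-type-like. Missense scores are
#' drawn from a two-component Gaussian mixture (a low mode near 0 and a high
#' mode near 1), matching the bimodal score distributions seen in
#' complementation-based variant effect maps. A configurable fraction of
#' missense variants is "hyper-complementing" with true score strictly above
#' 1. Synonymous variants score exactly 1; nonsense variants score exactly 0
#' except within the last `c_term_tolerance` residues, where truncation is
#' treated as tolerated (score 1).
#'
#' Reference codons are sampled from the sense codons excluding ATG and TGG so
#' that every position admits a synonymous alternative codon. Each variant
#' carries one canonical codon change (the most common human codon for the
#' target residue), which fixes the nucleotide-level edits seen by the read
#' simulator.
#'
#' @param protein_length number of residues (>= 30).
#' @param hyper_fraction proportion of missense variants drawn as
#'   hyper-complementing, in `[0, 0.2]`. Default 0.025.
#' @param bimodal_params list with `weights` (two mixture weights summing to
#'   1), `means` and `sds` (length-2 each) for the missense score mixture.
#' @param c_term_tolerance number of C-terminal residues where truncations
#'   are tolerated (default 14).
#' @param seed integer seed; the map is deterministic given the seed.
#' @return object of class `ground_truth_map`: a list with `protein_length`,
#'   `aa_seq`, `cds`, `variants` (data.frame: key, pos, ref_aa, alt_aa,
#'   class, true_score, codon_ref, codon_alt), `nt_changes` (data.table of
#'   per-variant nucleotide edits: key, nt_pos 0-based, alt_base),
#'   `hyper_fraction`, `c_term_tolerance`.
#' @export
generate_ground_truth <- function(protein_length,
                                  hyper_fraction = 0.025,
                                  bimodal_params = list(
                                    weights = c(0.35, 0.65),
                                    means = c(0.05, 1.0),
                                    sds = c(0.15, 0.15)),
                                  c_term_tolerance = 14,
                                  seed = 1) {
  stopifnot(protein_length >= 30,
            hyper_fraction >= 0, hyper_fraction <= 0.2)
  w <- bimodal_params$weights
  if (length(w) != 2L || abs(sum(w) - 1) > 1e-8) {
    stop("invalid mixture weights (must sum to 1)")
  }
  with_seed(seed, {
    gc <- genetic_code()
    pool <- names(gc)[gc != "*" & !names(gc) %in% c("ATG", "TGG")]
    codons <- sample(pool, protein_length, replace = TRUE)
    aa <- unname(gc[codons])

    per_pos <- lapply(seq_len(protein_length), function(p) {
      ref <- aa[p]
      alts <- c(setdiff(AA_ALPHABET, ref), "*", ref)  # missense, nonsense, syn
      data.frame(pos = p, ref_aa = ref, alt_aa = alts,
                 stringsAsFactors = FALSE)
    })
    v <- do.call(rbind, per_pos)
    v$key <- make_key(v$ref_aa, v$pos, v$alt_aa)
    v$class <- variant_class(v$ref_aa, v$alt_aa)

    score <- numeric(nrow(v))
    score[v$class == "synonymous"] <- 1
    ns <- v$class == "nonsense"
    score[ns] <- ifelse(v$pos[ns] > protein_length - c_term_tolerance, 1, 0)
    mis <- which(v$class == "missense")
    hyper <- runif(length(mis)) < hyper_fraction
    comp <- 1L + (runif(length(mis)) < w[2])
    # low mode: Gaussian near 0; high mode: half-normal folded below its
    # mean so that only designated hyper-complementing variants exceed 1
    mix <- ifelse(comp == 1L,
                  rnorm(length(mis), bimodal_params$means[1],
                        bimodal_params$sds[1]),
                  bimodal_params$means[2] -
                    abs(rnorm(length(mis), 0, bimodal_params$sds[2])))
    score[mis] <- ifelse(hyper, 1 + rexp(length(mis), rate = 8), mix)
    v$true_score <- score

    # canonical codon change per variant
    v$codon_ref <- codons[v$pos]
    v$codon_alt <- vapply(seq_len(nrow(v)), function(i) {
      target <- v$alt_aa[i]
      cand <- PREFERRED_CODON[[target]]
      if (cand != v$codon_ref[i]) return(cand)
      setdiff(codons_for(target), v$codon_ref[i])[1L]
    }, "")

    nt <- nt_changes_table(v)
    structure(list(protein_length = protein_length,
                   aa_seq = paste(aa, collapse = ""),
                   cds = paste(codons, collapse = ""),
                   variants = v,
                   nt_changes = nt,
                   hyper_fraction = hyper_fraction,
                   c_term_tolerance = c_term_tolerance,
                   seed = seed),
              class = "ground_truth_map")
  })
}

# Long table of nucleotide edits implied by each variant's codon change.
nt_changes_table <- function(variants) {
  rows <- lapply(0:2, function(off) {
    r <- substr(variants$codon_ref, off + 1L, off + 1L)
    a <- substr(variants$codon_alt, off + 1L, off + 1L)
    keep <- r != a
    data.table::as.data.table(list(
      key = variants$key[keep],
      nt_pos = (variants$pos[keep] - 1L) * 3L + off,
      alt_base = a[keep]))
  })
  out <- data.table::rbindlist(rows)
  data.table::setkeyv(out, "key")
  out
}

#' @export
print.ground_truth_map <- function(x, ...) {
  cat("Ground-truth variant fitness map\n")
  cat("  protein length:", x$protein_length, "residues;",
      nrow(x$variants), "variants\n")
  tb <- table(x$variants$class)
  cat("  classes:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  nh <- sum(x$variants$true_score > 1 & x$variants$class == "missense")
  cat("  hyper-complementing missense:", nh, "\n")
  invisible(x)
}

#' Describe a mutagenized clone library
#'
#' @param mean_variants_per_clone mean amino-acid changes per clone (Poisson
#'   mean). Default 1.7, the typical load of oligo-directed codon
#'   randomization libraries.
#' @param n_clones number of clones in the pool.
#' @param region_bounds list of `c(start, end)` 1-based inclusive residue
#'   intervals; the intervals must partition the protein. `NULL` (default)
#'   means two equal halves, assigned when the pool is simulated.
#' @param wt_clone_fraction extra probability mass of forced wild-type
#'   clones (default 0; Poisson draws can still yield 0 changes).
#' @return object of class `library_model`.
#' @export
library_model <- function(mean_variants_per_clone = 1.7,
                          n_clones = 100000,
                          region_bounds = NULL,
                          wt_clone_fraction = 0) {
  stopifnot(mean_variants_per_clone > 0, n_clones >= 1,
            wt_clone_fraction >= 0, wt_clone_fraction <= 1)
  structure(list(mean_variants_per_clone = mean_variants_per_clone,
                 n_clones = as.integer(n_clones),
                 region_bounds = region_bounds,
                 wt_clone_fraction = wt_clone_fraction),
            class = "library_model")
}

#' Describe the tile sequencing design
#'
#' @param depth_per_tile expected read pairs per tile.
#' @param tile_length tile length in bp; must be a multiple of 3 so tiles
#'   respect codon boundaries.
#' @param per_base_error per-base miscall probability in `[0, 0.75)`.
#' @param phred_offset ASCII offset for FASTQ quality encoding (default 33).
#' @return object of class `sequencing_model`.
#' @export
sequencing_model <- function(depth_per_tile = 500000,
                             tile_length = 150,
                             per_base_error = 0.001,
                             phred_offset = 33L) {
  stopifnot(depth_per_tile >= 1, tile_length >= 3,
            tile_length %% 3 == 0,
            per_base_error >= 0, per_base_error < 0.75)
  structure(list(depth_per_tile = as.integer(depth_per_tile),
                 tile_length = as.integer(tile_length),
                 per_base_error = per_base_error,
                 phred_offset = as.integer(phred_offset)),
            class = "sequencing_model")
}

#' Describe the in-silico selection
#'
#' Growth is exponential and affine in true score: a clone of score s grows
#' at rate `stop_syn_growth_gap * s`, so score-0 (nonsense-like) and score-1
#' (wild-type-like) clones differ by `generations * stop_syn_growth_gap`
#' log-units after selection.
#'
#' @param generations duration of selective growth (in doublings of the
#'   growth-rate unit).
#' @param stop_syn_growth_gap log-growth-rate difference between score-1 and
#'   score-0 clones.
#' @param noise_sd standard deviation of multiplicative log-normal noise per
#'   clone.
#' @return object of class `selection_model`.
#' @export
selection_model <- function(generations = 4,
                            stop_syn_growth_gap = 1,
                            noise_sd = 0.05) {
  stopifnot(generations > 0, stop_syn_growth_gap > 0, noise_sd >= 0)
  structure(list(generations = generations,
                 stop_syn_growth_gap = stop_syn_growth_gap,
                 noise_sd = noise_sd),
            class = "selection_model")
}

default_regions <- function(protein_length) {
  half <- floor(protein_length / 2)
  list(c(1L, half), c(half + 1L, protein_length))
}

check_regions <- function(region_bounds, protein_length) {
  rb <- lapply(region_bounds, as.integer)
  starts <- vapply(rb, `[`, 0L, 1L)
  ends <- vapply(rb, `[`, 0L, 2L)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (any(starts > ends) || starts[1L] != 1L ||
      ends[length(ends)] != protein_length ||
      (length(starts) > 1L && any(starts[-1L] != ends[-length(ends)] + 1L))) {
    stop("region bounds must partition [1, protein_length]")
  }
  if (any(ends > protein_length)) stop("region bounds outside protein")
  lapply(seq_along(starts), function(i) c(starts[i], ends[i]))
}

#' Simulate a codon-randomized clone pool
#'
#' Each clone is assigned one mutagenesis region uniformly at random and
#' carries a Poisson-distributed number of amino-acid changes (truncated at
#' the region size), at positions sampled without replacement within its
#' region; the substituted variant at each position is drawn uniformly from
#' the enumerated changes (19 missense, 1 nonsense, 1 synonymous) at that
#' position. Clone abundances are exponential draws normalized to sum to 1.
#'
#' @param truth a [generate_ground_truth()] map.
#' @param lib a [library_model()].
#' @param seed integer seed.
#' @return object of class `clone_pool`: list with `clones` (data.frame:
#'   clone, region, n_var, abundance), `clone_variants` (data.table: clone,
#'   key), `marginal` (data.frame: key, frequency — abundance-weighted
#'   marginal frequency of each variant), `region_bounds`.
#' @export
simulate_clone_pool <- function(truth, lib, seed = 1) {
  stopifnot(inherits(truth, "ground_truth_map"), inherits(lib, "library_model"))
  bounds <- check_regions(lib$region_bounds %||%
                            default_regions(truth$protein_length),
                          truth$protein_length)
  with_seed(seed, {
    n <- lib$n_clones
    region <- sample.int(length(bounds), n, replace = TRUE)
    k <- rpois(n, lib$mean_variants_per_clone)
    if (lib$wt_clone_fraction > 0) {
      k[runif(n) < lib$wt_clone_fraction] <- 0L
    }
    sizes <- vapply(bounds, function(b) b[2] - b[1] + 1L, 0L)
    k <- pmin(k, sizes[region])

    idx <- which(k > 0L)
    pos_list <- lapply(idx, function(i) {
      b <- bounds[[region[i]]]
      sample(seq.int(b[1], b[2]), k[i])
    })
    all_pos <- unlist(pos_list, use.names = FALSE)
    all_clone <- rep(idx, k[idx])

    # uniform choice among the 21 enumerated variants at each sampled position
    vs <- truth$variants[order(truth$variants$pos), ]
    keys_by_pos <- matrix(vs$key, nrow = truth$protein_length, byrow = TRUE)
    nv <- ncol(keys_by_pos)
    keys <- keys_by_pos[cbind(all_pos, sample.int(nv, length(all_pos),
                                                  replace = TRUE))]

    ab <- rexp(n)
    ab <- ab / sum(ab)
    cv <- data.table::as.data.table(list(clone = all_clone, key = keys))
    data.table::setkeyv(cv, "clone")
    marg <- cv[data.table::data.table(clone = seq_len(n), abundance = ab),
               on = "clone", nomatch = NULL][, .(frequency = sum(abundance)),
                                             by = key]
    structure(list(clones = data.frame(clone = seq_len(n), region = region,
                                       n_var = k, abundance = ab),
                   clone_variants = cv,
                   marginal = as.data.frame(marg),
                   region_bounds = bounds),
              class = "clone_pool")
  })
}

#' Apply in-silico selection to a clone pool
#'
#' A clone's fitness is the minimum true score over the variants it carries
#' (wild-type clones have fitness 1): loss of function is treated as
#' epistatically dominant, as expected for rescue of an essential-gene
#' phenotype. Each abundance is multiplied by
#' `exp(generations * stop_syn_growth_gap * fitness)` and a per-clone
#' log-normal noise factor, then renormalized.
#'
#' @param pool a [simulate_clone_pool()] result.
#' @param truth the matching ground-truth map.
#' @param sel a [selection_model()].
#' @param seed integer seed (used for the noise draw).
#' @return a new `clone_pool` with post-selection abundances and marginal
#'   frequencies; clone fitness is recorded in `clones$fitness`.
#' @export
simulate_selection <- function(pool, truth, sel, seed = 1) {
  stopifnot(inherits(pool, "clone_pool"), inherits(sel, "selection_model"))
  if (nrow(pool$clones) == 0L) stop("empty clone pool")
  ab <- pool$clones$abundance
  if (abs(sum(ab) - 1) > 1e-6) stop("pool abundances must sum to 1")

  score <- setNames(truth$variants$true_score, truth$variants$key)
  cv <- pool$clone_variants
  fitness <- rep(1, nrow(pool$clones))
  if (nrow(cv)) {
    fit_tab <- cv[, .(fitness = min(score[key])), by = clone]
    fitness[fit_tab$clone] <- fit_tab$fitness
  }

  growth <- exp(sel$generations * sel$stop_syn_growth_gap * fitness)
  noise <- with_seed(seed, exp(rnorm(length(ab), 0, sel$noise_sd)))
  ab2 <- ab * growth * noise
  ab2 <- ab2 / sum(ab2)

  out <- pool
  out$clones$abundance <- ab2
  out$clones$fitness <- fitness
  marg <- cv[data.table::data.table(clone = pool$clones$clone,
                                    abundance = ab2),
             on = "clone", nomatch = NULL][, .(frequency = sum(abundance)),
                                           by = key]
  out$marginal <- as.data.frame(marg)
  out
}

#' A pool containing only wild-type clones
#'
#' Mirrors the wild-type ORF control library sequenced alongside the variant
#' pools: identical reference sequence, no variants, same sequencing model.
#'
#' @param truth a ground-truth map (provides region bounds context only).
#' @param n_clones number of (identical) clones; abundance is uniform.
#' @return a `clone_pool` with no variants.
#' @export
wt_control_pool <- function(truth, n_clones = 1L) {
  structure(list(clones = data.frame(clone = seq_len(n_clones),
                                     region = 1L, n_var = 0L,
                                     abundance = rep(1 / n_clones, n_clones)),
                 clone_variants = data.table::as.data.table(
                   list(clone = integer(), key = character())),
                 marginal = data.frame(key = character(),
                                       frequency = numeric()),
                 region_bounds = default_regions(truth$protein_length)),
            class = "clone_pool")
}

tile_table <- function(cds_length, tile_length) {
  if (cds_length %% tile_length != 0) {
    stop("reference length must divide into whole tiles")
  }
  n <- cds_length %/% tile_length
  data.frame(tile = seq_len(n),
             start = (seq_len(n) - 1L) * tile_length,   # 0-based half-open
             end = seq_len(n) * tile_length)
}

# Sparse per-tile read-pair records: one row per (pair, read, position) where
# the observed base differs from the reference. Positions are 0-based coding
# coordinates. Exact per-base iid error model: the number of miscalled cells
# per read-set is Binomial(n_pairs * tile_length, e) and the cells are chosen
# uniformly without replacement, which is equivalent to independent
# Bernoulli(e) errors per base.
sim_tile_records <- function(pool, seqm, truth, tile_row, n_pairs, seed) {
  with_seed(seed, {
    tl <- seqm$tile_length
    start <- tile_row$start
    ref_chars <- strsplit(truth$cds, "")[[1]]

    clone_idx <- sample.int(nrow(pool$clones), n_pairs, replace = TRUE,
                            prob = pool$clones$abundance)
    pair_clone <- data.table::data.table(pair = seq_len(n_pairs),
                                         clone = clone_idx)

    # nucleotide edits of each clone falling inside this tile
    cv <- pool$clone_variants
    if (nrow(cv)) {
      edits <- merge(cv, truth$nt_changes, by = "key",
                     allow.cartesian = TRUE)
      edits <- edits[nt_pos >= start & nt_pos < start + tl]
    } else {
      edits <- data.table::as.data.table(list(
        key = character(), clone = integer(),
        nt_pos = integer(), alt_base = character()))
    }
    var_rec <- merge(pair_clone, edits, by = "clone",
                     allow.cartesian = TRUE)[, .(pair, pos = nt_pos,
                                                 base = alt_base)]

    err_one_read <- function(read_id) {
      ncells <- as.double(n_pairs) * tl
      nerr <- rbinom(1L, ncells, seqm$per_base_error)
      if (nerr == 0L) {
        return(data.table::data.table(pair = integer(), read = integer(),
                                      pos = integer(), base = character()))
      }
      cells <- sample(ncells, nerr)
      pr <- as.integer((cells - 1) %/% tl) + 1L
      ps <- as.integer((cells - 1) %% tl) + start
      e <- data.table::data.table(pair = pr, read = read_id, pos = ps)
      # true base: clone's alt at variant positions, else reference
      e <- merge(e, var_rec, by = c("pair", "pos"), all.x = TRUE)
      e[, true_base := ifelse(is.na(base), ref_chars[pos + 1L], base)]
      bases <- c("A", "C", "G", "T")
      pick <- matrix(bases, nrow = nrow(e), ncol = 4, byrow = TRUE)
      keepm <- pick != e$true_base
      alt3 <- matrix(t(pick)[t(keepm)], ncol = 3, byrow = TRUE)
      e[, obs := alt3[cbind(seq_len(.N), sample.int(3L, .N, replace = TRUE))]]
      e[, .(pair, read, pos, base = obs)]
    }
    err <- data.table::rbindlist(list(err_one_read(1L), err_one_read(2L)))

    rec <- data.table::rbindlist(list(
      var_rec[, .(pair, read = 1L, pos, base)],
      var_rec[, .(pair, read = 2L, pos, base)]))
    if (nrow(err)) {
      rec <- rec[!err, on = c("pair", "read", "pos")]
      err_keep <- err[base != ref_chars[pos + 1L]]
      rec <- data.table::rbindlist(list(rec, err_keep))
    }
    rec[, tile := tile_row$tile]
    list(records = rec, pair_clone = pair_clone)
  })
}

#' Simulate tiled paired-end duplex sequencing of a clone pool
#'
#' Each read pair covers exactly one tile on both strands. Sequencing errors
#' are injected independently per read at the configured per-base rate; base
#' qualities are the Phred score of that rate (capped at 93 for error-free
#' simulations). The result uses a sparse mismatch representation — one
#' record per (pair, read, position) differing from the reference — which is
#' exactly equivalent to full read strings (see [materialize_pairs()]) and
#' scales to millions of pairs.
#'
#' @param pool a `clone_pool`.
#' @param seqm a [sequencing_model()].
#' @param truth the ground-truth map providing the reference coding sequence
#'   and each variant's canonical codon change.
#' @param seed integer seed.
#' @return object of class `read_pair_set`: list with `records` (data.table:
#'   tile, pair, read, pos, base), `pair_clone` (data.table: tile, pair,
#'   clone), `tiles`, `n_pairs` (per tile), `qual` (constant Phred score),
#'   `per_base_error`, `reference`, `phred_offset`.
#' @export
simulate_read_pairs <- function(pool, seqm, truth, seed = 1) {
  stopifnot(inherits(pool, "clone_pool"), inherits(seqm, "sequencing_model"),
            inherits(truth, "ground_truth_map"))
  tiles <- tile_table(nchar(truth$cds), seqm$tile_length)
  recs <- vector("list", nrow(tiles))
  pcs <- vector("list", nrow(tiles))
  for (i in seq_len(nrow(tiles))) {
    out <- sim_tile_records(pool, seqm, truth, tiles[i, ],
                            seqm$depth_per_tile, child_seed(seed, i))
    recs[[i]] <- out$records
    pc <- out$pair_clone
    pc[, tile := tiles$tile[i]]
    pcs[[i]] <- pc
  }
  qual <- if (seqm$per_base_error > 0) {
    min(93L, as.integer(round(-10 * log10(seqm$per_base_error))))
  } else 93L
  structure(list(records = data.table::rbindlist(recs),
                 pair_clone = data.table::rbindlist(pcs),
                 tiles = tiles,
                 n_pairs = seqm$depth_per_tile,
                 qual = qual,
                 per_base_error = seqm$per_base_error,
                 reference = truth$cds,
                 phred_offset = seqm$phred_offset),
            class = "read_pair_set")
}

#' @export
print.read_pair_set <- function(x, ...) {
  cat("Tiled duplex read-pair set\n")
  cat("  tiles:", nrow(x$tiles), "x", x$n_pairs, "pairs;",
      nrow(x$records), "mismatch records\n")
  cat("  base quality: Phred", x$qual,
      sprintf("(per-base error %g)\n", x$per_base_error))
  invisible(x)
}
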