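# Duplex variant calling and count tables. A variant is called only where
# both reads of a pair agree on the same non-reference base and the Bayesian
# posterior that the shared call is real exceeds a threshold (default 90%).

#' Posterior probability that a concordant duplex call is real
#'
#' Both reads of a pair report the same non-reference base with Phred
#' qualities `q1` and `q2` (error probabilities e1, e2). Two hypotheses are
#' compared: the variant is real (likelihood `(1-e1)(1-e2)`) or both reads
#' independently miscalled the reference base as this particular alternate
#' (likelihood `(e1/3)(e2/3)`, the error probability spread uniformly over
#' the three non-reference bases). With equal prior odds,
#'
#' \deqn{P = \frac{(1-e_1)(1-e_2)}{(1-e_1)(1-e_2) + (e_1/3)(e_2/3)}}
#'
#' At Phred 40 on both reads the posterior is within 1e-9 of 1; at Phred 3 it
#' is 0.899, just below the 90% calling threshold.
#'
#' @param q1,q2 Phred quality scores (vectorized).
#' @return posterior probabilities.
#' @export
duplex_posterior <- function(q1, q2) {
  e1 <- 10^(-q1 / 10)
  e2 <- 10^(-q2 / 10)
  num <- (1 - e1) * (1 - e2)
  num / (num + (e1 / 3) * (e2 / 3))
}

#' Call variants from one aligned read pair
#'
#' A mismatch is considered only where both reads of the pair agree on the
#' same non-reference base; discordant positions are never called. Calls with
#' posterior probability at or below `posterior_threshold` are dropped.
#'
#' @param pair list with `offset` (0-based coding coordinate of the first
#'   covered base), `calls_fwd`/`calls_rev` (base strings of equal length)
#'   and `quals_fwd`/`quals_rev` (integer Phred vectors of the same length).
#' @param reference coding sequence (character string).
#' @param posterior_threshold calling threshold in (0, 1); default 0.9.
#' @return data.frame with columns `pos` (0-based), `ref`, `alt`,
#'   `posterior`; zero rows when nothing is called.
#' @export
call_pair <- function(pair, reference, posterior_threshold = 0.9) {
  stopifnot(posterior_threshold > 0, posterior_threshold < 1)
  b1 <- strsplit(pair$calls_fwd, "")[[1]]
  b2 <- strsplit(pair$calls_rev, "")[[1]]
  q1 <- pair$quals_fwd
  q2 <- pair$quals_rev
  if (length(b1) != length(b2) || length(q1) != length(b1) ||
      length(q2) != length(b2)) {
    stop("malformed read pair: call and quality lengths differ")
  }
  off <- pair$offset
  if (off < 0 || off + length(b1) > nchar(reference)) {
    stop("read pair outside reference coordinates")
  }
  refv <- strsplit(substr(reference, off + 1L, off + length(b1)), "")[[1]]
  cand <- which(b1 == b2 & b1 != refv)
  if (!length(cand)) {
    return(data.frame(pos = integer(), ref = character(), alt = character(),
                      posterior = numeric()))
  }
  post <- duplex_posterior(q1[cand], q2[cand])
  keep <- post > posterior_threshold
  data.frame(pos = off + cand[keep] - 1L, ref = refv[cand][keep],
             alt = b1[cand][keep], posterior = post[keep],
             stringsAsFactors = FALSE)
}

#' Translate nucleotide calls to amino-acid variants
#'
#' Multiple nucleotide changes within one codon of the same read pair are
#' translated jointly through the standard genetic code. Stop gains are
#' tagged nonsense; same-residue codon changes are tagged synonymous.
#'
#' @param calls data.frame with `pos` (0-based coding coordinate) and `alt`
#'   columns, e.g. from [call_pair()].
#' @param reference coding sequence; its length must be a multiple of 3.
#' @return data.frame with `pos` (1-based residue), `ref_aa`, `alt_aa`,
#'   `class`, `key` — one row per affected codon.
#' @export
translate_calls <- function(calls, reference) {
  if (nchar(reference) %% 3 != 0) {
    stop("coding sequence length must be divisible by 3")
  }
  if (nrow(calls) == 0L) {
    return(data.frame(pos = integer(), ref_aa = character(),
                      alt_aa = character(), class = character(),
                      key = character()))
  }
  if (any(calls$pos < 0 | calls$pos >= nchar(reference))) {
    stop("call position outside coding sequence")
  }
  gc <- genetic_code()
  codon0 <- calls$pos %/% 3L
  out <- lapply(split(seq_len(nrow(calls)), codon0), function(i) {
    c0 <- calls$pos[i[1]] %/% 3L
    ref_codon <- substr(reference, c0 * 3L + 1L, c0 * 3L + 3L)
    chars <- strsplit(ref_codon, "")[[1]]
    chars[calls$pos[i] %% 3L + 1L] <- calls$alt[i]
    data.frame(pos = c0 + 1L,
               ref_aa = unname(gc[ref_codon]),
               alt_aa = unname(gc[paste(chars, collapse = "")]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$class <- variant_class(out$ref_aa, out$alt_aa)
  out$key <- make_key(out$ref_aa, out$pos, out$alt_aa)
  out
}

#' Tabulate duplex variant calls into a count table
#'
#' Applies the duplex concordance-and-posterior rule to every read pair,
#' translates calls to amino-acid variants (joint translation within codons)
#' and aggregates counts per variant. Frequencies are counts normalized by
#' the sequencing depth of the covering tile.
#'
#' @param x a `read_pair_set` from [simulate_read_pairs()], or a data.frame
#'   of materialized pairs as returned by [materialize_pairs()].
#' @param posterior_threshold duplex calling threshold (default 0.9).
#' @param condition,replicate labels attached to the table.
#' @param ... passed between methods.
#' @return a `count_table` data.frame with columns `key`, `pos`, `ref_aa`,
#'   `alt_aa`, `class`, `tile`, `count`, `depth`, `frequency`; attributes
#'   `condition` and `replicate`.
#' @export
tabulate_pairs <- function(x, posterior_threshold = 0.9,
                           condition = NA_character_, replicate = NA_integer_,
                           ...) {
  UseMethod("tabulate_pairs")
}

#' @rdname tabulate_pairs
#' @export
tabulate_pairs.read_pair_set <- function(x, posterior_threshold = 0.9,
                                         condition = NA_character_,
                                         replicate = NA_integer_, ...) {
  rec <- x$records
  if (nrow(rec) == 0L) {
    warning("empty read stream; returning empty count table")
    return(empty_count_table(x$tiles, x$n_pairs, condition, replicate))
  }
  g <- rec[, .(N = .N, sr = sum(read), b1 = base[1L], b2 = base[.N]),
           by = .(tile, pair, pos)]
  # exactly one record per read of the pair, agreeing on the same base
  calls <- g[N == 2L & sr == 3L & b1 == b2]
  data.table::setnames(calls, "b1", "base")
  post <- duplex_posterior(x$qual, x$qual)
  if (post <= posterior_threshold || nrow(calls) == 0L) {
    return(empty_count_table(x$tiles, x$n_pairs, condition, replicate))
  }
  aa <- translate_call_records(calls, x$reference)
  counts <- aa[, .(count = .N), by = .(key, pos, ref_aa, alt_aa, class, tile)]
  counts[, depth := x$n_pairs]
  counts[, frequency := count / depth]
  out <- as.data.frame(counts[order(pos, alt_aa)])
  finish_count_table(out, condition, replicate)
}

# joint per-codon translation of called records (data.table path)
translate_call_records <- function(calls, reference) {
  gc <- genetic_code()
  calls <- data.table::copy(calls)
  calls[, codon0 := pos %/% 3L]
  calls[, off := pos %% 3L]
  wide <- data.table::dcast(calls, tile + pair + codon0 ~ off,
                            value.var = "base")
  for (col in c("0", "1", "2")) {
    if (!col %in% names(wide)) wide[, (col) := NA_character_]
  }
  ref_codon <- substr(rep(reference, nrow(wide)),
                      wide$codon0 * 3L + 1L, wide$codon0 * 3L + 3L)
  c1 <- ifelse(is.na(wide$`0`), substr(ref_codon, 1, 1), wide$`0`)
  c2 <- ifelse(is.na(wide$`1`), substr(ref_codon, 2, 2), wide$`1`)
  c3 <- ifelse(is.na(wide$`2`), substr(ref_codon, 3, 3), wide$`2`)
  alt_codon <- paste0(c1, c2, c3)
  out <- data.table::data.table(
    tile = wide$tile, pair = wide$pair,
    pos = wide$codon0 + 1L,
    ref_aa = unname(gc[ref_codon]),
    alt_aa = unname(gc[alt_codon]))
  out[, class := variant_class(ref_aa, alt_aa)]
  out[, key := make_key(ref_aa, pos, alt_aa)]
  out
}

#' @rdname tabulate_pairs
#' @param reference coding sequence (required for the data.frame method).
#' @export
tabulate_pairs.data.frame <- function(x, posterior_threshold = 0.9,
                                      condition = NA_character_,
                                      replicate = NA_integer_,
                                      reference, ...) {
  if (nrow(x) == 0L) {
    warning("empty read stream; returning empty count table")
    return(finish_count_table(
      data.frame(key = character(), pos = integer(), ref_aa = character(),
                 alt_aa = character(), class = character(), tile = integer(),
                 count = integer(), depth = integer(), frequency = numeric()),
      condition, replicate))
  }
  depth <- table(x$tile_id)
  rows <- lapply(seq_len(nrow(x)), function(i) {
    pair <- list(offset = x$offset[i], calls_fwd = x$calls_fwd[i],
                 calls_rev = x$calls_rev[i],
                 quals_fwd = decode_quals(x$quals_fwd[i], attr(x, "phred_offset") %||% 33L),
                 quals_rev = decode_quals(x$quals_rev[i], attr(x, "phred_offset") %||% 33L))
    calls <- call_pair(pair, reference, posterior_threshold)
    if (nrow(calls) == 0L) return(NULL)
    aa <- translate_calls(calls, reference)
    aa$tile <- x$tile_id[i]
    aa
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    counts <- data.frame(key = character(), pos = integer(),
                         ref_aa = character(), alt_aa = character(),
                         class = character(), tile = integer(),
                         count = integer())
  } else {
    counts <- as.data.frame(data.table::as.data.table(rows)[
      , .(count = .N), by = .(key, pos, ref_aa, alt_aa, class, tile)])
  }
  counts$depth <- as.integer(depth[as.character(counts$tile)])
  counts$frequency <- counts$count / counts$depth
  finish_count_table(counts[order(counts$pos, counts$alt_aa), ],
                     condition, replicate)
}

decode_quals <- function(q, phred_offset = 33L) {
  if (is.numeric(q)) return(q)
  utf8ToInt(q) - phred_offset
}

empty_count_table <- function(tiles, n_pairs, condition, replicate) {
  finish_count_table(
    data.frame(key = character(), pos = integer(), ref_aa = character(),
               alt_aa = character(), class = character(), tile = integer(),
               count = integer(), depth = integer(), frequency = numeric()),
    condition, replicate)
}

finish_count_table <- function(df, condition, replicate) {
  rownames(df) <- NULL
  attr(df, "condition") <- condition
  attr(df, "replicate") <- replicate
  class(df) <- c("count_table", "data.frame")
  df
}

#' Materialize sparse read pairs as full strings
#'
#' Expands the sparse mismatch representation of a `read_pair_set` into
#' explicit per-pair call and quality strings (one row per pair), suitable
#' for [call_pair()], FASTQ export and small-scale inspection. Intended for
#' modest numbers of pairs; the sparse representation is authoritative at
#' scale.
#'
#' @param rps a `read_pair_set`.
#' @param tiles tiles to materialize (default: all).
#' @param max_pairs safety cap on the number of pairs (default 200000).
#' @return data.frame with `tile_id`, `pair_id`, `offset`, `calls_fwd`,
#'   `calls_rev`, `quals_fwd`, `quals_rev` (quality strings in
#'   FASTQ encoding); attribute `phred_offset`.
#' @export
materialize_pairs <- function(rps, tiles = NULL, max_pairs = 200000) {
  stopifnot(inherits(rps, "read_pair_set"))
  tl <- rps$tiles
  if (!is.null(tiles)) tl <- tl[tl$tile %in% tiles, , drop = FALSE]
  if (nrow(tl) * rps$n_pairs > max_pairs) {
    stop("refusing to materialize ", nrow(tl) * rps$n_pairs,
         " pairs; raise max_pairs if intended")
  }
  qchar <- intToUtf8(rps$qual + rps$phred_offset)
  out <- lapply(seq_len(nrow(tl)), function(i) {
    t0 <- tl$start[i]
    len <- tl$end[i] - tl$start[i]
    ref_chars <- strsplit(substr(rps$reference, t0 + 1L, t0 + len), "")[[1]]
    m1 <- matrix(ref_chars, nrow = len, ncol = rps$n_pairs)
    m2 <- m1
    rec <- rps$records[tile == tl$tile[i]]
    r1 <- rec[read == 1L]
    r2 <- rec[read == 2L]
    if (nrow(r1)) m1[cbind(r1$pos - t0 + 1L, r1$pair)] <- r1$base
    if (nrow(r2)) m2[cbind(r2$pos - t0 + 1L, r2$pair)] <- r2$base
    data.frame(tile_id = tl$tile[i], pair_id = seq_len(rps$n_pairs),
               offset = t0,
               calls_fwd = apply(m1, 2, paste, collapse = ""),
               calls_rev = apply(m2, 2, paste, collapse = ""),
               quals_fwd = strrep(qchar, len),
               quals_rev = strrep(qchar, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "phred_offset") <- rps$phred_offset
  out
}
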