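# Plain-text interchange: FASTA/FASTQ, count-table TSV, MaveDB-style score
# CSV, reference-set CSV, key-value config files.

#' Write a reference coding sequence as FASTA
#' @param sequence DNA string.
#' @param path output file.
#' @param name sequence name.
#' @export
write_reference_fasta <- function(sequence, path, name = "reference") {
  x <- Biostrings::DNAStringSet(setNames(sequence, name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a coding sequence from FASTA
#' @param path FASTA file; the first record is used.
#' @return character string.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  as.character(x[[1L]])
}

#' Export read pairs as a FASTQ file pair
#'
#' Writes materialized read pairs to `<prefix>_1.fastq` / `<prefix>_2.fastq`
#' with headers carrying the tile and 0-based offset
#' (`@p<pair> tile=<tile> offset=<offset>`).
#'
#' @param pairs data.frame from [materialize_pairs()], or a `read_pair_set`
#'   (materialized on the fly; mind the pair count).
#' @param prefix output path prefix.
#' @param ... passed to [materialize_pairs()] when `pairs` is a
#'   `read_pair_set`.
#' @return invisibly, the two file paths.
#' @export
write_fastq_pairs <- function(pairs, prefix, ...) {
  if (inherits(pairs, "read_pair_set")) pairs <- materialize_pairs(pairs, ...)
  hdr <- sprintf("@p%d tile=%s offset=%d", pairs$pair_id, pairs$tile_id,
                 pairs$offset)
  f1 <- paste0(prefix, "_1.fastq")
  f2 <- paste0(prefix, "_2.fastq")
  writeLines(rbind(hdr, pairs$calls_fwd, "+", pairs$quals_fwd), f1)
  writeLines(rbind(hdr, pairs$calls_rev, "+", pairs$quals_rev), f2)
  invisible(c(f1, f2))
}

#' Read a FASTQ file pair written by [write_fastq_pairs()]
#'
#' @param file1,file2 forward/reverse FASTQ paths.
#' @param phred_offset quality encoding offset (default 33).
#' @return data.frame in the [materialize_pairs()] layout.
#' @export
read_fastq_pairs <- function(file1, file2, phred_offset = 33L) {
  parse_one <- function(f) {
    l <- readLines(f)
    if (length(l) %% 4 != 0) stop("truncated FASTQ: ", f)
    hdr <- l[seq(1, length(l), by = 4)]
    m <- regmatches(hdr, regexec("tile=([^ ]+) offset=([0-9]+)", hdr))
    list(tile = vapply(m, `[`, "", 2L),
         offset = as.integer(vapply(m, `[`, "", 3L)),
         calls = l[seq(2, length(l), by = 4)],
         quals = l[seq(4, length(l), by = 4)])
  }
  a <- parse_one(file1)
  b <- parse_one(file2)
  if (length(a$calls) != length(b$calls)) stop("unpaired FASTQ files")
  out <- data.frame(tile_id = a$tile, pair_id = seq_along(a$calls),
                    offset = a$offset,
                    calls_fwd = a$calls, calls_rev = b$calls,
                    quals_fwd = a$quals, quals_rev = b$quals,
                    stringsAsFactors = FALSE)
  attr(out, "phred_offset") <- phred_offset
  out
}

#' Write a count table as TSV
#'
#' Columns: variant (HGVS protein string), key, condition, replicate, count,
#' depth, frequency plus position/class metadata.
#'
#' @param table a `count_table`.
#' @param path output file.
#' @export
write_count_table <- function(table, path) {
  out <- data.frame(
    variant = hgvs_pro(table$ref_aa, table$pos, table$alt_aa),
    key = table$key,
    condition = attr(table, "condition") %||% NA_character_,
    replicate = attr(table, "replicate") %||% NA_integer_,
    pos = table$pos, ref_aa = table$ref_aa, alt_aa = table$alt_aa,
    class = table$class, tile = table$tile,
    count = table$count, depth = table$depth, frequency = table$frequency)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table TSV written by [write_count_table()]
#' @param path input file.
#' @return a `count_table`.
#' @export
read_count_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  finish_count_table(
    df[, c("key", "pos", "ref_aa", "alt_aa", "class", "tile", "count",
           "depth", "frequency")],
    df$condition[1L], df$replicate[1L])
}

#' Write a score table in MaveDB-compatible CSV layout
#'
#' Core columns `hgvs_pro`, `score`, `sd`, `se` followed by extended
#' columns (enrichment ratio, region, filter status, delta score where
#' present).
#'
#' @param scores score data.frame with `key`, `fs`, `sigma`, `n_rep` and
#'   optionally `phi`, `region`, `passed_filters`, `delta`.
#' @param path output file.
#' @export
write_score_table <- function(scores, path) {
  pk <- parse_key(scores$key)
  out <- data.frame(
    hgvs_pro = hgvs_pro(pk$ref_aa, pk$pos, pk$alt_aa),
    score = scores$fs,
    sd = scores$sigma * sqrt(pmax(scores$n_rep, 1L)),
    se = scores$sigma)
  for (col in c("phi", "region", "passed_filters", "delta", "class")) {
    if (col %in% names(scores)) out[[col]] <- scores[[col]]
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read reference variant sets as CSV
#'
#' @param variants data.frame with `variant`, `clinical_label`, `maf`,
#'   `n_homozygotes`, optionally `source`.
#' @param path file path.
#' @export
write_reference_variants <- function(variants, path) {
  write.csv(variants, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_reference_variants
#' @export
read_reference_variants <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a scoring configuration as a key-value file
#'
#' @param config a [score_config()].
#' @param path output file.
#' @export
write_config <- function(config, path) {
  vals <- vapply(config, function(v) {
    if (is.null(v)) "NULL" else paste(format(v, digits = 12), collapse = ",")
  }, "")
  writeLines(paste0(names(config), " = ", vals), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  l <- readLines(path)
  kv <- strsplit(l, " = ", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- x[2L]
    if (v == "NULL") return(NULL)
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[`, "", 1L)
  structure(vals, class = "score_config")
}
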