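# Shared helpers: scoped RNG, variant keys, codon tables.

#' Evaluate an expression under a temporary RNG seed
#'
#' All stochastic operations in the package take an explicit seed and restore
#' the caller's random stream afterwards, so no function mutates global
#' random state.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Derive a reproducible child seed
#'
#' Deterministic mixing of a parent seed and a stream index; result stays
#' within 32-bit integer range.
#'
#' @param seed parent seed.
#' @param i stream index.
#' @return integer seed.
#' @export
child_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 44488 * 48271 + as.double(i)) %% 2147483647 + 1)
}

# The 20 standard residues, alphabetical by one-letter code.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE <- c(A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe",
              G = "Gly", H = "His", I = "Ile", K = "Lys", L = "Leu",
              M = "Met", N = "Asn", P = "Pro", Q = "Gln", R = "Arg",
              S = "Ser", T = "Thr", V = "Val", W = "Trp", Y = "Tyr",
              `*` = "Ter")

# One fixed codon per residue (the most frequently used human codon), used as
# the canonical codon change for each amino-acid level variant.
PREFERRED_CODON <- c(A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC",
                     G = "GGC", H = "CAC", I = "ATC", K = "AAG", L = "CTG",
                     M = "ATG", N = "AAC", P = "CCC", Q = "CAG", R = "CGG",
                     S = "AGC", T = "ACC", V = "GTG", W = "TGG", Y = "TAC",
                     `*` = "TAA")

genetic_code <- function() Biostrings::GENETIC_CODE

codons_for <- function(aa) {
  gc <- genetic_code()
  names(gc)[gc == aa]
}

translate_codon <- function(codon) {
  unname(genetic_code()[codon])
}

#' Build a variant key
#'
#' Keys are compact amino-acid substitution identifiers of the form
#' `<ref><pos><alt>` (e.g. `"A123V"`); nonsense variants use `"*"` as the
#' alternate residue and synonymous variants repeat the reference residue.
#'
#' @param ref_aa reference residue (one-letter).
#' @param pos 1-based residue position.
#' @param alt_aa alternate residue (one-letter, `"*"` for stop).
#' @return character vector of keys.
#' @export
make_key <- function(ref_aa, pos, alt_aa) {
  paste0(ref_aa, pos, alt_aa)
}

#' Parse variant keys
#'
#' @param key character vector of keys produced by [make_key()].
#' @return data.frame with columns `key`, `ref_aa`, `pos`, `alt_aa`, `class`.
#' @export
parse_key <- function(key) {
  m <- regmatches(key, regexec("^([A-Z])([0-9]+)([A-Z*])$", key))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stop("malformed variant key: ", paste(key[bad], collapse = ", "))
  ref <- vapply(m, `[`, "", 2L)
  pos <- as.integer(vapply(m, `[`, "", 3L))
  alt <- vapply(m, `[`, "", 4L)
  data.frame(key = key, ref_aa = ref, pos = pos, alt_aa = alt,
             class = variant_class(ref, alt), stringsAsFactors = FALSE)
}

#' Classify a substitution
#'
#' @param ref_aa,alt_aa one-letter residues (`"*"` = stop).
#' @return `"synonymous"`, `"nonsense"` or `"missense"`.
#' @export
variant_class <- function(ref_aa, alt_aa) {
  ifelse(alt_aa == "*", "nonsense",
         ifelse(alt_aa == ref_aa, "synonymous", "missense"))
}

#' Format protein-level HGVS strings
#'
#' @param ref_aa,pos,alt_aa substitution components (one-letter residues).
#' @return e.g. `"p.Ala123Val"`, `"p.Trp40Ter"`, `"p.Ala123="`.
#' @export
hgvs_pro <- function(ref_aa, pos, alt_aa) {
  alt3 <- ifelse(alt_aa == ref_aa, "=", unname(AA_THREE[alt_aa]))
  paste0("p.", unname(AA_THREE[ref_aa]), pos, alt3)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
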