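# Shared fixture builders. Everything is generated in code at test time.

# A small count table with the columns the scoring functions expect.
make_count_table <- function(key, count, depth = 10000L, tile = 1L,
                             condition = "nonselect", replicate = 1L) {
  pk <- mavescore::parse_key(key)
  df <- data.frame(key = key, pos = pk$pos, ref_aa = pk$ref_aa,
                   alt_aa = pk$alt_aa, class = pk$class,
                   tile = tile, count = count, depth = depth,
                   frequency = count / depth, stringsAsFactors = FALSE)
  attr(df, "condition") <- condition
  attr(df, "replicate") <- replicate
  class(df) <- c("count_table", "data.frame")
  df
}

# An enrichment table built directly from phi values (bypassing counts), for
# exercising scale computation and score anchoring in isolation.
make_enrichment_table <- function(key, phi, f_ns = 1e-3) {
  pk <- mavescore::parse_key(key)
  out <- data.frame(key = key, pos = pk$pos, ref_aa = pk$ref_aa,
                    alt_aa = pk$alt_aa, class = pk$class, tile = 1L,
                    f_ns = f_ns, f_s = phi * f_ns, f_wt_ns = 0, f_wt_s = 0,
                    f_ns_adj = f_ns, f_s_adj = phi * f_ns, phi = phi,
                    usable = is.finite(phi) & phi > 0, floored = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_table", "data.frame")
  out
}

# Deterministic keys over one region: nonsense/synonymous/missense ladders.
# Residues chosen arbitrarily; positions 1..n.
ladder_keys <- function(n, alt) {
  mavescore::make_key(rep("A", n), seq_len(n), alt)
}

# A small simulated experiment shared by several counting tests.
small_sim <- function(protein_length = 30, n_clones = 400, depth = 400,
                      tile_length = 30, per_base_error = 0,
                      seed = 42, pool_seed = 7) {
  truth <- mavescore::generate_ground_truth(protein_length, seed = 5)
  lib <- mavescore::library_model(n_clones = n_clones,
                                  region_bounds = list(c(1, protein_length)))
  pool <- mavescore::simulate_clone_pool(truth, lib, seed = pool_seed)
  seqm <- mavescore::sequencing_model(depth_per_tile = depth,
                                      tile_length = tile_length,
                                      per_base_error = per_base_error)
  rps <- mavescore::simulate_read_pairs(pool, seqm, truth, seed = seed)
  list(truth = truth, lib = lib, pool = pool, seqm = seqm, rps = rps)
}
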