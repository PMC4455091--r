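# Fixtures built in code: profile rows, evidence tables, tiny read sets.

make_profile <- function(me3 = 0, me1 = 0, k27 = 0, me9 = 0,
                         gfp1 = 0, gfp2 = 0, id = "P1") {
  data.frame(protein_id = id, empai_H3K4me3 = me3, empai_H3K4me1 = me1,
             empai_H3K27ac = k27, empai_H3K9me3 = me9,
             empai_GFP_r1 = gfp1, empai_GFP_r2 = gfp2,
             stringsAsFactors = FALSE)
}

make_profiles <- function(...) do.call(rbind, list(...))

# One evidence row; emPAI value is encoded through n_observed/n_observable.
ev_row <- function(protein, channel, replicate, score, n_obs, n_obl = 10,
                   validated = TRUE) {
  data.frame(protein_id = protein, channel = channel,
             replicate = replicate, mascot_score = score,
             n_observed = n_obs, n_observable = n_obl,
             manually_validated = validated, stringsAsFactors = FALSE)
}

# GRanges of reads given 1-based starts and a common width.
reads_gr <- function(chrom, start, width = 50) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, width = width))
}

# Peak table with summit at the midpoint unless given.
peaks_fix <- function(chrom, summit, p_value = 1e-12, read_count = 500,
                      half = 200) {
  chipms::peak_table(chrom = chrom, start = summit - half,
                     end = summit + half, summit = summit,
                     p_value = p_value, read_count = read_count)
}

# Small but non-degenerate simulation for unit tests.
small_config <- function(seed = 11, ...) {
  defaults <- list(seed = seed,
                   chrom_lengths = c(chr1 = 1.5e6, chr2 = 1.5e6),
                   n_promoters = 40, n_enhancers = 60, n_hetero = 8,
                   n_factors_per_class = 5, n_bound_regions = 15,
                   reads_per_track = 12000, n_targets = 10)
  do.call(chipms::sim_config, utils::modifyList(defaults, list(...)))
}

# Independent average-rank computation (O(n^2), no rank()/cor()).
brute_ranks <- function(x) {
  vapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, numeric(1))
}

# Independent Spearman: Pearson product-moment formula on brute ranks.
brute_spearman <- function(a, b) {
  ra <- brute_ranks(a); rb <- brute_ranks(b)
  da <- ra - mean(ra); db <- rb - mean(rb)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# Independent single-linkage clustering of pooled summits: connected
# components of the "within max_dist on same chromosome" graph.
brute_clusters <- function(chrom, summit, max_dist) {
  n <- length(summit)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    chrom[i] == chrom[j] & abs(summit[i] - summit[j]) <= max_dist)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        m <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}
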