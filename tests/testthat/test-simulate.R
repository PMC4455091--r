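# Synthetic-data generator: determinism, planted structure and the noise
# models the pipeline assumes.

test_that("region planting honours counts, TSS anchoring and spacing", {
  cfg <- small_config()
  g <- make_genome_and_regions(cfg)
  tab <- table(g$regions$class)
  expect_equal(unname(tab["promoter"]), cfg$n_promoters)
  expect_equal(unname(tab["enhancer"]), cfg$n_enhancers)
  expect_equal(unname(tab["heterochromatin"]), cfg$n_hetero)
  # every promoter center sits at a TSS (within 1 bp)
  prom <- g$regions[g$regions$class == "promoter", ]
  d <- abs(g$tss$tss[match(prom$region_id, g$tss$region_id)] - 1 -
             prom$center)
  expect_true(all(d <= 1))
  # enhancers are at least 5 kb from every TSS
  enh <- g$regions[g$regions$class == "enhancer", ]
  dd <- vapply(seq_len(nrow(enh)), function(i)
    min(abs(g$tss$tss[g$tss$chrom == enh$chrom[i]] - 1 - enh$center[i])),
    numeric(1))
  expect_true(all(dd >= 5000))
  # regions never overlap
  gr <- GenomicRanges::GRanges(g$regions$chrom,
                               IRanges::IRanges(g$regions$start + 1,
                                                g$regions$end))
  expect_equal(max(GenomicRanges::countOverlaps(gr, gr)), 1)
  # zero-enhancer config
  g0 <- make_genome_and_regions(small_config(n_enhancers = 0))
  expect_false("enhancer" %in% g0$regions$class)
  # infeasible packing errors out
  expect_error(make_genome_and_regions(
    sim_config(chrom_lengths = c(chr1 = 1e5), n_promoters = 500)), "pack")
})

test_that("the generator is fully deterministic under a fixed seed", {
  s1 <- simulate_dataset(small_config(seed = 21))
  s2 <- simulate_dataset(small_config(seed = 21))
  expect_identical(s1$regions, s2$regions)
  expect_identical(s1$factors$evidence, s2$factors$evidence)
  expect_identical(s1$marks$reads$H3K4me3, s2$marks$reads$H3K4me3)
  expect_identical(s1$expression$counts, s2$expression$counts)
  s3 <- simulate_dataset(small_config(seed = 22))
  expect_false(identical(s1$factors$evidence, s3$factors$evidence))
  # generators can be re-run independently of each other
  g <- make_genome_and_regions(small_config(seed = 21))
  expect_identical(simulate_mark_tracks(g, small_config(seed = 21))$peaks,
                   s1$marks$peaks)
})

test_that("mark tracks concentrate signal on their territory", {
  cfg <- small_config(seed = 5)
  g <- make_genome_and_regions(cfg)
  mk <- simulate_mark_tracks(g, cfg)
  # the H3K4me3 top bin coincides with a promoter
  tr <- bin_coverage(mk$reads$H3K4me3, g$seqlengths, cfg$bin_width)
  top <- top_bins(tr, 1)
  prom <- g$regions[g$regions$class == "promoter", ]
  hit <- prom$chrom == top$chrom &
    prom$center %/% cfg$bin_width == top$bin
  expect_true(any(hit))
  # mark peak p-values clear the downstream retention cut
  expect_true(all(mk$peaks$H3K4me3$p_value <= 1e-10))
  # weak promoter-proximal H3K4me1 peaks exist (fodder for the
  # enhancer-assignment filter)
  expect_gt(nrow(mk$peaks$H3K4me1), sum(g$regions$class == "enhancer"))
})

test_that("with zero enrichment, marks are indistinguishable from input", {
  cfg <- small_config(seed = 9, signal_fraction = 0)
  g <- make_genome_and_regions(cfg)
  mk <- simulate_mark_tracks(g, cfg)
  tr_mark <- bin_coverage(mk$reads$H3K4me3, g$seqlengths, cfg$bin_width)
  tr_inp <- bin_coverage(mk$reads$input, g$seqlengths, cfg$bin_width)
  ks <- suppressWarnings(stats::ks.test(tr_mark$counts, tr_inp$counts))
  expect_gt(ks$p.value, 0.01)
})

test_that("factor evidence reflects planted classes; decoys fail filters", {
  cfg <- small_config(seed = 8, empai_sigma = 0)
  g <- make_genome_and_regions(cfg)
  f <- simulate_factor_data(g, cfg)
  ms <- ms_location_pipeline(f$evidence)
  # zero noise: planted truth recovered exactly
  loc <- ms$calls$location[match(f$truth$factor_id, ms$calls$protein_id)]
  expect_equal(loc, f$truth$class)
  # decoy fates, by construction
  all_prof <- ms$profiles
  sticky <- grepl("^decoy_sticky", all_prof$protein_id)
  expect_true(all(!all_prof$passed_gfp[sticky]))
  indisc <- grepl("^decoy_indisc", all_prof$protein_id)
  expect_true(all(!all_prof$passed_discrimination[indisc]))
  # weak-score decoys never make it past the Mascot gate
  expect_false(any(grepl("^decoy_weak", all_prof$protein_id)))
})

test_that("high-activity factors carry elevated H3K27ac ratios", {
  # construction property, pooled over several seeds: the planted activity
  # tier of promoter/enhancer factors drives their H3K27ac ratio
  tiers <- numeric(); ratios <- numeric()
  for (s in 13:15) {
    cfg <- small_config(seed = s)
    g <- make_genome_and_regions(cfg)
    f <- simulate_factor_data(g, cfg)
    ms <- ms_location_pipeline(f$evidence)
    calls <- ms$calls[grepl("^factor_", ms$calls$protein_id), ]
    cls <- f$truth$class[match(calls$protein_id, f$truth$factor_id)]
    keep <- cls %in% c("promoter", "enhancer")
    expect_true(all(!is.na(calls$h3k27ac_ratio[keep])))
    tiers <- c(tiers, f$truth$activity_tier[
      match(calls$protein_id[keep], f$truth$factor_id)])
    ratios <- c(ratios, calls$h3k27ac_ratio[keep])
  }
  hi <- tiers > stats::median(tiers)
  expect_gt(stats::median(ratios[hi]), stats::median(ratios[!hi]))
})

test_that("knockout expression plants recoverable targets", {
  cfg <- small_config(seed = 4, nb_dispersion = 0, probe_sd = 0)
  g <- make_genome_and_regions(cfg)
  f <- simulate_factor_data(g, cfg)
  ex <- simulate_expression(g, f, cfg)
  agg <- aggregate_probes(ex$probes)
  hits <- target_genes(ex$bound_genes, agg, direction = "down")
  # fourfold planted knockdowns all pass the twofold rule at zero noise
  expect_setequal(hits, ex$true_targets)
  # targets are bound genes of the knockout factor
  expect_true(all(ex$true_targets %in% ex$bound_genes))
  # zero effect size: nothing passes beyond the planted false-positive rate
  cfg0 <- small_config(seed = 4, nb_dispersion = 0, probe_sd = 0,
                       knockout_log2fc = 0)
  ex0 <- simulate_expression(g, f, cfg0)
  hits0 <- target_genes(ex0$bound_genes, aggregate_probes(ex0$probes),
                        direction = "down")
  expect_lte(length(hits0), ceiling(0.05 * length(ex0$bound_genes)))
})

test_that("written datasets are byte-identical across runs and round-trip", {
  cfg <- small_config(seed = 17, n_promoters = 10, n_enhancers = 12,
                      n_hetero = 3, n_factors_per_class = 2,
                      reads_per_track = 2000)
  sim <- simulate_dataset(cfg)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_sim_dataset(sim, d1, tracks = sim$factors$truth$factor_id[1])
  write_sim_dataset(simulate_dataset(cfg), d2,
                    tracks = sim$factors$truth$factor_id[1])
  files <- list.files(d1)
  expect_true(length(files) > 10)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  # round trips through the standard formats
  sizes <- read_genome_sizes(file.path(d1, "genome.sizes.tsv"))
  expect_equal(sizes, sim$seqlengths)
  pk <- read_narrowpeak(file.path(d1, "H3K4me3.narrowPeak"))
  expect_equal(pk$summit, sim$marks$peaks$H3K4me3$summit)
  expect_equal(pk$p_value, sim$marks$peaks$H3K4me3$p_value, tolerance = 1e-4)
  tss <- read_tss(file.path(d1, "tss.bed"))
  expect_setequal(tss$tss, sim$tss$tss)
  ev <- read_ms_evidence(file.path(d1, "ms_evidence.tsv"))
  expect_equal(nrow(ev), nrow(sim$factors$evidence))
  cov <- read_coverage(file.path(d1, "H3K4me3.bedgraph"))
  expect_equal(sum(cov$score * GenomicRanges::width(cov)),
               sum(GenomicRanges::width(sim$marks$reads$H3K4me3)))
})
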