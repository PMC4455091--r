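## Seeded synthetic-data generator: a small genome with planted promoter,
## enhancer and heterochromatin regions, mark-specific ChIP read tracks
## over Poisson-like background, factor tracks and MS evidence whose emPAI
## structure reflects the planted location classes, and a knockout
## expression experiment with planted target genes.  Every generator
## derives its own child seed from the run seed, so modules can be
## regenerated independently and a fixed seed gives byte-identical output.

child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k * 1000003) %% 2147483647)
}

#' Configuration for the synthetic ChIP-MS dataset
#'
#' Defaults describe the study conditions the generator emulates at desk
#' scale: a 2 x 5 Mb genome, 200 promoters, 400 enhancers and 20
#' heterochromatin blocks; 60 factors (20 per planted class); 50,000 reads
#' per ChIP track with 60% of reads in signal; lognormal multiplicative
#' emPAI noise (sigma 0.3); negative-binomial expression counts
#' (dispersion 0.05) with 30 planted knockout targets at fourfold
#' down-regulation.
#'
#' @param seed Run seed (integer).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n_promoters,n_enhancers,n_hetero Planted region counts.
#' @param n_factors_per_class Factors planted per location class.
#' @param n_bound_regions Regions of its class each factor binds.
#' @param reads_per_track Reads per ChIP track.
#' @param read_length Read length in bp.
#' @param bin_width Genome bin width for correlation analyses.
#' @param signal_fraction Fraction of a track's reads drawn from its
#'   signal territory (the rest are uniform background).
#' @param empai_sigma Lognormal sigma of emPAI noise.
#' @param activity_sigma Lognormal sigma of the per-region H3K27ac
#'   activity multiplier.
#' @param nb_dispersion Negative-binomial dispersion of expression counts.
#' @param knockout_log2fc Planted log2 fold change of target genes in the
#'   knockout (default -2, i.e. fourfold down).
#' @param n_targets Number of planted target genes.
#' @param probe_sd SD of per-probe log2 fold-change noise.
#' @param n_tissues Number of atlas tissues (including ESC).
#' @return A list with class \code{"chipms_sim_config"}.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                       n_promoters = 200, n_enhancers = 400, n_hetero = 20,
                       n_factors_per_class = 20, n_bound_regions = 60,
                       reads_per_track = 50000, read_length = 50,
                       bin_width = 1000, signal_fraction = 0.6,
                       empai_sigma = 0.3, activity_sigma = 0.5,
                       nb_dispersion = 0.05, knockout_log2fc = -2,
                       n_targets = 30, probe_sd = 0.2, n_tissues = 10) {
  cfg <- as.list(environment())
  stopifnot(all(unlist(cfg[c("n_promoters", "n_enhancers", "n_hetero",
                             "n_factors_per_class")]) >= 0),
            signal_fraction >= 0, signal_fraction <= 1,
            empai_sigma >= 0, nb_dispersion >= 0)
  structure(cfg, class = "chipms_sim_config")
}

REGION_WIDTHS <- c(promoter = 2000, enhancer = 1500,
                   heterochromatin = 10000)

#' Plant a genome of non-overlapping regulatory regions
#'
#' Chromosomes are divided into 14-kb slots; promoter, enhancer and
#' heterochromatin regions occupy randomly chosen distinct slots, so
#' regions never overlap, every promoter sits at a TSS, and every enhancer
#' is more than 5 kb from any TSS.  Each promoter and enhancer receives a
#' lognormal activity multiplier that later scales its H3K27ac signal.
#'
#' @param config A [sim_config()].
#' @return A list: \code{seqlengths}, \code{regions} (region_id, chrom,
#'   0-based start/end/center, class, activity), \code{tss} (gene table
#'   with 1-based TSS and gene \code{length}).
#' @export
make_genome_and_regions <- function(config) {
  set.seed(child_seed(config$seed, 1))
  slot <- 14000
  n_slots <- floor(config$chrom_lengths / slot)
  total <- config$n_promoters + config$n_enhancers + config$n_hetero
  if (total > sum(n_slots))
    stop("cannot pack ", total, " regions into ", sum(n_slots), " slots")
  slots <- data.frame(
    chrom = rep(names(config$chrom_lengths), n_slots),
    idx = unlist(lapply(n_slots, seq_len)) - 1L,
    stringsAsFactors = FALSE)
  pick <- slots[sample(nrow(slots), total), , drop = FALSE]
  class <- rep(c("promoter", "enhancer", "heterochromatin"),
               c(config$n_promoters, config$n_enhancers, config$n_hetero))
  width <- REGION_WIDTHS[class]
  center <- pick$idx * slot + slot %/% 2L
  regions <- data.frame(
    region_id = sprintf("%s_%04d", substr(class, 1, 4), seq_len(total)),
    chrom = pick$chrom,
    start = as.integer(center - width %/% 2),
    end = as.integer(center + width %/% 2),
    center = as.integer(center),
    class = class,
    activity = ifelse(class == "heterochromatin", 1,
                      stats::rlnorm(total, 0, config$activity_sigma)),
    stringsAsFactors = FALSE)
  ord <- order(regions$chrom, regions$start)
  regions <- regions[ord, , drop = FALSE]
  rownames(regions) <- NULL
  prom <- regions[regions$class == "promoter", , drop = FALSE]
  tss <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(nrow(prom))),
    chrom = prom$chrom,
    tss = prom$center + 1L,                    # 1-based, at region center
    strand = sample(c("+", "-"), nrow(prom), replace = TRUE),
    length = sample(1000:10000, nrow(prom), replace = TRUE),
    region_id = prom$region_id,
    stringsAsFactors = FALSE)
  list(seqlengths = config$chrom_lengths, regions = regions, tss = tss)
}

## Draw reads: background uniform over the genome plus signal placed on a
## territory (region indices with weights); returns a GRanges.
draw_reads <- function(n, seqlengths, regions, weights, config) {
  n_sig <- if (length(weights) && sum(weights) > 0)
    round(config$signal_fraction * n) else 0
  n_bg <- n - n_sig
  total_len <- sum(seqlengths)
  cum <- cumsum(as.numeric(seqlengths))
  gpos <- sort(runif(n_bg, 0, total_len))
  chrom_i <- findInterval(gpos, c(0, cum), rightmost.closed = TRUE)
  bg_chrom <- names(seqlengths)[chrom_i]
  bg_pos <- floor(gpos - c(0, cum)[chrom_i])
  chrom <- bg_chrom
  pos <- bg_pos
  if (n_sig > 0) {
    ri <- sample(seq_len(nrow(regions)), n_sig, replace = TRUE,
                 prob = weights)
    width <- regions$end[ri] - regions$start[ri]
    offs <- ifelse(regions$class[ri] == "heterochromatin",
                   runif(n_sig, 0, width),
                   pmin(pmax(stats::rnorm(n_sig, width / 2, width / 5),
                             0), width))
    chrom <- c(chrom, regions$chrom[ri])
    pos <- c(pos, regions$start[ri] + offs)
  }
  rl <- config$read_length
  start0 <- pmax(0, pmin(floor(pos - rl / 2),
                         seqlengths[chrom] - rl))
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start0 + 1, width = rl),
                         strand = sample(c("+", "-"), length(pos),
                                         replace = TRUE))
}

## Peak calls at the centers of a set of regions, given the track's reads.
call_planted_peaks <- function(regions, reads, neglog10p) {
  if (nrow(regions) == 0)
    return(peak_table(character(), integer(), integer(), integer()))
  win <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$center + 1L - 500L,
                                    regions$center + 500L))
  cnt <- GenomicRanges::countOverlaps(win, reads)
  peak_table(chrom = regions$chrom,
             start = pmin(regions$start, regions$center - 500L),
             end = pmax(regions$end, regions$center + 500L),
             summit = regions$center,
             p_value = 10^(-neglog10p),
             read_count = cnt,
             name = regions$region_id)
}

#' Simulate histone-mark ChIP tracks, input and mark peak calls
#'
#' Reads follow the mark-to-location map: H3K4me3 at promoters, H3K4me1
#' at enhancers (with weak signal at promoter flanks), H3K27ac at
#' promoters and enhancers scaled by their activity multiplier, H3K9me3
#' over heterochromatin blocks; the input is uniform background.  Peak
#' summits are emitted at planted region centers with p-values decreasing
#' in enrichment; the weak promoter-proximal H3K4me1 peaks are emitted
#' too, so the enhancer-assignment filter has something to remove.
#'
#' @param genome Output of [make_genome_and_regions()].
#' @param config The [sim_config()].
#' @return A list with \code{reads} (named list of \code{GRanges},
#'   including \code{input}) and \code{peaks} (named list of peak tables).
#' @export
simulate_mark_tracks <- function(genome, config) {
  set.seed(child_seed(config$seed, 2))
  r <- genome$regions
  is_p <- r$class == "promoter"
  is_e <- r$class == "enhancer"
  is_h <- r$class == "heterochromatin"
  weights <- list(
    H3K4me3 = ifelse(is_p, 1, 0),
    H3K4me1 = ifelse(is_e, 1, ifelse(is_p, 0.15, 0)),
    H3K27ac = ifelse(is_p | is_e, r$activity, 0),
    H3K9me3 = ifelse(is_h, 1, 0))
  reads <- lapply(weights, function(w)
    draw_reads(config$reads_per_track, genome$seqlengths, r, w, config))
  reads$input <- draw_reads(config$reads_per_track, genome$seqlengths, r,
                            numeric(nrow(r)), config)
  peaks <- list(
    H3K4me3 = call_planted_peaks(r[is_p, ], reads$H3K4me3, 15),
    H3K4me1 = {
      strong <- call_planted_peaks(r[is_e, ], reads$H3K4me1, 15)
      weak <- call_planted_peaks(r[is_p, ], reads$H3K4me1, 11)
      rbind(strong, weak)
    },
    H3K27ac = call_planted_peaks(r[is_p | is_e, ], reads$H3K27ac, 15),
    H3K9me3 = call_planted_peaks(r[is_h, ], reads$H3K9me3, 12))
  list(reads = reads, peaks = peaks)
}

## emPAI affinity of each planted class for each ChIP channel.  The K27ac
## affinity is further scaled by the factor's activity tier.
CLASS_AFFINITY <- rbind(
  promoter        = c(H3K4me3 = 1.00, H3K4me1 = 0.15, H3K27ac = 0.45,
                      H3K9me3 = 0.02),
  enhancer        = c(H3K4me3 = 0.15, H3K4me1 = 1.00, H3K27ac = 0.45,
                      H3K9me3 = 0.02),
  heterochromatin = c(H3K4me3 = 0.02, H3K4me1 = 0.02, H3K27ac = 0.02,
                      H3K9me3 = 1.00))

#' Simulate factor ChIP tracks, peak calls and the MS evidence table
#'
#' Each planted factor binds a random subset of the regions of its class;
#' its reads concentrate there.  Its expected emPAI in each ChIP channel
#' is proportional to the affinity of its class for that channel (times
#' the factor's activity tier for H3K27ac), perturbed by lognormal noise
#' and quantised through the observable-peptide count.  Decoy proteins are
#' planted to exercise each inclusion filter: GFP-sticky background
#' proteins, indiscriminate chromatin binders, and low-Mascot-score
#' identifications.
#'
#' @param genome Output of [make_genome_and_regions()].
#' @param config The [sim_config()].
#' @return A list: \code{truth} (factor_id, class, activity_tier,
#'   expected_included), \code{reads} and \code{peaks} (named per factor),
#'   \code{evidence} (MS evidence data.frame covering factors and decoys),
#'   \code{bound_regions} (named list of region ids),
#'   \code{knockout_factor} (the designated perturbation factor).
#' @export
simulate_factor_data <- function(genome, config) {
  set.seed(child_seed(config$seed, 3))
  r <- genome$regions
  classes <- rownames(CLASS_AFFINITY)
  n_f <- config$n_factors_per_class
  truth <- data.frame(
    factor_id = sprintf("factor_%s_%02d",
                        rep(substr(classes, 1, 4), each = n_f),
                        rep(seq_len(n_f), length(classes))),
    class = rep(classes, each = n_f),
    stringsAsFactors = FALSE)
  reads <- list(); peaks <- list(); bound <- list()
  activity_tier <- numeric(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cls <- truth$class[i]
    ridx <- which(r$class == cls)
    take <- sample(ridx, min(config$n_bound_regions, length(ridx)))
    ## a factor occupies its whole class territory, strongly at a
    ## designated subset (where peaks are called) and weakly elsewhere
    w <- numeric(nrow(r)); w[ridx] <- 0.25; w[take] <- 1
    fid <- truth$factor_id[i]
    bound[[fid]] <- r$region_id[take]
    reads[[fid]] <- draw_reads(config$reads_per_track, genome$seqlengths,
                               r, w, config)
    peaks[[fid]] <- call_planted_peaks(r[take, ], reads[[fid]], 14)
    activity_tier[i] <- mean(r$activity[take])
  }
  truth$activity_tier <- activity_tier
  truth$expected_included <- TRUE

  ev <- list()
  emit <- function(protein, ch, rep_i, target, n_obl, score_fun) {
    n_obs <- round(n_obl * log10(target + 1))
    if (n_obs < 1) return(NULL)
    data.frame(protein_id = protein, channel = ch, replicate = rep_i,
               mascot_score = score_fun(n_obs), n_observed = n_obs,
               n_observable = n_obl, manually_validated = TRUE,
               stringsAsFactors = FALSE)
  }
  hi_score <- function(n_obs) round(35 + 18 * n_obs + runif(1, 0, 10), 1)
  lo_score <- function(n_obs) round(runif(1, 20, 40), 1)
  for (i in seq_len(nrow(truth))) {
    fid <- truth$factor_id[i]
    aff <- CLASS_AFFINITY[truth$class[i], ]
    aff["H3K27ac"] <- aff["H3K27ac"] * truth$activity_tier[i]
    b <- stats::rlnorm(1, log(0.4), 0.5)
    n_obl <- sample(15:60, 1)
    top_ch <- names(aff)[which.max(aff)]
    for (ch in MARK_CHANNELS) {
      for (rep_i in 1:2) {
        target <- b * aff[[ch]] * stats::rlnorm(1, 0, config$empai_sigma)
        if (ch == top_ch)       # planted identifications are never empty
          target <- max(target, (10^(1 / n_obl) - 1) * 1.01)
        ev[[length(ev) + 1]] <- emit(fid, ch, rep_i, target, n_obl,
                                     hi_score)
      }
    }
    for (rep_i in 1:2) {        # GFP background
      target <- b * 0.02 * stats::rlnorm(1, 0, config$empai_sigma)
      ev[[length(ev) + 1]] <- emit(fid, "GFP", rep_i, target, n_obl,
                                   hi_score)
    }
  }
  add_decoys <- function(prefix, n, mark_mult, gfp_mult, score_fun) {
    for (k in seq_len(n)) {
      pid <- sprintf("%s_%02d", prefix, k)
      b <- stats::rlnorm(1, log(0.5), 0.3)
      n_obl <- sample(15:60, 1)
      for (ch in MARK_CHANNELS) for (rep_i in 1:2) {
        target <- b * mark_mult * stats::rlnorm(1, 0, 0.05)
        target <- max(target, (10^(1 / n_obl) - 1) * 1.01)
        ev[[length(ev) + 1]] <<- emit(pid, ch, rep_i, target, n_obl,
                                      score_fun)
      }
      for (rep_i in 1:2) {
        target <- b * gfp_mult * stats::rlnorm(1, 0, 0.05)
        if (gfp_mult > 0)
          target <- max(target, (10^(1 / n_obl) - 1) * 1.01)
        ev[[length(ev) + 1]] <<- emit(pid, "GFP", rep_i, target, n_obl,
                                      score_fun)
      }
    }
  }
  add_decoys("decoy_sticky", 5, mark_mult = 0.5, gfp_mult = 0.6, hi_score)
  add_decoys("decoy_indisc", 5, mark_mult = 0.5, gfp_mult = 0, hi_score)
  add_decoys("decoy_weak", 5, mark_mult = 0.5, gfp_mult = 0, lo_score)
  evidence <- do.call(rbind, ev)
  rownames(evidence) <- NULL
  list(truth = truth, reads = reads, peaks = peaks, evidence = evidence,
       bound_regions = bound, knockout_factor = truth$factor_id[1])
}

#' Simulate the knockout expression experiment and tissue atlas
#'
#' Negative-binomial counts for two wild-type and two knockout replicates
#' with unequal library sizes; a probe-level fold-change table in which
#' planted targets of the knockout factor are down-regulated by the
#' configured log2 fold change with adjusted p-values below 0.10; and a
#' genes x tissues expression atlas in which most target genes reach
#' their maximal expression outside ESCs.
#'
#' @param genome Output of [make_genome_and_regions()].
#' @param factors Output of [simulate_factor_data()].
#' @param config The [sim_config()].
#' @return A list: \code{genes} (gene table with lengths),
#'   \code{probes} (probe-level fold changes), \code{counts} (matrix,
#'   WT1/WT2/KO1/KO2), \code{atlas}, \code{bound_genes},
#'   \code{true_targets}.
#' @export
simulate_expression <- function(genome, factors, config) {
  set.seed(child_seed(config$seed, 4))
  genes <- genome$tss
  kb_regions <- factors$bound_regions[[factors$knockout_factor]]
  bound <- sort(genes$gene_id[genes$region_id %in% kb_regions])
  n_t <- min(config$n_targets, length(bound))
  targets <- sort(sample(bound, n_t))
  lfc <- stats::rnorm(nrow(genes), 0, 0.25)
  names(lfc) <- genes$gene_id
  lfc[targets] <- config$knockout_log2fc +
    stats::rnorm(n_t, 0, 0.15)
  ## probe-level microarray read-out
  n_probes <- sample(1:3, nrow(genes), replace = TRUE)
  probes <- data.frame(
    gene_id = rep(genes$gene_id, n_probes),
    probe_id = sprintf("probe_%05d", seq_len(sum(n_probes))),
    stringsAsFactors = FALSE)
  probes$fold_change <- 2^(lfc[probes$gene_id] +
                             stats::rnorm(nrow(probes), 0, config$probe_sd))
  is_target_probe <- probes$gene_id %in% targets
  probes$adjusted_p <- ifelse(is_target_probe,
                              runif(nrow(probes), 0.001, 0.05),
                              runif(nrow(probes), 0.2, 1))
  ## RNA-seq style counts
  mu <- stats::rlnorm(nrow(genes), log(500), 1)
  sf_true <- c(WT1 = 1, WT2 = 1.3, KO1 = 0.85, KO2 = 1.15)
  size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
  draw <- function(m) if (is.finite(size))
    stats::rnbinom(length(m), mu = m, size = size) else round(m)
  counts <- cbind(WT1 = draw(mu * sf_true["WT1"]),
                  WT2 = draw(mu * sf_true["WT2"]),
                  KO1 = draw(mu * 2^lfc * sf_true["KO1"]),
                  KO2 = draw(mu * 2^lfc * sf_true["KO2"]))
  rownames(counts) <- genes$gene_id
  ## tissue atlas with a designated maximal tissue per gene
  tissues <- c("ESC", "testis", "brain", "liver", "heart", "kidney",
               "lung", "muscle", "spleen", "thymus")[seq_len(config$n_tissues)]
  max_tissue <- ifelse(
    genes$gene_id %in% targets,
    ifelse(runif(nrow(genes)) < 0.6, "testis",
           sample(setdiff(tissues, "ESC"), nrow(genes), replace = TRUE)),
    ifelse(runif(nrow(genes)) < 0.3, "ESC",
           sample(tissues, nrow(genes), replace = TRUE)))
  base <- stats::rlnorm(nrow(genes), log(100), 0.5)
  atlas <- matrix(base * runif(nrow(genes) * length(tissues), 0.1, 0.8),
                  nrow = nrow(genes), ncol = length(tissues),
                  dimnames = list(genes$gene_id, tissues))
  atlas[cbind(seq_len(nrow(genes)), match(max_tissue, tissues))] <-
    base * 5
  list(genes = genes, probes = probes, counts = counts, atlas = atlas,
       bound_genes = bound, true_targets = targets,
       true_log2fc = lfc)
}

#' Generate the complete synthetic dataset
#'
#' Runs all generators under one run seed and returns the in-memory
#' dataset; see [write_sim_dataset()] for the on-disk form.
#'
#' @param config A [sim_config()].
#' @return A list: \code{config}, \code{seqlengths}, \code{regions},
#'   \code{tss}, \code{marks}, \code{factors}, \code{expression}.
#' @export
simulate_dataset <- function(config = sim_config()) {
  genome <- make_genome_and_regions(config)
  marks <- simulate_mark_tracks(genome, config)
  factors <- simulate_factor_data(genome, config)
  expression <- simulate_expression(genome, factors, config)
  list(config = config, seqlengths = genome$seqlengths,
       regions = genome$regions, tss = genome$tss, marks = marks,
       factors = factors, expression = expression)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits genome sizes TSV, TSS BED, region-truth BED, per-track bedGraph
#' coverage and BED reads, narrowPeak calls, the MS evidence TSV, counts
#' and atlas TSVs and a truth JSON.  Two runs with the same configuration
#' produce byte-identical files.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @param tracks Which factor tracks to write (default: none, marks only;
#'   the full factor set can be large).
#' @return The directory, invisibly.
#' @export
write_sim_dataset <- function(sim, dir, tracks = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_genome_sizes(sim$seqlengths, p("genome.sizes.tsv"))
  write_tss_bed(sim$tss, p("tss.bed"))
  reg <- sim$regions
  utils::write.table(
    data.frame(reg$chrom, reg$start, reg$end, reg$region_id,
               round(reg$activity, 4), ".", reg$class),
    p("regions.truth.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  for (nm in names(sim$marks$reads)) {
    write_coverage_bedgraph(sim$marks$reads[[nm]], sim$seqlengths,
                            p(paste0(nm, ".bedgraph")))
    if (nm != "input")
      write_narrowpeak(sim$marks$peaks[[nm]],
                       p(paste0(nm, ".narrowPeak")))
  }
  for (nm in intersect(tracks, names(sim$factors$reads))) {
    write_coverage_bedgraph(sim$factors$reads[[nm]], sim$seqlengths,
                            p(paste0(nm, ".bedgraph")))
    write_narrowpeak(sim$factors$peaks[[nm]], p(paste0(nm, ".narrowPeak")))
  }
  utils::write.table(sim$factors$evidence, p("ms_evidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = rownames(sim$expression$counts),
                                sim$expression$counts),
                     p("counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(gene_id = rownames(sim$expression$atlas),
                                sim$expression$atlas),
                     p("atlas.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$expression$probes, p("probes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(factors = sim$factors$truth,
                knockout_factor = sim$factors$knockout_factor,
                bound_genes = sim$expression$bound_genes,
                true_targets = sim$expression$true_targets)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             p("truth.json"))
  invisible(dir)
}
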