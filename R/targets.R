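## Bound-gene and target-gene calling, expression normalisation and the
## summary statistics used to compare target-gene sets (median expression,
## rank tests, tissue-of-maximal-expression enrichment).

#' Genes bound by a factor (peak summit near a TSS)
#'
#' A gene is bound when at least one filtered peak summit lies within
#' \code{tss_window} bp (inclusive) of any of its transcription start
#' sites.
#'
#' @param peaks Filtered peak table.
#' @param genes Gene table with columns \code{gene_id, chrom, tss}
#'   (1-based TSS position); a gene may have several TSS rows.
#' @param tss_window Window in bp (e.g. 1000 for promoter-proximal
#'   binding, 20000 for a distal binder).
#' @return Character vector of bound gene ids (sorted, unique).
#' @export
bound_genes <- function(peaks, genes, tss_window) {
  stopifnot(tss_window > 0)
  if (nrow(peaks) == 0 || nrow(genes) == 0) return(character())
  tssg <- tss_granges(genes)
  win <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(pmax(1L, peaks$summit + 1L - tss_window),
                                  peaks$summit + 1L + tss_window))
  hits <- GenomicRanges::findOverlaps(tssg, win)
  sort(unique(genes$gene_id[unique(S4Vectors::queryHits(hits))]))
}

#' Aggregate probe-level fold changes to genes
#'
#' Multiple array probes mapping to the same gene are aggregated by
#' averaging their fold changes; the adjusted p-value of the most
#' significant probe is carried along.
#'
#' @param probes Data.frame with columns \code{gene_id, fold_change,
#'   adjusted_p}.
#' @return One row per gene: \code{gene_id, fold_change, adjusted_p}.
#' @export
aggregate_probes <- function(probes) {
  stopifnot(all(c("gene_id", "fold_change") %in% names(probes)))
  fc <- tapply(probes$fold_change, probes$gene_id, mean)
  adjp <- if (!is.null(probes$adjusted_p))
    tapply(probes$adjusted_p, probes$gene_id, min)
  else rep(NA_real_, length(fc))
  data.frame(gene_id = names(fc), fold_change = as.numeric(fc),
             adjusted_p = as.numeric(adjp[names(fc)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Target genes: bound genes with a significant expression response
#'
#' A bound gene is a target when its (probe-aggregated) expression changes
#' at least \code{min_fold}-fold upon perturbation of the factor
#' (two-sided by default, or restricted to one direction) and, when
#' \code{max_adj_p} is given, its adjusted p-value is at most that cut.
#' Fold changes are perturbed-over-reference ratios.
#'
#' @param bound Character vector of bound gene ids.
#' @param gene_fc Gene-level table from [aggregate_probes()] (columns
#'   \code{gene_id, fold_change, adjusted_p}).
#' @param min_fold Minimum fold difference (default 2).
#' @param max_adj_p Adjusted p-value cut (default 0.10); \code{NULL} to
#'   skip the significance requirement.
#' @param direction \code{"both"}, \code{"down"} or \code{"up"}.
#' @return Character vector of target gene ids (sorted).
#' @export
target_genes <- function(bound, gene_fc, min_fold = 2, max_adj_p = 0.10,
                         direction = c("both", "down", "up")) {
  direction <- match.arg(direction)
  stopifnot(min_fold >= 1)
  g <- gene_fc[gene_fc$gene_id %in% bound, , drop = FALSE]
  if (nrow(g) == 0) return(character())
  if (any(!is.na(g$fold_change) & g$fold_change <= 0))
    stop("fold_change must be positive")
  lfc <- log2(g$fold_change)
  hit <- !is.na(lfc) & abs(lfc) >= log2(min_fold)
  hit <- hit & switch(direction, both = TRUE, down = lfc < 0, up = lfc > 0)
  if (!is.null(max_adj_p))
    hit <- hit & !is.na(g$adjusted_p) & g$adjusted_p <= max_adj_p
  sort(g$gene_id[hit])
}

#' Median-of-ratios size factors
#'
#' For each replicate, the median over genes of the ratio of its counts to
#' a geometric-mean pseudo-reference, computed over genes with positive
#' counts in every replicate.  This is the standard library-size estimator
#' for count matrices that is robust to a minority of differentially
#' expressed genes.
#'
#' @param counts Numeric matrix, genes x replicates.
#' @return Positive numeric vector of per-replicate size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1) return(stats::setNames(1, colnames(counts)))
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok))
    stop("no gene has positive counts in every replicate")
  logref <- rowMeans(log(counts[ok, , drop = FALSE]))
  sf <- apply(counts[ok, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - logref)))
  if (any(sf <= 0)) stop("nonpositive size factor")
  sf
}

#' Normalised expression as reads per kilobase
#'
#' Counts are divided by their size factors, averaged over replicates, and
#' scaled by gene length: \code{mean(norm counts) * 1000 / length}.
#'
#' @param counts Genes x replicates count matrix (rownames = gene ids).
#' @param lengths Named vector of gene lengths in bp.
#' @param sf Size factors; computed with [size_factors()] when NULL.
#' @return Named numeric vector of reads-per-kb values.
#' @export
reads_per_kb <- function(counts, lengths, sf = NULL) {
  counts <- as.matrix(counts)
  if (is.null(sf)) sf <- size_factors(counts)
  lengths <- lengths[rownames(counts)]
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("every gene needs a positive length")
  norm <- sweep(counts, 2, sf, "/")
  rowMeans(norm) * 1000 / lengths
}

#' Compare expression between two gene sets
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparison of an expression
#' measure between two gene sets: exact when both sets have at most
#' \code{exact_max} genes and there are no ties, otherwise the
#' tie-corrected normal approximation.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param expr Named numeric vector (e.g. from [reads_per_kb()]).
#' @param exact_max Largest set size for the exact test (default 20).
#' @return A list: per-set \code{n} and \code{median}, the
#'   \code{median_ratio} (b over a) and the Mann-Whitney \code{p_value}.
#' @export
compare_expression <- function(set_a, set_b, expr, exact_max = 20) {
  xa <- expr[intersect(set_a, names(expr))]
  xb <- expr[intersect(set_b, names(expr))]
  if (length(xa) == 0 || length(xb) == 0) stop("empty gene set")
  exact <- max(length(xa), length(xb)) <= exact_max &&
    !anyDuplicated(c(xa, xb))
  p <- stats::wilcox.test(xa, xb, alternative = "two.sided",
                          exact = exact)$p.value
  list(n_a = length(xa), n_b = length(xb),
       median_a = stats::median(xa), median_b = stats::median(xb),
       median_ratio = stats::median(xb) / stats::median(xa),
       p_value = p)
}

#' Tissue of maximal expression per gene
#'
#' @param atlas Genes x tissues expression matrix (rownames = gene ids).
#' @return Named character vector: for each gene, the tissue with the
#'   highest expression (first column wins ties).
#' @export
tissue_of_max <- function(atlas) {
  atlas <- as.matrix(atlas)
  stats::setNames(colnames(atlas)[apply(atlas, 1, which.max)],
                  rownames(atlas))
}

#' Fold change in the maximally expressing tissue over a reference tissue
#'
#' For each gene, the highest expression among non-reference tissues
#' divided by its expression in the reference tissue (e.g. ESCs).
#'
#' @param gene_set Gene ids (default: all atlas genes).
#' @param atlas Genes x tissues matrix.
#' @param reference Reference tissue column name.
#' @return Named numeric vector of fold changes.
#' @export
fold_to_max_tissue <- function(atlas, gene_set = rownames(atlas),
                               reference = "ESC") {
  atlas <- as.matrix(atlas)
  if (!reference %in% colnames(atlas))
    stop("reference tissue not in atlas")
  gene_set <- intersect(gene_set, rownames(atlas))
  other <- atlas[gene_set, setdiff(colnames(atlas), reference),
                 drop = FALSE]
  apply(other, 1, max) / atlas[gene_set, reference]
}

#' Enrichment of tissues-of-maximal-expression within a gene set
#'
#' For each tissue, the number of set genes maximally expressed there and
#' the fold enrichment over the atlas-wide expectation:
#' \code{FE = (fraction of set maximal in tissue) / (fraction of all atlas
#' genes maximal in tissue)}.
#'
#' @param gene_set Character vector of gene ids.
#' @param atlas Genes x tissues matrix.
#' @return A data.frame \code{tissue, n, fold_enrichment}, ordered by
#'   decreasing \code{n} then tissue name.
#' @export
tissue_enrichment <- function(gene_set, atlas) {
  gene_set <- intersect(gene_set, rownames(atlas))
  if (length(gene_set) == 0) stop("empty gene set")
  maxt <- tissue_of_max(atlas)
  bg <- table(factor(maxt, levels = colnames(atlas)))
  fg <- table(factor(maxt[gene_set], levels = colnames(atlas)))
  fe <- (as.numeric(fg) / length(gene_set)) /
    (as.numeric(bg) / nrow(atlas))
  out <- data.frame(tissue = colnames(atlas), n = as.integer(fg),
                    fold_enrichment = fe, stringsAsFactors = FALSE)
  out <- out[order(-out$n, out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full expression summary for one or more gene sets
#'
#' Convenience wrapper producing, for each named gene set, its size and
#' median reads-per-kb, pairwise Mann-Whitney comparisons between
#' consecutive sets, and (when an atlas is supplied) the
#' tissue-of-maximal-expression enrichment table.
#'
#' @param gene_sets Named list of gene-id vectors.
#' @param counts Genes x replicates count matrix.
#' @param lengths Named gene lengths (bp).
#' @param atlas Optional genes x tissues matrix.
#' @return A list with \code{rpk}, \code{set_summary},
#'   \code{comparisons} and \code{tissue_tables}.
#' @export
expression_summaries <- function(gene_sets, counts, lengths, atlas = NULL) {
  rpk <- reads_per_kb(counts, lengths)
  set_summary <- data.frame(
    set = names(gene_sets),
    n = vapply(gene_sets, function(g)
      length(intersect(g, names(rpk))), integer(1)),
    median_rpk = vapply(gene_sets, function(g)
      stats::median(rpk[intersect(g, names(rpk))]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  comparisons <- list()
  if (length(gene_sets) >= 2) {
    for (i in seq_len(length(gene_sets) - 1)) {
      nm <- paste(names(gene_sets)[i], "vs", names(gene_sets)[i + 1])
      comparisons[[nm]] <- compare_expression(gene_sets[[i]],
                                              gene_sets[[i + 1]], rpk)
    }
  }
  tissue_tables <- if (!is.null(atlas))
    lapply(gene_sets, tissue_enrichment, atlas = atlas) else NULL
  list(rpk = rpk, set_summary = set_summary, comparisons = comparisons,
       tissue_tables = tissue_tables)
}
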