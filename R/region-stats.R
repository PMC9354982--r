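#' Normalize counts for rank-based testing
#'
#' Per-spot total-count scaling to the median library size. The downstream
#' rank-sum test is invariant to the subsequent log1p transform, and fold
#' changes are taken on the normalized-count scale, so the linear matrix is
#' returned.
#' @param counts Sparse transcripts-by-spots matrix.
#' @return Dense normalized matrix.
#' @keywords internal
normalize_depth <- function(counts) {
  lib <- Matrix::colSums(counts)
  med <- stats::median(lib[lib > 0])
  sf <- ifelse(lib > 0, med / lib, 0)
  as.matrix(counts %*% Matrix::Diagonal(x = sf))
}

#' Region marker detection by rank-sum test
#'
#' For every feature and region, a two-sided Wilcoxon rank-sum test (normal
#' approximation with tie correction) of normalized expression in the region
#' against all other spots, Benjamini-Hochberg adjusted within each region's
#' family. The fold change is the log2 ratio of normalized means with a
#' pseudo-count of 1. Constant features get `p = 1` and zero fold change by
#' convention.
#'
#' @param mat A `spot_matrix` with region labels in `spot_meta$region`.
#' @return `data.frame` with `feature_id`, `region`, `log2_fold_change`,
#'   `p_value`, `bh_adjusted_p`.
#' @export
rank_sum_markers <- function(mat) {
  region <- mat$spot_meta$region
  if (length(unique(region)) < 2) stopf("at least two regions required")
  small <- names(which(table(region) < 2))
  if (length(small)) stopf("region '%s' has fewer than 2 spots", small[1])
  x <- normalize_depth(mat$counts)
  feat <- mat$tx_meta$transcript_id
  out <- list()
  for (r in unique(region)) {
    inr <- region == r
    p <- numeric(nrow(x)); lfc <- numeric(nrow(x))
    for (i in seq_len(nrow(x))) {
      a <- x[i, inr]; b <- x[i, !inr]
      if (max(c(a, b)) == min(c(a, b))) {
        p[i] <- 1; lfc[i] <- 0
      } else {
        p[i] <- stats::wilcox.test(a, b, exact = FALSE)$p.value
        lfc[i] <- log2((mean(a) + 1) / (mean(b) + 1))
      }
    }
    out[[r]] <- data.frame(feature_id = feat, region = r,
                           log2_fold_change = lfc, p_value = p,
                           bh_adjusted_p = stats::p.adjust(p, "BH"),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select per-region transcripts from the marker table
#'
#' Transcripts with `log2_fold_change > logfc_min` and raw `p < p_max` (the
#' selection the class-enrichment step consumes); set `use_adjusted = TRUE`
#' to threshold the BH-adjusted p instead.
#'
#' @param markers Output of [rank_sum_markers()].
#' @param logfc_min,p_max Selection thresholds (defaults 0.1 and 0.05).
#' @param use_adjusted Use `bh_adjusted_p` instead of `p_value`.
#' @return Named list region -> character vector of feature ids.
#' @export
select_region_transcripts <- function(markers, logfc_min = 0.1, p_max = 0.05,
                                      use_adjusted = FALSE) {
  if (!nrow(markers)) return(stats::setNames(list(), character(0)))
  p <- if (use_adjusted) markers$bh_adjusted_p else markers$p_value
  keep <- markers$log2_fold_change > logfc_min & p < p_max
  lapply(split(markers$feature_id[keep], markers$region[keep]), unique)
}

#' Transcript-class enrichment between region sets
#'
#' Fisher exact test of a 2x2 table crossing (target class vs other classes)
#' with (foreground vs background regions), over the region-selected
#' transcripts. Exact-match (`=`) transcripts are excluded before tabulation,
#' per the non-equality convention. The odds ratio is the sample odds ratio
#' `(a d) / (b c)`.
#'
#' @param selected Named list region -> transcript ids
#'   ([select_region_transcripts()]).
#' @param classes Named character vector transcript id -> class code.
#' @param target_class Class code(s) of interest, e.g. `c("m", "n")` for
#'   intron retention.
#' @param foreground_regions,background_regions Disjoint region sets.
#' @return List of class `enrichment_result` with `contingency`,
#'   `odds_ratio`, `p_value`.
#' @export
class_enrichment <- function(selected, classes, target_class,
                             foreground_regions, background_regions) {
  if (length(intersect(foreground_regions, background_regions)))
    stopf("foreground and background regions must be disjoint")
  pick <- function(regions) {
    tx <- unique(unlist(selected[regions], use.names = FALSE))
    cl <- classes[tx]
    cl[!is.na(cl) & cl != "="]
  }
  fg <- pick(foreground_regions)
  bg <- pick(background_regions)
  a <- sum(fg %in% target_class); b <- length(fg) - a
  cc <- sum(bg %in% target_class); d <- length(bg) - cc
  tab <- matrix(c(a, b, cc, d), nrow = 2,
                dimnames = list(class = c("target", "other"),
                                regions = c("foreground", "background")))
  or <- (a * d) / (b * cc)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else stats::fisher.test(tab)$p.value
  structure(list(target_class = target_class,
                 foreground_regions = foreground_regions,
                 background_regions = background_regions,
                 contingency = tab,
                 odds_ratio = if (degenerate) NA_real_ else or,
                 p_value = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> class %s: %s vs %s\n",
              paste(x$target_class, collapse = "/"),
              paste(x$foreground_regions, collapse = "+"),
              paste(x$background_regions, collapse = "+")))
  print(x$contingency)
  cat(sprintf("  odds ratio %.3g, p = %.3g\n", x$odds_ratio, x$p_value))
  invisible(x)
}

#' Compare isoform diversity between regions
#'
#' Per region, counts the number of distinct detected isoforms per gene among
#' the region-selected transcripts, then compares every pair of regions with
#' a two-sided Mann-Whitney U test (normal approximation, tie and continuity
#' correction). Pairs where either region has fewer than 2 genes are flagged
#' and skipped; regions with no genes are dropped with a warning.
#'
#' @param gene_map Named list gene id -> transcript ids (or a catalog
#'   annotation `data.frame` with `gene_id` and `transcript_id`).
#' @param selected Named list region -> transcript ids.
#' @return `data.frame` of pairwise comparisons with per-region mean isoforms
#'   per gene, U statistic and p-value.
#' @export
isoform_diversity_test <- function(gene_map, selected) {
  if (is.data.frame(gene_map))
    gene_map <- split(gene_map$transcript_id, gene_map$gene_id)
  tx2gene <- stats::setNames(rep(names(gene_map), lengths(gene_map)),
                             unlist(gene_map, use.names = FALSE))
  per_region <- lapply(selected, function(tx) {
    g <- tx2gene[tx]
    g <- g[!is.na(g)]
    if (!length(g)) return(integer(0))
    as.integer(table(g))
  })
  empty <- names(per_region)[lengths(per_region) == 0]
  if (length(empty)) {
    warning("regions with no detected genes excluded: ",
            paste(empty, collapse = ", "), call. = FALSE)
    per_region <- per_region[lengths(per_region) > 0]
  }
  regs <- names(per_region)
  if (length(regs) < 2)
    return(data.frame(region_a = character(0), region_b = character(0)))
  pairs <- utils::combn(regs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    ra <- pairs[1, k]; rb <- pairs[2, k]
    a <- per_region[[ra]]; b <- per_region[[rb]]
    skip <- length(a) < 2 || length(b) < 2
    if (!skip) {
      if (max(c(a, b)) == min(c(a, b))) {
        u <- length(a) * length(b) / 2; p <- 1
      } else {
        wt <- stats::wilcox.test(a, b, exact = FALSE)
        u <- unname(wt$statistic); p <- wt$p.value
      }
    } else { u <- NA_real_; p <- NA_real_ }
    data.frame(region_a = ra, region_b = rb,
               n_genes_a = length(a), n_genes_b = length(b),
               mean_isoforms_a = mean(a), mean_isoforms_b = mean(b),
               u_statistic = u, p_value = p, skipped = skip,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
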