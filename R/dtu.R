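#' Differential transcript usage design
#'
#' A two-group contrast between disjoint, non-empty spot sets.
#'
#' @param group_a,group_b Character vectors of spot barcodes.
#' @param name_a,name_b Group labels.
#' @return An object of class `dtu_design`.
#' @export
dtu_design <- function(group_a, group_b, name_a = "A", name_b = "B") {
  if (!length(group_a) || !length(group_b))
    stopf("both design groups must be non-empty")
  if (length(intersect(group_a, group_b)))
    stopf("design groups must be disjoint")
  structure(list(group_a = group_a, group_b = group_b,
                 name_a = name_a, name_b = name_b,
                 contrast = paste0(name_a, ":", name_b)),
            class = "dtu_design")
}

#' Build a design from region labels
#'
#' `contrast` is `"regionA:regionB"` for a pairwise comparison or
#' `"regionA:rest"` to compare one region against all others.
#'
#' @param mat A `spot_matrix` with `spot_meta$region`.
#' @param contrast Contrast string.
#' @export
design_from_regions <- function(mat, contrast) {
  parts <- strsplit(contrast, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stopf("contrast must be 'A:B' or 'A:rest'")
  region <- mat$spot_meta$region
  bc <- mat$spot_meta$barcode
  a <- bc[region == parts[1]]
  b <- if (parts[2] == "rest") bc[region != parts[1]] else bc[region == parts[2]]
  dtu_design(a, b, parts[1], parts[2])
}

#' Filter transcripts for differential usage testing
#'
#' Keeps multi-exon transcripts of genes that retain at least two isoforms,
#' expressed above the counts-per-million threshold `1e6 / median library
#' size` in at least `max(min_spots, 10%% of the smallest group)` design
#' spots, and with a total count of at least `min_total`. The two-isoform
#' rule is re-checked after each removal pass until a fixed point.
#'
#' @param mat A `spot_matrix` with `gene_id` and `n_exons` metadata.
#' @param design A [dtu_design()].
#' @param min_frac Minimum expressed-spot fraction of the smallest group
#'   (default 0.10).
#' @param min_spots Floor on the expressed-spot requirement (default 2).
#' @param min_total Minimum total count (default 1).
#' @return Character vector of retained transcript ids.
#' @export
filter_dtu_input <- function(mat, design, min_frac = 0.10, min_spots = 2,
                             min_total = 1) {
  spots <- c(design$group_a, design$group_b)
  miss <- setdiff(spots, mat$spot_meta$barcode)
  if (length(miss)) stopf("design spots absent from matrix: %s", miss[1])
  sub <- mat$counts[, match(spots, mat$spot_meta$barcode), drop = FALSE]
  lib <- Matrix::colSums(sub)
  cpm_thr <- 1e6 / stats::median(lib[lib > 0])
  cpm <- Matrix::t(Matrix::t(sub) * ifelse(lib > 0, 1e6 / lib, 0))
  n_req <- max(min_spots,
               ceiling(min_frac * min(length(design$group_a),
                                      length(design$group_b))))
  keep <- !is.na(mat$tx_meta$n_exons) & mat$tx_meta$n_exons >= 2
  keep <- keep & Matrix::rowSums(cpm > cpm_thr) >= n_req
  keep <- keep & Matrix::rowSums(sub) >= min_total
  gene <- mat$tx_meta$gene_id
  repeat {
    tab <- table(gene[keep])
    drop <- keep & gene %in% names(tab)[tab < 2]
    if (!any(drop)) break
    keep <- keep & !drop
  }
  mat$tx_meta$transcript_id[keep]
}

# Vectorized two-group quasi-binomial fit; K and N are dense transcripts x
# spots matrices of transcript counts and gene totals. The group-saturated
# logit model has a closed-form maximum likelihood fit (the IRLS fixed
# point): fitted usage per group is the pooled proportion. Pearson dispersion
# is floored at 1 and scales the Wald standard error; df = n_used - 2.
fit_two_group_all <- function(K, N, in_b) {
  used <- N > 0
  nA_spots <- rowSums(used[, !in_b, drop = FALSE])
  nB_spots <- rowSums(used[, in_b, drop = FALSE])
  bad <- nA_spots < 2 | nB_spots < 2
  ka <- rowSums(K[, !in_b, drop = FALSE]); na <- rowSums(N[, !in_b, drop = FALSE])
  kb <- rowSums(K[, in_b, drop = FALSE]); nb <- rowSums(N[, in_b, drop = FALSE])
  sep <- ka == 0 | ka == na | kb == 0 | kb == nb
  ka <- ka + 0.5 * sep; na <- na + sep
  kb <- kb + 0.5 * sep; nb <- nb + sep
  pa <- ka / na; pb <- kb / nb
  lor <- stats::qlogis(pb) - stats::qlogis(pa)
  se0 <- sqrt(1 / (na * pa * (1 - pa)) + 1 / (nb * pb * (1 - pb)))
  fit <- matrix(pa, nrow(K), ncol(K))
  fit[, in_b] <- matrix(pb, nrow(K), sum(in_b))
  term <- (K - N * fit)^2 / (N * fit * (1 - fit))
  term[!used] <- 0
  df <- rowSums(used) - 2L
  disp <- pmax(1, rowSums(term) / df)
  se <- se0 * sqrt(disp)
  t <- lor / se
  p <- 2 * stats::pt(-abs(t), df)
  p[bad | df <= 0] <- 1
  lor[bad] <- NA_real_
  data.frame(log_odds_ratio = lor, std_error = se, t_statistic = t,
             df = as.integer(df), dispersion = disp, p_value = p,
             flagged = bad | sep | df <= 0)
}

# Scalar wrapper used by fit_usage_glm.
fit_two_group <- function(k, n, in_b, haldane_flag = FALSE) {
  use <- n > 0
  if (sum(use & !in_b) < 2 || sum(use & in_b) < 2)
    return(list(lor = NA_real_, se = NA_real_, t = NA_real_,
                df = NA_integer_, dispersion = NA_real_, p = 1,
                flagged = TRUE))
  k <- k[use]; n <- n[use]; g <- in_b[use]
  ka <- sum(k[!g]); na <- sum(n[!g])
  kb <- sum(k[g]); nb <- sum(n[g])
  flagged <- FALSE
  if (ka == 0 || ka == na || kb == 0 || kb == nb) {
    # separation: Haldane-Anscombe 0.5 adjustment on the aggregated table
    ka <- ka + 0.5; na <- na + 1
    kb <- kb + 0.5; nb <- nb + 1
    flagged <- TRUE
  }
  pa <- ka / na; pb <- kb / nb
  lor <- stats::qlogis(pb) - stats::qlogis(pa)
  se0 <- sqrt(1 / (na * pa * (1 - pa)) + 1 / (nb * pb * (1 - pb)))
  fit <- ifelse(g, pb, pa)
  pear <- (k - n * fit)^2 / (n * fit * (1 - fit))
  df <- length(k) - 2L
  disp <- max(1, sum(pear) / df)
  se <- se0 * sqrt(disp)
  t <- lor / se
  list(lor = lor, se = se, t = t, df = df, dispersion = disp,
       p = 2 * stats::pt(-abs(t), df), flagged = flagged)
}

#' Quasi-binomial usage model for one transcript
#'
#' The response per spot is (transcript count, gene total minus transcript
#' count) with a logit link and a two-level group covariate; the reported
#' effect is the log-odds ratio of usage in group B versus group A. The
#' standard error is scaled by the square root of the Pearson dispersion
#' (floored at 1); inference uses a t distribution on `n - 2` degrees of
#' freedom. Complete separation (usage 0 or 1 in a group) triggers a
#' Haldane-Anscombe 0.5 adjustment and a flag; fewer than two usable spots in
#' a group yields a flagged result with `p = 1`.
#'
#' @param mat A `spot_matrix`.
#' @param design A [dtu_design()].
#' @param transcript Transcript id.
#' @param retained Transcript ids defining the gene total (default: all of
#'   the gene's transcripts present in the matrix).
#' @return One-row `data.frame` with `gene_id`, `transcript_id`,
#'   `log_odds_ratio`, `std_error`, `t_statistic`, `df`, `dispersion`,
#'   `p_value`, `flagged`.
#' @export
fit_usage_glm <- function(mat, design, transcript, retained = NULL) {
  ti <- match(transcript, mat$tx_meta$transcript_id)
  if (is.na(ti)) stopf("transcript %s not in matrix", transcript)
  gene <- mat$tx_meta$gene_id[ti]
  fam <- which(mat$tx_meta$gene_id == gene &
                 (is.null(retained) | mat$tx_meta$transcript_id %in% retained))
  spots <- c(design$group_a, design$group_b)
  js <- match(spots, mat$spot_meta$barcode)
  k <- as.numeric(mat$counts[ti, js])
  n <- Matrix::colSums(mat$counts[fam, js, drop = FALSE])
  in_b <- spots %in% design$group_b
  f <- fit_two_group(k, n, in_b)
  data.frame(gene_id = gene, transcript_id = transcript,
             log_odds_ratio = f$lor, std_error = f$se, t_statistic = f$t,
             df = f$df, dispersion = f$dispersion, p_value = f$p,
             flagged = f$flagged, stringsAsFactors = FALSE)
}

#' Stage-wise adjustment at a target overall FDR
#'
#' Stage 1 screens genes on the Sidak-corrected minimum transcript p-value
#' (`1 - (1 - min p)^T`; Bonferroni available), Benjamini-Hochberg adjusted
#' across genes at `ofdr`. Stage 2 confirms transcripts within screened genes
#' with a Holm correction at `ofdr`. A transcript is `confirmed` when it
#' passes both stages.
#'
#' @param results `data.frame` with `gene_id`, `transcript_id`, `p_value`.
#' @param ofdr Target overall false discovery rate (default 0.05).
#' @param screen_method `"sidak"` (default) or `"bonferroni"`.
#' @return `results` with added `gene_screen_p`, `gene_screen_bh`,
#'   `screened`, `stage2_adjusted_p`, `confirmed`.
#' @export
stagewise_adjust <- function(results, ofdr = 0.05,
                             screen_method = c("sidak", "bonferroni")) {
  screen_method <- match.arg(screen_method)
  if (!nrow(results)) {
    results$gene_screen_p <- numeric(0); results$gene_screen_bh <- numeric(0)
    results$screened <- logical(0); results$stage2_adjusted_p <- numeric(0)
    results$confirmed <- logical(0)
    return(results)
  }
  if (anyNA(results$p_value)) stopf("all results must carry a valid p-value")
  by_gene <- split(seq_len(nrow(results)), results$gene_id)
  screen <- vapply(by_gene, function(idx) {
    minp <- min(results$p_value[idx]); T <- length(idx)
    if (screen_method == "sidak") 1 - (1 - minp)^T else min(1, T * minp)
  }, numeric(1))
  screen_bh <- stats::p.adjust(screen, "BH")
  screened_gene <- screen_bh <= ofdr
  results$gene_screen_p <- screen[match(results$gene_id, names(by_gene))]
  results$gene_screen_bh <- screen_bh[match(results$gene_id, names(by_gene))]
  results$screened <- screened_gene[match(results$gene_id, names(by_gene))]
  results$stage2_adjusted_p <- NA_real_
  for (g in names(by_gene)[screened_gene]) {
    idx <- by_gene[[g]]
    results$stage2_adjusted_p[idx] <- stats::p.adjust(results$p_value[idx],
                                                      "holm")
  }
  results$confirmed <- results$screened &
    !is.na(results$stage2_adjusted_p) & results$stage2_adjusted_p <= ofdr
  results
}

#' Call isoform switches among confirmed transcripts
#'
#' A gene switches when at least two confirmed transcripts in the same
#' contrast have opposite-sign log-odds ratios.
#'
#' @param results Output of [stagewise_adjust()] (one contrast).
#' @return `data.frame` with one row per switching gene: the confirmed
#'   transcripts and their log-odds ratios (comma-separated).
#' @export
detect_switches <- function(results) {
  conf <- results[results$confirmed & !is.na(results$log_odds_ratio), ,
                  drop = FALSE]
  rows <- lapply(split(conf, conf$gene_id), function(d) {
    if (nrow(d) < 2 || !any(d$log_odds_ratio > 0) ||
        !any(d$log_odds_ratio < 0)) return(NULL)
    data.frame(gene_id = d$gene_id[1], n_confirmed = nrow(d),
               transcripts = paste(d$transcript_id, collapse = ","),
               log_odds_ratios = paste(sprintf("%.4g", d$log_odds_ratio),
                                       collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(gene_id = character(0), n_confirmed = integer(0),
                      transcripts = character(0),
                      log_odds_ratios = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize switch calls across contrasts
#'
#' Per-contrast switching-gene counts (the region-by-region heatmap input)
#' plus the total across contrasts, both with and without deduplicating genes
#' that switch in several contrasts.
#'
#' @param switches Named list of [detect_switches()] tables (or [run_dtu()]
#'   outputs), one per contrast.
#' @return List with `per_contrast` (`data.frame` of contrast, n_genes),
#'   `total` and `total_unique_genes`.
#' @export
switch_summary <- function(switches) {
  tabs <- lapply(switches, function(s) if (is.list(s) && !is.data.frame(s))
    s$switches else s)
  per <- data.frame(contrast = names(tabs) %||% seq_along(tabs),
                    n_genes = vapply(tabs, nrow, integer(1)),
                    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  list(per_contrast = per, total = sum(per$n_genes),
       total_unique_genes = length(unique(unlist(
         lapply(tabs, `[[`, "gene_id")))))
}

#' Differential transcript usage between regions
#'
#' Filters transcripts ([filter_dtu_input()]), fits the quasi-binomial usage
#' model per retained transcript, applies the stage-wise adjustment and calls
#' isoform switches.
#'
#' @param mat A `spot_matrix` with region labels.
#' @param contrast Contrast string (`"A:B"` or `"A:rest"`), or a
#'   [dtu_design()].
#' @param ofdr Target overall FDR (default 0.05).
#' @param ... Passed to [filter_dtu_input()].
#' @return List with `results`, `switches` and the `design`.
#' @export
run_dtu <- function(mat, contrast, ofdr = 0.05, ...) {
  design <- if (inherits(contrast, "dtu_design")) contrast
            else design_from_regions(mat, contrast)
  retained <- filter_dtu_input(mat, design, ...)
  if (!length(retained))
    return(list(results = data.frame(), switches = data.frame(),
                design = design))
  spots <- c(design$group_a, design$group_b)
  js <- match(spots, mat$spot_meta$barcode)
  in_b <- spots %in% design$group_b
  ti <- match(retained, mat$tx_meta$transcript_id)
  gene <- mat$tx_meta$gene_id[ti]
  K <- as.matrix(mat$counts[ti, js, drop = FALSE])
  N <- rowsum(K, gene)[gene, , drop = FALSE]  # gene totals over retained
  fits <- fit_two_group_all(K, N, in_b)
  results <- cbind(data.frame(gene_id = gene, transcript_id = retained,
                              stringsAsFactors = FALSE), fits)
  results <- stagewise_adjust(results, ofdr)
  results$contrast <- design$contrast
  list(results = results, switches = detect_switches(results),
       design = design)
}
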