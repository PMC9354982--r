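usage_flip <- list(A = list(g1 = c(0.8, 0.2)), B = list(g1 = c(0.2, 0.8)))

test_that("design construction validates groups", {
  expect_error(dtu_design(character(0), "s1"), "non-empty")
  expect_error(dtu_design(c("s1", "s2"), c("s2", "s3")), "disjoint")
  cm <- simulate_counts(list(g1 = c("t1", "t2")), c("A", "B", "C"), 4,
                        depth = 20, seed = 1)
  d <- design_from_regions(cm, "A:rest")
  expect_equal(length(d$group_a), 4)
  expect_equal(length(d$group_b), 8)
})

test_that("input filtering applies the multi-exon, expression and gene rules", {
  counts <- rbind(t1 = c(20, 20, 20, 20), t2 = c(10, 10, 10, 10),
                  t3 = c(15, 15, 15, 15), t4 = c(0, 0, 0, 0),
                  t5 = c(12, 12, 12, 12), t6 = c(14, 14, 14, 14))
  m <- toy_matrix(counts, regions = rep(c("A", "B"), each = 2),
                  gene_id = c("g1", "g1", "g2", "g2", "g3", "g3"),
                  n_exons = c(2L, 2L, 2L, 2L, 1L, 2L))
  d <- design_from_regions(m, "A:B")
  kept <- filter_dtu_input(m, d, min_spots = 2)
  # g1 keeps both isoforms; g2 loses t4 (all zero) hence g2 entirely;
  # g3's t5 is single-exon, so g3 collapses to one isoform and is dropped
  expect_equal(sort(kept), c("t1", "t2"))
})

test_that("two-group closed form reproduces the aggregated log-odds example", {
  counts <- rbind(t1 = c(15, 15, 5, 5), t2 = c(15, 15, 20, 20))
  m <- toy_matrix(counts, regions = rep(c("A", "B"), each = 2),
                  gene_id = c("g1", "g1"))
  d <- design_from_regions(m, "A:B")
  f <- fit_usage_glm(m, d, "t1")
  expect_equal(f$log_odds_ratio, -log(4), tolerance = 1e-8)
  expect_equal(f$df, 2L)

  # identical usage in both groups: LOR 0, t 0, p 1
  counts0 <- rbind(t1 = c(5, 5, 5, 5), t2 = c(5, 5, 5, 5))
  m0 <- toy_matrix(counts0, regions = rep(c("A", "B"), each = 2),
                   gene_id = c("g1", "g1"))
  f0 <- fit_usage_glm(m0, design_from_regions(m0, "A:B"), "t1")
  expect_equal(f0$log_odds_ratio, 0)
  expect_equal(f0$t_statistic, 0)
  expect_equal(f0$p_value, 1)
})

test_that("label swap flips the sign and scaling leaves the estimate fixed", {
  cm <- simulate_counts(list(g1 = c("t1", "t2")), c("A", "B"), 30,
                        usage = usage_flip, depth = 40, seed = 9)
  f_ab <- fit_usage_glm(cm, design_from_regions(cm, "A:B"), "t1")
  f_ba <- fit_usage_glm(cm, design_from_regions(cm, "B:A"), "t1")
  expect_equal(f_ba$log_odds_ratio, -f_ab$log_odds_ratio, tolerance = 1e-12)
  expect_equal(abs(f_ba$t_statistic), abs(f_ab$t_statistic), tolerance = 1e-12)

  cm3 <- cm
  cm3$counts <- cm$counts * 3
  f3 <- fit_usage_glm(cm3, design_from_regions(cm3, "A:B"), "t1")
  expect_equal(f3$log_odds_ratio, f_ab$log_odds_ratio, tolerance = 1e-12)

  # complement bookkeeping: the two isoforms of a gene mirror each other
  f_t2 <- fit_usage_glm(cm, design_from_regions(cm, "A:B"), "t2")
  expect_equal(f_t2$log_odds_ratio, -f_ab$log_odds_ratio, tolerance = 1e-12)
})

test_that("closed-form fit agrees with the quasi-binomial GLM", {
  cm <- simulate_counts(list(g1 = c("t1", "t2")), c("A", "B"), 30,
                        usage = list(A = list(g1 = c(0.7, 0.3)),
                                     B = list(g1 = c(0.4, 0.6))),
                        depth = 40, seed = 3)
  f <- fit_usage_glm(cm, design_from_regions(cm, "A:B"), "t1")
  k <- as.numeric(cm$counts["t1", ])
  n <- as.numeric(Matrix::colSums(cm$counts))
  grp <- factor(cm$spot_meta$region, levels = c("A", "B"))
  gl <- stats::glm(cbind(k, n - k) ~ grp, family = stats::quasibinomial())
  sm <- summary(gl)$coefficients[2, ]
  expect_gt(summary(gl)$dispersion, 1)  # floor inactive in this fixture
  expect_equal(f$log_odds_ratio, unname(sm["Estimate"]), tolerance = 1e-9)
  expect_equal(f$std_error, unname(sm["Std. Error"]), tolerance = 1e-9)
  expect_equal(f$t_statistic, unname(sm["t value"]), tolerance = 1e-9)
  expect_equal(f$p_value, unname(sm["Pr(>|t|)"]), tolerance = 1e-9)
})

test_that("separation triggers the Haldane-Anscombe adjustment with a flag", {
  counts <- rbind(t1 = c(10, 12, 0, 0), t2 = c(5, 6, 20, 22))
  m <- toy_matrix(counts, regions = rep(c("A", "B"), each = 2),
                  gene_id = c("g1", "g1"))
  f <- fit_usage_glm(m, design_from_regions(m, "A:B"), "t1")
  expect_true(f$flagged)
  expect_true(is.finite(f$log_odds_ratio))
  expect_lt(f$log_odds_ratio, 0)
})

test_that("stage-wise adjustment screens with Sidak and confirms with Holm", {
  res <- data.frame(gene_id = c("g1", "g2", "g2"),
                    transcript_id = c("t1", "t2", "t3"),
                    log_odds_ratio = c(1, 2, -1),
                    p_value = c(0.01, 0.01, 0.5))
  out <- stagewise_adjust(res, ofdr = 0.05)
  expect_equal(out$gene_screen_p[out$gene_id == "g1"], 0.01)        # T = 1
  expect_equal(out$gene_screen_p[out$gene_id == "g2"][1],
               1 - 0.99^2)                                           # 0.0199
  expect_true(all(out$gene_screen_bh <= 1))
  expect_true(all(out$screened[out$confirmed]))
  # Holm within g2: 0.01 * 2 = 0.02 <= 0.05 confirmed; 0.5 not
  g2 <- out[out$gene_id == "g2", ]
  expect_equal(g2$stage2_adjusted_p, c(0.02, 0.5))
  expect_equal(g2$confirmed, c(TRUE, FALSE))

  bonf <- stagewise_adjust(res, screen_method = "bonferroni")
  expect_equal(bonf$gene_screen_p[bonf$gene_id == "g2"][1], 0.02)
})

test_that("switch calling requires confirmed opposite-sign effects", {
  res <- data.frame(gene_id = c("g1", "g1", "g2", "g2"),
                    transcript_id = c("a", "b", "c", "d"),
                    log_odds_ratio = c(1.2, -0.9, 1.2, 0.8),
                    confirmed = TRUE)
  sw <- detect_switches(res)
  expect_equal(sw$gene_id, "g1")
  res$confirmed <- c(TRUE, FALSE, TRUE, TRUE)
  expect_equal(nrow(detect_switches(res)), 0)
})

test_that("switch summaries count per contrast and deduplicate totals", {
  sw <- function(genes) data.frame(gene_id = genes, n_confirmed = 2L,
                                   transcripts = "a,b",
                                   log_odds_ratios = "1,-1",
                                   stringsAsFactors = FALSE)
  s <- switch_summary(list("A:B" = sw(c("g1", "g2")), "A:C" = sw("g1")))
  expect_equal(s$per_contrast$n_genes, c(2L, 1L))
  expect_equal(s$total, 3L)
  expect_equal(s$total_unique_genes, 2L)
})

test_that("run_dtu recovers a planted usage flip as a switch", {
  gmap <- c(list(g1 = c("g1_t1", "g1_t2")),
            stats::setNames(lapply(2:10, function(i)
              sprintf("g%d_t%d", i, 1:2)), sprintf("g%d", 2:10)))
  usage <- list(A = list(g1 = c(0.8, 0.2)), B = list(g1 = c(0.2, 0.8)))
  cm <- simulate_counts(gmap, c("A", "B"), 100, usage = usage, depth = 60,
                        seed = 71)
  d <- run_dtu(cm, "A:B")
  expect_true("g1" %in% d$switches$gene_id)
  g1 <- d$results[d$results$gene_id == "g1", ]
  expect_equal(sort(sign(g1$log_odds_ratio)), c(-1, 1))
  true_lor <- stats::qlogis(0.8) - stats::qlogis(0.2)
  expect_lt(abs(abs(g1$log_odds_ratio[1]) - true_lor), 0.3)
  # scalar and vectorized paths agree
  f <- fit_usage_glm(cm, design_from_regions(cm, "A:B"), "g1_t1",
                     retained = d$results$transcript_id)
  i <- match("g1_t1", d$results$transcript_id)
  expect_equal(d$results$log_odds_ratio[i], f$log_odds_ratio,
               tolerance = 1e-12)
  expect_equal(d$results$p_value[i], f$p_value, tolerance = 1e-12)
})
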