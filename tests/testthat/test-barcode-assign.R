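make_fixture <- function(n = 60, seed = 17, min_hamming = 5) {
  list(wl = make_whitelist(n, 16, seed = seed, min_hamming = min_hamming),
       lay = read_layout())
}

test_that("adapter location finds the window on both strands", {
  fx <- make_fixture()
  rd <- simulate_reads(fx$wl, fx$lay, error_model(0, 0, 0), 20, seed = 1)
  loc <- locate_barcode_region(rd$sequence, fx$lay)
  expect_true(all(loc$found))
  expect_true(all(loc$adapter_identity == 1))
  expect_true(all(loc$window_start == nchar(fx$lay$adapter_seq) + 1))

  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rd$sequence)))
  loc_rc <- locate_barcode_region(rc, fx$lay)
  expect_true(all(loc_rc$orientation == "-"))
  expect_equal(loc_rc$window_start, loc$window_start)

  set.seed(2)
  junk <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""), "")
  expect_true(all(!locate_barcode_region(junk, fx$lay)$found))
})

test_that("whitelist matching is exact, ranked, and oracle-equivalent", {
  fx <- make_fixture()
  bc <- fx$wl$barcode[5]
  hit <- match_whitelist(bc, fx$wl, max_dist = 2)
  expect_equal(hit$barcode[1], bc)
  expect_equal(hit$edit_distance[1], 0L)

  mut <- bc
  substr(mut, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(bc, 3, 3))[1]
  hit <- match_whitelist(mut, fx$wl, max_dist = 2)
  expect_equal(nrow(hit), 1)  # min pairwise Hamming 5 isolates the truth
  expect_equal(hit$edit_distance, 1L)
  expect_equal(hit$barcode, bc)

  set.seed(3)
  far <- paste(sample(c("A", "C", "G", "T"), 16, TRUE), collapse = "")
  d_or <- lev_oracle(far, fx$wl$barcode)
  got <- match_whitelist(far, fx$wl, max_dist = 2)
  expect_equal(sort(got$barcode), sort(fx$wl$barcode[d_or <= 2]))
  if (min(d_or) > 2) expect_equal(nrow(got), 0)
})

test_that("feature vectors match their definitions on zero-noise reads", {
  fx <- make_fixture()
  rd <- simulate_reads(fx$wl, fx$lay, error_model(0, 0, 0), 5, seed = 4)
  loc <- locate_barcode_region(rd$sequence, fx$lay)
  f <- compute_features(rd$sequence[1], loc[1, ], rd$true_barcode[1], fx$wl,
                        fx$lay, max_dist = 2)
  expect_equal(f$bc_edit_distance, 0L)
  expect_equal(f$adapter_identity, 1.0)
  expect_equal(f$position_offset, 0L)
  expect_equal(f$margin, 3L)  # no other candidate within 2: cap 3 minus 0

  # sole candidate at distance 1 -> margin = cap(3) - 1 = 2
  mut <- rd$sequence[1]
  p <- nchar(fx$lay$adapter_seq) + 2
  substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"), substr(mut, p, p))[1]
  f1 <- compute_features(mut, locate_barcode_region(mut, fx$lay)[1, ],
                         rd$true_barcode[1], fx$wl, fx$lay, max_dist = 2)
  expect_equal(f1$bc_edit_distance, 1L)
  expect_equal(f1$margin, 2L)
})

test_that("median abundance falls in the middle quantile bin", {
  wl <- make_whitelist(21, 16, seed = 2)
  wl$short_read_count <- seq_len(21) * 10  # median = 110
  rd <- simulate_reads(wl, read_layout(), error_model(0, 0, 0), 40, seed = 3)
  i <- match(wl$barcode[11], rd$true_barcode)
  skip_if(is.na(i))  # seed-fixed; the median barcode is drawn in 40 reads
  loc <- locate_barcode_region(rd$sequence[i], read_layout())
  f <- compute_features(rd$sequence[i], loc[1, ], wl$barcode[11], wl,
                        read_layout(), n_abundance_bins = 3)
  expect_equal(f$abundance_bin, 2L)
})

test_that("naive Bayes matches the Laplace-smoothed closed form", {
  n <- 1000
  feats <- data.frame(bc_edit_distance = rep(c(0L, 1L), each = n),
                      margin = 2L, adapter_identity = 0.9,
                      position_offset = 0L, abundance_bin = 4L)
  labels <- rep(c(TRUE, FALSE), each = n)
  m <- fit_naive_bayes(feats, labels, n_bins = 2)
  post <- nb_posterior(m, feats[c(1, n + 1), ])
  expect_equal(post[1], 1001 / 1002, tolerance = 1e-12)
  expect_equal(post[2], 1 / 1002, tolerance = 1e-12)

  # uninformative features: posterior equals the prior 0.5
  flat <- data.frame(bc_edit_distance = rep(c(0L, 1L), 1000),
                     margin = rep(c(1L, 3L), 1000),
                     adapter_identity = 1, position_offset = 0L,
                     abundance_bin = 1L)
  m0 <- fit_naive_bayes(flat, rep(c(TRUE, FALSE), each = 1000), n_bins = 2)
  expect_equal(nb_posterior(m0, flat[1:4, ]), rep(0.5, 4), tolerance = 1e-12)

  expect_error(fit_naive_bayes(feats, rep(TRUE, nrow(feats))), "both")
})

test_that("hand-built model reproduces product-rule arithmetic and clamps", {
  m <- structure(list(
    prior_true = 0.6, prior_false = 0.4,
    features = list(
      bc_edit_distance = list(edges = 0.5,
                              log_p_true = log(c(0.9, 0.1)),
                              log_p_false = log(c(0.3, 0.7))),
      margin = list(edges = 1.5,
                    log_p_true = log(c(0.2, 0.8)),
                    log_p_false = log(c(0.6, 0.4))))),
    class = "nb_barcode_model")
  f <- data.frame(bc_edit_distance = 0, margin = 3)
  num <- 0.6 * 0.9 * 0.8
  den <- num + 0.4 * 0.3 * 0.4
  expect_equal(nb_posterior(m, f), num / den, tolerance = 1e-12)

  # values beyond the last edge clamp to the boundary bin
  f_hi <- data.frame(bc_edit_distance = 99, margin = 99)
  f_edge <- data.frame(bc_edit_distance = 1, margin = 2)
  expect_equal(nb_posterior(m, f_hi), nb_posterior(m, f_edge))
})

test_that("assignment is exact on clean reads and monotone in the cutoff", {
  fx <- shared_assign_fixture()
  em <- fx$em
  model <- fx$model

  clean <- simulate_reads(fx$wl, fx$lay, error_model(0, 0, 0), 300, seed = 52)
  asg <- assign_barcodes(stats::setNames(clean$sequence, clean$read_id),
                         fx$wl, fx$lay, model)
  expect_true(all(!is.na(asg$barcode)))
  expect_identical(asg$barcode, clean$true_barcode)
  expect_true(all(asg$score >= 0 & asg$score <= 1))

  noisy <- simulate_reads(fx$wl, fx$lay, em, 1500, decoy_fraction = 0.2,
                          seed = 53)
  rates <- vapply(c(0, 0.5, 0.9, 0.99), function(ct) {
    a <- assign_barcodes(stats::setNames(noisy$sequence, noisy$read_id),
                         fx$wl, fx$lay, model, cutoff = ct)
    mean(!is.na(a$barcode))
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
})

test_that("empty input yields an empty table with a zeroed summary", {
  fx <- shared_assign_fixture()
  out <- assign_barcodes(character(0), fx$wl, fx$lay, fx$model)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "summary")$reads, rep(0L, 4))
})

test_that("assignment tables round-trip through TSV", {
  fx <- shared_assign_fixture()
  rd <- simulate_reads(fx$wl, fx$lay, error_model(0.02, 0.02, 0.02), 50,
                       seed = 11)
  asg <- assign_barcodes(stats::setNames(rd$sequence, rd$read_id), fx$wl,
                         fx$lay, fx$model)
  f <- tempfile(fileext = ".tsv")
  write_assignments(asg, f)
  back <- read_assignments(f)
  expect_equal(back$read_id, asg$read_id)
  expect_equal(back$barcode, asg$barcode)
  expect_equal(back$score, asg$score, tolerance = 1e-9)
})
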