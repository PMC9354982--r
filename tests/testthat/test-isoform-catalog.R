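two_exon <- function(id = "t1", gene = "g1", chrom = "c1", strand = "+",
                     e1 = c(1, 100), e2 = c(201, 300))
  transcript_model(id, gene, chrom, strand, rbind(e1, e2))

test_that("transcript models normalize exon order and reject bad input", {
  tx <- transcript_model("t", "g", "c1", "+", rbind(c(201, 300), c(1, 100)))
  expect_equal(tx$exons[, 1], c(1, 201))
  expect_equal(unname(tx_introns(tx)), matrix(c(101L, 200L), 1))
  expect_error(transcript_model("t", "g", "c1", "*", rbind(c(1, 10))),
               "unstranded")
  expect_error(transcript_model("t", "g", "c1", "+",
                                rbind(c(1, 100), c(50, 200))), "overlap")
})

test_that("GTF round-trips, normalizes exon order, and flags missing ids", {
  cat <- list(two_exon(), two_exon("t2", "g2", "c1", "-", c(500, 600),
                                   c(700, 820)))
  f <- tempfile(fileext = ".gtf")
  write_gtf(cat, f)
  back <- read_gtf(f)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$exons, cat[[1]]$exons)
  expect_equal(back[[2]]$strand, "-")
  expect_equal(back[[2]]$gene_id, "g2")

  # exon lines given out of order come back as a sorted chain
  shuffled <- tempfile(fileext = ".gtf")
  writeLines(c(
    'c1\tx\texon\t201\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'c1\tx\texon\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'),
    shuffled)
  tx <- read_gtf(shuffled)[[1]]
  expect_equal(tx$exons[, 1], c(1, 201))

  empty <- tempfile(fileext = ".gtf")
  writeLines(character(0), empty)
  expect_equal(read_gtf(empty), list())

  noid <- tempfile(fileext = ".gtf")
  writeLines(c(
    'c1\tx\texon\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'c1\tx\texon\t201\t300\t.\t+\t.\tgene_id "g1";'), noid)
  expect_error(read_gtf(noid), "line 2")
})

test_that("catalog merging collapses intron chains and drops single-exon", {
  a <- two_exon("a", e1 = c(10, 100), e2 = c(201, 290))
  b <- two_exon("b", e1 = c(1, 100), e2 = c(201, 320))  # same chain, wider
  mono <- transcript_model("m", "g1", "c1", "+", rbind(c(400, 500)))
  merged <- merge_catalogs(list(list(a, mono), list(b)))
  expect_equal(length(merged), 1)
  expect_equal(merged[[1]]$exons, rbind(c(1L, 100L), c(201L, 320L)),
               ignore_attr = TRUE)

  # disjoint chains concatenate
  c2 <- two_exon("c", chrom = "c2")
  m2 <- merge_catalogs(list(list(a), list(c2)))
  expect_equal(length(m2), 2)

  # idempotence, including stable ids
  again <- merge_catalogs(list(m2))
  expect_equal(again, m2)
})

test_that("class codes follow the priority rules on constructed cases", {
  ref3 <- transcript_model("R", "G", "c1", "+",
                           rbind(c(1, 100), c(201, 300), c(401, 500)))
  idx <- build_reference_index(list(ref3))

  # identical intron chain
  q_eq <- transcript_model("q", "g", "c1", "+",
                           rbind(c(5, 100), c(201, 300), c(401, 480)))
  expect_equal(classify_transcript(q_eq, idx)$code, "=")

  # I1 matched, I2 retained inside the last exon -> m
  q_m <- transcript_model("q", "g", "c1", "+",
                          rbind(c(1, 100), c(201, 500)))
  expect_equal(classify_transcript(q_m, idx)$code, "m")

  # antisense exonic overlap
  q_x <- transcript_model("q", "g", "c1", "-", rbind(c(50, 150), c(251, 320)))
  expect_equal(classify_transcript(q_x, idx)$code, "x")

  # same query strand-flipped with only exonic overlap: o <-> x
  q_o <- transcript_model("q", "g", "c1", "+", rbind(c(80, 120), c(601, 700)))
  expect_equal(classify_transcript(q_o, idx)$code, "o")
  q_o$strand <- "-"
  expect_equal(classify_transcript(q_o, idx)$code, "x")

  # inside a single reference intron / reference inside a query intron
  q_i <- transcript_model("q", "g", "c1", "+", rbind(c(110, 130), c(150, 190)))
  expect_equal(classify_transcript(q_i, idx)$code, "i")
  q_y <- transcript_model("q", "g", "c1", "+", rbind(c(-300, -200), c(600, 700)))
  expect_equal(classify_transcript(q_y, idx)$code, "y")

  # containment: query chain holds the reference chain contiguously
  q_k <- transcript_model("q", "g", "c1", "+",
                          rbind(c(1, 100), c(201, 300), c(401, 500),
                                c(601, 700)))
  expect_equal(classify_transcript(q_k, idx)$code, "k")

  # other chromosome -> u
  q_u <- transcript_model("q", "g", "c9", "+", rbind(c(1, 100), c(201, 300)))
  expect_equal(classify_transcript(q_u, idx)$code, "u")

  expect_error(classify_transcript(q_u, list(ref3)), "indexed")
})

test_that("classification is invariant under coordinate translation", {
  set.seed(42)
  for (i in 1:50) {
    q <- random_tx("q")
    r <- random_tx("r")
    c0 <- classify_transcript(q, build_reference_index(list(r)))$code
    shift <- function(tx, by) {
      tx$exons <- tx$exons + by
      tx
    }
    c1 <- classify_transcript(shift(q, 1000L),
                              build_reference_index(list(shift(r, 1000L))))$code
    expect_identical(c1, c0)
  }
})

test_that("prioritized classifier agrees with the per-code predicate oracle", {
  set.seed(7)
  for (i in 1:300) {
    q <- random_tx("q")
    r <- random_tx("r")
    got <- classify_transcript(q, build_reference_index(list(r)))$code
    expect_identical(got, oracle_classify(q, list(r)),
                     label = sprintf("pair %d: got %s", i, got))
  }
})

test_that("catalog annotation inherits genes and tabulates classes", {
  ref <- simulate_reference(8, seed = 12)
  ann_self <- annotate_catalog(ref, ref)
  expect_true(all(ann_self$class_code == "="))
  expect_equal(ann_self$gene_id, vapply(ref, `[[`, "", "gene_id"))
  freq <- attr(ann_self, "class_freq")
  expect_equal(unname(freq["="]), 8L)
  expect_equal(sum(freq), 8L)

  catg <- simulate_catalog(ref, n_ir = 6, n_junction_variants = 6,
                           n_antisense = 6, seed = 13)
  ann <- annotate_catalog(catg, ref)
  truth <- vapply(catg, `[[`, "", "truth")
  expect_true(all(ann$class_code[truth == "retained_intron"] %in% c("m", "n")))
  expect_true(all(ann$class_code[truth == "junction_skip"] == "j"))
  expect_true(all(ann$class_code[truth == "antisense"] == "x"))
  expect_true(all(ann$class_code[truth == "reference"] == "="))
  # antisense variants get novel gene ids
  expect_true(all(startsWith(ann$gene_id[truth == "antisense"], "NOVG")))

  empty <- annotate_catalog(list(), ref)
  expect_equal(nrow(empty), 0)
})
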