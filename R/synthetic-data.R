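#' Default adapter anchor
#'
#' Fixed 22-nt sequence placed immediately upstream of the spatial barcode in
#' simulated reads and used as the anchoring pattern during barcode location.
#' Matches the partial Illumina read-1 primer found 5' of the barcode in
#' spot-barcoded cDNA libraries.
#' @export
DEFAULT_ADAPTER <- "CTACACGACGCTCTTCCGATCT"

#' Per-base sequencing error model
#'
#' @param sub_rate,ins_rate,del_rate Per-base substitution, insertion and
#'   deletion probabilities; each in `[0, 1)` and summing to less than 1.
#' @param seed Optional integer seed attached to the model.
#' @return An object of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.05, ins_rate = 0.05, del_rate = 0.05,
                        seed = NULL) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates >= 1))
    stopf("error rates must lie in [0, 1)")
  if (sum(rates) >= 1)
    stopf("sub_rate + ins_rate + del_rate must be < 1")
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, seed = seed),
            class = "error_model")
}

#' Read layout of a spot-barcoded long read
#'
#' Describes the expected structure adapter + barcode + UMI + poly-T + cDNA.
#' The barcode and UMI (plus one anchoring base) must fit in the 29 bases that
#' the short-read design allocates to read 1.
#'
#' @param adapter_seq Anchor sequence upstream of the barcode.
#' @param barcode_len,umi_len Barcode and UMI lengths (defaults 16 and 12).
#' @param polyt_len Length of the simulated poly-T stretch.
#' @param orientation One of `"forward"`, `"reverse-complement"`, `"mixed"`.
#'   Mixed reads are reverse-complemented with probability 0.5, as in direct
#'   cDNA sequencing.
#' @return An object of class `read_layout`.
#' @export
read_layout <- function(adapter_seq = DEFAULT_ADAPTER, barcode_len = 16,
                        umi_len = 12, polyt_len = 20,
                        orientation = c("forward", "reverse-complement", "mixed")) {
  orientation <- match.arg(orientation)
  if (!nzchar(adapter_seq)) stopf("adapter_seq must be non-empty")
  if (barcode_len + umi_len + 1 > 29)
    stopf("barcode_len + umi_len + 1 must be <= 29 (short-read read-1 design)")
  structure(list(adapter_seq = toupper(adapter_seq), barcode_len = barcode_len,
                 umi_len = umi_len, polyt_len = polyt_len,
                 orientation = orientation),
            class = "read_layout")
}

#' Generate a spatial barcode whitelist
#'
#' Samples `n_spots` distinct fixed-length barcodes, optionally enforcing a
#' minimum pairwise Hamming distance, places them on an integer grid and
#' attaches simulated short-read abundances. The realized minimum pairwise
#' Hamming distance is recorded in attribute `min_pairwise_hamming`.
#'
#' @param n_spots Number of spots (barcodes).
#' @param barcode_len Barcode length; `4^barcode_len` must be at least `n_spots`.
#' @param grid Integer vector `c(nx, ny)`; defaults to a near-square grid.
#' @param seed Integer seed.
#' @param min_hamming Minimum pairwise Hamming distance to enforce (1 = only
#'   distinctness).
#' @param abundance_mean Mean of the negative binomial used to simulate
#'   short-read counts per barcode.
#' @return A `data.frame` of class `whitelist` with columns `barcode`, `x`,
#'   `y`, `short_read_count`.
#' @export
make_whitelist <- function(n_spots, barcode_len = 16, grid = NULL, seed = 1,
                           min_hamming = 1, abundance_mean = 1000) {
  if (n_spots < 1) stopf("n_spots must be >= 1")
  if (barcode_len * log(4) < log(n_spots))
    stopf("4^%d = %.0f barcodes cannot host %d spots", barcode_len,
          4^barcode_len, n_spots)
  with_seed(seed, {
    kept <- character(0)
    tries <- 0L
    while (length(kept) < n_spots) {
      tries <- tries + 1L
      if (tries > 200L)
        stopf("could not sample %d barcodes of length %d at min Hamming %d",
              n_spots, barcode_len, min_hamming)
      cand <- unique(random_seq(2L * (n_spots - length(kept)) + 10L, barcode_len))
      cand <- setdiff(cand, kept)
      if (min_hamming > 1) {
        keep <- .greedy_min_hamming(cand, as.integer(min_hamming), kept)
        cand <- cand[keep]
      }
      kept <- c(kept, cand)
    }
    kept <- kept[seq_len(n_spots)]
    if (is.null(grid)) {
      nx <- ceiling(sqrt(n_spots))
      grid <- c(nx, ceiling(n_spots / nx))
    }
    idx <- seq_len(n_spots) - 1L
    wl <- data.frame(barcode = kept,
                     x = idx %% grid[1],
                     y = idx %/% grid[1],
                     short_read_count = stats::rnbinom(n_spots, mu = abundance_mean,
                                                       size = 5),
                     stringsAsFactors = FALSE)
    attr(wl, "min_pairwise_hamming") <-
      if (n_spots >= 2) .min_pairwise_hamming(kept) else NA_integer_
    class(wl) <- c("whitelist", "data.frame")
    wl
  })
}

#' Write / read a whitelist TSV
#'
#' Columns: `barcode`, `x`, `y`, `short_read_count`.
#' @param whitelist A `whitelist` data frame.
#' @param path File path.
#' @export
write_whitelist <- function(whitelist, path) {
  utils::write.table(as.data.frame(whitelist), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_whitelist
#' @export
read_whitelist <- function(path) {
  wl <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "integer",
                                         "numeric"))
  need <- c("barcode", "x", "y", "short_read_count")
  if (!all(need %in% names(wl))) stopf("whitelist TSV must have columns %s",
                                       paste(need, collapse = ", "))
  if (anyDuplicated(wl$barcode)) stopf("whitelist barcodes must be unique")
  if (length(unique(nchar(wl$barcode))) > 1)
    stopf("whitelist barcodes must all have the same length")
  class(wl) <- c("whitelist", "data.frame")
  wl
}

# Corrupt one read: `chars` is a character vector of bases. Substitutions are
# applied first, then deletions and insertions, each i.i.d. per base.
corrupt_chars <- function(chars, em) {
  L <- length(chars)
  sub <- stats::runif(L) < em$sub_rate
  if (any(sub)) {
    n <- sum(sub)
    repl <- BASES[(match(chars[sub], BASES) - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L]
    chars[sub] <- repl
  }
  del <- stats::runif(L) < em$del_rate
  ins <- stats::runif(L) < em$ins_rate
  if (!any(del) && !any(ins)) return(chars)
  out <- vector("list", L)
  for (i in seq_len(L)) {
    base <- if (del[i]) character(0) else chars[i]
    if (ins[i]) base <- c(base, sample(BASES, 1L))
    out[[i]] <- base
  }
  unlist(out, use.names = FALSE)
}

#' Simulate spot-barcoded long reads with ground truth
#'
#' Each read is adapter + barcode + UMI + poly-T + random cDNA, corrupted by
#' the per-base error model. A configurable fraction of decoy reads carries a
#' barcode-length segment guaranteed to be at Levenshtein distance at least
#' `decoy_min_dist` from every whitelist barcode.
#'
#' @param whitelist A `whitelist`.
#' @param layout A `read_layout`.
#' @param errors An `error_model`.
#' @param n_reads Number of reads.
#' @param abundance Optional per-spot sampling weights (defaults to uniform).
#' @param decoy_fraction Fraction of reads with a non-whitelist barcode.
#' @param decoy_min_dist Guaranteed Levenshtein separation of decoy segments
#'   from the whitelist.
#' @param cdna_len Length of the random cDNA fragment.
#' @param transcript_ids,transcript_weights Optional transcript identity truth
#'   assigned per read (used to derive read-to-transcript call tables).
#' @param seed Integer seed (defaults to the error model's seed).
#' @return A `data.frame` of class `ground_truth_reads` with columns
#'   `read_id`, `sequence`, `true_barcode`, `true_umi`, `true_transcript_id`,
#'   `strand`, `is_decoy`.
#' @export
simulate_reads <- function(whitelist, layout, errors, n_reads,
                           abundance = NULL, decoy_fraction = 0,
                           decoy_min_dist = 3, cdna_len = 150,
                           transcript_ids = NULL, transcript_weights = NULL,
                           seed = NULL) {
  stopifnot(inherits(layout, "read_layout"), inherits(errors, "error_model"))
  if (n_reads <= 0) stopf("n_reads must be > 0")
  if (!is.null(abundance)) {
    if (length(abundance) != nrow(whitelist)) stopf("abundance length mismatch")
    abundance <- abundance / sum(abundance)
  }
  seed <- seed %||% errors$seed %||% 1L
  with_seed(seed, {
    bl <- layout$barcode_len
    n_decoy <- round(decoy_fraction * n_reads)
    is_decoy <- rep(FALSE, n_reads)
    if (n_decoy > 0) is_decoy[sample.int(n_reads, n_decoy)] <- TRUE

    pick <- sample.int(nrow(whitelist), n_reads, replace = TRUE,
                       prob = abundance)
    bc <- whitelist$barcode[pick]
    if (n_decoy > 0) {
      decoys <- character(0)
      while (length(decoys) < n_decoy) {
        cand <- random_seq(2L * (n_decoy - length(decoys)) + 5L, bl)
        d <- .lev_matrix(cand, whitelist$barcode, as.integer(decoy_min_dist - 1L))
        ok <- apply(d, 1, min) >= decoy_min_dist
        decoys <- c(decoys, cand[ok])
      }
      bc[is_decoy] <- decoys[seq_len(n_decoy)]
    }
    umi <- random_seq(n_reads, layout$umi_len)
    cdna <- random_seq(n_reads, cdna_len)
    clean <- paste0(layout$adapter_seq, bc, umi,
                    strrep("T", layout$polyt_len), cdna)

    no_err <- errors$sub_rate == 0 && errors$ins_rate == 0 && errors$del_rate == 0
    seqs <- if (no_err) clean else
      vapply(strsplit(clean, "", fixed = TRUE),
             function(ch) paste(corrupt_chars(ch, errors), collapse = ""),
             character(1))

    strand <- rep("+", n_reads)
    flip <- switch(layout$orientation,
                   "forward" = rep(FALSE, n_reads),
                   "reverse-complement" = rep(TRUE, n_reads),
                   "mixed" = stats::runif(n_reads) < 0.5)
    if (any(flip)) {
      seqs[flip] <- reverse_complement(seqs[flip])
      strand[flip] <- "-"
    }

    tx <- rep(NA_character_, n_reads)
    if (!is.null(transcript_ids))
      tx <- sample(transcript_ids, n_reads, replace = TRUE,
                   prob = transcript_weights)

    out <- data.frame(read_id = sprintf("read_%06d", seq_len(n_reads)),
                      sequence = seqs,
                      true_barcode = ifelse(is_decoy, NA_character_, bc),
                      true_umi = umi,
                      true_transcript_id = tx,
                      strand = strand,
                      is_decoy = is_decoy,
                      stringsAsFactors = FALSE)
    class(out) <- c("ground_truth_reads", "data.frame")
    out
  })
}

#' Write reads to FASTQ
#'
#' Constant placeholder base qualities are emitted (`I`).
#' @param reads A `ground_truth_reads` data frame or a named character vector.
#' @param path Output path (`.gz` supported).
#' @export
write_fastq <- function(reads, path) {
  if (is.data.frame(reads)) {
    seqs <- reads$sequence
    names(seqs) <- reads$read_id
  } else seqs <- reads
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(
                                strrep("I", Biostrings::width(x))))
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' Performs structural validation and fails naming the first malformed record.
#' @param path FASTQ path (`.gz` supported).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(stats::setNames(character(0), character(0)))
  if (length(lines) %% 4 != 0)
    stopf("malformed FASTQ '%s': %d lines is not a multiple of 4",
          path, length(lines))
  hdr <- lines[seq(1, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stopf("malformed FASTQ '%s': record %d ('%s')", path, bad[1],
          hdr[bad[1]])
  seqs <- toupper(lines[seq(2, length(lines), by = 4)])
  ids <- sub("\\s.*$", "", sub("^@", "", hdr))
  stats::setNames(seqs, ids)
}

#' Simulate a multi-exon reference annotation
#'
#' Genes are laid out sequentially on one chromosome with large inter-gene
#' gaps (so engineered antisense variants only overlap their own locus),
#' alternating strand, one transcript per gene.
#'
#' @param n_genes Number of genes.
#' @param exons_range Range of exon counts per transcript.
#' @param exon_len,intron_len Ranges for exon and intron lengths.
#' @param gene_gap Gap between consecutive gene loci.
#' @param chrom Chromosome name.
#' @param seed Integer seed.
#' @return A list of [transcript_model()] objects.
#' @export
simulate_reference <- function(n_genes, exons_range = c(2, 8),
                               exon_len = c(80, 300), intron_len = c(80, 500),
                               gene_gap = 5000, chrom = "chrS", seed = 1) {
  with_seed(seed, {
    pos <- 1000L
    out <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      k <- sample(seq(exons_range[1], exons_range[2]), 1)
      el <- sample(seq(exon_len[1], exon_len[2]), k, replace = TRUE)
      il <- if (k > 1) sample(seq(intron_len[1], intron_len[2]), k - 1,
                              replace = TRUE) else integer(0)
      starts <- pos + c(0L, cumsum(el[-k] + il))
      ends <- starts + el - 1L
      strand <- if (g %% 2 == 1) "+" else "-"
      out[[g]] <- transcript_model(sprintf("ref_tx_%04d", g),
                                   sprintf("gene_%04d", g), chrom, strand,
                                   cbind(starts, ends))
      pos <- ends[k] + gene_gap
    }
    out
  })
}

#' Simulate an assembled catalog with engineered variants
#'
#' Emits a copy of every reference transcript plus the requested number of
#' retained-intron variants (one intron absorbed into a merged exon), junction
#' variants (one skipped internal exon, requiring references with at least 4
#' exons so a reference intron is preserved) and antisense variants (two-exon
#' transcript on the opposite strand overlapping a reference exon). Each
#' emitted transcript carries a `truth` label for classifier validation.
#'
#' @param reference List of [transcript_model()] (multi-exon for IR variants).
#' @param n_ir,n_junction_variants,n_antisense Variant counts.
#' @param seed Integer seed.
#' @return List of `transcript_model` objects, each with a `truth` element in
#'   `reference`, `retained_intron`, `junction_skip`, `antisense`.
#' @export
simulate_catalog <- function(reference, n_ir = 0, n_junction_variants = 0,
                             n_antisense = 0, seed = 1) {
  n_ex <- vapply(reference, function(tx) nrow(tx$exons), integer(1))
  if (n_ir > 0 && !any(n_ex >= 2))
    stopf("retained-intron variants require multi-exon reference transcripts")
  if (n_junction_variants > 0 && !any(n_ex >= 4))
    stopf("junction variants require reference transcripts with >= 4 exons")
  with_seed(seed, {
    out <- lapply(reference, function(tx) {
      tx$transcript_id <- paste0(tx$transcript_id, ".copy")
      tx$truth <- "reference"
      tx
    })
    add <- function(tx) out[[length(out) + 1L]] <<- tx

    for (i in seq_len(n_ir)) {
      ref <- reference[[sample(which(n_ex >= 2), 1)]]
      j <- sample.int(nrow(ref$exons) - 1L, 1)  # intron j retained
      ex <- ref$exons
      merged <- rbind(if (j > 1) ex[seq_len(j - 1), , drop = FALSE],
                      c(ex[j, 1], ex[j + 1, 2]),
                      if (j + 1 < nrow(ex)) ex[seq(j + 2, nrow(ex)), , drop = FALSE])
      v <- transcript_model(sprintf("%s.ir%d", ref$transcript_id, i),
                            ref$gene_id, ref$chrom, ref$strand, merged)
      v$truth <- "retained_intron"
      add(v)
    }
    for (i in seq_len(n_junction_variants)) {
      ref <- reference[[sample(which(n_ex >= 4), 1)]]
      k <- nrow(ref$exons)
      skip <- sample(seq(2L, k - 1L), 1)
      v <- transcript_model(sprintf("%s.skip%d", ref$transcript_id, i),
                            ref$gene_id, ref$chrom, ref$strand,
                            ref$exons[-skip, , drop = FALSE])
      v$truth <- "junction_skip"
      add(v)
    }
    for (i in seq_len(n_antisense)) {
      ref <- reference[[sample.int(length(reference), 1)]]
      widths <- ref$exons[, 2] - ref$exons[, 1]
      j <- which.max(widths)
      s <- ref$exons[j, 1]; e <- ref$exons[j, 2]
      a <- s + min(10L, max(0L, e - s - 20L))
      b <- min(e, a + 80L)
      v <- transcript_model(sprintf("%s.as%d", ref$transcript_id, i),
                            paste0(ref$gene_id, "-AS"), ref$chrom,
                            if (ref$strand == "+") "-" else "+",
                            rbind(c(a, b), c(b + 150L, b + 250L)))
      v$truth <- "antisense"
      add(v)
    }
    out
  })
}

#' Simulate a transcript-by-spot count matrix with known usage
#'
#' Per spot, each gene's total is drawn from a negative binomial with mean
#' `depth`; transcript counts are multinomial given the region's usage vector
#' (Dirichlet-multinomial when `usage_concentration` is finite). Within every
#' spot, transcript counts of a gene sum exactly to the drawn gene total.
#'
#' @param catalog Either a named list mapping gene id to a character vector of
#'   transcript ids, or a list of [transcript_model()] objects.
#' @param regions Character vector of region labels.
#' @param n_spots_per_region Spots per region.
#' @param usage Named list region -> (named list gene -> usage vector summing
#'   to 1 over that gene's transcripts). A single gene->usage list is recycled
#'   across regions. Missing genes default to uniform usage.
#' @param depth Mean gene total per spot (> 0).
#' @param nb_size Negative binomial size (dispersion) parameter; `Inf` gives
#'   Poisson totals.
#' @param usage_concentration Dirichlet concentration scale; `Inf` disables
#'   usage overdispersion.
#' @param seed Integer seed.
#' @return A [spot_count_matrix()] with region labels in the spot metadata.
#' @export
simulate_counts <- function(catalog, regions, n_spots_per_region, usage = NULL,
                            depth = 50, nb_size = 10,
                            usage_concentration = Inf, seed = 1) {
  if (depth <= 0) stopf("depth must be > 0")
  if (is.list(catalog) && length(catalog) && inherits(catalog[[1]], "transcript_model")) {
    gene_map <- split(vapply(catalog, `[[`, "", "transcript_id"),
                      vapply(catalog, `[[`, "", "gene_id"))
    nex <- vapply(catalog, function(tx) nrow(tx$exons), integer(1))
    names(nex) <- vapply(catalog, `[[`, "", "transcript_id")
  } else {
    gene_map <- catalog
    nex <- NULL
  }
  if (!is.null(usage) && !is.null(names(usage)) &&
      all(names(usage) %in% names(gene_map)))
    usage <- stats::setNames(rep(list(usage), length(regions)), regions)

  tx_ids <- unlist(gene_map, use.names = FALSE)
  gene_of <- rep(names(gene_map), lengths(gene_map))
  n_tx <- length(tx_ids)
  n_spots <- n_spots_per_region * length(regions)
  region_of <- rep(regions, each = n_spots_per_region)

  get_usage <- function(region, gene, k) {
    u <- usage[[region]][[gene]]
    if (is.null(u)) return(rep(1 / k, k))
    if (length(u) != k) stopf("usage vector for gene %s has length %d, expected %d",
                              gene, length(u), k)
    if (abs(sum(u) - 1) > 1e-8)
      stopf("usage vector for gene %s in region %s does not sum to 1", gene, region)
    u
  }

  with_seed(seed, {
    counts <- matrix(0, nrow = n_tx, ncol = n_spots,
                     dimnames = list(tx_ids, sprintf("spot_%05d", seq_len(n_spots))))
    row0 <- 0L
    for (g in seq_along(gene_map)) {
      k <- length(gene_map[[g]])
      gene <- names(gene_map)[g]
      tot <- if (is.finite(nb_size))
        stats::rnbinom(n_spots, mu = depth, size = nb_size)
      else stats::rpois(n_spots, depth)
      for (r in regions) {
        idx <- which(region_of == r)
        u <- get_usage(r, gene, k)
        if (is.finite(usage_concentration)) {
          a <- matrix(stats::rgamma(length(idx) * k,
                                    shape = rep(usage_concentration * u,
                                                each = length(idx))),
                      nrow = length(idx))
          p <- a / rowSums(a)
        } else {
          p <- matrix(u, nrow = length(idx), ncol = k, byrow = TRUE)
        }
        remaining <- tot[idx]
        prem <- rep(1, length(idx))
        for (t in seq_len(k)) {
          if (t < k) {
            pt <- ifelse(prem > 0, pmin(1, p[, t] / prem), 0)
            kt <- stats::rbinom(length(idx), remaining, pt)
          } else kt <- remaining
          counts[row0 + t, idx] <- kt
          remaining <- remaining - kt
          prem <- prem - p[, t]
        }
      }
      row0 <- row0 + k
    }
    tx_meta <- data.frame(transcript_id = tx_ids, gene_id = gene_of,
                          n_exons = if (is.null(nex)) 2L else
                            unname(nex[tx_ids]),
                          class_code = NA_character_,
                          stringsAsFactors = FALSE)
    side <- ceiling(sqrt(n_spots_per_region))
    off <- (match(region_of, regions) - 1L) * (side + 2L)
    within <- stats::ave(seq_len(n_spots), region_of, FUN = seq_along) - 1L
    spot_meta <- data.frame(barcode = colnames(counts),
                            x = off + within %% side, y = within %/% side,
                            region = region_of, stringsAsFactors = FALSE)
    spot_count_matrix(counts, tx_meta, spot_meta)
  })
}
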