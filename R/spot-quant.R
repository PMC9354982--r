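#' Transcript-by-spot count matrix
#'
#' Sparse non-negative integer counts plus transcript and spot metadata.
#'
#' @param counts A sparse (or dense) transcripts-by-spots matrix.
#' @param tx_meta `data.frame` with at least `transcript_id`; typically also
#'   `gene_id`, `class_code`, `n_exons`.
#' @param spot_meta `data.frame` with at least `barcode`; typically also `x`,
#'   `y` and a `region` label.
#' @return An object of class `spot_matrix`.
#' @export
spot_count_matrix <- function(counts, tx_meta, spot_meta) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (nrow(counts) != nrow(tx_meta) || ncol(counts) != nrow(spot_meta))
    stopf("count matrix dimensions (%d x %d) do not match metadata (%d x %d)",
          nrow(counts), ncol(counts), nrow(tx_meta), nrow(spot_meta))
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stopf("counts must be non-negative integers")
  rownames(counts) <- tx_meta$transcript_id
  colnames(counts) <- spot_meta$barcode
  structure(list(counts = counts, tx_meta = tx_meta, spot_meta = spot_meta),
            class = "spot_matrix")
}

#' @export
print.spot_matrix <- function(x, ...) {
  cat(sprintf("<spot_matrix> %d transcripts x %d spots, %d non-zero entries\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  if (!is.null(x$spot_meta$region) && !all(is.na(x$spot_meta$region)))
    cat("  regions:", paste(names(table(x$spot_meta$region)), collapse = ", "),
        "\n")
  invisible(x)
}

subset_spots <- function(mat, idx) {
  spot_count_matrix(mat$counts[, idx, drop = FALSE], mat$tx_meta,
                    mat$spot_meta[idx, , drop = FALSE])
}

#' Collapse UMIs to molecule counts (directional adjacency)
#'
#' Two UMIs are connected when their Hamming distance is 1 and the read count
#' of the more abundant one is at least `2 * count(v) - 1`; molecules are the
#' connected components grown greedily from the most abundant unvisited UMI.
#'
#' @param umis Character vector of UMIs (one per read) or unique UMIs when
#'   `counts` is given.
#' @param counts Optional read counts per unique UMI.
#' @return Integer molecule count.
#' @export
dedup_umis <- function(umis, counts = NULL) {
  if (!length(umis)) stopf("empty UMI set")
  if (length(unique(nchar(umis))) > 1)
    stopf("inconsistent UMI lengths within a (spot, transcript) group")
  if (is.null(counts)) {
    tab <- table(umis)
    umis <- names(tab)
    counts <- as.integer(tab)
  }
  n <- length(umis)
  if (n == 1) return(1L)
  ord <- order(-counts, umis)
  umis <- umis[ord]; counts <- counts[ord]
  H <- .hamming_matrix(umis)
  visited <- logical(n)
  roots <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    roots <- roots + 1L
    visited[i] <- TRUE
    frontier <- i
    while (length(frontier)) {
      u <- frontier[1]; frontier <- frontier[-1]
      nb <- which(!visited & H[u, ] == 1L & counts[u] >= 2L * counts - 1L)
      if (length(nb)) {
        visited[nb] <- TRUE
        frontier <- c(frontier, nb)
      }
    }
  }
  roots
}

#' Build a transcript-by-spot matrix from assignments and transcript calls
#'
#' Joins read-to-barcode assignments with read-to-transcript calls, collapses
#' PCR duplicates per (spot, transcript) group with [dedup_umis()], and
#' returns a [spot_count_matrix()] over all whitelist spots. Reads without an
#' assigned barcode are dropped (count logged as attribute
#' `n_dropped_unassigned`).
#'
#' @param assignments `data.frame` with `read_id`, `barcode` (`NA` when
#'   unassigned).
#' @param calls `data.frame` with `read_id`, `transcript_id`, `umi`.
#' @param whitelist A `whitelist`.
#' @param tx_meta Optional transcript metadata joined by `transcript_id`.
#' @export
build_matrix <- function(assignments, calls, whitelist, tx_meta = NULL) {
  dup <- calls$read_id[duplicated(calls$read_id)]
  if (length(dup)) {
    conflicting <- vapply(unique(dup), function(id) {
      rows <- calls[calls$read_id == id, c("transcript_id", "umi")]
      nrow(unique(rows)) > 1
    }, logical(1))
    if (any(conflicting))
      stopf("conflicting duplicate read_id in calls: %s",
            paste(utils::head(unique(dup)[conflicting], 3), collapse = ", "))
    calls <- calls[!duplicated(calls$read_id), ]
  }
  assigned <- assignments[!is.na(assignments$barcode),
                          c("read_id", "barcode")]
  m <- merge(calls, assigned, by = "read_id")
  n_dropped <- nrow(calls) - nrow(m)

  tx_ids <- sort(unique(calls$transcript_id))
  mat <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(length(tx_ids), nrow(whitelist)))
  if (nrow(m)) {
    grp <- split(m$umi, list(factor(m$barcode, levels = whitelist$barcode),
                             factor(m$transcript_id, levels = tx_ids)),
                 drop = TRUE, sep = "\r")
    mol <- vapply(grp, dedup_umis, integer(1))
    keyparts <- strsplit(names(grp), "\r", fixed = TRUE)
    jj <- match(vapply(keyparts, `[`, "", 1), whitelist$barcode)
    ii <- match(vapply(keyparts, `[`, "", 2), tx_ids)
    mat <- Matrix::sparseMatrix(i = ii, j = jj, x = mol,
                                dims = c(length(tx_ids), nrow(whitelist)))
  }
  tm <- data.frame(transcript_id = tx_ids, stringsAsFactors = FALSE)
  if (!is.null(tx_meta)) {
    tm <- merge(tm, tx_meta, by = "transcript_id", all.x = TRUE, sort = FALSE)
    tm <- tm[match(tx_ids, tm$transcript_id), , drop = FALSE]
  } else {
    tm$gene_id <- NA_character_
    tm$class_code <- NA_character_
    tm$n_exons <- NA_integer_
  }
  sm <- data.frame(barcode = whitelist$barcode, x = whitelist$x,
                   y = whitelist$y, region = NA_character_,
                   stringsAsFactors = FALSE)
  out <- spot_count_matrix(mat, tm, sm)
  attr(out, "n_dropped_unassigned") <- n_dropped
  out
}

#' Quality-control filtering of a spot matrix
#'
#' Spots are kept when their total count and detected-transcript number lie
#' strictly inside the given bounds and the count fraction from flagged genes
#' (e.g. ribosomal) is below `flag_cap`; transcripts must then be detected in
#' at least `min_spots` surviving spots. Rules are applied in that order and
#' iterated to a fixed point, so the filter is idempotent; the report counts
#' removals per rule.
#'
#' @param mat A `spot_matrix`.
#' @param counts_range,features_range Open intervals for per-spot totals and
#'   detected transcripts (defaults 50--4000 and 50--2000).
#' @param flag_genes Character vector of gene ids whose count fraction is
#'   capped.
#' @param flag_cap Maximum flagged-gene fraction (default 0.4).
#' @param min_spots Minimum number of spots a transcript must be detected in
#'   (default 2).
#' @return Filtered `spot_matrix` with attribute `qc_report`.
#' @export
qc_filter <- function(mat, counts_range = c(50, 4000),
                      features_range = c(50, 2000), flag_genes = NULL,
                      flag_cap = 0.4, min_spots = 2) {
  stopifnot(counts_range[1] < counts_range[2],
            features_range[1] < features_range[2])
  removed <- c(spot_counts = 0L, spot_features = 0L, spot_flagged = 0L,
               feature_min_spots = 0L)
  repeat {
    counts <- mat$counts
    tot <- Matrix::colSums(counts)
    keep <- tot > counts_range[1] & tot < counts_range[2]
    removed["spot_counts"] <- removed["spot_counts"] + sum(!keep)
    nfeat <- Matrix::colSums(counts[, keep, drop = FALSE] > 0)
    ok_feat <- nfeat > features_range[1] & nfeat < features_range[2]
    removed["spot_features"] <- removed["spot_features"] + sum(!ok_feat)
    keep[keep] <- ok_feat
    if (!is.null(flag_genes) && sum(keep)) {
      fl <- mat$tx_meta$gene_id %in% flag_genes
      sub <- counts[, keep, drop = FALSE]
      frac <- Matrix::colSums(sub[fl, , drop = FALSE]) / Matrix::colSums(sub)
      frac[is.na(frac)] <- 0
      ok_fl <- frac < flag_cap
      removed["spot_flagged"] <- removed["spot_flagged"] + sum(!ok_fl)
      keep[keep] <- ok_fl
    }
    mat2 <- subset_spots(mat, which(keep))
    det <- Matrix::rowSums(mat2$counts > 0)
    keep_tx <- det >= min_spots
    removed["feature_min_spots"] <- removed["feature_min_spots"] + sum(!keep_tx)
    mat2 <- spot_count_matrix(mat2$counts[keep_tx, , drop = FALSE],
                              mat2$tx_meta[keep_tx, , drop = FALSE],
                              mat2$spot_meta)
    stable <- ncol(mat2$counts) == ncol(mat$counts) &&
      nrow(mat2$counts) == nrow(mat$counts)
    mat <- mat2
    if (stable) break
  }
  if (ncol(mat$counts) == 0)
    warning("qc_filter removed all spots", call. = FALSE)
  attr(mat, "qc_report") <- data.frame(rule = names(removed),
                                       removed = unname(removed),
                                       stringsAsFactors = FALSE)
  mat
}

#' Write / read a spot matrix directory
#'
#' MatrixMarket `matrix.mtx` plus `features.tsv` (transcript metadata) and
#' `barcodes.tsv` (spot metadata); round-trips with [read_matrix_dir()].
#' @param mat A `spot_matrix`.
#' @param dir Directory (created if needed).
#' @export
write_matrix_dir <- function(mat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(mat$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(mat$tx_meta, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(mat$spot_meta, file.path(dir, "barcodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_matrix_dir
#' @export
read_matrix_dir <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  tx <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  sp <- utils::read.table(file.path(dir, "barcodes.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  sp$barcode <- as.character(sp$barcode)
  tx$transcript_id <- as.character(tx$transcript_id)
  spot_count_matrix(counts, tx, sp)
}
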