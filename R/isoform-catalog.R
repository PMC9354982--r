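#' Transcript model
#'
#' A stranded exon chain on one chromosome, the unit of catalogs,
#' classification and quantification. Coordinates are 1-based inclusive (GTF
#' convention). Exons are sorted and must not overlap; introns are the gaps
#' between consecutive exons.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`; unstranded transcripts are rejected because
#'   strand drives antisense-versus-overlap classification.
#' @param exons Two-column matrix of (start, end).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons) {
  if (!strand %in% c("+", "-"))
    stopf("transcript %s: strand must be '+' or '-' (unstranded not allowed)",
          transcript_id)
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] < exons[, 1]))
    stopf("transcript %s: exon end < start", transcript_id)
  if (nrow(exons) > 1 && any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stopf("transcript %s: overlapping or abutting exons", transcript_id)
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d [%s], %d exon(s)\n",
              x$transcript_id, x$gene_id, x$chrom, x$exons[1, 1],
              x$exons[nrow(x$exons), 2], x$strand, nrow(x$exons)))
  invisible(x)
}

#' Intron coordinates of a transcript
#' @param tx A `transcript_model`.
#' @return Two-column integer matrix (start, end); zero rows for single-exon
#'   transcripts.
#' @export
tx_introns <- function(tx) {
  k <- nrow(tx$exons)
  if (k < 2) return(matrix(integer(0), ncol = 2,
                           dimnames = list(NULL, c("start", "end"))))
  cbind(start = tx$exons[-k, 2] + 1L, end = tx$exons[-1, 1] - 1L)
}

tx_span <- function(tx) c(tx$exons[1, 1], tx$exons[nrow(tx$exons), 2])

chain_key <- function(tx) {
  intr <- tx_introns(tx)
  paste(intr[, 1], intr[, 2], sep = "-", collapse = ";")
}

#' Read transcript models from a GTF file
#'
#' Exon features are grouped by `transcript_id`; exon order within a record is
#' normalized. Fails naming the offending line when an exon lacks a
#' `transcript_id` attribute.
#'
#' @param path GTF file path.
#' @return List of [transcript_model()], sorted by (chrom, start).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (length(readLines(path, n = 1)) == 0) return(list())
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & gr$type == "exon"]
  if (length(gr) == 0) return(list())
  txid <- gr$transcript_id
  if (is.null(txid) || anyNA(txid)) {
    lines <- readLines(path)
    is_exon <- grepl("\t(exon)\t", lines)
    bad <- which(is_exon & !grepl("transcript_id", lines))
    stopf("GTF '%s': exon feature without transcript_id (line %s)", path,
          if (length(bad)) bad[1] else "?")
  }
  gene <- gr$gene_id %||% rep(NA_character_, length(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stopf("GTF '%s': unstranded exon features", path)
  df <- data.frame(tx = txid, gene = gene,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = strand,
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  out <- lapply(split(df, df$tx), function(d)
    transcript_model(d$tx[1], d$gene[1], d$chrom[1], d$strand[1],
                     cbind(d$start, d$end)))
  sort_catalog(unname(out))
}

sort_catalog <- function(catalog) {
  if (!length(catalog)) return(catalog)
  ch <- vapply(catalog, `[[`, "", "chrom")
  st <- vapply(catalog, function(tx) tx$exons[1, 1], integer(1))
  en <- vapply(catalog, function(tx) tx$exons[nrow(tx$exons), 2], integer(1))
  id <- vapply(catalog, `[[`, "", "transcript_id")
  catalog[order(ch, st, en, id)]
}

#' Write transcript models to GTF
#' @param catalog List of `transcript_model`.
#' @param path Output path.
#' @export
write_gtf <- function(catalog, path) {
  if (!length(catalog)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  rows <- lapply(catalog, function(tx) {
    data.frame(chrom = tx$chrom, start = tx$exons[, 1], end = tx$exons[, 2],
               strand = tx$strand, transcript_id = tx$transcript_id,
               gene_id = tx$gene_id %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$type <- "exon"
  gr$source <- "isospot"
  gr$transcript_id <- df$transcript_id
  gr$gene_id <- df$gene_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Merge transcript catalogs into a non-redundant set
#'
#' Single-exon transcripts are removed, then transcripts sharing (chrom,
#' strand, intron chain) collapse to one record whose terminal exons span the
#' union of the members' ends. New stable identifiers (`TX.000001`, ...) are
#' assigned in (chrom, start) order; merging the merged catalog with itself
#' returns it unchanged.
#'
#' @param catalogs A list of catalogs (each a list of `transcript_model`), or
#'   a single catalog.
#' @return List of merged `transcript_model` objects.
#' @export
merge_catalogs <- function(catalogs) {
  if (length(catalogs) && inherits(catalogs[[1]], "transcript_model"))
    catalogs <- list(catalogs)
  if (!length(catalogs)) stopf("at least one catalog required")
  all_tx <- unlist(catalogs, recursive = FALSE)
  all_tx <- Filter(function(tx) nrow(tx$exons) >= 2, all_tx)
  if (!length(all_tx)) return(list())
  key <- vapply(all_tx, function(tx)
    paste(tx$chrom, tx$strand, chain_key(tx), sep = "|"), character(1))
  groups <- split(all_tx, key)
  merged <- lapply(groups, function(g) {
    ids <- vapply(g, `[[`, "", "transcript_id")
    g <- g[order(ids)]
    ex <- g[[1]]$exons
    ex[1, 1] <- min(vapply(g, function(tx) tx$exons[1, 1], integer(1)))
    k <- nrow(ex)
    ex[k, 2] <- max(vapply(g, function(tx) tx$exons[nrow(tx$exons), 2],
                           integer(1)))
    transcript_model("tmp", g[[1]]$gene_id, g[[1]]$chrom, g[[1]]$strand, ex)
  })
  merged <- sort_catalog(unname(merged))
  for (i in seq_along(merged))
    merged[[i]]$transcript_id <- sprintf("TX.%06d", i)
  merged
}

# --- classification -------------------------------------------------------

exonic_overlap_bp <- function(exA, exB) {
  tot <- 0L
  for (i in seq_len(nrow(exA)))
    for (j in seq_len(nrow(exB))) {
      o <- min(exA[i, 2], exB[j, 2]) - max(exA[i, 1], exB[j, 1]) + 1L
      if (o > 0) tot <- tot + o
    }
  tot
}

intron_in_set <- function(intron, chain) {
  nrow(chain) > 0 && any(chain[, 1] == intron[1] & chain[, 2] == intron[2])
}

contiguous_subchain <- function(sub, chain) {
  m <- nrow(sub); n <- nrow(chain)
  if (m == 0 || n < m) return(FALSE)
  for (i in seq_len(n - m + 1)) {
    if (all(chain[i:(i + m - 1), 1] == sub[, 1]) &&
        all(chain[i:(i + m - 1), 2] == sub[, 2])) return(TRUE)
  }
  FALSE
}

CLASS_PRIORITY <- c("=", "k", "m", "n", "j", "o", "x", "i", "y", "u")

# Highest-priority code describing how query q relates to a single reference
# r (same chromosome assumed). Returns NA when no code applies.
code_vs_ref <- function(q, r) {
  qi <- tx_introns(q); ri <- tx_introns(r)
  ov <- exonic_overlap_bp(q$exons, r$exons)
  same <- q$strand == r$strand
  if (same) {
    if (nrow(qi) == nrow(ri) &&
        (nrow(qi) > 0 && all(qi == ri) || (nrow(qi) == 0 && ov > 0)))
      return("=")
    if (nrow(ri) > 0 && nrow(qi) > nrow(ri) && contiguous_subchain(ri, qi))
      return("k")
    if (nrow(ri) > 0 && ov > 0) {
      in_exon <- apply(ri, 1, function(intr)
        any(q$exons[, 1] <= intr[1] & intr[2] <= q$exons[, 2]))
      matched <- apply(ri, 1, function(intr) intron_in_set(intr, qi))
      if (all(in_exon | matched) && any(in_exon)) return("m")
    }
    if (nrow(ri) > 0) {
      in_exon_any <- any(apply(ri, 1, function(intr)
        any(q$exons[, 1] <= intr[1] & intr[2] <= q$exons[, 2])))
      if (in_exon_any) return("n")
    }
    if (nrow(qi) > 0 && nrow(ri) > 0) {
      shared <- any(apply(qi, 1, function(intr) intron_in_set(intr, ri)))
      if (shared) return("j")
    }
    if (ov > 0) return("o")
  } else {
    if (ov > 0) return("x")
  }
  qs <- tx_span(q); rs <- tx_span(r)
  if (nrow(ri) > 0 && any(ri[, 1] <= qs[1] & qs[2] <= ri[, 2])) return("i")
  if (nrow(qi) > 0 && any(qi[, 1] <= rs[1] & rs[2] <= qi[, 2])) return("y")
  NA_character_
}

#' Build a reference index for classification
#' @param reference List of `transcript_model`.
#' @return An object of class `reference_index`.
#' @export
build_reference_index <- function(reference) {
  spans <- t(vapply(reference, tx_span, integer(2)))
  structure(list(txs = reference,
                 chrom = vapply(reference, `[[`, "", "chrom"),
                 start = spans[, 1], end = spans[, 2],
                 ids = vapply(reference, `[[`, "", "transcript_id")),
            class = "reference_index")
}

#' Classify a transcript against a reference annotation
#'
#' Assigns the single highest-priority class code over all span-overlapping
#' reference transcripts, with priority `=` > `k` > `m` > `n` > `j` > `o` >
#' `x` > `i` > `y` > `u`:
#' `=` identical intron chain (same strand); `k` the query's intron chain
#' contains a reference chain as a contiguous sub-chain; `m` every reference
#' intron is matched or retained inside a query exon, with at least one
#' retained; `n` at least one reference intron retained but `m` fails; `j` at
#' least one shared intron; `o` same-strand exonic overlap; `x` antisense
#' exonic overlap; `i` query inside a single reference intron; `y` reference
#' inside a single query intron; `u` no overlap. Ties between references at
#' the same code are broken by larger exonic overlap, then reference id.
#'
#' @param query A `transcript_model`.
#' @param index A [build_reference_index()] object.
#' @return List with elements `code` and `ref_transcript_id` (`NA` for `u`).
#' @export
classify_transcript <- function(query, index) {
  if (!inherits(index, "reference_index"))
    stopf("reference must be indexed with build_reference_index()")
  qs <- tx_span(query)
  cand <- which(index$chrom == query$chrom &
                  index$start <= qs[2] & index$end >= qs[1])
  if (!length(cand)) return(list(code = "u", ref_transcript_id = NA_character_))
  codes <- character(length(cand))
  ovs <- integer(length(cand))
  for (i in seq_along(cand)) {
    r <- index$txs[[cand[i]]]
    codes[i] <- code_vs_ref(query, r)
    ovs[i] <- exonic_overlap_bp(query$exons, r$exons)
  }
  ok <- !is.na(codes)
  if (!any(ok)) return(list(code = "u", ref_transcript_id = NA_character_))
  rank <- match(codes, CLASS_PRIORITY)
  ord <- order(rank, -ovs, index$ids[cand])
  best <- ord[ok[ord]][1]
  list(code = codes[best], ref_transcript_id = index$ids[cand[best]])
}

#' Annotate a catalog against a reference
#'
#' Classifies every transcript, inherits the matched reference's gene id for
#' codes `=`, `k`, `m`, `n`, `j`, `o`, and assigns novel gene ids (clustered
#' by same-strand span overlap) for `x`, `i`, `y`, `u`. The class frequency
#' table is attached as attribute `class_freq`.
#'
#' @param catalog,reference Lists of `transcript_model`.
#' @return `data.frame` with columns `transcript_id`, `class_code`,
#'   `ref_transcript_id`, `gene_id`.
#' @export
annotate_catalog <- function(catalog, reference) {
  if (!length(catalog)) {
    out <- data.frame(transcript_id = character(0), class_code = character(0),
                      ref_transcript_id = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "class_freq") <- table(factor(character(0), levels = CLASS_PRIORITY))
    return(out)
  }
  index <- build_reference_index(reference)
  cls <- lapply(catalog, classify_transcript, index = index)
  codes <- vapply(cls, `[[`, "", "code")
  refs <- vapply(cls, `[[`, "", "ref_transcript_id")
  ref_gene <- stats::setNames(vapply(reference, function(tx)
    tx$gene_id %||% NA_character_, character(1)),
    vapply(reference, `[[`, "", "transcript_id"))
  gene <- ifelse(codes %in% c("=", "k", "m", "n", "j", "o"),
                 unname(ref_gene[refs]), NA_character_)
  novel <- which(is.na(gene))
  if (length(novel)) {
    gr <- GenomicRanges::GRanges(
      vapply(catalog[novel], `[[`, "", "chrom"),
      IRanges::IRanges(vapply(catalog[novel], function(tx) tx_span(tx)[1], integer(1)),
                       vapply(catalog[novel], function(tx) tx_span(tx)[2], integer(1))),
      strand = vapply(catalog[novel], `[[`, "", "strand"))
    red <- GenomicRanges::reduce(gr)
    hit <- GenomicRanges::findOverlaps(gr, red)
    cluster <- rep(NA_integer_, length(novel))
    cluster[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
    gene[novel] <- sprintf("NOVG.%04d", cluster)
  }
  out <- data.frame(transcript_id = vapply(catalog, `[[`, "", "transcript_id"),
                    class_code = codes, ref_transcript_id = refs,
                    gene_id = gene, stringsAsFactors = FALSE)
  attr(out, "class_freq") <- table(factor(codes, levels = CLASS_PRIORITY))
  out
}
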