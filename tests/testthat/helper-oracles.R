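# Independent oracles the implementation is checked against.

# Plain Levenshtein distance via base R's adist (generalized edit distance in
# C), independent of the package's banded DP.
lev_oracle <- function(a, b) as.integer(utils::adist(a, b))

# Two-sided Fisher exact p by full enumeration of the hypergeometric support
# (point-probability rule: sum over tables no more probable than observed).
fisher_enum_oracle <- function(a, b, cc, d) {
  supp <- max(0, a + cc - (cc + d)):min(a + b, a + cc)
  probs <- stats::dhyper(supp, a + b, cc + d, a + cc)
  p0 <- stats::dhyper(a, a + b, cc + d, a + cc)
  min(1, sum(probs[probs <= p0 * (1 + 1e-7)]))
}

# --- brute-force class-code checker --------------------------------------
# Evaluates each code's predicate independently (position sets and intron
# token strings) and returns the first code, in priority order, satisfied by
# any reference.

tx_positions <- function(tx)
  unlist(lapply(seq_len(nrow(tx$exons)),
                function(i) seq(tx$exons[i, 1], tx$exons[i, 2])))

intron_tokens <- function(tx) {
  intr <- tx_introns(tx)
  if (!nrow(intr)) return(character(0))
  sprintf("%d:%d", intr[, 1], intr[, 2])
}

oracle_code_pair <- function(q, r) {
  if (q$chrom != r$chrom) return(character(0))
  qa <- tx_positions(q); ra <- tx_positions(r)
  ov <- length(intersect(qa, ra)) > 0
  qt <- intron_tokens(q); rt <- intron_tokens(r)
  qi <- tx_introns(q); ri <- tx_introns(r)
  same <- q$strand == r$strand
  in_ex <- if (nrow(ri)) apply(ri, 1, function(intr)
    any(q$exons[, 1] <= intr[1] & intr[2] <= q$exons[, 2])) else logical(0)
  matched <- rt %in% qt
  chain_str <- function(tok) paste0("|", paste(tok, collapse = "|"), "|")
  ok <- c(
    "=" = same && length(qt) == length(rt) && all(qt == rt) && ov,
    "k" = same && length(rt) > 0 && length(qt) > length(rt) &&
      grepl(chain_str(rt), chain_str(qt), fixed = TRUE),
    "m" = same && ov && length(rt) > 0 && all(in_ex | matched) && any(in_ex),
    "n" = same && length(rt) > 0 && any(in_ex),
    "j" = same && length(qt) > 0 && length(rt) > 0 &&
      length(intersect(qt, rt)) > 0,
    "o" = same && ov,
    "x" = !same && ov,
    "i" = nrow(ri) > 0 && any(ri[, 1] <= min(qa) & max(qa) <= ri[, 2]),
    "y" = nrow(qi) > 0 && any(qi[, 1] <= min(ra) & max(ra) <= qi[, 2]))
  names(ok)[ok]
}

oracle_classify <- function(q, refs) {
  prio <- c("=", "k", "m", "n", "j", "o", "x", "i", "y")
  hits <- lapply(refs, oracle_code_pair, q = q)
  for (code in prio) if (any(vapply(hits, function(h) code %in% h, logical(1))))
    return(code)
  "u"
}

# Random multi-purpose transcript on a compact coordinate range so random
# query/reference pairs overlap often.
random_tx <- function(id = "q", chrom = "c1", max_exons = 6) {
  k <- sample.int(max_exons, 1)
  el <- sample(3:40, k, replace = TRUE)
  il <- if (k > 1) sample(2:40, k - 1, replace = TRUE) else integer(0)
  start <- sample.int(150, 1)
  starts <- start + c(0L, cumsum(el[-k] + il))
  transcript_model(id, paste0(id, "_g"), chrom,
                   sample(c("+", "-"), 1), cbind(starts, starts + el - 1L))
}

# Toy spot matrix from a dense count matrix and region labels.
toy_matrix <- function(counts, regions = NULL, gene_id = NULL, n_exons = 2L) {
  tx <- data.frame(transcript_id = rownames(counts) %||%
                     sprintf("t%03d", seq_len(nrow(counts))),
                   gene_id = gene_id %||% sprintf("g%03d", seq_len(nrow(counts))),
                   n_exons = n_exons, class_code = NA_character_,
                   stringsAsFactors = FALSE)
  sp <- data.frame(barcode = colnames(counts) %||%
                     sprintf("s%03d", seq_len(ncol(counts))),
                   x = seq_len(ncol(counts)), y = 0L,
                   region = regions %||% NA_character_,
                   stringsAsFactors = FALSE)
  rownames(counts) <- tx$transcript_id
  colnames(counts) <- sp$barcode
  spot_count_matrix(counts, tx, sp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
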