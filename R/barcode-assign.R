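#' Locate the barcode search window downstream of the adapter
#'
#' The adapter is aligned semi-globally (adapter end-to-end, read ends free)
#' against both orientations of each read; if the better orientation reaches
#' at least `identity_min` identity, the barcode window starts immediately
#' after the adapter on that strand. Coordinates refer to the oriented read
#' (the read itself for `+`, its reverse complement for `-`).
#'
#' @param reads Character vector of read sequences.
#' @param layout A [read_layout()].
#' @param identity_min Minimum adapter identity, `1 - dist/len` (default 0.7).
#' @return `data.frame` with columns `found`, `orientation`, `window_start`,
#'   `window_end`, `adapter_identity`.
#' @export
locate_barcode_region <- function(reads, layout, identity_min = 0.7) {
  if (!length(reads))
    return(data.frame(found = logical(0), orientation = character(0),
                      window_start = integer(0), window_end = integer(0),
                      adapter_identity = numeric(0)))
  if (any(!nzchar(reads))) stopf("empty read sequence")
  ad <- layout$adapter_seq
  fwd <- .semiglobal(ad, reads)
  rev <- .semiglobal(ad, reverse_complement(reads))
  use_rev <- rev$dist < fwd$dist
  best <- fwd
  best[use_rev, ] <- rev[use_rev, ]
  identity <- pmax(0, 1 - best$dist / nchar(ad))
  found <- identity >= identity_min
  data.frame(found = found,
             orientation = ifelse(found, ifelse(use_rev, "-", "+"), NA),
             window_start = ifelse(found, best$end + 1L, NA_integer_),
             window_end = ifelse(found, best$end + layout$barcode_len, NA_integer_),
             adapter_identity = ifelse(found, identity, NA_real_),
             stringsAsFactors = FALSE)
}

#' Error-tolerant whitelist matching
#'
#' Exhaustive banded Levenshtein comparison of an extracted segment against
#' the whole whitelist.
#'
#' @param segment Extracted barcode-window sequence; its length must lie
#'   within `barcode_len +/- max_dist`.
#' @param whitelist A `whitelist`.
#' @param max_dist Maximum edit distance (default 2).
#' @return `data.frame` of candidates (`barcode`, `edit_distance`) within
#'   `max_dist`, sorted by distance, then decreasing short-read abundance,
#'   then barcode; zero rows when nothing matches.
#' @export
match_whitelist <- function(segment, whitelist, max_dist = 2) {
  bl <- nchar(whitelist$barcode[1])
  if (abs(nchar(segment) - bl) > max_dist)
    stopf("segment length %d outside barcode_len %d +/- %d", nchar(segment),
          bl, max_dist)
  d <- drop(.lev_matrix(segment, whitelist$barcode, as.integer(max_dist)))
  hit <- which(d <= max_dist)
  out <- data.frame(barcode = whitelist$barcode[hit],
                    edit_distance = d[hit], stringsAsFactors = FALSE)
  ab <- whitelist$short_read_count[hit]
  out[order(out$edit_distance, -ab, out$barcode), , drop = FALSE]
}

abundance_bin_of <- function(x, abundances, n_bins) {
  f <- vapply(x, function(v) mean(abundances <= v), numeric(1))
  pmin(n_bins, 1L + as.integer(floor(f * n_bins)))
}

#' Barcode alignment features for one candidate
#'
#' Deterministic feature vector used by the naive Bayes scorer:
#' `bc_edit_distance` (segment vs candidate), `margin` (distance to the best
#' other whitelist barcode, capped at `max_dist + 1`, minus the best
#' distance), `adapter_identity`, `position_offset` (semi-global start of the
#' candidate in a widened window minus the expected start) and
#' `abundance_bin` (quantile bin of the candidate's short-read count).
#'
#' @param read Read sequence.
#' @param location One row of [locate_barcode_region()] output.
#' @param candidate Candidate barcode.
#' @param whitelist A `whitelist`.
#' @param layout A [read_layout()].
#' @param max_dist Maximum edit distance used in matching.
#' @param n_abundance_bins Number of abundance quantile bins (default 8).
#' @return One-row `data.frame` of features.
#' @export
compute_features <- function(read, location, candidate, whitelist, layout,
                             max_dist = 2, n_abundance_bins = 8) {
  oriented <- if (location$orientation == "-") reverse_complement(read) else read
  seg <- substr(oriented, location$window_start, location$window_end)
  d <- drop(.lev_matrix(seg, whitelist$barcode, as.integer(max_dist)))
  best <- d[match(candidate, whitelist$barcode)]
  others <- d[whitelist$barcode != candidate]
  second <- if (length(others)) min(min(others), max_dist + 1L) else max_dist + 1L
  ws <- max(1L, location$window_start - max_dist)
  wide <- substr(oriented, ws, location$window_end + max_dist)
  al <- .semiglobal(candidate, wide)
  offset <- (ws + al$start[1] - 1L) - location$window_start
  data.frame(bc_edit_distance = as.integer(best),
             margin = as.integer(second - best),
             adapter_identity = location$adapter_identity,
             position_offset = as.integer(offset),
             abundance_bin = abundance_bin_of(
               whitelist$short_read_count[match(candidate, whitelist$barcode)],
               whitelist$short_read_count, n_abundance_bins))
}

# Vectorized location -> candidate -> feature pipeline shared by training and
# assignment. Returns a data.frame with one row per input read; reads without
# adapter or candidate have NA feature rows. `match_cap` widens the candidate
# search beyond max_dist (used in training, where distant candidates provide
# the labeled false class); margin is capped at match_cap + 1.
extract_candidates <- function(reads, whitelist, layout, max_dist = 2,
                               identity_min = 0.7, n_abundance_bins = 8,
                               match_cap = max_dist) {
  n <- length(reads)
  loc <- locate_barcode_region(reads, layout, identity_min)
  out <- data.frame(candidate = rep(NA_character_, n),
                    bc_edit_distance = NA_integer_, margin = NA_integer_,
                    adapter_identity = loc$adapter_identity,
                    position_offset = NA_integer_,
                    abundance_bin = NA_integer_,
                    umi = NA_character_,
                    adapter_found = loc$found, stringsAsFactors = FALSE)
  idx <- which(loc$found)
  if (!length(idx)) return(out)

  oriented <- reads[idx]
  neg <- loc$orientation[idx] == "-"
  oriented[neg] <- reverse_complement(oriented[neg])
  seg <- substr(oriented, loc$window_start[idx], loc$window_end[idx])

  # whitelist columns ordered by the tie-break (abundance desc, barcode asc)
  # so that max.col(ties = "first") realizes it
  bc_order <- order(-whitelist$short_read_count, whitelist$barcode)
  bcs <- whitelist$barcode[bc_order]
  cap <- as.integer(match_cap)
  best_d <- integer(length(idx)); best_j <- integer(length(idx))
  second_d <- integer(length(idx))
  chunk <- 4000L
  for (lo in seq(1L, length(idx), by = chunk)) {
    hi <- min(lo + chunk - 1L, length(idx))
    D <- .lev_matrix(seg[lo:hi], bcs, cap)
    bj <- max.col(-D, ties.method = "first")
    rows <- seq_len(nrow(D))
    bd <- D[cbind(rows, bj)]
    D[cbind(rows, bj)] <- cap + 1L
    sd <- do.call(pmin, lapply(seq_len(ncol(D)), function(j) D[, j]))
    best_d[lo:hi] <- bd; best_j[lo:hi] <- bj; second_d[lo:hi] <- sd
  }
  hit <- best_d <= cap
  cand <- ifelse(hit, bcs[best_j], NA_character_)
  out$candidate[idx] <- cand
  out$bc_edit_distance[idx] <- ifelse(hit, best_d, NA_integer_)
  out$margin[idx] <- ifelse(hit, pmin(second_d, cap + 1L) - best_d, NA_integer_)
  out$abundance_bin[idx[hit]] <- abundance_bin_of(
    whitelist$short_read_count[match(cand[hit], whitelist$barcode)],
    whitelist$short_read_count, n_abundance_bins)
  out$umi[idx] <- substr(oriented, loc$window_end[idx] + 1L,
                         loc$window_end[idx] + layout$umi_len)

  # position offset: semi-global placement of the candidate in a widened
  # window, grouped by candidate so the aligner runs once per barcode
  ws <- pmax(1L, loc$window_start[idx] - cap)
  wide <- substr(oriented, ws, loc$window_end[idx] + cap)
  off <- rep(NA_integer_, length(idx))
  for (bc in unique(cand[hit])) {
    sel <- which(hit & cand == bc)
    al <- .semiglobal(bc, wide[sel])
    off[sel] <- (ws[sel] + al$start - 1L) - loc$window_start[idx[sel]]
  }
  out$position_offset[idx] <- off
  out
}

#' Fit the naive Bayes barcode classifier
#'
#' Discrete naive Bayes over equal-frequency feature bins with Laplace
#' add-one smoothing; class priors are the empirical label frequencies.
#'
#' @param features `data.frame` of feature vectors (columns
#'   `bc_edit_distance`, `margin`, `adapter_identity`, `position_offset`,
#'   `abundance_bin`).
#' @param is_correct Logical label per row (candidate equals the true
#'   barcode).
#' @param n_bins Target number of equal-frequency bins per feature.
#' @param laplace Smoothing pseudo-count.
#' @return An object of class `nb_barcode_model`.
#' @export
fit_naive_bayes <- function(features, is_correct, n_bins = 8, laplace = 1) {
  feat_cols <- c("bc_edit_distance", "margin", "adapter_identity",
                 "position_offset", "abundance_bin")
  feat_cols <- intersect(feat_cols, names(features))
  keep <- stats::complete.cases(features[feat_cols]) & !is.na(is_correct)
  features <- features[keep, , drop = FALSE]
  is_correct <- is_correct[keep]
  if (length(unique(is_correct)) < 2)
    stopf("both correct and false examples are required to fit the model")
  n_true <- sum(is_correct); n_false <- sum(!is_correct)
  fs <- lapply(feat_cols, function(f) {
    x <- features[[f]]
    qs <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                          names = FALSE)
    inner <- unique(qs[-c(1, n_bins + 1)])
    B <- length(inner) + 1L
    bin <- bin_values(x, inner)
    tab_t <- tabulate(bin[is_correct], nbins = B)
    tab_f <- tabulate(bin[!is_correct], nbins = B)
    list(edges = inner,
         log_p_true = log((tab_t + laplace) / (n_true + laplace * B)),
         log_p_false = log((tab_f + laplace) / (n_false + laplace * B)))
  })
  names(fs) <- feat_cols
  structure(list(prior_true = n_true / length(is_correct),
                 prior_false = n_false / length(is_correct),
                 features = fs, n_train = length(is_correct)),
            class = "nb_barcode_model")
}

bin_values <- function(x, inner) {
  if (!length(inner)) return(rep(1L, length(x)))
  findInterval(x, inner, left.open = TRUE) + 1L
}

#' Posterior probability of a correct barcode assignment
#'
#' Applies the naive Bayes product rule in log space; feature values outside
#' the training range clamp to the boundary bins.
#'
#' @param model An [fit_naive_bayes()] model.
#' @param features `data.frame` of feature vectors.
#' @return Numeric posterior in `[0, 1]` per row.
#' @export
nb_posterior <- function(model, features) {
  lt <- rep(log(model$prior_true), nrow(features))
  lf <- rep(log(model$prior_false), nrow(features))
  for (f in names(model$features)) {
    spec <- model$features[[f]]
    bin <- bin_values(features[[f]], spec$edges)
    lt <- lt + spec$log_p_true[bin]
    lf <- lf + spec$log_p_false[bin]
  }
  1 / (1 + exp(lf - lt))
}

#' Train the barcode model on a labeled simulation
#'
#' Simulates reads with the given layout and error model (including decoys),
#' runs the location/matching/feature pipeline, labels each scored candidate
#' against the simulation's ground truth, and fits the naive Bayes model.
#'
#' During training the candidate search is widened to `max_dist + 2` so that
#' decoy reads (and reads whose barcode was corrupted beyond `max_dist`)
#' contribute scored-but-wrong candidates -- the labeled false class. At
#' assignment time only candidates within `max_dist` are scored.
#'
#' @inheritParams simulate_reads
#' @param n_reads Training reads (default 20000).
#' @param max_dist,identity_min,n_bins Pipeline and model parameters.
#' @param seed Integer seed for the training simulation.
#' @return An `nb_barcode_model` with attribute `training` (labeled feature
#'   table).
#' @export
train_barcode_model <- function(whitelist, layout, errors, n_reads = 20000,
                                decoy_fraction = 0.3, max_dist = 2,
                                identity_min = 0.7, n_bins = 8, seed = 1) {
  sim <- simulate_reads(whitelist, layout, errors, n_reads,
                        decoy_fraction = decoy_fraction,
                        decoy_min_dist = min(3, max_dist + 1), seed = seed)
  feats <- extract_candidates(sim$sequence, whitelist, layout, max_dist,
                              identity_min, match_cap = max_dist + 2L)
  ok <- !is.na(feats$candidate)
  label <- !is.na(sim$true_barcode) & feats$candidate == sim$true_barcode
  model <- fit_naive_bayes(feats[ok, , drop = FALSE], label[ok],
                           n_bins = n_bins)
  attr(model, "training") <- cbind(feats[ok, , drop = FALSE],
                                   is_correct = label[ok])
  model
}

#' Assign spatial barcodes to reads
#'
#' Per read: adapter location, error-tolerant whitelist matching (ties at
#' equal distance broken by higher short-read abundance, then lexicographic),
#' naive Bayes scoring of the best candidate, and assignment when the
#' posterior reaches `cutoff`. The per-step attrition (adapter found,
#' candidate found, assigned) is attached as attribute `summary`.
#'
#' @param reads FASTQ path or named character vector of sequences.
#' @param whitelist A `whitelist`.
#' @param layout A [read_layout()].
#' @param model A fitted `nb_barcode_model`.
#' @param cutoff Posterior cutoff (default 0.95).
#' @param max_dist Maximum barcode edit distance (default 2).
#' @param identity_min Adapter identity threshold (default 0.7).
#' @return `data.frame` with `read_id`, `barcode` (`NA` below cutoff),
#'   `score`, `score_0_100`, the feature columns and `umi`.
#' @export
assign_barcodes <- function(reads, whitelist, layout, model, cutoff = 0.95,
                            max_dist = 2, identity_min = 0.7) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_fastq(reads)
  if (is.data.frame(reads)) {
    seqs <- stats::setNames(reads$sequence, reads$read_id)
  } else seqs <- reads
  ids <- names(seqs) %||% sprintf("read_%06d", seq_along(seqs))
  n <- length(seqs)
  if (n == 0) {
    out <- data.frame(read_id = character(0), barcode = character(0),
                      score = numeric(0), score_0_100 = numeric(0))
    attr(out, "summary") <- data.frame(
      step = c("input", "adapter_found", "candidate_found", "assigned"),
      reads = c(0L, 0L, 0L, 0L), stringsAsFactors = FALSE)
    return(out)
  }
  feats <- extract_candidates(unname(seqs), whitelist, layout, max_dist,
                              identity_min)
  has_cand <- !is.na(feats$candidate)
  score <- rep(NA_real_, n)
  if (any(has_cand))
    score[has_cand] <- nb_posterior(model, feats[has_cand, , drop = FALSE])
  assigned <- has_cand & score >= cutoff
  out <- data.frame(read_id = ids,
                    barcode = ifelse(assigned, feats$candidate, NA_character_),
                    score = score,
                    score_0_100 = round(100 * score, 2),
                    bc_edit_distance = feats$bc_edit_distance,
                    margin = feats$margin,
                    adapter_identity = feats$adapter_identity,
                    position_offset = feats$position_offset,
                    abundance_bin = feats$abundance_bin,
                    umi = feats$umi, stringsAsFactors = FALSE)
  attr(out, "summary") <- data.frame(
    step = c("input", "adapter_found", "candidate_found", "assigned"),
    reads = c(n, sum(feats$adapter_found), sum(has_cand), sum(assigned)),
    stringsAsFactors = FALSE)
  out
}

#' Write / read an assignment table TSV
#' @param assignments Output of [assign_barcodes()].
#' @param path File path.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "",
                          stringsAsFactors = FALSE)
  df$read_id <- as.character(df$read_id)
  df$barcode <- as.character(df$barcode)
  df
}
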