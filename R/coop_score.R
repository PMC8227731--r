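#' Scoring configuration for TF-pair cooperation
#'
#' Bundles the distance constraint, the background scaling factor, the
#' significance threshold and the shuffling settings. Defaults follow the
#' recommended settings of the PMI co-occurrence method: site gaps of
#' 5-20 bp, background scaling `alpha = 0.2`, significance at z >= 3,
#' 10 dinucleotide-preserving shuffle replicates, log base 2.
#'
#' @param d_min,d_max Inclusive gap bounds in bp between two sites
#'   (edge-to-edge by default; see `distance`).
#' @param alpha Background scaling factor in `[-1, +1]`: the corrected
#'   score is `PMI - (1 + alpha) * AVG(PMI)`. `alpha = -1` switches the
#'   correction off.
#' @param z_threshold Significance threshold on the z-score (inclusive).
#' @param n_shuffles Number of shuffled-corpus replicates for the
#'   background average.
#' @param log_base Base of the PMI logarithm.
#' @param seed Master seed for the shuffle replicates.
#' @param distance `"edge"` (gap between intervals, negative when
#'   overlapping) or `"center"` (distance between site midpoints).
#' @param homotypic Keep pairs of sites that share a TF name? Default
#'   `FALSE`: cooperation is reported between distinct factors.
#' @param shuffle `"dinucleotide"` (default) or `"mononucleotide"`
#'   background shuffling.
#' @return Object of class `scoring_config`.
#' @export
scoring_config <- function(d_min = 5L, d_max = 20L, alpha = 0.2,
                           z_threshold = 3.0, n_shuffles = 10L,
                           log_base = 2, seed = 1L,
                           distance = c("edge", "center"),
                           homotypic = FALSE,
                           shuffle = c("dinucleotide", "mononucleotide")) {
  distance <- match.arg(distance)
  shuffle <- match.arg(shuffle)
  stopifnot(d_min >= 0L, d_min <= d_max, n_shuffles >= 1L, log_base > 1)
  if (alpha < -1 || alpha > 1) stop("alpha must lie in [-1, +1]")
  structure(list(d_min = as.integer(d_min), d_max = as.integer(d_max),
                 alpha = alpha, z_threshold = z_threshold,
                 n_shuffles = as.integer(n_shuffles), log_base = log_base,
                 seed = as.integer(seed), distance = distance,
                 homotypic = homotypic, shuffle = shuffle),
            class = "scoring_config")
}

# Canonical unordered pair label: TF names sorted lexicographically.
pair_key <- function(tf_a, tf_b) {
  swap <- tf_a > tf_b
  a <- ifelse(swap, tf_b, tf_a)
  b <- ifelse(swap, tf_a, tf_b)
  list(tf_a = a, tf_b = b, key = paste(a, b, sep = "\t"))
}

#' Enumerate distance-constrained site pairs
#'
#' For every unordered pair of predicted sites within one promoter, the
#' distance is the edge-to-edge gap `max(start) - min(end)` (negative
#' when the sites overlap); a pair is emitted when
#' `d_min <= distance <= d_max`. Pairs of sites sharing a TF name are
#' skipped unless `config$homotypic` is set — even when the sites come
#' from different matrices of that TF.
#'
#' @param sites Site data frame from [scan_promoters].
#' @param config A [scoring_config].
#' @return Data frame with columns `tf_a`, `tf_b` (canonically ordered),
#'   `promoter_id`, `distance`; zero rows when nothing co-occurs.
#' @export
enumerate_pairs <- function(sites, config = scoring_config()) {
  empty <- data.frame(tf_a = character(), tf_b = character(),
                      promoter_id = character(), distance = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(sites) < 2L) return(empty)
  out <- list()
  for (s in split(sites, sites$promoter_id)) {
    m <- nrow(s)
    if (m < 2L) next
    idx <- utils::combn(m, 2L)
    i <- idx[1L, ]; j <- idx[2L, ]
    if (config$distance == "edge") {
      d <- pmax(s$start[i], s$start[j]) - pmin(s$end[i], s$end[j])
    } else {
      d <- abs((s$start[i] + s$end[i]) - (s$start[j] + s$end[j])) / 2
    }
    keep <- d >= config$d_min & d <= config$d_max
    if (!config$homotypic) keep <- keep & s$tf_name[i] != s$tf_name[j]
    if (!any(keep)) next
    pk <- pair_key(s$tf_name[i][keep], s$tf_name[j][keep])
    out[[length(out) + 1L]] <- data.frame(
      tf_a = pk$tf_a, tf_b = pk$tf_b,
      promoter_id = s$promoter_id[1L],
      distance = as.integer(round(d[keep])),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$tf_a, res$tf_b, res$promoter_id, res$distance), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Pointwise mutual information of co-occurring TF pairs
#'
#' Frequencies are summed over the whole promoter set: for pair (a, b),
#' `p_ab = f_ab / F_pairs` with `f_ab` the number of distance-qualified
#' site pairs and `F_pairs` their total over all pairs; the marginals
#' `p_a = f_a / F_sites` use each TF's total predicted site count. Then
#' `PMI(a;b) = log(p_ab / (p_a p_b))` in `config$log_base`. Pairs never
#' observed under the distance constraint get no PMI row (they are
#' excluded, not scored at -Inf).
#'
#' @param pairs Pair occurrences from [enumerate_pairs].
#' @param sites Site data frame the pairs were derived from.
#' @param config A [scoring_config].
#' @return Data frame with columns `tf_a`, `tf_b`, `f_ab`, `f_a`, `f_b`,
#'   `pmi`, one row per observed pair.
#' @export
pmi <- function(pairs, sites, config = scoring_config()) {
  if (nrow(pairs) == 0L)
    stop("no co-occurrences under distance constraints")
  key <- paste(pairs$tf_a, pairs$tf_b, sep = "\t")
  tab <- table(key)
  f_ab <- as.vector(tab)
  keys <- names(tab)
  split_keys <- strsplit(keys, "\t", fixed = TRUE)
  tf_a <- vapply(split_keys, `[`, "", 1L)
  tf_b <- vapply(split_keys, `[`, "", 2L)
  site_counts <- table(sites$tf_name)
  F_pairs <- sum(f_ab)
  F_sites <- sum(site_counts)
  f_a <- as.vector(site_counts[tf_a])
  f_b <- as.vector(site_counts[tf_b])
  p_ab <- f_ab / F_pairs
  p_a <- f_a / F_sites
  p_b <- f_b / F_sites
  res <- data.frame(tf_a = tf_a, tf_b = tf_b, f_ab = f_ab,
                    f_a = f_a, f_b = f_b,
                    pmi = log(p_ab / (p_a * p_b), base = config$log_base),
                    stringsAsFactors = FALSE)
  res <- res[order(res$tf_a, res$tf_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Derive a reproducible 31-bit stream seed from a master seed and a
# label, so different pipeline stages draw from independent streams.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

#' Background PMI from shuffled promoters
#'
#' Estimates each pair's background cooperation level: every promoter is
#' shuffled preserving its dinucleotide (or mononucleotide) composition,
#' the shuffled corpus is rescanned and re-scored with [pmi], and the
#' pair's background average `AVG(PMI)` is the arithmetic mean over
#' `config$n_shuffles` replicates, with replicates where the pair never
#' co-occurs contributing 0. Pairs absent from every replicate therefore
#' get `AVG = 0` (no background cooperation).
#'
#' @param promoters A `promoter_set`.
#' @param pwms List of `pwm` objects.
#' @param profile A [scan_profile].
#' @param config A [scoring_config]; `config$seed` seeds the shuffles.
#' @return Named numeric vector of background averages keyed by
#'   `"tf_a\ttf_b"`.
#' @export
background_avg_pmi <- function(promoters, pwms, profile = scan_profile(),
                               config = scoring_config()) {
  sums <- numeric(0)
  for (r in seq_len(config$n_shuffles)) {
    shuf <- promoters
    seed_r <- derive_seed(config$seed, paste0("background_shuffle_", r))
    shuf$sequence <- shuffle_sequences(promoters$sequence, seed = seed_r,
                                       mode = config$shuffle)
    ssites <- scan_promoters(shuf, pwms, profile)
    spairs <- enumerate_pairs(ssites, config)
    if (nrow(spairs) == 0L) next
    sp <- pmi(spairs, ssites, config)
    k <- paste(sp$tf_a, sp$tf_b, sep = "\t")
    new <- setdiff(k, names(sums))
    if (length(new)) sums[new] <- 0
    sums[k] <- sums[k] + sp$pmi
  }
  sums / config$n_shuffles
}

#' Background-corrected PMI
#'
#' `PMIcor = PMI - (1 + alpha) * AVG(PMI)`: the scaled background average
#' is subtracted from the foreground PMI. `alpha = -1` leaves PMI
#' unchanged; `alpha = +1` doubles the background penalty.
#'
#' @param pmi_value Foreground PMI (vectorized).
#' @param avg_value Background average PMI (vectorized).
#' @param alpha Scaling factor in `[-1, +1]`.
#' @return `pmi_value - (1 + alpha) * avg_value`.
#' @export
#' @examples
#' pmi_cor(1.0, 0.5, alpha = 0.2)  # 0.4
pmi_cor <- function(pmi_value, avg_value, alpha = 0.2) {
  if (any(alpha < -1 | alpha > 1)) stop("alpha must lie in [-1, +1]")
  pmi_value - (1 + alpha) * avg_value
}

#' Transform corrected PMI values to z-scores
#'
#' Centers and scales by the population (divide-by-n) standard deviation
#' over all scored pairs. A zero-variance input maps to all-zero
#' z-scores.
#'
#' @param x Numeric vector of corrected PMI values (>= 2 finite values).
#' @return Numeric vector of z-scores, same length and names as `x`.
#' @export
zscore_transform <- function(x) {
  if (sum(is.finite(x)) < 2L)
    stop("need at least 2 finite values for the z-transform")
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  if (sdev == 0) return(x * 0)
  (x - mu) / sdev
}

#' Score TF-pair cooperation across a promoter set
#'
#' The full pair-statistics pipeline: scan the promoters, enumerate
#' distance-qualified heterotypic site pairs, compute each pair's PMI,
#' estimate the shuffled-background average, apply the alpha-scaled
#' correction and z-transform the corrected values.
#'
#' @param promoters A `promoter_set` (already overlap/duplicate filtered
#'   if desired).
#' @param pwms List of `pwm` objects.
#' @param profile A [scan_profile].
#' @param config A [scoring_config].
#' @param sites Optional precomputed site table for these promoters.
#' @return Data frame of class `pair_statistics` with columns `tf_a`,
#'   `tf_b`, `f_ab`, `f_a`, `f_b`, `pmi`, `avg_pmi`, `pmi_cor`, `z`,
#'   `significant`, sorted by descending `z`.
#' @export
score_pairs <- function(promoters, pwms, profile = scan_profile(),
                        config = scoring_config(), sites = NULL) {
  if (is.null(sites)) sites <- scan_promoters(promoters, pwms, profile)
  pairs <- enumerate_pairs(sites, config)
  stats <- pmi(pairs, sites, config)
  if (nrow(stats) < 2L)
    stop("need at least 2 co-occurring TF pairs to compute z-scores")
  bg <- background_avg_pmi(promoters, pwms, profile, config)
  k <- paste(stats$tf_a, stats$tf_b, sep = "\t")
  stats$avg_pmi <- ifelse(k %in% names(bg), bg[k], 0)
  stats$avg_pmi[is.na(stats$avg_pmi)] <- 0
  stats$pmi_cor <- pmi_cor(stats$pmi, stats$avg_pmi, config$alpha)
  stats$z <- zscore_transform(stats$pmi_cor)
  stats$significant <- stats$z >= config$z_threshold
  stats <- stats[order(-stats$z, stats$tf_a, stats$tf_b), , drop = FALSE]
  rownames(stats) <- NULL
  class(stats) <- c("pair_statistics", "data.frame")
  stats
}

#' Filter and rank significant pairs
#'
#' Subset of the pair statistics with `z >= config$z_threshold`
#' (inclusive), sorted by descending z with deterministic lexicographic
#' tie-breaking.
#'
#' @param stats `pair_statistics` from [score_pairs].
#' @param config A [scoring_config].
#' @return Filtered `pair_statistics` (possibly zero rows).
#' @export
significant_pairs <- function(stats, config = scoring_config()) {
  res <- stats[stats$z >= config$z_threshold, , drop = FALSE]
  res <- res[order(-res$z, res$tf_a, res$tf_b), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("pair_statistics", "data.frame")
  res
}

#' Write a pair-statistics table as TSV
#'
#' Numeric columns are printed at full precision (17 significant digits)
#' so the table round-trips bit-exactly.
#'
#' @param stats `pair_statistics` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(stats, path) {
  out <- as.data.frame(stats)
  for (col in c("pmi", "avg_pmi", "pmi_cor", "z"))
    out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a pair-statistics table written by [write_pairs_tsv]
#' @param path TSV path.
#' @return `pair_statistics` data frame.
#' @export
read_pairs_tsv <- function(path) {
  res <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(tf_a = "character",
                                          tf_b = "character"))
  class(res) <- c("pair_statistics", "data.frame")
  res
}
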