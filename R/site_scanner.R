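#' Scan cutoff profile
#'
#' Cutoffs applied to the MATCH-style core and matrix similarity scores.
#' The defaults (0.75 core, 0.80 matrix) are conventional conservative
#' values; both can be overridden globally here or per matrix via
#' `per_matrix`, a data frame with columns `id`, `core_cutoff`,
#' `matrix_cutoff`.
#'
#' @param core_cutoff,matrix_cutoff Scalars in `[0, 1]`.
#' @param per_matrix Optional per-matrix override table.
#' @return Object of class `scan_profile`.
#' @export
scan_profile <- function(core_cutoff = 0.75, matrix_cutoff = 0.80,
                         per_matrix = NULL) {
  stopifnot(core_cutoff >= 0, core_cutoff <= 1,
            matrix_cutoff >= 0, matrix_cutoff <= 1)
  structure(list(core_cutoff = core_cutoff, matrix_cutoff = matrix_cutoff,
                 per_matrix = per_matrix),
            class = "scan_profile")
}

# Precompute the scoring tables for one PWM: an L x 5 weight matrix
# (columns A,C,G,T,N where N takes the per-position minimum, so an N can
# never create a site) plus min/max normalizers for the full matrix and
# for the 5-position core.
scan_tables <- function(pwm) {
  iv <- information_vector(pwm)
  f <- pwm$freq
  w <- iv * f                              # L x 4, recycled by column
  wmin <- iv * apply(f, 1L, min)
  wmax <- iv * apply(f, 1L, max)
  W <- cbind(w, N = wmin)
  core <- core_positions(pwm)
  list(W = W, L = pwm$length, core = core,
       min_all = sum(wmin), max_all = sum(wmax),
       min_core = sum(wmin[core]), max_core = sum(wmax[core]))
}

# Map a DNA string to integer codes 1..5 (A,C,G,T,N; any other IUPAC
# ambiguity code is treated as N).
encode_dna <- function(seq) {
  lut <- rep(5L, 256L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt(toupper(seq))]
}

# Raw (normalized) matrix and core scores for every window start of an
# encoded sequence against one precomputed PWM table. Returns a list of
# two numeric vectors of length n - L + 1 (empty if the sequence is
# shorter than the matrix).
window_scores <- function(codes, tab) {
  n <- length(codes); L <- tab$L
  nw <- n - L + 1L
  if (nw < 1L) return(list(matrix = numeric(0), core = numeric(0)))
  sc_all <- numeric(nw); sc_core <- numeric(nw)
  in_core <- seq_len(L) %in% tab$core
  for (i in seq_len(L)) {
    v <- unname(tab$W[i, codes[i:(i + nw - 1L)]])
    sc_all <- sc_all + v
    if (in_core[i]) sc_core <- sc_core + v
  }
  den_all <- tab$max_all - tab$min_all
  den_core <- tab$max_core - tab$min_core
  list(
    matrix = if (den_all > 0) (sc_all - tab$min_all) / den_all else rep(0, nw),
    core = if (den_core > 0) (sc_core - tab$min_core) / den_core else rep(0, nw)
  )
}

#' MATCH-style matrix similarity of a window against a PWM
#'
#' The information-weighted, min-max normalized similarity
#' `(Current - Min) / (Max - Min)` with
#' `Current = sum_i I(i) f(i, w_i)`, `Max`/`Min` the per-position
#' maxima/minima. An `N` contributes the position minimum (penalizing,
#' never site-creating). Returns 0 for an all-uniform matrix
#' (`Max == Min`).
#'
#' @param pwm A `pwm` object.
#' @param window DNA string of length `pwm$length`.
#' @return Score in `[0, 1]`.
#' @export
matrix_similarity <- function(pwm, window) {
  if (nchar(window) != pwm$length)
    stop("window length ", nchar(window), " != PWM length ", pwm$length)
  window_scores(encode_dna(window), scan_tables(pwm))$matrix
}

#' MATCH-style core similarity of a window against a PWM
#'
#' [matrix_similarity] restricted to the 5 most conserved consecutive
#' positions ([core_positions]); for matrices of length 5 or less it
#' equals the full matrix similarity.
#'
#' @inheritParams matrix_similarity
#' @return Score in `[0, 1]`.
#' @export
core_similarity <- function(pwm, window) {
  if (nchar(window) != pwm$length)
    stop("window length ", nchar(window), " != PWM length ", pwm$length)
  window_scores(encode_dna(window), scan_tables(pwm))$core
}

#' Predict binding sites in one promoter
#'
#' Slides every PWM over every offset of the promoter sequence and its
#' reverse complement, and emits a binding site wherever both the core
#' and the matrix similarity reach their cutoffs. Minus-strand hits are
#' reported in forward-strand coordinates (0-based half-open offsets
#' within the promoter). Overlapping hits of the same PWM are all kept;
#' the co-occurrence statistics operate on the full site list.
#'
#' @param promoter One-row `promoter_set` (or any list with `gene_id` and
#'   `sequence`).
#' @param pwms List of `pwm` objects.
#' @param profile A [scan_profile].
#' @param .tables Precomputed [scan_tables] (internal reuse).
#' @return Data frame of sites with columns `promoter_id`, `tf_name`,
#'   `pwm_id`, `start`, `end`, `strand`, `core_score`, `matrix_score`,
#'   sorted by (start, end, tf_name, strand).
#' @export
scan_promoter <- function(promoter, pwms, profile = scan_profile(),
                          .tables = NULL) {
  seq <- promoter$sequence
  id <- promoter$gene_id
  if (is.null(.tables)) .tables <- lapply(pwms, scan_tables)
  codes_f <- encode_dna(seq)
  codes_r <- c(4L, 3L, 2L, 1L, 5L)[rev(codes_f)]  # reverse complement
  n <- length(codes_f)
  acc <- list()
  for (k in seq_along(pwms)) {
    p <- pwms[[k]]; tab <- .tables[[k]]
    cc <- profile$core_cutoff; mc <- profile$matrix_cutoff
    if (!is.null(profile$per_matrix)) {
      row <- match(p$id, profile$per_matrix$id)
      if (!is.na(row)) {
        cc <- profile$per_matrix$core_cutoff[row]
        mc <- profile$per_matrix$matrix_cutoff[row]
      }
    }
    for (strand in c("+", "-")) {
      sc <- window_scores(if (strand == "+") codes_f else codes_r, tab)
      hit <- which(sc$core >= cc & sc$matrix >= mc)
      if (length(hit) == 0L) next
      start0 <- hit - 1L                      # 0-based offset on scanned strand
      if (strand == "-") start0 <- n - (start0 + tab$L)
      acc[[length(acc) + 1L]] <- data.frame(
        promoter_id = id, tf_name = p$tf_name, pwm_id = p$id,
        start = start0, end = start0 + tab$L, strand = strand,
        core_score = sc$core[hit], matrix_score = sc$matrix[hit],
        stringsAsFactors = FALSE)
    }
  }
  if (length(acc) == 0L) return(empty_sites())
  res <- do.call(rbind, acc)
  res <- res[order(res$start, res$end, res$tf_name, res$strand), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_sites <- function() {
  data.frame(promoter_id = character(), tf_name = character(),
             pwm_id = character(), start = integer(), end = integer(),
             strand = character(), core_score = numeric(),
             matrix_score = numeric(), stringsAsFactors = FALSE)
}

#' Predict binding sites across a promoter set
#'
#' [scan_promoter] applied to every promoter, with the PWM scoring tables
#' computed once.
#'
#' @param promoters A `promoter_set`.
#' @param pwms List of `pwm` objects.
#' @param profile A [scan_profile].
#' @return Combined site data frame (see [scan_promoter]).
#' @export
scan_promoters <- function(promoters, pwms, profile = scan_profile()) {
  tables <- lapply(pwms, scan_tables)
  res <- lapply(seq_len(nrow(promoters)), function(i)
    scan_promoter(promoters[i, ], pwms, profile, .tables = tables))
  res <- do.call(rbind, res)
  if (is.null(res)) res <- empty_sites()
  rownames(res) <- NULL
  res
}

#' Write a site table as TSV
#'
#' Scores are printed to 6 decimal places; row order is the scanner's
#' deterministic sort.
#'
#' @param sites Site data frame from [scan_promoters].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  out <- sites
  out$core_score <- sprintf("%.6f", out$core_score)
  out$matrix_score <- sprintf("%.6f", out$matrix_score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a site table written by [write_sites_tsv]
#' @param path TSV path.
#' @return Site data frame.
#' @export
read_sites_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(promoter_id = "character",
                                   tf_name = "character",
                                   pwm_id = "character"))
}

#' Write sites as BED6
#'
#' `name` is the TF name and `score` is `round(1000 * matrix_score)`;
#' coordinates are promoter-local.
#'
#' @inheritParams write_sites_tsv
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(sites$promoter_id, sites$start, sites$end,
                    sites$tf_name, round(1000 * sites$matrix_score),
                    sites$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
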