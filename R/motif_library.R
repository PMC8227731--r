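DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' A `pwm` holds a factor's positional base-count model together with the
#' pseudocount-regularized frequency matrix derived from it. The frequency
#' matrix is what all downstream scoring uses; counts are kept verbatim so
#' motif files round-trip exactly.
#'
#' @param id Matrix accession string (e.g. `"V$GATA4_Q3"` or `"MA0001.1"`).
#' @param counts Numeric L x 4 matrix of non-negative base counts, columns
#'   ordered A, C, G, T. L must be at least 4.
#' @param tf_name Factor label used as the pairing unit. Defaults to
#'   [normalize_tf_name]`(id)`.
#' @param pseudocount Value added to every count cell before row
#'   normalization; guarantees strictly positive frequencies so log terms
#'   stay finite. Default `1e-3`.
#'
#' @return An object of class `pwm` with fields `id`, `tf_name`, `counts`,
#'   `freq` and `length`.
#' @export
#' @examples
#' m <- matrix(c(8, 0, 0, 0,
#'               0, 8, 0, 0,
#'               0, 0, 8, 0,
#'               0, 0, 0, 8), nrow = 4, byrow = TRUE)
#' pwm <- new_pwm("V$TOY_01", m)
#' pwm$tf_name  # "TOY"
new_pwm <- function(id, counts, tf_name = normalize_tf_name(id),
                    pseudocount = 1e-3) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L)
    stop("PWM '", id, "': counts must have 4 columns (A,C,G,T)")
  if (nrow(counts) < 4L)
    stop("PWM '", id, "': need at least 4 positions, got ", nrow(counts))
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("PWM '", id, "': counts must be finite and non-negative")
  storage.mode(counts) <- "double"
  colnames(counts) <- DNA_BASES
  rownames(counts) <- NULL
  reg <- counts + pseudocount
  freq <- reg / rowSums(reg)
  obj <- structure(
    list(id = id, tf_name = tf_name, counts = counts, freq = freq,
         length = nrow(counts)),
    class = "pwm"
  )
  validate_pwm(obj)
  obj
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (TF %s), %d positions\nconsensus: %s\n",
              x$id, x$tf_name, x$length, consensus(x)))
  invisible(x)
}

validate_pwm <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  if (pwm$length != nrow(pwm$counts) || pwm$length != nrow(pwm$freq))
    stop("PWM '", pwm$id, "': length field disagrees with matrix rows")
  if (any(abs(rowSums(pwm$freq) - 1) > 1e-9))
    stop("PWM '", pwm$id, "': frequency rows must sum to 1")
  if (any(pwm$freq <= 0))
    stop("PWM '", pwm$id, "': frequencies must be strictly positive")
  invisible(pwm)
}

#' Per-position argmax consensus of a PWM
#' @param pwm A [new_pwm] object.
#' @return Character scalar of length `pwm$length`.
#' @export
consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$freq, 1L, which.max)], collapse = "")
}

#' Normalize a motif accession to a TF pairing name
#'
#' Strips the site-type prefix (`V$`, `F$`, ...) and a trailing quality or
#' version suffix (`_01`, `_Q3`, ...), then uppercases. This name is the
#' unit at which binding sites are pooled and pairs are reported: several
#' matrices for one factor all contribute sites under a single name, the
#' level at which cooperation networks are usually discussed.
#'
#' @param id Matrix accession or identifier string.
#' @return Character TF name.
#' @export
#' @examples
#' normalize_tf_name("V$STAT6_01")  # "STAT6"
#' normalize_tf_name("V$GATA4_Q3")  # "GATA4"
normalize_tf_name <- function(id) {
  x <- sub("^[A-Za-z]+\\$", "", id)
  x <- sub("_Q?[0-9]+$", "", x)
  toupper(x)
}

#' Read PWMs from a TRANSFAC flat file
#'
#' Parses the TRANSFAC matrix flat-file dialect: records introduced by
#' `AC`/`ID` lines, a `P0` column header, numbered count rows with exactly
#' four numeric fields (an optional trailing consensus letter is ignored),
#' terminated by `//`. Counts are preserved exactly; the TF name is
#' derived from the `ID` field via [normalize_tf_name].
#'
#' @param path Path to the motif file.
#' @param pseudocount Passed to [new_pwm].
#' @return List of `pwm` objects.
#' @export
read_transfac <- function(path, pseudocount = 1e-3) {
  lines <- readLines(path, warn = FALSE)
  pwms <- list()
  ac <- id <- NULL
  rows <- list()
  in_matrix <- FALSE
  flush_record <- function(lineno) {
    if (is.null(ac) && is.null(id) && length(rows) == 0L) return(NULL)
    if (length(rows) == 0L)
      stop("TRANSFAC record '", ac %||% id %||% "?",
           "' near line ", lineno, " has no count rows")
    acc <- ac %||% id
    counts <- do.call(rbind, rows)
    new_pwm(acc, counts, tf_name = normalize_tf_name(id %||% acc),
            pseudocount = pseudocount)
  }
  for (k in seq_along(lines)) {
    ln <- lines[[k]]
    tag <- substr(ln, 1L, 2L)
    if (tag == "//") {
      p <- flush_record(k)
      if (!is.null(p)) pwms[[length(pwms) + 1L]] <- p
      ac <- id <- NULL; rows <- list(); in_matrix <- FALSE
    } else if (tag == "AC") {
      ac <- trimws(substr(ln, 3L, nchar(ln)))
    } else if (tag == "ID") {
      id <- trimws(substr(ln, 3L, nchar(ln)))
    } else if (tag == "P0" || tag == "PO") {
      in_matrix <- TRUE
    } else if (in_matrix && grepl("^[0-9]", ln)) {
      fields <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      vals <- suppressWarnings(as.numeric(fields[-1L]))
      # drop one trailing non-numeric consensus letter if present
      if (length(vals) >= 1L && is.na(vals[length(vals)]) &&
          grepl("^[A-Za-z]+$", fields[length(fields)]))
        vals <- vals[-length(vals)]
      if (length(vals) != 4L || anyNA(vals))
        stop("TRANSFAC matrix '", ac %||% id %||% "?", "': count row at line ",
             k, " does not have 4 numeric fields: '", ln, "'")
      rows[[length(rows) + 1L]] <- vals
    } else if (tag == "XX" || !nzchar(trimws(ln))) {
      next
    }
  }
  if (!is.null(ac) || !is.null(id) || length(rows) > 0L)
    stop("TRANSFAC file '", path, "': last record (accession '",
         ac %||% id %||% "?", "') is missing its '//' terminator")
  pwms
}

#' Write PWMs to a TRANSFAC flat file
#'
#' Inverse of [read_transfac]: counts are written verbatim so that a
#' read/write/read round trip reproduces identical matrices.
#'
#' @param pwms List of `pwm` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transfac <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(c(sprintf("AC  %s", p$id),
                 "XX",
                 sprintf("ID  %s", p$id),
                 "XX",
                 "P0      A      C      G      T"), con)
    for (i in seq_len(p$length)) {
      writeLines(sprintf("%02d  %s", i,
                         paste(formatC(p$counts[i, ], format = "g",
                                       digits = 15, width = 5),
                               collapse = "  ")), con)
    }
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}

#' Read PWMs from a JASPAR PFM file
#'
#' Accepts the JASPAR 2016+ format: a `>ID name` header followed by four
#' base rows, either bracketed (`A [ 4 19 0 ]`) or bare numbers. Rows are
#' mapped to A, C, G, T in file order.
#'
#' @inheritParams read_transfac
#' @return List of `pwm` objects (empty list for an empty file).
#' @export
read_jaspar <- function(path, pseudocount = 1e-3) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0L)
    stop("JASPAR file '", path, "': no '>' header found")
  bounds <- c(hdr_idx, length(lines) + 1L)
  pwms <- vector("list", length(hdr_idx))
  for (r in seq_along(hdr_idx)) {
    hdr <- sub("^>\\s*", "", lines[hdr_idx[r]])
    toks <- strsplit(trimws(hdr), "[[:space:]]+")[[1]]
    acc <- toks[1L]
    name <- if (length(toks) >= 2L) toks[2L] else acc
    body <- lines[seq(hdr_idx[r] + 1L, length.out = bounds[r + 1L] - hdr_idx[r] - 1L)]
    if (length(body) != 4L)
      stop("JASPAR record '", acc, "': expected 4 base rows, found ",
           length(body))
    rows <- lapply(body, function(ln) {
      ln <- gsub("^[[:space:]]*[ACGTacgt][[:space:]]*", "", ln)
      ln <- gsub("[][]", " ", ln)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]]))
      if (anyNA(vals) || length(vals) == 0L)
        stop("JASPAR record '", acc, "': non-numeric count row")
      vals
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L)
      stop("JASPAR record '", acc, "': base rows have unequal lengths (",
           paste(lens, collapse = ", "), ")")
    counts <- t(do.call(rbind, rows))  # rows were per-base; transpose to L x 4
    pwms[[r]] <- new_pwm(acc, counts, tf_name = toupper(name),
                         pseudocount = pseudocount)
  }
  pwms
}

#' Per-position information content of a PWM
#'
#' Computes, in natural-log units, `I(i) = sum_b f(i,b) * ln(4 f(i,b))` —
#' the relative entropy of position `i` against the uniform base
#' distribution. A uniform position scores 0; a near-degenerate position
#' approaches `ln 4`. This vector weights positions in the MATCH-style
#' similarity scores and defines the conserved core.
#'
#' @param pwm A `pwm` object.
#' @return Numeric vector of length `pwm$length`, entries in `[0, ln 4]`.
#' @export
information_vector <- function(pwm) {
  f <- pwm$freq
  rowSums(f * log(4 * f))
}

#' Most conserved 5-position core of a PWM
#'
#' Returns the 5 consecutive positions maximizing the summed information
#' vector, with ties broken leftmost. For matrices shorter than 5
#' positions the whole matrix is the core.
#'
#' @param pwm A `pwm` object.
#' @return Integer vector of (1-based) consecutive positions.
#' @export
core_positions <- function(pwm) {
  L <- pwm$length
  if (L <= 5L) return(seq_len(L))
  iv <- information_vector(pwm)
  sums <- vapply(seq_len(L - 4L), function(s) sum(iv[s:(s + 4L)]), numeric(1))
  s <- which.max(sums)  # which.max is leftmost on ties
  s:(s + 4L)
}

#' Summarize a motif library
#'
#' One row per matrix: accession, TF name, length, and the position with
#' maximal information content.
#'
#' @param pwms List of `pwm` objects.
#' @return A data frame with columns `id`, `tf_name`, `length`,
#'   `max_info_pos`, `consensus`.
#' @export
motif_summary <- function(pwms) {
  data.frame(
    id = vapply(pwms, `[[`, "", "id"),
    tf_name = vapply(pwms, `[[`, "", "tf_name"),
    length = vapply(pwms, `[[`, 0L, "length"),
    max_info_pos = vapply(pwms, function(p) which.max(information_vector(p)),
                          0L),
    consensus = vapply(pwms, consensus, ""),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
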