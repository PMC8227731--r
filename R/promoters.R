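#' Construct a promoter set
#'
#' Internal constructor/validator for the promoter table used throughout
#' the pipeline: one row per gene with its genomic window and the
#' (strand-oriented) sequence. Coordinates are 0-based half-open, as in
#' BED, so adjacency is unambiguous and touching windows do not overlap.
#'
#' @param gene_id,chrom,start,end,strand,sequence Parallel vectors.
#' @param clipped Logical; whether the window was truncated at a
#'   chromosome end.
#' @return Data frame of class `promoter_set`.
#' @keywords internal
promoter_set <- function(gene_id, chrom, start, end, strand, sequence,
                         clipped = FALSE) {
  sequence <- toupper(sequence)
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   sequence = as.character(sequence),
                   clipped = rep_len(as.logical(clipped), length(gene_id)),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0L) {
    stopifnot(all(df$end > df$start),
              all(df$strand %in% c("+", "-")),
              all(nchar(df$sequence) == df$end - df$start))
    bad <- grepl("[^ACGTN]", df$sequence)
    if (any(bad))
      stop("promoter '", df$gene_id[which(bad)[1]],
           "': sequence contains characters outside A,C,G,T,N")
  }
  class(df) <- c("promoter_set", "data.frame")
  df
}

#' Read a TSS table from a BED-like file
#'
#' Expects at least 4 tab-separated columns `chrom start end name`
#' (optionally `score strand`; the score is ignored). The TSS is taken as
#' the interval start on `+` and `end - 1` on `-` (single-base BED
#' records have both equal). When several records share a gene name the
#' first wins and the rest are dropped with a warning.
#'
#' @param path BED file path.
#' @return Data frame with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 4L) stop("TSS BED file needs >= 4 columns")
  strand <- if (ncol(raw) >= 6L) raw[[6]] else rep("+", nrow(raw))
  strand[!strand %in% c("+", "-")] <- "+"
  tss <- ifelse(strand == "+", raw[[2]], raw[[3]] - 1L)
  df <- data.frame(gene_id = as.character(raw[[4]]),
                   chrom = as.character(raw[[1]]),
                   tss = as.integer(tss), strand = strand,
                   stringsAsFactors = FALSE)
  dup <- duplicated(df$gene_id)
  if (any(dup)) {
    warning("duplicate TSS records dropped (first kept) for: ",
            paste(unique(df$gene_id[dup]), collapse = ", "))
    df <- df[!dup, , drop = FALSE]
  }
  df
}

#' Extract strand-aware promoter windows around TSSs
#'
#' For each gene the window covers `upstream` bases before and
#' `downstream` bases after its transcription start site, measured along
#' the transcribed strand (default -500/+100, a 600 bp window). On the
#' `+` strand the genomic interval is `[tss - upstream, tss + downstream)`;
#' on the `-` strand it is `[tss - downstream + 1, tss + upstream + 1)`
#' and the returned sequence is reverse-complemented so that position 0 is
#' always the most upstream base. Windows are clipped at chromosome ends
#' (and flagged `clipped`); genes whose window is empty after clipping are
#' skipped with a warning.
#'
#' @param tss_table Data frame with columns `gene_id`, `chrom`, `tss`
#'   (0-based), `strand`, e.g. from [read_tss_bed].
#' @param genome A named [Biostrings::DNAStringSet] or path to a genome
#'   FASTA.
#' @param upstream,downstream Non-negative window arms in bp.
#' @return A `promoter_set` data frame.
#' @export
extract_promoters <- function(tss_table, genome, upstream = 500L,
                              downstream = 100L) {
  stopifnot(upstream >= 0L, downstream >= 0L)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  dup <- duplicated(tss_table$gene_id)
  if (any(dup)) {
    warning("duplicate gene_id records dropped (first kept): ",
            paste(unique(tss_table$gene_id[dup]), collapse = ", "))
    tss_table <- tss_table[!dup, , drop = FALSE]
  }
  out <- vector("list", nrow(tss_table))
  for (i in seq_len(nrow(tss_table))) {
    g <- tss_table[i, ]
    if (!g$chrom %in% names(genome))
      stop("gene '", g$gene_id, "': chromosome '", g$chrom,
           "' not found in genome")
    clen <- Biostrings::width(genome[g$chrom])
    if (g$strand == "+") {
      s <- g$tss - upstream; e <- g$tss + downstream
    } else {
      s <- g$tss - downstream + 1L; e <- g$tss + upstream + 1L
    }
    s0 <- max(s, 0L); e0 <- min(e, clen)
    if (e0 <= s0) {
      warning("gene '", g$gene_id, "': promoter window empty after ",
              "clipping; skipped")
      next
    }
    seq <- Biostrings::subseq(genome[[g$chrom]], start = s0 + 1L, end = e0)
    if (g$strand == "-") seq <- Biostrings::reverseComplement(seq)
    out[[i]] <- promoter_set(g$gene_id, g$chrom, s0, e0, g$strand,
                             as.character(seq),
                             clipped = (s0 != s || e0 != e))
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L)
    return(promoter_set(character(), character(), integer(), integer(),
                        character(), character(), logical()))
  res <- do.call(rbind, out)
  class(res) <- c("promoter_set", "data.frame")
  rownames(res) <- NULL
  res
}

#' Remove promoters that overlap other promoters
#'
#' Two promoters overlap when their genomic intervals share at least one
#' base on the same chromosome (half-open intervals: touching windows do
#' not overlap). Under the default `"drop-all"` policy every member of an
#' overlapping cluster is removed, keeping only promoters that overlap
#' nothing; `"keep-first"` instead retains the first (by input order)
#' member of each cluster. Overlap filtering guards the co-occurrence
#' counts against double-counting sites shared by stacked promoters.
#'
#' @param promoters A `promoter_set`.
#' @param policy `"drop-all"` (default) or `"keep-first"`.
#' @return List with elements `kept` and `removed` (both `promoter_set`s);
#'   `removed` carries a `reason` column.
#' @export
filter_overlapping <- function(promoters, policy = c("drop-all", "keep-first")) {
  policy <- match.arg(policy)
  n <- nrow(promoters)
  drop <- logical(n)
  if (n > 1L) {
    ov <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (promoters$chrom[i] == promoters$chrom[j] &&
          promoters$start[i] < promoters$end[j] &&
          promoters$start[j] < promoters$end[i]) {
        ov[i, j] <- ov[j, i] <- TRUE
      }
    }
    if (policy == "drop-all") {
      drop <- rowSums(ov) > 0L
    } else {
      for (i in seq_len(n)) {
        if (drop[i]) next
        later <- which(ov[i, ] & seq_len(n) > i)
        drop[later] <- TRUE
      }
    }
  }
  kept <- promoters[!drop, , drop = FALSE]
  removed <- promoters[drop, , drop = FALSE]
  if (nrow(removed) > 0L) removed$reason <- "overlaps_other_promoter"
  class(kept) <- class(promoters)
  rownames(kept) <- NULL; rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' Remove exact-duplicate promoter sequences
#'
#' Drops promoters whose sequence is byte-identical to an earlier one
#' (first occurrence kept). This is the redundancy filter for
#' near-identical promoters arising from gene duplication or duplicated
#' TSS annotations; similarity-based clustering below exact identity is
#' deliberately out of scope.
#'
#' @param promoters A `promoter_set`.
#' @return List with elements `kept` and `removed`.
#' @export
filter_duplicate_sequences <- function(promoters) {
  dup <- duplicated(promoters$sequence)
  kept <- promoters[!dup, , drop = FALSE]
  removed <- promoters[dup, , drop = FALSE]
  if (nrow(removed) > 0L) removed$reason <- "duplicate_sequence"
  class(kept) <- class(promoters)
  rownames(kept) <- NULL; rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}

#' Read promoters from a FASTA file
#'
#' Headers may carry an optional coordinate token
#' `chrom:start-end(strand)` after the gene id, which is parsed into
#' genomic provenance; records without one are assigned a synthetic
#' coordinate system (one private chromosome per record) so that
#' [filter_overlapping] is a no-op on them.
#'
#' @param path FASTA path.
#' @return A `promoter_set`.
#' @export
read_promoter_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  hdrs <- names(seqs)
  ids <- sub("\\s.*$", "", hdrs)
  if (anyDuplicated(ids))
    stop("duplicate FASTA header: '", ids[duplicated(ids)][1], "'")
  coord_re <- "([^[:space:]]+):([0-9]+)-([0-9]+)\\(([+-])\\)"
  m <- regmatches(hdrs, regexec(coord_re, hdrs))
  has <- lengths(m) == 5L
  chrom <- ifelse(has, vapply(m, function(x) if (length(x)) x[2] else "", ""),
                  paste0("synthetic_", ids))
  start <- ifelse(has,
                  as.integer(vapply(m, function(x) if (length(x)) x[3] else "0", "")),
                  0L)
  end <- ifelse(has,
                as.integer(vapply(m, function(x) if (length(x)) x[4] else "0", "")),
                Biostrings::width(seqs))
  strand <- ifelse(has, vapply(m, function(x) if (length(x)) x[5] else "+", ""),
                   "+")
  promoter_set(ids, chrom, start, end, strand, as.character(seqs))
}

#' Write promoters to FASTA
#'
#' Headers are `gene_id chrom:start-end(strand)`, the format
#' [read_promoter_fasta] parses back.
#'
#' @param promoters A `promoter_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(promoters, path) {
  seqs <- Biostrings::DNAStringSet(promoters$sequence)
  names(seqs) <- sprintf("%s %s:%d-%d(%s)", promoters$gene_id,
                         promoters$chrom, promoters$start, promoters$end,
                         promoters$strand)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
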