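# Run `code` under a temporarily seeded RNG, restoring the caller's
# stream afterwards so library calls never perturb user simulations.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Returns a random permutation of `seq` with exactly the original
#' dinucleotide (adjacent-pair) counts, via the Eulerian-path
#' construction: the sequence is a walk on the graph whose vertices are
#' bases and whose edge multiset is the dinucleotide counts; a random
#' last-edge arborescence into the terminal base is drawn (rejection
#' sampling), the remaining out-edges are permuted uniformly, and the
#' walk is replayed. First and last characters are preserved, as the
#' construction requires.
#'
#' @param seq DNA string (length >= 2).
#' @param seed Optional integer seed (local to this call; the global RNG
#'   stream is untouched).
#' @return Shuffled DNA string with identical dinucleotide counts.
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
  with_seed(seed, {
    s <- strsplit(seq, "")[[1]]
    n <- length(s)
    if (n <= 3L) return(seq)
    verts <- unique(s)
    if (length(verts) == 1L) return(seq)
    from <- s[-n]; to <- s[-1L]
    adj <- split(to, factor(from, levels = verts))
    last <- s[n]
    # Draw last-edges until they form an arborescence into the terminal
    # vertex: from every vertex with out-edges, following the chosen
    # last edges must reach `last` without cycling.
    repeat {
      last_edge <- vapply(verts, function(v) {
        if (v == last || length(adj[[v]]) == 0L) NA_character_
        else adj[[v]][sample.int(length(adj[[v]]), 1L)]
      }, "")
      ok <- TRUE
      for (v in verts) {
        if (v == last || length(adj[[v]]) == 0L) next
        cur <- v; steps <- 0L
        while (cur != last) {
          cur <- last_edge[[cur]]
          steps <- steps + 1L
          if (is.na(cur) || steps > length(verts)) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) break
    }
    # Per-vertex edge order: uniform permutation of the non-last edges,
    # then the chosen last edge.
    order_of <- lapply(verts, function(v) {
      edges <- adj[[v]]
      if (length(edges) == 0L) return(character(0))
      if (v == last) return(edges[sample.int(length(edges))])
      li <- match(last_edge[[v]], edges)
      rest <- edges[-li]
      if (length(rest) > 1L) rest <- rest[sample.int(length(rest))]
      c(rest, edges[li])
    })
    names(order_of) <- verts
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    out <- character(n)
    out[1L] <- s[1L]
    cur <- s[1L]
    for (i in 2:n) {
      nxt <- order_of[[cur]][ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      out[i] <- nxt
      cur <- nxt
    }
    paste(out, collapse = "")
  })
}

#' Mononucleotide shuffle
#'
#' Uniform random permutation of the bases (base composition preserved,
#' dinucleotide structure destroyed).
#'
#' @inheritParams dinucleotide_shuffle
#' @return Shuffled DNA string.
#' @export
mononucleotide_shuffle <- function(seq, seed = NULL) {
  with_seed(seed, {
    s <- strsplit(seq, "")[[1]]
    paste(s[sample.int(length(s))], collapse = "")
  })
}

#' Shuffle a vector of sequences under one seed
#'
#' Each sequence gets its own sub-seed derived from `seed` and its index,
#' so the result is reproducible and independent of vector order
#' changes elsewhere.
#'
#' @param seqs Character vector of DNA strings.
#' @param seed Integer seed.
#' @param mode `"dinucleotide"` or `"mononucleotide"`.
#' @return Character vector of shuffled sequences.
#' @export
shuffle_sequences <- function(seqs, seed,
                              mode = c("dinucleotide", "mononucleotide")) {
  mode <- match.arg(mode)
  fun <- if (mode == "dinucleotide") dinucleotide_shuffle
         else mononucleotide_shuffle
  vapply(seq_along(seqs), function(i)
    fun(seqs[[i]], seed = derive_seed(seed, paste0("seq", i))), "")
}

#' Count dinucleotides in a sequence
#'
#' @param seq DNA string.
#' @return Named integer table of adjacent-pair counts.
#' @export
dinucleotide_counts <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  if (length(s) < 2L) return(table(character(0)))
  table(paste0(s[-length(s)], s[-1L]))
}

#' Simulate a set of informative PWMs
#'
#' Generates synthetic motifs for benchmarking: at each position one
#' dominant base carries probability `dominant` and the other three split
#' the remainder evenly. Counts are scaled to `depth` pseudo-observations
#' so the matrices resemble count-based library entries.
#'
#' @param n Number of matrices.
#' @param length Motif length in bp (default 10).
#' @param dominant Dominant-base probability per position (default 0.85,
#'   an informative but not degenerate motif).
#' @param prefix Accession prefix; matrices are named
#'   `<prefix><k>_01` with TF name `<prefix><k>`.
#' @param depth Pseudo-observation count (default 100).
#' @param seed Integer seed.
#' @return List of `pwm` objects.
#' @export
simulate_pwms <- function(n, length = 10L, dominant = 0.85,
                          prefix = "SYNTF", depth = 100, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n), function(k) {
      dom <- sample.int(4L, length, replace = TRUE)
      freq <- matrix((1 - dominant) / 3, nrow = length, ncol = 4L)
      freq[cbind(seq_len(length), dom)] <- dominant
      new_pwm(sprintf("%s%d_01", prefix, k), freq * depth,
              tf_name = sprintf("%s%d", prefix, k))
    })
  })
}

#' Specification of a synthetic promoter corpus
#'
#' Describes a benchmark corpus: background promoters of a fixed length
#' (default 600 bp, matching a -500/+100 TSS window) with controlled
#' base composition, a fraction of promoters carrying a planted
#' cooperative motif pair at a controlled gap, and independently placed
#' decoy motifs that form a true null for specificity checks.
#'
#' @param n_promoters Corpus size (default 200, a study-scale gene-list
#'   size).
#' @param length Promoter length in bp.
#' @param background Either a length-4 mononucleotide probability vector
#'   (A,C,G,T) or a 4x4 dinucleotide transition matrix (rows = current
#'   base, must each sum to 1).
#' @param planted_pairs List of lists with fields `pwm_a`, `pwm_b`
#'   (`pwm` objects), `penetrance` in `[0,1]` (fraction of promoters
#'   carrying the pair) and `gap_range` (length-2 integer vector of
#'   inclusive gap bounds in bp).
#' @param decoys List of lists with fields `pwm` and `rate` (expected
#'   decoy sites per promoter, Poisson).
#' @param seed Integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_promoters = 200L, length = 600L,
                           background = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25),
                           planted_pairs = list(), decoys = list(),
                           seed = 1L) {
  if (is.matrix(background)) {
    stopifnot(nrow(background) == 4L, ncol(background) == 4L,
              all(abs(rowSums(background) - 1) < 1e-8))
  } else {
    stopifnot(length(background) == 4L, abs(sum(background) - 1) < 1e-8)
  }
  for (pp in planted_pairs) {
    stopifnot(inherits(pp$pwm_a, "pwm"), inherits(pp$pwm_b, "pwm"),
              pp$penetrance >= 0, pp$penetrance <= 1,
              length(pp$gap_range) == 2L,
              pp$gap_range[1] <= pp$gap_range[2])
  }
  for (d in decoys) stopifnot(inherits(d$pwm, "pwm"), d$rate >= 0)
  structure(list(n_promoters = as.integer(n_promoters),
                 length = as.integer(length), background = background,
                 planted_pairs = planted_pairs, decoys = decoys,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Sample one site realization from a PWM's frequency model.
sample_site <- function(pwm) {
  paste(DNA_BASES[apply(pwm$freq, 1L, function(p) sample.int(4L, 1L, prob = p))],
        collapse = "")
}

sample_background <- function(len, background) {
  if (is.matrix(background)) {
    out <- integer(len)
    out[1L] <- sample.int(4L, 1L)
    for (i in 2:len)
      out[i] <- sample.int(4L, 1L, prob = background[out[i - 1L], ])
    paste(DNA_BASES[out], collapse = "")
  } else {
    paste(sample(DNA_BASES, len, replace = TRUE, prob = background),
          collapse = "")
  }
}

# Find a placement interval of width `w` not intersecting any interval
# in `occupied` (two-column matrix of 0-based half-open intervals).
# Returns the 0-based start or NA after `tries` rejections.
place_free <- function(w, len, occupied, tries = 200L) {
  for (t in seq_len(tries)) {
    s <- sample.int(len - w + 1L, 1L) - 1L
    if (nrow(occupied) == 0L ||
        all(s + w <= occupied[, 1L] | s >= occupied[, 2L]))
      return(s)
  }
  NA_integer_
}

#' Generate a synthetic promoter corpus with known ground truth
#'
#' Background sequence is sampled from the spec's composition model; each
#' planted pair lands in a `penetrance` fraction of promoters as one site
#' of each motif (bases drawn from the PWM frequencies, forward strand),
#' separated by a gap drawn uniformly from `gap_range`, at a uniformly
#' random feasible offset; decoy sites are placed independently with
#' Poisson counts. Placements never overwrite previously planted sites
#' (rejection sampling with a retry cap). The same spec and seed always
#' produce byte-identical output.
#'
#' @param spec A [synthetic_spec].
#' @return List with `promoters` (a `promoter_set` with non-overlapping
#'   synthetic coordinates) and `truth` (data frame of planted sites:
#'   `promoter_id`, `tf_name`, `pwm_id`, `start`, `end`, `kind`,
#'   `pair_id`, `gap`).
#' @export
generate_corpus <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$n_promoters; len <- spec$length
    ids <- sprintf("synth_g%03d", seq_len(n))
    seqs <- character(n)
    truth <- list()
    carriers <- lapply(spec$planted_pairs, function(pp)
      sort(sample.int(n, round(pp$penetrance * n))))
    for (i in seq_len(n)) {
      seq_chars <- strsplit(sample_background(len, spec$background), "")[[1]]
      occupied <- matrix(integer(0), ncol = 2L)
      for (p in seq_along(spec$planted_pairs)) {
        if (!(i %in% carriers[[p]])) next
        pp <- spec$planted_pairs[[p]]
        la <- pp$pwm_a$length; lb <- pp$pwm_b$length
        gap <- sample(seq(pp$gap_range[1], pp$gap_range[2]), 1L)
        span <- la + gap + lb
        if (span > len)
          stop("promoter '", ids[i], "': planted pair span ", span,
               " exceeds promoter length ", len)
        s <- place_free(span, len, occupied)
        if (is.na(s))
          stop("promoter '", ids[i],
               "': could not place planted pair after retries")
        site_a <- sample_site(pp$pwm_a)
        site_b <- sample_site(pp$pwm_b)
        seq_chars[(s + 1L):(s + la)] <- strsplit(site_a, "")[[1]]
        sb <- s + la + gap
        seq_chars[(sb + 1L):(sb + lb)] <- strsplit(site_b, "")[[1]]
        occupied <- rbind(occupied, c(s, s + la), c(sb, sb + lb))
        truth[[length(truth) + 1L]] <- data.frame(
          promoter_id = ids[i],
          tf_name = c(pp$pwm_a$tf_name, pp$pwm_b$tf_name),
          pwm_id = c(pp$pwm_a$id, pp$pwm_b$id),
          start = c(s, sb), end = c(s + la, sb + lb),
          kind = "planted_pair", pair_id = p, gap = gap,
          stringsAsFactors = FALSE)
      }
      for (d in spec$decoys) {
        k <- stats::rpois(1L, d$rate)
        if (k == 0L) next
        ld <- d$pwm$length
        for (j in seq_len(k)) {
          s <- place_free(ld, len, occupied)
          if (is.na(s)) next  # crowded promoter: skip this decoy copy
          site <- sample_site(d$pwm)
          seq_chars[(s + 1L):(s + ld)] <- strsplit(site, "")[[1]]
          occupied <- rbind(occupied, c(s, s + ld))
          truth[[length(truth) + 1L]] <- data.frame(
            promoter_id = ids[i], tf_name = d$pwm$tf_name,
            pwm_id = d$pwm$id, start = s, end = s + ld,
            kind = "decoy", pair_id = NA_integer_, gap = NA_integer_,
            stringsAsFactors = FALSE)
        }
      }
      seqs[i] <- paste(seq_chars, collapse = "")
    }
    promoters <- promoter_set(
      gene_id = ids, chrom = "synthetic_chr",
      start = (seq_len(n) - 1L) * (len + 100L),
      end = (seq_len(n) - 1L) * (len + 100L) + len,
      strand = "+", sequence = seqs)
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(promoter_id = character(), tf_name = character(),
                 pwm_id = character(), start = integer(), end = integer(),
                 kind = character(), pair_id = integer(), gap = integer(),
                 stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    list(promoters = promoters, truth = truth)
  })
}

#' Evaluate planted-pair recovery from a scored corpus
#'
#' Cross-references a pair-statistics table with a corpus truth table:
#' for each planted pair realized in the truth table (pairs whose
#' penetrance put them in no promoter are omitted) it reports the
#' z-score, the rank by descending z
#' among all scored pairs, and whether it passed the significance
#' threshold; false positives are significant pairs that are neither
#' planted nor share a TF with a planted pair.
#'
#' @param stats `pair_statistics` from [score_pairs].
#' @param truth Truth table from [generate_corpus].
#' @param spec The [synthetic_spec] the corpus came from.
#' @return List with `planted` (per-pair report data frame) and
#'   `false_positives` (count).
#' @export
evaluate_recovery <- function(stats, truth, spec) {
  ord <- order(-stats$z, stats$tf_a, stats$tf_b)
  ranked <- stats[ord, , drop = FALSE]
  key <- paste(ranked$tf_a, ranked$tf_b, sep = "\t")
  realized <- unique(stats::na.omit(truth$pair_id))
  planted <- lapply(realized, function(p) {
    pp <- spec$planted_pairs[[p]]
    pk <- pair_key(pp$pwm_a$tf_name, pp$pwm_b$tf_name)
    hit <- match(pk$key, key)
    data.frame(pair_id = p, tf_a = pk$tf_a, tf_b = pk$tf_b,
               scored = !is.na(hit),
               z = if (is.na(hit)) NA_real_ else ranked$z[hit],
               rank = hit,
               significant = if (is.na(hit)) FALSE else
                 ranked$significant[hit],
               stringsAsFactors = FALSE)
  })
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(pair_id = integer(), tf_a = character(), tf_b = character(),
               scored = logical(), z = numeric(), rank = integer(),
               significant = logical(), stringsAsFactors = FALSE)
  planted_tfs <- unlist(lapply(spec$planted_pairs[realized], function(pp)
    c(pp$pwm_a$tf_name, pp$pwm_b$tf_name)))
  sig <- ranked[ranked$significant, , drop = FALSE]
  fp <- sum(!(sig$tf_a %in% planted_tfs) & !(sig$tf_b %in% planted_tfs))
  list(planted = planted, false_positives = fp)
}
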