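# Independent brute-force oracles, written from first principles against
# the scoring definitions (no shared code with the package internals).

oracle_info <- function(freq_row) {
  sum(freq_row * log(4 * freq_row))
}

# Window score computed character by character from the PWM frequency
# matrix: Current = sum_i I(i) f(i, w_i), min-max normalized.
oracle_window_score <- function(pwm, window, positions = seq_len(pwm$length)) {
  chars <- strsplit(window, "")[[1]]
  cur <- mx <- mn <- 0
  for (i in positions) {
    iv <- oracle_info(pwm$freq[i, ])
    fi <- switch(chars[i],
                 A = pwm$freq[i, "A"], C = pwm$freq[i, "C"],
                 G = pwm$freq[i, "G"], T = pwm$freq[i, "T"],
                 min(pwm$freq[i, ]))
    cur <- cur + iv * fi
    mx <- mx + iv * max(pwm$freq[i, ])
    mn <- mn + iv * min(pwm$freq[i, ])
  }
  if (mx == mn) return(0)
  (cur - mn) / (mx - mn)
}

# Brute-force 5-window core: best summed information window, leftmost tie.
oracle_core <- function(pwm) {
  L <- pwm$length
  if (L <= 5) return(seq_len(L))
  iv <- vapply(seq_len(L), function(i) oracle_info(pwm$freq[i, ]), 0)
  best <- -Inf; at <- 1
  for (s in seq_len(L - 4)) {
    w <- sum(iv[s:(s + 4)])
    if (w > best + 1e-12) { best <- w; at <- s }
  }
  at:(at + 4)
}

oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]), collapse = "")
}

# Window-by-window scan of one sequence with both strands; emits hits
# passing both cutoffs, in forward coordinates (0-based half-open).
oracle_scan <- function(id, seq, pwms, core_cutoff, matrix_cutoff) {
  n <- nchar(seq)
  rows <- list()
  for (p in pwms) {
    L <- p$length
    if (L > n) next
    core <- oracle_core(p)
    for (strand in c("+", "-")) {
      s_use <- if (strand == "+") seq else oracle_revcomp(seq)
      for (off in 0:(n - L)) {
        win <- substr(s_use, off + 1, off + L)
        cs <- oracle_window_score(p, win, core)
        ms <- oracle_window_score(p, win)
        if (cs >= core_cutoff && ms >= matrix_cutoff) {
          st <- if (strand == "+") off else n - (off + L)
          rows[[length(rows) + 1]] <- data.frame(
            promoter_id = id, tf_name = p$tf_name, pwm_id = p$id,
            start = st, end = st + L, strand = strand,
            core_score = cs, matrix_score = ms, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(promoter_id = character(), tf_name = character(),
                      pwm_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      core_score = numeric(), matrix_score = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, out$tf_name, out$strand), ]
  rownames(out) <- NULL
  out
}

# Brute-force double loop over all site pairs under the gap rule.
oracle_pairs <- function(sites, d_min, d_max, homotypic = FALSE) {
  rows <- list()
  for (pid in unique(sites$promoter_id)) {
    s <- sites[sites$promoter_id == pid, ]
    m <- nrow(s)
    if (m < 2) next
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (!homotypic && s$tf_name[i] == s$tf_name[j]) next
      d <- max(s$start[i], s$start[j]) - min(s$end[i], s$end[j])
      if (d >= d_min && d <= d_max) {
        ab <- sort(c(s$tf_name[i], s$tf_name[j]))
        rows[[length(rows) + 1]] <- data.frame(
          tf_a = ab[1], tf_b = ab[2], promoter_id = pid,
          distance = d, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(tf_a = character(), tf_b = character(),
                      promoter_id = character(), distance = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# Random site table on synthetic promoters, for pair-count oracles.
random_sites <- function(n_sites, n_promoters = 3, n_tfs = 4, len = 200) {
  starts <- sample(0:(len - 12), n_sites, replace = TRUE)
  widths <- sample(6:12, n_sites, replace = TRUE)
  data.frame(
    promoter_id = sample(sprintf("p%d", seq_len(n_promoters)), n_sites,
                         replace = TRUE),
    tf_name = sample(LETTERS[seq_len(n_tfs)], n_sites, replace = TRUE),
    pwm_id = "M1", start = starts, end = starts + widths,
    strand = "+", core_score = 1, matrix_score = 1,
    stringsAsFactors = FALSE)
}

make_promoters <- function(seqs, ids = sprintf("g%d", seq_along(seqs))) {
  read_promoter_fasta_obj <- data.frame(
    gene_id = ids, chrom = paste0("synthetic_", ids),
    start = 0L, end = nchar(seqs), strand = "+",
    sequence = toupper(seqs), clipped = FALSE, stringsAsFactors = FALSE)
  class(read_promoter_fasta_obj) <- c("promoter_set", "data.frame")
  read_promoter_fasta_obj
}

# A small, fixed, informative PWM for direct-score tests: consensus ACGTA.
fixture_pwm <- function(id = "V$FIX_01", dominant = 0.85, L = 5,
                        cons = c("A", "C", "G", "T", "A")) {
  freq <- matrix((1 - dominant) / 3, nrow = L, ncol = 4,
                 dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(L)) freq[i, cons[i]] <- dominant
  new_pwm(id, freq * 100)
}
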