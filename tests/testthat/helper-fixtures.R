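# Shared fixtures for the pipeline and end-to-end tests.

mk_stats <- function(pairs, z) {
  n <- length(pairs)
  df <- data.frame(tf_a = vapply(pairs, `[`, "", 1),
                   tf_b = vapply(pairs, `[`, "", 2),
                   f_ab = rep(1L, n), f_a = rep(1L, n), f_b = rep(1L, n),
                   pmi = rep(0, n), avg_pmi = rep(0, n),
                   pmi_cor = rep(0, n), z = z,
                   significant = rep(TRUE, n),
                   stringsAsFactors = FALSE)
  class(df) <- c("pair_statistics", "data.frame")
  df
}

random_network <- function(n_tfs = 8, n_edges = 6, label = "x") {
  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  pairs <- t(replicate(n_edges, sort(sample(tfs, 2))))
  keep <- which(!duplicated(paste(pairs[, 1], pairs[, 2])))
  build_network(mk_stats(lapply(keep, function(i) pairs[i, ]),
                         stats::rnorm(length(keep), 4, 0.5)), label)
}

# Study-shaped fixture: two corpora sharing planted pair TF1-TF2, with a
# private pair each (TF3-TF4 for A, TF5-TF6 for B). Every TF also occurs
# as an independent decoy in both corpora so no factor has a vanishing
# marginal, and 12 further decoy TFs populate the null pair distribution.
study_pwms <- simulate_pwms(18, seed = 301)
study_fixture <- local({
  pair <- function(a, b) list(pwm_a = study_pwms[[a]], pwm_b = study_pwms[[b]],
                              penetrance = 0.9, gap_range = c(5, 20))
  decoys <- function(extra) c(
    lapply(study_pwms[extra], function(p) list(pwm = p, rate = 0.5)),
    lapply(study_pwms[7:18], function(p) list(pwm = p, rate = 0.5)))
  spec_a <- synthetic_spec(n_promoters = 150, length = 500,
                           planted_pairs = list(pair(1, 2), pair(3, 4)),
                           decoys = decoys(5:6), seed = 21)
  spec_b <- synthetic_spec(n_promoters = 150, length = 500,
                           planted_pairs = list(pair(1, 2), pair(5, 6)),
                           decoys = decoys(3:4), seed = 22)
  corp_a <- generate_corpus(spec_a)
  corp_b <- generate_corpus(spec_b)
  corp_b$promoters$gene_id <- sub("synth_g", "synth_h",
                                  corp_b$promoters$gene_id)
  list(a = corp_a, b = corp_b)
})
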