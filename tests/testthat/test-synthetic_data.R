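test_that("dinucleotide shuffling preserves pair counts exactly", {
  set.seed(47)
  for (k in 1:200) {
    n <- sample(4:120, 1)
    seq <- random_dna(n, prob = stats::runif(4, 0.1, 1))
    out <- dinucleotide_shuffle(seq, seed = k)
    expect_equal(nchar(out), n)
    expect_equal(dinucleotide_counts(out), dinucleotide_counts(seq))
    expect_equal(substr(out, 1, 1), substr(seq, 1, 1))
    expect_equal(substr(out, n, n), substr(seq, n, n))
  }
})

test_that("forced arrangements shuffle to themselves", {
  expect_equal(dinucleotide_shuffle("AAAA", seed = 1), "AAAA")
  expect_equal(dinucleotide_shuffle("AC", seed = 1), "AC")
  expect_equal(dinucleotide_shuffle("ACG", seed = 1), "ACG")
})

test_that("ACGCA shuffles land in the brute-force enumerated valid set", {
  seq <- "ACGCA"
  ref <- dinucleotide_counts(seq)
  # enumerate every permutation of the middle characters keeping the
  # first and last fixed, and keep those with identical pair counts
  mid <- strsplit(substr(seq, 2, 4), "")[[1]]
  perms <- unique(apply(
    expand.grid(i = 1:3, j = 1:3, k = 1:3), 1L,
    function(ix) if (length(unique(ix)) == 3)
      paste0("A", paste(mid[ix], collapse = ""), "A") else NA))
  perms <- perms[!is.na(perms)]
  valid <- perms[vapply(perms, function(s)
    identical(dinucleotide_counts(s), ref), TRUE)]
  expect_true(length(valid) >= 1)
  outs <- vapply(1:50, function(s) dinucleotide_shuffle(seq, seed = s), "")
  expect_true(all(outs %in% valid))
})

test_that("long shuffles actually randomize the arrangement", {
  set.seed(53)
  seq <- random_dna(300)
  outs <- vapply(1:5, function(s) dinucleotide_shuffle(seq, seed = s), "")
  expect_true(all(outs != seq))
  expect_equal(length(unique(outs)), 5L)
})

test_that("mononucleotide shuffling preserves base composition", {
  seq <- "AACCGGTTACGT"
  out <- mononucleotide_shuffle(seq, seed = 3)
  expect_equal(sort(strsplit(out, "")[[1]]), sort(strsplit(seq, "")[[1]]))
})

test_that("shuffling never perturbs the caller's RNG stream", {
  set.seed(99)
  a <- stats::runif(1)
  set.seed(99)
  invisible(dinucleotide_shuffle("ACGTACGTACGT", seed = 5))
  b <- stats::runif(1)
  expect_identical(a, b)
})

test_that("full-penetrance corpora plant the pair in every promoter", {
  pwms <- simulate_pwms(2, seed = 61)
  spec <- synthetic_spec(n_promoters = 50, length = 300,
                         planted_pairs = list(list(pwm_a = pwms[[1]],
                                                   pwm_b = pwms[[2]],
                                                   penetrance = 1.0,
                                                   gap_range = c(5, 20))),
                         seed = 61)
  corp <- generate_corpus(spec)
  expect_equal(nrow(corp$promoters), 50L)
  expect_true(all(nchar(corp$promoters$sequence) == 300L))
  per_prom <- table(corp$truth$promoter_id)
  expect_equal(length(per_prom), 50L)
  expect_true(all(per_prom == 2L))           # one site of each motif
  gaps <- unique(corp$truth[, c("promoter_id", "gap")])$gap
  expect_true(all(gaps >= 5 & gaps <= 20))
  # truth coordinates lie inside the promoter and match the gap
  expect_true(all(corp$truth$start >= 0 & corp$truth$end <= 300))
  byp <- split(corp$truth, corp$truth$promoter_id)
  for (tr in byp) {
    tr <- tr[order(tr$start), ]
    expect_equal(tr$start[2] - tr$end[1], tr$gap[1])
  }
})

test_that("zero-penetrance corpora contain decoys only", {
  pwms <- simulate_pwms(3, seed = 67)
  spec <- synthetic_spec(n_promoters = 20, length = 200,
                         planted_pairs = list(list(pwm_a = pwms[[1]],
                                                   pwm_b = pwms[[2]],
                                                   penetrance = 0,
                                                   gap_range = c(5, 20))),
                         decoys = list(list(pwm = pwms[[3]], rate = 1)),
                         seed = 67)
  corp <- generate_corpus(spec)
  expect_true(all(corp$truth$kind == "decoy"))
})

test_that("corpus generation is a bijection from (spec, seed) to bytes", {
  pwms <- simulate_pwms(3, seed = 5)
  mk_spec <- function(seed) synthetic_spec(
    n_promoters = 15, length = 250,
    planted_pairs = list(list(pwm_a = pwms[[1]], pwm_b = pwms[[2]],
                              penetrance = 0.5, gap_range = c(5, 20))),
    decoys = list(list(pwm = pwms[[3]], rate = 0.5)), seed = seed)
  c1 <- generate_corpus(mk_spec(8))
  c2 <- generate_corpus(mk_spec(8))
  c3 <- generate_corpus(mk_spec(9))
  expect_identical(c1$promoters$sequence, c2$promoters$sequence)
  expect_identical(c1$truth, c2$truth)
  expect_false(identical(c1$promoters$sequence, c3$promoters$sequence))
})

test_that("planted gaps are uniform over the configured range", {
  pwms <- simulate_pwms(2, length = 6, seed = 13)
  spec <- synthetic_spec(n_promoters = 10000, length = 60,
                         planted_pairs = list(list(pwm_a = pwms[[1]],
                                                   pwm_b = pwms[[2]],
                                                   penetrance = 1,
                                                   gap_range = c(5, 20))),
                         seed = 13)
  corp <- generate_corpus(spec)
  gaps <- unique(corp$truth[, c("promoter_id", "gap")])$gap
  expect_equal(length(gaps), 10000L)
  tab <- table(factor(gaps, levels = 5:20))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.01)
})

test_that("recovery reports rank planted pairs and count false positives", {
  pwms <- simulate_pwms(6, seed = 37)
  spec <- synthetic_spec(n_promoters = 80, length = 500,
                         planted_pairs = list(list(pwm_a = pwms[[1]],
                                                   pwm_b = pwms[[2]],
                                                   penetrance = 0.5,
                                                   gap_range = c(5, 20))),
                         decoys = lapply(pwms[3:6], function(p)
                           list(pwm = p, rate = 0.5)),
                         seed = 37)
  corp <- generate_corpus(spec)
  stats_df <- score_pairs(corp$promoters, pwms,
                          config = scoring_config(n_shuffles = 3, seed = 37))
  rec <- evaluate_recovery(stats_df, corp$truth, spec)
  expect_equal(nrow(rec$planted), 1L)
  expect_true(rec$planted$scored)
  expect_equal(rec$planted$tf_a, "SYNTF1")
  expect_true(rec$planted$rank >= 1)
  expect_true(rec$false_positives >= 0)

  # with no planted sites the report's planted section is empty and all
  # significant pairs count as false positives
  spec0 <- synthetic_spec(n_promoters = 80, length = 500,
                          planted_pairs = list(list(pwm_a = pwms[[1]],
                                                    pwm_b = pwms[[2]],
                                                    penetrance = 0,
                                                    gap_range = c(5, 20))),
                          decoys = lapply(pwms[3:6], function(p)
                            list(pwm = p, rate = 1)),
                          seed = 38)
  corp0 <- generate_corpus(spec0)
  stats0 <- score_pairs(corp0$promoters, pwms,
                        config = scoring_config(n_shuffles = 3, seed = 38))
  rec0 <- evaluate_recovery(stats0, corp0$truth, spec0)
  expect_equal(nrow(rec0$planted), 0L)
  expect_equal(rec0$false_positives, sum(stats0$significant))
})

test_that("stronger penetrance earns higher z than weaker penetrance", {
  # the pair TFs also occur as abundant independent background sites, so
  # their marginals are comparable between the two pairs and the
  # co-occurrence signal, not PMI's low-frequency bias, drives the score
  pwms <- simulate_pwms(8, seed = 43)
  wins <- 0L
  for (s in 1:6) {
    spec <- synthetic_spec(
      n_promoters = 100, length = 400,
      planted_pairs = list(
        list(pwm_a = pwms[[1]], pwm_b = pwms[[2]], penetrance = 0.5,
             gap_range = c(5, 20)),
        list(pwm_a = pwms[[3]], pwm_b = pwms[[4]], penetrance = 0.2,
             gap_range = c(5, 20))),
      decoys = c(lapply(pwms[1:4], function(p) list(pwm = p, rate = 2)),
                 lapply(pwms[5:8], function(p) list(pwm = p, rate = 0.5))),
      seed = 500 + s)
    corp <- generate_corpus(spec)
    stats_df <- score_pairs(corp$promoters, pwms,
                            config = scoring_config(n_shuffles = 3,
                                                    seed = 500 + s))
    rec <- evaluate_recovery(stats_df, corp$truth, spec)
    z1 <- rec$planted$z[rec$planted$pair_id == 1]
    z2 <- rec$planted$z[rec$planted$pair_id == 2]
    if (length(z1) == 1 && length(z2) == 1 && !is.na(z1) && !is.na(z2) &&
        z1 >= z2) wins <- wins + 1L
  }
  expect_gte(wins, 5L)
})
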