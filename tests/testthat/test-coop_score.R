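site_row <- function(pid, tf, start, end) {
  data.frame(promoter_id = pid, tf_name = tf, pwm_id = paste0("M_", tf),
             start = start, end = end, strand = "+", core_score = 1,
             matrix_score = 1, stringsAsFactors = FALSE)
}

test_that("gap boundaries 5 and 20 are kept; 4, 21 and overlaps are dropped", {
  mk <- function(gap) rbind(site_row("p1", "A", 90, 100),
                            site_row("p1", "B", 100 + gap, 110 + gap))
  cfg <- scoring_config()
  expect_equal(nrow(enumerate_pairs(mk(5), cfg)), 1L)
  expect_equal(enumerate_pairs(mk(5), cfg)$distance, 5L)
  expect_equal(nrow(enumerate_pairs(mk(20), cfg)), 1L)
  expect_equal(nrow(enumerate_pairs(mk(4), cfg)), 0L)
  expect_equal(nrow(enumerate_pairs(mk(21), cfg)), 0L)
  expect_equal(nrow(enumerate_pairs(mk(0), cfg)), 0L)
  expect_equal(nrow(enumerate_pairs(mk(-5), cfg)), 0L)   # overlapping
})

test_that("homotypic site pairs are skipped by default, kept on request", {
  s <- rbind(site_row("p1", "A", 0, 10), site_row("p1", "A", 18, 28))
  s$pwm_id <- c("M_A1", "M_A2")   # different matrices, same TF
  expect_equal(nrow(enumerate_pairs(s, scoring_config())), 0L)
  expect_equal(nrow(enumerate_pairs(s, scoring_config(homotypic = TRUE))), 1L)
})

test_that("pair counts match the brute-force double loop on random site sets", {
  set.seed(17)
  cfg <- scoring_config()
  for (k in 1:30) {
    s <- random_sites(sample(4:25, 1))
    got <- enumerate_pairs(s, cfg)
    want <- oracle_pairs(s, cfg$d_min, cfg$d_max)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(sort(paste(got$tf_a, got$tf_b, got$distance)),
                   sort(paste(want$tf_a, want$tf_b, want$distance)))
    }
  }
})

test_that("PMI reproduces the hand-enumerated toy corpus", {
  # two promoters, each one A site and one B site 10 bp apart:
  # f_ab = 2 (the only pairs), f_a = f_b = 2, F_pairs = 2, F_sites = 4
  # p_ab = 1, p_a = p_b = 1/2 -> PMI = log2(4) = 2
  s <- rbind(site_row("p1", "A", 0, 10), site_row("p1", "B", 20, 30),
             site_row("p2", "A", 50, 60), site_row("p2", "B", 70, 80))
  cfg <- scoring_config()
  res <- pmi(enumerate_pairs(s, cfg), s, cfg)
  expect_equal(nrow(res), 1L)
  expect_equal(res$f_ab, 2L)
  expect_equal(res$f_a, 2L)
  expect_equal(res$pmi, 2.0)
})

test_that("PMI is symmetric and invariant to doubling all counts", {
  s1 <- rbind(site_row("p1", "A", 0, 10), site_row("p1", "B", 20, 30),
              site_row("p1", "C", 45, 55), site_row("p1", "D", 65, 75))
  cfg <- scoring_config()
  res1 <- pmi(enumerate_pairs(s1, cfg), s1, cfg)
  # A-B and C-D have identical counts -> identical PMI
  expect_equal(res1$pmi[res1$tf_a == "A"], res1$pmi[res1$tf_a == "C"])
  # duplicate the whole corpus on a second promoter: all counts double
  s2 <- rbind(s1, within(s1, promoter_id <- "p2"))
  res2 <- pmi(enumerate_pairs(s2, cfg), s2, cfg)
  expect_equal(res2$pmi, res1$pmi)
  # no qualifying co-occurrence at all is an error
  lone <- site_row("p1", "A", 0, 10)
  expect_error(pmi(enumerate_pairs(lone, cfg), lone, cfg),
               "no co-occurrences")
})

test_that("the background correction follows PMI - (1+alpha)*AVG", {
  expect_equal(pmi_cor(1.0, 0.5, alpha = 0.2), 0.4)
  expect_equal(pmi_cor(1.7, 0.3, alpha = -1), 1.7)
  expect_equal(pmi_cor(2.5, 0, alpha = 0.9), 2.5)
  expect_error(pmi_cor(1, 1, alpha = 1.5), "alpha")
  set.seed(29)
  for (k in 1:50) {
    p <- stats::rnorm(1); a <- stats::rnorm(1); al <- stats::runif(1, -1, 1)
    expect_equal(pmi_cor(p, a, al), p - (1 + al) * a, tolerance = 1e-12)
  }
})

test_that("z-transform uses the population standard deviation", {
  expect_equal(zscore_transform(c(0.4, 0.4, 0.4)), c(0, 0, 0))
  z <- zscore_transform(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-4)
  expect_equal(round(z[3], 4), 1.2247)
  x <- stats::rnorm(20)
  expect_equal(zscore_transform(x + 5), zscore_transform(x),
               tolerance = 1e-12)
  expect_error(zscore_transform(1.0), "at least 2")
})

test_that("significance at z >= 3 is inclusive and deterministically ordered", {
  stats_df <- data.frame(tf_a = c("A", "B", "A", "C"),
                         tf_b = c("B", "C", "C", "D"),
                         f_ab = 1L, f_a = 1L, f_b = 1L, pmi = 0,
                         avg_pmi = 0, pmi_cor = 0,
                         z = c(3.0, 2.999, 4.5, 4.5),
                         significant = NA, stringsAsFactors = FALSE)
  class(stats_df) <- c("pair_statistics", "data.frame")
  sig <- significant_pairs(stats_df, scoring_config())
  expect_equal(nrow(sig), 3L)
  expect_equal(sig$z[1], 4.5)
  expect_equal(sig$tf_a, c("A", "C", "A"))   # z desc, then lexicographic
  expect_false("B" %in% sig$tf_a[sig$tf_b == "C"])
  expect_equal(nrow(significant_pairs(stats_df[0, ], scoring_config())), 0L)
})

test_that("background averages are zero for pairs absent from every shuffle", {
  # a pair planted with penetrance 1 at a fixed gap dominates the
  # foreground; after dinucleotide shuffling its sites disperse, so its
  # background average is overwhelmingly likely to be 0 on a tiny corpus
  pwms <- simulate_pwms(5, length = 8, dominant = 0.95, seed = 71)
  spec <- synthetic_spec(n_promoters = 30, length = 300,
                         planted_pairs = list(list(pwm_a = pwms[[1]],
                                                   pwm_b = pwms[[2]],
                                                   penetrance = 1,
                                                   gap_range = c(5, 20))),
                         decoys = lapply(pwms[3:5], function(p)
                           list(pwm = p, rate = 1)),
                         seed = 71)
  corp <- generate_corpus(spec)
  cfg <- scoring_config(n_shuffles = 3, seed = 71)
  bg <- background_avg_pmi(corp$promoters, pwms, scan_profile(), cfg)
  sts <- score_pairs(corp$promoters, pwms, scan_profile(), cfg)
  k <- paste(sts$tf_a, sts$tf_b, sep = "\t")
  expect_true(all(sts$avg_pmi[!(k %in% names(bg))] == 0))
  expect_true(all(is.finite(sts$avg_pmi)))
  expect_equal(sts$pmi_cor, sts$pmi - 1.2 * sts$avg_pmi, tolerance = 1e-12)
})

test_that("on i.i.d. corpora the shuffled background tracks the foreground PMI", {
  # random promoters have no cooperative structure, so the background
  # average for a frequently co-occurring pair converges on its
  # foreground PMI; with 20 replicates the gap is within Monte Carlo error
  set.seed(83)
  pwms <- simulate_pwms(3, length = 6, dominant = 0.7, seed = 83)
  p <- make_promoters(vapply(1:60, function(i) random_dna(400), ""))
  prof <- scan_profile(0.5, 0.5)
  sites <- scan_promoters(p, pwms, prof)
  cfg <- scoring_config(n_shuffles = 20, seed = 83)
  fg <- pmi(enumerate_pairs(sites, cfg), sites, cfg)
  bg <- background_avg_pmi(p, pwms, prof, cfg)
  frequent <- fg[fg$f_ab >= 8, ]
  expect_gt(nrow(frequent), 0)
  for (i in seq_len(nrow(frequent))) {
    key <- paste(frequent$tf_a[i], frequent$tf_b[i], sep = "\t")
    expect_lt(abs(frequent$pmi[i] - bg[[key]]), 1.0)
  }
})

test_that("the scoring pipeline is bit-reproducible under a fixed seed", {
  pwms <- simulate_pwms(4, seed = 19)
  spec <- synthetic_spec(n_promoters = 30, length = 300,
                         planted_pairs = list(list(pwm_a = pwms[[1]],
                                                   pwm_b = pwms[[2]],
                                                   penetrance = 0.6,
                                                   gap_range = c(5, 20))),
                         decoys = list(list(pwm = pwms[[3]], rate = 0.5),
                                       list(pwm = pwms[[4]], rate = 0.5)),
                         seed = 19)
  corp <- generate_corpus(spec)
  cfg <- scoring_config(n_shuffles = 3, seed = 19)
  s1 <- score_pairs(corp$promoters, pwms, scan_profile(), cfg)
  s2 <- score_pairs(corp$promoters, pwms, scan_profile(), cfg)
  expect_identical(s1, s2)
})

test_that("pair tables round-trip bit-exactly through TSV", {
  stats_df <- data.frame(tf_a = c("A", "B"), tf_b = c("B", "C"),
                         f_ab = c(3L, 1L), f_a = c(5L, 2L), f_b = c(4L, 7L),
                         pmi = c(1.234567890123456, -0.5),
                         avg_pmi = c(0.1, 0), pmi_cor = c(1.11, -0.5),
                         z = c(1 / 3, -sqrt(2)), significant = c(FALSE, FALSE),
                         stringsAsFactors = FALSE)
  class(stats_df) <- c("pair_statistics", "data.frame")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pairs_tsv(stats_df, f)
  back <- read_pairs_tsv(f)
  expect_identical(back$z, stats_df$z)
  expect_identical(back$pmi, stats_df$pmi)
})
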