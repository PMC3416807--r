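toy_corpus <- function() {
  # 10 studies; "pain" in 4; region v active in 3 of the 4 pain studies and
  # 1 of the 6 others
  tibble::tibble(
    study_id = sprintf("s%02d", 1:10),
    pain = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
    touch = c(1, 1, 0, 0, 1, 1, 0, 0, 0, 0),
    v = c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0))
}

test_that("jaccard association covers the closed-form and edge cases", {
  corp <- toy_corpus()
  self <- jaccard_association(corp, "pain", "pain")
  expect_equal(self$jaccard, 1)
  expect_equal(self$ln_jaccard, 0)

  j <- jaccard_association(corp, "pain", "touch")
  # |A n B| = 2, |A u B| = 4 + 4 - 2 = 6 here; build the printed 2/4 case
  corp2 <- tibble::tibble(study_id = sprintf("s%d", 1:4),
                          a = c(1, 1, 1, 0), b = c(1, 1, 0, 1))
  j2 <- jaccard_association(corp2, "a", "b")
  expect_equal(j2$jaccard, 0.5)
  expect_equal(j2$ln_jaccard, -log(2))
  expect_equal(j2$ln_jaccard, -0.6931, tolerance = 1e-4)

  disj <- tibble::tibble(study_id = c("s1", "s2"), a = c(1, 0), b = c(0, 1))
  expect_equal(jaccard_association(disj, "a", "b")$jaccard, 0)
  expect_equal(jaccard_association(disj, "a", "b")$ln_jaccard, -Inf)

  expect_error(jaccard_association(corp, "pain", "nope"), "nope")
})

test_that("jaccard is symmetric and bounded by the smaller set", {
  corp <- generate_corpus(corpus_spec(60, terms = c("a", "b", "c"),
                                      p_term = 0.4, seed = 7))
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    j1 <- jaccard_association(corp, pair[1], pair[2])
    j2 <- jaccard_association(corp, pair[2], pair[1])
    expect_equal(j1$jaccard, j2$jaccard)
    expect_equal(j1$jaccard, jaccard_oracle(corp, pair[1], pair[2]))
    expect_lte(j1$jaccard,
               min(j1$n_a, j1$n_b) / max(1, max(j1$n_a, j1$n_b)))
  }
})

test_that("phenotype map thresholds edges on ln(J)", {
  corp <- toy_corpus()
  ph_all <- phenotype_map(corp, c("pain", "touch", "v"),
                          threshold_ln_j = -Inf)
  # complete graph on co-occurring term pairs
  expect_equal(nrow(ph_all$edges), 3)

  ph_strict <- phenotype_map(corp, c("pain", "touch", "v"),
                             threshold_ln_j = 0)
  expect_equal(nrow(ph_strict$edges), 0)  # only identical study sets pass
  ident <- tibble::tibble(study_id = c("s1", "s2"), a = c(1, 1),
                          b = c(1, 1), c = c(1, 0))
  expect_equal(phenotype_map(ident, c("a", "b", "c"),
                             threshold_ln_j = -1e-12)$edges$term_b, "b")

  # edge list equals a brute-force pairwise filter
  kept <- ph_all$edges
  brute <- t(utils::combn(c("pain", "touch", "v"), 2))
  keep <- apply(brute, 1, function(pr)
    log(jaccard_oracle(corp, pr[1], pr[2])) > -10)
  ph10 <- phenotype_map(corp, c("pain", "touch", "v"))
  expect_equal(nrow(ph10$edges), sum(keep))
  expect_equal(ph10$ln_j["pain", "touch"], ph10$ln_j["touch", "pain"])
})

test_that("forward inference is exhaustive counting", {
  corp <- toy_corpus()
  fwd <- forward_inference(corp, "pain", "v")
  expect_equal(fwd$p_act_given_term, 0.75)  # 3 of the 4 pain studies
  expect_equal(fwd$p_act_given_term, forward_oracle(corp, "pain", "v"))

  # term present in every study: forward inference is the overall rate
  allt <- dplyr::mutate(corp, pain = 1)
  expect_equal(forward_inference(allt, "pain", "v")$p_act_given_term,
               mean(corp$v))

  corp_big <- generate_corpus(corpus_spec(20, terms = "t", p_term = 0.5,
                                          p_act_given_term = 0.6,
                                          p_act_given_notterm = 0.2,
                                          seed = 9))
  f <- forward_inference(corp_big, "t")
  expect_true(f$p_act_given_term >= 0 && f$p_act_given_term <= 1)
  expect_equal(f$p_act_given_term, forward_oracle(corp_big, "t",
                                                  "region_1"))
})

test_that("reverse inference applies Bayes' rule under both priors", {
  corp <- toy_corpus()
  emp <- reverse_inference(corp, "pain", "v")
  # P(act|term) = 3/4, P(act|!term) = 1/6, P(term) = 0.4 ->
  # 0.3 / (0.3 + 0.1) = 0.75
  expect_equal(emp$p_term_given_act, 0.75)
  # with the empirical prior Bayes' rule must equal direct counting
  expect_equal(emp$p_term_given_act,
               reverse_oracle_empirical(corp, "pain", "v"))

  uni <- reverse_inference(corp, "pain", "v", prior = 0.5)
  expect_equal(uni$p_term_given_act,
               0.75 * 0.5 / (0.75 * 0.5 + (1 / 6) * 0.5))
  expect_equal(uni$p_term_given_act, 0.8182, tolerance = 1e-4)

  # uninformative likelihood: posterior equals the prior
  flat <- tibble::tibble(study_id = sprintf("s%d", 1:8),
                         t = c(1, 1, 1, 1, 0, 0, 0, 0),
                         r = c(1, 0, 1, 0, 1, 0, 1, 0))
  expect_equal(reverse_inference(flat, "t", "r", prior = 0.3)$p_term_given_act,
               0.3)

  # never-active region: undefined posterior, not 0
  none <- dplyr::mutate(corp, v = 0)
  expect_true(is.na(reverse_inference(none, "pain", "v")$p_term_given_act))
})

test_that("inference matches exhaustive counting on random small corpora", {
  for (s in 1:5) {
    corp <- generate_corpus(corpus_spec(sample(8:20, 1), terms = "t",
                                        p_term = 0.5,
                                        p_act_given_term = 0.7,
                                        p_act_given_notterm = 0.2,
                                        seed = 100 + s))
    if (sum(corp$t) == 0 || sum(corp$region_1) == 0) next
    expect_equal(forward_inference(corp, "t")$p_act_given_term,
                 forward_oracle(corp, "t", "region_1"))
    expect_equal(reverse_inference(corp, "t")$p_term_given_act,
                 reverse_oracle_empirical(corp, "t", "region_1"))
  }
})

test_that("specificity overlap computes Dice against a conjunction map", {
  g <- toy_mask(8, 2)
  mk <- function(idx, val = 1) {
    v <- array(0, dim(g$values)); v[idx] <- val
    volume_map(v, g$voxel_size, g$origin, g$mask)
  }
  rev_map <- mk(c(1, 2, 3), 0.9)
  conj_same <- mk(c(1, 2, 3))
  expect_equal(specificity_overlap(rev_map, conj_same, 0.5)$dice, 1)
  conj_disj <- mk(c(10, 11))
  expect_equal(specificity_overlap(rev_map, conj_disj, 0.5)$dice, 0)
  conj_part <- mk(c(2, 3, 9, 10))
  out <- specificity_overlap(rev_map, conj_part, 0.5)
  expect_equal(out$dice, 2 * 2 / (3 + 4))
  expect_equal(out$n_intersect, 2)
})
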