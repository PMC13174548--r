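test_that("enrichment score reproduces hand-computed running sums", {
  # unweighted, top block: running sum reaches +1 after the two hits
  s4 <- setNames(c(4, 3, 2, 1), c("w", "x", "y", "z"))
  top <- preranked_es(s4, c("w", "x"), weight_p = 0)
  expect_equal(top$es, 1)
  expect_equal(top$peak_index, 2)

  # weighted example: scores (3,2,1,0.5), set at ranks {1,3}
  sc <- setNames(c(3, 2, 1, 0.5), c("a", "b", "c", "d"))
  es <- preranked_es(sc, c("a", "c"), weight_p = 1)
  expect_equal(es$running, c(0.75, 0.25, 0.5, 0))
  expect_equal(es$es, 0.75)
  expect_equal(es$peak_index, 1)

  # bottom block mirrors to -1
  bottom <- preranked_es(s4, c("y", "z"), weight_p = 0)
  expect_equal(bottom$es, -1)

  expect_error(preranked_es(s4, names(s4)), "degenerate")
  expect_error(preranked_es(s4, "absent"), "intersect")
})

test_that("enrichment score agrees with the cumulative-sum oracle", {
  set.seed(20)
  for (i in 1:300) {
    n <- sample(20:120, 1)
    scores <- setNames(rnorm(n), sprintf("g%04d", sample.int(9999, n)))
    set <- sample(names(scores), sample(3:min(15, n - 1), 1))
    for (wp in c(0, 1)) {
      es <- preranked_es(scores, set, weight_p = wp)
      ref <- oracle_es(scores, set, wp)
      expect_equal(abs(es$es), abs(ref), tolerance = 1e-12)
      # sign is only defined when the extrema are not an exact tie
      if (abs(max(es$running) + min(es$running)) > 1e-9) {
        expect_equal(sign(es$es), sign(ref))
      }
      expect_lte(abs(es$es), 1)
    }
  }
})

test_that("enrichment score obeys mirror symmetry under score negation", {
  set.seed(21)
  for (i in 1:50) {
    scores <- setNames(rnorm(60), sprintf("g%03d", 1:60))
    set <- sample(names(scores), 8)
    a <- preranked_es(scores, set, weight_p = 1)$es
    b <- preranked_es(-scores, set, weight_p = 1)$es
    expect_equal(b, -a, tolerance = 1e-9)
  }
})

test_that("permutation null is deterministic and detects planted blocks", {
  set.seed(22)
  scores <- setNames(sort(rnorm(1000), decreasing = TRUE),
                     sprintf("g%04d", 1:1000))
  planted <- names(scores)[sample(1:100, 12)]  # top decile
  r1 <- permutation_null(scores, planted, n_perm = 500, seed = 5)
  r2 <- permutation_null(scores, planted, n_perm = 500, seed = 5)
  expect_identical(r1$nes, r2$nes)
  expect_identical(r1$p_nominal, r2$p_nominal)
  expect_lte(r1$p_nominal, 0.01)
  expect_gt(r1$nes, 1)

  # exact enumeration for a tiny case
  tiny <- setNames(c(5, 4, 3, 2, 1), letters[1:5])
  ex <- permutation_null(tiny, c("a", "b"), n_perm = 100, seed = 1)
  expect_true(ex$exact)
  expect_equal(ex$n_perm, choose(5, 2))
})

test_that("drug-target enrichment flags a designed active class", {
  set.seed(23)
  lib <- c(lapply(1:5, function(i) compound_model(sprintf("xpo1i_%d", i),
                                                  top = 100, bottom = 10,
                                                  ec50 = 10^runif(1, 1.5, 3),
                                                  hill = 1,
                                                  annotated_target = "XPO1")),
           lapply(1:35, function(i) compound_model(sprintf("inact_%d", i),
                                                   top = 100, bottom = 100,
                                                   ec50 = 1000,
                                                   annotated_target = "other")))
  pt <- simulate_single_agent_screen(lib, noise_cv = 0.05, seed = 23)
  act <- single_agent_activity(list(m1 = pt))
  sets <- set_collection(list(XPO1 = sprintf("xpo1i_%d", 1:5),
                              tiny = c("inact_1", "inact_2")))
  expect_warning(res <- dsea(act, sets, n_perm = 500, seed = 7), "tiny")
  expect_equal(res$set, "XPO1")  # 2-member set skipped
  expect_gt(res$es, 0.8)
  expect_lte(res$p_nominal, 0.01)
})

test_that("differential abundance matches the textbook Welch computation", {
  trt <- matrix(c(1.0, 1.2, 0.8), 1, dimnames = list("P1", NULL))
  ctl <- matrix(c(0.0, 0.2, -0.2), 1, dimnames = list("P1", NULL))
  rec <- differential_abundance(trt, ctl)
  expect_equal(rec$log2fc, 1)
  expect_equal(rec$p, oracle_welch_p(c(1, 1.2, 0.8), c(0, 0.2, -0.2)),
               tolerance = 1e-12)
  expect_equal(rec$rank_metric, 1 * -log10(rec$p))
  expect_true(rec$sig_up)

  # exact shift with zero variance: degenerate flag, extreme p
  trt0 <- matrix(c(1, 1, 1), 1, dimnames = list("P1", NULL))
  ctl0 <- matrix(c(0, 0, 0), 1, dimnames = list("P1", NULL))
  d <- differential_abundance(trt0, ctl0)
  expect_true(d$degenerate)
  expect_equal(d$log2fc, 1)
  expect_equal(differential_abundance(trt0, trt0)$p, 1)
})

test_that("rank metric is odd in log2fc and monotone in significance", {
  expect_equal(1 * -log10(0.01), 2)
  lfc <- c(-2, -1, 1, 2)
  expect_equal(lfc * -log10(0.01), -rev(lfc) * -log10(0.01))
  p <- c(0.5, 0.05, 0.005)
  expect_true(all(diff(1 * -log10(p)) > 0))
})

test_that("leading edge collects members up to the peak (or from the trough)", {
  sc <- setNames(c(3, 2, 1, 0.5), c("a", "b", "c", "d"))
  es <- preranked_es(sc, c("a", "c"), weight_p = 1)  # peak at rank 1
  expect_equal(leading_edge(es), "a")

  s4 <- setNames(c(4, 3, 2, 1), c("w", "x", "y", "z"))
  expect_equal(leading_edge(preranked_es(s4, c("w", "x"), weight_p = 0)),
               c("w", "x"))
  expect_equal(leading_edge(preranked_es(s4, c("y", "z"), weight_p = 0)),
               c("y", "z"))
})

test_that("BH adjustment follows the step-up rule over a batch", {
  batch <- data.frame(set = letters[1:4], p_nominal = c(0.01, 0.02, 0.03, 0.04))
  adj <- fdr_adjust(batch)
  expect_equal(adj$fdr_bh, rep(0.04, 4))
  expect_true(all(adj$fdr_bh >= adj$p_nominal))
  expect_equal(fdr_adjust(data.frame(p_nominal = 0.2))$fdr_bh, 0.2)
  expect_equal(fdr_adjust(data.frame(p_nominal = rep(1, 5)))$fdr_bh, rep(1, 5))
})

test_that("overlap analysis recovers planted shared regulation", {
  mk_records <- function(down_ids, up_ids, universe) {
    data.frame(protein_id = universe,
               log2fc = ifelse(universe %in% down_ids, -1,
                               ifelse(universe %in% up_ids, 1, 0)),
               p = ifelse(universe %in% c(down_ids, up_ids), 0.001, 0.9),
               sig_down = universe %in% down_ids,
               sig_up = universe %in% up_ids,
               stringsAsFactors = FALSE)
  }
  uni <- sprintf("P%03d", 1:50)
  recs <- list(c1 = mk_records(uni[1:10], uni[40], uni),
               c2 = mk_records(uni[6:15], uni[40:41], uni))
  ov <- overlap_analysis(recs)
  expect_equal(ov$down$intersection, uni[6:10])
  expect_equal(ov$up$intersection, uni[40])
  expect_equal(sort(ov$down$regions[["c1"]]), uni[1:5])
  # identical significant sets: intersection is the full set
  same <- overlap_analysis(list(a = recs$c1, b = recs$c1))
  expect_equal(same$down$intersection, uni[1:10])
  # disjoint sets: empty intersection
  dis <- overlap_analysis(list(a = mk_records(uni[1:3], NULL, uni),
                               b = mk_records(uni[10:12], NULL, uni)))
  expect_length(dis$down$intersection, 0)
})

test_that("combination-exclusive proteins require combo-only regulation in all models", {
  uni <- sprintf("P%03d", 1:30)
  mk <- function(down) data.frame(protein_id = uni,
                                  sig_down = uni %in% down,
                                  sig_up = FALSE, stringsAsFactors = FALSE)
  combo <- list(m1 = mk(uni[1:6]), m2 = mk(uni[3:8]))
  singles <- list(mk(uni[5]), mk(uni[20]))
  # down in combo of both models: 3..6; protein 5 is hit by a single agent
  expect_equal(combination_exclusive(combo, singles), uni[c(3, 4, 6)])
})
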