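test_that("HSA reference takes the stronger single agent on either scale", {
  m <- combination_matrix("A", "B", c(0, 1), c(0, 1),
                          rbind(c(100, 70), c(80, 55)), scale = "viability")
  ref <- hsa_reference(m)
  expect_true(is.na(ref[1, 1]) && is.na(ref[2, 1]) && is.na(ref[1, 2]))
  expect_equal(ref[2, 2], 70)  # min(80, 70)

  inh <- as_inhibition(m)
  expect_equal(hsa_reference(inh)[2, 2], 30)  # max(20, 30) = 100 - 70
  # involutive scale conversion
  expect_equal(as_viability(inh)$response, m$response)

  # inert partner: reference equals the other margin everywhere
  inert <- combination_matrix("A", "B", c(0, 1, 2), c(0, 1, 2),
                              rbind(c(100, 100, 100), c(70, 60, 50),
                                    c(40, 45, 42)), scale = "viability")
  ref <- hsa_reference(inert)
  expect_equal(ref[2, 2:3], c(70, 70))
  expect_equal(ref[3, 2:3], c(40, 40))
})

test_that("Excess HSA sums interior deviations from the reference", {
  # hand computation: margins A alone (80, 60), B alone (70, 50);
  # references min-pair to [70 50; 60 50], interior [60 40; 50 30]
  # -> per-well excess [-10 -10; -10 -20], total -50
  m <- combination_matrix("A", "B", c(0, 1, 2), c(0, 1, 2),
                          rbind(c(100, 70, 50),
                                c(80, 60, 40),
                                c(60, 50, 30)), scale = "viability")
  s <- excess_hsa(m)
  expect_equal(as.vector(s$per_well_excess), c(-10, -10, -10, -20))
  expect_equal(s$excess_hsa, -50)
  expect_equal(s$n_interior_wells, 4)
  expect_equal(sum(s$per_well_excess), s$excess_hsa, tolerance = 1e-9)

  # observed == reference -> exactly zero
  null_m <- combination_matrix("A", "B", c(0, 1), c(0, 1),
                               rbind(c(100, 70), c(80, 70)), scale = "viability")
  expect_equal(excess_hsa(null_m)$excess_hsa, 0)

  # 81 interior wells each 25 below reference -> -2025, a hit at -2000
  flat80 <- c(100, rep(80, 9))
  resp <- outer(flat80, flat80, pmin)
  resp[2:10, 2:10] <- resp[2:10, 2:10] - 25
  big <- combination_matrix("A", "B", c(0, 1:9), c(0, 1:9), resp,
                            scale = "viability")
  s <- excess_hsa(big)
  expect_equal(s$excess_hsa, -2025)
  expect_true(s$hit)
})

test_that("Excess HSA matches the double-loop oracle and is symmetric", {
  set.seed(10)
  for (i in 1:50) {
    m <- random_combo_matrix(sample(3:8, 1), sample(3:8, 1))
    s <- excess_hsa(m)
    expect_equal(s$excess_hsa, oracle_excess_hsa(m), tolerance = 1e-9)
    # drug swap (transpose) leaves the score unchanged
    tm <- combination_matrix(m$drug_b, m$drug_a, m$doses_b, m$doses_a,
                             t(m$response), scale = m$scale)
    expect_equal(excess_hsa(tm)$excess_hsa, s$excess_hsa, tolerance = 1e-9)
    # scale duality: the same wells scored as inhibition give the same score
    im <- combination_matrix(m$drug_a, m$drug_b, m$doses_a, m$doses_b,
                             100 - m$response, scale = "inhibition")
    expect_equal(excess_hsa(im)$excess_hsa, s$excess_hsa, tolerance = 1e-9)
    # surface is the negated per-well excess
    expect_equal(hsa_surface(m), -s$per_well_excess, tolerance = 1e-12)
  }
})

test_that("hit calling uses a strict threshold and ascending order", {
  mk <- function(total) structure(list(drug_a = "A", drug_b = "B",
                                       model_id = NULL, time_h = NULL,
                                       excess_hsa = total,
                                       per_well_excess = matrix(total),
                                       n_interior_wells = 1,
                                       threshold = -2000, hit = total < -2000),
                                  class = "synergy_score")
  hits <- call_hits(list(mk(-2025), mk(-2000), mk(-3000), mk(500)), -2000)
  expect_equal(hits$excess_hsa, c(-3000, -2025))  # -2000 exactly is not a hit
  expect_equal(nrow(call_hits(list(), -2000)), 0)
})

test_that("model averaging requires one pair and averages grids", {
  a <- compound_model("a", top = 100, bottom = 10, ec50 = 100)
  b <- compound_model("b", top = 100, bottom = 20, ec50 = 200)
  da <- default_matrix_doses(a); db <- default_matrix_doses(b)
  s1 <- excess_hsa(simulate_combination_matrix(a, b, da, db,
                                               interaction_spec("potency_shift", 2),
                                               noise_cv = 0.1, seed = 1, model_id = "m1"))
  s2 <- excess_hsa(simulate_combination_matrix(a, b, da, db,
                                               interaction_spec("potency_shift", 2),
                                               noise_cv = 0.1, seed = 2, model_id = "m2"))
  avg <- average_across_models(list(s1, s2))
  expect_equal(avg$excess_hsa, mean(c(s1$excess_hsa, s2$excess_hsa)))
  expect_equal(avg$per_well_excess,
               (s1$per_well_excess + s2$per_well_excess) / 2)
  expect_equal(average_across_models(list(s1))$excess_hsa, s1$excess_hsa)

  s3 <- s2; s3$drug_b <- "other"
  expect_error(average_across_models(list(s1, s3)), "same drug pair")
})

test_that("profile clustering groups identical profiles first", {
  # A and B have identical profiles against shared partners C, D, E
  panel <- data.frame(
    drug_a = c("A", "A", "A", "A", "B", "B", "B", "C", "C", "D"),
    drug_b = c("B", "C", "D", "E", "C", "D", "E", "D", "E", "E"),
    excess_hsa = c(-5, -10, -20, -30, -10, -20, -30, -55, -15, -70))
  cl <- profile_cluster(panel)
  expect_s3_class(cl, "combo_profile_clustering")
  expect_equal(cl$correlations["A", "B"], 1, tolerance = 1e-12)
  first_merge <- rownames(cl$correlations)[-cl$hclust$merge[1, ]]
  expect_setequal(first_merge, c("A", "B"))
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)

  # hand-checked correlations on a tiny designed panel
  p2 <- data.frame(
    drug_a = c("A", "A", "A", "A", "B", "B", "B", "C", "C", "D"),
    drug_b = c("B", "C", "D", "E", "C", "D", "E", "D", "E", "E"),
    excess_hsa = c(-5, -10, -20, -30, -12, -18, -33, -40, -50, -60))
  cl2 <- profile_cluster(p2)
  # correlation of A and B profiles over shared partners C, D, E
  expect_equal(cl2$correlations["A", "B"],
               manual_pearson(c(-10, -20, -30), c(-12, -18, -33)),
               tolerance = 1e-12)
  # first merge joins the closest pair at height 1 - max off-diagonal r
  R <- cl2$correlations; diag(R) <- NA
  expect_equal(cl2$hclust$height[1], 1 - max(R, na.rm = TRUE), tolerance = 1e-12)
})

test_that("zero-variance profiles are flagged and placed last", {
  panel <- data.frame(
    drug_a = c("A", "A", "A", "B", "B", "C"),
    drug_b = c("B", "C", "Z", "C", "Z", "Z"),
    excess_hsa = c(-10, -20, -7, -30, -7, -7))
  # Z scores -7 against everyone: zero variance profile
  cl <- profile_cluster(panel)
  expect_equal(cl$flagged, "Z")
  expect_equal(utils::tail(cl$order, 1), "Z")
})

test_that("partner ranking is symmetric for the strongest pair", {
  set.seed(12)
  lib <- lapply(1:6, function(i) random_compound(paste0("c", i)))
  tab <- score_planted_panel(lib, c("c2", "c5"), seed = 3, shift = 3)
  expect_equal(rank_partners(tab, "c2", 1)$partner, "c5")
  expect_equal(rank_partners(tab, "c5", 1)$partner, "c2")
  full <- rank_partners(tab, "c2", 100)
  expect_equal(nrow(full), 5)  # k beyond panel returns everything
  expect_equal(full$excess_hsa, sort(full$excess_hsa))
  expect_error(rank_partners(tab, "nope"), "anchor")
})

test_that("time-course scoring demands consistent grids", {
  a <- compound_model("a", top = 100, bottom = 5, ec50 = 100)
  b <- compound_model("b", top = 100, bottom = 10, ec50 = 300)
  mats <- simulate_timecourse_matrices(a, b, times = c(4, 12, 24), onset = 6,
                                       noise_cv = 0, seed = 2)
  tc <- timecourse_synergy(mats)
  expect_equal(tc$time_h, c(4, 12, 24))
  mats[[2]]$doses_a <- mats[[2]]$doses_a * 2
  expect_error(timecourse_synergy(mats), "share")
})
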