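# Shared fixtures and independent oracles. Oracles are deliberately
# naive (explicit loops, no shared code with the package internals).

# A minimal valid plate: 2 dmso + 2 empty controls and one compound well.
tiny_plate_df <- function(signal = 550000, conc = 100) {
  data.frame(
    plate_id = "p1",
    well_id = c("A01", "A02", "A03", "A04", "A05"),
    row = 1L, col = 1:5,
    compound_id = c(NA, NA, NA, NA, "drugX"),
    concentration = c(0, 0, 0, 0, conc),
    role = c("dmso", "dmso", "empty", "empty", "compound"),
    signal = c(1e6, 1e6, 1e5, 1e5, signal),
    stringsAsFactors = FALSE)
}

write_tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# Brute-force Excess HSA: explicit double loop over interior wells.
oracle_excess_hsa <- function(m) {
  v <- if (m$scale == "inhibition") 100 - m$response else m$response
  ia <- which(m$doses_a == 0); ib <- which(m$doses_b == 0)
  total <- 0
  for (i in seq_along(m$doses_a)) {
    for (j in seq_along(m$doses_b)) {
      if (m$doses_a[i] > 0 && m$doses_b[j] > 0) {
        ref <- min(v[i, ib], v[ia, j])
        total <- total + (v[i, j] - ref)
      }
    }
  }
  total
}

# Direct cumulative-sum reference for the preranked enrichment score.
oracle_es <- function(scores, set, weight_p) {
  o <- order(-scores, names(scores))
  s <- scores[o]
  hit <- names(s) %in% set
  n <- length(s); nh <- sum(hit)
  denom <- sum(abs(s[hit])^weight_p)
  run <- 0; best <- 0
  for (k in seq_len(n)) {
    run <- run + if (hit[k]) abs(s[[k]])^weight_p / denom else -1 / (n - nh)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Textbook Welch two-sample t (unequal variances), two-sided p.
oracle_welch_p <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(t), df)
}

manual_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# Random compound with its EC50 inside a 100-fold dose window.
random_compound <- function(id) {
  compound_model(id, top = 100, bottom = runif(1, 0, 30),
                 ec50 = 10^runif(1, 1, 3), hill = runif(1, 0.8, 2))
}

# A combination matrix with arbitrary responses (margins included).
random_combo_matrix <- function(na = 5, nb = 4) {
  combination_matrix(
    "A", "B",
    doses_a = c(0, sort(10^runif(na - 1, 0, 3))),
    doses_b = c(0, sort(10^runif(nb - 1, 0, 3))),
    response = matrix(runif(na * nb, -5, 110), na, nb),
    scale = "viability")
}

# Score all pairwise matrices of a compound panel, planting one
# potency-shift pair; everything else is HSA-null.
score_planted_panel <- function(lib, planted, seed, shift = 3, noise_cv = 0.1) {
  ids <- vapply(lib, `[[`, "", "compound_id")
  names(lib) <- ids
  pairs <- drug_pairs(ids)
  scores <- lapply(seq_len(nrow(pairs)), function(r) {
    a <- lib[[pairs$drug_a[r]]]; b <- lib[[pairs$drug_b[r]]]
    ia <- if (setequal(c(a$compound_id, b$compound_id), planted)) {
      interaction_spec("potency_shift", shift)
    } else interaction_spec("hsa_null")
    excess_hsa(simulate_combination_matrix(
      a, b, default_matrix_doses(a), default_matrix_doses(b),
      interaction = ia, noise_cv = noise_cv, seed = seed * 1000 + r))
  })
  synergy_table(scores)
}
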