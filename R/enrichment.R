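# Preranked set enrichment with an explicit permutation null, replicate
# differential abundance with composite rank metric, leading-edge
# extraction, and cross-condition overlap / exclusivity analysis.

# Sort a named score vector into ranked order: descending score, ties
# broken by id so every run is deterministic.
rank_scores <- function(scores) {
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    stop_validation("scores must be uniquely named by item id")
  }
  if (any(!is.finite(scores))) stop_validation("scores must be finite")
  scores[order(-scores, names(scores))]
}

#' Preranked enrichment score
#'
#' Classic weighted Kolmogorov-Smirnov running sum: walking down the
#' ranked list, the sum rises by `|score|^weight_p / sum_set(|score|^weight_p)`
#' at set members and falls by `1/(N - N_set)` elsewhere; the enrichment
#' score is the running-sum value of maximal absolute deviation (signed),
#' always in `[-1, 1]`.
#'
#' @param scores Named numeric vector of item scores (any order; ranked
#'   internally, descending, ties by id).
#' @param set Character vector of member ids; must intersect the list and
#'   not cover it.
#' @param weight_p Score weight exponent (0 = unweighted, 1 = classic).
#' @return List of class `es_result`: `es`, `peak_index`, `running`,
#'   `order` (ranked ids), `hits` (logical), `n_hits`.
#' @export
preranked_es <- function(scores, set, weight_p = 1) {
  s <- rank_scores(scores)
  hits <- names(s) %in% set
  n <- length(s); nh <- sum(hits)
  if (nh == 0) stop_validation("set does not intersect the ranked list")
  if (nh == n) stop_validation("degenerate set: covers the whole ranked list")
  w <- abs(s)^weight_p
  inc <- numeric(n)
  inc[hits] <- w[hits] / sum(w[hits])
  inc[!hits] <- -1 / (n - nh)
  running <- cumsum(inc)
  peak <- which.max(abs(running))
  structure(list(es = running[peak], peak_index = peak, running = running,
                 order = names(s), hits = hits, n_hits = nh,
                 weight_p = weight_p),
            class = "es_result")
}

# Null ES for index sets over a pre-ranked weight vector; shared by the
# sampling and enumerating branches.
null_es_one <- function(w, idx, n) {
  nh <- length(idx)
  inc <- rep(-1 / (n - nh), n)
  inc[idx] <- w[idx] / sum(w[idx])
  running <- cumsum(inc)
  running[which.max(abs(running))]
}

#' Permutation null for a preranked enrichment score
#'
#' Draws `n_perm` random same-size member sets from the ranked list (or
#' enumerates all of them when `choose(N, N_set) <= 10000`), computes
#' their enrichment scores, and reports a sign-stratified nominal p-value
#' `(1 + #{same-sign |null| >= |es|}) / (1 + #same-sign null)` together
#' with `nes = es / mean(|same-sign null es|)`.
#'
#' @inheritParams preranked_es
#' @param n_perm Number of permutations (`>= 100`).
#' @param seed Integer seed; equal seeds give identical results.
#' @param exact_limit Enumerate the null exactly when the number of
#'   same-size sets is at most this.
#' @return List of class `enrichment_result`: `es`, `nes`, `p_nominal`,
#'   `peak_index`, `n_perm`, `exact`, `degenerate` (no same-sign null
#'   draws; p then reported at its resolution limit), `null_es`.
#' @export
permutation_null <- function(scores, set, n_perm = 1000, seed = 1,
                             weight_p = 1, exact_limit = 10000) {
  if (n_perm < 100) stop_validation("n_perm must be >= 100")
  obs <- preranked_es(scores, set, weight_p)
  s <- rank_scores(scores)
  w <- abs(s)^weight_p
  n <- length(s); nh <- obs$n_hits
  exact <- is.finite(choose(n, nh)) && choose(n, nh) <= exact_limit
  null_es <- if (exact) {
    apply(utils::combn(n, nh), 2, function(idx) null_es_one(w, idx, n))
  } else {
    with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        null_es_one(w, sample.int(n, nh), n)
      }, 0)
    })
  }
  same <- null_es[sign(null_es) == sign(obs$es) | null_es == 0]
  degenerate <- length(same) == 0
  p <- if (degenerate) 1 / (length(null_es) + 1) else {
    (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
  }
  nes <- if (degenerate) NA_real_ else obs$es / mean(abs(same))
  structure(list(es = obs$es, nes = nes, p_nominal = p,
                 peak_index = obs$peak_index,
                 n_perm = length(null_es), exact = exact,
                 degenerate = degenerate, null_es = null_es),
            class = "enrichment_result")
}

#' Leading-edge members of an enrichment result
#'
#' For a positive enrichment score, the set members at or before the
#' running-sum peak; for a negative score, those at or after the trough.
#'
#' @param es_result An `es_result` from [preranked_es()] (or any object
#'   with `order`, `hits`, `peak_index`, `es`).
#' @return Character vector of leading-edge item ids, in rank order.
#' @export
leading_edge <- function(es_result) {
  idx <- if (es_result$es >= 0) {
    seq_len(es_result$peak_index)
  } else {
    seq(es_result$peak_index, length(es_result$order))
  }
  es_result$order[idx][es_result$hits[idx]]
}

#' Benjamini-Hochberg adjustment over an enrichment batch
#'
#' @param results Data frame with a `p_nominal` (or `p`) column.
#' @param alpha Significance level on the adjusted values.
#' @return The data frame with `fdr_bh` and `significant` columns.
#' @export
fdr_adjust <- function(results, alpha = 0.05) {
  pcol <- if ("p_nominal" %in% names(results)) "p_nominal" else "p"
  if (!pcol %in% names(results)) stop_validation("no p-value column found")
  results$fdr_bh <- stats::p.adjust(results[[pcol]], method = "BH")
  results$significant <- results$fdr_bh < alpha
  results
}

#' Preranked GSEA over a set collection
#'
#' Runs [preranked_es()] + [permutation_null()] for every set with at
#' least `min_size` members in the ranked list, extracts leading edges,
#' and BH-adjusts the nominal p-values over the batch. Undersized sets are
#' skipped with a warning.
#'
#' @inheritParams permutation_null
#' @param sets A [set_collection()] (or named list of member vectors).
#' @param min_size Minimum set overlap with the list (default 3).
#' @return Data frame `set, n_hits_in_list, es, nes, p_nominal, fdr_bh,
#'   significant, leading_edge` (pipe-joined member ids).
#' @export
preranked_gsea <- function(scores, sets, n_perm = 1000, seed = 1,
                           weight_p = 1, min_size = 3) {
  if (!length(sets)) stop_validation("empty set collection")
  ids <- names(rank_scores(scores))
  sizes <- vapply(sets, function(m) sum(ids %in% m), 0L)
  skip <- names(sets)[sizes < min_size]
  if (length(skip)) {
    warning("skipping set(s) with fewer than ", min_size,
            " members in the ranked list: ", paste(skip, collapse = ", "))
  }
  keep <- setdiff(names(sets), skip)
  if (!length(keep)) stop_validation("no set meets the minimum size")
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, length(keep)))
  rows <- lapply(seq_along(keep), function(k) {
    nm <- keep[k]
    es <- preranked_es(scores, sets[[nm]], weight_p)
    nul <- permutation_null(scores, sets[[nm]], n_perm = n_perm,
                            seed = seeds[k], weight_p = weight_p)
    data.frame(set = nm, n_hits_in_list = es$n_hits, es = es$es,
               nes = nul$nes, p_nominal = nul$p_nominal,
               leading_edge = paste(leading_edge(es), collapse = "|"),
               stringsAsFactors = FALSE)
  })
  out <- fdr_adjust(do.call(rbind, rows))
  out[order(out$p_nominal, out$set),
      c("set", "n_hits_in_list", "es", "nes", "p_nominal", "fdr_bh",
        "significant", "leading_edge")]
}

#' Drug-target set enrichment on an activity ranking
#'
#' Ranks compounds by activity using the score `-mean_z_auc` (so the most
#' active compounds, with the lowest Z-AUC, sit at the top of the list
#' with positive scores) and tests each annotated drug-target set for
#' enrichment among the actives via permutation preranked GSEA.
#'
#' @param activity Ranked activity table from [aggregate_activity()]
#'   (needs `compound_id` and `mean_z_auc`).
#' @param drug_sets A [set_collection()] of target-class compound sets.
#' @inheritParams permutation_null
#' @param min_size Minimum compounds per set in the library (default 3;
#'   smaller sets are skipped with a warning).
#' @return The [preranked_gsea()] results table.
#' @export
dsea <- function(activity, drug_sets, n_perm = 1000, seed = 1, min_size = 3) {
  scores <- stats::setNames(-activity$mean_z_auc, activity$compound_id)
  preranked_gsea(scores, drug_sets, n_perm = n_perm, seed = seed,
                 weight_p = 1, min_size = min_size)
}

#' Replicate differential abundance
#'
#' Per protein: `log2fc = mean(treated) - mean(control)` of replicate
#' log2 intensities; a two-sided Welch t-test p-value; the composite rank
#' metric `log2fc * (-log10 p)`; and significance flags at
#' `|log2fc| > log2fc_cut` and `p < p_cut`. When both arms have zero
#' variance the test is degenerate: p = 1 for equal means, else the
#' smallest representable double, with `degenerate = TRUE`.
#'
#' @param treated,control Numeric matrices (proteins x replicates, `>= 2`
#'   columns) with matching rownames (protein ids).
#' @param log2fc_cut,p_cut Significance thresholds (defaults 0.5, 0.05).
#' @return Data frame `protein_id, log2fc, p, rank_metric, sig_down,
#'   sig_up, degenerate`.
#' @export
differential_abundance <- function(treated, control, log2fc_cut = 0.5,
                                   p_cut = 0.05) {
  treated <- as.matrix(treated); control <- as.matrix(control)
  if (ncol(treated) < 2 || ncol(control) < 2) {
    stop_validation("need >= 2 replicates per arm")
  }
  if (is.null(rownames(treated)) || !identical(rownames(treated), rownames(control))) {
    stop_validation("treated and control must share identical protein rownames")
  }
  n <- nrow(treated)
  log2fc <- rowMeans(treated) - rowMeans(control)
  p <- numeric(n); degenerate <- logical(n)
  for (i in seq_len(n)) {
    tv <- treated[i, ]; cv <- control[i, ]
    if (stats::var(tv) == 0 && stats::var(cv) == 0) {
      degenerate[i] <- TRUE
      p[i] <- if (log2fc[i] == 0) 1 else .Machine$double.xmin
    } else {
      p[i] <- stats::t.test(tv, cv, var.equal = FALSE)$p.value
    }
  }
  data.frame(protein_id = rownames(treated), log2fc = unname(log2fc),
             p = p, rank_metric = unname(log2fc * -log10(p)),
             sig_down = unname(log2fc < -log2fc_cut & p < p_cut),
             sig_up = unname(log2fc > log2fc_cut & p < p_cut),
             degenerate = degenerate, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Differential abundance from a simulated proteomics table
#'
#' Convenience wrapper splitting the `control_*` / `treated_*` columns of
#' [simulate_proteomics()] output.
#'
#' @param sim Data frame from [simulate_proteomics()].
#' @inheritParams differential_abundance
#' @return See [differential_abundance()].
#' @export
proteomics_differential <- function(sim, log2fc_cut = 0.5, p_cut = 0.05) {
  trt <- as.matrix(sim[grep("^treated_", names(sim))])
  ctl <- as.matrix(sim[grep("^control_", names(sim))])
  rownames(trt) <- rownames(ctl) <- sim$protein_id
  differential_abundance(trt, ctl, log2fc_cut = log2fc_cut, p_cut = p_cut)
}

sig_ids <- function(records, direction) {
  col <- switch(direction, down = "sig_down", up = "sig_up",
                stop_validation("direction must be 'down' or 'up'"))
  records$protein_id[records[[col]]]
}

#' Cross-condition overlap of significant proteins
#'
#' For each direction, collects the significant protein sets of every
#' condition, the intersection across all conditions, and exclusive Venn
#' region counts keyed by membership pattern (condition names joined by
#' `&`).
#'
#' @param records Named list of [differential_abundance()] tables, one
#'   per condition, over a shared protein universe.
#' @param directions Directions to analyse (`"down"`, `"up"` or both).
#' @return Named list per direction with `per_condition` (sig id sets),
#'   `intersection` (ids significant in every condition) and `regions`
#'   (named list of exclusive region member ids).
#' @export
overlap_analysis <- function(records, directions = c("down", "up")) {
  if (length(records) < 2 || is.null(names(records))) {
    stop_validation("records must be a named list of >= 2 condition tables")
  }
  universes <- lapply(records, `[[`, "protein_id")
  if (length(Reduce(intersect, universes)) == 0) {
    stop_validation("conditions have disjoint protein universes")
  }
  out <- lapply(directions, function(dir) {
    sets <- lapply(records, sig_ids, direction = dir)
    all_sig <- sort(unique(unlist(sets)))
    pattern <- vapply(all_sig, function(p) {
      paste(names(sets)[vapply(sets, function(s) p %in% s, TRUE)], collapse = "&")
    }, "")
    list(per_condition = sets,
         intersection = Reduce(intersect, sets),
         regions = split(all_sig, pattern))
  })
  stats::setNames(out, directions)
}

#' Proteins regulated exclusively by the combination
#'
#' Proteins significantly regulated (down by default) by the combination
#' treatment in *every* cell model while not significantly regulated in
#' the same direction by *any* single-agent treatment in any model.
#'
#' @param combo_records Named list (per model) of combination-treatment
#'   [differential_abundance()] tables.
#' @param single_records List of single-agent tables (any model/agent).
#' @param direction `"down"` (default) or `"up"`.
#' @return Sorted character vector of protein ids.
#' @export
combination_exclusive <- function(combo_records, single_records,
                                  direction = "down") {
  if (!length(combo_records) || !length(single_records)) {
    stop_validation("need both combination and single-agent tables")
  }
  universes <- lapply(c(combo_records, single_records), `[[`, "protein_id")
  if (length(Reduce(intersect, universes)) == 0) {
    stop_validation("tables have disjoint protein universes")
  }
  in_all_combo <- Reduce(intersect, lapply(combo_records, sig_ids,
                                           direction = direction))
  in_any_single <- unique(unlist(lapply(single_records, sig_ids,
                                        direction = direction)))
  sort(setdiff(in_all_combo, in_any_single))
}
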