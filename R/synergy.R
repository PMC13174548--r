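# Dose-matrix combination scoring against the Highest-Single-Agent
# reference: Excess HSA, hit calling, per-well surfaces, combination
# profile clustering, partner ranking and time-course synergy.

#' Construct a two-drug dose matrix
#'
#' A factorial response grid over two dose series, each containing a
#' single zero dose (the untreated margin). Responses are either percent
#' viability or percent inhibition (`inhibition = 100 - viability`).
#'
#' @param drug_a,drug_b Compound identifiers.
#' @param doses_a,doses_b Dose vectors, nM, each containing 0 exactly
#'   once; rows of `response` follow `doses_a`, columns `doses_b`.
#' @param response Numeric matrix, `length(doses_a)` x `length(doses_b)`.
#' @param scale `"viability"` or `"inhibition"`.
#' @param model_id Optional cell-model label.
#' @param time_h Optional time tag in hours.
#' @return An object of class `combination_matrix`.
#' @export
combination_matrix <- function(drug_a, drug_b, doses_a, doses_b, response,
                               scale = c("viability", "inhibition"),
                               model_id = NULL, time_h = NULL) {
  scale <- match.arg(scale)
  check_matrix_doses(doses_a, "doses_a")
  check_matrix_doses(doses_b, "doses_b")
  response <- as.matrix(response)
  if (!all(dim(response) == c(length(doses_a), length(doses_b)))) {
    stop_validation("response grid dimensions do not match dose lists")
  }
  structure(list(drug_a = as.character(drug_a), drug_b = as.character(drug_b),
                 doses_a = as.numeric(doses_a), doses_b = as.numeric(doses_b),
                 response = response, scale = scale,
                 model_id = model_id, time_h = time_h),
            class = "combination_matrix")
}

#' @export
print.combination_matrix <- function(x, ...) {
  cat(sprintf("%s x %s dose matrix (%d x %d, %s scale%s%s)\n",
              x$drug_a, x$drug_b, length(x$doses_a), length(x$doses_b),
              x$scale,
              if (!is.null(x$model_id)) paste0(", ", x$model_id) else "",
              if (!is.null(x$time_h)) sprintf(", %g h", x$time_h) else ""))
  invisible(x)
}

#' Convert a dose matrix to the viability scale
#'
#' The inhibition/viability conversion `100 - x` is exact and involutive.
#'
#' @param matrix A `combination_matrix`.
#' @return The same matrix on the viability scale.
#' @export
as_viability <- function(matrix) {
  if (matrix$scale == "viability") return(matrix)
  matrix$response <- 100 - matrix$response
  matrix$scale <- "viability"
  matrix
}

#' Convert a dose matrix to the inhibition scale
#' @param matrix A `combination_matrix`.
#' @return The same matrix on the inhibition scale.
#' @export
as_inhibition <- function(matrix) {
  if (matrix$scale == "inhibition") return(matrix)
  matrix$response <- 100 - matrix$response
  matrix$scale <- "inhibition"
  matrix
}

#' Highest-Single-Agent reference grid
#'
#' For interior wells (both doses > 0) the HSA reference is the stronger
#' single agent at the matching marginal doses: on the viability scale
#' `ref(i,j) = min(margin_a(i), margin_b(j))`; on the inhibition scale the
#' max of the inhibition margins (the same reference, `100 -` the other).
#'
#' @param matrix A `combination_matrix` with both zero-dose margins.
#' @return Matrix of reference responses on the matrix's own scale, `NA`
#'   on the margins.
#' @export
hsa_reference <- function(matrix) {
  v <- as_viability(matrix)
  ia <- which(v$doses_a == 0)
  ib <- which(v$doses_b == 0)
  margin_a <- v$response[, ib]   # drug A alone, indexed by doses_a
  margin_b <- v$response[ia, ]   # drug B alone, indexed by doses_b
  ref <- outer(margin_a, margin_b, pmin)
  ref[ia, ] <- NA_real_
  ref[, ib] <- NA_real_
  if (matrix$scale == "inhibition") ref <- 100 - ref
  ref
}

#' Excess HSA synergy score
#'
#' Sums, over all interior wells (both doses > 0), the observed percent
#' viability minus the HSA reference. Negative totals mean killing beyond
#' the best single agent (synergy); the score is a sum, not a mean, so a
#' 10x10 matrix with 81 interior wells each 25 points below reference
#' scores -2025.
#'
#' @param matrix A `combination_matrix` (converted to viability
#'   internally).
#' @param threshold Hit threshold on the summed score (default -2000,
#'   strict `<`).
#' @return An object of class `synergy_score` with `excess_hsa`,
#'   `per_well_excess` (interior grid), `n_interior_wells` and `hit`.
#' @export
excess_hsa <- function(matrix, threshold = -2000) {
  v <- as_viability(matrix)
  ref <- hsa_reference(v)
  interior <- !is.na(ref)
  obs <- v$response
  bad <- interior & !is.finite(obs)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    stop_validation("non-finite interior response at well(s): ",
                    paste(sprintf("(%g nM, %g nM)", v$doses_a[idx[, 1]],
                                  v$doses_b[idx[, 2]]), collapse = ", "))
  }
  excess <- obs - ref
  pw <- excess[v$doses_a != 0, v$doses_b != 0, drop = FALSE]
  dimnames(pw) <- list(v$doses_a[v$doses_a != 0], v$doses_b[v$doses_b != 0])
  total <- sum(pw)
  structure(list(drug_a = v$drug_a, drug_b = v$drug_b,
                 model_id = v$model_id, time_h = v$time_h,
                 excess_hsa = total, per_well_excess = pw,
                 n_interior_wells = length(pw),
                 threshold = threshold, hit = total < threshold),
            class = "synergy_score")
}

#' @export
print.synergy_score <- function(x, ...) {
  cat(sprintf("Excess HSA %s + %s%s: %.1f over %d interior wells (mean %.2f)%s\n",
              x$drug_a, x$drug_b,
              if (!is.null(x$model_id)) paste0(" [", x$model_id, "]") else "",
              x$excess_hsa, x$n_interior_wells,
              x$excess_hsa / x$n_interior_wells,
              if (x$hit) sprintf("  HIT (< %g)", x$threshold) else ""))
  invisible(x)
}

#' Per-well HSA synergy surface (inhibition scale)
#'
#' `surface(i,j) = observed inhibition - max(margin inhibitions)` over
#' interior wells; positive values mean synergy. Numerically this is the
#' negation of the per-well viability excess.
#'
#' @param matrix A `combination_matrix`.
#' @return Interior grid of synergy values (positive = synergy).
#' @export
hsa_surface <- function(matrix) {
  -excess_hsa(matrix)$per_well_excess
}

#' Average synergy scores across cell models
#'
#' @param scores List of `synergy_score` objects for the same drug pair
#'   (one per model). Per-well grids are averaged only when all dose grids
#'   match; otherwise the averaged score omits them.
#' @param threshold Hit threshold applied to the averaged score.
#' @return A `synergy_score` with `model_id = "mean"`.
#' @export
average_across_models <- function(scores, threshold = -2000) {
  stopifnot(length(scores) >= 1, all(vapply(scores, inherits, TRUE, "synergy_score")))
  pair <- c(scores[[1]]$drug_a, scores[[1]]$drug_b)
  same <- vapply(scores, function(s) {
    identical(c(s$drug_a, s$drug_b), pair)
  }, TRUE)
  if (!all(same)) stop_validation("all scores must refer to the same drug pair")
  total <- mean(vapply(scores, `[[`, 0, "excess_hsa"))
  dims_equal <- length(unique(lapply(scores, function(s) dimnames(s$per_well_excess)))) == 1
  pw <- if (dims_equal) {
    Reduce(`+`, lapply(scores, `[[`, "per_well_excess")) / length(scores)
  } else NULL
  structure(list(drug_a = pair[1], drug_b = pair[2], model_id = "mean",
                 time_h = NULL, excess_hsa = total, per_well_excess = pw,
                 n_interior_wells = if (!is.null(pw)) length(pw) else
                   scores[[1]]$n_interior_wells,
                 threshold = threshold, hit = total < threshold),
            class = "synergy_score")
}

#' Tabulate synergy scores
#'
#' @param scores List of `synergy_score` objects.
#' @return Data frame `drug_a, drug_b, model_id, excess_hsa,
#'   n_interior_wells, per_well_mean, hit`.
#' @export
synergy_table <- function(scores) {
  if (inherits(scores, "synergy_score")) scores <- list(scores)
  do.call(rbind, lapply(scores, function(s) {
    data.frame(drug_a = s$drug_a, drug_b = s$drug_b,
               model_id = s$model_id %||% NA_character_,
               excess_hsa = s$excess_hsa,
               n_interior_wells = s$n_interior_wells,
               per_well_mean = s$excess_hsa / s$n_interior_wells,
               hit = s$hit, stringsAsFactors = FALSE)
  }))
}

#' Call synergy hits
#'
#' Strict threshold on the summed Excess HSA (`score < threshold`), with
#' the result sorted ascending so the strongest synergy comes first.
#'
#' @param scores List of `synergy_score` objects or a data frame with an
#'   `excess_hsa` column.
#' @param threshold Hit threshold (default -2000).
#' @return Data frame of hits sorted ascending by `excess_hsa`; empty
#'   input gives an empty table.
#' @export
call_hits <- function(scores, threshold = -2000) {
  df <- if (is.data.frame(scores)) scores else if (length(scores)) {
    synergy_table(scores)
  } else {
    data.frame(drug_a = character(), drug_b = character(),
               model_id = character(), excess_hsa = numeric(),
               n_interior_wells = integer(), per_well_mean = numeric(),
               hit = logical(), stringsAsFactors = FALSE)
  }
  df$hit <- df$excess_hsa < threshold
  hits <- df[df$hit, , drop = FALSE]
  hits <- hits[order(hits$excess_hsa), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' All unordered drug pairs of a panel
#'
#' @param compounds Character vector of compound ids (or a list of
#'   [compound_model()] objects).
#' @return Data frame `drug_a, drug_b` with `choose(n, 2)` rows.
#' @export
drug_pairs <- function(compounds) {
  if (is.list(compounds)) compounds <- vapply(compounds, `[[`, "", "compound_id")
  n <- length(compounds)
  if (n < 2) stop_validation("need >= 2 compounds")
  idx <- utils::combn(n, 2)
  data.frame(drug_a = compounds[idx[1, ]], drug_b = compounds[idx[2, ]],
             stringsAsFactors = FALSE)
}

# Symmetric profile matrix (compounds x partners) of Excess HSA from an
# all-pairs score table; diagonal NA.
profile_matrix <- function(panel_scores) {
  stopifnot(all(c("drug_a", "drug_b", "excess_hsa") %in% names(panel_scores)))
  ids <- sort(unique(c(panel_scores$drug_a, panel_scores$drug_b)))
  P <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  # average duplicates (e.g. both orientations or per-model rows)
  key <- paste(pmin(panel_scores$drug_a, panel_scores$drug_b),
               pmax(panel_scores$drug_a, panel_scores$drug_b), sep = "\r")
  agg <- tapply(panel_scores$excess_hsa, key, mean)
  ab <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  P[cbind(ab[, 1], ab[, 2])] <- as.numeric(agg)
  P[cbind(ab[, 2], ab[, 1])] <- as.numeric(agg)
  P
}

#' Cluster compounds by their combination profiles
#'
#' Each compound's profile is its vector of Excess HSA scores against
#' every panel partner (the self pair excluded). Profiles are compared by
#' Pearson correlation over shared partners, converted to the distance
#' `1 - r`, and clustered agglomeratively (average linkage by default).
#' Compounds with a zero-variance profile have undefined correlations;
#' they are flagged and appended after the clustered leaves rather than
#' silently dropped.
#'
#' @param panel_scores All-pairs score table (`drug_a, drug_b,
#'   excess_hsa`), e.g. from [synergy_table()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return List of class `combo_profile_clustering`: `order` (compound
#'   ids, deterministic leaf order plus flagged compounds last),
#'   `hclust`, `correlations`, `flagged`.
#' @export
profile_cluster <- function(panel_scores, linkage = "average") {
  P <- profile_matrix(panel_scores)
  if (nrow(P) < 3) stop_validation("need >= 3 compounds to cluster")
  sds <- apply(P, 1, stats::sd, na.rm = TRUE)
  flagged <- rownames(P)[!is.finite(sds) | sds == 0]
  keep <- setdiff(rownames(P), flagged)
  if (length(keep) < 2) stop_validation("fewer than 2 compounds with informative profiles")
  R <- stats::cor(t(P[keep, , drop = FALSE]), use = "pairwise.complete.obs")
  hc <- stats::hclust(stats::as.dist(1 - R), method = linkage)
  structure(list(order = c(keep[hc$order], flagged), hclust = hc,
                 correlations = R, flagged = flagged, linkage = linkage),
            class = "combo_profile_clustering")
}

#' @export
print.combo_profile_clustering <- function(x, ...) {
  cat(sprintf("Combination-profile clustering of %d compounds (%s linkage)\n",
              length(x$order), x$linkage))
  cat("  leaf order:", paste(x$order, collapse = ", "), "\n")
  if (length(x$flagged)) {
    cat("  flagged (zero-variance profile):",
        paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Rank combination partners of an anchor compound
#'
#' @param panel_scores All-pairs score table (`drug_a, drug_b,
#'   excess_hsa`).
#' @param anchor Compound id whose partners to rank.
#' @param k Number of top partners to return (truncated to the panel
#'   size).
#' @return Data frame `partner, excess_hsa, rank`, ascending (rank 1 =
#'   strongest synergy).
#' @export
rank_partners <- function(panel_scores, anchor, k = 10) {
  P <- profile_matrix(panel_scores)
  if (!anchor %in% rownames(P)) stop_validation("anchor not in panel: ", anchor)
  v <- P[anchor, ]
  v <- v[names(v) != anchor & !is.na(v)]
  o <- order(v, names(v))
  out <- data.frame(partner = names(v)[o], excess_hsa = unname(v[o]),
                    stringsAsFactors = FALSE)
  out$rank <- seq_len(nrow(out))
  utils::head(out, k)
}

#' Excess HSA across a time course
#'
#' Scores each time-tagged matrix and reports the trajectory plus the
#' time of maximal absolute synergy.
#'
#' @param matrices List of `combination_matrix` objects sharing one drug
#'   pair and dose grid, each with a `time_h` tag.
#' @param threshold Hit threshold passed to [excess_hsa()].
#' @return Data frame `time_h, excess_hsa, hit`, with attribute
#'   `peak_time` (argmax of `|excess_hsa|`).
#' @export
timecourse_synergy <- function(matrices, threshold = -2000) {
  stopifnot(length(matrices) >= 1)
  pair <- c(matrices[[1]]$drug_a, matrices[[1]]$drug_b)
  grids <- lapply(matrices, function(m) list(m$doses_a, m$doses_b))
  if (length(unique(grids)) != 1 ||
      !all(vapply(matrices, function(m) identical(c(m$drug_a, m$drug_b), pair), TRUE))) {
    stop_validation("matrices must share one drug pair and dose grid")
  }
  times <- vapply(matrices, function(m) m$time_h %||% NA_real_, 0)
  if (anyNA(times)) stop_validation("every matrix needs a time_h tag")
  scores <- vapply(matrices, function(m) excess_hsa(m, threshold)$excess_hsa, 0)
  o <- order(times)
  out <- data.frame(time_h = times[o], excess_hsa = scores[o],
                    hit = scores[o] < threshold)
  attr(out, "peak_time") <- out$time_h[which.max(abs(out$excess_hsa))]
  out
}
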