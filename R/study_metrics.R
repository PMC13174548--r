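# Closed-form study metrics: summed-Z signature scoring, percentile
# quartile stratification, tumor-volume formulas, apoptotic index.

#' Summed-Z gene-signature score
#'
#' Per sample, the sum of expression Z-scores over the signature genes
#' present in the matrix. Missing signature genes are dropped (and
#' counted), not imputed, so scores computed over different gene
#' universes should be compared with care.
#'
#' @param z_matrix Samples-by-genes numeric matrix of Z-scores with
#'   dimnames.
#' @param signature Character vector of signature gene names; at least
#'   one must be present.
#' @return Data frame `sample_id, score, n_genes_used, n_genes_missing`.
#' @export
signature_score <- function(z_matrix, signature) {
  present <- intersect(signature, colnames(z_matrix))
  if (!length(present)) stop_validation("no signature gene present in the matrix")
  sub <- z_matrix[, present, drop = FALSE]
  data.frame(sample_id = rownames(z_matrix) %||% as.character(seq_len(nrow(z_matrix))),
             score = unname(rowSums(sub)),
             n_genes_used = length(present),
             n_genes_missing = length(setdiff(signature, present)),
             stringsAsFactors = FALSE)
}

#' Percentile quartile stratification
#'
#' Ranks samples by a driver value and cuts the ranks at the 25/50/75
#' percentiles: stratum `Qk` contains ranks with
#' `floor(4 * (rank - 1) / n) + 1 == k`, so Q1 is the lowest quartile,
#' strata sizes differ by at most one, and any extra samples fall in the
#' lower strata first (n = 9 gives sizes 3, 2, 2, 2). Ties keep their
#' input order (stable first-occurrence ranks).
#'
#' @param values Numeric driver values, optionally named by sample;
#'   length `>= 8`, not all equal.
#' @return Data frame `sample_id, value, stratum` (factor Q1-Q4) in input
#'   order.
#' @export
quartile_stratify <- function(values) {
  n <- length(values)
  if (n < 8) stop_validation("need >= 8 samples for quartile strata")
  if (length(unique(values)) == 1) stop_validation("no variation in driver values")
  r <- rank(values, ties.method = "first")
  stratum <- floor(4 * (r - 1) / n) + 1
  data.frame(sample_id = names(values) %||% as.character(seq_len(n)),
             value = unname(values),
             stratum = factor(paste0("Q", stratum), levels = paste0("Q", 1:4)),
             stringsAsFactors = FALSE)
}

#' Driver-quartile signature summary
#'
#' Stratifies samples into quartiles of a driver gene's expression and
#' summarizes the signature score per stratum — the tidy table a
#' downstream rank test (e.g. Kruskal-Wallis with post hoc comparisons)
#' consumes.
#'
#' @param z_matrix Samples-by-genes Z-score matrix.
#' @param driver_gene Column used for stratification.
#' @param signature Signature gene names (excluding the driver).
#' @return List with `samples` (per-sample score + stratum) and `summary`
#'   (per-stratum n, mean and median score).
#' @export
quartile_signature <- function(z_matrix, driver_gene, signature) {
  if (!driver_gene %in% colnames(z_matrix)) {
    stop_validation("driver gene not in matrix: ", driver_gene)
  }
  sc <- signature_score(z_matrix, setdiff(signature, driver_gene))
  st <- quartile_stratify(stats::setNames(z_matrix[, driver_gene],
                                          rownames(z_matrix)))
  samples <- merge(sc, st[, c("sample_id", "stratum")], by = "sample_id",
                   sort = FALSE)
  agg <- do.call(rbind, lapply(split(samples$score, samples$stratum), function(v) {
    data.frame(n = length(v), mean_score = mean(v), median_score = stats::median(v))
  }))
  list(samples = samples,
       summary = data.frame(stratum = rownames(agg), agg, row.names = NULL,
                            stringsAsFactors = FALSE))
}

#' Caliper tumor volume
#'
#' `V = L * W^2 / 2` in cubic millimetres; if width exceeds length the
#' two are swapped with a warning (length is the longer dimension by
#' convention).
#'
#' @param length_mm,width_mm Caliper dimensions, mm, `> 0`.
#' @return Volume, cubic mm.
#' @export
tumor_volume_caliper <- function(length_mm, width_mm) {
  if (any(length_mm <= 0) || any(width_mm <= 0)) {
    stop_validation("dimensions must be positive")
  }
  swap <- width_mm > length_mm
  if (any(swap)) {
    warning("width > length for ", sum(swap), " measurement(s); swapping")
    tmp <- length_mm[swap]
    length_mm[swap] <- width_mm[swap]
    width_mm[swap] <- tmp
  }
  length_mm * width_mm^2 / 2
}

#' Endpoint (ellipsoid) tumor volume
#'
#' `V = L * W * H * pi / 6` in cubic millimetres.
#'
#' @param length_mm,width_mm,height_mm Dimensions, mm, `> 0`.
#' @return Volume, cubic mm.
#' @export
tumor_volume_endpoint <- function(length_mm, width_mm, height_mm) {
  if (any(length_mm <= 0) || any(width_mm <= 0) || any(height_mm <= 0)) {
    stop_validation("dimensions must be positive")
  }
  length_mm * width_mm * height_mm * pi / 6
}

#' Confluence-normalized apoptotic index
#'
#' Caspase-positive object count divided by percent confluence,
#' normalized to the baseline (0-hour) index:
#' `(count / confluence) / baseline_index`.
#'
#' @param caspase_positive_count Caspase 3/7-positive cell count, `>= 0`.
#' @param percent_confluence Percent confluence, `> 0`.
#' @param baseline_index Raw index (count/confluence) at 0 h, `> 0`.
#' @return Normalized apoptotic index (1 = baseline level).
#' @export
apoptotic_index <- function(caspase_positive_count, percent_confluence,
                            baseline_index) {
  if (any(percent_confluence <= 0)) stop_validation("confluence must be > 0")
  if (any(baseline_index <= 0)) stop_validation("baseline index must be > 0")
  if (any(caspase_positive_count < 0)) stop_validation("count must be >= 0")
  (caspase_positive_count / percent_confluence) / baseline_index
}
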