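# Single-agent activity: control-anchored normalization, dose-averaged
# viability (AUC), library Z-transform (Z-AUC), cross-model aggregation.

#' Normalize plate signal to percent viability
#'
#' Per plate, viability = 100 * (signal - mean(empty)) /
#' (mean(dmso) - mean(empty)), so DMSO wells average 100 and empty wells
#' 0. Values are not clipped; noise can push them outside `[0, 100]`.
#'
#' @param plate A validated `plate_table` (see [read_plate_table()]).
#' @param clip Clip viability to `[0, 100]` (off by default to preserve
#'   the noise structure the Z statistics assume).
#' @return Data frame `compound_id, dose, viability, plate_id` with one
#'   row per compound well.
#' @export
normalize_viability <- function(plate, clip = FALSE) {
  plate <- validate_plate_table(as.data.frame(plate))
  out <- lapply(split(plate, plate$plate_id), function(sub) {
    m_dmso <- mean(sub$signal[sub$role == "dmso"])
    m_empty <- mean(sub$signal[sub$role == "empty"])
    if (m_dmso <= m_empty) {
      stop_validation("inverted controls on plate ", sub$plate_id[1],
                      ": mean DMSO (", signif(m_dmso, 6),
                      ") <= mean empty (", signif(m_empty, 6), ")")
    }
    cw <- sub[sub$role == "compound", ]
    data.frame(compound_id = cw$compound_id, dose = cw$concentration,
               viability = 100 * (cw$signal - m_empty) / (m_dmso - m_empty),
               plate_id = cw$plate_id, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (clip) out$viability <- pmin(pmax(out$viability, 0), 100)
  out
}

#' Dose-averaged viability (AUC)
#'
#' Trapezoidal integral of viability over log10(dose), divided by the
#' log10 dose range, i.e. the dose-averaged viability: a curve flat at
#' `v`% returns `v`, and lower AUC means higher activity. Duplicate doses
#' are averaged before integration.
#'
#' @param doses Dose vector, nM, `> 0`, at least 2 distinct values.
#' @param responses Percent viability.
#' @param curve Optional `pl4` fit: when supplied, the integral is taken
#'   over the fitted curve evaluated on a fine log-dose grid spanning the
#'   same range instead of the raw points.
#' @return Scalar AUC in percent viability units.
#' @export
compute_auc <- function(doses, responses, curve = NULL) {
  if (length(doses) != length(responses)) {
    stop_validation("doses and responses must have equal length")
  }
  ok <- is.finite(doses) & is.finite(responses) & doses > 0
  doses <- doses[ok]; responses <- responses[ok]
  if (length(unique(doses)) < 2) stop_validation("need >= 2 distinct positive doses")
  if (anyDuplicated(doses)) {
    agg <- tapply(responses, doses, mean)
    doses <- as.numeric(names(agg)); responses <- as.numeric(agg)
  }
  o <- order(doses)
  x <- log10(doses[o]); y <- responses[o]
  if (!is.null(curve)) {
    x <- seq(min(x), max(x), length.out = 201)
    y <- predict(curve, 10^x)
  }
  trapz(x, y) / diff(range(x))
}

#' Z-transform a vector of AUC values
#'
#' Library-wide standardization within one cell model:
#' `z = (auc - mean(auc)) / sd(auc)` with the sample (n-1) standard
#' deviation. Lower Z-AUC means higher activity.
#'
#' @param aucs Numeric vector, length `>= 3`, non-constant.
#' @return Z-AUC vector with mean 0 and sample SD 1.
#' @export
z_transform <- function(aucs) {
  if (length(aucs) < 3) stop_validation("need >= 3 compounds to Z-transform")
  s <- stats::sd(aucs)
  if (!is.finite(s) || s == 0) stop_validation("zero variance: cannot Z-transform")
  (aucs - mean(aucs)) / s
}

#' Per-model activity table from normalized responses
#'
#' Computes per-compound AUC and library Z-AUC within one cell model.
#'
#' @param normalized Output of [normalize_viability()] for one model.
#' @param from_fit Integrate the fitted 4PL instead of the raw points.
#' @return Data frame `compound_id, auc, z_auc`, one row per compound.
#' @export
model_activity <- function(normalized, from_fit = FALSE) {
  sp <- split(normalized, normalized$compound_id)
  auc <- vapply(sp, function(d) {
    curve <- if (from_fit) fit_4pl(d$dose, d$viability) else NULL
    if (!is.null(curve) && (curve$flat || !curve$converged)) curve <- NULL
    compute_auc(d$dose, d$viability, curve = curve)
  }, 0)
  data.frame(compound_id = names(sp), auc = unname(auc),
             z_auc = z_transform(unname(auc)),
             stringsAsFactors = FALSE)
}

#' Aggregate activity across cell models
#'
#' Outer-joins per-model Z-AUC tables, averages Z-AUC over the models in
#' which each compound was screened, and ranks ascending (rank 1 = most
#' active, i.e. lowest mean Z-AUC; ties broken by compound id).
#' Compounds present in no model are dropped with a warning.
#'
#' @param per_model Named list of per-model activity tables
#'   (`compound_id`, `z_auc`), e.g. from [model_activity()].
#' @return Data frame with per-model Z-AUC columns, `n_models`,
#'   `mean_z_auc` and `rank`, sorted by rank.
#' @export
aggregate_activity <- function(per_model) {
  if (!length(per_model)) stop_validation("need >= 1 model")
  if (is.null(names(per_model))) names(per_model) <- paste0("model_", seq_along(per_model))
  tabs <- lapply(names(per_model), function(m) {
    t <- per_model[[m]]
    stats::setNames(t[, c("compound_id", "z_auc")], c("compound_id", paste0("z_auc.", m)))
  })
  merged <- Reduce(function(a, b) merge(a, b, by = "compound_id", all = TRUE), tabs)
  zcols <- grep("^z_auc\\.", names(merged))
  zmat <- as.matrix(merged[, zcols, drop = FALSE])
  n_models <- rowSums(!is.na(zmat))
  if (any(n_models == 0)) {
    warning("dropping ", sum(n_models == 0), " compound(s) present in no model")
    keep <- n_models > 0
    merged <- merged[keep, , drop = FALSE]
    zmat <- zmat[keep, , drop = FALSE]
    n_models <- n_models[keep]
  }
  merged$n_models <- n_models
  merged$mean_z_auc <- rowMeans(zmat, na.rm = TRUE)
  o <- order(merged$mean_z_auc, merged$compound_id)
  merged <- merged[o, , drop = FALSE]
  merged$rank <- seq_len(nrow(merged))
  rownames(merged) <- NULL
  merged
}

#' Full single-agent activity pipeline
#'
#' Normalizes each model's plates, computes per-model AUC/Z-AUC, and
#' aggregates into a cross-model ranked activity table.
#'
#' @param plates Named list (one entry per cell model) of `plate_table`s.
#' @param from_fit Integrate fitted curves rather than raw points.
#' @return The ranked activity table of [aggregate_activity()].
#' @export
single_agent_activity <- function(plates, from_fit = FALSE) {
  per_model <- lapply(plates, function(p) {
    model_activity(normalize_viability(p), from_fit = from_fit)
  })
  aggregate_activity(per_model)
}
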