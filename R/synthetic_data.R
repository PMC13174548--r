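# Seeded generators for plate screens, dose matrices, proteomics replicate
# tables and cohort expression. Each generator is deterministic given its
# seed and attaches a ground-truth sidecar (attribute "truth") so
# downstream recovery tests can compare estimates against the latent model.

#' Latent compound model
#'
#' A compound's latent four-parameter logistic dose-response truth:
#' viability(dose) = bottom + (top - bottom) / (1 + (dose/ec50)^hill),
#' in percent, with dose in nanomolar.
#'
#' @param compound_id Compound identifier.
#' @param top,bottom Plateau viabilities in percent; `0 <= bottom <= top <= 120`.
#' @param ec50 Half-maximal concentration, nM, `> 0`.
#' @param hill Hill slope, in `(0.3, 5]`.
#' @param annotated_target Mechanistic target label (used by drug-set
#'   enrichment truth checks).
#' @param active Logical flag marking the compound as a designed active.
#' @return An object of class `compound_model`.
#' @export
compound_model <- function(compound_id, top = 100, bottom = 100, ec50 = 1000,
                           hill = 1, annotated_target = NA_character_,
                           active = bottom < top) {
  if (!(bottom >= 0 && bottom <= top && top <= 120)) {
    stop_validation("require 0 <= bottom <= top <= 120 for ", compound_id)
  }
  if (!(ec50 > 0)) stop_validation("ec50 must be > 0 for ", compound_id)
  if (!(hill > 0.3 && hill <= 5)) stop_validation("hill must be in (0.3, 5] for ", compound_id)
  structure(list(compound_id = compound_id, top = top, bottom = bottom,
                 ec50 = ec50, hill = hill, annotated_target = annotated_target,
                 active = isTRUE(active)),
            class = "compound_model")
}

#' Latent 4PL viability
#'
#' @param model A [compound_model()].
#' @param dose Dose vector in nM (0 allowed; gives `top`).
#' @return Percent viability.
#' @export
latent_viability <- function(model, dose) {
  model$bottom + (model$top - model$bottom) / (1 + (dose / model$ec50)^model$hill)
}

#' Interaction specification for combination simulation
#'
#' `hsa_null` makes every interior well equal the stronger (lower
#' viability) single agent; `independence` multiplies fractional
#' viabilities; `potency_shift` is the synergy-generating mechanism: in the
#' presence of the partner, each agent acts as if its dose were multiplied
#' by `shift_factor` (dose equivalence), which guarantees responses at or
#' below the HSA reference without encoding the Excess HSA statistic
#' itself. `shift_factor = 1` reduces `potency_shift` to `hsa_null`.
#'
#' @param mode One of `"hsa_null"`, `"independence"`, `"potency_shift"`.
#' @param shift_factor Dose-equivalence factor `>= 1`; only used by
#'   `potency_shift`.
#' @return An `interaction_spec` object.
#' @export
interaction_spec <- function(mode = c("hsa_null", "independence", "potency_shift"),
                             shift_factor = 1) {
  mode <- match.arg(mode)
  if (mode == "potency_shift" && (!is.finite(shift_factor) || shift_factor < 1)) {
    stop_validation("shift_factor must be >= 1")
  }
  structure(list(mode = mode, shift_factor = shift_factor),
            class = "interaction_spec")
}

#' Retrieve a simulator's ground-truth sidecar
#'
#' @param x Any simulator output.
#' @return The truth table attached by the generator (or `NULL`).
#' @export
sim_truth <- function(x) attr(x, "truth", exact = TRUE)

#' Simulate a single-agent qHTS plate screen
#'
#' Emulates an n-point serial-dilution viability screen read out as raw
#' luminescence: each compound is laid out as `n_points` wells at doses
#' `top_dose * dilution^-(0:(n_points-1))`; every plate carries DMSO and
#' empty negative controls plus positive-control wells simulated at the
#' empty-well (fully cytotoxic) level. Compound signal is
#' `empty_mean + (dmso_mean - empty_mean) * viability/100`, viability from
#' the compound's latent 4PL, with multiplicative log-normal noise of
#' coefficient of variation `noise_cv` applied to every well.
#'
#' Defaults mirror an 11-point 1:3 series from 45000 nM down to
#' `45000/3^10 ~ 0.76` nM in 1536-well plates.
#'
#' @param library List of [compound_model()] objects.
#' @param n_points Doses per compound (`>= 2`).
#' @param top_dose Highest dose, nM.
#' @param dilution Serial dilution ratio (`> 1`).
#' @param controls_per_plate Number of DMSO wells and of empty wells per
#'   plate (each).
#' @param noise_cv Multiplicative noise coefficient of variation.
#' @param seed Integer seed; equal seeds give identical tables.
#' @param dmso_mean,empty_mean Mean luminescence of the negative controls.
#' @param wells_per_plate Plate capacity (default 1536).
#' @param n_positive Positive-control wells per plate.
#' @return A `plate_table` with a truth sidecar of the latent parameters.
#' @export
simulate_single_agent_screen <- function(library, n_points = 11,
                                         top_dose = 45000, dilution = 3,
                                         controls_per_plate = 16,
                                         noise_cv = 0.1, seed = 1,
                                         dmso_mean = 5e5, empty_mean = 2.5e4,
                                         wells_per_plate = 1536,
                                         n_positive = 4) {
  if (!length(library)) stop_validation("compound library is empty")
  if (n_points < 2) stop_validation("n_points must be >= 2")
  if (dilution <= 1) stop_validation("dilution must be > 1")
  stopifnot(all(vapply(library, inherits, TRUE, "compound_model")))
  doses <- top_dose * dilution^-(seq_len(n_points) - 1)
  ctrl_wells <- 2 * controls_per_plate + n_positive
  per_plate <- max(1L, (wells_per_plate - ctrl_wells) %/% n_points)
  with_seed(seed, {
    chunks <- split(library, ceiling(seq_along(library) / per_plate))
    out <- vector("list", length(chunks))
    for (ci in seq_along(chunks)) {
      plate_id <- sprintf("plate_%03d", ci)
      chunk <- chunks[[ci]]
      role <- c(rep("dmso", controls_per_plate),
                rep("empty", controls_per_plate),
                rep("positive_control", n_positive),
                rep("compound", n_points * length(chunk)))
      compound_id <- c(rep(NA_character_, ctrl_wells),
                       rep(vapply(chunk, `[[`, "", "compound_id"), each = n_points))
      conc <- c(rep(0, ctrl_wells), rep(doses, length(chunk)))
      v <- unlist(lapply(chunk, latent_viability, dose = doses), use.names = FALSE)
      mu <- c(rep(dmso_mean, controls_per_plate),
              rep(empty_mean, controls_per_plate + n_positive),
              empty_mean + (dmso_mean - empty_mean) * v / 100)
      idx <- seq_along(role)
      df <- data.frame(
        plate_id = plate_id,
        well_id = sprintf("%s%02d", row_label((idx - 1) %/% 48 + 1),
                          (idx - 1) %% 48 + 1),
        row = (idx - 1) %/% 48 + 1,
        col = (idx - 1) %% 48 + 1,
        compound_id = compound_id,
        concentration = conc,
        role = role,
        signal = mu * lognormal_factors(length(mu), noise_cv),
        stringsAsFactors = FALSE)
      out[[ci]] <- df
    }
    plates <- do.call(rbind, out)
    rownames(plates) <- NULL
    truth <- data.frame(
      compound_id = vapply(library, `[[`, "", "compound_id"),
      top = vapply(library, `[[`, 0, "top"),
      bottom = vapply(library, `[[`, 0, "bottom"),
      ec50 = vapply(library, `[[`, 0, "ec50"),
      hill = vapply(library, `[[`, 0, "hill"),
      annotated_target = vapply(library, `[[`, "", "annotated_target"),
      active = vapply(library, `[[`, TRUE, "active"),
      stringsAsFactors = FALSE)
    structure(validate_plate_table(plates), truth = truth, seed = seed)
  })
}

# Row labels A..Z, AA, AB, ... for plates deeper than 26 rows.
row_label <- function(r) {
  ifelse(r <= 26, LETTERS[r],
         paste0(LETTERS[(r - 1) %/% 26], LETTERS[(r - 1) %% 26 + 1]))
}

# Latent combination viability grid for one interaction mode; margins
# always follow the single-agent curves (shift applies only when the
# partner dose is > 0).
latent_combination <- function(a, b, doses_a, doses_b, interaction) {
  sf <- if (interaction$mode == "potency_shift") interaction$shift_factor else 1
  eff_a <- outer(doses_a, ifelse(doses_b > 0, sf, 1))   # dose of A per cell
  eff_b <- outer(ifelse(doses_a > 0, sf, 1), doses_b)   # dose of B per cell
  va <- latent_viability(a, eff_a)
  vb <- latent_viability(b, eff_b)
  if (interaction$mode == "independence") va * vb / 100 else pmin(va, vb)
}

#' Simulate a two-drug dose-matrix combination experiment
#'
#' Margins (zero-dose row/column) follow each compound's latent 4PL; the
#' interior follows the [interaction_spec()]: `hsa_null` gives
#' `min(vA, vB)`, `independence` gives `vA * vB / 100`, and
#' `potency_shift` gives the HSA surface with each agent's dose multiplied
#' by `shift_factor` whenever the partner is present. Multiplicative
#' log-normal noise is applied per well.
#'
#' @param a,b [compound_model()] objects.
#' @param doses_a,doses_b Dose vectors in nM, each containing 0 exactly
#'   once, all other doses positive and distinct.
#' @param interaction An [interaction_spec()].
#' @param noise_cv Noise coefficient of variation.
#' @param seed Integer seed.
#' @param model_id Optional cell-model label.
#' @param time_h Optional time tag, hours.
#' @return A [combination_matrix()] on the viability scale with the
#'   noise-free latent grid as truth sidecar.
#' @export
simulate_combination_matrix <- function(a, b, doses_a, doses_b,
                                        interaction = interaction_spec("hsa_null"),
                                        noise_cv = 0.1, seed = 1,
                                        model_id = NULL, time_h = NULL) {
  check_matrix_doses(doses_a, "doses_a")
  check_matrix_doses(doses_b, "doses_b")
  latent <- latent_combination(a, b, doses_a, doses_b, interaction)
  with_seed(seed, {
    noisy <- latent * matrix(lognormal_factors(length(latent), noise_cv),
                             nrow(latent), ncol(latent))
    m <- combination_matrix(a$compound_id, b$compound_id, doses_a, doses_b,
                            noisy, scale = "viability", model_id = model_id,
                            time_h = time_h)
    attr(m, "truth") <- list(latent = latent, interaction = interaction,
                             a = a, b = b)
    m
  })
}

check_matrix_doses <- function(doses, what) {
  if (sum(doses == 0) != 1) stop_validation(what, " must contain 0 exactly once")
  if (anyDuplicated(doses)) stop_validation("duplicate dose in ", what)
  if (any(doses < 0)) stop_validation(what, " must be non-negative")
}

#' Default 9-point 1:2 dose series around a compound's EC50
#'
#' @param model A [compound_model()].
#' @param n Number of non-zero doses.
#' @param dilution Step ratio.
#' @return Ascending dose vector in nM including 0.
#' @export
default_matrix_doses <- function(model, n = 9, dilution = 2) {
  c(0, sort(model$ec50 * dilution^(seq_len(n) - ceiling(n / 2))))
}

#' Simulate a time-course of combination matrices
#'
#' All drug effects (margins and interaction alike) are scaled by a
#' saturating onset ramp `r(t) = 1 - exp(-(t - onset)/tau)` for
#' `t > onset`, 0 before, applied as
#' `v_t = 100 - r(t) * (100 - v_endpoint)`; the Excess HSA of the ramped
#' matrix is exactly `r(t)` times the endpoint Excess HSA in the
#' noise-free case, so synergy is absent before onset and maximal at the
#' final time point.
#'
#' @inheritParams simulate_combination_matrix
#' @param times Ascending time points, hours.
#' @param onset Hour at which drug effect begins.
#' @param tau Ramp time constant, hours; default spans a third of the
#'   post-onset window.
#' @return List of time-tagged `combination_matrix` objects.
#' @export
simulate_timecourse_matrices <- function(a, b, times = seq(2, 24, by = 2),
                                         onset = 8,
                                         doses_a = default_matrix_doses(a),
                                         doses_b = default_matrix_doses(b),
                                         interaction = interaction_spec("potency_shift", 3),
                                         noise_cv = 0.1, seed = 1,
                                         model_id = NULL, tau = NULL) {
  if (is.unsorted(times, strictly = TRUE)) {
    stop_validation("times must be strictly ascending")
  }
  if (is.null(tau)) tau <- max((max(times) - onset) / 3, 1)
  check_matrix_doses(doses_a, "doses_a")
  check_matrix_doses(doses_b, "doses_b")
  latent_end <- latent_combination(a, b, doses_a, doses_b, interaction)
  with_seed(seed, {
    lapply(seq_along(times), function(k) {
      t <- times[k]
      ramp <- if (t <= onset) 0 else 1 - exp(-(t - onset) / tau)
      latent <- 100 - ramp * (100 - latent_end)
      noisy <- latent * matrix(lognormal_factors(length(latent), noise_cv),
                               nrow(latent), ncol(latent))
      m <- combination_matrix(a$compound_id, b$compound_id, doses_a, doses_b,
                              noisy, scale = "viability",
                              model_id = model_id, time_h = t)
      attr(m, "truth") <- list(latent = latent, ramp = ramp,
                               interaction = interaction)
      m
    })
  })
}

#' Simulate a two-condition replicate proteomics table
#'
#' Per-protein baseline log2 intensities with Gaussian replicate noise;
#' treated replicates of proteins belonging to an affected set are shifted
#' by that set's log2 effect. Protein ids are `P0001 ... Pnnnn`; affected
#' set members must be drawn from that universe.
#'
#' @param n_proteins Universe size.
#' @param n_reps Replicates per arm (`>= 2`).
#' @param affected_sets A [set_collection()] of protein-id sets (may be
#'   empty).
#' @param shifts Named numeric vector of per-set log2 shifts (names
#'   matching `affected_sets`). Overlapping sets must agree on the shift
#'   at every shared protein.
#' @param sigma Replicate log2 intensity standard deviation.
#' @param seed Integer seed.
#' @param baseline_mean,baseline_sd Distribution of per-protein baselines.
#' @return Data frame `protein_id, control_1..n, treated_1..n` with a
#'   truth sidecar of per-protein true shifts.
#' @export
simulate_proteomics <- function(n_proteins = 1000, n_reps = 3,
                                affected_sets = set_collection(list()),
                                shifts = numeric(), sigma = 0.2, seed = 1,
                                baseline_mean = 20, baseline_sd = 2) {
  if (n_reps < 2) stop_validation("n_reps must be >= 2")
  if (length(affected_sets) && !setequal(names(affected_sets), names(shifts))) {
    stop_validation("shifts must be named to match affected_sets")
  }
  if (any(!is.finite(shifts))) stop_validation("shifts must be finite")
  universe <- sprintf("P%04d", seq_len(n_proteins))
  true_shift <- stats::setNames(rep(0, n_proteins), universe)
  assigned <- stats::setNames(rep(NA_character_, n_proteins), universe)
  for (nm in names(affected_sets)) {
    members <- affected_sets[[nm]]
    if (!all(members %in% universe)) {
      stop_validation("set ", nm, " has members outside the protein universe")
    }
    clash <- members[!is.na(assigned[members]) & true_shift[members] != shifts[[nm]]]
    if (length(clash)) {
      stop_validation("conflicting shifts for protein(s) ",
                      paste(utils::head(clash, 3), collapse = ", "),
                      " between sets ", assigned[clash[1]], " and ", nm)
    }
    true_shift[members] <- shifts[[nm]]
    assigned[members] <- nm
  }
  with_seed(seed, {
    baseline <- stats::rnorm(n_proteins, baseline_mean, baseline_sd)
    ctrl <- baseline + matrix(stats::rnorm(n_proteins * n_reps, 0, sigma),
                              n_proteins, n_reps)
    trt <- baseline + true_shift +
      matrix(stats::rnorm(n_proteins * n_reps, 0, sigma), n_proteins, n_reps)
    df <- data.frame(protein_id = universe, ctrl, trt, stringsAsFactors = FALSE)
    names(df) <- c("protein_id", sprintf("control_%d", seq_len(n_reps)),
                   sprintf("treated_%d", seq_len(n_reps)))
    structure(df,
              truth = data.frame(protein_id = universe, true_shift = true_shift,
                                 affected_set = assigned, row.names = NULL,
                                 stringsAsFactors = FALSE),
              seed = seed)
  })
}

#' Simulate a cohort expression Z-score matrix
#'
#' One driver gene is standard normal across samples; each signature gene
#' is `coupling * driver + sqrt(1 - coupling^2) * noise` (so its marginal
#' stays standard normal and its correlation with the driver equals
#' `coupling`); background genes are independent standard normal.
#'
#' @param n_samples Number of samples (`>= 8` so quartiles are usable).
#' @param driver_gene Driver gene name.
#' @param signature_genes Character vector of signature gene names
#'   (must exclude the driver).
#' @param coupling Driver-signature correlation in `[0, 1]`.
#' @param n_background Independent background genes.
#' @param seed Integer seed.
#' @return Samples-by-genes numeric matrix of Z scores.
#' @export
simulate_cohort <- function(n_samples = 400, driver_gene = "XPO1",
                            signature_genes = sprintf("SIG%02d", 1:59),
                            coupling = 0.5, n_background = 100, seed = 1) {
  if (n_samples < 8) stop_validation("n_samples must be >= 8")
  if (coupling < 0 || coupling > 1) stop_validation("coupling must be in [0, 1]")
  if (driver_gene %in% signature_genes) {
    stop_validation("signature_genes must exclude the driver gene")
  }
  with_seed(seed, {
    driver <- stats::rnorm(n_samples)
    sig <- coupling * driver +
      sqrt(1 - coupling^2) * matrix(stats::rnorm(n_samples * length(signature_genes)),
                                    n_samples, length(signature_genes))
    bg <- matrix(stats::rnorm(n_samples * n_background), n_samples, n_background)
    z <- cbind(driver, sig, bg)
    dimnames(z) <- list(sprintf("S%04d", seq_len(n_samples)),
                        c(driver_gene, signature_genes,
                          sprintf("BG%03d", seq_len(n_background))))
    structure(z, truth = list(driver_gene = driver_gene,
                              signature_genes = signature_genes,
                              coupling = coupling), seed = seed)
  })
}

#' Simulate a correlated two-model screen
#'
#' Generates one compound library screened in two cell models whose latent
#' per-compound activities correlate at `rho`: activity_m =
#' `sqrt(rho) * shared + sqrt(1-rho) * model-specific`. Activity drives
#' both depth of kill (the 4PL bottom plateau, affinely, clamped to
#' `[0, 100]`) and potency (`log10 EC50`, affinely, clamped one decade
#' inside the tested range), so more active compounds are both more
#' potent and more cytotoxic. Because the dose-averaged viability (AUC)
#' is close to affine in both drivers over these ranges, the
#' between-model Pearson correlation of AUC profiles recovers `rho` up to
#' mild plate-noise attenuation (a few percent at `noise_cv = 0.1`).
#'
#' @param n_compounds Library size.
#' @param rho Latent between-model activity correlation.
#' @param models Two model labels.
#' @param noise_cv Plate noise coefficient of variation.
#' @param seed Integer seed.
#' @param n_points,top_dose,dilution Dose-series design.
#' @param controls_per_plate DMSO/empty control wells per plate.
#' @return List with `plates` (named list of `plate_table` per model),
#'   `truth` (per-compound latent activities) and `rho`.
#' @export
simulate_two_model_screen <- function(n_compounds = 200, rho = 0.72,
                                      models = c("LNCaP95", "VCaPCR"),
                                      noise_cv = 0.1, seed = 1,
                                      n_points = 11, top_dose = 45000,
                                      dilution = 3, controls_per_plate = 48) {
  if (length(models) != 2) stop_validation("exactly two models required")
  if (rho < 0 || rho > 1) stop_validation("rho must be in [0, 1]")
  lowest <- top_dose * dilution^-(n_points - 1)
  mid <- sqrt(top_dose * lowest)   # geometric mid of the tested range
  with_seed(seed, {
    shared <- stats::rnorm(n_compounds)
    act <- sapply(models, function(m) {
      sqrt(rho) * shared + sqrt(1 - rho) * stats::rnorm(n_compounds)
    })
    seeds <- sample.int(.Machine$integer.max, 2)
    ids <- sprintf("cmpd_%04d", seq_len(n_compounds))
    plates <- lapply(1:2, function(k) {
      bottoms <- pmin(pmax(50 - 18 * act[, k], 0), 100)
      ec50 <- pmin(pmax(10^(log10(mid) - 0.55 * act[, k]),
                        lowest * dilution), top_dose / dilution)
      lib <- lapply(seq_len(n_compounds), function(i) {
        compound_model(ids[i], top = 100, bottom = bottoms[i],
                       ec50 = ec50[i], hill = 1)
      })
      simulate_single_agent_screen(lib, n_points = n_points,
                                   top_dose = top_dose, dilution = dilution,
                                   controls_per_plate = controls_per_plate,
                                   noise_cv = noise_cv, seed = seeds[k])
    })
    names(plates) <- models
    truth <- data.frame(compound_id = ids, stringsAsFactors = FALSE)
    truth[[paste0("activity_", models[1])]] <- act[, 1]
    truth[[paste0("activity_", models[2])]] <- act[, 2]
    list(plates = plates, truth = truth, rho = rho)
  })
}
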