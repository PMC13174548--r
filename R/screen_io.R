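# Readers/writers for the tabular formats the pipeline touches: long-format
# plate tables, GMT set files, long-format dose-matrix tables, run
# configuration, and generic results CSV output.

PLATE_COLUMNS <- c("plate_id", "well_id", "row", "col", "compound_id",
                   "concentration", "role", "signal")
PLATE_ROLES <- c("compound", "dmso", "empty", "positive_control")

#' Read a long-format plate table
#'
#' Reads per-well screening data from a CSV with columns `plate_id`,
#' `well_id`, `row`, `col`, `compound_id`, `concentration`, `role` and
#' `signal`, validates it, and returns a `plate_table` data frame.
#' Concentrations are stored in nanomolar; set `unit = "uM"` (or supply a
#' `concentration_unit` column with values `"nM"`/`"uM"`) when the file is
#' recorded in micromolar. Roles are canonicalized by trimming whitespace
#' and lower-casing, so `"DMSO "` parses as `dmso`; `positive` is accepted
#' as a synonym for `positive_control`.
#'
#' @param path Path to a CSV file.
#' @param unit File-wide concentration unit, `"nM"` (default) or `"uM"`,
#'   used when no `concentration_unit` column is present.
#' @return A data frame of class `plate_table`, row order preserved, with
#'   concentrations in nanomolar.
#' @export
read_plate_table <- function(path, unit = c("nM", "uM")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop_schema("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(PLATE_COLUMNS, names(df))
  if (length(missing)) {
    stop_schema("plate table is missing required column(s): ",
                paste(missing, collapse = ", "))
  }
  if ("concentration_unit" %in% names(df)) {
    u <- tolower(trimws(df$concentration_unit))
    bad <- setdiff(unique(u), c("nm", "um"))
    if (length(bad)) stop_schema("unknown concentration_unit value(s): ",
                                 paste(bad, collapse = ", "))
    df$concentration <- df$concentration * ifelse(u == "um", 1000, 1)
    df$concentration_unit <- NULL
  } else if (unit == "uM") {
    df$concentration <- df$concentration * 1000
  }
  df$role <- canonical_role(df$role)
  df$compound_id[!is.na(df$compound_id) & trimws(df$compound_id) == ""] <- NA_character_
  validate_plate_table(df)
}

canonical_role <- function(role) {
  r <- tolower(trimws(as.character(role)))
  r[r == "positive"] <- "positive_control"
  bad <- setdiff(unique(r), PLATE_ROLES)
  if (length(bad)) {
    stop_schema("unknown role value(s): ", paste(bad, collapse = ", "),
                "; expected one of ", paste(PLATE_ROLES, collapse = ", "))
  }
  r
}

#' Validate a plate table
#'
#' Checks the invariants a downstream normalization step relies on: unique
#' (plate, well) keys, non-negative signals, at least two DMSO and two
#' empty wells per plate, and compound wells carrying a compound id and a
#' positive dose.
#'
#' @param df A data frame with the plate-table columns.
#' @return The validated data frame, classed `plate_table`.
#' @export
validate_plate_table <- function(df) {
  neg <- which(!is.finite(df$signal) | df$signal < 0)
  if (length(neg)) {
    w <- df[neg[1], ]
    stop_validation("non-finite or negative signal at plate ", w$plate_id,
                    " well ", w$well_id)
  }
  key <- paste(df$plate_id, df$well_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ][1, ]
    stop_validation("duplicate well: plate ", d$plate_id, " well ", d$well_id)
  }
  cmp <- df$role == "compound"
  if (any(cmp & (is.na(df$compound_id) | is.na(df$concentration) |
                 df$concentration <= 0))) {
    bad <- df[cmp & (is.na(df$compound_id) | is.na(df$concentration) |
                     df$concentration <= 0), ][1, ]
    stop_validation("compound well without compound_id or positive dose: plate ",
                    bad$plate_id, " well ", bad$well_id)
  }
  for (p in unique(df$plate_id)) {
    sub <- df[df$plate_id == p, ]
    if (sum(sub$role == "dmso") < 2 || sum(sub$role == "empty") < 2) {
      stop_validation("plate ", p, " needs >= 2 dmso and >= 2 empty wells")
    }
  }
  class(df) <- c("plate_table", "data.frame")
  df
}

#' Read a GMT set file
#'
#' Parses the tab-separated GMT dialect (set name, description, then member
#' ids) into a named list of character vectors with a parallel
#' `description` attribute. Duplicate members within a set are collapsed.
#' An empty file yields an empty collection with a warning.
#'
#' @param path Path to a GMT file.
#' @return A `set_collection`: named list of unique member vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_schema("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(set_collection(list()))
  }
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop_schema("GMT parse error at line ", i, ": fewer than 3 fields")
    }
    nm <- f[1]
    if (nm %in% names(sets)) stop_schema("duplicate set name at line ", i, ": ", nm)
    members <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (!length(members)) stop_schema("GMT parse error at line ", i, ": empty set")
    sets[[nm]] <- members
    desc[nm] <- f[2]
  }
  set_collection(sets, desc)
}

#' Construct a set collection
#'
#' @param sets Named list of character member vectors (members are
#'   de-duplicated).
#' @param description Optional named character vector of descriptions.
#' @return A `set_collection` object.
#' @export
set_collection <- function(sets, description = NULL) {
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)) || any(!nzchar(names(sets)))) {
      stop_validation("set names must be present and unique")
    }
    sets <- lapply(sets, function(m) unique(as.character(m)))
    if (any(lengths(sets) == 0)) stop_validation("sets must be non-empty")
  }
  structure(sets, description = description, class = c("set_collection", "list"))
}

#' @export
print.set_collection <- function(x, ...) {
  cat("Set collection with", length(x), "set(s)\n")
  for (nm in utils::head(names(x), 10)) {
    cat(sprintf("  %s (%d members)\n", nm, length(x[[nm]])))
  }
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Write a results table to CSV
#'
#' Writes any pipeline results data frame to CSV with full numeric
#' precision (15 significant digits), so a write/read round trip is
#' value-preserving well beyond 12 significant digits.
#'
#' @param table A data frame; empty tables are refused unless
#'   `allow_empty = TRUE` (a header-only file is then written).
#' @param path Output file path; the parent directory must exist.
#' @param allow_empty Permit writing a zero-row table.
#' @export
write_results <- function(table, path, allow_empty = FALSE) {
  if (!is.data.frame(table)) stop_validation("table must be a data frame")
  if (nrow(table) == 0 && !allow_empty) {
    stop_validation("refusing to write an empty table (use allow_empty = TRUE)")
  }
  if (!dir.exists(dirname(path))) {
    stop(errorCondition(paste0("cannot write ", path, ": directory does not exist"),
                        class = c("synscreen_io_error", "error")))
  }
  utils::write.csv(format_full_precision(table), path, row.names = FALSE,
                   quote = TRUE, na = "")
  invisible(path)
}

format_full_precision <- function(df) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- sprintf("%.15g", df[[j]])
      v[is.na(df[[j]])] <- NA
      df[[j]] <- v
    }
  }
  df
}

#' Read a results CSV written by [write_results()]
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop_schema("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write combination matrices in long format
#'
#' Serializes a list of [combination_matrix()] objects to one long CSV with
#' columns `drug_a, drug_b, model_id, time_h, dose_a_nM, dose_b_nM,
#' response, scale` — one row per well, zero-dose margins included.
#'
#' @param matrices A `combination_matrix` or list of them.
#' @param path Output CSV path.
#' @export
write_combination_matrices <- function(matrices, path) {
  if (inherits(matrices, "combination_matrix")) matrices <- list(matrices)
  rows <- lapply(matrices, function(m) {
    g <- expand.grid(i = seq_along(m$doses_a), j = seq_along(m$doses_b))
    data.frame(drug_a = m$drug_a, drug_b = m$drug_b,
               model_id = m$model_id %||% NA_character_,
               time_h = m$time_h %||% NA_real_,
               dose_a_nM = m$doses_a[g$i], dose_b_nM = m$doses_b[g$j],
               response = m$response[cbind(g$i, g$j)], scale = m$scale,
               stringsAsFactors = FALSE)
  })
  write_results(do.call(rbind, rows), path)
}

#' Read long-format combination matrices
#'
#' Inverse of [write_combination_matrices()]: groups rows by
#' (drug_a, drug_b, model_id, time_h) and rebuilds validated
#' [combination_matrix()] objects.
#'
#' @param path CSV path with the long matrix schema.
#' @return A list of `combination_matrix` objects.
#' @export
read_combination_matrices <- function(path) {
  df <- read_results(path)
  need <- c("drug_a", "drug_b", "dose_a_nM", "dose_b_nM", "response", "scale")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_schema("matrix table is missing required column(s): ",
                paste(missing, collapse = ", "))
  }
  if (is.null(df$model_id)) df$model_id <- NA_character_
  if (is.null(df$time_h)) df$time_h <- NA_real_
  key <- paste(df$drug_a, df$drug_b, df$model_id, df$time_h, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(sub) {
    da <- sort(unique(sub$dose_a_nM))
    db <- sort(unique(sub$dose_b_nM))
    resp <- matrix(NA_real_, length(da), length(db))
    resp[cbind(match(sub$dose_a_nM, da), match(sub$dose_b_nM, db))] <- sub$response
    combination_matrix(
      drug_a = sub$drug_a[1], drug_b = sub$drug_b[1],
      doses_a = da, doses_b = db, response = resp,
      scale = sub$scale[1],
      model_id = if (is.na(sub$model_id[1])) NULL else sub$model_id[1],
      time_h = if (is.na(sub$time_h[1])) NULL else sub$time_h[1])
  })
}

#' Read a run configuration file
#'
#' Loads a YAML key-value file of run settings and fills in documented
#' defaults: `seed` (1), `noise_cv` (0.1), `hit_threshold` (-2000),
#' `n_permutations` (1000), `log2fc_cut` (0.5), `p_cut` (0.05),
#' `linkage` ("average"), `out_dir` ("."). Unknown keys are rejected so
#' typos fail loudly.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(seed = 1L, noise_cv = 0.1, hit_threshold = -2000,
                   n_permutations = 1000L, log2fc_cut = 0.5, p_cut = 0.05,
                   linkage = "average", out_dir = ".")
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop_schema("config file not found: ", path)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown)) {
      stop_schema("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(user)] <- user
  }
  num <- c("seed", "noise_cv", "hit_threshold", "n_permutations",
           "log2fc_cut", "p_cut")
  if (!all(vapply(cfg[num], function(v) is.numeric(v) && is.finite(v), TRUE))) {
    stop_validation("all numeric config values must be finite")
  }
  structure(cfg, class = c("run_config", "list"))
}
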