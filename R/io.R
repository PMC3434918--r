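#' Read a plant-level fitness table
#'
#' Reads a comma-separated table with one row per plant and the fixed header
#' `plant_id, medicago_genotype, rhizobium_mix, soil_treatment, replicate,
#' nodule_count, fruit_count` (an optional logical `contamination` column is
#' accepted).  Categorical labels are kept verbatim (case-sensitive, no
#' coercion); counts must be non-negative integers.  Uninoculated plants
#' (`rhizobium_mix == "control"`) must have `nodule_count == 0` unless their
#' `contamination` flag is set, mirroring the check of control roots for
#' nodules in the greenhouse.
#'
#' @param path path to a CSV file with a mandatory header.
#' @param verbose print the inferred categorical levels (default `TRUE` in
#'   interactive use).
#'
#' @return A validated `data.frame` of plant records (character labels,
#'   integer counts), with the inferred levels attached as attribute
#'   `"levels"`.
#' @seealso [write_plant_table()], [check_balance()]
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_plant_table(simulate_experiment(sim_params(seed = 1)), p)
#' dat <- read_plant_table(p, verbose = FALSE)
#' nrow(dat)
#' @export
read_plant_table <- function(path, verbose = interactive()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  missing <- setdiff(.plant_columns, names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (nrow(raw) == 0L) {
    warning("empty table (header only): returning 0 records")
    out <- raw[, union(.plant_columns, intersect("contamination", names(raw))),
               drop = FALSE]
    for (col in c("replicate", "nodule_count", "fruit_count"))
      out[[col]] <- integer(0)
    return(validate_records(out))
  }
  out <- raw[, union(.plant_columns, intersect("contamination", names(raw))),
             drop = FALSE]
  for (col in c("replicate", "nodule_count", "fruit_count")) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v) | v != round(v) | (col != "replicate" & v < 0))
    if (length(bad))
      stop(sprintf("column '%s': invalid count '%s' at data row %d (must be a nonnegative integer)",
                   col, raw[[col]][bad[1]], bad[1]))
    out[[col]] <- as.integer(v)
  }
  if ("contamination" %in% names(out))
    out$contamination <- toupper(out$contamination) %in% c("TRUE", "T", "1", "YES")
  out <- validate_records(out)
  if (verbose) {
    lv <- attr(out, "levels")
    message(sprintf("read %d records; genotypes: %s; mixes: %s; soils: %s",
                    nrow(out),
                    paste(lv$medicago_genotype, collapse = ", "),
                    paste(lv$rhizobium_mix, collapse = ", "),
                    paste(lv$soil_treatment, collapse = ", ")))
  }
  out
}

# internal: enforce the PlantRecord invariants on any data.frame
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(.plant_columns, names(records))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  for (col in c("replicate", "nodule_count", "fruit_count")) {
    v <- records[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != round(v)))
      stop(sprintf("column '%s' must hold integers", col))
    if (col != "replicate" && any(v < 0))
      stop(sprintf("column '%s' must be nonnegative", col))
    records[[col]] <- as.integer(v)
  }
  key <- do.call(paste, c(records[c("medicago_genotype", "rhizobium_mix",
                                    "soil_treatment", "replicate")],
                          sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (genotype, mix, soil, replicate) combination at row ",
         which(duplicated(key))[1])
  contam <- if ("contamination" %in% names(records)) records$contamination else
    rep(FALSE, nrow(records))
  bad <- records$rhizobium_mix == .control_mix & records$nodule_count > 0 & !contam
  if (any(bad))
    stop("uninoculated control plant(s) with nodules but no contamination flag: ",
         paste(records$plant_id[bad], collapse = ", "))
  attr(records, "levels") <- list(
    medicago_genotype = sort(unique(records$medicago_genotype)),
    rhizobium_mix = sort(unique(records$rhizobium_mix)),
    soil_treatment = sort(unique(records$soil_treatment)))
  records
}

#' Write a plant-level table to CSV
#'
#' Inverse of [read_plant_table()]: counts are written as integers and labels
#' verbatim, so `read_plant_table(write_plant_table(x, p))` round-trips
#' exactly.
#'
#' @param records validated plant records.
#' @param path output path.
#' @param force overwrite an existing file (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_plant_table <- function(records, path, force = FALSE) {
  records <- validate_records(records)
  refuse_overwrite(path, force)
  cols <- intersect(c(.plant_columns, "contamination"), names(records))
  write.csv(as.data.frame(records)[, cols, drop = FALSE], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

refuse_overwrite <- function(path, force) {
  if (file.exists(path) && !force)
    stop("refusing to overwrite existing file (use force = TRUE): ", path,
         call. = FALSE)
  invisible(TRUE)
}

#' Write analysis result tables
#'
#' Writes ANOVA tables (columns `source, df, ss, f, p`, one file per
#' response) and the correlation table (columns `environment, n, r_G, se_rG,
#' r_E, se_rE`) as CSV at full precision, plus a machine-readable JSON report
#' bundling both with their diagnostics.
#'
#' @param anovas a list of [fitness_anova()] results (possibly empty).
#' @param correlations a `correlation_table` from [estimate_correlations()],
#'   or `NULL`.
#' @param dir output directory (created if needed).
#' @param force overwrite existing files.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(anovas = list(), correlations = NULL, dir = ".",
                          force = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (a in anovas) {
    stopifnot(inherits(a, "fitness_anova"))
    path <- file.path(dir, sprintf("anova_%s.csv", attr(a, "response_label")))
    refuse_overwrite(path, force)
    write.csv(as.data.frame(a), path, row.names = FALSE, quote = FALSE)
    written <- c(written, path)
  }
  path <- file.path(dir, "correlations.csv")
  refuse_overwrite(path, force)
  ctab <- if (is.null(correlations)) {
    data.frame(environment = character(0), n = integer(0),
               r_G = numeric(0), se_rG = numeric(0),
               r_E = numeric(0), se_rE = numeric(0))
  } else as.data.frame(correlations)
  write.csv(format(ctab, digits = 15, trim = TRUE), path,
            row.names = FALSE, quote = FALSE)
  written <- c(written, path)

  jpath <- file.path(dir, "report.json")
  refuse_overwrite(jpath, force)
  report <- list(
    anova = lapply(anovas, function(a)
      list(response = attr(a, "response_label"),
           r_squared = attr(a, "r_squared"),
           table = as.data.frame(a))),
    correlations = if (is.null(correlations)) NULL else
      lapply(unclass(correlations), correlation_report))
  jsonlite::write_json(report, jpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(written, jpath))
}

# internal: one CorrelationResult as a plain list for JSON
correlation_report <- function(cr) {
  list(environment = cr$environment, n = cr$n,
       r_G = cr$r_G, se_rG = cr$se_rG, r_E = cr$r_E, se_rE = cr$se_rE,
       jackknife_replicates = cr$jackknife_replicates,
       diagnostics = cr$diagnostics)
}
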