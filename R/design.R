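#' Describe the factorial design of an experiment
#'
#' A design specification records the intended dimensions of a balanced
#' genotype x rhizobium-mix x soil factorial: `g = n_genotypes * n_mixes`
#' host-genotype x mix associations per soil environment, each replicated
#' `k` times, optionally with an uninoculated control series (one pseudo-mix
#' level crossed with every genotype and soil).
#'
#' @param n_genotypes number of host plant genotypes (default 6).
#' @param n_mixes number of rhizobium inocula (default 2), excluding the
#'   uninoculated control.
#' @param include_control logical; does the design carry uninoculated
#'   control plants (default `TRUE`)?
#' @param n_soils number of soil environments (default 2).
#' @param k replicates per cell (default 5).
#'
#' @return An object of class `"design_spec"`: a list with the five
#'   arguments plus `g`, the number of associations per environment.
#' @examples
#' design_spec()          # the default 6 x 2 (+control) x 2 x 5 layout
#' design_spec(k = 3)$g   # g depends only on genotypes and mixes
#' @export
design_spec <- function(n_genotypes = 6L, n_mixes = 2L, include_control = TRUE,
                        n_soils = 2L, k = 5L) {
  dims <- c(n_genotypes = n_genotypes, n_mixes = n_mixes,
            n_soils = n_soils, k = k)
  if (any(dims < 1) || any(dims != round(dims)))
    stop("all design dimensions must be positive integers")
  structure(list(n_genotypes = as.integer(n_genotypes),
                 n_mixes = as.integer(n_mixes),
                 include_control = isTRUE(include_control),
                 n_soils = as.integer(n_soils),
                 k = as.integer(k),
                 g = as.integer(n_genotypes) * as.integer(n_mixes)),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(
    "Factorial design: %d genotypes x %d mixes%s x %d soils, k = %d (g = %d associations/environment)\n",
    x$n_genotypes, x$n_mixes,
    if (x$include_control) " (+ control)" else "",
    x$n_soils, x$k, x$g))
  invisible(x)
}

#' Check that a plant-level table is balanced
#'
#' Verifies that every (genotype, mix, soil) cell present in `records` holds
#' the same number of replicates.  The method-of-moments estimator downstream
#' is only defined for balanced data, so [crossproducts_manova()] and
#' [fitness_anova()] refuse tables for which this check fails.
#'
#' If a [design_spec()] is supplied the observed dimensions and replicate
#' count are additionally compared against the intended ones; otherwise `k`
#' is inferred as the (unique) per-cell count.
#'
#' @param records a plant-level `data.frame` as returned by
#'   [read_plant_table()] or [simulate_experiment()].
#' @param design optional [design_spec()] to compare against.
#'
#' @return An object of class `"balance_report"`: a list with elements
#'   `balanced` (logical), `k` (inferred replicates per cell, `NA` when
#'   unbalanced), `g` (associations per environment among inoculated plants),
#'   `n_records`, `cell_counts` (a data.frame of per-cell counts) and
#'   `offending` (the subset of cells that break balance).  The report never
#'   throws; consumers that require balance do.
#' @examples
#' dat <- simulate_experiment(sim_params(seed = 1))
#' check_balance(dat)
#' check_balance(dat[-1, ])   # one plant lost: no longer balanced
#' @export
check_balance <- function(records, design = NULL) {
  records <- validate_records(records)
  counts <- aggregate(list(n = records$plant_id),
                      by = list(medicago_genotype = records$medicago_genotype,
                                rhizobium_mix = records$rhizobium_mix,
                                soil_treatment = records$soil_treatment),
                      FUN = length)
  counts <- counts[order(counts$soil_treatment, counts$rhizobium_mix,
                         counts$medicago_genotype), , drop = FALSE]
  rownames(counts) <- NULL
  k_obs <- unique(counts$n)
  balanced <- length(k_obs) == 1L && nrow(records) > 0L
  k <- if (balanced) as.integer(k_obs) else NA_integer_
  inoculated <- counts[counts$rhizobium_mix != .control_mix, , drop = FALSE]
  g_per_env <- if (nrow(inoculated)) {
    tab <- table(inoculated$soil_treatment)
    if (length(unique(as.integer(tab))) == 1L) as.integer(tab[1]) else NA_integer_
  } else 0L
  offending <- counts[counts$n != stats::median(counts$n), , drop = FALSE]
  if (balanced) offending <- counts[0, , drop = FALSE]

  if (!is.null(design)) {
    stopifnot(inherits(design, "design_spec"))
    expected_cells <- design$n_genotypes *
      (design$n_mixes + design$include_control) * design$n_soils
    balanced <- balanced && nrow(counts) == expected_cells && k == design$k
  }
  structure(list(balanced = balanced, k = k, g = g_per_env,
                 n_records = nrow(records), cell_counts = counts,
                 offending = offending),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  if (x$balanced) {
    cat(sprintf("Balanced: %d records, g = %d associations/environment, k = %d replicates/cell\n",
                x$n_records, x$g, x$k))
  } else {
    cat(sprintf("NOT balanced (%d records). Offending cells:\n", x$n_records))
    print(x$offending)
  }
  invisible(x)
}

# internal: refuse unbalanced input with an informative message
require_balance <- function(records, what) {
  rep <- check_balance(records)
  if (!rep$balanced) {
    cells <- apply(rep$offending[, 1:3, drop = FALSE], 1L, paste, collapse = "/")
    stop(sprintf("%s requires a balanced design; offending cells: %s",
                 what, paste(cells, collapse = ", ")), call. = FALSE)
  }
  rep
}
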