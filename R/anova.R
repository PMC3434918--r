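#' Log-transform fruit counts
#'
#' The plant-fitness response is analysed on the log scale, `ln(fruit)`.
#' Uninoculated plants can set zero fruit, so the default policy uses
#' `ln(y + 1)`; the `"strict"` policy applies `ln(y)` and errors on zeros,
#' naming the offending plant.
#'
#' @param x a plant-level `data.frame` (column `fruit_count` is used and
#'   `plant_id` names offenders) or a numeric vector of counts.
#' @param offset_policy `"plus_one"` (default) or `"strict"`.
#' @return Numeric vector of transformed values.
#' @examples
#' ln_fruit(c(0, 1, 20))                       # ln(y + 1)
#' ln_fruit(c(1, 20), offset_policy = "strict") # ln(y)
#' @export
ln_fruit <- function(x, offset_policy = c("plus_one", "strict")) {
  offset_policy <- match.arg(offset_policy)
  y <- if (is.data.frame(x)) x$fruit_count else x
  if (any(y < 0)) stop("fruit counts must be nonnegative")
  if (offset_policy == "strict") {
    if (any(y == 0)) {
      who <- if (is.data.frame(x)) paste(x$plant_id[y == 0], collapse = ", ")
             else paste(which(y == 0), collapse = ", ")
      stop("strict ln transform undefined for zero fruit count (", who, ")")
    }
    log(y)
  } else {
    log(y + 1)
  }
}

# internal: pick the analysis response off a record table
response_values <- function(records, response, offset_policy = "plus_one") {
  switch(response,
         nodules = as.numeric(records$nodule_count),
         ln_fruit = ln_fruit(records, offset_policy),
         stop("unknown response: ", response))
}

#' Three-way fixed-effects ANOVA of a fitness component
#'
#' Fits the balanced crossed model `y ~ M + R + ST + M:ST + M:R + R:ST +
#' M:R:ST` with *Medicago* genotype (M), rhizobium mix (R) and soil
#' treatment (ST) as fixed factors, for either fitness component.  By
#' default uninoculated control plants are excluded (R has its inoculated
#' levels only); with `include_control = TRUE` the control series enters as
#' a third rhizobium level, the mode under which a soil main effect on
#' fruit set becomes detectable.
#'
#' On balanced data sequential and marginal sums of squares coincide, and
#' the factor and error SS add up to the total corrected SS; both identities
#' are relied on downstream and checked in the test-suite.
#'
#' @param records plant-level records.
#' @param response `"nodules"` or `"ln_fruit"`.
#' @param include_control include uninoculated plants as a rhizobium level?
#' @param offset_policy passed to [ln_fruit()].
#'
#' @return An object of class `"fitness_anova"`: a `data.frame` with columns
#'   `source, df, ss, f, p` (error row last, `f`/`p` `NA` there) and
#'   attributes `r_squared` and `response_label`.
#' @examples
#' dat <- simulate_experiment(sim_params(seed = 1))
#' fitness_anova(dat, "nodules")
#' @export
fitness_anova <- function(records, response = c("nodules", "ln_fruit"),
                          include_control = FALSE,
                          offset_policy = c("plus_one", "strict")) {
  response <- match.arg(response)
  offset_policy <- match.arg(offset_policy)
  records <- validate_records(records)
  if (!include_control)
    records <- records[records$rhizobium_mix != .control_mix, , drop = FALSE]
  require_balance(records, "fitness_anova")
  dat <- data.frame(
    y = response_values(records, response, offset_policy),
    M = factor(records$medicago_genotype),
    R = factor(records$rhizobium_mix),
    ST = factor(records$soil_treatment))
  n_cells <- nlevels(dat$M) * nlevels(dat$R) * nlevels(dat$ST)
  if (nrow(dat) - n_cells < 1L)
    stop("zero error degrees of freedom: need at least 2 replicates per cell")
  fit <- lm(y ~ M + R + ST + M:ST + M:R + R:ST + M:R:ST, data = dat)
  # a perfect fit is handled below as an explicit undefined-F error
  tab <- suppressWarnings(anova(fit))
  if (tab["Residuals", "Sum Sq"] <= .Machine$double.eps * sum(tab[["Sum Sq"]]) ||
      sum(tab[["Sum Sq"]]) == 0)
    stop("F statistics undefined: residual sum of squares is zero")
  labels <- c(M = "Medicago genotype (M)", R = "Rhizobium mix (R)",
              ST = "Soil treatment (ST)", `M:ST` = "M x ST", `M:R` = "M x R",
              `R:ST` = "R x ST", `M:R:ST` = "M x R x ST",
              Residuals = "Error")
  out <- data.frame(source = unname(labels[rownames(tab)]),
                    df = tab$Df, ss = tab$`Sum Sq`,
                    f = tab$`F value`, p = tab$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  ss_total <- sum(out$ss)
  structure(out,
            r_squared = 1 - out$ss[out$source == "Error"] / ss_total,
            response_label = response,
            n = nrow(dat),
            class = c("fitness_anova", "data.frame"))
}

#' @export
print.fitness_anova <- function(x, ...) {
  cat(sprintf("Three-way ANOVA of %s (N = %d, R^2 = %.2f)\n",
              attr(x, "response_label"), attr(x, "n"), attr(x, "r_squared")))
  y <- x
  y$ss <- signif(y$ss, 3)
  y$f <- ifelse(is.na(y$f), NA, signif(y$f, 3))
  y$p <- ifelse(is.na(y$p), NA, signif(y$p, 2))
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Post-hoc home/away contrast on plant-level responses
#'
#' Two-sample t test (pooled variance by default, Welch optionally)
#' comparing a fitness response between the two levels of `split_factor`,
#' restricted to a named subset of plant genotypes — e.g. nodule counts of
#' the thyme-sympatric `NA*` genotypes with their home (`"b"`) versus naive
#' (`"g"`) rhizobium mix.
#'
#' @param records plant-level records (uninoculated plants are dropped).
#' @param genotypes character vector of genotype labels to keep.
#' @param split_factor `"rhizobium_mix"` or `"soil_treatment"`.
#' @param response `"nodules"` or `"ln_fruit"`.
#' @param welch use the Welch (unequal-variance) t instead of pooled.
#' @param offset_policy passed to [ln_fruit()].
#'
#' @return An object of class `"fitness_contrast"`: a list with `label`,
#'   `t`, `df`, `p` (two-sided), `group_means` and `group_n`.
#' @examples
#' dat <- simulate_experiment(sim_params(seed = 1))
#' home_away_contrast(dat, c("NA1021", "NA216", "NA632"))
#' @export
home_away_contrast <- function(records, genotypes,
                               split_factor = c("rhizobium_mix", "soil_treatment"),
                               response = c("nodules", "ln_fruit"),
                               welch = FALSE,
                               offset_policy = c("plus_one", "strict")) {
  split_factor <- match.arg(split_factor)
  response <- match.arg(response)
  offset_policy <- match.arg(offset_policy)
  records <- validate_records(records)
  records <- records[records$rhizobium_mix != .control_mix &
                       records$medicago_genotype %in% genotypes, , drop = FALSE]
  lev <- sort(unique(records[[split_factor]]))
  if (length(lev) != 2L)
    stop("contrast needs exactly two levels of ", split_factor,
         "; found: ", paste(lev, collapse = ", "))
  y <- response_values(records, response, offset_policy)
  grp <- records[[split_factor]]
  if (any(table(grp) < 2L))
    stop("insufficient data: need at least 2 observations per group")
  tt <- t.test(y[grp == lev[1]], y[grp == lev[2]], var.equal = !welch)
  structure(list(label = sprintf("%s: %s vs %s (%s)", split_factor,
                                 lev[1], lev[2], response),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value,
                 group_means = setNames(as.numeric(tt$estimate), lev),
                 group_n = as.integer(table(grp)[lev])),
            class = "fitness_contrast")
}

#' @export
print.fitness_contrast <- function(x, ...) {
  cat(sprintf("%s\n  t = %.3f, df = %.4g, P = %.3g; means %s = %.3g (n=%d), %s = %.3g (n=%d)\n",
              x$label, x$t, x$df, x$p,
              names(x$group_means)[1], x$group_means[1], x$group_n[1],
              names(x$group_means)[2], x$group_means[2], x$group_n[2]))
  invisible(x)
}
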