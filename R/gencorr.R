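#' Between- and within-group sums of cross-products
#'
#' Low-level one-way MANOVA decomposition: for a bivariate response matrix
#' `Y` grouped into g groups of equal size k, computes the between-group
#' ("main effect") matrix \eqn{H = k \sum_i (\bar y_i - \bar y)(\bar y_i -
#' \bar y)'} and the residual matrix \eqn{E = \sum_{ij} (y_{ij} - \bar
#' y_i)(y_{ij} - \bar y_i)'}.  By construction `H + E` equals the total
#' corrected cross-product matrix.
#'
#' @param Y numeric matrix with one row per observation and 2 columns
#'   (trait order `(nodule_count, ln_fruit)` throughout the package).
#' @param groups grouping vector, one entry per row of `Y`.
#'
#' @return An object of class `"crossproducts"`: a list with `H`, `E`, `g`,
#'   `k`, `group_means` (g x 2), `group_labels` and `trait_labels`.
#' @seealso [crossproducts_manova()] for the record-level interface.
#' @export
sscp_matrices <- function(Y, groups) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (ncol(Y) != 2L) stop("Y must have exactly 2 trait columns")
  groups <- as.character(groups)
  if (length(groups) != nrow(Y)) stop("groups must match rows of Y")
  sizes <- table(groups)
  if (length(unique(as.integer(sizes))) != 1L)
    stop("unbalanced groups: all groups must have the same size; counts: ",
         paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "))
  g <- length(sizes)
  k <- as.integer(sizes[1])
  if (g < 2L) stop("degenerate design: need g >= 2 groups to estimate Cov_G")
  if (k < 2L) stop("degenerate design: need k >= 2 replicates to estimate Cov_E")
  m <- rowsum(Y, groups) / k                 # group means, sorted by label
  centred_means <- sweep(m, 2L, colMeans(Y))
  H <- k * crossprod(centred_means)
  resid <- Y - m[groups, , drop = FALSE]
  E <- crossprod(resid)
  dimnames(H) <- dimnames(E) <- list(.trait_labels, .trait_labels)
  structure(list(H = H, E = E, g = g, k = k,
                 group_means = m, group_labels = rownames(m),
                 trait_labels = .trait_labels),
            class = "crossproducts")
}

#' @export
print.crossproducts <- function(x, ...) {
  cat(sprintf("One-way MANOVA cross-products: g = %d groups, k = %d replicates\nH (between):\n",
              x$g, x$k))
  print(signif(x$H, 5))
  cat("E (residual):\n")
  print(signif(x$E, 5))
  invisible(x)
}

#' MANOVA cross-products over M x R associations in one environment
#'
#' Treats each host-genotype x rhizobium-mix association as one level of a
#' single grouping factor and decomposes the joint (nodule count, ln fruit)
#' response into between-association (`H`) and residual (`E`) cross-product
#' matrices.  Records must come from a single soil environment with
#' uninoculated plants already excluded, and the associations must be
#' balanced.
#'
#' @param records plant-level records from one environment, inoculated only.
#' @param offset_policy passed to [ln_fruit()].
#' @return A `"crossproducts"` object (see [sscp_matrices()]).
#' @examples
#' dat <- simulate_experiment(sim_params(seed = 1))
#' carv <- subset(dat, soil_treatment == "carvacrol" & rhizobium_mix != "control")
#' crossproducts_manova(carv)
#' @export
crossproducts_manova <- function(records, offset_policy = c("plus_one", "strict")) {
  offset_policy <- match.arg(offset_policy)
  records <- validate_records(records)
  if (length(unique(records$soil_treatment)) != 1L)
    stop("records span more than one soil environment; analyse one at a time")
  if (any(records$rhizobium_mix == .control_mix))
    stop("uninoculated control plants must be excluded before the MANOVA")
  Y <- cbind(as.numeric(records$nodule_count), ln_fruit(records, offset_policy))
  groups <- paste(records$medicago_genotype, records$rhizobium_mix, sep = ":")
  sscp_matrices(Y, groups)
}

#' Method-of-moments genetic and environmental covariance matrices
#'
#' Under the balanced one-way random-effects model the expected mean
#' cross-products are \eqn{E[E/(g(k-1))] = Cov_E} and \eqn{E[H/(g-1)] =
#' Cov_E + k\,Cov_G}, so the method-of-moments estimates are
#' \deqn{\widehat{Cov}_E = E / (g(k-1)), \qquad
#'       \widehat{Cov}_G = (H/(g-1) - \widehat{Cov}_E) / k.}
#' A diagonal entry of \eqn{\widehat{Cov}_G} can come out nonpositive; it is
#' flagged, never clamped, and [cov_to_cor()] then reports the correlation
#' as undefined.
#'
#' @param cp a `"crossproducts"` object.
#' @return An object of class `"cov_estimates"`: a list with `cov_G`,
#'   `cov_E`, `g`, `k` and `negative_variance_flags` (logical per trait,
#'   `TRUE` when the genetic variance estimate is nonpositive).
#' @examples
#' g <- 12; k <- 5
#' A <- matrix(c(1, .5, .5, 1), 2); B <- diag(2)
#' cp <- structure(list(H = (g - 1) * (k * A + B), E = g * (k - 1) * B,
#'                      g = g, k = k, trait_labels = c("t1", "t2")),
#'                 class = "crossproducts")
#' mom_covariances(cp)$cov_G   # recovers A exactly
#' @export
mom_covariances <- function(cp) {
  stopifnot(inherits(cp, "crossproducts"))
  cov_E <- cp$E / (cp$g * (cp$k - 1))
  cov_G <- (cp$H / (cp$g - 1) - cov_E) / cp$k
  flags <- diag(cov_G) <= 0
  names(flags) <- cp$trait_labels
  structure(list(cov_G = cov_G, cov_E = cov_E, g = cp$g, k = cp$k,
                 negative_variance_flags = flags),
            class = "cov_estimates")
}

#' @export
print.cov_estimates <- function(x, ...) {
  cat(sprintf("Method-of-moments covariance estimates (g = %d, k = %d)\nCov_G:\n", x$g, x$k))
  print(signif(x$cov_G, 4))
  cat("Cov_E:\n")
  print(signif(x$cov_E, 4))
  if (any(x$negative_variance_flags))
    cat("note: nonpositive genetic variance for ",
        paste(names(which(x$negative_variance_flags)), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Correlation from a 2x2 covariance matrix
#'
#' Returns the off-diagonal element divided by the square root of the
#' product of the diagonal.  When either diagonal entry is nonpositive (as
#' can happen for a method-of-moments `cov_G`) the correlation is undefined:
#' the function returns `NA` with the reason attached as attribute
#' `"reason"`, and never throws, so jackknife loops can proceed.
#'
#' @param m a 2x2 symmetric matrix.
#' @return A numeric scalar, `NA` with a `"reason"` attribute when undefined.
#' @examples
#' cov_to_cor(matrix(c(4, 2, 2, 4), 2))    # 0.5
#' cov_to_cor(matrix(c(-0.1, 0.3, 0.3, 2), 2))  # undefined
#' @export
cov_to_cor <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == 2L))
  d <- diag(m)
  if (any(d <= 0)) {
    traits <- colnames(m)
    if (is.null(traits)) traits <- paste("trait", 1:2)
    return(structure(NA_real_,
                     reason = paste0("nonpositive variance for ",
                                     paste(traits[d <= 0], collapse = " and "))))
  }
  unname(m[1, 2] / sqrt(prod(d)))
}

# internal: one statistic from (Y, groups); NA (with reason) when undefined
.statistic_from_groups <- function(Y, groups, statistic) {
  est <- mom_covariances(sscp_matrices(Y, groups))
  cov_to_cor(if (statistic == "r_G") est$cov_G else est$cov_E)
}

#' Delete-one-association jackknife standard error
#'
#' Recomputes the chosen correlation with each association left out in turn
#' (the full pipeline each time: cross-products, method-of-moments,
#' correlation) and returns the all-data point estimate together with the
#' delete-one-group jackknife standard error
#' \deqn{SE = \sqrt{\frac{g-1}{g} \sum_i (\theta_{(i)} - \bar\theta_{(\cdot)})^2}.}
#' Leave-one-out replicates that are undefined (nonpositive genetic
#' variance) are dropped from the sum, with `g` adjusted and the count
#' recorded; `na_action = "error"` makes that situation fatal instead.
#'
#' @param records plant-level records from one environment, inoculated only.
#' @param statistic `"r_G"` (default) or `"r_E"`.
#' @param offset_policy passed to [ln_fruit()].
#' @param na_action `"drop"` (default) or `"error"` for undefined replicates.
#' @return A list with `estimate` (all-data statistic, possibly `NA` with a
#'   reason), `se`, `replicates` (named vector of the g leave-one-out
#'   estimates, `NA` where undefined) and `n_dropped`.
#' @examples
#' dat <- simulate_experiment(sim_params(seed = 1))
#' carv <- subset(dat, soil_treatment == "carvacrol" & rhizobium_mix != "control")
#' jackknife_se(carv, "r_G")$se
#' @export
jackknife_se <- function(records, statistic = c("r_G", "r_E"),
                         offset_policy = c("plus_one", "strict"),
                         na_action = c("drop", "error")) {
  statistic <- match.arg(statistic)
  offset_policy <- match.arg(offset_policy)
  na_action <- match.arg(na_action)
  records <- validate_records(records)
  Y <- cbind(as.numeric(records$nodule_count), ln_fruit(records, offset_policy))
  groups <- paste(records$medicago_genotype, records$rhizobium_mix, sep = ":")
  jackknife_se_groups(Y, groups, statistic, na_action)
}

# internal fast path shared with estimate_environment
jackknife_se_groups <- function(Y, groups, statistic, na_action = "drop") {
  labels <- sort(unique(groups))
  g <- length(labels)
  if (g < 3L) stop("jackknife needs at least 3 associations")
  estimate <- .statistic_from_groups(Y, groups, statistic)
  reps <- vapply(labels, function(lab) {
    keep <- groups != lab
    as.numeric(.statistic_from_groups(Y[keep, , drop = FALSE], groups[keep],
                                      statistic))
  }, numeric(1))
  defined <- !is.na(reps)
  if (!all(defined) && na_action == "error")
    stop("undefined jackknife replicate(s) for association(s): ",
         paste(labels[!defined], collapse = ", "))
  m <- sum(defined)
  se <- if (m >= 2L) {
    th <- reps[defined]
    sqrt((m - 1) / m * sum((th - mean(th))^2))
  } else NA_real_
  list(estimate = estimate, se = se, replicates = reps,
       n_dropped = g - m)
}

#' Per-association genotypic means
#'
#' The joint genotypic-value estimates for each host-genotype x mix
#' association in one environment: the bivariate mean of (nodule count,
#' ln fruit) over its k replicates.
#'
#' @param records plant-level records from one environment, inoculated only.
#' @param offset_policy passed to [ln_fruit()].
#' @return A `data.frame` of class `"genotypic_means"` with columns
#'   `association, medicago_genotype, rhizobium_mix, mean_nodules,
#'   mean_ln_fruit, n`.
#' @export
genotypic_means <- function(records, offset_policy = c("plus_one", "strict")) {
  offset_policy <- match.arg(offset_policy)
  records <- validate_records(records)
  if (nrow(records) == 0L) stop("no records")
  if (any(records$rhizobium_mix == .control_mix))
    stop("uninoculated control plants must be excluded")
  df <- data.frame(
    medicago_genotype = records$medicago_genotype,
    rhizobium_mix = records$rhizobium_mix,
    nodules = as.numeric(records$nodule_count),
    lnf = ln_fruit(records, offset_policy))
  agg <- aggregate(df[c("nodules", "lnf")],
                   by = df[c("medicago_genotype", "rhizobium_mix")],
                   FUN = mean)
  names(agg)[names(agg) == "nodules"] <- "mean_nodules"
  names(agg)[names(agg) == "lnf"] <- "mean_ln_fruit"
  cnt <- aggregate(list(n = df$nodules),
                   by = df[c("medicago_genotype", "rhizobium_mix")],
                   FUN = length)
  agg <- merge(agg, cnt, by = c("medicago_genotype", "rhizobium_mix"))
  agg$n <- as.integer(agg$n)
  agg$association <- paste(agg$medicago_genotype, agg$rhizobium_mix, sep = ":")
  agg <- agg[order(agg$association),
             c("association", "medicago_genotype", "rhizobium_mix",
               "mean_nodules", "mean_ln_fruit", "n")]
  rownames(agg) <- NULL
  class(agg) <- c("genotypic_means", "data.frame")
  agg
}

#' Major-axis fit through bivariate genotypic means
#'
#' First principal axis of the 2x2 covariance matrix of the points, through
#' their centroid — the symmetric line-fitting used to display the joint
#' genotypic values of the two fitness components.
#'
#' @param points a two-column matrix/data.frame of (x, y) coordinates, or a
#'   [genotypic_means()] table (its `mean_nodules`, `mean_ln_fruit` columns
#'   are used, in that order).
#' @return A list with `slope`, `intercept`, `centroid` and `eigenvalues`.
#'   Errors when all points coincide or the point cloud is isotropic (equal
#'   eigenvalues: the major axis is not identified).
#' @examples
#' major_axis_fit(cbind(1:5, 2 * (1:5) + 1))  # slope 2, intercept 1
#' @export
major_axis_fit <- function(points) {
  if (inherits(points, "genotypic_means"))
    points <- points[, c("mean_nodules", "mean_ln_fruit")]
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 2L || nrow(pts) < 2L)
    stop("need at least 2 bivariate points")
  S <- cov(pts)
  if (all(abs(S) < .Machine$double.eps * 100))
    stop("degenerate: all points identical")
  ei <- eigen(S, symmetric = TRUE)
  if ((ei$values[1] - ei$values[2]) <= 1e-10 * ei$values[1])
    stop("major axis not identified: point cloud is isotropic (equal eigenvalues)")
  v <- ei$vectors[, 1]
  slope <- v[2] / v[1]
  centroid <- colMeans(pts)
  list(slope = slope, intercept = unname(centroid[2] - slope * centroid[1]),
       centroid = centroid, eigenvalues = ei$values)
}

#' Estimate r_G and r_E in one environment
#'
#' Composes the full per-environment pipeline: restrict to one soil
#' treatment, drop uninoculated plants, form the one-way MANOVA
#' cross-products over the M x R associations, invert to method-of-moments
#' `Cov_G`/`Cov_E`, take the broad-sense genetic and environmental
#' correlations, and attach delete-one-association jackknife standard
#' errors for both.
#'
#' @param records plant-level records (may span several environments).
#' @param environment soil-treatment label to analyse; may be omitted when
#'   `records` already holds a single environment.
#' @param offset_policy passed to [ln_fruit()].
#' @return An object of class `"correlation_result"`: a list with
#'   `environment`, `n` (number of associations g), `r_G`, `se_rG`, `r_E`,
#'   `se_rE`, `jackknife_replicates` (list with `r_G` and `r_E` vectors),
#'   `cov_estimates` and `diagnostics` (negative-variance and out-of-range
#'   flags, dropped-replicate counts, undefined reasons).
#' @examples
#' dat <- simulate_experiment(sim_params(seed = 1))
#' estimate_environment(dat, "carvacrol")
#' @export
estimate_environment <- function(records, environment = NULL,
                                 offset_policy = c("plus_one", "strict")) {
  offset_policy <- match.arg(offset_policy)
  records <- validate_records(records)
  if (!is.null(environment)) {
    records <- records[records$soil_treatment == environment, , drop = FALSE]
    if (nrow(records) == 0L) stop("no records for environment: ", environment)
  } else {
    environment <- unique(records$soil_treatment)
    if (length(environment) != 1L)
      stop("records span several environments; name one")
  }
  records <- records[records$rhizobium_mix != .control_mix, , drop = FALSE]
  Y <- cbind(as.numeric(records$nodule_count), ln_fruit(records, offset_policy))
  groups <- paste(records$medicago_genotype, records$rhizobium_mix, sep = ":")
  est <- mom_covariances(sscp_matrices(Y, groups))
  r_G <- cov_to_cor(est$cov_G)
  r_E <- cov_to_cor(est$cov_E)
  jk_G <- jackknife_se_groups(Y, groups, "r_G")
  jk_E <- jackknife_se_groups(Y, groups, "r_E")
  diagnostics <- list(
    negative_variance_flags = est$negative_variance_flags,
    r_G_undefined_reason = attr(r_G, "reason"),
    r_G_out_of_range = isTRUE(abs(as.numeric(r_G)) > 1),
    jackknife_dropped = c(r_G = jk_G$n_dropped, r_E = jk_E$n_dropped))
  structure(list(environment = environment, n = est$g,
                 r_G = as.numeric(r_G), se_rG = jk_G$se,
                 r_E = as.numeric(r_E), se_rE = jk_E$se,
                 jackknife_replicates = list(r_G = jk_G$replicates,
                                             r_E = jk_E$replicates),
                 cov_estimates = est, diagnostics = diagnostics),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s: n = %d associations; r_G = %s (SE %s); r_E = %.2f (SE %.2f)\n",
              x$environment, x$n,
              if (is.na(x$r_G)) "undefined" else sprintf("%.2f", x$r_G),
              if (is.na(x$se_rG)) "NA" else sprintf("%.2f", x$se_rG),
              x$r_E, x$se_rE))
  if (any(x$diagnostics$negative_variance_flags))
    cat("  note: nonpositive genetic variance flagged\n")
  if (any(x$diagnostics$jackknife_dropped > 0))
    cat(sprintf("  note: %d (r_G) / %d (r_E) undefined jackknife replicates dropped\n",
                x$diagnostics$jackknife_dropped["r_G"],
                x$diagnostics$jackknife_dropped["r_E"]))
  invisible(x)
}

#' Estimate r_G and r_E in every environment of a table
#'
#' Applies [estimate_environment()] to each soil-treatment level and
#' collects the rows of the resulting correlation table.
#'
#' @inheritParams estimate_environment
#' @return An object of class `"correlation_table"`: a list of
#'   `"correlation_result"`s, one per environment, with an
#'   `as.data.frame()` method giving columns `environment, n, r_G, se_rG,
#'   r_E, se_rE`.
#' @examples
#' dat <- simulate_experiment(sim_params(seed = 1))
#' as.data.frame(estimate_correlations(dat))
#' @export
estimate_correlations <- function(records, offset_policy = c("plus_one", "strict")) {
  offset_policy <- match.arg(offset_policy)
  records <- validate_records(records)
  envs <- sort(unique(records$soil_treatment))
  out <- lapply(envs, function(e)
    estimate_environment(records, e, offset_policy))
  names(out) <- envs
  class(out) <- "correlation_table"
  out
}

#' @export
as.data.frame.correlation_table <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), function(cr)
    data.frame(environment = cr$environment, n = cr$n,
               r_G = cr$r_G, se_rG = cr$se_rG,
               r_E = cr$r_E, se_rE = cr$se_rE,
               stringsAsFactors = FALSE)))
}

#' @export
print.correlation_table <- function(x, ...) {
  cat("Broad-sense genetic and environmental correlations by environment\n")
  df <- as.data.frame(x)
  df[, 3:6] <- signif(df[, 3:6], 2)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
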