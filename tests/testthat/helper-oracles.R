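# Independent oracles used by the tests.  These deliberately avoid the code
# paths under test: the factorial SS oracle works from marginal cell means
# (no lm/aov), and the covariance oracle goes through stats::cov on group
# means rather than the package's cross-product matrices.

# Balanced factorial sums of squares from marginal means (Moebius over
# factor subsets).  y: response; f: data.frame of factors.  Returns a named
# vector with one SS per term plus error and total.
oracle_factorial_ss <- function(y, f) {
  facs <- names(f)
  subsets <- unlist(lapply(seq_along(facs), function(m)
    utils::combn(facs, m, simplify = FALSE)), recursive = FALSE)
  gm <- mean(y)
  eff <- list()
  ss <- numeric(0)
  for (S in subsets) {
    key <- paste(S, collapse = ":")
    cellmean <- do.call(stats::ave, c(list(y), unname(f[S]), list(FUN = mean)))
    e <- cellmean - gm
    for (Tk in names(eff)) {
      Tset <- strsplit(Tk, ":", fixed = TRUE)[[1]]
      if (all(Tset %in% S) && length(Tset) < length(S)) e <- e - eff[[Tk]]
    }
    eff[[key]] <- e
    ss[key] <- sum(e^2)
  }
  fitted <- gm + Reduce(`+`, eff)
  c(ss, error = sum((y - fitted)^2), total = sum((y - gm)^2))
}

# Brute-force path to the genetic covariance: sample covariance of the
# group means minus Cov_E/k, with Cov_E the pooled within-group covariance.
oracle_cov_G <- function(Y, groups) {
  Y <- as.matrix(Y)
  labs <- sort(unique(groups))
  k <- sum(groups == labs[1])
  means <- t(vapply(labs, function(l) colMeans(Y[groups == l, , drop = FALSE]),
                    numeric(2)))
  within <- lapply(labs, function(l) {
    sub <- Y[groups == l, , drop = FALSE]
    stats::cov(sub) * (nrow(sub) - 1)
  })
  cov_E <- Reduce(`+`, within) / (length(labs) * (k - 1))
  stats::cov(means) - cov_E / k
}

# A small balanced plant table built from explicit per-cell counts.
# nod, fruit: vectors recycled over the replicate-within-cell grid.
toy_records <- function(genotypes = c("A", "B"), mixes = c("b", "g"),
                        soils = "control", k = 2, nod = NULL, fruit = NULL,
                        seed = 1) {
  grid <- expand.grid(replicate = seq_len(k),
                      medicago_genotype = genotypes,
                      rhizobium_mix = mixes,
                      soil_treatment = soils,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  set.seed(seed)
  if (is.null(nod)) nod <- rpois(n, 50)
  if (is.null(fruit)) fruit <- rpois(n, 12)
  data.frame(plant_id = sprintf("T%03d", seq_len(n)),
             medicago_genotype = grid$medicago_genotype,
             rhizobium_mix = grid$rhizobium_mix,
             soil_treatment = grid$soil_treatment,
             replicate = grid$replicate,
             nodule_count = as.integer(rep_len(nod, n)),
             fruit_count = as.integer(rep_len(fruit, n)),
             stringsAsFactors = FALSE)
}
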