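# Gene-positioning zoning assays and the composite statistical procedure
# for comparing radial chromatin profiles: per-bin permutation tests,
# Bonferroni adjustment and combined-probability region statistics, plus
# the chi-squared comparison used for zoning count data.

#' Equal-area zone boundaries of the nuclear disc
#'
#' Radii partitioning a disc of radius `R` into three concentric zones of
#' equal area: `r1 = R sqrt(2/3)` (outer boundary) and `r2 = R sqrt(1/3)`
#' (inner boundary). Zone 1 is the most peripheral ring, zone 3 the
#' central disc.
#'
#' @param nucleus_radius disc radius `R` (> 0).
#' @return named vector `c(r1 = ..., r2 = ...)`.
#' @export
zone_boundaries <- function(nucleus_radius) {
  if (nucleus_radius <= 0)
    cr_error("nucleus radius must be positive", "invalid_parameter")
  c(r1 = nucleus_radius * sqrt(2 / 3), r2 = nucleus_radius * sqrt(1 / 3))
}

#' Assign a spot to one of three equal-area concentric zones
#'
#' Zone 1 = most peripheral, zone 3 = most internal; a spot exactly on a
#' boundary goes to the more peripheral zone.
#'
#' @param r radial position(s) of the spot(s) in the disc plane.
#' @param nucleus_radius disc radius.
#' @return integer zone index (1, 2 or 3); vectorized over `r`.
#' @export
assign_zone <- function(r, nucleus_radius) {
  if (any(r < 0) || any(r > nucleus_radius))
    cr_error("spot outside the nuclear disc", "outside_disc")
  b <- unname(zone_boundaries(nucleus_radius))
  as.integer(ifelse(r >= b[1], 1L, ifelse(r >= b[2], 2L, 3L)))
}

#' Assign a spot to a decile bin between nucleolus edge and periphery
#'
#' The relative nucleolus-edge-to-nuclear-periphery position in `[0, 1]`
#' is mapped to bins `[0, 0.1) -> 0`, ..., `[0.9, 1] -> 9` (bin 0 closest
#' to the nucleolus edge, bin 9 closest to the periphery). Spots inside
#' the nucleolus (negative relative position) return `NA` and are flagged
#' via a warning rather than binned.
#'
#' @param relative_position numeric in `[0, 1]` (vectorized).
#' @return integer bin 0..9 (or `NA` for inside-nucleolus spots).
#' @export
assign_decile <- function(relative_position) {
  if (any(relative_position > 1, na.rm = TRUE))
    cr_error("relative position above 1", "invalid_parameter")
  inside <- relative_position < 0
  if (any(inside, na.rm = TRUE))
    warning(sum(inside, na.rm = TRUE),
            " spot(s) inside the nucleolus; flagged NA, not binned")
  out <- pmin(floor(relative_position * 10), 9L)
  out[inside] <- NA_integer_
  as.integer(out)
}

#' Relative nucleolus-edge to periphery position of a spot
#'
#' Projects the spot's distance from the nucleolus centre onto the
#' edge-to-periphery span of its radial direction.
#'
#' @param spot_dist distance of the spot from the nucleolus centre.
#' @param edge_dist nucleolus-centre-to-edge distance along the spot's
#'   direction.
#' @param periphery_dist nucleolus-centre-to-periphery distance along the
#'   same direction.
#' @return relative position (negative = inside nucleolus); vectorized.
#' @export
relative_edge_position <- function(spot_dist, edge_dist, periphery_dist) {
  if (any(periphery_dist <= edge_dist))
    cr_error("periphery must lie beyond the nucleolus edge",
             "invalid_parameter")
  (spot_dist - edge_dist) / (periphery_dist - edge_dist)
}

#' Pearson chi-squared comparison of two zone-count vectors
#'
#' Standard Pearson chi-squared test on the 2 x k contingency table of
#' two count vectors (no continuity correction), df = k - 1.
#'
#' @param a,b integer count vectors of equal length (same zone/bin
#'   structure).
#' @return list with `statistic`, `df`, `p_value`, and the underlying
#'   `htest`.
#' @export
chi_squared_zones <- function(a, b) {
  if (length(a) != length(b))
    cr_error("count vectors differ in length", "invalid_input")
  tab <- rbind(a, b)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0))
    cr_error("zero expected count; merge sparse categories first",
             "zero_expected")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, htest = ht)
}

profiles_to_matrix <- function(profiles) {
  if (inherits(profiles, "binned_profile")) profiles <- list(profiles)
  if (is.matrix(profiles)) return(profiles)
  do.call(rbind, lapply(profiles, function(p)
    if (inherits(p, "binned_profile")) p$intensity else as.numeric(p)))
}

#' Per-bin permutation test between two groups of radial profiles
#'
#' For each bin the statistic is the absolute difference of group means.
#' Nucleus-level condition labels are permuted `n_perm` times (seeded)
#' and the p-value is the add-one estimator
#' `(1 + #permuted >= observed) / (1 + n_perm)`, two-sided by
#' construction. With `exact = TRUE` all distinct label assignments are
#' enumerated instead and the p-value is the exact proportion of
#' assignments (including the observed one) whose statistic is at least
#' the observed.
#'
#' @param group_A,group_B lists of `binned_profile`s (or numeric
#'   matrices, nuclei in rows), each with >= 2 profiles.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @param exact enumerate all `choose(nA + nB, nA)` assignments.
#' @return numeric vector of raw p-values, one per bin, with attribute
#'   `observed` (the per-bin observed statistics).
#' @export
permutation_bin_test <- function(group_A, group_B, n_perm = 10000,
                                 seed = 1, exact = FALSE) {
  A <- profiles_to_matrix(group_A)
  B <- profiles_to_matrix(group_B)
  if (nrow(A) < 2L || nrow(B) < 2L)
    cr_error("each group needs at least 2 profiles", "invalid_input")
  if (ncol(A) != ncol(B)) cr_error("bin count mismatch", "invalid_input")
  if (!exact && n_perm < 99) cr_error("n_perm must be >= 99", "invalid_input")
  nA <- nrow(A); n <- nA + nrow(B)
  pool <- rbind(A, B)
  obs <- abs(colMeans(A) - colMeans(B))
  tot <- colSums(pool)
  stat_for <- function(idx_A) {
    mA <- colSums(pool[idx_A, , drop = FALSE]) / nA
    mB <- (tot - mA * nA) / (n - nA)
    abs(mA - mB)
  }
  if (exact) {
    combs <- utils::combn(n, nA)
    stats_mat <- apply(combs, 2, stat_for)  # bins x assignments
    p <- rowMeans(stats_mat >= obs - 1e-12)
  } else {
    count <- numeric(ncol(pool))
    with_local_seed(seed, {
      for (i in seq_len(n_perm)) {
        count <- count + (stat_for(sample.int(n, nA)) >= obs - 1e-12)
      }
    })
    p <- (1 + count) / (1 + n_perm)
  }
  attr(p, "observed") <- obs
  p
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` for each p-value; `m` defaults to the number of radial
#' bins tested (20).
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param m number of tests.
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = 20) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    cr_error("p-values must lie in [0, 1]", "invalid_parameter")
  pmin(1, m * p)
}

#' Combine p-values within a region
#'
#' Default (`method = "fisher"`): chi-squared statistic `-2 sum(log p)`
#' referred to the upper tail of a chi-squared distribution with `2k`
#' degrees of freedom. The selectable `"pearson"` variant uses
#' `-2 sum(log(1 - p))` referred to the lower tail. Both reduce to the
#' identity for a single p-value. Zero p-values are clamped to
#' `1/(n_perm + 1)` with a warning.
#'
#' @param p adjusted p-values of one region (>= 1 value).
#' @param method `"fisher"` (default) or `"pearson"`.
#' @param n_perm permutation count used to clamp zero p-values.
#' @return combined p-value with attribute `method`.
#' @export
combine_region <- function(p, method = c("fisher", "pearson"),
                           n_perm = 10000) {
  method <- match.arg(method)
  if (length(p) < 1L) cr_error("no p-values to combine", "invalid_input")
  if (any(p < 0 | p > 1)) cr_error("p-values must lie in [0, 1]",
                                   "invalid_parameter")
  if (any(p == 0)) {
    warning("zero p-value clamped to 1/(n_perm + 1)")
    p[p == 0] <- 1 / (n_perm + 1)
  }
  k <- length(p)
  out <- if (method == "fisher") {
    stats::pchisq(-2 * sum(log(p)), df = 2 * k, lower.tail = FALSE)
  } else {
    one <- 1 - p
    one[one == 0] <- 1 / (n_perm + 1)
    stats::pchisq(-2 * sum(log(one)), df = 2 * k, lower.tail = TRUE)
  }
  attr(out, "method") <- method
  out
}

region_bins <- function(centers = seq(2.5, 97.5, by = 5)) {
  list("0-30%" = which(centers >= 0 & centers <= 30),
       "35-65%" = which(centers >= 35 & centers <= 65),
       "70-100%" = which(centers >= 70 & centers <= 100))
}

#' Full profile-comparison pipeline between two conditions
#'
#' Per-bin permutation p-values, Bonferroni adjustment (`m = 20` by
#' default), then combined-probability p-values over the three regions
#' 0-30%, 35-65% and 70-100% of the centre-to-contour distance. The bins
#' centred at 32.5% and 67.5% fall in the gaps between regions and enter
#' no region.
#'
#' @inheritParams permutation_bin_test
#' @param m Bonferroni multiplier (default 20 bins).
#' @param combine_method `"fisher"` or `"pearson"`, see
#'   [combine_region()].
#' @return object of class `profile_comparison`: `p_raw`, `p_adjusted`
#'   (length 20), `region_p` (length 3, named), `regions`, `n_perm`,
#'   `seed`, `combine_method`.
#' @export
compare_condition_profiles <- function(group_A, group_B, n_perm = 10000,
                                       seed = 1, m = 20,
                                       combine_method = c("fisher", "pearson"),
                                       exact = FALSE) {
  combine_method <- match.arg(combine_method)
  p_raw <- permutation_bin_test(group_A, group_B, n_perm = n_perm,
                                seed = seed, exact = exact)
  p_adj <- bonferroni_adjust(as.numeric(p_raw), m = m)
  regs <- region_bins()
  region_p <- vapply(regs, function(idx)
    as.numeric(combine_region(p_adj[idx], method = combine_method,
                              n_perm = n_perm)), numeric(1))
  structure(list(p_raw = as.numeric(p_raw), p_adjusted = p_adj,
                 observed = attr(p_raw, "observed"),
                 region_p = region_p, regions = regs,
                 n_perm = n_perm, seed = seed,
                 combine_method = combine_method),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat("<profile_comparison>", x$n_perm, "permutations,",
      x$combine_method, "combination\n")
  cat("region p-values:\n")
  print(signif(x$region_p, 3))
  sig <- sum(x$p_adjusted < 0.05)
  cat(sig, "of 20 bins significant after Bonferroni (alpha = 0.05)\n")
  invisible(x)
}
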