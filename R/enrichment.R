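#' Exact null distribution of a multi-set intersection size
#'
#' Under the independence null, each additive's carrier set is an
#' independent, uniformly random subset of fixed size (its observed marginal
#' count) drawn from the `N` products of a food group. The size of the
#' intersection of `m` such subsets follows a chained ("multiset")
#' hypergeometric distribution, computed exactly by dynamic programming:
#' the intersection of the first subset with itself is its size; adding a
#' subset of size `s_j` maps an intersection of size `s` to `k` with
#' probability `dhyper(k, s, N - s, s_j)`.
#'
#' The mean of the resulting distribution equals the expected count
#' `N * prod(sizes / N)` used in the fold-enrichment denominator.
#'
#' @param N Background size (products in the food group).
#' @param sizes Integer vector (length >= 2) of per-additive carrier counts,
#'   each in `[0, N]`.
#' @return An `ets_null_dist` object: list with `support` (integers
#'   `0:min(sizes)`), `pmf`, `N` and `sizes`.
#' @examples
#' d <- null_intersection_distribution(30, c(10, 12, 8))
#' sum(d$support * d$pmf)  # equals 30 * (10/30) * (12/30) * (8/30)
#' @export
null_intersection_distribution <- function(N, sizes) {
  N <- as.integer(N)
  sizes <- as.integer(sizes)
  if (length(sizes) < 2) stop("need at least 2 set sizes")
  if (N <= 0) stop("N must be positive")
  if (any(sizes < 0 | sizes > N)) stop("sizes must lie in [0, N]")

  sizes_sorted <- sort(sizes)  # smallest first keeps the DP support minimal
  support <- 0:sizes_sorted[1]
  pmf <- as.numeric(support == sizes_sorted[1])
  for (s_j in sizes_sorted[-1]) {
    pmf <- hyper_step(pmf, support, N, s_j)
  }
  pmf <- pmax(pmf, 0)
  pmf <- pmf / sum(pmf)
  structure(list(support = support, pmf = pmf, N = N, sizes = sizes),
            class = "ets_null_dist")
}

# One DP step: given pmf over the current intersection size s (support
# 0:K), return the pmf of the intersection with a fresh random s_j-subset,
# P(k | s) = dhyper(k; s, N - s, s_j). Each column is computed from the
# hypergeometric ratio recurrence on the log scale (cheaper than dense
# lgamma-based dhyper over the full grid, and robust to tail underflow).
hyper_step <- function(pmf, support, N, s_j) {
  K <- support[length(support)]
  new_K <- min(K, s_j)
  out <- numeric(new_K + 1)
  for (si in which(pmf > 0)) {
    s <- support[si]
    kmin <- max(0, s + s_j - N)
    kmax <- min(s, s_j)
    if (kmax < kmin) next
    lf0 <- lchoose(s, kmin) + lchoose(N - s, s_j - kmin) - lchoose(N, s_j)
    ks <- kmin:kmax
    if (length(ks) > 1) {
      k <- ks[-length(ks)]
      lr <- log(s - k) + log(s_j - k) - log(k + 1) - log(N - s - s_j + k + 1)
      lf <- lf0 + c(0, cumsum(lr))
    } else {
      lf <- lf0
    }
    out[ks + 1] <- out[ks + 1] + pmf[si] * exp(lf)
  }
  out
}

#' @export
print.ets_null_dist <- function(x, ...) {
  cat("<ets_null_dist> N=", x$N, ", sizes=", paste(x$sizes, collapse = ","),
      ", mean=", format(sum(x$support * x$pmf), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Blaker's exact two-sided p-value
#'
#' Two-sided p-value for an observed intersection count against an exact
#' discrete null, allowing both over- and under-representation to be
#' detected. The acceptability of an outcome `x` is
#' `gamma(x) = min(P(X <= x), P(X >= x))`; the p-value sums the null
#' probability of every outcome whose acceptability does not exceed that of
#' the observed count (with a `1 + 1e-7` multiplier absorbing floating-point
#' ties).
#'
#' @param dist An [null_intersection_distribution()] result (any object with
#'   `support` and `pmf`).
#' @param observed Observed intersection count, in the support.
#' @return A p-value in `[0, 1]`, never below the smaller tail probability
#'   and never above twice it.
#' @export
blaker_two_sided_p <- function(dist, observed) {
  support <- dist$support
  pmf <- dist$pmf
  i <- match(observed, support)
  if (is.na(i)) stop("observed count ", observed, " outside the support")
  lower <- cumsum(pmf)
  upper <- rev(cumsum(rev(pmf)))
  accept <- pmin(lower, upper)
  min(1, sum(pmf[accept <= accept[i] * (1 + 1e-7)]))
}

log_fe_stat <- function(sub, N) {
  # sub: binary matrix restricted to the combination's columns
  observed <- sum(rowSums(sub) == ncol(sub))
  sizes <- colSums(sub)
  if (observed == 0 || any(sizes == 0)) return(NA_real_)
  log(observed / (N * prod(sizes / N)))
}

#' Bootstrap percentile interval for log fold enrichment
#'
#' Resamples products (rows) with replacement within the food group,
#' recomputes log fold enrichment of the combination per replicate, and
#' returns the 2.5/97.5 percentile bounds. Replicates with zero observed
#' count or an empty marginal have undefined log fold enrichment; they are
#' excluded from the percentiles and reported as `n_degenerate`.
#'
#' @param rows Binary matrix (products x codes) for one food group.
#' @param combo Character vector of column names forming the combination.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed for the resampling.
#' @return A list with `ci_lo`, `ci_hi` (on the log fold-enrichment scale;
#'   both `NA` and `all_degenerate = TRUE` when no replicate is defined),
#'   `n_degenerate` and `B`.
#' @export
bootstrap_ci_logfe <- function(rows, combo, B = 1000, seed = NULL) {
  if (B < 100) stop("B must be at least 100")
  sub <- rows[, combo, drop = FALSE]
  N <- nrow(sub)
  if (!is.null(seed)) set.seed(seed)
  bt <- boot::boot(sub, function(d, idx) log_fe_stat(d[idx, , drop = FALSE], N),
                   R = B)
  reps <- as.numeric(bt$t)
  defined <- reps[is.finite(reps)]
  n_degenerate <- B - length(defined)
  if (length(defined) == 0) {
    return(list(ci_lo = NA_real_, ci_hi = NA_real_,
                n_degenerate = n_degenerate, B = B, all_degenerate = TRUE))
  }
  q <- stats::quantile(defined, c(0.025, 0.975), names = FALSE, type = 7)
  list(ci_lo = q[1], ci_hi = q[2], n_degenerate = n_degenerate, B = B,
       all_degenerate = FALSE)
}

#' Fold-enrichment scan over additive combinations
#'
#' For each food group, lumps the additive codes (E40x/E42x/E45x/E47x),
#' keeps additives present in at least `prevalence_min` of the group's
#' products, and enumerates combinations of `combo_sizes` codes under
#' *at-least* semantics (a product carries the combination if its additive
#' set contains all of its codes, possibly with others). Combinations whose
#' expected count under independence, `N * prod(sizes / N)`, is below
#' `expected_min` are skipped. Each retained combination gets its observed
#' count, expected count, fold enrichment, exact two-sided p-value
#' ([blaker_two_sided_p()] on the chained-hypergeometric null), a
#' Benjamini-Hochberg q-value within the food group (an addition to the
#' two-sided p-values; no correction is part of the core definition), and a
#' bootstrap percentile interval of log fold enrichment when `B > 0`.
#'
#' @param products Tibble of eligible products with `ets_codes` and `group`
#'   columns (alternatively pass a prebuilt [presence_matrix()] via
#'   `matrix`).
#' @param group Optional character vector restricting the scan to these
#'   food groups.
#' @param prevalence_min Minimum within-group prevalence (proportion) for an
#'   additive to enter the scan (default 0.01).
#' @param expected_min Minimum expected product count for a combination to
#'   be tested (default 10).
#' @param combo_sizes Combination sizes to enumerate (default `2:4`).
#' @param B Bootstrap replicates for the log fold-enrichment interval;
#'   `B = 0` skips the interval.
#' @param seed Integer seed controlling the bootstrap.
#' @param lump Lump codes before scanning (default `TRUE`).
#' @param min_group_size Groups with fewer products are skipped with a
#'   warning (default 30).
#' @return An `ets_enrichment` tibble with columns `group`, `combo`, `size`,
#'   `n_group`, `observed`, `expected`, `fold_enrichment`, `p_two_sided`,
#'   `q_bh`, `ci_lo`, `ci_hi` (log fold-enrichment scale), `n_degenerate`,
#'   `B` and `seed`.
#' @export
enrichment_scan <- function(products, group = NULL, prevalence_min = 0.01,
                            expected_min = 10, combo_sizes = 2:4,
                            B = 1000, seed = NULL, lump = TRUE,
                            min_group_size = 30) {
  m <- presence_matrix(products, lump = lump)
  grp <- attr(m, "group")
  groups <- if (is.null(group)) sort(unique(stats::na.omit(grp))) else group
  out <- purrr::map_dfr(groups, function(g) {
    rows <- m[which(!is.na(grp) & grp == g), , drop = FALSE]
    N <- nrow(rows)
    if (N < min_group_size) {
      warning("group '", g, "' has ", N, " products (< ", min_group_size,
              "); skipped")
      return(NULL)
    }
    sizes_all <- colSums(rows)
    retained <- colnames(rows)[sizes_all / N >= prevalence_min]
    res <- purrr::map_dfr(combo_sizes[combo_sizes <= length(retained)],
                          function(k) {
      combos <- utils::combn(retained, k, simplify = FALSE)
      purrr::map_dfr(combos, function(combo) {
        sizes <- sizes_all[combo]
        expected <- N * prod(sizes / N)
        if (expected < expected_min) return(NULL)
        observed <- sum(rowSums(rows[, combo, drop = FALSE]) == k)
        tibble::tibble(
          group = g, combo = paste(combo, collapse = "&"), size = k,
          n_group = N, observed = observed, expected = expected,
          fold_enrichment = observed / expected,
          p_two_sided = blaker_two_sided_p(
            null_intersection_distribution(N, sizes), observed
          )
        )
      })
    })
    if (nrow(res) == 0) return(NULL)
    res$q_bh <- stats::p.adjust(res$p_two_sided, method = "BH")
    if (B > 0) {
      cis <- purrr::imap(strsplit(res$combo, "&", fixed = TRUE),
                         function(combo, i) {
        bootstrap_ci_logfe(rows, combo, B = B,
                           seed = if (is.null(seed)) NULL else
                             (seed + 7L * i) %% .Machine$integer.max)
      })
      res$ci_lo <- purrr::map_dbl(cis, "ci_lo")
      res$ci_hi <- purrr::map_dbl(cis, "ci_hi")
      res$n_degenerate <- purrr::map_int(cis, "n_degenerate")
    } else {
      res$ci_lo <- NA_real_
      res$ci_hi <- NA_real_
      res$n_degenerate <- NA_integer_
    }
    res$B <- B
    res$seed <- if (is.null(seed)) NA_integer_ else seed
    res
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      group = character(), combo = character(), size = integer(),
      n_group = integer(), observed = integer(), expected = double(),
      fold_enrichment = double(), p_two_sided = double(), q_bh = double(),
      ci_lo = double(), ci_hi = double(), n_degenerate = integer(),
      B = integer(), seed = integer()
    )
  }
  class(out) <- c("ets_enrichment", class(out))
  out
}

#' @export
tidy.ets_enrichment <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.ets_enrichment <- function(x, ...) {
  tibble::tibble(
    n_groups = dplyr::n_distinct(x$group),
    n_combos = nrow(x),
    n_significant = sum(x$p_two_sided < 0.05, na.rm = TRUE),
    max_fold_enrichment = if (nrow(x)) max(x$fold_enrichment, na.rm = TRUE)
      else NA_real_
  )
}
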