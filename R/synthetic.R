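#' Generate synthetic water samples
#'
#' Draws a two-season tap-water sample set with the statistical structure of
#' the reference survey: for each metal and season, `n_per_season`
#' concentrations from a log-normal moment-matched to the reference mean
#' and sd (see [dist_lognormal()]), optionally rejection-truncated to the
#' reference min-max range. Metals are drawn independently by default;
#' [inject_correlation()] can impose a rank correlation afterwards for
#' testing correlation analyses. Site identifiers are sequential labels
#' with uniformly jittered coordinates inside a cosmetic bounding box.
#'
#' Each metal x season pair owns a child RNG stream derived from `seed`, so
#' the generator is bit-reproducible and adding a metal does not perturb
#' the other draws.
#'
#' @param n_per_season samples per season (default 45, i.e. 90 in total for
#'   the default two-season design).
#' @param seed root RNG seed; random when `NULL`.
#' @param reference tibble of per-metal, per-season `mean`/`sd` (and, when
#'   `truncate = TRUE`, `min`/`max`), defaulting to [reference_summary()].
#' @param truncate reject draws outside the reference range (off by
#'   default: truncation biases the moments).
#' @param site_prefix prefix of the synthesized site labels.
#' @param bbox numeric `c(lon_min, lon_max, lat_min, lat_max)` for the
#'   cosmetic coordinates.
#' @return wide sample tibble: `site`, `season`, `latitude`, `longitude`
#'   and one column per metal (ug/L).
#' @examples
#' s <- generate_samples(seed = 1)
#' nrow(s) # 90
#' @export
generate_samples <- function(n_per_season = 45, seed = NULL,
                             reference = reference_summary(),
                             truncate = FALSE, site_prefix = "S",
                             bbox = c(52.45, 52.65, 29.55, 29.75)) {
  assert_number(n_per_season, "n_per_season", 1)
  n_per_season <- as.integer(n_per_season)
  if (is.null(seed)) seed <- sample.int(1073741823L, 1)
  metals <- unique(reference$metal)
  out <- tibble::tibble(
    site = rep(paste0(site_prefix, seq_len(n_per_season)), times = 2),
    season = rep(SEASONS, each = n_per_season)
  )
  set.seed(child_seed(seed, "coordinates"))
  lon <- stats::runif(n_per_season, bbox[1], bbox[2])
  lat <- stats::runif(n_per_season, bbox[3], bbox[4])
  out$latitude <- rep(lat, times = 2)
  out$longitude <- rep(lon, times = 2)
  for (m in metals) out[[m]] <- NA_real_
  for (m in metals) {
    for (s in SEASONS) {
      row <- reference[reference$metal == m & reference$season == s, ]
      if (nrow(row) != 1L) {
        stop("reference lacks a unique ", m, " ", s, " row", call. = FALSE)
      }
      spec <- dist_lognormal(row$mean, row$sd)
      set.seed(child_seed(seed, paste(m, s)))
      v <- draw_dist(spec, n_per_season)
      if (truncate) {
        if (!all(c("min", "max") %in% names(row)) ||
            is.na(row$min) || is.na(row$max)) {
          stop("truncation requested but reference lacks min/max for ",
               m, " ", s, call. = FALSE)
        }
        v <- truncated_draws(spec, n_per_season, row$min, row$max)
      }
      out[[m]][out$season == s] <- v
    }
  }
  validate_samples(out, metals = NULL)
}

# Rejection sampling into [lo, hi]; errors when the range holds almost no
# probability mass instead of looping forever.
truncated_draws <- function(spec, n, lo, hi, max_rounds = 1000L) {
  if (lo > hi) stop("truncation range has min > max", call. = FALSE)
  out <- numeric(0)
  for (round in seq_len(max_rounds)) {
    cand <- draw_dist(spec, max(n, 100L))
    out <- c(out, cand[cand >= lo & cand <= hi])
    if (length(out) >= n) return(out[seq_len(n)])
    if (round >= 20L && length(out) < round) {
      break
    }
  }
  stop("truncation range [", lo, ", ", hi,
       "] excludes nearly all probability mass", call. = FALSE)
}

#' Impose a target Spearman correlation between two metals
#'
#' Reorders one metal's seasonal values through a Gaussian-copula rank
#' coupling so that the realised Spearman correlation with a second metal
#' approaches `rho_target`, while leaving the marginal multiset of values
#' untouched (it is a pure permutation). `rho_target = 1` (or -1) yields the
#' exact comonotone (antitone) arrangement.
#'
#' The copula correlation is set to `2 sin(pi * rho_s / 6)`, the bivariate
#' normal's Spearman inversion, and the second metal's values are reassigned
#' by the ranks of the coupled Gaussian scores.
#'
#' @param samples wide sample tibble.
#' @param season season whose values are rearranged.
#' @param metals character pair: the first metal is left untouched, the
#'   second is reordered.
#' @param rho_target target Spearman correlation in `[-1, 1]`.
#' @param seed RNG seed for the coupling noise; random when `NULL`.
#' @return the modified sample tibble.
#' @examples
#' s <- generate_samples(seed = 1)
#' s2 <- inject_correlation(s, "winter", c("Fe", "Mn"), 0.62, seed = 2)
#' spearman_matrix(s2, "winter")$rho["Fe", "Mn"]
#' @export
inject_correlation <- function(samples, season, metals, rho_target,
                               seed = NULL) {
  season <- match_season(season)
  samples <- validate_samples(samples, metals = NULL)
  if (length(metals) != 2L || !all(metals %in% names(samples))) {
    stop("`metals` must name two metal columns of `samples`", call. = FALSE)
  }
  if (abs(rho_target) > 1) stop("|rho_target| must be <= 1", call. = FALSE)
  take <- samples$season == season
  a <- samples[[metals[1]]][take]
  b <- samples[[metals[2]]][take]
  n <- length(a)
  if (n < 5L) {
    stop("need at least 5 samples in the season to couple ranks reliably",
         call. = FALSE)
  }
  if (is.null(seed)) seed <- sample.int(1073741823L, 1)
  set.seed(child_seed(seed, "copula"))
  r <- 2 * sin(pi * rho_target / 6)
  z_a <- stats::qnorm((rank(a, ties.method = "average") - 0.5) / n)
  z_b <- r * z_a + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
  # reassign b's multiset by the coupled score ranks
  samples[[metals[2]]][take] <- sort(b)[rank(z_b, ties.method = "first")]
  samples
}
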