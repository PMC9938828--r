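#' Normality test of a concentration vector
#'
#' Kolmogorov-Smirnov-type normality testing with parameters estimated from
#' the data. The default applies the Lilliefors correction
#' ([nortest::lillie.test()]), which keeps the test calibrated when mean and
#' sd are estimated; `method = "ks"` runs the plain one-sample KS statistic
#' against the fitted normal (anti-conservative p-values, kept for
#' comparison with legacy analyses).
#'
#' @param x numeric vector, `n >= 4` for the Lilliefors form.
#' @param method `"lilliefors"` or `"ks"`.
#' @return list with `statistic`, `p.value`, `method`.
#' @export
normality_test <- function(x, method = c("lilliefors", "ks")) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2L) {
    return(list(statistic = NA_real_, p.value = NA_real_,
                method = method, degenerate = TRUE))
  }
  ht <- if (method == "lilliefors") {
    nortest::lillie.test(x)
  } else {
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  }
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       method = method, degenerate = FALSE)
}

#' Seasonal difference test for one metal
#'
#' Tests whether a metal's concentrations differ between winter and summer:
#' each season is first screened for normality (see [normality_test()]);
#' when both seasonal samples pass at `alpha`, a two-sided Welch t-test is
#' used, otherwise the two-sided Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param samples wide sample tibble (see [read_samples()]).
#' @param metal metal column to test.
#' @param alpha significance level for both the normality screen and the
#'   seasonal test.
#' @param normality method passed to [normality_test()].
#' @return one-row tibble: per-season normality p-values, the test used,
#'   its p-value and the significance flag. Degenerate inputs (a constant
#'   season) are flagged and never declared significant on the basis of a
#'   rank test of constants.
#' @examples
#' s <- generate_samples(seed = 1)
#' compare_seasons(s, "Fe")
#' @export
compare_seasons <- function(samples, metal, alpha = 0.05,
                            normality = c("lilliefors", "ks")) {
  normality <- match.arg(normality)
  samples <- validate_samples(samples, metals = NULL)
  if (!metal %in% names(samples)) {
    stop("metal column not present: ", metal, call. = FALSE)
  }
  w <- samples[[metal]][samples$season == "winter"]
  s <- samples[[metal]][samples$season == "summer"]
  w <- w[is.finite(w)]
  s <- s[is.finite(s)]
  if (length(w) < 3L || length(s) < 3L) {
    stop("need at least 3 samples per season for metal ", metal,
         call. = FALSE)
  }
  nw <- normality_test(w, normality)
  ns <- normality_test(s, normality)
  degenerate <- isTRUE(nw$degenerate) || isTRUE(ns$degenerate)
  if (degenerate) {
    # constant season(s): location tests are meaningless; report equality
    # of the constants instead of a rank test of ties
    p <- if (length(unique(c(w, s))) == 1L) 1 else NA_real_
    test <- "degenerate"
  } else if (!is.na(nw$p.value) && !is.na(ns$p.value) &&
             nw$p.value > alpha && ns$p.value > alpha) {
    test <- "t-test"
    p <- stats::t.test(w, s)$p.value
  } else {
    test <- "mann-whitney"
    p <- suppressWarnings(stats::wilcox.test(w, s, exact = FALSE))$p.value
  }
  tibble::tibble(
    metal = metal, n_winter = length(w), n_summer = length(s),
    p_normal_winter = nw$p.value, p_normal_summer = ns$p.value,
    test = test, p_value = p,
    significant = !is.na(p) && p < alpha,
    degenerate = degenerate
  )
}

#' Classify a correlation coefficient
#'
#' Strength bands on the absolute coefficient: weak (`|rho| < 0.5`),
#' moderate (`0.5 <= |rho| < 0.7`), strong (`|rho| >= 0.7`). The band edges,
#' left open by the strict inequalities of the usual statement, are assigned
#' to the higher band.
#'
#' @param rho correlation coefficient(s) in `[-1, 1]`.
#' @return `"weak"`, `"moderate"` or `"strong"`, vectorised; `NA` in,
#'   `NA` out.
#' @export
classify_correlation <- function(rho) {
  if (any(abs(rho) > 1, na.rm = TRUE)) {
    stop("|rho| cannot exceed 1", call. = FALSE)
  }
  out <- ifelse(abs(rho) >= 0.7, "strong",
                ifelse(abs(rho) >= 0.5, "moderate", "weak"))
  out[is.na(rho)] <- NA_character_
  out
}

#' Spearman correlation matrix of metals within a season
#'
#' Pairwise Spearman rank correlations between all metal columns in the
#' chosen season, with two-sided asymptotic p-values and the strength class
#' of each pair. A constant metal column makes its correlations undefined;
#' those entries are reported as `NA` with a warning.
#'
#' @param samples wide sample tibble.
#' @param season `"winter"` or `"summer"`.
#' @return a `spearman_matrix` list: `season`, `n`, matrices `rho`, `p`,
#'   `strength`, and a long tibble `pairs` (one row per unordered pair).
#' @examples
#' s <- generate_samples(seed = 1)
#' spearman_matrix(s, "winter")
#' @export
spearman_matrix <- function(samples, season) {
  season <- match_season(season)
  samples <- validate_samples(samples, metals = NULL)
  mcols <- metal_columns(samples)
  if (length(mcols) < 2L) {
    stop("need at least two metal columns", call. = FALSE)
  }
  sub <- samples[samples$season == season, mcols, drop = FALSE]
  if (nrow(sub) < 3L) {
    stop("need at least 3 samples in season ", season, call. = FALSE)
  }
  k <- length(mcols)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(mcols, mcols))
  diag(rho) <- 1
  diag(p) <- 0
  constant <- vapply(sub, function(v) length(unique(v)) < 2L, logical(1))
  if (any(constant)) {
    warning("constant metal column(s), correlations undefined: ",
            paste(mcols[constant], collapse = ", "), call. = FALSE)
  }
  pairs <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      if (!constant[i] && !constant[j]) {
        ct <- suppressWarnings(
          stats::cor.test(sub[[i]], sub[[j]], method = "spearman",
                          exact = FALSE))
        rho[i, j] <- rho[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
      rho_ij <- rho[i, j]
      pairs[[length(pairs) + 1L]] <- tibble::tibble(
        season = season, metal_a = mcols[i], metal_b = mcols[j],
        rho = rho_ij, p_value = p[i, j],
        strength = classify_correlation(rho_ij)
      )
    }
  }
  strength <- matrix(classify_correlation(rho), k, k,
                     dimnames = dimnames(rho))
  structure(list(season = season, n = nrow(sub), rho = rho, p = p,
                 strength = strength, pairs = do.call(rbind, pairs)),
            class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, ...) {
  cat(sprintf("<spearman_matrix: %s> n = %d\n", x$season, x$n))
  print(round(x$rho, 3))
  invisible(x)
}
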