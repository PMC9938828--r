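#' Contamination factor
#'
#' `Cf = M/S - 1`: the measured concentration relative to the permissible
#' standard, minus one. Negative whenever the water is below the standard.
#'
#' @param conc measured concentration M (ug/L), `>= 0`.
#' @param standard permissible standard S (ug/L), `> 0`.
#' @return contamination factor (dimensionless), vectorised.
#' @examples
#' contamination_factor(0.36, 15) # Pb winter mean against the EPA standard
#' @export
contamination_factor <- function(conc, standard) {
  if (any(!is.finite(standard) | standard <= 0)) {
    stop("standard S must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(conc) | conc < 0)) {
    stop("concentration M must be finite and >= 0", call. = FALSE)
  }
  conc / standard - 1
}

#' Degree of contamination
#'
#' The sum of per-metal contamination factors, `Cd = sum(Cf_i)`.
#'
#' @param cf numeric vector of contamination factors, nonempty.
#' @return the degree of contamination.
#' @export
degree_of_contamination <- function(cf) {
  if (!length(cf)) {
    stop("degree of contamination is undefined for an empty set of factors",
         call. = FALSE)
  }
  if (any(!is.finite(cf))) {
    stop("contamination factors must be finite", call. = FALSE)
  }
  sum(cf)
}

#' Classify the degree of contamination
#'
#' Bands: `> 3` high contamination, `1 < Cd <= 3` moderate, `<= 1`
#' significantly low. The band edges (1 and 3), left open by the strict
#' inequalities of the usual definition, are assigned to the lower-severity
#' class.
#'
#' @param cd degree of contamination, finite.
#' @return one of `"significantly_low"`, `"moderate"`, `"high"`, vectorised.
#' @export
classify_cd <- function(cd) {
  if (any(!is.finite(cd))) stop("Cd must be finite", call. = FALSE)
  ifelse(cd > 3, "high", ifelse(cd > 1, "moderate", "significantly_low"))
}

#' Unit weight of a metal
#'
#' `W = k/S`: weights inversely proportional to the permissible standard,
#' with proportionality constant `k` (conventionally 1, giving weights in
#' (0, 1] for standards >= 1 ug/L).
#'
#' @param standard permissible standard S (ug/L), `> 0`.
#' @param k proportionality constant, `> 0`.
#' @return unit weight, vectorised over `standard`.
#' @export
unit_weight <- function(standard, k = 1) {
  if (any(!is.finite(standard) | standard <= 0)) {
    stop("standard S must be finite and > 0", call. = FALSE)
  }
  assert_number(k, "k", 0, strict = TRUE)
  k / standard
}

#' HPI sub-index of a metal
#'
#' `Q = |M - I| / |S - I| * 100`: the measured excursion from the ideal
#' concentration as a percentage of the standard's excursion. Absolute
#' differences are used in both numerator and denominator (signs are
#' ignored), which keeps the sub-index well-defined when the ideal value
#' exceeds the standard, as for Mn (I = 100 > S = 50 ug/L under EPA).
#'
#' @param conc measured concentration M (ug/L).
#' @param standard permissible standard S (ug/L).
#' @param ideal ideal concentration I (ug/L); must differ from `standard`.
#' @return sub-index (dimensionless percent), vectorised.
#' @examples
#' sub_index(2.28, 50, 100) # 195.44
#' @export
sub_index <- function(conc, standard, ideal = 0) {
  if (any(standard == ideal)) {
    stop("standard equals ideal value: sub-index undefined", call. = FALSE)
  }
  if (any(!is.finite(conc) | conc < 0)) {
    stop("concentration M must be finite and >= 0", call. = FALSE)
  }
  abs(conc - ideal) / abs(standard - ideal) * 100
}

#' Heavy-metal pollution index
#'
#' The weighted arithmetic mean of the sub-indices,
#' `HPI = sum(W * Q) / sum(W)`.
#'
#' Two evaluation modes are provided. `"full"` (the default for new
#' analyses) keeps full floating-point precision. `"table"` emulates the
#' finite-precision arithmetic of published index tables, which carry
#' weights to four truncated decimals, sub-indices and their products to two
#' rounded decimals, and truncate both column sums to two decimals before
#' the final division; without this mode a published HPI of, e.g., 20.82
#' (= 12.08/0.58 with the truncated weight sum) is not recoverable from the
#' same inputs.
#'
#' @param w per-metal unit weights, named or in the same order as `q`.
#' @param q per-metal sub-indices.
#' @param rounding `"full"` or `"table"` (see Details).
#' @return the pollution index (dimensionless).
#' @examples
#' metals <- default_metals()
#' epa <- metals[metals$agency == "EPA", ]
#' w <- unit_weight(epa$standard)
#' q <- sub_index(c(Pb = 0.36, Hg = 0.32, Mn = 2.28, Fe = 8.72),
#'                epa$standard, epa$ideal)
#' hpi(w, q)                    # full precision
#' hpi(w, q, rounding = "table") # printed-table emulation
#' @export
hpi <- function(w, q, rounding = c("full", "table")) {
  rounding <- match.arg(rounding)
  if (!is.null(names(w)) && !is.null(names(q))) {
    if (!setequal(names(w), names(q))) {
      stop("weight/sub-index metal sets differ: ",
           paste(c(setdiff(names(w), names(q)), setdiff(names(q), names(w))),
                 collapse = ", "), call. = FALSE)
    }
    q <- q[names(w)]
  } else if (length(w) != length(q)) {
    stop("weights and sub-indices differ in length", call. = FALSE)
  }
  if (!length(w) || sum(w) <= 0) {
    stop("weights must be nonempty with a positive sum", call. = FALSE)
  }
  if (rounding == "full") {
    return(sum(w * q) / sum(w))
  }
  w4 <- trunc_decimals(w, 4)
  q2 <- round(q, 2)
  wq <- round(w4 * q2, 2)
  trunc_decimals(sum(wq), 2) / trunc_decimals(sum(w4), 2)
}

#' Classify the heavy-metal pollution index
#'
#' Bands: excellent (< 50), good (50-99.99), poor (100-199.99), very poor
#' (200-299.99), unsuitable for drinking (>= 300).
#'
#' @param x pollution index, `>= 0`.
#' @return one of `"excellent"`, `"good"`, `"poor"`, `"very_poor"`,
#'   `"unsuitable"`, vectorised.
#' @export
classify_hpi <- function(x) {
  if (any(!is.finite(x) | x < 0)) {
    stop("HPI must be finite and >= 0", call. = FALSE)
  }
  cut(x, breaks = c(-Inf, 50, 100, 200, 300, Inf), right = FALSE,
      labels = c("excellent", "good", "poor", "very_poor", "unsuitable")) |>
    as.character()
}

#' Contamination and pollution indices per agency and season
#'
#' Runs the whole index chain on seasonal mean concentrations: per-metal
#' contamination factors, unit weights, sub-indices and their products, and
#' per agency x season the degree of contamination and the pollution index
#' (full precision and printed-table emulation) with classification bands.
#'
#' @param summary tibble with columns `metal`, `season`, `mean` (ug/L), as
#'   returned by [summarize_samples()] or [reference_summary()].
#' @param metals metal registry (see [default_metals()]).
#' @param agencies agencies to evaluate; default all in the registry.
#' @param k proportionality constant of the unit weights.
#' @return list with `metals` (one row per agency x season x metal: `conc`,
#'   `cf`, `w`, `q`, `wq`) and `indices` (one row per agency x season: `cd`,
#'   `cd_class`, `hpi`, `hpi_table`, `hpi_class`).
#' @examples
#' compute_indices(reference_summary())$indices
#' @export
compute_indices <- function(summary, metals = default_metals(),
                            agencies = unique(metals$agency), k = 1) {
  needed <- c("metal", "season", "mean")
  missing <- setdiff(needed, names(summary))
  if (length(missing)) {
    stop("summary lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  per_metal <- list()
  per_group <- list()
  for (agency in agencies) {
    reg <- metals[metals$agency == agency, ]
    for (season in unique(summary$season)) {
      sub <- summary[summary$season == season, ]
      idx <- match(reg$metal, sub$metal)
      if (anyNA(idx)) {
        stop("summary lacks season ", season, " means for: ",
             paste(reg$metal[is.na(idx)], collapse = ", "), call. = FALSE)
      }
      conc <- sub$mean[idx]
      cf <- contamination_factor(conc, reg$standard)
      w <- unit_weight(reg$standard, k)
      q <- sub_index(conc, reg$standard, reg$ideal)
      per_metal[[length(per_metal) + 1L]] <- tibble::tibble(
        agency = agency, season = season, metal = reg$metal,
        conc = conc, cf = cf, w = w, q = q, wq = w * q
      )
      cd <- degree_of_contamination(cf)
      h <- hpi(w, q, rounding = "full")
      per_group[[length(per_group) + 1L]] <- tibble::tibble(
        agency = agency, season = season,
        cd = cd, cd_class = classify_cd(cd),
        hpi = h, hpi_table = hpi(w, q, rounding = "table"),
        hpi_class = classify_hpi(h)
      )
    }
  }
  list(metals = do.call(rbind, per_metal),
       indices = do.call(rbind, per_group))
}
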