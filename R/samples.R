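#' Read water-sample records
#'
#' Reads a CSV of per-site drinking-water records into a wide tibble with one
#' row per sample and one column per metal (concentrations in ug/L). Both
#' layouts are accepted: wide (columns `site`, `season`, one column per
#' metal, optional `latitude`/`longitude`) and long (columns `site`,
#' `season`, `metal`, `concentration`), which is pivoted to wide.
#'
#' Unparseable concentration cells and negative concentrations are reported
#' with their row numbers rather than silently dropped.
#'
#' @param path CSV file path.
#' @param metals metal registry used to validate metal columns; defaults to
#'   the packaged registry. Pass `NULL` to accept any metal columns.
#' @return tibble of validated samples (wide layout).
#' @seealso [write_samples()], [generate_samples()]
#' @export
read_samples <- function(path, metals = default_metals()) {
  if (!file.exists(path)) {
    stop("sample file not found: ", path, call. = FALSE)
  }
  # parse all cells as text and convert with R's correctly rounded strtod,
  # so written concentrations round-trip bit-exactly
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!all(c("site", "season") %in% names(raw))) {
    stop("sample file must name `site` and `season` columns: ", path,
         call. = FALSE)
  }
  for (nm in c("latitude", "longitude", "concentration")) {
    if (nm %in% names(raw)) {
      coerced <- suppressWarnings(as.numeric(raw[[nm]]))
      bad <- which(is.na(coerced) & !is.na(raw[[nm]]))
      if (length(bad)) {
        stop("unparseable ", nm, " in row(s) ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      }
      raw[[nm]] <- coerced
    }
  }
  if (all(c("metal", "concentration") %in% names(raw))) {
    raw <- long_to_wide(raw)
  }
  validate_samples(raw, metals = metals)
}

long_to_wide <- function(long) {
  keys <- unique(long[c("site", "season")])
  metals <- unique(long$metal)
  wide <- keys
  for (m in metals) {
    sub <- long[long$metal == m, ]
    idx <- match(paste(keys$site, keys$season),
                 paste(sub$site, sub$season))
    wide[[m]] <- sub$concentration[idx]
  }
  tibble::as_tibble(wide)
}

#' Validate a table of water samples
#'
#' Checks the container invariants: `season` takes only the values
#' `"winter"`/`"summer"`, every concentration is finite and non-negative,
#' and (when a registry is supplied) every metal column is known to it.
#'
#' @param samples wide tibble of samples.
#' @param metals metal registry, or `NULL` to skip the column check.
#' @return the validated samples, invisibly classed as a tibble.
#' @export
validate_samples <- function(samples, metals = default_metals()) {
  samples <- tibble::as_tibble(samples)
  if (!all(c("site", "season") %in% names(samples))) {
    stop("samples must have `site` and `season` columns", call. = FALSE)
  }
  bad_season <- !samples$season %in% SEASONS
  if (any(bad_season)) {
    stop("invalid season in row(s) ",
         paste(utils::head(which(bad_season), 5), collapse = ", "),
         ": season must be one of ", paste(SEASONS, collapse = "/"),
         call. = FALSE)
  }
  mcols <- metal_columns(samples)
  if (!is.null(metals)) {
    unknown <- setdiff(mcols, unique(metals$metal))
    if (length(unknown)) {
      stop("unknown metal column(s) not in the registry: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  for (m in mcols) {
    v <- samples[[m]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v))
      if (length(bad)) {
        stop("unparseable ", m, " concentration in row(s) ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      }
      samples[[m]] <- coerced
      v <- coerced
    }
    if (any(!is.na(v) & (!is.finite(v) | v < 0))) {
      bad <- which(!is.na(v) & (!is.finite(v) | v < 0))
      stop("negative or non-finite ", m, " concentration in row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  samples
}

metal_columns <- function(samples) {
  setdiff(names(samples), c("site", "season", "latitude", "longitude"))
}

#' Write water-sample records
#'
#' Writes the wide sample layout to CSV with a shortest-round-trip number
#' representation, so `read_samples(write_samples(x))` preserves every
#' concentration bit-exactly.
#'
#' @param samples wide tibble of samples.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  samples <- validate_samples(samples, metals = NULL)
  out <- samples
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      # 17 significant digits round-trip IEEE doubles exactly
      out[[nm]] <- sprintf("%.17g", out[[nm]])
    }
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Seasonal summary statistics of measured concentrations
#'
#' Computes n, min, max, mean and standard deviation (sample sd, n - 1
#' denominator) per metal and season, the descriptive layer of the pipeline.
#' The sd of a single observation is defined as 0, with a warning.
#'
#' @param samples wide tibble of samples.
#' @param metal optional metal name(s) to restrict to.
#' @param season optional season to restrict to.
#' @return tibble with columns `metal`, `season`, `n`, `min`, `max`,
#'   `mean`, `sd`.
#' @examples
#' s <- generate_samples(seed = 1)
#' summarize_samples(s, metal = "Fe", season = "winter")
#' @export
summarize_samples <- function(samples, metal = NULL, season = NULL) {
  samples <- validate_samples(samples, metals = NULL)
  mcols <- metal_columns(samples)
  if (!is.null(metal)) {
    missing <- setdiff(metal, mcols)
    if (length(missing)) {
      stop("metal column(s) not present: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    mcols <- metal
  }
  seasons <- if (is.null(season)) {
    intersect(SEASONS, unique(samples$season))
  } else {
    match_season(season)
  }
  rows <- list()
  for (m in mcols) {
    for (s in seasons) {
      v <- samples[[m]][samples$season == s]
      v <- v[!is.na(v)]
      if (!length(v)) {
        stop("no data for metal ", m, " in season ", s, call. = FALSE)
      }
      sdev <- if (length(v) == 1L) {
        warning("sd of a single ", m, " ", s,
                " observation is defined as 0", call. = FALSE)
        0
      } else {
        stats::sd(v)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        metal = m, season = s, n = length(v),
        min = min(v), max = max(v), mean = mean(v), sd = sdev
      )
    }
  }
  do.call(rbind, rows)
}
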