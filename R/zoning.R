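#' Load the sheep-breed critical THI registry
#'
#' Reads a `breed,cover,thi_limit` CSV of critical THI limits per breed
#' (cover type `hair` or `wool`). The packaged default reproduces the
#' published limits for the 21 main sheep breeds in Brazil, from 81.93
#' (Rabo Largo, hair) down to 71.99 (Hampshire, wool); hair breeds
#' generally tolerate higher THI than wool breeds.
#'
#' @param path CSV path; `NULL` loads the packaged registry.
#' @return Data frame `breed`, `cover`, `thi_limit`, ordered by
#'   descending limit.
#' @export
load_breed_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "breed_thi_limits.csv",
                        package = "thermozone", mustWork = TRUE)
  if (!file.exists(path)) stop("registry file not found: ", path)
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("breed", "cover", "thi_limit")
  if (!all(need %in% names(reg)))
    stop("registry must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(reg$breed)) {
    i <- which(duplicated(reg$breed))[1]
    stop("duplicate breed '", reg$breed[i], "' at line ", i + 1)
  }
  if (any(is.na(reg$thi_limit)) || !is.numeric(reg$thi_limit)) {
    i <- which(is.na(suppressWarnings(as.numeric(reg$thi_limit))))[1]
    stop("non-numeric thi_limit at line ", i + 1)
  }
  if (any(reg$thi_limit <= 0)) stop("thi_limit must be > 0")
  if (!all(reg$cover %in% c("hair", "wool")))
    stop("cover must be 'hair' or 'wool'")
  reg <- reg[order(-reg$thi_limit, reg$breed), , drop = FALSE]
  rownames(reg) <- NULL
  reg
}

#' Breeds suitable at a given THI
#'
#' A breed is suitable when the THI does not exceed its critical limit
#' (inclusive: a breed at exactly its limit is counted suitable, i.e.
#' working at, not beyond, its threshold).
#'
#' @param thi A single THI value.
#' @param registry Breed registry (default: packaged).
#' @return Registry rows with `thi_limit >= thi`, sorted by descending
#'   limit (possibly zero rows).
#' @export
suitable_breeds <- function(thi, registry = load_breed_registry()) {
  stopifnot(length(thi) == 1, is.numeric(thi))
  out <- registry[registry$thi_limit >= thi, , drop = FALSE]
  out <- out[order(-out$thi_limit, out$breed), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-breed suitability masks and area fractions over a kriged surface
#'
#' For each breed, marks the cells of a kriged THI surface where
#' `THI <= thi_limit`, and summarises the suitable area fraction overall
#' and per subregion. A breed is called usable in a subregion when at
#' least `min_fraction` of that subregion's valid cells are suitable
#' (default 1, i.e. 100%).
#'
#' @param kr A [predict_grid()] `kriging_result` of THI.
#' @param registry Breed registry.
#' @param min_fraction Fraction of cells required for a subregion to be
#'   usable (default 1).
#' @return Object of class `suitability_result`: list with `masks`
#'   (logical matrix, breeds x cells, `NA` for no-data cells), `summary`
#'   (data frame `breed`, `cover`, `thi_limit`, `area_pct`, one
#'   `pct_<region>` column per subregion, `usable_regions`), and `grid`
#'   (the underlying cell table).
#' @export
suitability_masks <- function(kr, registry = load_breed_registry(),
                              min_fraction = 1) {
  stopifnot(inherits(kr, "kriging_result"))
  g <- kr$grid
  if (nrow(g) == 0) stop("empty raster")
  valid <- !is.na(g$pred)
  if (!any(valid)) stop("raster has no predicted cells")
  regions <- unique(g$region)
  masks <- matrix(NA, nrow(registry), nrow(g),
                  dimnames = list(registry$breed, NULL))
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    lim <- registry$thi_limit[i]
    mk <- ifelse(valid, g$pred <= lim, NA)
    masks[i, ] <<- mk
    per <- vapply(regions, function(r) {
      sel <- valid & g$region == r
      if (!any(sel)) return(NA_real_)
      100 * mean(mk[sel])
    }, 0)
    usable <- regions[!is.na(per) & per >= 100 * min_fraction]
    out <- data.frame(breed = registry$breed[i], cover = registry$cover[i],
                      thi_limit = lim, area_pct = 100 * mean(mk[valid]),
                      stringsAsFactors = FALSE)
    for (r in regions) out[[paste0("pct_", gsub("[^A-Za-z0-9]+", "_", r))]] <-
      per[[r]]
    out$usable_regions <- paste(usable, collapse = "; ")
    out
  })
  structure(list(masks = masks, summary = do.call(rbind, rows), grid = g),
            class = "suitability_result")
}

#' @export
print.suitability_result <- function(x, ...) {
  cat("suitability_result:", nrow(x$summary), "breeds over",
      sum(!is.na(x$grid$pred)), "cells\n")
  print(x$summary[, c("breed", "cover", "thi_limit", "area_pct")], ...)
  invisible(x)
}

#' Empirical cumulative distribution of THI in one subregion and period
#'
#' Pools all point-year THI values of a named subregion over a period
#' (typically a quadrennial) and returns their empirical CDF.
#'
#' @param thi_df Multi-year THI table from [annual_thi()].
#' @param region_name Subregion name present in `thi_df$region`.
#' @param years Years pooled into the period.
#' @return Object of class `regional_cdf`: list with `region`, `period`
#'   (label), `years`, `values` (sorted) and `n`.
#' @export
regional_cdf <- function(thi_df, region_name, years) {
  if (!region_name %in% unique(thi_df$region))
    stop("unknown region: ", region_name)
  sel <- thi_df$region == region_name & thi_df$year %in% years
  if (!any(sel)) stop("no values for ", region_name, " in the given years")
  v <- sort(thi_df$thi[sel])
  structure(list(region = region_name,
                 period = paste0(min(years), "-", max(years)),
                 years = sort(unique(years)), values = v, n = length(v)),
            class = "regional_cdf")
}

#' Evaluate a regional empirical CDF at a threshold
#'
#' @param cdf A [regional_cdf()] object.
#' @param threshold THI threshold.
#' @param inclusive Count values equal to the threshold (default TRUE,
#'   i.e. `P(THI <= t)`); `FALSE` gives strict `P(THI < t)`.
#' @return Fraction in `[0, 1]`.
#' @export
cdf_at <- function(cdf, threshold, inclusive = TRUE) {
  stopifnot(inherits(cdf, "regional_cdf"))
  if (inclusive) mean(cdf$values <= threshold) else mean(cdf$values < threshold)
}

#' @export
print.regional_cdf <- function(x, ...) {
  cat("regional_cdf:", x$region, x$period, "- n =", x$n,
      " range", paste(signif(range(x$values), 5), collapse = " - "), "\n")
  invisible(x)
}

#' Default quadrennial periods
#'
#' Splits a 12-year series into three quadrennials; with the default
#' 2010-2021 series these are 2010-2013, 2014-2017 and 2018-2021.
#'
#' @param years Year vector (default `2010:2021`).
#' @return Named list of year vectors.
#' @export
quadrennials <- function(years = 2010:2021) {
  years <- sort(unique(years))
  p <- split(years, ceiling(seq_along(years) / 4))
  names(p) <- vapply(p, function(y) paste0(min(y), "-", max(y)), "")
  p
}
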