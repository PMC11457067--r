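#' Phenotype tables and site metadata
#'
#' Phenotypes travel in long format: one row per
#' (genotype_id, site, year, trait, value) with traits `biomass`
#' (square-root grams), `fall_height` (cm) and `flowering_time`
#' (day of year). Genotype metadata (subpopulation, admixed flag) is a
#' separate tibble keyed by `genotype_id`.
#'
#' @name phenotypes
NULL

PHENO_TRAITS <- c("biomass", "fall_height", "flowering_time")

#' Square-root transform raw biomass
#'
#' Spaced-plant biomass is analysed on the square-root-gram scale to
#' normalise the heavy right tail; plants recorded dead in spring or summer
#' carry a biomass of 0 g, which maps to 0.
#'
#' @param raw_grams Non-negative numeric vector of dry-weight grams.
#' @return `sqrt(raw_grams)`.
#' @export
transform_biomass <- function(raw_grams) {
  if (any(raw_grams < 0, na.rm = TRUE)) {
    stop("raw biomass must be non-negative (dead plants are 0 g)", call. = FALSE)
  }
  sqrt(raw_grams)
}

check_phenotypes <- function(table) {
  need <- c("genotype_id", "site", "trait", "value")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(table$trait), PHENO_TRAITS)
  if (length(bad)) {
    stop("unknown trait(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ft <- table$value[table$trait == "flowering_time"]
  if (any(ft < 1 | ft > 366, na.rm = TRUE)) {
    stop("flowering_time must lie in [1, 366]", call. = FALSE)
  }
  if (any(table$value[table$trait != "flowering_time"] < 0, na.rm = TRUE)) {
    stop("biomass and fall_height must be non-negative", call. = FALSE)
  }
  invisible(table)
}

#' Aggregate phenotype records to genotype-by-site means
#'
#' Replicate clones within a site-year are averaged into the
#' genotype–site–year cell first; cells are then averaged over the years in
#' which the genotype was scored (missing years are dropped from the mean,
#' never zero-filled, while recorded dead-plant zeros stay in). The result
#' has one row per (genotype, site, trait) and the operation is idempotent.
#'
#' @param table Long phenotype tibble with columns `genotype_id`, `site`,
#'   `trait`, `value` and optionally `year`.
#' @return Tibble with columns `genotype_id`, `site`, `trait`, `value`.
#' @export
aggregate_phenotypes <- function(table) {
  check_phenotypes(table)
  table <- dplyr::filter(table, !is.na(.data$value))
  if ("year" %in% names(table)) {
    table <- table |>
      dplyr::summarise(value = mean(.data$value),
                       .by = c("genotype_id", "site", "year", "trait"))
  }
  table |>
    dplyr::summarise(value = mean(.data$value),
                     .by = c("genotype_id", "site", "trait")) |>
    dplyr::arrange(.data$genotype_id, .data$site, .data$trait)
}

#' Per-genotype surrogate means over reference sites
#'
#' A breeding program would score yield surrogates (flowering time, fall
#' height) at one or two convenient sites only. This combines each
#' genotype's site-level surrogate values over the reference sites it
#' appears at (single-site fallback when only one is available); KBSM and
#' CLMB are the defaults because together they cover nearly the whole
#' panel.
#'
#' @param table Aggregated phenotype tibble (see [aggregate_phenotypes()]).
#' @param sites Character vector of reference site codes.
#' @param traits Surrogate traits to combine.
#' @return Tibble `genotype_id`, `trait`, `value`; genotypes absent from
#'   every reference site for a trait are absent from the output.
#' @export
surrogate_site_means <- function(table, sites = c("KBSM", "CLMB"),
                                 traits = c("flowering_time", "fall_height")) {
  check_phenotypes(table)
  table |>
    dplyr::filter(.data$site %in% sites, .data$trait %in% traits) |>
    dplyr::summarise(value = mean(.data$value),
                     .by = c("genotype_id", "trait")) |>
    dplyr::arrange(.data$genotype_id, .data$trait)
}

#' The ten common-garden sites
#'
#' Site metadata for the 10 field sites of the spaced-plant diversity-panel
#' trial, spanning 17 degrees of latitude from Kingsville, Texas to
#' Brookings, South Dakota, grouped into South, Middle and North breeding
#' regions.
#'
#' @return Tibble with columns `site`, `region`, `latitude`, `longitude`,
#'   `elevation`.
#' @export
switchgrass_sites <- function() {
  tibble::tribble(
    ~site,  ~region,  ~latitude, ~longitude, ~elevation,
    "KING", "South",    27.5498,   -97.8810,         22,
    "PKLE", "South",    30.3839,   -97.7293,        235,
    "TMPL", "South",    31.0433,   -97.3494,        182,
    "OVTN", "South",    32.3029,   -94.9794,        138,
    "STIL", "Middle",   35.9911,   -97.0464,        280,
    "CLMB", "Middle",   38.8969,   -92.2178,        268,
    "LINC", "North",    41.1543,   -96.4153,        348,
    "FRMI", "North",    41.8367,   -88.2396,        225,
    "KBSM", "Middle",   42.4196,   -85.3712,        289,
    "BRKG", "North",    44.3068,   -96.6705,        503
  )
}

#' Read / write phenotype and site tables
#'
#' TSV round trips are lossless on values to at least 10 significant
#' digits. Phenotype columns: `genotype_id`, `site`, `year`, `trait`,
#' `value` (`year` optional). Site columns: `site`, `region`, `latitude`,
#' `longitude`, `elevation`.
#'
#' @param path File path.
#' @param table Tibble to write.
#' @return The tibble read, or (invisibly) the path written.
#' @export
read_phenotypes <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        na = c("", "NA", "."))
  check_phenotypes(df)
  df
}

#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(table, path) {
  check_phenotypes(table)
  readr::write_tsv(table, path)
  invisible(path)
}

#' @rdname read_phenotypes
#' @export
read_sites <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_phenotypes
#' @export
write_sites <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}
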