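#' Sparse-testing cross-validation
#'
#' The evaluation machinery for untested (CV1) and partially tested (CV2)
#' genotypes, plus resource-limited surrogate scenarios: eligibility,
#' 8-fold assignment, per-genotype site masking, Gibbs-model fitting and
#' per-site predictive-ability scoring. Genotypes evaluated at more than
#' five sites form the validation populations (their multi-site means are
#' reliable observed breeding values); subpopulations with too few
#' eligible genotypes are dropped, as the Gulf subpopulation was in the
#' source study design.
#'
#' @name cv_engine
NULL

CV_SCENARIOS <- c("CV1", paste0("CV2_", 1:5), "FT", "FT_HT", "HT",
                  "B1", "B1_FT", "B5")

mix_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  as.integer((sum(parts * (7919L + seq_along(parts))) %% 2147483629) + 1)
}

#' Eligible validation genotypes per subpopulation
#'
#' Genotypes with biomass observations at `min_sites` or more sites
#' (`min_sites = 6` operationalises the "more than 5 sites" rule) and not
#' flagged admixed. Subpopulations with fewer than `min_genotypes`
#' eligible genotypes are dropped with a warning.
#'
#' @param table Aggregated phenotype tibble.
#' @param info Genotype metadata: `genotype_id`, `subpopulation`,
#'   `admixed`.
#' @param min_sites Minimum number of biomass sites.
#' @param min_genotypes Minimum eligible genotypes per subpopulation.
#' @return Tibble `subpopulation`, `genotype_id`, `n_sites`.
#' @export
eligible_validation_set <- function(table, info, min_sites = 6L,
                                    min_genotypes = 60L) {
  check_phenotypes(table)
  counts <- table |>
    dplyr::filter(.data$trait == "biomass", !is.na(.data$value)) |>
    dplyr::summarise(n_sites = dplyr::n_distinct(.data$site),
                     .by = "genotype_id")
  elig <- counts |>
    dplyr::inner_join(info, by = "genotype_id") |>
    dplyr::filter(.data$n_sites >= min_sites, !.data$admixed)
  sizes <- dplyr::count(elig, .data$subpopulation)
  drop <- sizes$subpopulation[sizes$n < min_genotypes]
  if (length(drop)) {
    warning("subpopulation(s) with < ", min_genotypes,
            " eligible genotypes dropped: ", paste(drop, collapse = ", "))
    elig <- dplyr::filter(elig, !.data$subpopulation %in% drop)
  }
  elig |>
    dplyr::select("subpopulation", "genotype_id", "n_sites") |>
    dplyr::arrange(.data$subpopulation, .data$genotype_id)
}

#' Randomly assign genotypes to folds
#'
#' Balanced assignment (sizes differ by at most 1), deterministic given
#' the seed, and exchangeable in input order: genotype IDs are sorted
#' before the draw, so any permutation of the input yields the same map.
#'
#' @param genotypes Character vector of genotype IDs.
#' @param k Number of folds (default 8).
#' @param seed Integer seed.
#' @return Tibble `genotype_id`, `fold`.
#' @export
assign_folds <- function(genotypes, k = 8L, seed = 1L) {
  genotypes <- sort(unique(as.character(genotypes)))
  n <- length(genotypes)
  if (n < k) stop("fewer genotypes (", n, ") than folds (", k, ")", call. = FALSE)
  set.seed(as.integer(seed))
  fold <- sample(rep(seq_len(k), length.out = n))
  tibble::tibble(genotype_id = genotypes, fold = fold) |>
    dplyr::arrange(.data$genotype_id)
}

#' Training mask for one validation fold under a scenario
#'
#' Returns a logical matrix over the response (TRUE = cell hidden from
#' training). Training genotypes keep all their data. For each validation
#' genotype, the scenario decides which observed cells stay visible:
#' \describe{
#'   \item{CV1}{nothing — an untested genotype.}
#'   \item{CV2_k / B1 / B5}{`k` biomass sites sampled uniformly without
#'     replacement from the genotype's observed sites (all of them, with
#'     a message, if it has fewer than `k`); `B1`/`B5` are the
#'     resource-scenario names for `CV2_1`/`CV2_5`.}
#'   \item{FT / HT / FT_HT}{only the flowering-time and/or fall-height
#'     surrogate column(s).}
#'   \item{B1_FT}{one biomass site plus flowering time.}
#' }
#' All other observed cells of validation genotypes are masked.
#'
#' @param Y Response matrix ([build_response()]).
#' @param validation Character vector of validation genotype IDs (rows of
#'   `Y`).
#' @param scenario One of `r paste(CV_SCENARIOS, collapse = ", ")`.
#' @param seed Integer seed for the site sampling.
#' @return Logical mask matrix shaped like `Y`.
#' @export
build_training_mask <- function(Y, validation, scenario, seed = 1L) {
  stopifnot(is.matrix(Y))
  scenario <- as.character(scenario)
  if (!scenario %in% CV_SCENARIOS) {
    stop("unknown scenario: ", scenario, call. = FALSE)
  }
  surr_cols <- intersect(colnames(Y), PHENO_TRAITS)
  site_cols <- setdiff(colnames(Y), surr_cols)
  keep_surr <- switch(scenario,
    FT = "flowering_time", HT = "fall_height",
    FT_HT = c("flowering_time", "fall_height"), B1_FT = "flowering_time",
    character(0))
  n_bio <- switch(scenario,
    CV2_1 = , B1 = , B1_FT = 1L, CV2_2 = 2L, CV2_3 = 3L, CV2_4 = 4L,
    CV2_5 = , B5 = 5L, 0L)
  missing_surr <- setdiff(keep_surr, colnames(Y))
  if (length(missing_surr)) {
    stop("scenario ", scenario, " needs response column(s): ",
         paste(missing_surr, collapse = ", "), call. = FALSE)
  }
  mask <- matrix(FALSE, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  validation <- intersect(validation, rownames(Y))
  set.seed(as.integer(seed))
  for (gid in validation) {
    obs <- !is.na(Y[gid, ])
    keep <- rep(FALSE, ncol(Y))
    names(keep) <- colnames(Y)
    if (n_bio > 0L) {
      obs_sites <- site_cols[obs[site_cols]]
      if (length(obs_sites) <= n_bio) {
        if (length(obs_sites) < n_bio) {
          message(gid, ": only ", length(obs_sites),
                  " observed site(s) for a ", n_bio, "-site scenario; keeping all")
        }
        keep[obs_sites] <- TRUE
      } else {
        keep[sample(obs_sites, n_bio)] <- TRUE
      }
    }
    keep[keep_surr] <- TRUE
    mask[gid, ] <- obs & !keep
  }
  mask
}

#' Predictive ability per site
#'
#' Pearson correlation between predicted and observed genotype-by-site
#' means over validation genotypes, computed per site. Sites with fewer
#' than `min_pairs` prediction/observation pairs are flagged and carry a
#' missing `r`; zero-variance predictions also give a missing `r` (never
#' a 0).
#'
#' @param predictions Tibble `genotype_id`, `column`, `predicted`
#'   ([predict_masked()]).
#' @param observations Tibble `genotype_id`, `column`, `observed`.
#' @param min_pairs Minimum pairs per site.
#' @return Tibble `site`, `r`, `n_pairs`, `excluded`.
#' @export
predictive_ability <- function(predictions, observations, min_pairs = 3L) {
  dplyr::inner_join(predictions, observations,
                    by = c("genotype_id", "column")) |>
    dplyr::summarise(
      r = if (dplyr::n() >= min_pairs && stats::sd(.data$predicted) > 0 &&
              stats::sd(.data$observed) > 0)
        stats::cor(.data$predicted, .data$observed) else NA_real_,
      n_pairs = dplyr::n(),
      .by = "column") |>
    dplyr::rename(site = "column") |>
    dplyr::mutate(excluded = .data$n_pairs < min_pairs)
}

#' Run the full cross-validation scheme
#'
#' For each retained subpopulation and each scenario, genotypes are
#' assigned to `k` folds (re-randomised each replicate); fold by fold the
#' validation genotypes' data are masked according to the scenario, the
#' Gibbs model is fitted to the remaining response, masked biomass cells
#' are predicted, and per-site predictive ability is scored over exactly
#' the genotype-site cells whose observations were hidden. With the
#' reference design (`k = 8`, `reps = 5`) that is 40 model fits per
#' subpopulation per scenario.
#'
#' @param table Aggregated phenotype tibble.
#' @param info Genotype metadata (`genotype_id`, `subpopulation`,
#'   `admixed`).
#' @param G Relationship matrix covering all genotypes in `table`.
#' @param scenarios Character vector of scenarios to run.
#' @param reps Replicates of the whole k-fold cycle.
#' @param k Folds.
#' @param seed Master seed; every fold/replicate/scenario derives its own
#'   sub-seed from it.
#' @param chain List of Gibbs settings (`n_iter`, `burn_in`, `thin`).
#' @param min_sites,min_genotypes Eligibility rules
#'   ([eligible_validation_set()]).
#' @param surrogate_sites Reference sites for surrogate columns.
#' @return Object of class `"cv_result"`: tibble with one row per
#'   (subpopulation, scenario, replicate, fold, site).
#' @export
run_scheme <- function(table, info, G,
                       scenarios = c("CV1", "CV2_1", "CV2_5"),
                       reps = 5L, k = 8L, seed = 1L,
                       chain = list(n_iter = 3000L, burn_in = 200L, thin = 5L),
                       min_sites = 6L, min_genotypes = 60L,
                       surrogate_sites = c("KBSM", "CLMB")) {
  check_phenotypes(table)
  stopifnot(all(scenarios %in% CV_SCENARIOS))
  elig <- eligible_validation_set(table, info, min_sites, min_genotypes)
  if (nrow(elig) == 0L) stop("no eligible validation genotypes", call. = FALSE)
  need_surr <- any(scenarios %in% c("FT", "HT", "FT_HT", "B1_FT"))
  surrogates <- if (need_surr) c("flowering_time", "fall_height") else NULL
  subpops <- unique(elig$subpopulation)

  res <- purrr::map(seq_along(subpops), function(si) {
    sp <- subpops[si]
    ids_sp <- info$genotype_id[info$subpopulation == sp]
    Y <- build_response(dplyr::filter(table, .data$genotype_id %in% ids_sp),
                        surrogates = surrogates,
                        surrogate_sites = surrogate_sites, scale = TRUE)
    obs_tbl <- tidy_response(Y)
    val_ids <- elig$genotype_id[elig$subpopulation == sp]
    purrr::map(seq_len(reps), function(rp) {
      folds <- assign_folds(val_ids, k = k, seed = mix_seed(seed, si, rp))
      purrr::map(scenarios, function(sc) {
        purrr::map(seq_len(k), function(fd) {
          active <- folds$genotype_id[folds$fold == fd]
          msk <- build_training_mask(Y, active, sc,
                                     seed = mix_seed(seed, si, rp, match(sc, CV_SCENARIOS), fd))
          Yt <- Y
          Yt[msk] <- NA
          post <- run_gibbs(Yt, G, n_iter = chain$n_iter,
                            burn_in = chain$burn_in, thin = chain$thin,
                            seed = mix_seed(seed, si, rp,
                                            match(sc, CV_SCENARIOS), fd, 99L))
          site_cols <- setdiff(colnames(Y), PHENO_TRAITS)
          score_mask <- msk
          score_mask[, intersect(colnames(Y), PHENO_TRAITS)] <- FALSE
          preds <- predict_masked(post, score_mask)
          predictive_ability(preds, obs_tbl) |>
            dplyr::mutate(subpopulation = sp, scenario = sc,
                          replicate = rp, fold = fd, .before = 1)
        }) |> purrr::list_rbind()
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  structure(res, class = c("cv_result", class(res)))
}

tidy_response <- function(Y) {
  tibble::as_tibble(unclass(Y), rownames = "genotype_id") |>
    tidyr::pivot_longer(-"genotype_id", names_to = "column",
                        values_to = "observed") |>
    dplyr::filter(!is.na(.data$observed))
}

#' Summarise predictive ability
#'
#' Unweighted means in the order site, then fold, then replicate, ending
#' with one mean ability per (subpopulation, scenario); sites flagged by
#' the minimum-pair rule are excluded.
#'
#' @param result A `"cv_result"` tibble.
#' @return Tibble `subpopulation`, `scenario`, `ability`, `n_cells`.
#' @export
cv_summary <- function(result) {
  result |>
    dplyr::filter(!.data$excluded, !is.na(.data$r)) |>
    dplyr::summarise(r = mean(.data$r), n = sum(.data$n_pairs),
                     .by = c("subpopulation", "scenario", "replicate", "fold")) |>
    dplyr::summarise(r = mean(.data$r), n = sum(.data$n),
                     .by = c("subpopulation", "scenario", "replicate")) |>
    dplyr::summarise(ability = mean(.data$r), n_cells = sum(.data$n),
                     .by = c("subpopulation", "scenario"))
}

#' Structural audit of a cross-validation scheme
#'
#' Rebuilds every fold/replicate mask without fitting anything and checks
#' the bookkeeping: folds partition the eligible set, masked and kept
#' cells of each validation genotype are disjoint and together exhaust
#' its observed cells, no training-row cell is ever masked, and the
#' number of planned model fits per subpopulation per scenario is
#' `k * reps`.
#'
#' @inheritParams run_scheme
#' @return Tibble with one row per (subpopulation, scenario):
#'   `n_fits`, `leakage_cells`, `folds_partition`, `masks_consistent`.
#' @export
cv_audit <- function(table, info, scenarios = c("CV1", "CV2_1", "CV2_5"),
                     reps = 5L, k = 8L, seed = 1L,
                     min_sites = 6L, min_genotypes = 60L,
                     surrogate_sites = c("KBSM", "CLMB")) {
  elig <- eligible_validation_set(table, info, min_sites, min_genotypes)
  need_surr <- any(scenarios %in% c("FT", "HT", "FT_HT", "B1_FT"))
  surrogates <- if (need_surr) c("flowering_time", "fall_height") else NULL
  subpops <- unique(elig$subpopulation)
  purrr::map(seq_along(subpops), function(si) {
    sp <- subpops[si]
    ids_sp <- info$genotype_id[info$subpopulation == sp]
    Y <- build_response(dplyr::filter(table, .data$genotype_id %in% ids_sp),
                        surrogates = surrogates,
                        surrogate_sites = surrogate_sites, scale = TRUE)
    val_ids <- elig$genotype_id[elig$subpopulation == sp]
    purrr::map(scenarios, function(sc) {
      n_fits <- 0L; leak <- 0L
      partition_ok <- TRUE; consistent <- TRUE
      for (rp in seq_len(reps)) {
        folds <- assign_folds(val_ids, k = k, seed = mix_seed(seed, si, rp))
        partition_ok <- partition_ok &&
          setequal(folds$genotype_id, val_ids) &&
          !anyDuplicated(folds$genotype_id) &&
          max(table(folds$fold)) - min(table(folds$fold)) <= 1L
        for (fd in seq_len(k)) {
          n_fits <- n_fits + 1L
          active <- folds$genotype_id[folds$fold == fd]
          msk <- build_training_mask(Y, active, sc,
                                     seed = mix_seed(seed, si, rp, match(sc, CV_SCENARIOS), fd))
          train_rows <- setdiff(rownames(Y), active)
          leak <- leak + sum(msk[train_rows, ])
          obs <- !is.na(Y[active, , drop = FALSE])
          kept <- obs & !msk[active, , drop = FALSE]
          consistent <- consistent &&
            all((kept | msk[active, , drop = FALSE]) == obs) &&
            !any(kept & msk[active, , drop = FALSE])
          # scored cells must be hidden from the training response
          Yt <- Y; Yt[msk] <- NA
          leak <- leak + sum(!is.na(Yt[active, , drop = FALSE]) &
                               msk[active, , drop = FALSE])
        }
      }
      tibble::tibble(subpopulation = sp, scenario = sc, n_fits = n_fits,
                     leakage_cells = leak, folds_partition = partition_ok,
                     masks_consistent = consistent)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

#' Plot mean predictive ability per scenario
#'
#' @param object A `"cv_result"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_result <- function(object, ...) {
  s <- cv_summary(object)
  ggplot2::ggplot(s, ggplot2::aes(.data$scenario, .data$ability,
                                  fill = .data$subpopulation)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "predictive ability (r)", fill = NULL) +
    ggplot2::theme_minimal()
}
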