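#' Synthetic diversity-panel generator
#'
#' Generates structured genotypes (Balding–Nichols subpopulation model)
#' and multi-site, multi-trait phenotypes carrying the statistical
#' structure the analysis assumes: genotype-by-environment correlations
#' decaying along the latitudinal site gradient, subpopulation-by-region
#' adaptation contrasts, yield surrogates genetically correlated with
#' biomass, unbalanced site replication, and winterkill-style dead-plant
#' zeros — so every analysis stage is testable without any download.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults emulate the diversity-panel study conditions: four
#' subpopulations sized as the study's validation populations, ten sites
#' over 17 degrees of latitude, genotype-by-environment correlation
#' decaying at 0.12 per degree of latitude (giving north–south site
#' correlations near 0.15 and within-region correlations near 0.8),
#' genetic correlations of 0.85 (height–biomass), 0.45
#' (flowering–biomass) and 0.31 (flowering–height), single-year biomass
#' heritability 0.6, and the study's replication profile (53% of
#' genotypes at 8–10 sites, 36% at 5 or fewer).
#'
#' @param n_genotypes Named integer vector of genotypes per
#'   subpopulation.
#' @param n_markers Number of biallelic markers.
#' @param fst Balding–Nichols divergence among subpopulations.
#' @param sites Site tibble ([switchgrass_sites()]).
#' @param decay GxE correlation decay per degree of latitude.
#' @param h2 Named single-observation heritabilities per trait.
#' @param r_bh,r_bf,r_hf Genetic correlations: biomass–height,
#'   biomass–flowering, height–flowering.
#' @param rep_profile Fractions of genotypes at 8–10 and at <= 5 sites
#'   (the remainder sit at 6–7).
#' @param missing_rate Fraction of missing marker calls sprinkled in.
#' @param admixed_frac Fraction of genotypes flagged admixed.
#' @param sigma_g Genetic standard deviations per trait (sqrt-g, cm,
#'   days).
#' @param trait_means Trait grand means.
#' @param lat_slope Per-trait change per unit of scaled latitude in the
#'   site means (biomass declines northward; height shorter, flowering
#'   later).
#' @param contrast Subpopulation-by-region adaptation contrast (sqrt-g):
#'   Midwest/Coastal gain it at the northern extreme and lose it at the
#'   southern extreme, Texas/Gulf the reverse.
#' @param dead_threshold Genetic deficit (sqrt-g) below which a genotype
#'   at a South-region site is recorded dead (biomass 0) with
#'   probability 0.5.
#' @param n_years Years of records per genotype-site cell.
#' @return A `"sim_config"` list.
#' @export
sim_config <- function(n_genotypes = c(Texas = 119, Coastal = 147,
                                       Midwest = 67, Gulf = 51),
                       n_markers = 2000L,
                       fst = 0.15,
                       sites = switchgrass_sites(),
                       decay = 0.12,
                       h2 = c(biomass = 0.6, fall_height = 0.65,
                              flowering_time = 0.7),
                       r_bh = 0.85, r_bf = 0.45, r_hf = 0.31,
                       rep_profile = c(high = 0.53, low = 0.36),
                       missing_rate = 0.02,
                       admixed_frac = 0.10,
                       sigma_g = c(biomass = 3, fall_height = 20,
                                   flowering_time = 12),
                       trait_means = c(biomass = 16, fall_height = 150,
                                       flowering_time = 185),
                       lat_slope = c(biomass = -3, fall_height = -10,
                                     flowering_time = 8),
                       contrast = 2,
                       dead_threshold = -4,
                       n_years = 3L) {
  Rt <- matrix(c(1, r_bh, r_bf,
                 r_bh, 1, r_hf,
                 r_bf, r_hf, 1), 3, 3,
               dimnames = rep(list(c("biomass", "fall_height",
                                     "flowering_time")), 2))
  if (min(eigen(Rt, symmetric = TRUE, only.values = TRUE)$values) < 0) {
    stop("trait correlation targets do not form a PSD matrix", call. = FALSE)
  }
  stopifnot(sum(rep_profile) <= 1, all(rep_profile >= 0),
            fst > 0, fst < 1)
  structure(list(
    n_genotypes = n_genotypes, n_markers = as.integer(n_markers), fst = fst,
    sites = sites, decay = decay, h2 = h2,
    trait_cor = Rt, rep_profile = rep_profile,
    missing_rate = missing_rate, admixed_frac = admixed_frac,
    sigma_g = sigma_g, trait_means = trait_means, lat_slope = lat_slope,
    contrast = contrast, dead_threshold = dead_threshold,
    n_years = as.integer(n_years)
  ), class = "sim_config")
}

#' Simulate structured genotypes
#'
#' Balding–Nichols model: ancestral allele frequencies uniform on
#' (0.05, 0.95); each subpopulation draws its own frequency from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`; individual dosages are
#' `Binomial(2, p_subpop)`. Missing calls are sprinkled at the configured
#' rate.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List: `dosage` (matrix) and `info` tibble (`genotype_id`,
#'   `subpopulation`, `admixed`).
#' @export
simulate_genotypes <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  m <- config$n_markers
  pops <- names(config$n_genotypes)
  p_anc <- runif(m, 0.05, 0.95)
  F <- config$fst
  a <- p_anc * (1 - F) / F
  b <- (1 - p_anc) * (1 - F) / F
  rows <- list()
  info <- list()
  for (sp in pops) {
    n_sp <- config$n_genotypes[[sp]]
    p_sp <- rbeta(m, a, b)
    d <- matrix(rbinom(n_sp * m, 2L, rep(p_sp, each = n_sp)), n_sp, m)
    ids <- sprintf("%s_%03d", toupper(substr(sp, 1, 2)), seq_len(n_sp))
    rownames(d) <- ids
    rows[[sp]] <- d
    info[[sp]] <- tibble::tibble(genotype_id = ids, subpopulation = sp)
  }
  dosage <- do.call(rbind, rows)
  colnames(dosage) <- sprintf("M%05d", seq_len(m))
  if (config$missing_rate > 0) {
    nmiss <- round(config$missing_rate * length(dosage))
    dosage[sample(length(dosage), nmiss)] <- NA
  }
  info <- purrr::list_rbind(info) |>
    dplyr::mutate(admixed = runif(dplyr::n()) < config$admixed_frac)
  list(dosage = dosage, info = info)
}

site_correlation <- function(sites, decay) {
  lat <- sites$latitude
  C <- exp(-decay * abs(outer(lat, lat, "-")))
  dimnames(C) <- list(sites$site, sites$site)
  C
}

#' Simulate multi-site, multi-trait phenotypes
#'
#' Breeding values are drawn from `MVN(0, Ta_true (x) G)` with `G`
#' computed from the supplied dosages and `Ta_true` assembled from the
#' latitudinal site-correlation matrix (biomass columns) and the
#' configured trait correlations (surrogate columns built on the
#' genotype's overall biomass factor, so they carry no site-specific
#' GxE). Site means follow the latitude gradient, subpopulations gain
#' their adaptation contrast near home regions, year-level residual
#' noise is sized per column to hit the target heritabilities,
#' replication is thinned to the configured profile, biomass is reported
#' on the sqrt-gram scale truncated at zero, and maladapted genotypes at
#' southern sites are recorded dead with probability one half.
#'
#' @param dosage Dosage matrix from [simulate_genotypes()] (missing calls
#'   allowed; they are mean-imputed for the kinship).
#' @param info Genotype metadata tibble.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List: `phenotypes` (long tibble with `year`), `truth` (list:
#'   `bv` genotype x column genetic values, `Ta` the true column
#'   covariance, `site_cor`, `G`, `biomass_factor`), and `info`.
#' @export
simulate_phenotypes <- function(dosage, info, config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  G <- realized_relationship(impute_missing(dosage))
  n <- nrow(G)
  ids <- rownames(G)
  sites <- config$sites
  ns <- nrow(sites)
  C <- site_correlation(sites, config$decay)
  # decay = 0 collapses C to rank one; ridge only when the factorization
  # needs it so the recorded truth covariance stays exact otherwise
  Lc <- tryCatch(t(chol(C)),
                 error = function(e) t(chol(C + diag(1e-8, nrow(C)))))
  U <- chol(unclass(G) + diag(1e-8, n)) # upper, G = U'U

  sg <- config$sigma_g
  # latent iid-N(0, G) columns: ns for biomass + 2 for surrogate noise
  Zl <- crossprod(U, matrix(rnorm(n * (ns + 2L)), n, ns + 2L))
  # weights mapping latents to output columns (so Ta_true = t(Om) %*% Om)
  w_b <- as.vector(t(Lc) %*% rep(1 / ns, ns))
  w_b <- w_b / sqrt(sum(w_b^2))         # biomass factor direction
  rt <- config$trait_cor
  ch <- (rt["flowering_time", "fall_height"] -
           rt["biomass", "fall_height"] * rt["biomass", "flowering_time"]) /
    sqrt(1 - rt["biomass", "fall_height"]^2)
  Om <- matrix(0, ns + 2L, ns + 2L)
  Om[seq_len(ns), seq_len(ns)] <- sg[["biomass"]] * t(Lc)
  Om[seq_len(ns), ns + 1L] <- sg[["fall_height"]] *
    rt["biomass", "fall_height"] * w_b
  Om[ns + 1L, ns + 1L] <- sg[["fall_height"]] *
    sqrt(1 - rt["biomass", "fall_height"]^2)
  Om[seq_len(ns), ns + 2L] <- sg[["flowering_time"]] *
    rt["biomass", "flowering_time"] * w_b
  Om[ns + 1L, ns + 2L] <- sg[["flowering_time"]] * ch
  Om[ns + 2L, ns + 2L] <- sg[["flowering_time"]] *
    sqrt(max(0, 1 - rt["biomass", "flowering_time"]^2 - ch^2))
  BV <- Zl %*% Om
  colnames(BV) <- c(sites$site, "fall_height", "flowering_time")
  rownames(BV) <- ids
  Ta_true <- crossprod(Om)
  dimnames(Ta_true) <- list(colnames(BV), colnames(BV))

  # subpopulation-by-region adaptation contrast on biomass columns
  lat_score <- 2 * (sites$latitude - min(sites$latitude)) /
    diff(range(sites$latitude)) - 1
  north_aff <- c(Midwest = 1, Coastal = 1, Texas = -1, Gulf = -1)
  aff <- north_aff[info$subpopulation[match(ids, info$genotype_id)]]
  shift <- config$contrast * outer(aff, lat_score)
  colnames(shift) <- sites$site
  gv_bio <- BV[, sites$site, drop = FALSE] + shift

  # site means per trait
  mu_site <- sapply(c("biomass", "fall_height", "flowering_time"),
                    function(tr) config$trait_means[[tr]] +
                      config$lat_slope[[tr]] * lat_score)
  rownames(mu_site) <- sites$site

  # replication profile: number of sites per genotype
  pr <- config$rep_profile
  cat_draw <- sample(c("high", "low", "mid"), n, replace = TRUE,
                     prob = c(pr[["high"]], pr[["low"]],
                              1 - pr[["high"]] - pr[["low"]]))
  n_sites_g <- ifelse(cat_draw == "high", sample(8:10, n, replace = TRUE),
               ifelse(cat_draw == "low", sample(3:5, n, replace = TRUE),
                      sample(6:7, n, replace = TRUE)))
  n_sites_g <- pmin(n_sites_g, ns)

  # residual year-level noise sized to the target heritability per column
  sd_noise <- function(tr, genetic_col) {
    vg <- stats::var(genetic_col)
    sqrt(vg * (1 - config$h2[[tr]]) / config$h2[[tr]])
  }
  south_sites <- sites$site[sites$region == "South"]

  recs <- vector("list", n)
  years <- seq(2019L, length.out = config$n_years)
  for (i in seq_len(n)) {
    ss <- sample(sites$site, n_sites_g[i])
    g_rec <- vector("list", length(ss))
    for (k in seq_along(ss)) {
      s <- ss[k]
      dead <- s %in% south_sites &&
        (BV[i, s] + shift[i, s]) < config$dead_threshold &&
        runif(1) < 0.5
      bio_noise <- sd_noise("biomass", gv_bio[, s])
      bio <- if (dead) rep(0, config$n_years) else
        pmax(0, mu_site[s, "biomass"] + gv_bio[i, s] +
               rnorm(config$n_years, 0, bio_noise))
      ht <- pmax(0, mu_site[s, "fall_height"] + BV[i, "fall_height"] +
                   rnorm(config$n_years, 0,
                         sd_noise("fall_height", BV[, "fall_height"])))
      fl <- pmin(366, pmax(1, mu_site[s, "flowering_time"] +
                             BV[i, "flowering_time"] +
                             rnorm(config$n_years, 0,
                                   sd_noise("flowering_time",
                                            BV[, "flowering_time"]))))
      g_rec[[k]] <- tibble::tibble(
        genotype_id = ids[i], site = s, year = rep(years, 3L),
        trait = rep(c("biomass", "fall_height", "flowering_time"),
                    each = config$n_years),
        value = c(bio, ht, fl))
    }
    recs[[i]] <- purrr::list_rbind(g_rec)
  }
  phen <- purrr::list_rbind(recs)

  truth <- list(
    bv = cbind(gv_bio, BV[, c("fall_height", "flowering_time")]),
    Ta = Ta_true,
    site_cor = C,
    G = G,
    biomass_factor = as.vector(Zl[, seq_len(ns)] %*% w_b *
                                 sg[["biomass"]]))
  names(truth$biomass_factor) <- ids
  list(phenotypes = phen, truth = truth, info = info)
}

#' Write a self-contained synthetic fixture to disk
#'
#' Sizes: `tiny` (40 genotypes x 200 markers x 4 sites — seconds,
#' round-trip checks), `small` (300 x 2,000 x 10) and `paperlike`
#' (384 x 5,000 x 10 with the study's subpopulation sizes and
#' replication profile). Writes `dosage.tsv`, `phenotypes.tsv`,
#' `sites.tsv`, `info.tsv` and `truth.json`.
#'
#' @param size `"tiny"`, `"small"` or `"paperlike"`.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return (Invisibly) a list with the generated objects and paths.
#' @export
make_fixture <- function(size = c("tiny", "small", "paperlike"),
                         seed = 1L, dir = tempfile("fixture")) {
  size <- match.arg(size)
  cfg <- switch(size,
    tiny = sim_config(
      n_genotypes = c(Texas = 10, Coastal = 10, Midwest = 10, Gulf = 10),
      n_markers = 200L,
      sites = dplyr::filter(switchgrass_sites(),
                            .data$site %in% c("KING", "STIL", "CLMB", "BRKG"))),
    small = sim_config(
      n_genotypes = c(Texas = 93, Coastal = 115, Midwest = 52, Gulf = 40),
      n_markers = 2000L),
    paperlike = sim_config(n_markers = 5000L))
  gen <- simulate_genotypes(cfg, seed = seed)
  sim <- simulate_phenotypes(gen$dosage, gen$info, cfg, seed = seed + 1L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    dosage = file.path(dir, "dosage.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    sites = file.path(dir, "sites.tsv"),
    info = file.path(dir, "info.tsv"),
    truth = file.path(dir, "truth.json"))
  write_dosage(gen$dosage, paths$dosage)
  write_phenotypes(sim$phenotypes, paths$phenotypes)
  write_sites(cfg$sites, paths$sites)
  readr::write_tsv(gen$info, paths$info)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(Ta = sim$truth$Ta, site_cor = sim$truth$site_cor,
           seed = seed, size = size),
      paths$truth, digits = NA, matrix = "rowmajor")
  }
  invisible(list(config = cfg, dosage = gen$dosage, info = gen$info,
                 phenotypes = sim$phenotypes, truth = sim$truth,
                 paths = paths))
}
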