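test_that("validation eligibility applies the more-than-5-sites boundary", {
  info <- tibble::tibble(
    genotype_id = c("a", "b", "c", "d"),
    subpopulation = "Texas", admixed = c(FALSE, FALSE, FALSE, TRUE))
  tab <- tibble::tibble(
    genotype_id = rep(c("a", "b", "c", "d"), times = c(5, 6, 7, 8)),
    site = c(paste0("S", 1:5), paste0("S", 1:6), paste0("S", 1:7),
             paste0("S", 1:8)),
    trait = "biomass", value = 10)
  elig <- eligible_validation_set(tab, info, min_genotypes = 1)
  # 5 sites excluded, 6 included; admixed excluded regardless
  expect_setequal(elig$genotype_id, c("b", "c"))

  # small subpopulations are dropped (51 eligible < 60 threshold)
  info2 <- tibble::tibble(genotype_id = sprintf("g%03d", 1:51),
                          subpopulation = "Gulf", admixed = FALSE)
  tab2 <- tidyr::expand_grid(genotype_id = info2$genotype_id,
                             site = paste0("S", 1:6)) |>
    dplyr::mutate(trait = "biomass", value = 12)
  expect_warning(e2 <- eligible_validation_set(tab2, info2), "Gulf")
  expect_equal(nrow(e2), 0L)

  # counting oracle on a synthetic fixture
  fx <- small_fixture()
  agg <- aggregate_phenotypes(fx$phenotypes)
  suppressWarnings(e3 <- eligible_validation_set(agg, fx$info,
                                                 min_genotypes = 1))
  counts <- agg |>
    dplyr::filter(trait == "biomass") |>
    dplyr::summarise(n = dplyr::n_distinct(site), .by = genotype_id)
  oracle <- counts$genotype_id[counts$n >= 6]
  oracle <- setdiff(oracle, fx$info$genotype_id[fx$info$admixed])
  expect_setequal(e3$genotype_id, oracle)
})

test_that("fold assignment is balanced, deterministic and exchangeable", {
  g80 <- sprintf("g%03d", 1:80)
  f <- assign_folds(g80, k = 8, seed = 3)
  expect_equal(unname(table(f$fold)), rep(10L, 8), ignore_attr = TRUE)

  g83 <- sprintf("g%03d", 1:83)
  f83 <- assign_folds(g83, k = 8, seed = 3)
  expect_setequal(as.integer(table(f83$fold)), c(10L, 11L))
  expect_equal(sum(table(f83$fold)), 83L)

  expect_identical(assign_folds(g83, k = 8, seed = 3), f83)
  # shuffled input, same seed policy on sorted IDs -> same map
  expect_identical(assign_folds(sample(g83), k = 8, seed = 3), f83)
  expect_error(assign_folds(g80[1:5], k = 8), "fewer genotypes")
})

test_that("training masks implement each scenario's visibility rule", {
  set.seed(2)
  Y <- matrix(rnorm(20 * 12), 20, 12,
              dimnames = list(sprintf("g%02d", 1:20),
                              c(switchgrass_sites()$site,
                                "flowering_time", "fall_height")))
  Y[1, 3] <- NA                      # g01 unobserved at one site
  val <- c("g01", "g02", "g03")

  m_cv1 <- build_training_mask(Y, val, "CV1", seed = 1)
  Yt <- Y; Yt[m_cv1] <- NA
  expect_true(all(is.na(Yt[val, ])))           # fully hidden
  expect_identical(Yt[setdiff(rownames(Y), val), ],
                   Y[setdiff(rownames(Y), val), ])

  # CV2_5 on a genotype with 9 observed sites: 5 kept, 4 masked
  m5 <- build_training_mask(Y, "g01", "CV2_5", seed = 1)
  expect_equal(sum(m5["g01", switchgrass_sites()$site]), 4L)
  expect_equal(sum(m5["g01", c("flowering_time", "fall_height")]), 2L)

  # FT keeps only the flowering column
  mft <- build_training_mask(Y, "g02", "FT", seed = 1)
  expect_false(mft["g02", "flowering_time"])
  expect_true(all(mft["g02", switchgrass_sites()$site]))
  expect_true(mft["g02", "fall_height"])

  # B1_FT keeps one biomass site plus flowering
  mb <- build_training_mask(Y, "g02", "B1_FT", seed = 1)
  expect_equal(sum(!mb["g02", switchgrass_sites()$site]), 1L)
  expect_false(mb["g02", "flowering_time"])

  # masked-cell inventory equals the set-difference oracle
  m2 <- build_training_mask(Y, val, "CV2_2", seed = 7)
  for (g in val) {
    obs <- which(!is.na(Y[g, ]))
    kept <- which(!is.na(Y[g, ]) & !m2[g, ])
    expect_equal(sort(c(kept, which(m2[g, ]))), obs)
    expect_length(intersect(kept, which(m2[g, ])), 0)
  }
  expect_error(build_training_mask(Y, val, "XX"), "unknown scenario")

  # genotype with fewer observed sites than k keeps all, with a message
  Ythin <- Y; Ythin["g04", switchgrass_sites()$site[-(1:3)]] <- NA
  expect_message(mth <- build_training_mask(Ythin, "g04", "CV2_5", seed = 1),
                 "keeping all")
  expect_equal(sum(mth["g04", switchgrass_sites()$site]), 0L)
})

test_that("predictive ability is a per-site Pearson correlation with guards", {
  obs <- tibble::tibble(genotype_id = sprintf("g%d", 1:5), column = "S1",
                        observed = c(3, 1, 4, 1, 5))
  pred <- dplyr::mutate(obs, predicted = observed) |>
    dplyr::select(-observed)
  expect_equal(predictive_ability(pred, obs)$r, 1)
  pred2 <- dplyr::mutate(pred, predicted = -predicted)
  expect_equal(predictive_ability(pred2, obs)$r, -1)

  pred3 <- dplyr::mutate(pred, predicted = c(2.2, 0.5, 3.9, 1.4, 4.4))
  expect_equal(predictive_ability(pred3, obs)$r,
               cor(c(2.2, 0.5, 3.9, 1.4, 4.4), obs$observed))

  # fewer than 3 pairs: flagged, r missing
  out <- predictive_ability(pred[1:2, ], obs[1:2, ])
  expect_true(out$excluded)
  expect_true(is.na(out$r))

  # zero-variance predictions: r missing, never 0
  pred4 <- dplyr::mutate(pred, predicted = 7)
  expect_true(is.na(predictive_ability(pred4, obs)$r))
})

test_that("the scheme audit finds no leakage and the reference fit count", {
  fx <- small_fixture()
  agg <- aggregate_phenotypes(fx$phenotypes)
  suppressWarnings(
    audit <- cv_audit(agg, fx$info,
                      scenarios = c("CV1", "CV2_2", "B5", "FT_HT", "B1_FT"),
                      reps = 5, k = 8, seed = 11)
  )
  expect_gt(nrow(audit), 0)
  expect_true(all(audit$leakage_cells == 0))
  expect_true(all(audit$n_fits == 40L))      # 8 folds x 5 reps
  expect_true(all(audit$folds_partition))
  expect_true(all(audit$masks_consistent))
})

test_that("a small scheme run returns finite abilities in tidy form", {
  fx <- small_fixture()
  agg <- aggregate_phenotypes(fx$phenotypes)
  suppressWarnings(
    res <- run_scheme(agg, fx$info, fx$truth$G,
                      scenarios = c("CV1", "B1"),
                      reps = 1, k = 2, seed = 15,
                      chain = list(n_iter = 500, burn_in = 100, thin = 5))
  )
  expect_s3_class(res, "cv_result")
  expect_setequal(unique(res$scenario), c("CV1", "B1"))
  s <- cv_summary(res)
  expect_true(all(is.finite(s$ability)))
  expect_true(all(s$ability >= -1 & s$ability <= 1))
  # partially tested genotypes beat untested ones
  wide <- tidyr::pivot_wider(s, names_from = "scenario",
                             values_from = "ability",
                             id_cols = "subpopulation")
  expect_true(all(wide$B1 > wide$CV1))
})
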