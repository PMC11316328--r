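test_that("k-fold plans partition 738 accessions into sizes 73/74", {
  plans <- kfold_plan(738, 10, seed = 100)
  sizes <- sort(vapply(plans, function(p) length(p$test), integer(1)))
  expect_equal(sizes, c(73L, 73L, 74L, 74L, 74L, 74L, 74L, 74L, 74L, 74L))
  tests <- unlist(lapply(plans, `[[`, "test"))
  expect_equal(sort(tests), 1:738)           # union covers everything once
  for (p in plans) {
    expect_length(intersect(p$train, p$test), 0L)
    expect_equal(sort(c(p$train, p$test)), 1:738)
  }
  expect_identical(kfold_plan(738, 10, seed = 100), plans)  # deterministic
  expect_false(identical(kfold_plan(738, 10, seed = 101), plans))
  expect_error(kfold_plan(100, 1), "k")
  expect_error(kfold_plan(5, 10), "n")
})

test_that("across-population plans hold out the distant groups", {
  groups <- rep(c("IND", "JAP", "AUS", "ARO", "ADM"),
                c(451, 166, 75, 17, 29))
  plan <- across_population_plan(groups)
  expect_equal(length(plan$test), 46L)
  expect_equal(length(plan$train), 692L)
  expect_setequal(unique(groups[plan$test]), c("ARO", "ADM"))
  expect_equal(sort(c(plan$train, plan$test)), seq_along(groups))
  expect_error(across_population_plan(groups,
                                      holdout = unique(groups)), "empty training")
  expect_error(across_population_plan(groups, holdout = "XXX"), "holdout")
})

test_that("inner splits take the floor-20% validation share", {
  s <- inner_split(1:100, 0.2, seed = 102)
  expect_length(s$validation, 20L)
  expect_length(s$train, 80L)
  s2 <- inner_split(1:101, 0.2, seed = 102)
  expect_length(s2$validation, 20L)
  expect_length(s2$train, 81L)
  expect_setequal(c(s$train, s$validation), 1:100)
  expect_length(intersect(s$train, s$validation), 0L)
  expect_error(inner_split(1:100, 1.2), "fraction")
  expect_error(inner_split(1:3), "too small")
})

test_that("mse matches hand values and scales quadratically", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(0, 0), c(1, 3)), 5)
  y <- rnorm(10); yh <- rnorm(10)
  expect_equal(mse(3 * y, 3 * yh), 9 * mse(y, yh), tolerance = 1e-12)
  expect_error(mse(1:3, 1:4), "length")
})

test_that("binary cross-entropy matches hand values", {
  expect_equal(binary_cross_entropy(c(0, 1), c(0.5, 0.5)), log(2))
  expect_equal(binary_cross_entropy(c(1, 0), c(0.9, 0.2)),
               -(log(0.9) + log(0.8)) / 2)
  expect_equal(binary_cross_entropy(c(1, 0), c(0.9, 0.2)), 0.16425,
               tolerance = 1e-4)
  expect_lt(binary_cross_entropy(c(1, 0, 1), c(1, 0, 1)), 1e-10)
  expect_error(binary_cross_entropy(c(0, 2), c(0.5, 0.5)), "0/1")
})

test_that("a small experiment produces one row per cell with sane losses", {
  sim <- small_panel(seed = 103, n = c(IND = 50, JAP = 35, AUS = 25,
                                       ARO = 10, ADM = 10),
                     markers = c(SNP = 150, `MITE-DTX` = 25, `RLX-RIX` = 20,
                                 DEL = 40, DUP = 20, INV = 15),
                     fst = 0.08)
  ph <- simulate_phenotypes(
    sim$genotypes,
    trait_spec("quantitative", h2 = 0.6,
               class_variance_shares = c(SNP = 0.5, DEL = 0.5),
               n_causal_per_class = 15, seed = 5),
    "gw", sim$groups)
  phb <- simulate_phenotypes(
    sim$genotypes,
    trait_spec("binary", h2 = 0.6,
               class_variance_shares = c(SNP = 1),
               n_causal_per_class = 20, seed = 6),
    "cd", sim$groups)
  P <- phenotype_table(sim$genotypes$accession_ids, sim$groups,
                       data.frame(gw = ph$phenotypes$traits$gw,
                                  cd = phb$phenotypes$traits$cd),
                       c(gw = "quantitative", cd = "binary"))
  rep <- run_experiment(
    sim$genotypes, P, traits = c("gw", "cd"), scheme = "kfold", k = 2,
    models = c("rkhs", "bayesc", "mlp", "multi_input"),
    strategies = c("COMBINED_VARIANTS", "SNPS", "MULTIPLE_INPUTS"),
    top_k = 60, mcmc = test_mcmc_settings(2000, 200, 2),
    tuner = list(n_configs = 2L, first_epochs = 2L, max_epochs = 5L,
                 patience = 2L, batch_size = 16L),
    seed = 104)
  L <- rep$losses
  # cells: rkhs x {CV, SNPS, MI}, bayesc x {CV, SNPS}, mlp x {CV, SNPS},
  # multi_input x {MI} = 8 cells x 2 folds x 2 traits
  expect_equal(nrow(L), 8L * 2L * 2L)
  expect_true(all(!is.na(L$loss)),
              info = paste(unique(na.omit(L$error)), collapse = " | "))
  expect_true(all(L$loss >= 0))
  expect_true(all(L$metric[L$trait == "gw"] == "MSE"))
  expect_true(all(L$metric[L$trait == "cd"] == "binary_cross_entropy"))
  # summary has one row per trait x scheme with the minimal mean loss
  expect_equal(nrow(rep$summary), 2L)
  agg <- aggregate(loss ~ trait + model + strategy, L, mean)
  for (tr in c("gw", "cd")) {
    expect_equal(rep$summary$loss[rep$summary$trait == tr],
                 min(agg$loss[agg$trait == tr]))
  }
  expect_equal(rep$meta$binary_mapping, "class {1,2} -> {0,1}")
})

test_that("failed cells are logged, not dropped", {
  sim <- small_panel(seed = 105, n = c(A = 40),
                     markers = c(SNP = 60))  # no SVs: multi-input must fail
  ph <- simulate_phenotypes(sim$genotypes,
                            trait_spec("quantitative", h2 = 0.5,
                                       n_causal_per_class = 10, seed = 7),
                            "t", sim$groups)
  rep <- run_experiment(sim$genotypes, ph$phenotypes, scheme = "kfold", k = 2,
                        models = c("rkhs", "multi_input"),
                        strategies = c("SNPS", "MULTIPLE_INPUTS"),
                        top_k = 30, mcmc = test_mcmc_settings(1000, 100, 2),
                        seed = 106)
  L <- rep$losses
  mi <- L[L$model == "multi_input", ]
  expect_true(all(is.na(mi$loss)))
  expect_true(all(grepl("six marker classes", mi$error)))
  expect_true(all(!is.na(L$loss[L$model == "rkhs"])))
})

test_that("the across-population scheme trains on the large groups only", {
  sim <- small_panel(seed = 107, n = c(IND = 40, JAP = 30, AUS = 20,
                                       ARO = 8, ADM = 8),
                     markers = c(SNP = 120, DEL = 30), fst = 0.08)
  ph <- simulate_phenotypes(sim$genotypes,
                            trait_spec("quantitative", h2 = 0.6,
                                       class_variance_shares = c(SNP = 1),
                                       n_causal_per_class = 20, seed = 8),
                            "t", sim$groups)
  rep <- run_experiment(sim$genotypes, ph$phenotypes,
                        scheme = "across_population",
                        models = "rkhs", strategies = "SNPS", top_k = 50,
                        mcmc = test_mcmc_settings(1500, 200, 2), seed = 108)
  expect_equal(nrow(rep$losses), 1L)
  expect_false(is.na(rep$losses$loss))
  expect_equal(rep$losses$scheme, "across_population")
})

test_that("loss reports round-trip to disk", {
  losses <- data.frame(trait = "t", model = "rkhs", strategy = "SNPS",
                       scheme = "kfold", fold = 1L, loss = 0.5,
                       metric = "MSE", seed = 1L, config = "abc",
                       error = NA_character_, stringsAsFactors = FALSE)
  rep <- structure(list(losses = losses, summary = summarize_min_loss(losses),
                        meta = list(seed = 1L)), class = "loss_report")
  base <- file.path(withr::local_tempdir(), "report")
  write_loss_report(rep, base)
  expect_true(file.exists(paste0(base, ".tsv")))
  back <- read.delim(paste0(base, ".tsv"))
  expect_equal(back$loss, 0.5)
  meta <- jsonlite::read_json(paste0(base, "_meta.json"))
  expect_equal(meta$seed, 1L)
})
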