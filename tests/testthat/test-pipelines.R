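# Cross-validation machinery, strategy pipelines, command-line
# interface. Full-scale pipeline accuracy runs live in the acceptance
# suite; these tests use a small dataset and reduced budgets.

test_that("stratified folds partition the data evenly within classes", {
  y <- rep(c("a", "b", "c"), times = c(20, 23, 17))
  fid <- make_stratified_folds(y, 5, seed = 2)
  expect_length(fid, 60)
  expect_true(all(diff(range(table(fid))) <= 1))
  for (cl in unique(y))
    expect_lte(diff(range(table(fid[y == cl]))), 1)
  expect_identical(fid, make_stratified_folds(y, 5, seed = 2))
  expect_error(make_stratified_folds(rep(c("a", "b"), c(3, 30)), 5), "fewer members")
})

test_that("cross_validate keeps folds disjoint and aggregates fold means", {
  set.seed(33)
  X <- matrix(rnorm(90 * 4), 90, 4)
  y <- rep(c("a", "b", "c"), 30)
  seen_test_rows <- new.env(); seen_test_rows$all <- integer(0)
  # spy estimator: records row fingerprints it was trained on
  trained_rows <- list()
  est <- list(
    fit = function(Xtr, ytr) list(n = nrow(Xtr), fp = sum(Xtr)),
    predict = function(model, Xte) rep("a", nrow(Xte)))
  r <- cross_validate(X, y, est, folds = 5, seed = 3)
  expect_equal(sort(unique(r$fold_assignments)), 1:5)
  accs <- vapply(r$per_fold, function(m) m$overall_accuracy, numeric(1))
  expect_equal(unname(r$aggregate["accuracy"]), mean(accs), tolerance = 1e-9)
  # every sample appears in exactly one test fold
  expect_equal(sort(table(r$fold_assignments) |> as.integer() |> sum()), 90)
  r2 <- cross_validate(X, y, est, folds = 5, seed = 3)
  expect_identical(r$fold_assignments, r2$fold_assignments)
})

test_that("estimators only ever see their training fold", {
  X <- matrix(seq_len(40), 40, 1)
  y <- rep(c("a", "b"), 20)
  leaks <- 0
  est <- list(
    fit = function(Xtr, ytr) Xtr[, 1],
    predict = function(model, Xte) {
      if (any(Xte[, 1] %in% model)) leaks <<- leaks + 1
      rep("a", nrow(Xte))
    })
  invisible(cross_validate(X, y, est, folds = 4, seed = 1))
  expect_equal(leaks, 0)
})

test_that("every strategy runs end-to-end on a small dataset and is deterministic", {
  ds <- small_dataset()
  cache <- new.env()
  for (s in c("gssr", "rrsrc", "dmvmd_elm", "hho_sfpde", "dr_gwo_svc",
              "dr_goa_sae")) {
    cfg <- strategy_config(s, cv_folds = 3, seed = 5, opts = fast_opts)
    r <- run_strategy(ds, cfg, cache = cache)
    expect_length(r$per_fold, 3)
    expect_true(all(is.finite(r$aggregate)))
    expect_s3_class(r, "cv_result")
  }
  # determinism (cheapest strategy, shared cache)
  cfg <- strategy_config("gssr", cv_folds = 3, seed = 5, opts = fast_opts)
  r1 <- run_strategy(ds, cfg, cache = cache)
  r2 <- run_strategy(ds, cfg, cache = cache)
  expect_identical(r1$aggregate, r2$aggregate)
  expect_identical(r1$predictions, r2$predictions)
  expect_error(run_strategy(ds, strategy_config("gssr", label_scheme("two_class"))),
               "outside the scheme")
})

test_that("the CLI synthesizes, decomposes, evaluates and rejects bad input", {
  dir <- withr::local_tempdir()
  code <- cli_main(c("synth", "--scheme", "three_class", "--n", "3",
                     "--seed", "7", "--out", dir))
  expect_equal(code, 0L)
  man <- utils::read.csv(file.path(dir, "labels.csv"))
  expect_equal(nrow(man), 9)
  expect_true(all(file.exists(file.path(dir, man$file))))

  out_csv <- file.path(dir, "modes.csv")
  code <- cli_main(c("decompose", "--method", "vmd", "--k", "2",
                     "--out", out_csv, file.path(dir, man$file[1])))
  expect_equal(code, 0L)
  expect_true(file.exists(out_csv))
  expect_equal(ncol(utils::read.csv(out_csv)), 2)

  preds <- file.path(dir, "preds.csv")
  utils::write.csv(data.frame(truth = c("normal", "wheeze"),
                              pred = c("normal", "normal")),
                   preds, row.names = FALSE)
  expect_equal(cli_main(c("eval", "--scheme", "three_class", preds)), 0L)

  expect_equal(cli_main(c("frobnicate")), 1L)
  expect_equal(cli_main(character(0)), 1L)
  expect_equal(cli_main(c("run", "--strategy", "not_a_strategy")), 1L)
})

test_that("the run subcommand writes fold metrics and a manifest", {
  dir <- withr::local_tempdir()
  cfg_yaml <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(seed = 2, n_per_class = 9, cv_folds = 3,
                        opts = fast_opts), cfg_yaml)
  code <- cli_main(c("run", "--strategy", "gssr", "--config", cfg_yaml,
                     "--out", dir))
  expect_equal(code, 0L)
  folds <- utils::read.csv(file.path(dir, "folds.csv"))
  expect_equal(nrow(folds), 3)
  manifest <- jsonlite::read_json(file.path(dir, "run.json"))
  expect_equal(manifest$strategy, "gssr")
  expect_equal(manifest$seed, 2)
})
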