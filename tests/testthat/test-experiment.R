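small_config_ <- function(seed = 5L, activation = "rectified_softsign") {
  cfg <- default_run_config(seed = seed)
  cfg$data$n_per_class <- 10L
  cfg$data$image_size <- c(96L, 96L)
  cfg$activation$name <- activation
  cfg$training$max_epochs <- 2L
  cfg$training$batch_size <- 8L
  cfg$training$learning_rate <- 1e-3
  cfg
}

test_that("a run produces the full set of artifacts and metrics", {
  out <- file.path(tempdir(), "run_rs")
  unlink(out, recursive = TRUE)
  res <- run_experiment(small_config_(), out_dir = out)
  expect_s3_class(res, "run_result")
  expect_equal(nrow(res$per_class), 4)          # one metrics row per class
  expect_true(res$test_accuracy >= 0 && res$test_accuracy <= 1)
  expect_length(res$roc, 4)
  expect_match(res$config_digest, "^[a-f0-9]{32}$")
  for (f in c("config.yaml", "metrics.csv", "confusion.csv", "roc.csv",
              "history.csv", "summary.csv", "model.rds"))
    expect_true(file.exists(file.path(out, f)), info = f)
  metrics <- read.csv(file.path(out, "metrics.csv"))
  expect_equal(nrow(metrics), 4)
  unlink(out, recursive = TRUE)
})

test_that("identical configs give identical results", {
  r1 <- run_experiment(small_config_())
  r2 <- run_experiment(small_config_())
  expect_identical(r1$test_accuracy, r2$test_accuracy)
  expect_identical(r1$history, r2$history)
  expect_identical(unclass(r1$confusion), unclass(r2$confusion))
  expect_identical(r1$config_digest, r2$config_digest)
})

test_that("an unknown activation fails before any computation", {
  cfg <- small_config_()
  cfg$activation$name <- "maxout"
  t0 <- Sys.time()
  expect_error(run_experiment(cfg), "unknown activation")
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 5)
})

test_that("config files round-trip through YAML", {
  cfg <- small_config_(seed = 9L)
  f <- tempfile(fileext = ".yaml")
  write_run_config(cfg, f)
  cfg2 <- read_run_config(f)
  expect_equal(cfg2$seed, 9L)
  expect_equal(cfg2$activation$name, cfg$activation$name)
  expect_equal(cfg2$training$max_epochs, cfg$training$max_epochs)
  unlink(f)
})

test_that("the sweep pairs every activation on the same data and split", {
  cfg <- small_config_()
  tab <- run_sweep(cfg, activations = c("relu", "softsign"))
  expect_equal(nrow(tab), 2)
  expect_true(all(is.na(tab$error)))
  results <- attr(tab, "results")
  expect_length(results, 2)
  # pairing contract: the sweep's held-out samples equal the ones a fresh
  # split with the same seed selects, for every activation
  ph <- generate_phantoms(n_per_class = cfg$data$n_per_class,
                          image_size = cfg$data$image_size,
                          noise_sd = cfg$data$noise_sd, seed = cfg$seed)
  sp <- split_dataset(ph, cfg$split$fractions, seed = cfg$seed)
  expect_identical(attr(tab, "test_indices"), attr(sp, "indices")$test)
  expect_identical(sum(results$relu$confusion), length(sp$test))
  expect_identical(sum(results$softsign$confusion), length(sp$test))
  expect_equal(nrow(results$relu$history), nrow(results$softsign$history))
})

test_that("a failing activation is recorded and the sweep continues", {
  cfg <- small_config_()
  cfg$training$max_epochs <- 1L
  tab <- run_sweep(cfg, activations = c("bogus", "relu"))
  expect_equal(nrow(tab), 2)
  bad <- tab[tab$activation == "bogus", ]
  expect_match(bad$error, "unknown activation")
  expect_true(is.na(bad$test_accuracy))
  expect_true(is.na(tab[tab$activation == "relu", "error"]))
})

test_that("every activation learns clean phantoms in a paired sweep", {
  cfg <- default_run_config(seed = 3L)
  cfg$data$n_per_class <- 50L
  cfg$data$image_size <- c(96L, 96L)
  cfg$data$noise_sd <- 0.02
  cfg$training$max_epochs <- 10L
  cfg$training$batch_size <- 4L
  tab <- run_sweep(cfg)
  expect_equal(nrow(tab), 9)
  expect_true(all(is.na(tab$error)))
  expect_true(all(tab$test_accuracy > 0.8),
              info = paste(tab$activation, round(tab$test_accuracy, 3),
                           collapse = "; "))
})
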