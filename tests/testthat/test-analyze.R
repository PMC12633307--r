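test_that("the analysis pipeline writes coherent result files", {
  out <- tempfile("qsbrun")
  cfg_path <- system.file("extdata", "toggle_P6_nh2.yaml",
                          package = "qsdbound")
  res <- qsb_analyze(config = cfg_path, out_dir = out)
  expect_equal(res$n_states, 357L)
  expect_equal(res$lam, 1.9258e-3, tolerance = 1e-3)
  js <- jsonlite::read_json(file.path(out, "result.json"))
  expect_equal(js$lambda_per_s, res$lam)
  expect_equal(js$A, res$A)
  expect_equal(js$config_hash, res$config_hash)
  bounds <- read.csv(file.path(out, "bounds.csv"))
  expect_equal(bounds$switching_upper,
               switching_probability_upper(res$lam, res$A, bounds$t))
  qsd_csv <- read.csv(file.path(out, "qsd.csv"))
  expect_equal(sum(qsd_csv$probability), 1, tolerance = 1e-9)
  expect_named(qsd_csv, c("S1", "S2", "probability"))
})

test_that("starting from the QSD reports zero compensation", {
  cfg <- toggle_table_config(2, 2)
  res <- qsb_analyze(cfg$net, cfg$region, initial = "qsd", times = 100)
  expect_lte(res$A, 1e-6)
})

test_that("repeated runs are bit-identical (library and CLI share one path)", {
  cfg_path <- system.file("extdata", "toggle_P6_nh2.yaml",
                          package = "qsdbound")
  out1 <- tempfile(); out2 <- tempfile()
  qsb_analyze(config = cfg_path, out_dir = out1)
  qsb_analyze(config = cfg_path, out_dir = out2)
  expect_identical(readLines(file.path(out1, "result.json")),
                   readLines(file.path(out2, "result.json")))
  expect_identical(readLines(file.path(out1, "bounds.csv")),
                   readLines(file.path(out2, "bounds.csv")))
})

test_that("the robustness-table builder reports bounds per configuration", {
  tab <- qsb_table(P = c(2, 6), nh = 2, times = c(21600, 86400))
  expect_equal(nrow(tab), 2L)
  expect_named(tab, c("P", "nh", "lambda", "inv_lambda", "below_floor", "A",
                      "n_states", "P_exit_by_6h", "P_exit_by_24h"))
  expect_true(all(tab$P_exit_by_24h >= tab$P_exit_by_6h - 1e-12))
  expect_true(all(tab$lambda > 0))
  # fast-switching member saturates within a day
  expect_gt(tab$P_exit_by_24h[tab$P == 2], 0.999)
})

test_that("the validation suite passes on a small fixture end to end", {
  cfg <- toggle_table_config(2, 2)
  rep <- qsb_validate(cfg$net, cfg$region, cfg$x0)
  expect_true(all(rep$pass))
  # the oversize guard refuses before building the transient oracle
  big <- toggle_table_config(6, 2)
  expect_error(qsb_validate(big$net, big$region, big$x0, max_states = 100),
               "limited to")
})

test_that("the command-line front end runs the same pipeline", {
  cli <- system.file("cli", "qsb.R", package = "qsdbound")
  cfg_path <- system.file("extdata", "toggle_P6_nh2.yaml",
                          package = "qsdbound")
  out <- tempfile("clirun")
  libs <- paste0("R_LIBS=", paste(.libPaths(), collapse = ":"))
  status <- system2("Rscript", c(cli, "analyze", "--config",
                                 shQuote(cfg_path), "--out", shQuote(out)),
                    stdout = TRUE, stderr = TRUE, env = libs)
  expect_true(file.exists(file.path(out, "result.json")))
  ref <- tempfile("libref")
  qsb_analyze(config = cfg_path, out_dir = ref)
  expect_identical(readLines(file.path(out, "result.json")),
                   readLines(file.path(ref, "result.json")))
  # malformed invocation exits with a usage error
  bad <- suppressWarnings(
    system2("Rscript", c(cli, "analyze"), stdout = TRUE, stderr = TRUE,
            env = libs))
  expect_equal(attr(bad, "status"), 2)
})
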