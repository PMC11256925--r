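test_that("the main fit recovers a planted population end to end", {
  sim <- generate_mixture(n_cells = 500, n_rare = 12, n_genes = 600,
                          n_marker_genes = 40, marker_rate = 6, seed = 51)
  fit <- sccross(sim$counts, sim$sample_map, normalize = "cpm")
  expect_s3_class(fit, "sccross")
  expect_equal(fit$params$kappa, 100 / 500)
  expect_length(fit$runs, 1)
  expect_equal(f1_score(fit$biclusters[[1]]$cells, sim$rare_cells)$f1, 1.0)

  # methods
  expect_output(print(fit), "run 1")
  expect_output(print(summary(fit)), "top genes")
  co <- coef(fit)
  expect_true(all(diff(co) <= 0))
  expect_true(all(co > 0))
  expect_named(co)

  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off(), add = TRUE)
  expect_silent(plot(fit))
})

test_that("a character sample vector is accepted in place of a map", {
  inst <- rand_instance(1)
  counts <- matrix(abs(inst$m) * 10, 8, 10)
  fit <- sccross(counts, rep(c("a", "b"), each = 5), filter = FALSE,
                 kappa = 0.5)
  expect_s3_class(fit, "sccross")
  expect_equal(fit$sample_map$samples, c("a", "b"))
})

test_that("input validation rejects malformed fits early", {
  counts <- matrix(1, 4, 6)
  expect_error(sccross(counts, rep("a", 5)), "per cell")
  expect_error(sccross("no", rep("a", 5)), "matrix")
  expect_error(sccross(counts, rep("a", 6), mu = 2), "mu")
  expect_error(coef(sccross(counts, rep("a", 6), filter = FALSE,
                            kappa = 1), run = 5), "no run")
})

test_that("the command-line wrapper runs the simulate and run pipeline", {
  cli <- system.file("cli", "sccross.R", package = "scCross")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  d <- withr::local_tempdir()
  simdir <- file.path(d, "sim")
  out <- system2(rscript, c(cli, "simulate", "--n-cells", "200",
                            "--n-genes", "300", "--n-rare", "8",
                            "--n-marker-genes", "20", "--seed", "3",
                            "--out", simdir),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(simdir, "matrix.mtx")))

  rundir <- file.path(d, "run")
  out2 <- system2(rscript, c(cli, "run", "--counts", simdir,
                             "--samples", file.path(simdir, "samples.tsv"),
                             "--layout", "mtx", "--normalize", "cpm",
                             "--out", rundir),
                  stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(rundir, "report.json")))
  rep <- jsonlite::read_json(file.path(rundir, "report.json"),
                             simplifyVector = TRUE)
  expect_equal(rep$parameters$kappa, 100 / 200)
})
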