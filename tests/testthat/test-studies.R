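# Case-study drivers and the command-line surface.

test_that("a reduced yeast study assembles a coherent report", {
  cfg <- yeast_study_config(epsilon_range = 1:2, n_starts = 4,
                            resilience_starts = 4, seed = 1)
  st <- run_yeast_study(cfg, include_overestimation = FALSE)
  expect_s3_class(st, "fmoop_study")
  expect_equal(st$primal_front$epsilon, 1:2)
  expect_true(all(st$primal_front$feasible))
  expect_true(all(st$resilience_front$feasible))
  # resilience never beats primal at the same budget
  expect_true(all(st$resilience_front$ratio_PYK <=
                    st$primal_front$ratio_PYK * (1 + 1e-6)))
  # fixed-pattern comparison solution present and feasible
  expect_false(is.null(st$fixed_pattern_nlp))
  expect_true(st$fixed_pattern_nlp$feasible)
  expect_identical(sort(st$fixed_pattern_nlp$modulated_ids),
                   c("HXT", "PFK"))
  expect_equal(st$census$n_pairs, 28L)
  # every front row re-validates against the crisp constraints
  for (s in attr(st$primal_front, "solutions"))
    expect_true(attr(check_feasible(yeast_model(), s, cfg$bounds),
                     "feasible"))
  td <- tempfile()
  write_study_report(st, td)
  expect_true(file.exists(file.path(td, "primal_front.tsv")))
  expect_true(file.exists(file.path(td, "resilience_front.tsv")))
  expect_true(file.exists(file.path(td, "run_log.json")))
  unlink(td, recursive = TRUE)
})

test_that("cli validates the bundled fixtures", {
  expect_output(st <- run_cli(c("validate-model", "--model", "yeast")),
                "OK:")
  expect_identical(st, 0L)
  expect_output(run_cli(c("validate-model", "--model", "ecoli")), "OK:")
})

test_that("cli solve writes reproducible outputs", {
  d1 <- tempfile(); d2 <- tempfile()
  args <- c("solve", "--model", "yeast", "--problem", "primal",
            "--epsilon", "1", "--target", "PYK", "--n-starts", "3",
            "--seed", "7")
  expect_output(run_cli(c(args, "--out", d1)), "HXT")
  expect_output(run_cli(c(args, "--out", d2)), "HXT")
  expect_identical(readLines(file.path(d1, "result.tsv")),
                   readLines(file.path(d2, "result.tsv")))
  tab <- utils::read.delim(file.path(d1, "result.tsv"))
  expect_equal(tab$epsilon, 1L)
  expect_gt(tab$ratio_PYK, 2)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the installed executable script runs end to end", {
  script <- system.file("cli", "enzopt.R", package = "enzopt")
  fixture <- system.file("extdata", "yeast_fermentation_gma.json",
                         package = "enzopt")
  res <- system2(file.path(R.home("bin"), "Rscript"),
                 c(script, "validate-model", "--model", shQuote(fixture)),
                 stdout = TRUE, stderr = TRUE)
  expect_identical(attr(res, "status"), NULL)   # exit 0
  expect_true(any(grepl("OK:", res)))
})
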