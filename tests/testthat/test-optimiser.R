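test_that("parameter specs: validation and genome encoding", {
  expect_error(parameter_spec("a"), "bounds")
  expect_error(parameter_spec("a", bounds = c(2, 1)), "lower bound")
  expect_error(parameter_spec("a", frozen = TRUE), "value")
  specs <- list(parameter_spec("cm", value = 1, frozen = TRUE),
                parameter_spec("g1", bounds = c(0, 1)),
                parameter_spec("g2", bounds = c(-1, 1)))
  expect_identical(ephysopt:::free_param_names(specs), c("g1", "g2"))
  pv <- ephysopt:::genome_to_params(specs, c(0.3, -0.5))
  expect_identical(pv, c(cm = 1, g1 = 0.3, g2 = -0.5))
  expect_error(ephysopt:::genome_to_params(specs, 1), "length")
})

test_that("bounds are enforced at evaluation entry", {
  ev <- sphere_evaluator(2)
  expect_error(evaluate_genome(ev, c(1.5, 0.5)), "bounds.*x1")
  expect_equal(evaluate_genome(ev, c(0.5, 0.5)), c(0, 0))
})

test_that("sphere problem: optimiser makes >= 10x progress by gen 20", {
  ev <- sphere_evaluator(2)
  ratios <- vapply(1:20, function(s) {
    res <- run_optimisation(ev, optimisation_config(
      offspring_size = 20, max_ngen = 20, seed = s))
    lb <- res$logbook
    lb$min[lb$gen == 0] / max(lb$min[lb$gen == 20], .Machine$double.eps)
  }, numeric(1))
  expect_gte(median(ratios), 10)
})

test_that("logbook min is non-increasing and hall of fame is sorted", {
  ev <- sphere_evaluator(2)
  res <- run_optimisation(ev, optimisation_config(offspring_size = 12,
                                                  max_ngen = 8, seed = 5))
  expect_true(all(diff(res$logbook$min) <= 0))
  expect_true(!is.unsorted(res$hall_of_fame$objective_sum))
  expect_equal(res$hall_of_fame$objective_sum,
               rowSums(res$hall_of_fame[, c("obj1", "obj2")]))
})

test_that("identical seed + serial map reproduces the run exactly", {
  ev <- sphere_evaluator(2)
  cfg <- optimisation_config(offspring_size = 16, max_ngen = 5, seed = 99)
  r1 <- run_optimisation(ev, cfg)
  r2 <- run_optimisation(ev, cfg)
  expect_identical(r1$hall_of_fame, r2$hall_of_fame)
  expect_identical(r1$final_population, r2$final_population)
  expect_identical(r1$logbook, r2$logbook)
})

test_that("checkpoint restore continues bit-identically", {
  ev <- sphere_evaluator(2)
  ck <- tempfile(fileext = ".rds")
  cfg <- optimisation_config(offspring_size = 14, max_ngen = 6, seed = 3,
                             checkpoint_period = 3, checkpoint_path = ck)
  full <- run_optimisation(ev, cfg)
  # rerun only to generation 3, then resume from its checkpoint
  cfg3 <- optimisation_config(offspring_size = 14, max_ngen = 3, seed = 3,
                              checkpoint_period = 3, checkpoint_path = ck)
  run_optimisation(ev, cfg3)
  resumed <- run_optimisation(ev, cfg, resume = ck)
  expect_identical(resumed$hall_of_fame, full$hall_of_fame)
  expect_identical(resumed$final_population, full$final_population)
  expect_identical(resumed$logbook, full$logbook)
  # byte-identical hall-of-fame CSVs
  f1 <- tempfile(); f2 <- tempfile()
  write_hall_of_fame(full, f1)
  write_hall_of_fame(resumed, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("frozen parameters reach the evaluation with their exact value", {
  seen <- new.env()
  seen$vals <- numeric(0)
  specs <- list(parameter_spec("fixed", value = 4.25, frozen = TRUE),
                parameter_spec("free", bounds = c(0, 1)))
  ev <- evaluator(specs, "obj", function(g) {
    pv <- ephysopt:::genome_to_params(specs, g)
    seen$vals <- c(seen$vals, pv[["fixed"]])
    abs(pv[["free"]] - 0.5)
  }, name = "frozen_check")
  run_optimisation(ev, optimisation_config(offspring_size = 8, max_ngen = 2,
                                           seed = 1))
  expect_true(length(seen$vals) > 0)
  expect_true(all(seen$vals == 4.25))
})

test_that("evaluation errors become the penalty vector, run continues", {
  specs <- list(parameter_spec("x", bounds = c(0, 1)))
  ev <- evaluator(specs, c("a", "b"), function(g) {
    if (g[1] > 0.5) stop("simulated failure")
    c(g[1], 1 - g[1])
  }, name = "flaky")
  res <- run_optimisation(ev, optimisation_config(offspring_size = 10,
                                                  max_ngen = 3, seed = 2,
                                                  penalty = 250))
  objs <- res$final_population$objectives
  bad <- res$final_population$genomes[, 1] > 0.5
  expect_true(all(objs[bad, ] == 250))
  expect_equal(nrow(objs), 10)
})

test_that("map_fn is used and must preserve order", {
  calls <- new.env(); calls$n <- 0L
  counting_map <- function(x, f) { calls$n <- calls$n + 1L; lapply(x, f) }
  ev <- sphere_evaluator(1)
  res <- run_optimisation(ev, optimisation_config(offspring_size = 6,
                                                  max_ngen = 2, seed = 8),
                          map_fn = counting_map)
  expect_identical(calls$n, 3L)  # init + one per generation
  expect_equal(nrow(res$final_population$genomes), 6)
})
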