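#' Optimisation settings
#'
#' Collects the knobs of the IBEA run. The population size equals
#' `offspring_size` (mu = lambda); each generation breeds
#' `offspring_size` offspring from tournament-selected parents, merges
#' them with the parents and applies environmental selection back to
#' `offspring_size`.
#'
#' @param offspring_size Offspring (and population) size, >= 2.
#' @param max_ngen Number of generations, >= 1.
#' @param kappa IBEA fitness scaling factor (> 0).
#' @param cx_prob Crossover probability per parent pair.
#' @param mut_prob Per-gene mutation probability; default `1/genome_length`.
#' @param eta Distribution index for SBX crossover and polynomial mutation.
#' @param seed Integer RNG seed; the whole run is reproducible from it
#'   under a serial map.
#' @param checkpoint_period Write a checkpoint every this many
#'   generations (`NULL` = no checkpointing).
#' @param checkpoint_path File path for checkpoints.
#' @param hof_size Hall-of-fame capacity.
#' @param penalty Objective value assigned to every objective of an
#'   individual whose evaluation raised an error.
#' @return An object of class `optimisation_config`.
#' @export
optimisation_config <- function(offspring_size = 100, max_ngen = 10,
                                kappa = 0.05, cx_prob = 0.7, mut_prob = NULL,
                                eta = 10, seed = 1, checkpoint_period = NULL,
                                checkpoint_path = NULL, hof_size = 10,
                                penalty = 250) {
  stopifnot(offspring_size >= 2, max_ngen >= 1, kappa > 0,
            cx_prob >= 0, cx_prob <= 1, eta > 0, hof_size >= 1, penalty >= 0)
  if (!is.null(mut_prob)) stopifnot(mut_prob >= 0, mut_prob <= 1)
  structure(
    list(offspring_size = as.integer(offspring_size),
         max_ngen = as.integer(max_ngen), kappa = kappa, cx_prob = cx_prob,
         mut_prob = mut_prob, eta = eta, seed = as.integer(seed),
         checkpoint_period = checkpoint_period,
         checkpoint_path = checkpoint_path,
         hof_size = as.integer(hof_size), penalty = penalty),
    class = "optimisation_config"
  )
}

#' @export
print.optimisation_config <- function(x, ...) {
  cat("<optimisation_config>\n")
  cat(sprintf("  offspring_size: %d   max_ngen: %d   seed: %d\n",
              x$offspring_size, x$max_ngen, x$seed))
  cat(sprintf("  kappa: %g  cx_prob: %g  mut_prob: %s  eta: %g\n",
              x$kappa, x$cx_prob,
              if (is.null(x$mut_prob)) "1/ngenes" else format(x$mut_prob),
              x$eta))
  invisible(x)
}

# evaluate a list of genomes through map_fn; evaluation errors become the
# penalty vector so the population size stays fixed
evaluate_genomes <- function(evaluator, genomes, map_fn, penalty) {
  n_obj <- length(evaluator$objective_names)
  res <- map_fn(genomes, function(g) {
    tryCatch(
      {
        v <- evaluate_genome(evaluator, g)
        if (length(v) != n_obj || any(!is.finite(v)) || any(v < 0))
          stop("evaluator returned an invalid objective vector")
        v
      },
      error = function(e) rep(penalty, n_obj)
    )
  })
  do.call(rbind, res)
}

# hall of fame: keep the `capacity` best unique genomes by objective sum
update_hof <- function(hof, genomes, objectives, birth, capacity) {
  cand_g <- rbind(hof$genomes, genomes)
  cand_o <- rbind(hof$objectives, objectives)
  cand_b <- c(hof$birth, birth)
  sums <- rowSums(cand_o)
  ord <- order(sums)
  cand_g <- cand_g[ord, , drop = FALSE]
  cand_o <- cand_o[ord, , drop = FALSE]
  cand_b <- cand_b[ord]
  dup <- duplicated(cand_g)
  cand_g <- cand_g[!dup, , drop = FALSE]
  cand_o <- cand_o[!dup, , drop = FALSE]
  cand_b <- cand_b[!dup]
  keep <- seq_len(min(capacity, nrow(cand_g)))
  list(genomes = cand_g[keep, , drop = FALSE],
       objectives = cand_o[keep, , drop = FALSE],
       birth = cand_b[keep])
}

#' Run an IBEA optimisation
#'
#' Evolves a population of bounded real-valued genomes against the
#' objective vectors returned by `evaluator`, using adaptive IBEA with
#' the additive epsilon indicator. Returns the final population, a
#' hall of fame sorted ascending by the sum of the objectives, a
#' per-generation logbook and the parent-child genealogy.
#'
#' The logbook column `min` tracks the best objective sum encountered so
#' far (the hall of fame is elitist), so it is non-increasing; `mean` and
#' `max` describe the current population.
#'
#' @param evaluator An [evaluator()] object.
#' @param config An [optimisation_config()].
#' @param map_fn Order-preserving map used to evaluate a list of genomes;
#'   default `lapply` (serial). A parallel drop-in must preserve order
#'   and propagate per-item errors.
#' @param resume Path to a checkpoint file to restore and continue from;
#'   the run then proceeds to `config$max_ngen` bit-identically to an
#'   uninterrupted run (serial map).
#' @return An object of class `optimisation_result`: list with
#'   `final_population`, `hall_of_fame` (data frame), `logbook`
#'   (data frame), `history` (data frame) and `config`.
#' @export
run_optimisation <- function(evaluator, config, map_fn = lapply,
                             resume = NULL) {
  stopifnot(inherits(config, "optimisation_config"))
  bounds <- free_bounds(evaluator$param_specs)
  d <- ncol(bounds)
  if (d == 0L) stop("evaluator has no free parameters")
  lower <- bounds[1, ]; upper <- bounds[2, ]
  mu <- config$offspring_size
  mut_prob <- if (is.null(config$mut_prob)) 1 / d else config$mut_prob
  n_obj <- length(evaluator$objective_names)

  history <- list()
  if (is.null(resume)) {
    set.seed(config$seed)
    # generation 0: uniform random population within bounds
    genomes <- matrix(stats::runif(mu * d, min = rep(lower, each = mu),
                                   max = rep(upper, each = mu)), mu, d)
    objectives <- evaluate_genomes(evaluator, mat_rows(genomes), map_fn,
                                   config$penalty)
    birth <- rep(0L, mu)
    next_id <- mu + 1L
    history[[1]] <- data.frame(id = seq_len(mu), gen = 0L,
                               parent1 = NA_integer_, parent2 = NA_integer_)
    ids <- seq_len(mu)
    hof <- list(genomes = genomes[0, , drop = FALSE],
                objectives = objectives[0, , drop = FALSE],
                birth = integer(0))
    hof <- update_hof(hof, genomes, objectives, birth, config$hof_size)
    logbook <- data.frame(gen = 0L, nevals = mu,
                          min = min(rowSums(hof$objectives)),
                          mean = mean(rowSums(objectives)),
                          max = max(rowSums(objectives)))
    start_gen <- 1L
  } else {
    ck <- readRDS(resume)
    if (!identical(ck$format, "ephysopt-checkpoint-1"))
      stop("unrecognized checkpoint format in ", resume)
    genomes <- ck$genomes; objectives <- ck$objectives; birth <- ck$birth
    ids <- ck$ids; next_id <- ck$next_id
    hof <- ck$hof; logbook <- ck$logbook; history <- ck$history
    assign(".Random.seed", ck$rng_state, envir = globalenv())
    start_gen <- ck$gen + 1L
  }

  if (start_gen <= config$max_ngen) {
    for (gen in seq(start_gen, config$max_ngen)) {
      fa <- ibea_fitness(objectives, config$kappa)
      parents_idx <- tournament_select(fa$fitness, rowSums(objectives), mu)
      off_genomes <- vary(genomes[parents_idx, , drop = FALSE], lower, upper,
                          cx_prob = config$cx_prob, mut_prob = mut_prob,
                          eta = config$eta)
      off_objs <- evaluate_genomes(evaluator, mat_rows(off_genomes), map_fn,
                                   config$penalty)
      off_ids <- seq(next_id, length.out = mu)
      next_id <- next_id + mu
      p1 <- ids[parents_idx]
      # SBX partner of offspring i is its pair neighbour (1<->2, 3<->4, ...)
      partner <- seq_len(mu) + ifelse(seq_len(mu) %% 2 == 1L, 1L, -1L)
      p2 <- ifelse(partner <= mu, ids[parents_idx[pmin(partner, mu)]],
                   NA_integer_)
      history[[length(history) + 1L]] <-
        data.frame(id = off_ids, gen = gen, parent1 = p1, parent2 = p2)

      merged_g <- rbind(genomes, off_genomes)
      merged_o <- rbind(objectives, off_objs)
      merged_b <- c(birth, rep(gen, mu))
      merged_i <- c(ids, off_ids)
      keep <- environmental_selection(merged_o, mu, config$kappa)
      genomes <- merged_g[keep, , drop = FALSE]
      objectives <- merged_o[keep, , drop = FALSE]
      birth <- merged_b[keep]
      ids <- merged_i[keep]

      hof <- update_hof(hof, off_genomes, off_objs, rep(gen, mu),
                        config$hof_size)
      logbook <- rbind(logbook,
                       data.frame(gen = gen, nevals = mu,
                                  min = min(rowSums(hof$objectives)),
                                  mean = mean(rowSums(objectives)),
                                  max = max(rowSums(objectives))))

      if (!is.null(config$checkpoint_period) &&
          !is.null(config$checkpoint_path) &&
          gen %% config$checkpoint_period == 0L) {
        saveRDS(list(format = "ephysopt-checkpoint-1", gen = gen,
                     genomes = genomes, objectives = objectives,
                     birth = birth, ids = ids, next_id = next_id,
                     hof = hof, logbook = logbook, history = history,
                     rng_state = get(".Random.seed", envir = globalenv())),
                config$checkpoint_path)
      }
    }
  }

  pnames <- free_param_names(evaluator$param_specs)
  colnames(genomes) <- pnames
  colnames(hof$genomes) <- pnames
  colnames(objectives) <- evaluator$objective_names
  colnames(hof$objectives) <- evaluator$objective_names

  hof_df <- data.frame(rank = seq_len(nrow(hof$genomes)),
                       objective_sum = rowSums(hof$objectives),
                       hof$objectives, hof$genomes, check.names = FALSE)
  structure(
    list(final_population = list(genomes = genomes, objectives = objectives,
                                 birth = birth),
         hall_of_fame = hof_df,
         logbook = logbook,
         history = do.call(rbind, history),
         config = config,
         evaluator_name = evaluator$name),
    class = "optimisation_result"
  )
}

mat_rows <- function(m) lapply(seq_len(nrow(m)), function(i) m[i, ])

#' @export
print.optimisation_result <- function(x, ...) {
  cat("<optimisation_result>", x$evaluator_name, "\n")
  cat(sprintf("  generations: %d   evaluations: %d\n",
              max(x$logbook$gen), sum(x$logbook$nevals)))
  cat(sprintf("  best objective sum: %g\n", x$hall_of_fame$objective_sum[1]))
  invisible(x)
}

#' Best genome of a finished run
#'
#' @param result An `optimisation_result`.
#' @return Named numeric vector: the hall-of-fame rank-1 genome.
#' @export
best_genome <- function(result) {
  hof <- result$hall_of_fame
  non_par <- c("rank", "objective_sum")
  obj_names <- setdiff(colnames(hof), non_par)
  # parameter columns come after the objective columns
  n_obj <- ncol(hof) - 2L - ncol(result$final_population$genomes)
  par_cols <- seq(2L + n_obj + 1L, ncol(hof))
  g <- as.numeric(hof[1, par_cols])
  names(g) <- colnames(hof)[par_cols]
  g
}

#' Write the hall of fame as CSV
#'
#' One row per individual: rank, objective sum, each objective, each
#' parameter. Numbers are written with full precision so that identical
#' runs give byte-identical files.
#'
#' @param result An `optimisation_result`.
#' @param path Output file.
#' @export
write_hall_of_fame <- function(result, path) {
  df <- result$hall_of_fame
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the logbook as JSON lines
#'
#' @param result An `optimisation_result`.
#' @param path Output file, one JSON record per generation.
#' @export
write_logbook <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(result$logbook))) {
    writeLines(jsonlite::toJSON(as.list(result$logbook[i, ]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
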