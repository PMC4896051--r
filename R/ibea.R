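#' Additive epsilon indicator between two normalized objective vectors
#'
#' For minimization problems the additive epsilon indicator
#' `I(a, b) = max_i (a_i - b_i)` is the smallest amount by which `a` must
#' be improved (shifted down) in every objective so that it weakly
#' dominates `b`. It is negative when `a` already dominates `b`.
#'
#' Vectors are expected to be normalized to `[0, 1]` per dimension over
#' the pooled population under comparison (see [ibea_fitness()]).
#'
#' @param a_objs,b_objs Numeric objective vectors of equal length.
#' @return Scalar indicator value.
#' @examples
#' epsilon_indicator(c(0.2, 0.3), c(0.5, 0.6)) # -0.3
#' @export
epsilon_indicator <- function(a_objs, b_objs) {
  if (length(a_objs) != length(b_objs))
    stop("objective vectors differ in length (", length(a_objs), " vs ",
         length(b_objs), ")")
  max(a_objs - b_objs)
}

# per-dimension min-max normalization; degenerate dimensions map to 0
normalize_objectives <- function(objectives) {
  lo <- apply(objectives, 2, min)
  hi <- apply(objectives, 2, max)
  rng <- hi - lo
  out <- sweep(objectives, 2, lo, "-")
  for (j in seq_len(ncol(out))) {
    out[, j] <- if (rng[j] > 0) out[, j] / rng[j] else 0
  }
  out
}

# pairwise indicator matrix: I[y, x] = epsilon_indicator(obj[y, ], obj[x, ])
indicator_matrix <- function(norm_objs) {
  n <- nrow(norm_objs)
  I <- matrix(-Inf, n, n)
  for (j in seq_len(ncol(norm_objs))) {
    I <- pmax(I, outer(norm_objs[, j], norm_objs[, j], "-"))
  }
  diag(I) <- 0
  I
}

#' IBEA fitness assignment
#'
#' Assigns the scalar IBEA fitness to each row of an objective matrix:
#' objectives are min-max normalized per dimension, the pairwise additive
#' epsilon indicator `I(y, x)` is computed, rescaled by its maximum
#' absolute value `c` (adaptive IBEA), and each individual `x` receives
#' `fitness(x) = sum_{y != x} -exp(-I(y, x) / (c * kappa))`. Larger
#' fitness is better; a dominating individual has the greatest fitness.
#'
#' @param objectives Numeric `n x m` matrix of non-negative objective
#'   scores (rows = individuals, columns = objectives; minimization).
#' @param kappa Positive scaling factor (default 0.05).
#' @return List with `fitness` (length-n vector), `indicator` (the `n x n`
#'   indicator matrix on normalized objectives) and `c` (the rescaling
#'   constant), the latter two reused by [environmental_selection()].
#' @references Zitzler & Kuenzli (2004), indicator-based selection in
#'   multiobjective search.
#' @export
ibea_fitness <- function(objectives, kappa = 0.05) {
  objectives <- as.matrix(objectives)
  if (!all(is.finite(objectives))) {
    bad <- which(!apply(objectives, 1, function(r) all(is.finite(r))))
    stop("non-finite objectives for individual(s): ",
         paste(bad, collapse = ", "))
  }
  stopifnot(kappa > 0)
  n <- nrow(objectives)
  if (n == 1L)
    return(list(fitness = 0, indicator = matrix(0, 1, 1), c = 1))
  I <- indicator_matrix(normalize_objectives(objectives))
  c_abs <- max(abs(I))
  if (c_abs <= 0) c_abs <- 1 # all objective vectors identical
  E <- exp(-I / (c_abs * kappa))
  diag(E) <- 0
  list(fitness = -colSums(E), indicator = I, c = c_abs)
}

#' IBEA environmental selection
#'
#' Iteratively removes the individual with the worst (smallest) IBEA
#' fitness until `target_size` remain, updating the fitness of the
#' survivors incrementally by adding back `exp(-I(removed, y) / (c * kappa))`.
#' Normalization and the rescaling constant `c` are fixed once on the full
#' input population, as in the canonical algorithm.
#'
#' Ties on fitness are broken deterministically by the smaller row index.
#'
#' @param objectives Numeric `n x m` objective matrix.
#' @param target_size Number of individuals to keep (>= 1).
#' @param kappa Positive scaling factor.
#' @return Integer vector of the kept row indices, in original order.
#' @export
environmental_selection <- function(objectives, target_size, kappa = 0.05) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n == 0L) stop("empty population")
  stopifnot(target_size >= 1)
  if (n <= target_size) return(seq_len(n))
  fa <- ibea_fitness(objectives, kappa)
  fitness <- fa$fitness
  E <- exp(-fa$indicator / (fa$c * kappa))
  diag(E) <- 0
  alive <- rep(TRUE, n)
  n_alive <- n
  while (n_alive > target_size) {
    idx_alive <- which(alive)
    worst <- idx_alive[which.min(fitness[idx_alive])]
    alive[worst] <- FALSE
    n_alive <- n_alive - 1L
    # removing `worst` deletes its -exp term from every survivor's sum
    fitness <- fitness + E[worst, ]
  }
  which(alive)
}

# binary tournament on IBEA fitness; ties -> smaller objective sum, then
# random. Returns `n_select` row indices (with replacement).
tournament_select <- function(fitness, obj_sums, n_select) {
  n <- length(fitness)
  winners <- integer(n_select)
  for (k in seq_len(n_select)) {
    ij <- sample.int(n, 2L, replace = TRUE)
    i <- ij[1]; j <- ij[2]
    winners[k] <- if (fitness[i] > fitness[j]) i
      else if (fitness[j] > fitness[i]) j
      else if (obj_sums[i] < obj_sums[j]) i
      else if (obj_sums[j] < obj_sums[i]) j
      else ij[1 + (stats::runif(1) < 0.5)]
  }
  winners
}

#' Bounded real-coded variation: SBX crossover + polynomial mutation
#'
#' Applies pairwise simulated-binary crossover (probability `cx_prob`,
#' distribution index `eta`) to consecutive parent pairs, then bounded
#' polynomial mutation (per-gene probability `mut_prob`, same index).
#' Offspring genes are guaranteed to lie within the bounds.
#'
#' @param parents Numeric matrix of parent genomes (rows = individuals).
#' @param lower,upper Numeric vectors of per-gene bounds.
#' @param cx_prob Probability of crossing each pair.
#' @param mut_prob Per-gene mutation probability (default `1/ngenes`).
#' @param eta Distribution index (larger = offspring closer to parents).
#' @return Matrix of offspring genomes, same shape as `parents`.
#' @export
vary <- function(parents, lower, upper, cx_prob = 0.7, mut_prob = NULL,
                 eta = 10) {
  parents <- as.matrix(parents)
  d <- ncol(parents)
  n <- nrow(parents)
  if (is.null(mut_prob)) mut_prob <- 1 / d
  off <- parents
  # SBX on consecutive pairs
  for (k in seq_len(n %/% 2)) {
    i <- 2L * k - 1L; j <- 2L * k
    if (stats::runif(1) < cx_prob) {
      cx <- sbx_pair(off[i, ], off[j, ], lower, upper, eta)
      off[i, ] <- cx[[1]]; off[j, ] <- cx[[2]]
    }
  }
  # bounded polynomial mutation
  for (i in seq_len(n)) {
    off[i, ] <- polynomial_mutate(off[i, ], lower, upper, mut_prob, eta)
  }
  off[] <- pmin(pmax(off, matrix(lower, n, d, byrow = TRUE)),
                matrix(upper, n, d, byrow = TRUE))
  off
}

# simulated binary crossover of one pair (Deb & Agrawal 1995, bounded form)
sbx_pair <- function(x1, x2, lower, upper, eta) {
  d <- length(x1)
  c1 <- x1; c2 <- x2
  for (g in seq_len(d)) {
    if (stats::runif(1) > 0.5) next          # each gene crossed with prob 0.5
    if (abs(x1[g] - x2[g]) < 1e-14) next
    y1 <- min(x1[g], x2[g]); y2 <- max(x1[g], x2[g])
    lo <- lower[g]; hi <- upper[g]
    u <- stats::runif(1)
    beta_q <- function(beta) {
      alpha <- 2 - beta^(-(eta + 1))
      if (u <= 1 / alpha) (u * alpha)^(1 / (eta + 1))
      else (1 / (2 - u * alpha))^(1 / (eta + 1))
    }
    beta1 <- 1 + 2 * (y1 - lo) / (y2 - y1)
    beta2 <- 1 + 2 * (hi - y2) / (y2 - y1)
    bq1 <- beta_q(beta1); bq2 <- beta_q(beta2)
    v1 <- 0.5 * ((y1 + y2) - bq1 * (y2 - y1))
    v2 <- 0.5 * ((y1 + y2) + bq2 * (y2 - y1))
    if (stats::runif(1) < 0.5) { c1[g] <- v2; c2[g] <- v1 }
    else { c1[g] <- v1; c2[g] <- v2 }
  }
  list(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

# bounded polynomial mutation (Deb & Goyal 1996)
polynomial_mutate <- function(x, lower, upper, mut_prob, eta) {
  for (g in seq_along(x)) {
    if (stats::runif(1) >= mut_prob) next
    lo <- lower[g]; hi <- upper[g]
    if (hi <= lo) next
    y <- x[g]
    d1 <- (y - lo) / (hi - lo)
    d2 <- (hi - y) / (hi - lo)
    u <- stats::runif(1)
    mpow <- 1 / (eta + 1)
    if (u < 0.5) {
      val <- 2 * u + (1 - 2 * u) * (1 - d1)^(eta + 1)
      dq <- val^mpow - 1
    } else {
      val <- 2 * (1 - u) + 2 * (u - 0.5) * (1 - d2)^(eta + 1)
      dq <- 1 - val^mpow
    }
    x[g] <- min(max(y + dq * (hi - lo), lo), hi)
  }
  x
}
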