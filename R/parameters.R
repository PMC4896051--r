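#' Define a model parameter
#'
#' A `parameter_spec` describes one named model parameter. A parameter is
#' either *free*, in which case it carries lower/upper bounds and
#' contributes one dimension to the optimiser's genome, or *frozen*, in
#' which case it carries an exact value and is excluded from the search.
#'
#' @param name Unique parameter name.
#' @param bounds Numeric length-2 vector `c(lower, upper)`; required for
#'   free parameters.
#' @param value Exact value; required for frozen parameters.
#' @param frozen Logical; `TRUE` fixes the parameter at `value`.
#'
#' @return An object of class `parameter_spec`.
#' @examples
#' parameter_spec("gnabar", bounds = c(0.05, 0.125))
#' parameter_spec("cm", value = 1.0, frozen = TRUE)
#' @export
parameter_spec <- function(name, bounds = NULL, value = NULL, frozen = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (frozen) {
    if (is.null(value) || !is.finite(value))
      stop("frozen parameter '", name, "' requires a finite value")
    bounds <- c(value, value)
  } else {
    if (is.null(bounds) || length(bounds) != 2L || !all(is.finite(bounds)))
      stop("free parameter '", name, "' requires finite bounds c(lower, upper)")
    if (bounds[1] > bounds[2])
      stop("parameter '", name, "': lower bound exceeds upper bound")
  }
  structure(
    list(name = name, lower_bound = bounds[1], upper_bound = bounds[2],
         frozen = isTRUE(frozen), value = if (frozen) value else NULL),
    class = "parameter_spec"
  )
}

#' @export
print.parameter_spec <- function(x, ...) {
  if (x$frozen) {
    cat(sprintf("<parameter_spec> %s = %g (frozen)\n", x$name, x$value))
  } else {
    cat(sprintf("<parameter_spec> %s in [%g, %g]\n",
                x$name, x$lower_bound, x$upper_bound))
  }
  invisible(x)
}

# free (non-frozen) specs, in declaration order
free_params <- function(specs) {
  Filter(function(p) !p$frozen, specs)
}

# bounds matrix (2 x d) of the free parameters
free_bounds <- function(specs) {
  fp <- free_params(specs)
  vapply(fp, function(p) c(p$lower_bound, p$upper_bound), numeric(2))
}

free_param_names <- function(specs) {
  vapply(free_params(specs), `[[`, character(1), "name")
}

# merge a genome with the frozen values into a full named parameter vector
genome_to_params <- function(specs, genome) {
  fp_names <- free_param_names(specs)
  if (length(genome) != length(fp_names))
    stop("genome length ", length(genome), " != number of free parameters ",
         length(fp_names))
  out <- numeric(length(specs))
  names(out) <- vapply(specs, `[[`, character(1), "name")
  gi <- 1L
  for (i in seq_along(specs)) {
    if (specs[[i]]$frozen) {
      out[i] <- specs[[i]]$value
    } else {
      out[i] <- genome[gi]
      gi <- gi + 1L
    }
  }
  out
}

# check a genome against the free-parameter bounds; used at evaluation entry
check_genome_bounds <- function(specs, genome, tol = 1e-12) {
  b <- free_bounds(specs)
  if (length(genome) != ncol(b))
    stop("genome length mismatch: got ", length(genome), ", expected ", ncol(b))
  bad <- genome < b[1, ] - tol | genome > b[2, ] + tol
  if (any(bad))
    stop("genome violates bounds for parameter(s): ",
         paste(free_param_names(specs)[bad], collapse = ", "))
  invisible(TRUE)
}
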