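#' Mutation-model parameters
#'
#' Bundles the per-gene per-division mutation probability with the gene
#' counts and the transformation requirements of the multistage model.
#' `u` has no default: it must be supplied explicitly from a published
#' estimate of the per-gene mutation probability incurred by a single
#' somatic cell division (values on the order of `1e-7` are typical for
#' human coding genes).
#'
#' @param u Probability that a given coding gene mutates in one cell
#'   division (dimensionless, per gene per division). Must satisfy
#'   `0 <= u < 1e-3`; the model lives in the rare-mutation regime.
#' @param n_min Minimum number of oncogenic mutations required for
#'   transformation of a single cell (integer, `1..n_onco`).
#' @param S Sequence multiplicity: the average number of distinct
#'   mutational sequences (gene sets and/or temporal orderings) that
#'   achieve transformation. Scalar, `> 0`, applied to every sequence
#'   length. Under the default ordering model it is capped at `n_min!`
#'   when the per-cell probability is assembled.
#' @param n_onco Number of glioma proto-oncogenes (default 29, the size
#'   of the packaged oncogene set; see [load_oncogene_set()]).
#' @param G Total number of protein-encoding genes (default 18440).
#'
#' @return An object of class `mutation_params`: a named list with
#'   elements `u`, `n_min`, `S`, `n_onco`, `G` and the derived per-division
#'   oncogenic hit probability `u_o = n_onco * u`.
#' @examples
#' mutation_params(u = 1e-7, n_min = 5, S = 30)
#' @export
mutation_params <- function(u, n_min, S = 1, n_onco = 29L, G = 18440L) {
  check_number(u, "u", lower = 0)
  if (u >= 1e-3) {
    abort("`u` must be below 1e-3: the model assumes rare per-division mutation.")
  }
  n_onco <- check_count(n_onco, "n_onco", lower = 1L)
  G <- check_count(G, "G", lower = 1L)
  n_min <- check_count(n_min, "n_min", lower = 1L)
  if (n_min > n_onco) abort("`n_min` must not exceed `n_onco`.")
  if (n_onco > G) abort("`n_onco` must not exceed `G`.")
  check_number(S, "S")
  if (S <= 0) abort("`S` must be positive.")
  structure(
    list(u = u, n_min = n_min, S = S, n_onco = n_onco, G = G,
         u_o = n_onco * u),
    class = "mutation_params"
  )
}

#' @export
print.mutation_params <- function(x, ...) {
  cat("<mutation_params>\n")
  cat(sprintf("  u = %g per gene per division (u_o = %g over %d oncogenes)\n",
              x$u, x$u_o, x$n_onco))
  cat(sprintf("  n_min = %d of %d oncogenes, S = %g sequences, G = %d genes\n",
              x$n_min, x$n_onco, x$S, x$G))
  invisible(x)
}

#' Per-division probability of an oncogenic hit
#'
#' Probability that any one of the glioma oncogenes mutates in a single
#' cell division: `u_o = n_onco * u`. All genes are assumed to mutate
#' with equal probability, so the oncogenic hit rate is just the per-gene
#' rate scaled by the number of oncogenes.
#'
#' @param params A [mutation_params()] object.
#' @return The per-division oncogenic hit probability `u_o`.
#' @examples
#' oncogenic_hit_probability(mutation_params(u = 1e-7, n_min = 5))
#' @export
oncogenic_hit_probability <- function(params) {
  stopifnot(inherits(params, "mutation_params"))
  params$u_o
}

#' Exact binomial probability of x oncogenic hits
#'
#' Probability that exactly `x` of `d` cell divisions produced an
#' oncogenic mutation, each division hitting an oncogene independently
#' with probability `u_o`. Computed in log space
#' (`lchoose + x log u_o + (d - x) log1p(-u_o)`) for stability at the
#' large division counts a stem cell accumulates over a lifetime. This is
#' the exact reference against which the Poisson approximation
#' ([prob_x_hits_poisson()]) is validated.
#'
#' @param x Number of oncogenic hits (non-negative integer; vectorised).
#' @param d Number of cell divisions. Fractional `d` (from integrating a
#'   division-rate schedule) is rounded to the nearest integer.
#' @param u_o Per-division oncogenic hit probability, in `[0, 1]`.
#' @return Probability of exactly `x` hits; `0` when `x > d`.
#' @examples
#' prob_x_hits_binomial(0, 1000, 1e-6)
#' @export
prob_x_hits_binomial <- function(x, d, u_o) {
  check_number(u_o, "u_o", lower = 0, upper = 1)
  check_number(d, "d", lower = 0)
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) ||
      any(x != round(x))) {
    abort("`x` must be non-negative whole numbers.")
  }
  d <- round(d)
  out <- numeric(length(x))
  ok <- x <= d
  if (any(ok)) {
    if (u_o == 0) {
      out[ok] <- as.numeric(x[ok] == 0)
    } else if (u_o == 1) {
      out[ok] <- as.numeric(x[ok] == d)
    } else {
      lp <- lchoose(d, x[ok]) + x[ok] * log(u_o) + (d - x[ok]) * log1p(-u_o)
      out[ok] <- exp(lp)
    }
  }
  out[out < 1e-300] <- 0
  out
}

#' Poisson probability of x oncogenic hits
#'
#' Poisson approximation to [prob_x_hits_binomial()] with intensity
#' `lambda = u_o * D(t)`: accurate when the division count is large and
#' the per-division hit probability small, which holds across the human
#' lifespan for mutation probabilities of order `1e-7` per gene.
#'
#' @param x Number of oncogenic hits (non-negative integer; vectorised).
#' @param lambda Poisson intensity, `>= 0` (vectorised; recycled against
#'   `x` by the usual rules when one has length 1).
#' @return `lambda^x * exp(-lambda) / x!`.
#' @examples
#' prob_x_hits_poisson(1, 0.01)
#' @export
prob_x_hits_poisson <- function(x, lambda) {
  if (!is.numeric(lambda) || any(!is.finite(lambda)) || any(lambda < 0)) {
    abort("`lambda` must be non-negative and finite.")
  }
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) ||
      any(x != round(x))) {
    abort("`x` must be non-negative whole numbers.")
  }
  out <- dpois(x, lambda)
  out[out < 1e-300] <- 0
  out
}

# ordering seam: fraction of x-hit outcomes that transform, given S
ordering_fraction <- function(x, S, n_onco, ordering) {
  switch(ordering,
    fraction = {
      cap <- factorial(x)
      if (any(S > cap)) {
        abort(sprintf(
          "`S` exceeds the ordering cap x! = %g at x = %d: at most x! temporal orderings of x hits exist.",
          min(cap[S > cap]), x[which(S > cap)[1]]))
      }
      S / cap
    },
    all = rep(1, length(x)),
    permutation = {
      # number of ordered x-gene sequences drawn from the oncogene set
      perms <- exp(lfactorial(n_onco) - lfactorial(n_onco - x))
      if (any(S > perms)) {
        abort(sprintf(
          "`S` exceeds the ordering cap n_onco!/(n_onco-x)! = %g at x = %d.",
          min(perms[S > perms]), x[which(S > perms)[1]]))
      }
      S / perms
    },
    abort("`ordering` must be one of \"fraction\", \"all\", \"permutation\".")
  )
}

#' Probability that x hits occurred in a transforming order
#'
#' Weights the Poisson probability of `x` oncogenic hits by the fraction
#' of their temporal orderings that achieve transformation. Under the
#' default `"fraction"` model, `x` hits can arrive in `x!` orders of
#' which on average `S` transform, giving
#' `p_x = (S / x!) * lambda^x * exp(-lambda) / x!` - the factorial
#' denominator appearing twice makes long mutational sequences doubly
#' unlikely. `ordering = "all"` treats every order as transforming
#' (equivalent to `S = x!`), recovering the plain Poisson term;
#' `"permutation"` normalises `S` by the number of ordered `x`-gene
#' sequences drawn from the oncogene set.
#'
#' @inheritParams prob_x_hits_poisson
#' @param S Sequence multiplicity, `0 < S <= x!` under the default model.
#' @param n_onco Oncogene count, used only by the `"permutation"` model.
#' @param ordering Ordering model; see Details.
#' @return Probability that exactly `x` hits occurred and transformed.
#' @examples
#' prob_x_transforming(5, lambda = 0.05, S = 30)
#' @export
prob_x_transforming <- function(x, lambda, S, n_onco = 29L,
                                ordering = c("fraction", "all", "permutation")) {
  ordering <- match.arg(ordering)
  if (!is.numeric(x) || any(x < 1) || any(x != round(x))) {
    abort("`x` must be whole numbers >= 1: transformation needs at least one hit.")
  }
  check_number(S, "S")
  if (S <= 0) abort("`S` must be positive.")
  prob_x_hits_poisson(x, lambda) * ordering_fraction(x, S, n_onco, ordering)
}

#' Per-cell probability of oncogenic transformation
#'
#' Total probability that a single stem cell with accumulated mutation
#' intensity `lambda = u_o * D(t)` has undergone oncogenic
#' transformation: the sum of [prob_x_transforming()] over all possible
#' numbers of oncogenic hits, from the minimum `n_min` up to the size of
#' the oncogene set. Unlike the classical Armitage-Doll model, no single
#' hit count is privileged - every sufficient count contributes.
#'
#' @param lambda Poisson mutation intensity (vectorised, `>= 0`).
#' @param params A [mutation_params()] object.
#' @param ordering Ordering model passed to [prob_x_transforming()].
#' @return Per-cell transformation probability `P1` in `[0, 1]`, same
#'   length as `lambda`.
#' @examples
#' p <- mutation_params(u = 1e-7, n_min = 5, S = 30)
#' per_cell_transformation_prob(c(0, 0.05, 0.1), p)
#' @export
per_cell_transformation_prob <- function(lambda, params,
                                         ordering = c("fraction", "all",
                                                      "permutation")) {
  ordering <- match.arg(ordering)
  stopifnot(inherits(params, "mutation_params"))
  if (!is.numeric(lambda) || any(!is.finite(lambda)) || any(lambda < 0)) {
    abort("`lambda` must be non-negative and finite.")
  }
  if (params$n_min > params$n_onco) {
    warn("`n_min` exceeds `n_onco`: no attainable hit count, returning 0.")
    return(numeric(length(lambda)))
  }
  xs <- params$n_min:params$n_onco
  frac <- ordering_fraction(xs, params$S, params$n_onco, ordering)
  # Poisson-term recurrence p_x = p_(x-1) * lambda / x, much cheaper than
  # repeated dpois over a dense age grid; underflows (lambda > ~745) flush
  # to zero, consistent with the 1e-300 floor below
  p1 <- numeric(length(lambda))
  term <- exp(-lambda)
  for (x in seq_len(params$n_onco)) {
    term <- term * lambda / x
    if (x >= params$n_min) p1 <- p1 + frac[x - params$n_min + 1L] * term
  }
  p1[p1 < 1e-300] <- 0
  pmin(p1, 1)
}
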