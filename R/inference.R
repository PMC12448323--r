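## Maximum-likelihood estimation of (t2, t3) from site-pattern counts and
## of theta by marginalizing the multinomial likelihood over the
## coalescent prior on the times.

#' Joint coalescent density of the two coalescence times
#'
#' Density of `(t2, t3)` for a sample of three lineages from a
#' single panmictic population with scaled mutation rate `theta`:
#' the first coalescence waits an exponential time with rate `6/theta`
#' (three pairs, each at `2/theta`) and the second an independent
#' exponential with rate `2/theta`, so
#' `f(t2, t3) = (6/theta) exp(-6 t3/theta) (2/theta) exp(-2 (t2-t3)/theta)`
#' on `0 <= t3 <= t2`.  The implied means are `E[t3] = theta/6` and
#' `E[t2] = theta/6 + theta/2`.
#'
#' @inheritParams pattern_probs
#' @param theta population-scaled mutation rate, `> 0`.
#' @param log if `TRUE` return the log density.
#' @return Density value(s).
#' @export
coal_density <- function(t2, t3, theta, log = FALSE) {
  .check_times(t2, t3)
  if (!is.finite(theta) || theta <= 0) stop("theta must be > 0")
  ld <- log(12) - 2 * log(theta) - 6 * t3 / theta - 2 * (t2 - t3) / theta
  if (log) ld else exp(ld)
}

## Gauss-Legendre nodes/weights on [0, 1] via the Golub-Welsch
## eigenvalue construction; memoized per order.
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre01 <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  j <- seq_len(n - 1)
  beta <- j / sqrt(4 * j^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(j, j + 1)] <- beta
  J[cbind(j + 1, j)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  res <- list(nodes = (x[ord] + 1) / 2, weights = w[ord] / 2)
  .gl_cache[[key]] <- res
  res
}

## Quadrature grid for the marginal likelihood: tensor product of a
## Gauss-Legendre rule in u = t3/t2 on the unit interval with a
## composite Gauss-Legendre rule in y = log(t2) over [log(1e-13),
## log(150)].  The log-t2 panels resolve every scale the integrand can
## have: the prior knee at t2 ~ theta for any theta in the search
## interval, and the likelihood bump, whose log-scale width is
## ~1/sqrt(n sites).  The grid does not depend on theta or on the
## counts, so the pattern log-likelihood can be evaluated once per
## dataset and reused across theta evaluations.
.marg_grid_cache <- new.env(parent = emptyenv())
.marginal_grid <- function(nodes_u, panel_nodes) {
  key <- paste(nodes_u, panel_nodes)
  if (!is.null(.marg_grid_cache[[key]])) return(.marg_grid_cache[[key]])
  glu <- gauss_legendre01(nodes_u)
  glp <- gauss_legendre01(panel_nodes)
  edges <- seq(log(1e-13), log(150), length.out = 65)   # 64 panels
  y <- lwy <- numeric(0)
  for (i in seq_len(length(edges) - 1)) {
    h <- edges[i + 1] - edges[i]
    y <- c(y, edges[i] + h * glp$nodes)
    lwy <- c(lwy, log(h * glp$weights))
  }
  nt <- length(y)
  g <- list(
    u = rep(glu$nodes, times = nt),
    t2 = rep(exp(y), each = nodes_u),
    ## quadrature log-weights plus the Jacobian t2^2 of (t3, t2) ->
    ## (u, y = log t2)
    lw = rep(log(glu$weights), times = nt) + rep(lwy + 2 * y, each = nodes_u))
  .marg_grid_cache[[key]] <- g
  g
}

## per-dataset setup: pattern log-likelihood on the grid
.marginal_setup <- function(counts, topology, nodes = 64) {
  g <- .marginal_grid(nodes, max(6L, nodes %/% 5L))
  pos <- which(unclass(counts) > 0L)
  cnt <- as.numeric(counts)[pos]
  pr <- pattern_prob_row(topology, g$t2, g$u * g$t2)[, pos, drop = FALSE]
  list(base = g$lw + as.vector(log(pr) %*% cnt),
       t2 = g$t2, t3 = g$u * g$t2)
}

.marginal_eval <- function(setup, theta) {
  vapply(theta, function(th) {
    v <- setup$base + log(12) - 2 * log(th) -
      6 * setup$t3 / th - 2 * (setup$t2 - setup$t3) / th
    m <- max(v)
    if (m == -Inf) return(-Inf)       # likelihood underflow: log L = -Inf
    out <- m + log(sum(exp(v - m)))
    if (is.nan(out))
      stop("quadrature for the marginal likelihood did not converge ",
           "(NaN at theta = ", th, ")", call. = FALSE)
    out
  }, numeric(1))
}

#' Log marginal likelihood of theta given site-pattern counts
#'
#' Integrates the multinomial pattern likelihood over the coalescent
#' prior on the times,
#' `L(n | theta) = int_0^Inf int_0^t2 L(n | t2, t3) f(t2, t3 | theta) dt3 dt2`,
#' by deterministic tensor Gauss-Legendre quadrature after the change
#' of variables `u = t3/t2` (inner integral to the unit interval) and
#' `y = log(t2)` (outer integral over a composite panel rule covering
#' `t2` from 1e-13 to 150, so that both the prior scale `theta` and the
#' likelihood peak are resolved for any `theta` in the supported search
#' range).  The multinomial coefficient is omitted, consistently with
#' [loglik_patterns()].  Computation is on the log scale (log-sum-exp
#' over nodes), so large counts are safe.  The rule is tuned for locus
#' sizes up to a few tens of thousands of sites; far larger counts
#' concentrate the likelihood below the grid resolution.
#'
#' @inheritParams loglik_patterns
#' @param theta population-scaled mutation rate, `> 0` (may be a
#'   vector).
#' @param nodes quadrature order for the inner axis; the per-panel
#'   order of the outer composite rule scales with it (default 64,
#'   verified in the test-suite against refined grids and Monte-Carlo
#'   integration).
#' @return Log marginal likelihood (vector if `theta` is a vector).
#'   `-Inf` indicates likelihood underflow; NaN raises an error rather
#'   than being returned silently.
#' @export
marginal_loglik_theta <- function(counts, theta, topology, nodes = 64) {
  counts <- as_pattern_counts(counts)
  topology <- match.arg(topology, c("L", "R"))
  if (any(!is.finite(theta)) || any(theta <= 0)) stop("theta must be > 0")
  .marginal_eval(.marginal_setup(counts, topology, nodes), theta)
}

#' Maximum-likelihood estimate of theta from site-pattern counts
#'
#' Maximizes [marginal_loglik_theta()] over a bounded log-scale search
#' interval: a log-spaced multistart grid locates the basin and
#' [stats::optimize()] refines within the bracketing subinterval.  An
#' optimum within one grid step of the interval ends is flagged as a
#' boundary hit rather than silently clamped.
#'
#' @inheritParams marginal_loglik_theta
#' @param interval search interval for theta (default `[1e-4, 10]`).
#' @param n_grid size of the log-spaced multistart grid.
#' @return List of class `"theta_estimate"` with elements `theta_hat`,
#'   `logmarg_at_max`, `topology`, `converged`, `boundary`.
#' @export
mle_theta <- function(counts, topology, interval = c(1e-4, 10),
                      n_grid = 25, nodes = 64) {
  counts <- as_pattern_counts(counts)
  topology <- match.arg(topology, c("L", "R"))
  if (sum(counts) < 1L) stop("need at least one counted site")
  setup <- .marginal_setup(counts, topology, nodes)
  lg <- seq(log(interval[1]), log(interval[2]), length.out = n_grid)
  gv <- .marginal_eval(setup, exp(lg))
  i <- which.max(gv)
  lo <- lg[max(1L, i - 1L)]
  hi <- lg[min(n_grid, i + 1L)]
  opt <- optimize(function(l) .marginal_eval(setup, exp(l)),
                  c(lo, hi), maximum = TRUE, tol = 1e-10)
  boundary <- i == 1L || i == n_grid
  structure(list(theta_hat = exp(opt$maximum),
                 logmarg_at_max = opt$objective,
                 topology = topology,
                 converged = is.finite(opt$objective),
                 boundary = boundary),
            class = "theta_estimate")
}

#' Jointly estimate the two coalescence times by maximum likelihood
#'
#' Maximizes [loglik_patterns()] over the triangular region
#' `0 <= t3 <= t2` using the reparameterization `t3 = v * t2` with
#' `v` on the unit interval, bounded quasi-Newton search
#' (`optim(method = "L-BFGS-B")`) from several starting points, and a
#' final polish from the best optimum.  Estimates on the boundary
#' (`t3_hat = 0`, `t3_hat = t2_hat`, or `t2_hat = 0` for pure-constant
#' data) are returned with a `boundary` flag.
#'
#' @inheritParams loglik_patterns
#' @param t2_max upper bound of the `t2` search box (expected
#'   substitutions per site).
#' @param n_starts number of multistart points.
#' @return List of class `"time_estimate"` with elements `t2_hat`,
#'   `t3_hat`, `loglik_at_max`, `topology`, `converged`, `boundary`.
#' @export
mle_times <- function(counts, topology, t2_max = 10, n_starts = 5) {
  counts <- as_pattern_counts(counts)
  topology <- match.arg(topology, c("L", "R"))
  n <- sum(counts)
  if (n < 1L) stop("need at least one counted site")
  ## identity data: likelihood is maximized exactly at the origin
  if (counts[["xxx"]] == n)
    return(structure(list(t2_hat = 0, t3_hat = 0, loglik_at_max = 0,
                          topology = topology, converged = TRUE,
                          boundary = TRUE), class = "time_estimate"))
  negll <- function(par) {
    if (par[1] < 0 || par[1] > t2_max || par[2] < 0 || par[2] > 1)
      return(1e12)
    v <- loglik_patterns(counts, par[1], par[1] * par[2], topology)
    if (!is.finite(v)) 1e12 else -v
  }
  starts <- cbind(t2 = c(0.05, 0.2, 1, 0.02, 3)[seq_len(n_starts)],
                  v = c(0.4, 0.5, 0.3, 0.7, 0.5)[seq_len(n_starts)])
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], negll, method = "L-BFGS-B",
            lower = c(1e-9, 0), upper = c(t2_max, 1),
            control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("time optimization failed from every start")
  ## derivative-free polish from the incumbent (a Nelder-Mead simplex
  ## near the optimum does not suffer L-BFGS-B line-search stalls)
  fit <- optim(best$par, negll, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  converged <- fit$convergence == 0 || best$convergence == 0
  if (fit$value <= best$value) best <- fit
  t2_hat <- best$par[[1]]
  v_hat <- best$par[[2]]
  structure(list(t2_hat = t2_hat, t3_hat = v_hat * t2_hat,
                 loglik_at_max = -best$value,
                 topology = topology,
                 converged = converged,
                 boundary = v_hat <= 1e-7 || v_hat >= 1 - 1e-7 ||
                   t2_hat <= 1e-7 || t2_hat >= t2_max - 1e-7),
            class = "time_estimate")
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat(sprintf("theta_hat = %.5g  (topology %s, log marginal L = %.4f%s)\n",
              x$theta_hat, x$topology, x$logmarg_at_max,
              if (x$boundary) ", boundary" else ""))
  invisible(x)
}

#' @export
print.time_estimate <- function(x, ...) {
  cat(sprintf(
    "t2_hat = %.5g, t3_hat = %.5g  (topology %s, logL = %.4f%s)\n",
    x$t2_hat, x$t3_hat, x$topology, x$loglik_at_max,
    if (x$boundary) ", boundary" else ""))
  invisible(x)
}
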