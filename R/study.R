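## Replicate studies of the bias induced by fitting a single gene tree
## to a locus split by one recombination event.

#' Configuration for the replicate bias studies
#'
#' Defaults mirror the theta study: 500 replicates of a 200-site locus
#' split 100/100 by the recombination, theta = 0.1, per-site
#' recombination rate 1e-5.  The coalescence-time study uses the same
#' rates with `nL = nR = 50000`.
#'
#' @param reps number of replicates (`>= 1`).
#' @param nL,nR sites left and right of the breakpoint.
#' @param theta,rec_rate as in [simulate_fig2_times()].
#' @param seed master seed; per-replicate substreams are derived from
#'   it so any replicate is reproducible in isolation.
#' @return List of class `"study_config"`.
#' @export
study_config <- function(reps = 500, nL = 100, nR = 100, theta = 0.1,
                         rec_rate = 1e-5, seed = 1) {
  stopifnot(reps >= 1, nL >= 0, nR >= 0, nL + nR >= 1)
  if (!is.finite(theta) || theta <= 0) stop("theta must be > 0")
  if (!is.finite(rec_rate) || rec_rate <= 0) stop("rec_rate must be > 0")
  structure(list(reps = as.integer(reps), nL = as.integer(nL),
                 nR = as.integer(nR), theta = theta, rec_rate = rec_rate,
                 seed = as.integer(seed)),
            class = "study_config")
}

.rep_seeds <- function(config) {
  set.seed(config$seed)
  sample.int(.Machine$integer.max - 1L, config$reps)
}

.run_replicates <- function(config, fun) {
  seeds <- .rep_seeds(config)
  rows <- vector("list", config$reps)
  failed <- integer(0)
  for (i in seq_len(config$reps)) {
    set.seed(seeds[i])
    rows[[i]] <- tryCatch(fun(i), error = function(e) {
      warning("replicate ", i, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(rows[[i]])) failed <- c(failed, i)
  }
  if (length(failed) > 0.01 * config$reps)
    stop("replicate failure rate above 1% (failed: ",
         paste(head(failed, 10), collapse = ", "), ")", call. = FALSE)
  do.call(rbind, rows)
}

.ci_halfwidth <- function(x) qnorm(0.975) * sd(x) / sqrt(length(x))

#' Replicate study of theta estimation on a recombinant locus
#'
#' Per replicate: draw conditional coalescence times for the
#' one-recombination ARG, draw `nL` tree-L and `nR` tree-R site-pattern
#' counts, and estimate theta by maximizing the marginal likelihood for
#' (i) the combined counts analysed with topology L, ignoring the
#' recombination ("M"); (ii) the left counts with topology L; (iii) the
#' right counts with topology R.  Reports the mean estimate of each
#' analysis with a normal-approximation 95% confidence half-width for
#' the mean.
#'
#' @param config a [study_config()].
#' @param nodes quadrature order passed to [mle_theta()].
#' @return Object of class `"theta_study"`: list with `summary` (means
#'   `theta_bar_L/R/M` and half-widths `ci_halfwidth_L/R/M`),
#'   `replicates` (per-replicate data frame) and `config`.
#' @export
run_theta_study <- function(config = study_config(), nodes = 64) {
  stopifnot(inherits(config, "study_config"))
  s <- config$nL + config$nR
  reps <- .run_replicates(config, function(i) {
    times <- simulate_fig2_times(config$theta, config$rec_rate, s,
                                 breakpoint = config$nL)
    cts <- simulate_pattern_counts(times, config$nL, config$nR)
    fM <- mle_theta(cts$combined, "L", nodes = nodes)
    fL <- mle_theta(cts$left, "L", nodes = nodes)
    fR <- mle_theta(cts$right, "R", nodes = nodes)
    data.frame(rep = i, tr = times$tr, t3L = times$t3L, t3R = times$t3R,
               t2 = times$t2,
               theta_M = fM$theta_hat, theta_L = fL$theta_hat,
               theta_R = fR$theta_hat,
               boundary = fM$boundary || fL$boundary || fR$boundary)
  })
  structure(list(
    summary = list(theta_bar_L = mean(reps$theta_L),
                   theta_bar_R = mean(reps$theta_R),
                   theta_bar_M = mean(reps$theta_M),
                   ci_halfwidth_L = .ci_halfwidth(reps$theta_L),
                   ci_halfwidth_R = .ci_halfwidth(reps$theta_R),
                   ci_halfwidth_M = .ci_halfwidth(reps$theta_M),
                   reps = nrow(reps)),
    replicates = reps, config = config), class = "theta_study")
}

#' Replicate study of coalescence-time estimation on a recombinant locus
#'
#' Per replicate: draw conditional coalescence times, draw site-pattern
#' counts, and jointly estimate `(t2, t3)` by maximum likelihood from
#' (i) the left counts with topology L, (ii) the right counts with
#' topology R (both correctly specified), and (iii) the combined counts
#' with topology L (misspecified: it ignores the recombination).  The
#' bias statistics of the misspecified analysis are
#' `B2 = mean(t2_hat - t2)` and `B3 = mean(t3_hat - (t3L + t3R)/2)`.
#'
#' @inheritParams run_theta_study
#' @return Object of class `"time_study"`: list with `summary` (mean
#'   true times `t2_bar`, `t3L_bar`, `t3R_bar`, biases `B2`, `B3`,
#'   mean relative errors of the correctly specified analyses, `reps`),
#'   `replicates` and `config`.
#' @export
run_time_study <- function(config = study_config(nL = 50000, nR = 50000)) {
  stopifnot(inherits(config, "study_config"))
  s <- config$nL + config$nR
  reps <- .run_replicates(config, function(i) {
    times <- simulate_fig2_times(config$theta, config$rec_rate, s,
                                 breakpoint = config$nL)
    cts <- simulate_pattern_counts(times, config$nL, config$nR)
    fL <- mle_times(cts$left, "L")
    fR <- mle_times(cts$right, "R")
    fM <- mle_times(cts$combined, "L")
    data.frame(rep = i, tr = times$tr, t3L = times$t3L, t3R = times$t3R,
               t2 = times$t2,
               t2_hat_L = fL$t2_hat, t3_hat_L = fL$t3_hat,
               t2_hat_R = fR$t2_hat, t3_hat_R = fR$t3_hat,
               t2_hat_M = fM$t2_hat, t3_hat_M = fM$t3_hat)
  })
  structure(list(
    summary = list(t2_bar = mean(reps$t2),
                   t3L_bar = mean(reps$t3L),
                   t3R_bar = mean(reps$t3R),
                   B2 = mean(reps$t2_hat_M - reps$t2),
                   B3 = mean(reps$t3_hat_M - (reps$t3L + reps$t3R) / 2),
                   rel_err_t3_left = mean(abs(reps$t3_hat_L - reps$t3L) /
                                            reps$t3L),
                   rel_err_t3_right = mean(abs(reps$t3_hat_R - reps$t3R) /
                                             reps$t3R),
                   rel_err_t2_left = mean(abs(reps$t2_hat_L - reps$t2) /
                                            reps$t2),
                   rel_err_t2_right = mean(abs(reps$t2_hat_R - reps$t2) /
                                             reps$t2),
                   reps = nrow(reps)),
    replicates = reps, config = config), class = "time_study")
}

#' Write a study report to disk
#'
#' Writes `replicates.tsv` (one row per replicate), `summary.tsv`
#' (one row of summary statistics) and `run_info.txt` (seed, full
#' configuration and version stamps enabling an exact re-run) into
#' `dir`.
#'
#' @param study a `"theta_study"` or `"time_study"`.
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(study, dir) {
  if (!inherits(study, c("theta_study", "time_study")))
    stop("expected a theta_study or time_study object")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("replicates.tsv", "summary.tsv", "run_info.txt"))
  write.table(study$replicates, paths[1], sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(as.data.frame(study$summary), paths[2], sep = "\t",
              row.names = FALSE, quote = FALSE)
  cfg <- study$config
  writeLines(c(
    paste0("study: ", class(study)[1]),
    paste0("seed: ", cfg$seed),
    paste0("reps: ", cfg$reps),
    paste0("nL: ", cfg$nL), paste0("nR: ", cfg$nR),
    paste0("theta: ", format(cfg$theta)),
    paste0("rec_rate: ", format(cfg$rec_rate)),
    paste0("package: recoal ",
           as.character(utils::packageVersion("recoal"))),
    paste0("R: ", R.version.string),
    paste0("timestamp: ", format(Sys.time(), tz = "UTC", usetz = TRUE))),
    paths[3])
  invisible(paths)
}

#' @export
print.theta_study <- function(x, ...) {
  s <- x$summary
  cat("theta study over", s$reps, "replicates",
      sprintf("(theta = %g, r = %g, nL = %d, nR = %d)\n",
              x$config$theta, x$config$rec_rate, x$config$nL, x$config$nR))
  cat(sprintf("  theta_bar_L = %.3f +/- %.3f\n", s$theta_bar_L,
              s$ci_halfwidth_L))
  cat(sprintf("  theta_bar_R = %.3f +/- %.3f\n", s$theta_bar_R,
              s$ci_halfwidth_R))
  cat(sprintf("  theta_bar_M = %.3f +/- %.3f  (combined, recombination",
              s$theta_bar_M, s$ci_halfwidth_M), "ignored)\n")
  invisible(x)
}

#' @export
print.time_study <- function(x, ...) {
  s <- x$summary
  cat("coalescence-time study over", s$reps, "replicates\n")
  cat(sprintf("  true means: t2 = %.4f, t3L = %.4f, t3R = %.4f\n",
              s$t2_bar, s$t3L_bar, s$t3R_bar))
  cat(sprintf("  misspecified-analysis bias: B2 = %.4f, B3 = %.4f\n",
              s$B2, s$B3))
  invisible(x)
}
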