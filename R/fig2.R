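## Conditional simulation of coalescence times on the single-recombination
## ARG for three sequences: one lineage (a) recombines at time tr before
## any coalescence; the left fragment then coalesces with b (at t3L) and
## the right fragment with c (at t3R), in either order; the two resulting
## lineages coalesce at the shared root age t2.  Histories containing any
## other event (a second recombination, a different coalescing pair,
## back-coalescence of the two fragments) are excluded.
##
## Because every stage of the conditioned pathway has constant competing
## rates, the holding time of each stage, given that the stage's required
## event fires, is simply exponential with the stage's *total* rate (the
## identity of the minimum of independent exponentials is independent of
## its value).  The "stagewise" sampler exploits this and is exact; the
## "rejection" sampler simulates the unconditional event process and
## discards non-conforming histories, and is retained as a validation
## oracle (it is far too slow at realistic recombination rates).

.fig2_stage_rates <- function(theta, rec_rate, s, k) {
  ## total event rates of the four stages of the conditioned pathway;
  ## stage 3 material depends on which fragment coalesced first
  list(
    r1 = 6 / theta + 3 * rec_rate * s,          # 3 intact lineages
    r2 = 12 / theta + 2 * rec_rate * s,         # aL, aR, b, c
    r3_left_first  = 6 / theta + rec_rate * (3 * s - k),
    r3_right_first = 6 / theta + rec_rate * (2 * s + k),
    r4 = 2 / theta + 2 * rec_rate * s           # two s-site ancestors
  )
}

#' Simulate coalescence times conditional on the one-recombination ARG
#'
#' Draws the event times `(tr, t3L, t3R, t2)` of the three-sequence
#' coalescent with recombination conditioned on the event sequence in
#' which a single recombination on one lineage, before any coalescence,
#' splits the locus into a left tree L = ((a,b),c) and a right tree
#' R = ((a,c),b) sharing the root age `t2`.  Whether the left or the
#' right fragment coalesces first is random (each order has equal
#' conditional probability).  All times are in expected substitutions
#' per site.
#'
#' @param theta population-scaled mutation rate (pairwise coalescence
#'   rate `2/theta`).
#' @param rec_rate per-site recombination rate, in the same time units:
#'   a lineage carrying `l` sites recombines at rate `rec_rate * l`.
#' @param seq_length number of sites `s` in the locus (`>= 2`).
#' @param breakpoint recombination breakpoint: sites `< breakpoint`
#'   descend through the left fragment.  Defaults to the midpoint.
#' @param reps number of independent draws.
#' @param method `"stagewise"` (exact, fast; the default) or
#'   `"rejection"` (unconditional event simulation with rejection of
#'   non-conforming histories; validation oracle, very slow unless
#'   `rec_rate * seq_length` is comparable to `6/theta`).
#' @param max_attempts attempt budget for the rejection sampler;
#'   exhausted budgets raise an error.
#' @return A data frame of class `"fig2_times"` with columns `tr`,
#'   `t3L`, `t3R`, `t2` and one row per replicate, satisfying
#'   `0 < tr < min(t3L, t3R)` and `max(t3L, t3R) < t2`.
#' @examples
#' set.seed(1)
#' simulate_fig2_times(0.1, 1e-5, 200, reps = 3)
#' @export
simulate_fig2_times <- function(theta, rec_rate, seq_length,
                                breakpoint = floor(seq_length / 2),
                                reps = 1L,
                                method = c("stagewise", "rejection"),
                                max_attempts = 1e7) {
  method <- match.arg(method)
  if (!is.finite(theta) || theta <= 0) stop("theta must be > 0")
  if (!is.finite(rec_rate) || rec_rate <= 0)
    stop("rec_rate must be > 0 (the ARG is conditioned on a recombination)")
  if (seq_length < 2) stop("seq_length must be >= 2")
  if (breakpoint < 1 || breakpoint > seq_length - 1)
    stop("breakpoint must lie strictly inside the locus")
  if (reps < 1) stop("reps must be >= 1")
  if (method == "stagewise")
    .fig2_stagewise(theta, rec_rate, seq_length, breakpoint, reps)
  else
    .fig2_rejection(theta, rec_rate, seq_length, breakpoint, reps,
                    max_attempts)
}

.fig2_result <- function(tr, t3L, t3R, t2) {
  structure(data.frame(tr = tr, t3L = t3L, t3R = t3R, t2 = t2),
            class = c("fig2_times", "data.frame"))
}

.fig2_stagewise <- function(theta, rec_rate, s, k, reps) {
  rt <- .fig2_stage_rates(theta, rec_rate, s, k)
  tr <- rexp(reps, rt$r1)
  t_first <- tr + rexp(reps, rt$r2)
  left_first <- runif(reps) < 0.5
  r3 <- ifelse(left_first, rt$r3_left_first, rt$r3_right_first)
  t_second <- t_first + rexp(reps, r3)
  t2 <- t_second + rexp(reps, rt$r4)
  .fig2_result(tr,
               t3L = ifelse(left_first, t_first, t_second),
               t3R = ifelse(left_first, t_second, t_first),
               t2 = t2)
}

## Rejection oracle.  Attempts are processed in vectorized batches; an
## attempt survives a stage only if the stage's realized event is the one
## the conditioning requires (including the breakpoint landing at `k`,
## drawn uniformly over the s - 1 internal positions of an intact
## lineage).  Holding times are drawn from the stage's total event rate.
.fig2_rejection <- function(theta, rec_rate, s, k, reps, max_attempts) {
  out_tr <- out_f <- out_s <- out_t2 <- numeric(0)
  out_lf <- logical(0)
  rt <- .fig2_stage_rates(theta, rec_rate, s, k)
  attempts <- 0
  batch <- max(1000L, as.integer(min(reps * 50, 1e6)))
  while (length(out_tr) < reps) {
    if (attempts >= max_attempts)
      stop("rejection sampler exhausted its attempt budget (",
           format(max_attempts, scientific = TRUE), " attempts); ",
           "acceptance is ~", signif((3 * rec_rate * s) / rt$r1 /
             (s - 1) / 9, 2), " - use method = \"stagewise\"",
           call. = FALSE)
    nb <- as.integer(min(batch, max_attempts - attempts))
    attempts <- attempts + nb
    ## stage 1: need a recombination (rate 3 r s of total r1) with the
    ## uniformly drawn breakpoint landing on k
    t1 <- rexp(nb, rt$r1)
    is_rec <- runif(nb) < (3 * rec_rate * s) / rt$r1
    bp_ok <- sample.int(s - 1, nb, replace = TRUE) == k
    keep <- is_rec & bp_ok
    t1 <- t1[keep]
    n <- length(t1)
    if (n == 0) next
    ## stage 2: need coalescence of (aL,b) or (aR,c): 2 of the 6 pairs,
    ## each pair has rate 2/theta within total r2
    d1 <- rexp(n, rt$r2)
    u <- runif(n)
    p_pair <- (2 / theta) / rt$r2
    hit_left <- u < p_pair
    hit_right <- !hit_left & u < 2 * p_pair
    keep <- hit_left | hit_right
    t1 <- t1[keep]; d1 <- d1[keep]; left_first <- hit_left[keep]
    n <- length(t1)
    if (n == 0) next
    ## stage 3: need the remaining fragment's coalescence: 1 of 3 pairs
    r3 <- ifelse(left_first, rt$r3_left_first, rt$r3_right_first)
    d2 <- rexp(n, r3)
    keep <- runif(n) < (2 / theta) / r3
    t1 <- t1[keep]; d1 <- d1[keep]; d2 <- d2[keep]
    left_first <- left_first[keep]
    n <- length(t1)
    if (n == 0) next
    ## stage 4: need the final coalescence (no recombination first)
    d3 <- rexp(n, rt$r4)
    keep <- runif(n) < (2 / theta) / rt$r4
    t1 <- t1[keep]; d1 <- d1[keep]; d2 <- d2[keep]; d3 <- d3[keep]
    left_first <- left_first[keep]
    out_tr <- c(out_tr, t1)
    out_f <- c(out_f, t1 + d1)
    out_s <- c(out_s, t1 + d1 + d2)
    out_t2 <- c(out_t2, t1 + d1 + d2 + d3)
    out_lf <- c(out_lf, left_first)
  }
  idx <- seq_len(reps)
  .fig2_result(out_tr[idx],
               t3L = ifelse(out_lf[idx], out_f[idx], out_s[idx]),
               t3R = ifelse(out_lf[idx], out_s[idx], out_f[idx]),
               t2 = out_t2[idx])
}

#' Draw multinomial site-pattern counts on the left and right trees
#'
#' Given one realization of the conditional coalescence times, draws
#' `nL` sites from the five-category multinomial with the tree-L
#' probabilities at `(t2, t3L)` and `nR` sites from the tree-R
#' probabilities at `(t2, t3R)`.
#'
#' @param times a one-row `"fig2_times"` data frame (or any list with
#'   elements `t2`, `t3L`, `t3R`).
#' @param nL,nR numbers of sites left and right of the breakpoint.
#' @return List with `"pattern_counts"` elements `left`, `right` and
#'   `combined` (the elementwise sum).
#' @export
simulate_pattern_counts <- function(times, nL, nR) {
  if (nL < 0 || nR < 0 || nL + nR < 1)
    stop("need non-negative nL, nR with nL + nR >= 1")
  t2 <- times$t2[1]; t3L <- times$t3L[1]; t3R <- times$t3R[1]
  draw <- function(n, topology, t3) {
    if (n == 0) return(pattern_counts())
    as_pattern_counts(drop(rmultinom(1, n, pattern_prob_row(topology, t2, t3))))
  }
  left <- draw(nL, "L", t3L)
  right <- draw(nR, "R", t3R)
  list(left = left, right = right,
       combined = as_pattern_counts(unclass(left) + unclass(right)))
}

#' Realize a three-sequence nucleotide alignment from pattern counts
#'
#' Produces an alignment of sequences a, b, c whose columns realize the
#' given site-pattern counts, left-block columns first.  Concrete
#' nucleotides are drawn uniformly among the assignments consistent
#' with each pattern, so [count_patterns()] on the result recovers the
#' inputs exactly.
#'
#' @param left_counts,right_counts `"pattern_counts"` vectors (the
#'   right block may be omitted for a single-tree locus).
#' @param file optional path; if given the alignment is also written as
#'   FASTA.
#' @return A 3 x n character matrix with rows `a`, `b`, `c`.
#' @export
emit_alignment <- function(left_counts, right_counts = pattern_counts(),
                           file = NULL) {
  left_counts <- as_pattern_counts(left_counts)
  right_counts <- as_pattern_counts(right_counts)
  cols <- cbind(.pattern_columns(left_counts), .pattern_columns(right_counts))
  rownames(cols) <- c("a", "b", "c")
  if (!is.null(file)) {
    ape::write.FASTA(ape::as.DNAbin(cols), file)
    return(invisible(cols))
  }
  cols
}

## one concrete ACGT column per requested pattern
.pattern_columns <- function(counts) {
  nuc <- c("A", "C", "G", "T")
  n <- sum(counts)
  out <- matrix("", 3, n)
  j <- 0L
  for (pat in pattern_levels()) {
    for (i in seq_len(counts[[pat]])) {
      pick <- sample(nuc)   # random permutation; x = pick[1], y = pick[2], ...
      col <- switch(pat,
        xxx = pick[c(1, 1, 1)],
        xyz = pick[1:3],
        yxx = pick[c(2, 1, 1)],
        xyx = pick[c(1, 2, 1)],
        xxy = pick[c(1, 1, 2)])
      j <- j + 1L
      out[, j] <- col
    }
  }
  out
}

#' @export
print.fig2_times <- function(x, ...) {
  cat("conditional one-recombination coalescence times (",
      nrow(x), " draw", if (nrow(x) != 1) "s", ")\n", sep = "")
  print.data.frame(head(x, 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
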