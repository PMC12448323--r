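## Site-pattern machinery for three sequences (a, b, c) under JC69 on a
## clock tree with first coalescence at t3 and root at t2.  The five
## informative patterns, in the fixed order used throughout, are
##   xxx  all three bases equal
##   xyz  all three distinct
##   yxx  a differs, b == c
##   xyx  b differs, a == c
##   xxy  c differs, a == b

#' @rdname count_patterns
#' @export
pattern_levels <- function() c("xxx", "xyz", "yxx", "xyx", "xxy")

.check_times <- function(t2, t3) {
  if (!is.numeric(t2) || !is.numeric(t3) || anyNA(t2) || anyNA(t3) ||
      any(!is.finite(t2)) || any(!is.finite(t3)))
    stop("t2 and t3 must be finite numeric values", call. = FALSE)
  if (any(t3 < 0) || any(t2 < 0))
    stop("coalescence times must be non-negative", call. = FALSE)
  if (any(t3 > t2))
    stop("t3 must not exceed t2", call. = FALSE)
  invisible(TRUE)
}

## vectorized core: returns a matrix with columns P, Q, P1, P2
.pattern_probs <- function(t2, t3) {
  e1 <- exp(-4 * (2 * t2 + t3) / 3)
  e2 <- exp(-8 * t2 / 3)
  e3 <- exp(-8 * t3 / 3)
  m <- cbind(P  = (6 * e1 + 6 * e2 + 3 * e3 + 1) / 16,
             Q  = 3 * (2 * e1 - 2 * e2 - e3 + 1) / 8,
             P1 = 3 * (-2 * e1 - 2 * e2 + 3 * e3 + 1) / 16,
             P2 = 3 * (-2 * e1 + 2 * e2 - e3 + 1) / 16)
  ## guard against cancellation pushing analytic zeros a few ulp outside [0, 1]
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

#' JC69 site-pattern probabilities on a three-taxon clock tree
#'
#' Closed-form probabilities of the five informative site patterns for
#' three sequences under JC69, parameterized by the root age `t2` and
#' the first coalescence time `t3` (both in expected substitutions per
#' site).  `P` is the probability of a constant column (xxx), `Q` of a
#' column with three distinct bases (xyz), and `P1`/`P2` are the two
#' shared-pair probabilities.  The pattern concordant with the tree
#' topology (xxy for L = ((a,b),c), xyx for R = ((a,c),b)) has
#' probability `P1`; the two discordant shared-pair patterns have
#' probability `P2`.  The identity `P + Q + P1 + 2 * P2 = 1` holds.
#'
#' @param t2 root age, `>= t3`.
#' @param t3 first coalescence time, `>= 0`.  Both arguments may be
#'   vectors of equal length.
#' @return For scalar input a named numeric vector `(P, Q, P1, P2)`;
#'   for vector input a matrix with those columns.
#' @seealso [pattern_prob_row()] for the probabilities arranged by
#'   pattern for a given topology, [pruning_probs()] for an independent
#'   computation by summation over internal states.
#' @examples
#' pattern_probs(0.08, 0.03)
#' @export
pattern_probs <- function(t2, t3) {
  .check_times(t2, t3)
  m <- .pattern_probs(t2, t3)
  if (length(t2) == 1L && length(t3) == 1L) drop(m) else m
}

#' Pattern probabilities arranged by site pattern for one topology
#'
#' Returns the probabilities of the five site patterns, in the order
#' `xxx, xyz, yxx, xyx, xxy`, for the left tree L = ((a,b),c) or the
#' right tree R = ((a,c),b).  `P` and `Q` do not depend on the
#' topology; the shared-pair probabilities `P1` and `P2` are swapped
#' between patterns xyx and xxy when the topology changes, and pattern
#' yxx (b == c) has probability `P2` under both topologies.
#'
#' @inheritParams pattern_probs
#' @param topology `"L"` or `"R"`.
#' @return Named numeric vector of length 5 summing to 1 (a matrix with
#'   one row per input element for vector input).
#' @export
pattern_prob_row <- function(topology, t2, t3) {
  topology <- match.arg(topology, c("L", "R"))
  .check_times(t2, t3)
  m <- .pattern_probs(t2, t3)
  out <- if (topology == "L")
    cbind(m[, "P"], m[, "Q"], m[, "P2"], m[, "P2"], m[, "P1"])
  else
    cbind(m[, "P"], m[, "Q"], m[, "P2"], m[, "P1"], m[, "P2"])
  colnames(out) <- pattern_levels()
  if (nrow(out) == 1L) drop(out) else out
}

#' Pattern probabilities by explicit summation over internal states
#'
#' Independent verification oracle for [pattern_probs()]: computes the
#' five site-pattern probabilities by enumerating all base assignments
#' at the two internal nodes of the three-taxon clock tree and
#' multiplying JC69 transition probabilities along branches (tip
#' branches of length `t3`, `t3`, `t2`; internal branch `t2 - t3`).
#' Deliberately written without reference to the closed forms; used in
#' the test-suite to validate them.
#'
#' @inheritParams pattern_prob_row
#' @return Named numeric vector of length 5 (order `xxx, xyz, yxx,
#'   xyx, xxy`) summing to 1.
#' @export
pruning_probs <- function(t2, t3, topology = "L") {
  topology <- match.arg(topology, c("L", "R"))
  .check_times(t2, t3)
  pjc <- function(t) {
    m <- matrix(1 / 4 - exp(-4 * t / 3) / 4, 4, 4)
    diag(m) <- 1 / 4 + 3 * exp(-4 * t / 3) / 4
    m
  }
  Ptip <- pjc(t3)        # pair tips, below the first coalescence
  Pout <- pjc(t2)        # outgroup tip, hangs from the root
  Pint <- pjc(t2 - t3)   # internal branch
  out <- setNames(numeric(5), pattern_levels())
  for (x in 1:4) for (y in 1:4) for (z in 1:4) {
    ## (x, y) = the coalescing pair, z = the odd taxon out
    p <- 0
    for (root in 1:4) for (u in 1:4)
      p <- p + 0.25 * Pint[root, u] * Ptip[u, x] * Ptip[u, y] * Pout[root, z]
    abc <- if (topology == "L") c(x, y, z) else c(x, z, y)
    lab <- classify_site(abc[1], abc[2], abc[3])
    out[lab] <- out[lab] + p
  }
  out
}

#' Classify an alignment column into one of the five site patterns
#'
#' @param a,b,c single bases (or equal-length vectors of bases) from
#'   sequences a, b and c.  Any atomic values may be compared; for
#'   nucleotide data use characters among `A, C, G, T` (case
#'   insensitive).  Ambiguity codes and gaps are rejected.
#' @return Character vector of pattern labels among
#'   `xxx, xyz, yxx, xyx, xxy`.
#' @examples
#' classify_site("A", "T", "T")  # "yxx"
#' @export
classify_site <- function(a, b, c) {
  if (length(a) != length(b) || length(b) != length(c))
    stop("a, b and c must have equal length", call. = FALSE)
  if (is.character(a) || is.character(b) || is.character(c)) {
    a <- toupper(a); b <- toupper(b); c <- toupper(c)
    bad <- !(a %in% c("A", "C", "G", "T")) | !(b %in% c("A", "C", "G", "T")) |
      !(c %in% c("A", "C", "G", "T"))
    if (any(bad))
      stop("unsupported characters (ambiguity codes or gaps?) at position(s) ",
           paste(head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  ifelse(a == b & b == c, "xxx",
  ifelse(a != b & b != c & a != c, "xyz",
  ifelse(b == c, "yxx",
  ifelse(a == c, "xyx", "xxy"))))
}

#' Construct and validate a vector of site-pattern counts
#'
#' @param nxxx,nxyz,nyxx,nxyx,nxxy non-negative integer counts of the
#'   five site patterns (sequences read in the order a, b, c).
#' @param x for `as_pattern_counts()`, a numeric vector of length 5,
#'   named or in the canonical order `xxx, xyz, yxx, xyx, xxy`.
#' @return An integer vector of class `"pattern_counts"` with the five
#'   canonical names.
#' @export
pattern_counts <- function(nxxx = 0, nxyz = 0, nyxx = 0, nxyx = 0, nxxy = 0) {
  as_pattern_counts(c(xxx = nxxx, xyz = nxyz, yxx = nyxx,
                      xyx = nxyx, xxy = nxxy))
}

#' @rdname pattern_counts
#' @export
as_pattern_counts <- function(x) {
  if (length(x) != 5L || anyNA(x) || any(x < 0) || any(x != round(x)))
    stop("pattern counts must be 5 non-negative integers", call. = FALSE)
  if (!is.null(names(x))) {
    if (!setequal(names(x), pattern_levels()))
      stop("pattern count names must be ", paste(pattern_levels(),
           collapse = ", "), call. = FALSE)
    x <- x[pattern_levels()]
  } else names(x) <- pattern_levels()
  structure(as.integer(x), names = pattern_levels(),
            class = "pattern_counts")
}

#' Tally site patterns in a three-sequence alignment
#'
#' @param x a 3-row character matrix (rows = sequences a, b, c), an
#'   [ape::DNAbin] alignment with 3 sequences, or the path to a FASTA
#'   file containing 3 aligned sequences.
#' @param skip_bad if `TRUE`, columns containing gaps or ambiguity
#'   codes are skipped with a warning instead of raising an error.
#' @return A `"pattern_counts"` vector; the counts sum to the number of
#'   retained columns.
#' @export
count_patterns <- function(x, skip_bad = FALSE) {
  m <- .as_alignment_matrix(x)
  ok <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  if (!all(ok)) {
    if (!skip_bad)
      stop("alignment contains gaps or ambiguity codes at column(s) ",
           paste(head(which(!ok), 5), collapse = ", "),
           "; use skip_bad = TRUE to drop them", call. = FALSE)
    warning("skipping ", sum(!ok), " column(s) with non-ACGT characters")
    m <- m[, ok, drop = FALSE]
  }
  lab <- classify_site(m[1, ], m[2, ], m[3, ])
  tab <- table(factor(lab, levels = pattern_levels()))
  as_pattern_counts(as.integer(tab))
}

.as_alignment_matrix <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- ape::read.FASTA(x)
  if (inherits(x, "DNAbin"))
    x <- toupper(as.character(as.matrix(x)))
  if (!is.matrix(x) || !is.character(x))
    stop("expected a character matrix, DNAbin alignment or FASTA path",
         call. = FALSE)
  if (nrow(x) != 3L)
    stop("exactly three sequences (a, b, c) are required", call. = FALSE)
  if (ncol(x) < 1L) stop("alignment has no columns", call. = FALSE)
  toupper(x)
}

#' Multinomial log-likelihood of site-pattern counts
#'
#' Computes `sum(n * log p)` where `p` are the pattern probabilities of
#' [pattern_prob_row()] at `(t2, t3)` for the given topology.  The
#' multinomial coefficient, which does not depend on the times, is
#' omitted.  Returns `-Inf` when a pattern with positive count has zero
#' probability (e.g. non-constant columns at `t2 = t3 = 0`).
#'
#' @param counts a `"pattern_counts"` vector (or anything accepted by
#'   [as_pattern_counts()]).
#' @inheritParams pattern_prob_row
#' @return Scalar log-likelihood.
#' @export
loglik_patterns <- function(counts, t2, t3, topology) {
  counts <- as_pattern_counts(counts)
  p <- pattern_prob_row(topology, t2, t3)
  pos <- counts > 0L
  if (!any(pos)) stop("all pattern counts are zero", call. = FALSE)
  if (any(p[pos] <= 0)) return(-Inf)
  sum(counts[pos] * log(p[pos]))
}

#' @export
print.pattern_counts <- function(x, ...) {
  cat("site-pattern counts (n =", sum(x), "sites)\n")
  print(setNames(as.integer(x), names(x)))
  invisible(x)
}
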