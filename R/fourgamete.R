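## Four-gamete test: under infinite sites, all four haplotypes at a pair
## of biallelic loci cannot be observed without at least one
## recombination between them.

#' Four-gamete test on a pair of biallelic sites
#'
#' Counts the distinct two-locus haplotypes among the sampled
#' chromosomes and flags recombination when all four allele
#' combinations are present.  The flag implies a recombination only
#' under the infinite-sites assumption: recurrent mutation at a site
#' can also produce four haplotypes.
#'
#' @param x,y allele vectors at the two sites, one element per
#'   chromosome (any atomic type).  Each site must be biallelic among
#'   the sampled chromosomes; monomorphic or >2-allele sites are
#'   rejected.
#' @return List of class `"pair_test"` with `n_haplotypes` (<= 4) and
#'   `recombination_inferred` (`TRUE` iff `n_haplotypes == 4`).
#' @examples
#' four_gamete_test(c("G", "A", "A"), c("T", "T", "C"))   # 3 haplotypes
#' four_gamete_test(c("G", "G", "A", "A"), c("T", "C", "T", "C"))
#' @export
four_gamete_test <- function(x, y) {
  if (length(x) != length(y))
    stop("allele vectors must have equal length", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing alleles are not supported in strict mode", call. = FALSE)
  for (v in list(x, y)) {
    k <- length(unique(v))
    if (k < 2L) stop("site is monomorphic", call. = FALSE)
    if (k > 2L) stop("site has more than two alleles", call. = FALSE)
  }
  n_hap <- nrow(unique(cbind(as.character(x), as.character(y))))
  structure(list(n_haplotypes = n_hap,
                 recombination_inferred = n_hap == 4L),
            class = "pair_test")
}

#' Scan all biallelic site pairs of a haplotype table or alignment
#'
#' Applies [four_gamete_test()] to every pair of biallelic sites.  The
#' count of incompatible (four-gamete) pairs is a lower-bound-style
#' signal: recombinations that do not produce all four haplotypes are
#' invisible to the test.
#'
#' @param x a chromosomes-by-sites matrix of alleles (e.g. the output
#'   of [sim_snp_haplotypes()]), an [ape::DNAbin] alignment, or a FASTA
#'   path (sequences become chromosomes, columns sites).
#' @return Object of class `"fourgamete_scan"`: list with `pairs`
#'   (data frame `site1`, `site2`, `n_haplotypes`,
#'   `recombination_inferred` over all biallelic pairs, in position
#'   order), `n_flagged`, `biallelic_sites` and `excluded_sites` (the
#'   monomorphic or >2-allele sites, listed rather than silently
#'   dropped).
#' @export
scan_fourgamete <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- ape::read.FASTA(x)
  if (inherits(x, "DNAbin")) x <- toupper(as.character(as.matrix(x)))
  if (!is.matrix(x)) stop("expected a chromosomes-by-sites matrix")
  n_allele <- apply(x, 2, function(col) length(unique(col)))
  bi <- which(n_allele == 2L)
  if (length(bi) < 2L)
    stop("need at least two biallelic sites (found ", length(bi), ")")
  prs <- utils::combn(bi, 2L)
  res <- apply(prs, 2, function(ij) {
    t <- four_gamete_test(x[, ij[1]], x[, ij[2]])
    c(ij[1], ij[2], t$n_haplotypes, t$recombination_inferred)
  })
  pairs <- data.frame(site1 = res[1, ], site2 = res[2, ],
                      n_haplotypes = res[3, ],
                      recombination_inferred = as.logical(res[4, ]))
  structure(list(pairs = pairs,
                 n_flagged = sum(pairs$recombination_inferred),
                 biallelic_sites = bi,
                 excluded_sites = setdiff(seq_len(ncol(x)), bi)),
            class = "fourgamete_scan")
}

#' @export
print.pair_test <- function(x, ...) {
  cat(x$n_haplotypes, "distinct haplotypes;",
      if (x$recombination_inferred)
        "recombination inferred (under infinite sites)\n"
      else "compatible with a single tree\n")
  invisible(x)
}

#' @export
print.fourgamete_scan <- function(x, ...) {
  cat("four-gamete scan:", length(x$biallelic_sites), "biallelic sites,",
      nrow(x$pairs), "pairs,", x$n_flagged, "incompatible\n")
  if (length(x$excluded_sites))
    cat("  excluded (not biallelic):",
        paste(head(x$excluded_sites, 10), collapse = ", "),
        if (length(x$excluded_sites) > 10) "...", "\n")
  invisible(x)
}
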