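## Single-population coalescent with recombination.  Time runs backwards
## from the sampled chromosomes in units of expected substitutions per
## site: with k extant lineages each pair coalesces at rate 2/theta, and
## a lineage carrying l sites of material ancestral to the sample
## recombines at rate rec_rate * l, the breakpoint falling uniformly on
## the internal positions of the lineage's ancestral span (so trapped
## non-ancestral segments are breakable, as in the full ARG).  Sites
## that have reached their most recent common ancestor are no longer
## ancestral to the sample and stop contributing to rates; the process
## ends when every site has done so.

#' Configuration for the coalescent-with-recombination simulator
#'
#' @param n_samples number of sampled chromosomes (`>= 2`).
#' @param seq_length number of sites per chromosome (`>= 1`).
#' @param theta population-scaled mutation rate per site; sets the time
#'   scale (expected substitutions per site), with pairwise coalescence
#'   rate `2/theta`.
#' @param rec_rate per-site recombination rate in the same units
#'   (`>= 0`).
#' @param seed optional integer seed applied at the start of
#'   [simulate_arg()].
#' @param max_events safety cap on the total event count; exceeding it
#'   signals a runaway simulation (misconfigured rates).
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 3, seq_length = 100, theta = 0.1,
                       rec_rate = 0, seed = NULL, max_events = 1e6) {
  stopifnot(n_samples >= 2, seq_length >= 1)
  if (!is.finite(theta) || theta <= 0) stop("theta must be finite and > 0")
  if (!is.finite(rec_rate) || rec_rate < 0)
    stop("rec_rate must be finite and >= 0")
  structure(list(n_samples = as.integer(n_samples),
                 seq_length = as.integer(seq_length),
                 theta = theta, rec_rate = rec_rate, seed = seed,
                 max_events = max_events),
            class = "sim_config")
}

#' Simulate an ancestral recombination graph
#'
#' Runs the competing-exponentials event process of the coalescent with
#' recombination until every site has reached its most recent common
#' ancestor.  The returned event list, together with the lineage ids it
#' references (tips are `1..n_samples`), fully determines the marginal
#' gene tree of every site; see [marginal_tree()].
#'
#' @param config a [sim_config()].
#' @return Object of class `"arg"`: a list with the `config`, the event
#'   data frame `events` (columns `type`, `time`, `child1`, `child2`,
#'   `parent1`, `parent2`, `breakpoint`), the number of recombination
#'   events `n_rec`, and `rec_exposure`, the history-integrated
#'   recombination intensity `rec_rate * sum_lineages length * lifetime`
#'   (the compensator of the recombination counting process, used by
#'   the calibration tests).
#' @examples
#' arg <- simulate_arg(sim_config(n_samples = 3, seq_length = 10,
#'                                theta = 0.1, rec_rate = 0.01, seed = 1))
#' count_distinct_trees(arg)
#' @export
simulate_arg <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_samples
  s <- config$seq_length
  theta <- config$theta
  r <- config$rec_rate

  ## active lineages: list of logical material vectors, named by id
  material <- lapply(seq_len(n), function(i) rep(TRUE, s))
  ids <- seq_len(n)
  next_id <- n + 1L
  carriers <- rep(n, s)        # lineages carrying each unresolved site
  unresolved <- rep(TRUE, s)

  ev_type <- character(0); ev_time <- numeric(0)
  ev_c1 <- ev_c2 <- ev_p1 <- ev_p2 <- ev_bp <- integer(0)
  t <- 0
  exposure <- 0
  n_events <- 0L

  lens <- vapply(material, sum, integer(1))
  while (any(unresolved)) {
    k <- length(ids)
    rate_coal <- k * (k - 1) / theta
    rate_rec <- r * sum(lens)
    total <- rate_coal + rate_rec
    if (total <= 0) stop("event rate fell to zero before completion")
    dt <- rexp(1, total)
    t <- t + dt
    exposure <- exposure + rate_rec * dt
    n_events <- n_events + 1L
    if (n_events > config$max_events)
      stop("event cap exceeded (", config$max_events,
           " events): runaway simulation, check theta/rec_rate",
           call. = FALSE)
    if (runif(1) < rate_rec / total) {
      ## recombination on a lineage chosen proportionally to material
      li <- sample.int(k, 1L, prob = lens)
      mat <- material[[li]]
      span <- range(which(mat))
      if (span[2] > span[1]) {
        bp <- span[1] + sample.int(span[2] - span[1], 1L)  # sites >= bp go right
      } else bp <- NA_integer_                             # unsplittable span
      left <- mat; right <- mat
      if (!is.na(bp)) {
        left[bp:s] <- FALSE
        right[seq_len(bp - 1L)] <- FALSE
      } else right[] <- FALSE
      id_l <- next_id; id_r <- next_id + 1L; next_id <- next_id + 2L
      ev_type <- c(ev_type, "rec"); ev_time <- c(ev_time, t)
      ev_c1 <- c(ev_c1, ids[li]); ev_c2 <- c(ev_c2, NA_integer_)
      ev_p1 <- c(ev_p1, id_l); ev_p2 <- c(ev_p2, id_r)
      ev_bp <- c(ev_bp, if (is.na(bp)) s + 1L else bp)
      ## replace child by the non-empty parents
      material[[li]] <- left; ids[li] <- id_l
      keep_l <- any(left)
      if (any(right)) { material <- c(material, list(right)); ids <- c(ids, id_r) }
      if (!keep_l) { material[[li]] <- NULL; ids <- ids[-li] }
      lens <- vapply(material, sum, integer(1))
    } else {
      pair <- sample.int(k, 2L)
      m1 <- material[[pair[1]]]; m2 <- material[[pair[2]]]
      pid <- next_id; next_id <- next_id + 1L
      ev_type <- c(ev_type, "coal"); ev_time <- c(ev_time, t)
      ev_c1 <- c(ev_c1, ids[pair[1]]); ev_c2 <- c(ev_c2, ids[pair[2]])
      ev_p1 <- c(ev_p1, pid); ev_p2 <- c(ev_p2, NA_integer_)
      ev_bp <- c(ev_bp, NA_integer_)
      merged <- m1 | m2
      ## sites where both children carried material lose one carrier;
      ## a site dropping to one carrier is resolved and leaves the
      ## ancestral material
      both <- m1 & m2 & unresolved
      carriers[both] <- carriers[both] - 1L
      done <- both & carriers == 1L
      if (any(done)) {
        unresolved[done] <- FALSE
        merged[done] <- FALSE
      }
      material[[pair[1]]] <- merged
      ids[pair[1]] <- pid
      material[[pair[2]]] <- NULL
      ids <- ids[-pair[2]]
      ## drop lineages emptied by resolution
      lens <- vapply(material, sum, integer(1))
      empty <- lens == 0L
      if (any(empty)) {
        material <- material[!empty]
        ids <- ids[!empty]
        lens <- lens[!empty]
      }
    }
  }
  structure(list(config = config,
                 events = data.frame(type = ev_type, time = ev_time,
                                     child1 = ev_c1, child2 = ev_c2,
                                     parent1 = ev_p1, parent2 = ev_p2,
                                     breakpoint = ev_bp),
                 n_rec = sum(ev_type == "rec"),
                 rec_exposure = exposure),
            class = "arg")
}

## Replay the event list at one site: returns the merge events (times
## and merged tip sets) that concern the site, oldest last.
.replay_site <- function(arg, site) {
  n <- arg$config$n_samples
  ## carrier map: lineage id -> indices of tips it represents at `site`
  carrier <- as.list(seq_len(n))
  names(carrier) <- as.character(seq_len(n))
  merges <- list()
  ev <- arg$events
  for (i in seq_len(nrow(ev))) {
    if (ev$type[i] == "coal") {
      a <- carrier[[as.character(ev$child1[i])]]
      b <- carrier[[as.character(ev$child2[i])]]
      if (!is.null(a) && !is.null(b)) {
        merges[[length(merges) + 1L]] <-
          list(time = ev$time[i], left = a, right = b, event = i)
        carrier[[as.character(ev$parent1[i])]] <- c(a, b)
        carrier[[as.character(ev$child1[i])]] <- NULL
        carrier[[as.character(ev$child2[i])]] <- NULL
        if (length(carrier[[as.character(ev$parent1[i])]]) == n) break
      } else if (!is.null(a) || !is.null(b)) {
        carrier[[as.character(ev$parent1[i])]] <- if (is.null(a)) b else a
        carrier[[as.character(ev$child1[i])]] <- NULL
        carrier[[as.character(ev$child2[i])]] <- NULL
      }
    } else {
      ch <- carrier[[as.character(ev$child1[i])]]
      if (!is.null(ch)) {
        tgt <- if (site < ev$breakpoint[i]) ev$parent1[i] else ev$parent2[i]
        carrier[[as.character(tgt)]] <- ch
        carrier[[as.character(ev$child1[i])]] <- NULL
      }
    }
  }
  merges
}

#' Extract the marginal gene tree of one site
#'
#' Follows, at each recombination node of the ARG, the parent lineage
#' carrying the site, and returns the resulting genealogy as an
#' ultrametric [ape::phylo] tree with branch lengths in expected
#' substitutions per site.  Tips are labelled `t1..tn` in sampling
#' order.
#'
#' @param arg an `"arg"` object from [simulate_arg()].
#' @param site site index in `1..seq_length`.
#' @return An [ape::phylo] tree.
#' @export
marginal_tree <- function(arg, site) {
  stopifnot(inherits(arg, "arg"))
  s <- arg$config$seq_length
  if (length(site) != 1L || is.na(site) || site < 1 || site > s)
    stop("site must be in 1..", s, call. = FALSE)
  merges <- .replay_site(arg, site)
  n <- arg$config$n_samples
  ## assemble newick bottom-up: each cluster tracked as (string, height)
  node_str <- as.list(paste0("t", seq_len(n)))
  node_h <- as.list(rep(0, n))
  key <- function(tips) paste(sort(tips), collapse = ",")
  reg <- new.env(parent = emptyenv())
  for (i in seq_len(n)) assign(key(i), list(str = node_str[[i]], h = 0), reg)
  for (m in merges) {
    a <- get(key(m$left), reg); b <- get(key(m$right), reg)
    str <- sprintf("(%s:%.12g,%s:%.12g)", a$str, m$time - a$h,
                   b$str, m$time - b$h)
    assign(key(c(m$left, m$right)), list(str = str, h = m$time), reg)
  }
  root <- get(key(seq_len(n)), reg)
  ape::read.tree(text = paste0(root$str, ";"))
}

#' Time to the most recent common ancestor at a site
#'
#' @inheritParams marginal_tree
#' @param site site index, or a vector of sites.
#' @return Numeric vector of site TMRCAs (the root time of each
#'   marginal tree).
#' @export
site_tmrca <- function(arg, site = 1L) {
  vapply(site, function(x) {
    m <- .replay_site(arg, x)
    m[[length(m)]]$time
  }, numeric(1))
}

## per-site signature of the marginal history: the ordered list of ARG
## event indices at which the site's lineages merge.  Two sites have
## identical (topology, times) marginal trees iff their signatures match.
.site_signatures <- function(arg) {
  vapply(seq_len(arg$config$seq_length), function(x)
    paste(vapply(.replay_site(arg, x), function(m) m$event, integer(1)),
          collapse = "|"), character(1))
}

#' Count distinct marginal gene trees along the locus
#'
#' Sites are grouped into equivalence classes of identical marginal
#' trees; adjacent and non-adjacent sites may share a class.  By
#' default trees differing only in node times are counted as distinct
#' (the recorded coalescence events, hence their times, must match);
#' `topology_only = TRUE` compares unlabelled-history topologies
#' instead.
#'
#' @inheritParams marginal_tree
#' @param topology_only compare topologies only, ignoring node times.
#' @return Integer count of distinct marginal trees.
#' @export
count_distinct_trees <- function(arg, topology_only = FALSE) {
  stopifnot(inherits(arg, "arg"))
  if (!topology_only) return(length(unique(.site_signatures(arg))))
  sig <- vapply(seq_len(arg$config$seq_length), function(x) {
    m <- .replay_site(arg, x)
    paste(vapply(m, function(e)
      paste(sort(c(e$left, e$right)), collapse = ","), character(1)),
      collapse = "|")
  }, character(1))
  length(unique(sig))
}

#' Write marginal trees to a Newick file
#'
#' @inheritParams marginal_tree
#' @param sites site indices (default: all sites).
#' @param file output path.
#' @return Invisibly, the list of trees written.
#' @export
write_marginal_trees <- function(arg, file, sites = NULL) {
  if (is.null(sites)) sites <- seq_len(arg$config$seq_length)
  trees <- lapply(sites, function(x) marginal_tree(arg, x))
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, file = file)
  invisible(trees)
}

#' Simulate infinite-sites SNP haplotypes on an ARG
#'
#' For each site, mutations are placed on the site's marginal gene tree
#' as a Poisson process with rate `mut_rate` per unit branch length
#' (branch lengths are already in expected substitutions per site, so
#' the natural rate is 1).  To honour the infinite-sites assumption a
#' site is emitted as a biallelic SNP only when exactly one mutation
#' fell on its tree; other sites are monomorphic (all zero).
#'
#' @inheritParams marginal_tree
#' @param mut_rate mutation rate per site per unit time.
#' @return An `n_samples x seq_length` 0/1 matrix; 1 marks the derived
#'   allele.
#' @export
sim_snp_haplotypes <- function(arg, mut_rate = 1) {
  n <- arg$config$n_samples
  s <- arg$config$seq_length
  out <- matrix(0L, n, s,
                dimnames = list(paste0("t", seq_len(n)), NULL))
  for (x in seq_len(s)) {
    merges <- .replay_site(arg, x)
    ## branch set: each cluster existing below a merge contributes a
    ## branch from its creation height to the merge time
    branches <- list()
    h <- setNames(rep(0, n), as.character(seq_len(n)))
    cl <- lapply(seq_len(n), identity)
    names(cl) <- as.character(seq_len(n))
    for (m in merges) {
      ka <- paste(sort(m$left), collapse = ",")
      kb <- paste(sort(m$right), collapse = ",")
      for (kk in c(ka, kb)) {
        branches[[length(branches) + 1L]] <-
          list(tips = cl[[kk]], len = m$time - h[[kk]])
      }
      knew <- paste(sort(c(m$left, m$right)), collapse = ",")
      cl[[knew]] <- c(cl[[ka]], cl[[kb]])
      h[[knew]] <- m$time
    }
    lens <- vapply(branches, function(b) b$len, numeric(1))
    nmut <- rpois(1, mut_rate * sum(lens))
    if (nmut == 1L) {
      b <- branches[[sample.int(length(branches), 1L, prob = lens)]]
      out[b$tips, x] <- 1L
    }
  }
  out
}

#' @export
print.arg <- function(x, ...) {
  cat("coalescent-with-recombination realization:",
      x$config$n_samples, "samples,", x$config$seq_length, "sites\n")
  cat("  events:", nrow(x$events), "(", x$n_rec, "recombinations ),",
      "distinct marginal trees:", count_distinct_trees(x), "\n")
  invisible(x)
}
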