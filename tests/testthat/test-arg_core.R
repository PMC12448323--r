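test_that("without recombination every site shares one marginal tree", {
  arg <- simulate_arg(sim_config(3, 12, theta = 0.1, rec_rate = 0, seed = 5))
  expect_identical(arg$n_rec, 0L)
  expect_identical(count_distinct_trees(arg), 1L)
  t1 <- marginal_tree(arg, 1)
  ts <- marginal_tree(arg, 12)
  expect_true(ape::all.equal.phylo(t1, ts, use.edge.length = TRUE))
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
})

test_that("pairwise TMRCA of n=2 matches theta/2 and events are ordered", {
  set.seed(7)
  cfg <- sim_config(2, 1, theta = 0.1, rec_rate = 0)
  tm <- replicate(4000, site_tmrca(simulate_arg(cfg)))
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 0.05), 3 * se)
  arg <- simulate_arg(sim_config(3, 30, theta = 0.2, rec_rate = 0.3, seed = 2))
  expect_true(all(diff(arg$events$time) > 0))
})

test_that("recombination event counts match the exposure compensator", {
  ## the count of recombination events minus the history-integrated
  ## intensity (rate x ancestral length, summed over lineages) is a
  ## mean-zero martingale; the paired difference isolates it sharply
  set.seed(17)
  ## realistic low rate: events are rare, so compare the total count to
  ## the summed compensator with a Poisson three-sigma band
  cfg <- sim_config(2, 200, theta = 0.1, rec_rate = 1e-5)
  sims <- replicate(8000, {
    a <- simulate_arg(cfg)
    c(a$n_rec, a$rec_exposure)
  })
  n_tot <- sum(sims[1, ]); e_tot <- sum(sims[2, ])
  expect_lt(abs(n_tot - e_tot), 3 * sqrt(max(e_tot, 1)) + 1)
  ## elevated rate: the per-replicate paired difference has power
  d <- replicate(2000, {
    a <- simulate_arg(sim_config(3, 50, theta = 0.2, rec_rate = 0.02))
    a$n_rec - a$rec_exposure
  })
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 3 * se + 1e-12)
})

test_that("marginal trees agree with the lineage-tracing oracle", {
  set.seed(23)
  for (i in 1:20) {
    arg <- simulate_arg(sim_config(3, 4, theta = 0.3, rec_rate = 0.5))
    for (site in 1:4) {
      tm_oracle <- oracle_pair_tmrca(arg, site)
      tr <- marginal_tree(arg, site)
      d <- ape::cophenetic.phylo(tr) / 2     # ultrametric: distance = 2 TMRCA
      ord <- paste0("t", 1:3)
      expect_equal(unname(d[ord, ord]), unname(tm_oracle), tolerance = 1e-9)
    }
  }
})

test_that("count_distinct_trees equals the all-pairs comparison oracle", {
  set.seed(29)
  for (i in 1:15) {
    arg <- simulate_arg(sim_config(3, 10, theta = 0.3, rec_rate = 0.4))
    mats <- lapply(1:10, function(s) oracle_pair_tmrca(arg, s))
    classes <- 0L
    seen <- list()
    for (m in mats) {
      new <- TRUE
      for (sm in seen) if (isTRUE(all.equal(m, sm, tolerance = 1e-12))) {
        new <- FALSE; break
      }
      if (new) { seen <- c(seen, list(m)); classes <- classes + 1L }
    }
    expect_identical(count_distinct_trees(arg), classes)
    expect_lte(count_distinct_trees(arg, topology_only = TRUE),
               count_distinct_trees(arg))
  }
})

test_that("a topology-relevant breakpoint partitions the sites into two classes", {
  set.seed(37)
  found <- FALSE
  for (i in 1:200) {
    arg <- simulate_arg(sim_config(3, 8, theta = 0.3, rec_rate = 0.12))
    if (arg$n_rec == 1L && count_distinct_trees(arg) == 2L) {
      sig <- vapply(1:8, function(s)
        paste(round(oracle_pair_tmrca(arg, s), 12), collapse = ","),
        character(1))
      ## sites within each side of the breakpoint share a class
      expect_identical(length(rle(sig)$values), 2L)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("first-event waiting time is exponential with the total rate", {
  set.seed(41)
  cfg <- sim_config(3, 20, theta = 0.2, rec_rate = 0.05)
  w <- replicate(2000, simulate_arg(cfg)$events$time[1])
  rate <- 3 * 2 / 0.2 + 0.05 * 3 * 20   # 3 pairs coalescence + recombination
  ks <- suppressWarnings(stats::ks.test(w, "pexp", rate))
  expect_gt(ks$p.value, 0.001)
})

test_that("distinct-tree count is stochastically non-decreasing in rec_rate", {
  set.seed(43)
  mean_classes <- vapply(c(0, 0.05, 0.5), function(r) {
    mean(replicate(150, count_distinct_trees(
      simulate_arg(sim_config(3, 10, theta = 0.2, rec_rate = r)))))
  }, numeric(1))
  expect_true(all(diff(mean_classes) > 0))
  expect_identical(mean_classes[1], 1)
})

test_that("validation and safety rails fire", {
  expect_error(sim_config(1, 10), "n_samples")
  expect_error(sim_config(3, 10, theta = Inf), "finite")
  expect_error(sim_config(3, 10, rec_rate = -1), "rec_rate")
  arg <- simulate_arg(sim_config(3, 5, theta = 0.1, rec_rate = 0, seed = 1))
  expect_error(marginal_tree(arg, 0), "site")
  expect_error(marginal_tree(arg, 6), "site")
  expect_error(
    simulate_arg(sim_config(3, 100, theta = 100, rec_rate = 10,
                            seed = 3, max_events = 50)),
    "event cap")
})

test_that("marginal trees serialize to Newick with branch lengths", {
  arg <- simulate_arg(sim_config(3, 6, theta = 0.2, rec_rate = 0.2, seed = 9))
  f <- tempfile(fileext = ".nwk")
  trees <- write_marginal_trees(arg, f)
  reread <- ape::read.tree(f)
  expect_identical(length(reread), 6L)
  expect_equal(sort(reread[[1]]$edge.length), sort(trees[[1]]$edge.length),
               tolerance = 1e-9)
  unlink(f)
})
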