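test_that("top-fraction selection is rank-exact with deterministic tie-breaks", {
  # cutoff is the k-th largest; fraction 1 keeps everything
  expect_equal(top_fraction_threshold(c(1, 5, 3, 9), 0.5), 5)
  expect_equal(top_fraction_threshold(c(4, 2, 7), 1.0), 2)

  # ties: [1,2,2,3] at fraction 0.5 keeps the 3 and the earlier-indexed 2
  tab <- make_table(c(1, 2, 2, 3))
  out <- apply_gate(tab, gate_top_fraction("CD133", 0.5))
  expect_equal(out$event_id, c(2L, 4L))

  # exact cardinality for many (n, fraction) pairs
  set.seed(12)
  for (i in 1:50) {
    n <- sample(1:400, 1)
    f <- runif(1, 0.01, 1)
    tab <- make_table(10^runif(n, 0, 3))
    expect_equal(n_events(apply_gate(tab, gate_top_fraction("CD133", f))),
                 ceiling(f * n))
  }
  expect_error(top_fraction_threshold(numeric(0), 0.2), "empty")
  expect_error(gate_top_fraction("CD133", 0), "\\(0, 1\\]")
})

test_that("threshold gates are exact, idempotent and identity when vacuous", {
  tab <- make_table(c(10, 20, 30, 40), labels = rep("beta", 4))
  ident <- apply_gate(tab, gate_threshold("CD133", 5, "above"))
  expect_equal(ident$event_id, tab$event_id)

  g <- gate_threshold("CD133", 25, "above")
  once <- apply_gate(tab, g)
  expect_equal(once$event_id, c(3L, 4L))
  expect_equal(apply_gate(once, g)$event_id, once$event_id)

  below <- apply_gate(tab, gate_threshold("CD133", 25, "below"))
  expect_equal(below$event_id, c(1L, 2L))

  expect_error(apply_gate(tab, gate_threshold("CD49a", 1)), "CD49a")
})

test_that("the positive-split gate recovers a well-separated positive mode", {
  set.seed(21)
  n <- 2000
  positive <- runif(n) < 0.6
  vals <- 10^rnorm(n, ifelse(positive, 3.4, 1.6), 0.18)
  tab <- make_table(vals, channel = "CD49a",
                    labels = ifelse(positive, "beta", "ductal"))
  out <- apply_gate(tab, gate_positive_split("CD49a"))
  expect_setequal(out$event_id, which(positive))

  # a manual cutoff overrides the heuristic
  manual <- apply_gate(tab, gate_positive_split("CD49a", cutoff = 10^2.5))
  expect_setequal(manual$event_id, which(vals > 10^2.5))
})

test_that("sequential gates use daughter-gate semantics and are order-sensitive", {
  tab <- make_table(c(10, 20, 30, 40), labels = rep("beta", 4))
  id2 <- apply_gates(tab, list(gate_threshold("CD133", 1),
                               gate_threshold("CD133", 1)))
  expect_equal(id2$event_id, tab$event_id)

  # top 50% of survivors, not of the original table
  seq_out <- apply_gates(tab, list(gate_threshold("CD133", 15),
                                   gate_top_fraction("CD133", 0.5)))
  expect_equal(seq_out$event_id, c(3L, 4L))  # ceiling(0.5*3) = 2 of {20,30,40}

  # empty intermediate survives as an empty result
  emptied <- apply_gates(tab, list(gate_threshold("CD133", 100),
                                   gate_top_fraction("CD133", 0.2)))
  expect_equal(n_events(emptied), 0)

  # order sensitivity on a hand-enumerable fixture: a conditional
  # top-fraction gate sees a different parent population in each order
  m <- matrix(c(10, 9, 1, 2,     # CD133
                10, 1, 10, 10),  # CD49a
              ncol = 2, dimnames = list(NULL, c("CD133", "CD49a")))
  two <- event_table(m, labels = rep("beta", 4))
  g1 <- gate_top_fraction("CD133", 0.5)
  g2 <- gate_threshold("CD49a", 5, "above")
  expect_equal(apply_gates(two, list(g1, g2))$event_id, 1L)
  expect_equal(apply_gates(two, list(g2, g1))$event_id, c(1L, 4L))

  # gate provenance accumulates in metadata
  expect_length(seq_out$metadata$gates, 2)
})

test_that("appending a gate never increases any class's event count", {
  set.seed(9)
  tab <- simulate_events(default_sc_islet_config(seed = 9), 3000,
                         timepoint = 7)
  counts <- function(t) table(factor(t$labels, levels = cell_classes()))
  g1 <- apply_gate(tab, gate_positive_split("CD49a"))
  g2 <- apply_gate(g1, gate_top_fraction("CD133", 0.2))
  expect_true(all(counts(g1) <= counts(tab)))
  expect_true(all(counts(g2) <= counts(g1)))
})

test_that("gate outputs match exhaustive per-event evaluation on small tables", {
  set.seed(55)
  for (i in 1:60) {
    n <- sample(1:30, 1)
    tab <- random_fixture(n)
    x <- channel_values(tab, "CD133")

    f <- runif(1, 0.05, 1)
    expect_equal(apply_gate(tab, gate_top_fraction("CD133", f))$event_id,
                 oracle_top_fraction_ids(x, tab$event_id, f))

    cut <- 10^runif(1, 1, 4)
    dir <- sample(c("above", "below"), 1)
    expect_equal(apply_gate(tab, gate_threshold("CD133", cut, dir))$event_id,
                 oracle_threshold_ids(x, tab$event_id, cut, dir))
  }
})

test_that("composition counts classes exactly and flags empty tables", {
  tab <- make_table(1:10, labels = c(rep("beta", 4), rep("ductal", 6)))
  comp <- composition(tab)
  expect_equal(comp$fractions[["beta"]], 0.4)
  expect_equal(sum(comp$fractions), 1)

  empty <- make_table(numeric(0))
  ec <- composition(empty)
  expect_equal(ec$n, 0)
  expect_true(all(is.na(ec$fractions)))

  tab10k <- simulate_events(default_sc_islet_config(seed = 2), 10000,
                            timepoint = 7)
  w <- default_sc_islet_config()$weights
  se <- sqrt(w * (1 - w) / 10000)
  expect_true(all(abs(composition(tab10k)$fractions - w) < 3 * se))

  expect_error(composition(make_table(1:3)), "labels")
})

test_that("sort outcomes account purity, yield and enrichment correctly", {
  tab <- make_table(1:10, labels = c(rep("beta", 5), rep("alpha_poly", 5)))

  all_out <- sort_outcome(tab, tab)
  expect_equal(all_out$yield_fraction, 1)
  expect_equal(all_out$enrichment[["beta"]], 1)
  expect_equal(all_out$enrichment[["alpha_poly"]], 1)
  expect_true(is.na(all_out$enrichment[["ductal"]]))  # absent pre-sort

  # hand-count: 50/50 pre, post = all 5 beta of 10
  post <- tab[1:5]
  out <- sort_outcome(tab, post)
  expect_equal(out$enrichment[["beta"]], 2)
  expect_equal(out$enrichment[["alpha_poly"]], 0)
  expect_equal(out$yield_fraction, 0.5)

  stranger <- make_table(1:3, labels = rep("beta", 3),
                         ) # default ids 1..3 but different table
  stranger$event_id <- c(98L, 99L, 100L)
  expect_error(sort_outcome(tab, stranger), "subset")
})

test_that("dual-marker sorting enriches beta and depletes alpha and ductal cells", {
  cfg <- default_sc_islet_config(seed = 17)
  tab <- simulate_events(cfg, 10000, timepoint = 7)

  cd133 <- apply_gate(tab, gate_top_fraction("CD133", 0.2))
  expect_gt(composition(cd133)$fractions[["beta"]],
            composition(tab)$fractions[["beta"]])

  dual <- apply_gates(tab, dual_sort_gates())
  out <- sort_outcome(tab, dual)
  expect_gt(out$enrichment[["beta"]], 1)
  expect_lt(out$enrichment[["alpha_poly"]], 1)

  # the CD49a pre-gate removes the ductal contamination CD133 alone lets in
  expect_lt(composition(dual)$fractions[["ductal"]],
            composition(cd133)$fractions[["ductal"]])
})
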