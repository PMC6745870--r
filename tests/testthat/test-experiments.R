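# Shared fixture for the experiment runners: a 60-tip regional chronogram
# with mixed assembly scenarios.
exp_fixture <- function(n_tips = 60, n_sites = 6, seed = 101) {
  ch <- simulate_chronogram(n_tips, seed = seed)
  sc <- default_scenarios(n_sites, n_tips)
  sc$richness <- pmax(sc$richness, 10)
  cm <- simulate_communities(ch, sc, seed = seed + 1)
  list(tree = ch, comm = cm, tax = derive_families(ch, 0.5))
}

test_that("Q1 at the full pool size reduces to the full-data pattern", {
  fx <- exp_fixture()
  q1 <- run_q1(fx$tree, fx$comm, sizes = 60, n_reps = 1, n_null = 199,
               seed = 5)
  full <- ses_phylodiv(fx$comm, tree = fx$tree, metric = "MPD",
                       n_reps = 199, seed = child_seed(5, 1 * 1e5 + 1))
  expect_equal(q1$results$pattern, full$pattern)
  pr <- q1$proportions
  ok <- !is.na(pr$clustered)
  vals <- unlist(pr[ok, c("clustered", "overdispersed", "random")])
  expect_true(all(vals %in% c(0, 1)))
})

test_that("Q1 runs are deterministic and proportions rows sum to one", {
  fx <- exp_fixture()
  a <- run_q1(fx$tree, fx$comm, sizes = c(20, 40), n_reps = 4, n_null = 99,
              seed = 6)
  b <- run_q1(fx$tree, fx$comm, sizes = c(20, 40), n_reps = 4, n_null = 99,
              seed = 6)
  expect_identical(a, b)
  pr <- a$proportions
  ok <- !is.na(pr$clustered)
  expect_equal(rowSums(pr[ok, c("clustered", "overdispersed", "random")]),
               rep(1, sum(ok)), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(pr$n + pr$n_na == 4))
})

test_that("Q2 strategies coincide exactly on a single-family pool", {
  fx <- exp_fixture()
  tax1 <- data.frame(species = sort(fx$tree$tip.label), family = "only")
  q2 <- run_q2(fx$tree, fx$comm, tax1, sizes = c(20, 40), n_reps = 3,
               n_null = 99, seed = 7)
  r <- q2$results[q2$results$strategy == "random", ]
  f <- q2$results[q2$results$strategy == "family_proportional", ]
  expect_equal(r$ses, f$ses)
  expect_identical(r$pattern, f$pattern)
})

test_that("Q2 reports both strategies with matched bookkeeping", {
  fx <- exp_fixture()
  q2 <- run_q2(fx$tree, fx$comm, fx$tax, sizes = c(20, 40), n_reps = 3,
               n_null = 99, seed = 8)
  counts <- table(q2$results$strategy, q2$results$size)
  expect_true(all(counts == counts[1, 1]))
  expect_true(all(c("random", "family_proportional") %in%
                    q2$proportions$strategy))
  # family-proportional realized sizes stay within one seat per family
  f <- q2$results[q2$results$strategy == "family_proportional", ]
  n_fam <- length(unique(fx$tax$family))
  expect_true(all(abs(f$realized_size - f$size) <= n_fam))
})

test_that("Q3 whole-pool clade never mismatches the full dataset", {
  fx <- exp_fixture()
  tax <- fx$tax
  tax$clade <- "whole"
  q3 <- run_q3(fx$tree, fx$comm, tax, clades = "whole", n_null = 499,
               seed = 9)
  cats <- q3$match_matrix[, "whole"]
  expect_false(any(grepl("mismatch", cats[!is.na(cats)])))
})

test_that("Q3 flags communities with too few clade members as NA", {
  fx <- exp_fixture()
  fams <- names(sort(table(fx$tax$family), decreasing = TRUE))
  q3 <- run_q3(fx$tree, fx$comm, fx$tax, clades = fams[1:2], n_null = 99,
               seed = 10)
  expect_identical(dim(q3$match_matrix),
                   c(nrow(fx$comm), 2L))
  for (cl in fams[1:2]) {
    members <- clade_subset(sort(fx$tree$tip.label), fx$tax, cl)
    n_in_comm <- rowSums(fx$comm[, members, drop = FALSE])
    expect_identical(unname(is.na(q3$match_matrix[, cl])),
                     unname(n_in_comm < 2))
  }
})

test_that("Q4 with an identity tree provider is degenerate by construction", {
  fx <- exp_fixture()
  q4 <- run_q4(fx$tree, fx$comm, sizes = 30, n_reps = 6, n_null = 99,
               seed = 11, tree_provider = function(pruned, size, rep) pruned)
  expect_equal(q4$pairs$ses_pruned, q4$pairs$ses_alternative)
  done <- q4$tests[q4$tests$n_pairs >= 5, ]
  expect_true(all(done$degenerate))
  expect_true(all(done$p_value == 1))

  # emulator with zero noise is the same identity
  q4b <- run_q4(fx$tree, fx$comm, sizes = 30, n_reps = 6, n_null = 99,
                seed = 11, n_nni = 0, tau = 0)
  expect_equal(q4b$pairs$ses_pruned, q4b$pairs$ses_alternative)
})

test_that("Q4 emulator defaults leave SES broadly unchanged on average", {
  fx <- exp_fixture()
  q4 <- run_q4(fx$tree, fx$comm, sizes = c(30, 45), n_reps = 10,
               n_null = 199, seed = 12)
  d <- q4$pairs$ses_alternative - q4$pairs$ses_pruned
  expect_lt(abs(mean(d, na.rm = TRUE)), 0.5)
  # alternative trees must cover the same taxa: alignment is enforced
  bad_provider <- function(pruned, size, rep) {
    ape::drop.tip(pruned, pruned$tip.label[1])
  }
  expect_error(run_q4(fx$tree, fx$comm, sizes = 30, n_reps = 2, n_null = 49,
                      seed = 12, tree_provider = bad_provider),
               "alignment failure")
})

test_that("Q5 pairing replays exactly under the same seed", {
  fx <- exp_fixture()
  a <- run_q5(fx$tree, fx$comm, sigma = 1, sizes = 30, n_reps = 5,
              n_null = 99, seed = 13)
  b <- run_q5(fx$tree, fx$comm, sigma = 1, sizes = 30, n_reps = 5,
              n_null = 99, seed = 13)
  expect_identical(a, b)
  expect_true(all(c("phylogram", "chronogram") %in% a$proportions$tree))
  expect_error(run_q5(fx$tree, fx$comm,
                      phylogram = simulate_chronogram(60, seed = 999),
                      sizes = 30, n_reps = 2, n_null = 49, seed = 13),
               "topology mismatch")
})

test_that("SES is invariant to global branch-length scaling", {
  fx <- exp_fixture()
  for (metric in c("MPD", "MNTD", "PD")) {
    base <- ses_phylodiv(fx$comm, tree = fx$tree, metric = metric,
                         n_reps = 199, seed = 14)
    for (c_scale in c(0.05, 20)) {
      scaled <- fx$tree
      scaled$edge.length <- scaled$edge.length * c_scale
      res <- ses_phylodiv(fx$comm, tree = scaled, metric = metric,
                          n_reps = 199, seed = 14)
      expect_identical(res$rank_p, base$rank_p)
      expect_identical(res$pattern, base$pattern)
      expect_equal(res$ses, base$ses, tolerance = 1e-9)
    }
  }
})
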