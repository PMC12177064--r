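test_that("iterative forest weights are normalized, enriched for signal, deterministic", {
  n <- 150; p <- 30
  X <- withr::with_seed(1, matrix(runif(n * p), n, p,
                                  dimnames = list(NULL, sprintf("t%02d", 1:p))))
  y <- withr::with_seed(2, 1.5 * (X[, "t07"] > 0.5) + rnorm(n, 0, 0.3))
  cfg <- rhsirf_config(irf_iterations = 3, n_trees = 60, n_bootstraps = 60, seed = 5)
  fit <- fit_irf(X, y, cfg, seed = 5)
  expect_equal(rowSums(fit$weights), rep(1, 4), tolerance = 1e-12)
  w7 <- fit$weights[, "t07"]
  expect_gt(w7[2], w7[1])                 # increases while concentrating
  expect_gt(w7[3], w7[2])
  expect_gt(w7[4], 0.9 * w7[3])           # may plateau once saturated
  expect_gt(w7[4], 1 / p)                 # well above uniform by iteration 3
  refit <- fit_irf(X, y, cfg, seed = 5)
  expect_identical(mica:::forest_digest(fit), mica:::forest_digest(refit))
  expect_error(fit_irf(X, rep(1, n), cfg), "constant")
})

test_that("signed path parsing matches a manual oracle including deepest-sign collapse", {
  # hand-built 3-node stump on taxon A
  stump <- data.frame(nodeID = 0:2, leftChild = c(1, NA, NA), rightChild = c(2, NA, NA),
                      splitvarName = c("A", NA, NA), splitval = c(0.5, NA, NA),
                      terminal = c(FALSE, TRUE, TRUE), prediction = c(NA, 1, 2))
  paths <- mica:::parse_tree_paths(stump)
  expect_length(paths, 2)
  expect_identical(paths[[1]]$signs, c(A = "low"))
  expect_identical(paths[[2]]$signs, c(A = "high"))
  # depth-3 tree that re-splits taxon A below its own high branch:
  # the deepest sign wins on that path
  ti <- data.frame(
    nodeID = 0:6,
    leftChild = c(1, 3, 5, NA, NA, NA, NA),
    rightChild = c(2, 4, 6, NA, NA, NA, NA),
    splitvarName = c("A", "B", "A", NA, NA, NA, NA),
    splitval = c(0.5, 0.2, 0.8, NA, NA, NA, NA),
    terminal = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    prediction = c(NA, NA, NA, 1, 2, 3, 4))
  paths <- mica:::parse_tree_paths(ti)
  signs <- lapply(paths, `[[`, "signs")
  expect_identical(signs[[1]], c(A = "low", B = "low"))
  expect_identical(signs[[2]], c(A = "low", B = "high"))
  expect_identical(signs[[3]], c(A = "low"))    # high at root, low at depth 2
  expect_identical(signs[[4]], c(A = "high"))
  # every path set from a depth-2 tree has size <= 2
  expect_true(all(lengths(signs) <= 2))
})

test_that("a single-predictor stump forest yields exactly the two signed singletons", {
  X <- data.frame(j = withr::with_seed(3, runif(100)))
  y <- 2 * (X$j > 0.5) + withr::with_seed(4, rnorm(100, 0, 0.1))
  cfg <- rhsirf_config(irf_iterations = 1, n_bootstraps = 10, max_depth = 1,
                       mtry = 1, signs = "both", seed = 6)
  fit <- fit_irf(X, y, cfg, seed = 6)
  paths <- extract_signed_paths(fit)
  keys <- unique(vapply(paths, function(p)
    paste0(names(p$signs), ifelse(p$signs == "high", "+", "-")), character(1)))
  expect_setequal(keys, c("j+", "j-"))
})

test_that("itemset support is anti-monotone and degenerate path sets behave", {
  st <- small_study(seed = 51, n = 140, n_taxa = 20)
  X <- quartiled(st$filtered, st$cohort)
  cfg <- rhsirf_config(n_bootstraps = 40, signs = "both", support = 0, seed = 8)
  fit <- fit_irf(X, st$cohort$y, cfg, seed = 8)
  mined <- mine_cooccurrences(extract_signed_paths(fit), cfg)
  freq <- setNames(mined$frequency, mined$itemset)
  pairs <- mined[mined$size == 2, ]
  for (i in seq_len(nrow(pairs))) {
    parts <- strsplit(pairs$itemset[i], ";", fixed = TRUE)[[1]]
    expect_lte(pairs$frequency[i], min(freq[parts]) + 1e-12)
  }
  expect_true(all(mined$frequency >= 0 & mined$frequency <= 1))
  # single path: all frequencies are exactly 1
  one <- list(list(signs = c(A = "high", B = "low"), weight = 7, pred = 1))
  m1 <- mine_cooccurrences(one, cfg)
  expect_true(all(m1$frequency == 1))
  expect_error(mine_cooccurrences(list(), cfg), "no paths")
})

test_that("a planted presence interaction is a top-ranked mined pair", {
  n <- 200; p <- 20
  X <- withr::with_seed(9, matrix(rbinom(n * p, 3, 0.4), n, p,
                                  dimnames = list(NULL, sprintf("t%02d", 1:p))))
  y <- withr::with_seed(10, 1 * (X[, "t05"] > 0 & X[, "t09"] > 0) + rnorm(n, 0, 0.3))
  cfg <- rhsirf_config(irf_iterations = 2, n_trees = 50, n_bootstraps = 50, seed = 11)
  mined <- mine_cooccurrences(extract_signed_paths(fit_irf(X, y, cfg, seed = 11)), cfg)
  top2 <- head(mined$itemset[mined$size == 2], 2)
  expect_true("t05+;t09+" %in% top2)
})

test_that("repeated-holdout stability is bounded, reproducible, and finds planted cliques", {
  st <- small_study(seed = 61, n = 160, n_taxa = 25,
                    cliques = list(planted_clique(c(12, 14),
                                                  effect = c(secure = 0.35, insecure = 0.35))))
  X <- quartiled(st$filtered, st$cohort)
  cfg <- fast_sirf(n_repeats = 20)
  stab <- repeated_holdout_stability(X, st$cohort$y, cfg)
  expect_true(all(stab$stability >= 0 & stab$stability <= 1))
  expect_true(all(diff(stab$stability) <= 0))
  again <- repeated_holdout_stability(X, st$cohort$y, cfg)
  expect_identical(stab, again)
  expect_true("ASV0012+;ASV0014+" %in% head(stab$itemset, 5))
  expect_error(repeated_holdout_stability(X[1:8, ], st$cohort$y[1:8], cfg), "small")
})

test_that("closed-loop selection reproduces the canonical cycle cases", {
  triangle <- itemset_table(c("A+;B+", "B+;C+", "A+;C+"), c(0.9, 0.8, 0.7))
  sel <- select_cliques_closed_loop(triangle, min_stability = 0)
  expect_length(sel, 1)
  expect_setequal(sel[[1]]$members, c("A", "B", "C"))
  lone <- select_cliques_closed_loop(itemset_table("A+;B+", 0.9), min_stability = 0)
  expect_setequal(lone[[1]]$members, c("A", "B"))      # 2-node loop
  chain <- select_cliques_closed_loop(itemset_table(c("A+;B+", "B+;C+"), c(0.9, 0.8)),
                                      min_stability = 0)
  expect_length(chain, 1)
  expect_setequal(chain[[1]]$members, c("A", "B"))     # C breaks closure
  expect_identical(select_cliques_closed_loop(triangle[0, ]), list())
  # disjoint accepted pairs become separate cliques
  two <- select_cliques_closed_loop(itemset_table(c("A+;B+", "C+;D+"), c(0.9, 0.8)),
                                    min_stability = 0)
  expect_length(two, 2)
  # a committed top pair is never broken open by later mutually-supporting noise
  star <- itemset_table(c("H+;P+", "H+;X+", "H+;Z+", "X+;Z+"), c(0.9, 0.5, 0.4, 0.3))
  sel <- select_cliques_closed_loop(star, min_stability = 0)
  expect_length(sel, 1)
  expect_setequal(sel[[1]]$members, c("H", "P"))
})

test_that("pure-noise outcomes do not produce stable itemsets", {
  # null calibration at the method's operating scale: a stratum of ~70
  # samples against the full taxon panel
  nul <- small_study(seed = 71, n = 360, n_taxa = 150, cliques = list(),
                     modifier_prevalence = 0.19)
  ins <- nul$cohort[nul$cohort$modifier == 1, ]
  X <- quartiled(nul$filtered, ins)
  cfg <- rhsirf_config(n_repeats = 40, n_bootstraps = 25, seed = 7)
  stab <- repeated_holdout_stability(X, ins$y, cfg)
  if (nrow(stab)) expect_lt(max(stab$stability), cfg$stability_threshold)
  # and stability under a permuted outcome never beats the planted signal
  sig <- small_study(seed = 61, n = 160, n_taxa = 25,
                     cliques = list(planted_clique(c(12, 14),
                                                   effect = c(secure = 0.35, insecure = 0.35))))
  Xs <- quartiled(sig$filtered, sig$cohort)
  fcfg <- fast_sirf(n_repeats = 25)
  obs <- repeated_holdout_stability(Xs, sig$cohort$y, fcfg)
  yperm <- withr::with_seed(5, sample(sig$cohort$y))
  perm <- repeated_holdout_stability(Xs, yperm, fcfg)
  key <- "ASV0012+;ASV0014+"
  s_obs <- ifelse(key %in% obs$itemset, obs$stability[obs$itemset == key], 0)
  s_perm <- ifelse(key %in% perm$itemset, perm$stability[perm$itemset == key], 0)
  expect_gt(s_obs, s_perm)
})
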