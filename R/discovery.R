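#' Configuration for repeated-holdout signed iterative random forests
#'
#' Full-scale defaults follow the published procedure: 1000 repeated random
#' 60/40 train/test holdouts, each fitting a forest of 250 trees grown on
#' bootstrap resamples of the training split. Tests and worked examples use
#' scaled-down counts via these knobs.
#'
#' @param n_repeats number of repeated random holdouts.
#' @param n_bootstraps bootstrap resamples (= trees) in each final forest.
#' @param train_fraction fraction of samples in the training partition.
#' @param irf_iterations iterative-reweighting rounds (the last round grows
#'   the forest whose paths are mined).
#' @param n_trees trees in the intermediate (reweighting) forests.
#' @param max_depth maximum tree depth; bounds signed-path length.
#' @param min_node minimal terminal-node size.
#' @param mtry candidate features per split (`NULL` = ranger default).
#' @param support minimum within-forest path frequency for an itemset to
#'   count as recovered in a holdout.
#' @param high_risk_only mine only decision paths whose leaves predict
#'   above-average risk, so itemsets describe combinations predictive of
#'   HIGHER outcome values (the direction of interest).
#' @param signs `"high"` (default) mines presence-based co-occurrences:
#'   only the high-abundance side of each split enters the itemset
#'   alphabet, because a clique is a joint-presence pattern. `"both"`
#'   retains low-signed features in itemsets as well.
#' @param stability_threshold recovery fraction across holdouts required
#'   for selection.
#' @param min_itemset_size,max_itemset_size itemset size range mined
#'   (cliques are size >= 2; 4 matches the largest clique of interest).
#' @param seed master seed; holdouts and forests are sub-seeded from it.
#' @return An object of class `rhsirf_config`.
#' @export
rhsirf_config <- function(n_repeats = 1000, n_bootstraps = 250,
                          train_fraction = 0.6, irf_iterations = 2,
                          n_trees = 50, max_depth = 4, min_node = 3,
                          mtry = NULL, support = 0.01,
                          high_risk_only = TRUE, signs = c("high", "both"),
                          stability_threshold = 0.5,
                          min_itemset_size = 2, max_itemset_size = 4,
                          seed = 1L) {
  signs <- match.arg(signs)
  if (train_fraction <= 0 || train_fraction >= 1) stopf("train_fraction must lie in (0,1)")
  counts <- c(n_repeats, n_bootstraps, irf_iterations, n_trees, max_depth, min_node)
  if (any(counts < 1)) stopf("all counts must be positive")
  if (min_itemset_size < 1 || max_itemset_size < min_itemset_size) {
    stopf("invalid itemset size range")
  }
  structure(list(n_repeats = as.integer(n_repeats),
                 n_bootstraps = as.integer(n_bootstraps),
                 train_fraction = train_fraction,
                 irf_iterations = as.integer(irf_iterations),
                 n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
                 min_node = as.integer(min_node), mtry = mtry,
                 support = support, high_risk_only = isTRUE(high_risk_only),
                 signs = signs,
                 stability_threshold = stability_threshold,
                 min_itemset_size = as.integer(min_itemset_size),
                 max_itemset_size = as.integer(max_itemset_size),
                 seed = as.integer(seed)),
            class = "rhsirf_config")
}

#' Fit an iterative random forest
#'
#' Round 1 samples split candidates uniformly; each later round samples
#' features in proportion to the previous round's impurity importance
#' (softened by a 10% uniform floor so weak features keep a nonzero chance,
#' and so the weight vector is valid whatever the importance profile).
#' The last round grows `n_bootstraps` trees, whose decision paths feed the
#' signed itemset miner; earlier rounds use `n_trees`.
#'
#' @param X samples x taxa predictor matrix or data.frame.
#' @param y transformed-outcome vector.
#' @param cfg an [rhsirf_config].
#' @param seed seed for this fit (defaults to `cfg$seed`).
#' @return object of class `irf_forest`: the final \pkg{ranger} forest, the
#'   per-iteration feature-weight matrix (rows sum to 1), and the training
#'   data used for leaf weighting.
#' @export
fit_irf <- function(X, y, cfg = rhsirf_config(), seed = cfg$seed) {
  X <- as.data.frame(X)
  if (nrow(X) != length(y)) stopf("X and y are not aligned")
  if (var(y) == 0) stopf("outcome is constant; nothing to fit")
  p <- ncol(X)
  mtry <- if (is.null(cfg$mtry)) max(1L, floor(p / 3)) else min(cfg$mtry, p)
  w <- rep(1 / p, p)
  weights <- matrix(NA_real_, cfg$irf_iterations + 1L, p,
                    dimnames = list(NULL, colnames(X)))
  weights[1, ] <- w
  fit <- NULL
  for (it in seq_len(cfg$irf_iterations)) {
    ntree <- if (it == cfg$irf_iterations) cfg$n_bootstraps else cfg$n_trees
    # verbose = FALSE silences ranger's note that importance values are
    # only comparable under equal split weights -- expected here, since
    # reweighting importance is the point of the iteration
    fit <- ranger::ranger(
      x = X, y = y, num.trees = ntree,
      mtry = mtry, min.node.size = cfg$min_node, max.depth = cfg$max_depth,
      split.select.weights = w, importance = "impurity",
      seed = subseed(seed, "irf-iter", it), num.threads = 1,
      oob.error = FALSE, verbose = FALSE
    )
    imp <- pmax(ranger::importance(fit), 0)
    w <- if (sum(imp) > 0) {
      0.9 * imp / sum(imp) + 0.1 / p
    } else {
      rep(1 / p, p)
    }
    weights[it + 1L, ] <- w
  }
  structure(list(forest = fit, weights = weights, X = X),
            class = "irf_forest")
}

# Parse one ranger treeInfo frame into signed root-to-leaf paths.
# Left child = "<= splitval" (low side), right child = "> splitval" (high).
# A taxon split on twice along a path keeps its deepest (most specific)
# sign. Returns a list of list(leaf = nodeID, signs = named chr vector).
parse_tree_paths <- function(ti) {
  kids <- split(ti, seq_len(nrow(ti)))
  byid <- setNames(kids, ti$nodeID)
  out <- list()
  walk <- function(node_id, signs) {
    nd <- byid[[as.character(node_id)]]
    if (isTRUE(nd$terminal)) {
      out[[length(out) + 1L]] <<- list(leaf = nd$nodeID, signs = signs)
      return(invisible(NULL))
    }
    v <- nd$splitvarName
    lo <- signs; lo[v] <- "low"
    hi <- signs; hi[v] <- "high"
    walk(nd$leftChild, lo)
    walk(nd$rightChild, hi)
  }
  walk(ti$nodeID[1], setNames(character(0), character(0)))
  out
}

#' Extract signed decision paths from a fitted forest
#'
#' One signed feature set per root-to-leaf path over every tree: taxon `j`
#' carries sign `high` if the path takes the `>` branch at a split on `j`,
#' `low` otherwise; repeats of a taxon on one path collapse to the deepest
#' sign. Each path is weighted by the number of training samples reaching
#' its leaf.
#'
#' @param forest an `irf_forest` from [fit_irf()].
#' @return list of paths, each `list(signs = named character vector
#'   ("high"/"low" by taxon), weight = leaf sample count, pred = leaf
#'   prediction)`.
#' @export
extract_signed_paths <- function(forest) {
  stopifnot(inherits(forest, "irf_forest"))
  fit <- forest$forest
  tn <- predict(fit, data = forest$X, type = "terminalNodes",
                num.threads = 1)$predictions
  paths <- list()
  for (t in seq_len(fit$num.trees)) {
    ti <- ranger::treeInfo(fit, t)
    counts <- table(tn[, t])
    predmap <- setNames(ti$prediction, as.character(ti$nodeID))
    for (pth in parse_tree_paths(ti)) {
      w <- counts[as.character(pth$leaf)]
      paths[[length(paths) + 1L]] <- list(
        signs = pth$signs,
        weight = if (is.na(w) || length(w) == 0) 0 else as.numeric(w),
        pred = unname(predmap[as.character(pth$leaf)])
      )
    }
  }
  paths
}

itemset_key <- function(taxa, signs) {
  ord <- order(taxa)
  paste(paste0(taxa[ord], ifelse(signs[ord] == "high", "+", "-")), collapse = ";")
}

#' Parse an itemset key back into members and signs
#'
#' Keys look like `"ASV0001+;ASV0002-"`: member taxa sorted
#' lexicographically, `+` = high side, `-` = low side.
#'
#' @param key itemset key string(s).
#' @return for one key, a list with `members` and `signs`.
#' @export
parse_itemset <- function(key) {
  parts <- strsplit(key, ";", fixed = TRUE)[[1]]
  sign <- ifelse(substring(parts, nchar(parts)) == "+", "high", "low")
  members <- substring(parts, 1, nchar(parts) - 1)
  list(members = members, signs = setNames(sign, members))
}

#' Mine frequent signed itemsets from decision paths
#'
#' Counts, for every signed itemset up to the configured size, the
#' leaf-weighted fraction of paths containing it (support). Support is
#' anti-monotone by construction: a superset can never be more frequent
#' than its subsets.
#'
#' @param paths signed paths from [extract_signed_paths()].
#' @param cfg an [rhsirf_config] (`support`, `max_itemset_size`).
#' @return data.frame: `itemset` key, `size`, `frequency`, sorted by
#'   decreasing frequency; only itemsets at or above the support floor.
#' @export
mine_cooccurrences <- function(paths, cfg = rhsirf_config()) {
  if (!length(paths)) stopf("no paths to mine")
  if (isTRUE(cfg$high_risk_only) && !is.null(paths[[1]]$pred)) {
    wts0 <- vapply(paths, `[[`, numeric(1), "weight")
    preds <- vapply(paths, `[[`, numeric(1), "pred")
    floor_pred <- sum(preds * wts0) / sum(wts0)
    keep <- preds > floor_pred
    if (any(keep)) paths <- paths[keep]
  }
  total <- sum(vapply(paths, `[[`, numeric(1), "weight"))
  if (total <= 0) stopf("all paths have zero weight")
  keys <- vector("list", length(paths))
  wts <- vector("list", length(paths))
  high_only <- !identical(cfg$signs, "both")
  for (i in seq_along(paths)) {
    signs <- paths[[i]]$signs
    if (high_only) signs <- signs[signs == "high"]
    k <- length(signs)
    if (k == 0) next
    taxa <- names(signs)
    subs <- character(0)
    for (sz in seq_len(min(k, cfg$max_itemset_size))) {
      cmb <- combn(k, sz)
      subs <- c(subs, apply(cmb, 2, function(ix) itemset_key(taxa[ix], signs[ix])))
    }
    keys[[i]] <- subs
    wts[[i]] <- rep(paths[[i]]$weight, length(subs))
  }
  key <- unlist(keys, use.names = FALSE)
  if (is.null(key) || !length(key)) {
    return(data.frame(itemset = character(0), size = integer(0),
                      frequency = numeric(0), stringsAsFactors = FALSE))
  }
  dt <- data.table::data.table(itemset = key, w = unlist(wts, use.names = FALSE))
  agg <- dt[, list(frequency = sum(w) / total), by = "itemset"]
  agg[, "size" := lengths(strsplit(agg$itemset, ";", fixed = TRUE))]
  agg <- agg[agg$frequency >= cfg$support, ]
  agg <- agg[order(-agg$frequency, agg$itemset), ]
  data.frame(itemset = agg$itemset, size = agg$size, frequency = agg$frequency,
             stringsAsFactors = FALSE)
}

#' Stability of signed itemsets over repeated holdouts
#'
#' For each repeat, a random `train_fraction` partition is drawn, an
#' iterative forest is fitted to the training part (trees on bootstrap
#' resamples), and signed itemsets are mined; an itemset is "recovered" in
#' a repeat when its within-forest frequency clears the support floor.
#' Stability is the recovery fraction across repeats.
#'
#' @param X samples x taxa predictors (filtered relative abundances).
#' @param y transformed outcome.
#' @param cfg an [rhsirf_config].
#' @return data.frame sorted by decreasing stability (ties: mean
#'   within-forest frequency, then lexicographic key): `itemset, size,
#'   stability, mean_frequency, n_recovered`.
#' @export
repeated_holdout_stability <- function(X, y, cfg = rhsirf_config()) {
  X <- as.data.frame(X)
  n <- nrow(X)
  n_train <- round(cfg$train_fraction * n)
  if (n_train < 8 || n - n_train < 1) {
    stopf("n = %d too small for a %.0f%% training partition", n, 100 * cfg$train_fraction)
  }
  counts <- new.env(parent = emptyenv())
  freqs <- new.env(parent = emptyenv())
  for (r in seq_len(cfg$n_repeats)) {
    idx <- with_seed(subseed(cfg$seed, "holdout", r), sample.int(n, n_train))
    fit <- fit_irf(X[idx, , drop = FALSE], y[idx], cfg,
                   seed = subseed(cfg$seed, "fit", r))
    mined <- mine_cooccurrences(extract_signed_paths(fit), cfg)
    mined <- mined[mined$size >= cfg$min_itemset_size, , drop = FALSE]
    for (i in seq_len(nrow(mined))) {
      k <- mined$itemset[i]
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
      freqs[[k]] <- (if (is.null(freqs[[k]])) 0 else freqs[[k]]) + mined$frequency[i]
    }
  }
  ks <- ls(counts)
  if (!length(ks)) {
    return(data.frame(itemset = character(0), size = integer(0),
                      stability = numeric(0), mean_frequency = numeric(0),
                      n_recovered = integer(0), stringsAsFactors = FALSE))
  }
  n_rec <- vapply(ks, function(k) counts[[k]], integer(1))
  mean_f <- vapply(ks, function(k) freqs[[k]], numeric(1)) / n_rec
  out <- data.frame(itemset = ks, size = lengths(strsplit(ks, ";", fixed = TRUE)),
                    stability = n_rec / cfg$n_repeats, mean_frequency = mean_f,
                    n_recovered = n_rec, stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$stability, -out$mean_frequency, out$itemset), , drop = FALSE]
}

#' Clique definition
#'
#' A set of member taxa with a presence rule (abundance > 0): the clique
#' indicator counts how many members a sample carries.
#'
#' @param members taxon ids whose presence is counted by the indicator.
#' @param signs optional named sign vector ("high"/"low") for reporting.
#' @param name human-readable clique name.
#' @param all_members all taxa in the selected network component (a
#'   superset of `members` when low-signed taxa are excluded).
#' @return object of class `clique_definition`.
#' @export
clique_definition <- function(members, signs = NULL, name = NULL,
                              all_members = members) {
  if (length(members) < 1) stopf("clique needs at least one member")
  structure(list(members = members, signs = signs,
                 name = if (is.null(name)) paste(members, collapse = "+") else name,
                 all_members = all_members),
            class = "clique_definition")
}

#' @export
print.clique_definition <- function(x, ...) {
  cat(sprintf("clique '%s': %s\n", x$name, paste(x$members, collapse = ", ")))
  invisible(x)
}

# TRUE for every node of `g` that lies on a cycle or belongs to a
# 2-node single-edge component (counted as a closed 2-loop).
closed_loop_ok <- function(g) {
  if (igraph::vcount(g) == 0) return(logical(0))
  on_cycle <- rep(FALSE, igraph::vcount(g))
  for (bc in igraph::biconnected_components(g)$components) {
    if (length(bc) >= 3) on_cycle[as.integer(bc)] <- TRUE
  }
  comp <- igraph::components(g)
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    if (length(vs) == 2) {
      sub <- igraph::induced_subgraph(g, vs)
      if (igraph::ecount(sub) == 1) on_cycle[vs] <- TRUE
    }
  }
  on_cycle
}

#' Select cliques whose co-occurrences close into loops
#'
#' Takes the top-ranked itemsets by stability (the "most frequently
#' occurring combinations"), builds a taxon graph whose edges are the
#' pairwise co-occurrences within them, and drops lowest-ranked itemsets
#' until every remaining taxon lies on a cycle of accepted edges (a lone
#' accepted edge counts as a closed 2-node loop). Each maximal connected
#' component of the surviving network becomes one clique; by default its
#' indicator counts only the high-signed members (falling back to all
#' members when fewer than two are high-signed).
#'
#' Candidates are ranked by their total occurrence frequency across
#' repeated holdouts and bootstraps (stability times mean within-forest
#' frequency). Selection is rank-based: it does not require candidates to
#' clear the `stability_threshold` "stable" flag, because stage 1 is a
#' hypothesis-generating miner whose output is error-controlled downstream
#' by permutation inference and cross-stratum validation.
#'
#' @param itemsets stability table from [repeated_holdout_stability()].
#' @param top_k number of top-ranked itemsets eligible for selection.
#' @param min_stability noise floor; itemsets below it are never selected.
#' @param include_low also count low-signed taxa in the indicator.
#' @return list of [clique_definition] objects (possibly empty).
#' @export
select_cliques_closed_loop <- function(itemsets, top_k = 10,
                                       min_stability = 0.1,
                                       include_low = FALSE) {
  if (!nrow(itemsets)) return(list())
  cand <- itemsets[itemsets$size >= 2 & itemsets$stability >= min_stability, ,
                   drop = FALSE]
  if (!nrow(cand)) return(list())
  score <- cand$stability * cand$mean_frequency
  cand <- cand[order(-score, cand$itemset), , drop = FALSE]
  cand <- head(cand, top_k)
  if (!nrow(cand)) return(list())
  parsed <- lapply(cand$itemset, parse_itemset)
  build_graph <- function(idx) {
    edges <- character(0)
    for (i in idx) {
      pr <- combn(sort(parsed[[i]]$members), 2)
      edges <- c(edges, as.vector(pr))
    }
    igraph::simplify(igraph::graph_from_edgelist(
      matrix(edges, ncol = 2, byrow = TRUE), directed = FALSE))
  }
  # Rank-protected greedy: higher-ranked itemsets, once committed, can
  # never be broken open by later arrivals. A new itemset commits (along
  # with any compatible pending ones) only if, after discarding pending
  # itemsets that violate closure, every remaining taxon lies on a cycle
  # or an isolated accepted edge.
  committed <- integer(0)
  pending <- integer(0)
  for (i in seq_len(nrow(cand))) {
    trial <- sort(c(committed, pending, i))
    repeat {
      g <- build_graph(trial)
      bad <- igraph::V(g)$name[!closed_loop_ok(g)]
      if (!length(bad)) break
      victims <- setdiff(trial, committed)
      victims <- victims[vapply(victims, function(j) any(parsed[[j]]$members %in% bad),
                                logical(1))]
      if (!length(victims)) { trial <- NULL; break }  # committed node violated
      trial <- setdiff(trial, max(victims))
      if (!length(trial)) break
    }
    if (is.null(trial)) {
      pending <- c(pending, i)        # cannot close without breaking a commitment
    } else {
      committed <- sort(union(committed, trial))
      pending <- setdiff(union(pending, i), committed)
    }
  }
  if (!length(committed)) return(list())
  g <- build_graph(committed)
  comp <- igraph::components(g)
  sel_rank <- committed
  out <- list()
  for (ci in seq_len(comp$no)) {
    taxa <- names(comp$membership)[comp$membership == ci]
    # sign per taxon: from the highest-ranked itemset containing it
    signs <- setNames(rep(NA_character_, length(taxa)), taxa)
    for (i in sel_rank) {
      s <- parsed[[i]]$signs
      hit <- intersect(names(s), taxa[is.na(signs[taxa])])
      signs[hit] <- s[hit]
    }
    members <- sort(taxa[signs[taxa] == "high"])
    if (length(members) < 2 && !include_low) members <- sort(taxa)
    if (include_low) members <- sort(taxa)
    out[[length(out) + 1L]] <- clique_definition(
      members = members, signs = signs,
      name = sprintf("clique_%d", length(out) + 1L), all_members = sort(taxa))
  }
  out
}

#' Edge list of the selected closed-loop network
#'
#' @param cliques list of [clique_definition]s.
#' @return data.frame `from, to, clique` suitable for TSV export.
#' @export
clique_network_edges <- function(cliques) {
  rows <- list()
  for (cl in cliques) {
    mem <- cl$all_members
    if (length(mem) < 2) next
    pr <- combn(sort(mem), 2)
    rows[[length(rows) + 1L]] <- data.frame(from = pr[1, ], to = pr[2, ],
                                            clique = cl$name, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(from = character(0), to = character(0), clique = character(0)))
  }
  do.call(rbind, rows)
}

# Stable digest of forest structure (for determinism checks).
forest_digest <- function(forest) {
  stopifnot(inherits(forest, "irf_forest"))
  txt <- character(0)
  for (t in seq_len(forest$forest$num.trees)) {
    ti <- ranger::treeInfo(forest$forest, t)
    txt <- c(txt, paste(ti$nodeID, ti$splitvarName, signif(ti$splitval, 10),
                        collapse = "|"))
  }
  subseed(0, paste(txt, collapse = "#"))
}
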