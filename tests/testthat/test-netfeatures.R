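test_that("node strength sums adjacent weights", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(node_strength(weighted_graph(tri)), rep(2, 3))
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5; w[1, 3] <- w[3, 1] <- 0.2
  w[2, 3] <- w[3, 2] <- 0.1
  expect_equal(node_strength(weighted_graph(w)), c(0.7, 0.6, 0.3))
  expect_equal(node_strength(weighted_graph(matrix(0, 4, 4))), rep(0, 4))
  # directed strength = in + out
  d <- matrix(0, 2, 2); d[2, 1] <- 0.4
  expect_equal(node_strength(weighted_graph(d, directed = TRUE)), c(0.4, 0.4))
})

test_that("group degree maxima match brute-force sub-matrix sums", {
  d <- matrix(0, 5, 5); d[2, 1] <- 0.4   # 1 -> 2 with weight 0.4
  g <- weighted_graph(d, directed = TRUE)
  dm <- in_out_degree_max(g, 1:5)
  expect_equal(unname(dm), c(0.4, 0.4))
  expect_equal(unname(in_out_degree_max(weighted_graph(matrix(0, 5, 5),
                                                       directed = TRUE), 1:5)),
               c(0, 0))
  set.seed(1)
  r <- matrix(abs(rnorm(25)), 5); diag(r) <- 0
  gr <- weighted_graph(r, directed = TRUE)
  dmr <- in_out_degree_max(gr, 1:5)
  expect_equal(dmr[["in"]], max(rowSums(r)))
  expect_equal(dmr[["out"]], max(colSums(r)))
  expect_error(in_out_degree_max(weighted_graph(tri <- {m <- matrix(1, 3, 3); diag(m) <- 0; m}), 1:3),
               "directed")
})

test_that("Onnela clustering matches closed forms", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(clustering_coefficient(weighted_graph(tri)), rep(1, 3))

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(clustering_coefficient(weighted_graph(star)), rep(0, 4))

  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 1
  w[1, 3] <- w[3, 1] <- 0.125
  cc <- clustering_coefficient(weighted_graph(w))
  expect_equal(cc[2], (1 * 1 * 0.125)^(1 / 3))
  expect_equal(clustering_coefficient(weighted_graph(matrix(0, 3, 3))),
               rep(0, 3))
})

test_that("betweenness matches exhaustive path enumeration on small graphs", {
  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- 1; path[2, 3] <- path[3, 2] <- 1
  expect_equal(betweenness_centrality(weighted_graph(path)), c(0, 1, 0))

  comp <- matrix(1, 5, 5); diag(comp) <- 0
  expect_equal(betweenness_centrality(weighted_graph(comp)), rep(0, 5))

  # brute force over all source-target pairs on a random 5-node graph
  set.seed(2)
  w <- matrix(runif(25, 0.1, 1), 5); w <- (w + t(w)) / 2; diag(w) <- 0
  g <- weighted_graph(w)
  lens <- 1 / w
  n <- 5
  paths_through <- numeric(n)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    best <- Inf; best_paths <- list()
    others <- setdiff(1:n, c(s, t))
    cand <- list(integer(0))
    for (k in seq_along(others)) {
      for (sub in utils::combn(others, k, simplify = FALSE)) {
        cand <- c(cand, perms(sub))
      }
    }
    for (mid in cand) {
      route <- c(s, mid, t)
      len <- sum(lens[cbind(route[-length(route)], route[-1])])
      if (len < best - 1e-12) {
        best <- len; best_paths <- list(route)
      } else if (abs(len - best) < 1e-12) {
        best_paths <- c(best_paths, list(route))
      }
    }
    for (v in 1:n) {
      frac <- mean(vapply(best_paths, function(r) v %in% r[-c(1, length(r))],
                          logical(1)))
      paths_through[v] <- paths_through[v] + frac
    }
  }
  expect_equal(betweenness_centrality(g),
               paths_through / ((n - 1) * (n - 2) / 2), tolerance = 1e-10)
})

test_that("global efficiency averages inverse shortest path lengths", {
  comp <- matrix(1, 4, 4); diag(comp) <- 0
  expect_equal(global_efficiency(weighted_graph(comp)), 1)
  expect_equal(global_efficiency(weighted_graph(matrix(0, 2, 2))), 0)
  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- 1; path[2, 3] <- path[3, 2] <- 1
  expect_equal(global_efficiency(weighted_graph(path)), (1 + 1 + 0.5) / 3)
})

test_that("graph measures are invariant under node relabeling and monotone", {
  set.seed(3)
  w <- matrix(runif(36, 0, 1), 6); w <- (w + t(w)) / 2; diag(w) <- 0
  perm <- sample(6)
  wp <- w[perm, perm]
  expect_equal(node_strength(weighted_graph(wp)),
               node_strength(weighted_graph(w))[perm])
  expect_equal(clustering_coefficient(weighted_graph(wp)),
               clustering_coefficient(weighted_graph(w))[perm])
  expect_equal(betweenness_centrality(weighted_graph(wp)),
               betweenness_centrality(weighted_graph(w))[perm])
  expect_equal(global_efficiency(weighted_graph(wp)),
               global_efficiency(weighted_graph(w)))
  # raising one weight cannot lower efficiency
  w2 <- w
  w2[2, 5] <- w2[5, 2] <- w2[2, 5] + 0.5
  expect_gte(global_efficiency(weighted_graph(w2)),
             global_efficiency(weighted_graph(w)))
})

test_that("asymmetry ratios are lateralization-insensitive and bounded", {
  expect_equal(asymmetry_ratio(2, 4), 2)
  expect_equal(asymmetry_ratio(4, 2), 2)
  expect_equal(asymmetry_ratio(3, 3), 1)
  expect_warning(r <- asymmetry_ratio(0.5, 0), "capping")
  expect_equal(r, 1e6)
})

test_that("the canonical taxonomy enumerates 784 unique features", {
  tax <- feature_taxonomy()
  expect_equal(nrow(tax), 784)
  expect_equal(anyDuplicated(tax$name), 0)
  counts <- table(tax$block)
  expect_equal(unname(counts[c("bandpower", "connectivity", "graph",
                               "asymmetry")]),
               c(40, 128, 468, 148), ignore_attr = TRUE)
  # MI appears only with the global band
  mi <- tax[tax$estimator == "mi", ]
  expect_true(all(mi$band == "global"))
  # directed degree maxima exist only for PDC
  deg <- tax[grepl("^degmax|^asym_degmax", tax$name), ]
  expect_true(all(deg$estimator == "pdc"))
})

test_that("feature assembly is total, ordered, and errors on missing blocks", {
  lay <- bipolar_montage()
  set.seed(4)
  mats <- list()
  for (est in c("imcoh", "plv", "pdc")) {
    for (b in c("delta", "theta", "alpha", "beta", "global")) {
      v <- matrix(abs(rnorm(18 * 18)), 18,
                  dimnames = list(lay$pairs$label, lay$pairs$label))
      if (est != "pdc") v <- (v + t(v)) / 2
      mats[[paste(est, b, sep = "_")]] <-
        epifc:::conn_matrix(v, est, b, est == "pdc", lay$pairs$label)
    }
  }
  v <- matrix(abs(rnorm(18 * 18)), 18,
              dimnames = list(lay$pairs$label, lay$pairs$label))
  mats[["mi_global"]] <- epifc:::conn_matrix((v + t(v)) / 2, "mi", "global",
                                             FALSE, lay$pairs$label)
  bp <- stats::setNames(abs(rnorm(40)),
                        feature_taxonomy()$name[1:40])
  f1 <- suppressWarnings(assemble_features(bp, mats, lay))
  expect_equal(length(f1), 784)
  expect_identical(names(f1), feature_taxonomy()$name)
  f2 <- suppressWarnings(assemble_features(bp, mats, lay))
  expect_identical(names(f1), names(f2))
  expect_error(suppressWarnings(assemble_features(bp, mats[-1], lay)),
               "missing feature")
})
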