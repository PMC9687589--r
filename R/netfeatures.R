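# Weighted-graph summaries of connectivity matrices. All adjacency matrices
# are nonnegative with zero diagonal; "directed" is true only for PDC.

as_adjacency <- function(g) {
  if (inherits(g, "conn_matrix")) {
    list(w = g$values, directed = g$directed)
  } else {
    list(w = as.matrix(g$w), directed = isTRUE(g$directed))
  }
}

#' Weighted graph from an adjacency matrix
#'
#' @param w Nonnegative weight matrix (zero diagonal enforced).
#' @param directed Whether edges are directed.
#' @return A `weighted_graph` list.
#' @export
weighted_graph <- function(w, directed = FALSE) {
  w <- as.matrix(w)
  if (any(w < 0)) stop("weights must be nonnegative")
  diag(w) <- 0
  if (!directed && !isSymmetric(unname(w), tol = 1e-10)) {
    stop("undirected graph requires a symmetric weight matrix")
  }
  structure(list(w = w, directed = directed), class = "weighted_graph")
}

#' Node strength
#'
#' Sum of the weights of all links adjacent to each node; for directed graphs
#' the in-strength plus out-strength.
#'
#' @param g A `weighted_graph` or `conn_matrix`.
#' @return Numeric vector, one value per node.
#' @export
node_strength <- function(g) {
  a <- as_adjacency(g)
  if (a$directed) rowSums(a$w) + colSums(a$w) else rowSums(a$w)
}

#' Maximum in- and out-strength within a scalp group
#'
#' Maxima over the group's nodes of the inward and outward strengths of the
#' group submatrix. The adjacency convention follows PDC: entry (i, j) is the
#' flow from j to i, so row sums are inward and column sums outward. Defined
#' for directed graphs (PDC) only.
#'
#' @param g A directed `weighted_graph` or `conn_matrix`.
#' @param group Node indices or names of the group.
#' @return Named vector `c(in = ..., out = ...)`.
#' @export
in_out_degree_max <- function(g, group) {
  a <- as_adjacency(g)
  if (!a$directed) stop("in/out degrees are defined for directed graphs only")
  if (is.character(group)) group <- match(group, rownames(a$w))
  sub <- a$w[group, group, drop = FALSE]
  c("in" = max(rowSums(sub)), out = max(colSums(sub)))
}

#' Onnela weighted clustering coefficient
#'
#' Weights are first normalized by the graph's maximum weight; with `what`
#' the normalized weights and `k_i` the binary degree,
#' `C_i = (sum_jh (w_ij w_ih w_jh)^(1/3)) / (k_i (k_i - 1))`. Directed
#' matrices are symmetrized as `(w + t(w)) / 2` first. A zero-weight graph
#' has all coefficients 0.
#'
#' @param g A `weighted_graph` or `conn_matrix`.
#' @return Numeric vector, one coefficient per node, in `[0, 1]`.
#' @export
clustering_coefficient <- function(g) {
  a <- as_adjacency(g)
  w <- if (a$directed) (a$w + t(a$w)) / 2 else a$w
  mx <- max(w)
  if (mx == 0) return(numeric(nrow(w)))
  wh <- (w / mx)^(1 / 3)
  k <- rowSums(w > 0)
  cyc <- diag(wh %*% wh %*% wh)
  cc <- numeric(nrow(w))
  ok <- k > 1
  cc[ok] <- cyc[ok] / (k[ok] * (k[ok] - 1))
  cc
}

# igraph object with edge lengths 1/weight.
as_igraph_lengths <- function(w, directed) {
  g <- igraph::graph_from_adjacency_matrix(w, weighted = TRUE,
                                           mode = if (directed) "directed"
                                           else "undirected", diag = FALSE)
  igraph::E(g)$length <- 1 / igraph::E(g)$weight
  g
}

#' Betweenness centrality
#'
#' Fraction of all shortest paths (edge lengths `1 / weight`) passing through
#' each node, normalized by the number of source-target pairs excluding the
#' node: `(n-1)(n-2)` for directed graphs, `(n-1)(n-2)/2` for undirected.
#'
#' @param g A `weighted_graph` or `conn_matrix`.
#' @return Numeric vector of normalized centralities in `[0, 1]`.
#' @export
betweenness_centrality <- function(g) {
  a <- as_adjacency(g)
  n <- nrow(a$w)
  if (n < 3) return(numeric(n))
  if (max(a$w) == 0) return(numeric(n))
  ig <- as_igraph_lengths(a$w, a$directed)
  bc <- igraph::betweenness(ig, directed = a$directed,
                            weights = igraph::E(ig)$length)
  denom <- if (a$directed) (n - 1) * (n - 2) else (n - 1) * (n - 2) / 2
  unname(bc) / denom
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest path length (edge
#' lengths `1 / weight`); unreachable pairs contribute 0.
#'
#' @param g A `weighted_graph` or `conn_matrix`.
#' @return Scalar efficiency.
#' @export
global_efficiency <- function(g) {
  a <- as_adjacency(g)
  n <- nrow(a$w)
  if (n < 2) return(0)
  if (max(a$w) == 0) return(0)
  ig <- as_igraph_lengths(a$w, a$directed)
  d <- igraph::distances(ig, mode = "out", weights = igraph::E(ig)$length)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d) & row(d) != col(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Hemispheric asymmetry ratio
#'
#' `max(left, right) / min(left, right)`: lateralization-insensitive, always
#' >= 1 for positive inputs. If the smaller summary is <= 0 the ratio is
#' defined as `(max + eps) / eps` capped at 1e6 (with a warning), with
#' `eps = 1e-12`.
#'
#' @param left,right Scalar group summaries.
#' @return The ratio.
#' @export
asymmetry_ratio <- function(left, right) {
  hi <- max(left, right); lo <- min(left, right)
  if (lo <= 0) {
    warning("non-positive group summary in asymmetry ratio; capping at 1e6")
    eps <- 1e-12
    return(min((hi + eps) / eps, 1e6))
  }
  hi / lo
}

# quiet variant used during bulk assembly (degenerate inputs already logged)
asym_ratio_quiet <- function(left, right) {
  suppressWarnings(asymmetry_ratio(left, right))
}

#' The canonical feature taxonomy
#'
#' Enumerates, in canonical order, every feature the extraction pipeline
#' produces: 40 band-power features, 128 connectivity group summaries
#' (IMCOH/PLV/PDC over five bands, MI global only), 468 graph features
#' (directed degree maxima for PDC; node strength with PDC mean-only;
#' clustering; betweenness; efficiency) and 148 asymmetry ratios (anterior
#' and posterior left/right ratios of the group means, degree maxima and
#' efficiencies). The total is fixed at 784.
#'
#' @return A tibble with columns `name`, `block`, `estimator`, `band`,
#'   `group`, `stat` (784 rows).
#' @export
#' @examples
#' nrow(feature_taxonomy())  # 784
feature_taxonomy <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cache <<- build_feature_taxonomy()
    cache
  }
})

build_feature_taxonomy <- function() {
  groups <- c("AL", "AR", "PL", "PR")
  pairs <- c(ant = "ant", post = "post")
  bands5 <- c("delta", "theta", "alpha", "beta", "global")
  est_bands <- function(est) if (est == "mi") "global" else bands5
  rows <- list()
  add <- function(name, block, estimator, band, group, stat) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      name = name, block = block, estimator = estimator, band = band,
      group = group, stat = stat)
  }

  # band power (32) + total absolute power (8)
  for (b in c("delta", "theta", "alpha", "beta")) for (g in groups)
    for (s in c("median", "sd"))
      add(paste("bp", b, g, s, sep = "_"), "bandpower", "bp", b, g, s)
  for (g in groups) for (s in c("median", "sd"))
    add(paste("tap", g, s, sep = "_"), "bandpower", "tap", "global", g, s)

  # connectivity group summaries (128)
  for (est in c("imcoh", "plv", "mi", "pdc")) for (b in est_bands(est))
    for (g in groups) for (s in c("mean", "sd"))
      add(paste("conn", est, b, g, s, sep = "_"), "connectivity", est, b, g, s)

  # graph: degree maxima, PDC only (40)
  for (b in bands5) for (g in groups) for (s in c("in", "out"))
    add(paste("degmax", "pdc", b, g, s, sep = "_"), "graph", "pdc", b, g, s)
  # node strength (108): mean+sd except PDC mean-only
  for (est in c("imcoh", "plv", "mi", "pdc")) for (b in est_bands(est))
    for (g in groups)
      for (s in if (est == "pdc") "mean" else c("mean", "sd"))
        add(paste("strength", est, b, g, s, sep = "_"), "graph", est, b, g, s)
  # clustering (128) and betweenness (128)
  for (meas in c("clust", "btw"))
    for (est in c("imcoh", "plv", "mi", "pdc")) for (b in est_bands(est))
      for (g in groups) for (s in c("mean", "sd"))
        add(paste(meas, est, b, g, s, sep = "_"), "graph", est, b, g, s)
  # efficiency (64)
  for (est in c("imcoh", "plv", "mi", "pdc")) for (b in est_bands(est))
    for (g in groups)
      add(paste("eff", est, b, g, sep = "_"), "graph", est, b, g, "value")

  # asymmetry (148): ant + post ratios
  for (b in bands5) for (p in pairs) for (s in c("in", "out"))
    add(paste("asym", "degmax", "pdc", b, p, s, sep = "_"), "asymmetry",
        "pdc", b, p, s)
  for (meas in c("strength", "clust", "btw"))
    for (est in c("imcoh", "plv", "mi", "pdc")) for (b in est_bands(est))
      for (p in pairs)
        add(paste("asym", meas, est, b, p, sep = "_"), "asymmetry", est, b,
            p, "mean")
  for (est in c("imcoh", "plv", "mi", "pdc")) for (b in est_bands(est))
    for (p in pairs)
      add(paste("asym", "eff", est, b, p, sep = "_"), "asymmetry", est, b,
          p, "value")

  out <- dplyr::bind_rows(rows)
  stopifnot(nrow(out) == 784L, !anyDuplicated(out$name))
  out
}

# Graph + asymmetry features for one connectivity matrix.
graph_feature_block <- function(cm, layout = bipolar_montage()) {
  est <- cm$estimator; b <- cm$band
  groups <- layout$groups
  labels <- rownames(cm$values)
  out <- c()

  ns <- node_strength(cm)
  cc <- clustering_coefficient(cm)
  bc <- betweenness_centrality(cm)
  names(ns) <- names(cc) <- names(bc) <- labels

  gstat <- list()
  for (g in names(groups)) {
    gi <- groups[[g]]
    if (est == "pdc") {
      dm <- in_out_degree_max(cm, gi)
      out[paste("degmax", est, b, g, "in", sep = "_")] <- dm[["in"]]
      out[paste("degmax", est, b, g, "out", sep = "_")] <- dm[["out"]]
    }
    out[paste("strength", est, b, g, "mean", sep = "_")] <- mean(ns[gi])
    if (est != "pdc") {
      out[paste("strength", est, b, g, "sd", sep = "_")] <- pop_sd(ns[gi])
    }
    out[paste("clust", est, b, g, "mean", sep = "_")] <- mean(cc[gi])
    out[paste("clust", est, b, g, "sd", sep = "_")] <- pop_sd(cc[gi])
    out[paste("btw", est, b, g, "mean", sep = "_")] <- mean(bc[gi])
    out[paste("btw", est, b, g, "sd", sep = "_")] <- pop_sd(bc[gi])
    idx <- match(gi, labels)
    eff <- global_efficiency(weighted_graph(cm$values[idx, idx],
                                            directed = cm$directed))
    out[paste("eff", est, b, g, sep = "_")] <- eff
    gstat[[g]] <- list(strength = mean(ns[gi]), clust = mean(cc[gi]),
                       btw = mean(bc[gi]), eff = eff,
                       degmax = if (est == "pdc") in_out_degree_max(cm, gi))
  }

  for (p in c(ant = "ant", post = "post")) {
    lg <- if (p == "ant") "AL" else "PL"
    rg <- if (p == "ant") "AR" else "PR"
    if (est == "pdc") {
      out[paste("asym", "degmax", est, b, p, "in", sep = "_")] <-
        asym_ratio_quiet(gstat[[lg]]$degmax[["in"]], gstat[[rg]]$degmax[["in"]])
      out[paste("asym", "degmax", est, b, p, "out", sep = "_")] <-
        asym_ratio_quiet(gstat[[lg]]$degmax[["out"]], gstat[[rg]]$degmax[["out"]])
    }
    for (meas in c("strength", "clust", "btw", "eff")) {
      out[paste("asym", meas, est, b, p, sep = "_")] <-
        asym_ratio_quiet(gstat[[lg]][[meas]], gstat[[rg]][[meas]])
    }
  }
  out
}

# Connectivity group-summary features for one matrix.
conn_feature_block <- function(cm, layout = bipolar_montage()) {
  s <- summarize_groups(cm, layout)
  out <- c()
  for (r in seq_len(nrow(s))) {
    out[paste("conn", cm$estimator, cm$band, s$group[r], "mean", sep = "_")] <-
      s$mean[r]
    out[paste("conn", cm$estimator, cm$band, s$group[r], "sd", sep = "_")] <-
      s$sd[r]
  }
  out
}

#' Assemble the canonical per-subject feature vector
#'
#' Concatenates the band-power block and, for every connectivity matrix, the
#' group-summary, graph and asymmetry blocks, then orders everything by the
#' canonical taxonomy. Errors if any taxonomy entry is missing.
#'
#' @param bp_features Named vector from [bandpower_features()].
#' @param conn_matrices List of `conn_matrix` objects covering IMCOH, PLV and
#'   PDC in all five bands and MI in the global band.
#' @param layout A [bipolar_montage()].
#' @return Named numeric vector of length 784 in canonical order.
#' @export
assemble_features <- function(bp_features, conn_matrices,
                              layout = bipolar_montage()) {
  feats <- bp_features
  for (cm in conn_matrices) {
    feats <- c(feats, conn_feature_block(cm, layout),
               graph_feature_block(cm, layout))
  }
  tax <- feature_taxonomy()
  missing <- setdiff(tax$name, names(feats))
  if (length(missing) > 0) {
    stop("missing feature(s): ", paste(utils::head(missing, 12),
                                       collapse = ", "),
         if (length(missing) > 12) sprintf(" ... (%d total)", length(missing)))
  }
  feats[tax$name]
}
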