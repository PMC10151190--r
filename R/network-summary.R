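#' Fold-averaged, z-scored connection weights
#'
#' Averages per-fold elastic-net weight vectors elementwise, z-transforms the
#' means over the standardization population, and marks connections with
#' `|z|` above the threshold as significant. By default the standardization
#' population is the features with a nonzero fold-mean weight: in sparse
#' models the structural zeros would otherwise dominate the spread.
#'
#' @param fold_weights List of equal-length per-fold weight vectors, a
#'   folds x features matrix, or a list of `fold_model`s.
#' @param z_thr Significance threshold on `|z|` (default 3.29, two-sided
#'   p < 0.001).
#' @param population `"nonzero"` (default) or `"all"`: which features define
#'   the z standardization.
#' @return A `weight_map`: list with `mean_weights`, `z_weights` (`NA`
#'   outside the population), `significant` (logical), `z_thr`.
#' @export
average_weights_z <- function(fold_weights, z_thr = 3.29,
                              population = c("nonzero", "all")) {
  population <- match.arg(population)
  if (is.list(fold_weights)) {
    fold_weights <- lapply(fold_weights, function(f) {
      if (inherits(f, "fold_model")) f$weights else f
    })
    lens <- lengths(fold_weights)
    if (length(unique(lens)) != 1L) stop("fold weight vectors differ in length", call. = FALSE)
    fold_weights <- do.call(rbind, fold_weights)
  }
  mw <- colMeans(fold_weights)
  pop <- if (population == "nonzero") which(mw != 0) else seq_along(mw)
  z <- rep(NA_real_, length(mw))
  sig <- rep(FALSE, length(mw))
  if (length(pop) >= 2L && isTRUE(stats::sd(mw[pop]) > 0)) {
    z[pop] <- (mw[pop] - mean(mw[pop])) / stats::sd(mw[pop])
    sig <- !is.na(z) & abs(z) > z_thr
  } else {
    warning("degenerate weight spread: no significant connections")
  }
  structure(list(mean_weights = mw, z_weights = z, significant = sig,
                 z_thr = z_thr, population = population),
            class = "weight_map")
}

#' Nodal degree of significant model connections
#'
#' For every node, sums the (absolute, by default) fold-mean weights of its
#' incident significant connections, and reports the proportion of those
#' connections carrying positive weight. Nodes with no incident significant
#' connection have degree 0 and an undefined (NA) proportion.
#'
#' @param weight_map A `weight_map` from [average_weights_z()].
#' @param pair_map Feature-to-ROI-pair map ([pair_index_map()]); must cover
#'   every feature.
#' @param signed Use the signed sum instead of the absolute sum.
#' @return A `node_summary` data frame: `node`, `degree`, `n_connections`,
#'   `positive_proportion`.
#' @export
nodal_degree <- function(weight_map, pair_map, signed = FALSE) {
  stopifnot(inherits(weight_map, "weight_map"))
  if (nrow(pair_map) != length(weight_map$mean_weights)) {
    stop("pair_map does not cover the feature vector", call. = FALSE)
  }
  K <- max(pair_map$i, pair_map$j)
  sig <- which(weight_map$significant)
  deg <- numeric(K)
  npos <- integer(K)
  ntot <- integer(K)
  for (f in sig) {
    w <- weight_map$mean_weights[f]
    contrib <- if (signed) w else abs(w)
    for (node in c(pair_map$i[f], pair_map$j[f])) {
      deg[node] <- deg[node] + contrib
      ntot[node] <- ntot[node] + 1L
      if (w > 0) npos[node] <- npos[node] + 1L
    }
  }
  structure(data.frame(node = seq_len(K),
                       degree = deg,
                       n_connections = ntot,
                       positive_proportion = ifelse(ntot > 0, npos / ntot,
                                                    NA_real_)),
            class = c("node_summary", "data.frame"))
}

#' Top-degree nodes
#'
#' The k highest-degree nodes, ties broken by lower node id. Nodes with zero
#' degree are never returned; if fewer than k nodes have nonzero degree, all
#' of them are returned (with a message).
#'
#' @param summary A `node_summary` from [nodal_degree()].
#' @param k Number of nodes (default 10).
#' @return Integer vector of node ids, ordered by decreasing degree.
#' @export
top_nodes <- function(summary, k = 10L) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  nz <- summary[summary$degree > 0, , drop = FALSE]
  ord <- nz[order(-nz$degree, nz$node), "node"]
  if (length(ord) < k) {
    message(sprintf("only %d node(s) have nonzero degree", length(ord)))
    return(as.integer(ord))
  }
  as.integer(ord[seq_len(k)])
}

#' Filter significant connections by node membership
#'
#' Keeps significant connections with at least one endpoint in `node_ids` —
#' a visualization aid for dense models, not a refitted model.
#'
#' @param weight_map A `weight_map`.
#' @param pair_map The feature-to-pair map.
#' @param node_ids Nodes of interest.
#' @return Data frame `feature`, `i`, `j`, `weight` of retained connections.
#' @export
filter_by_nodes <- function(weight_map, pair_map, node_ids) {
  sig <- which(weight_map$significant)
  keep <- sig[pair_map$i[sig] %in% node_ids | pair_map$j[sig] %in% node_ids]
  data.frame(feature = keep,
             i = pair_map$i[keep],
             j = pair_map$j[keep],
             weight = weight_map$mean_weights[keep])
}
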