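# Root-trunk-branch trajectory: 2-D components, a minimum-spanning-tree
# backbone over cluster centroids, root selection by naiveness, per-cell
# pseudotime by projection onto incident backbone edges, and structural
# branch assignment with score-based branch naming.

#' Two-dimensional trajectory components
#'
#' Deterministic 2-D reduction (top-2 principal components of the z-score
#' matrix, fixed sign convention).
#'
#' @param signatures genes x cells z-score matrix.
#' @return cells x 2 matrix (component1, component2).
#' @export
reduce_components <- function(signatures) {
  comps <- pca_reduce(signatures, n_pcs = 2)
  colnames(comps) <- c("component1", "component2")
  comps
}

#' Minimum-spanning-tree backbone over cluster centroids
#'
#' Kruskal MST over the complete Euclidean graph on cluster centroids; ties
#' are broken by lexicographic (label1, label2) edge order, so the tree is
#' deterministic. The centroid space is whatever reduction is passed in —
#' the full PC space by default (see \code{\link{infer_trajectory}}), since a
#' 2-D projection cannot faithfully embed several orthogonal branch
#' programs.
#'
#' @param components cells x d matrix (d >= 2).
#' @param clusters factor of cluster labels per cell.
#' @return Object of class \code{backbone_tree}: list(centroids, edges) where
#'   edges has columns from, to, length.
#' @export
fit_backbone <- function(components, clusters) {
  labs <- sort(unique(as.character(clusters)))
  if (length(labs) < 1) sc_stop("at least one cluster required")
  cents <- do.call(rbind, lapply(labs, function(cl)
    colMeans(components[as.character(clusters) == cl, , drop = FALSE])))
  rownames(cents) <- labs
  if (length(labs) == 1) {
    warning("single cluster: trivial single-node backbone")
    return(structure(list(centroids = cents,
                          edges = data.frame(from = character(0), to = character(0),
                                             length = numeric(0))),
                     class = "backbone_tree"))
  }
  # all candidate edges, sorted by (length, from, to)
  pairs <- t(utils::combn(labs, 2))
  len <- sqrt(rowSums((cents[pairs[, 1], , drop = FALSE] -
                       cents[pairs[, 2], , drop = FALSE])^2))
  ord <- order(len, pairs[, 1], pairs[, 2])
  # Kruskal with union-find
  parent <- setNames(labs, labs)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  edges <- list()
  for (i in ord) {
    a <- find(pairs[i, 1]); b <- find(pairs[i, 2])
    if (a != b) {
      parent[[a]] <- b
      edges[[length(edges) + 1L]] <- data.frame(
        from = pairs[i, 1], to = pairs[i, 2], length = len[i])
      if (length(edges) == length(labs) - 1) break
    }
  }
  structure(list(centroids = cents, edges = do.call(rbind, edges)),
            class = "backbone_tree")
}

#' @method print backbone_tree
#' @export
print.backbone_tree <- function(x, ...) {
  cat(sprintf("backbone_tree: %d node(s), %d edge(s)\n",
              nrow(x$centroids), nrow(x$edges)))
  invisible(x)
}

backbone_graph <- function(tree) {
  igraph::graph_from_data_frame(tree$edges, directed = FALSE,
                                vertices = rownames(tree$centroids))
}

#' Select the trajectory root cluster
#'
#' The root is the leaf cluster (backbone degree 1) with the maximal median
#' naiveness score; ties are broken by the lower median exhaustion score.
#'
#' @param tree a \code{backbone_tree}.
#' @param scores data.frame from \code{\link{score_panel}} with
#'   \code{naiveness} and \code{exhaustion} columns.
#' @param clusters factor of cluster labels per cell, aligned to
#'   \code{scores}.
#' @return Root cluster label.
#' @export
select_root <- function(tree, scores, clusters) {
  labs <- rownames(tree$centroids)
  if (length(labs) == 1) return(labs)
  g <- backbone_graph(tree)
  leaves <- labs[igraph::degree(g)[labs] == 1]
  med <- function(col, cl) median(scores[[col]][as.character(clusters) == cl])
  naive <- vapply(leaves, med, numeric(1), col = "naiveness")
  best <- leaves[naive == max(naive)]
  if (length(best) > 1) {
    exh <- vapply(best, med, numeric(1), col = "exhaustion")
    best <- best[order(exh, best)][1]
  }
  best
}

# geodesic distance from root to every centroid along the tree
root_distances <- function(tree, root) {
  g <- backbone_graph(tree)
  d <- igraph::distances(g, v = root, weights = igraph::E(g)$length)
  setNames(as.numeric(d), colnames(d))
}

#' Per-cell pseudotime
#'
#' Each cell is projected onto the backbone edges incident to its cluster's
#' centroid node (nearest-point projection in component space); its
#' pseudotime is the geodesic distance from the root centroid to the
#' projected point. Cells in the root cluster at the root centroid get 0.
#'
#' @param tree a \code{backbone_tree}.
#' @param root root cluster label (see \code{\link{select_root}}).
#' @param components cells x d matrix (the space the backbone was fitted in).
#' @param clusters factor of cluster labels per cell.
#' @return named numeric vector of pseudotimes (>= 0).
#' @export
assign_pseudotime <- function(tree, root, components, clusters) {
  labs <- rownames(tree$centroids)
  rd <- if (nrow(tree$edges)) root_distances(tree, root) else setNames(0, labs)
  cents <- tree$centroids
  e <- tree$edges
  pt <- numeric(nrow(components))
  for (cl in labs) {
    idx <- which(as.character(clusters) == cl)
    if (!length(idx)) next
    inc <- which(e$from == cl | e$to == cl)
    if (!length(inc)) { pt[idx] <- rd[[cl]]; next }
    cand <- matrix(Inf, nrow = length(idx), ncol = length(inc))  # distance to edge
    ptc <- matrix(0, nrow = length(idx), ncol = length(inc))     # pseudotime on edge
    x <- components[idx, , drop = FALSE]
    for (j in seq_along(inc)) {
      ed <- e[inc[j], ]
      u <- cents[ed$from, ]; v <- cents[ed$to, ]
      uv <- v - u
      L2 <- sum(uv^2)
      t_par <- pmin(1, pmax(0, as.numeric(sweep(x, 2, u) %*% uv) / L2))
      proj <- outer(t_par, uv) + rep(u, each = length(t_par))
      cand[, j] <- sqrt(rowSums((x - proj)^2))
      # pseudotime along the edge, measured from the root-nearer endpoint
      if (rd[[ed$to]] >= rd[[ed$from]])
        ptc[, j] <- rd[[ed$from]] + t_par * ed$length
      else
        ptc[, j] <- rd[[ed$from]] - t_par * ed$length
    }
    pick <- max.col(-cand, ties.method = "first")
    pt[idx] <- ptc[cbind(seq_along(idx), pick)]
  }
  pt <- pmax(pt, 0)
  names(pt) <- rownames(components)
  pt
}

#' Structural branch assignment
#'
#' Clusters on the path from the root to the first node of backbone degree
#' >= 3 form the trunk (the root cluster itself is labeled "root"); each
#' maximal subtree beyond the branching node becomes one branch
#' ("branch_1", ..., ordered by lexicographically smallest member label).
#' Cells inherit their cluster's label. A path graph yields root + trunk
#' only; a star rooted at its center yields one branch per leaf and an empty
#' trunk.
#'
#' @param tree a \code{backbone_tree}.
#' @param root root cluster label.
#' @param clusters factor of cluster labels per cell.
#' @return factor of per-cell labels in {root, trunk, branch_1..branch_B}
#'   with attribute \code{cluster_branch} (the per-cluster map).
#' @export
assign_branches <- function(tree, root, clusters) {
  labs <- rownames(tree$centroids)
  cl_lab <- setNames(rep("trunk", length(labs)), labs)
  cl_lab[root] <- "root"
  if (nrow(tree$edges)) {
    g <- backbone_graph(tree)
    deg <- igraph::degree(g)
    # walk from the root until the first branching node
    order_from_root <- igraph::dfs(g, root = root, unreachable = FALSE)$order
    path_nodes <- root
    branch_node <- NULL
    if (deg[root] >= 3) {
      branch_node <- root
    } else {
      cur <- root; prev <- NA
      repeat {
        nb <- setdiff(names(igraph::neighbors(g, cur)), prev)
        if (!length(nb)) break              # pure path: no branching node
        if (deg[cur] >= 3) { branch_node <- cur; break }
        prev <- cur; cur <- nb[1]
        path_nodes <- c(path_nodes, cur)
        if (deg[cur] >= 3) { branch_node <- cur; break }
      }
    }
    if (!is.null(branch_node)) {
      trunk_nodes <- path_nodes[seq_len(match(branch_node, path_nodes))]
      cl_lab[setdiff(trunk_nodes, root)] <- "trunk"
      # subtrees hanging off the branching node
      g2 <- igraph::delete_vertices(g, branch_node)
      comp <- igraph::components(g2)
      memb <- igraph::membership(comp)
      sub_ids <- setdiff(unique(memb[setdiff(names(memb), trunk_nodes)]), NA)
      firsts <- vapply(sub_ids, function(id)
        min(names(memb)[memb == id]), character(1))
      sub_ids <- sub_ids[order(firsts)]
      for (k in seq_along(sub_ids)) {
        nodes_k <- names(memb)[memb == sub_ids[k]]
        nodes_k <- setdiff(nodes_k, trunk_nodes)
        cl_lab[nodes_k] <- paste0("branch_", k)
      }
    } else {
      cl_lab[setdiff(labs, root)] <- "trunk"   # path graph
    }
  }
  out <- factor(cl_lab[as.character(clusters)],
                levels = unique(c("root", "trunk",
                                  sort(setdiff(unique(cl_lab), c("root", "trunk"))))))
  names(out) <- names(clusters)
  attr(out, "cluster_branch") <- cl_lab
  out
}

#' Name branches by phenotype score profiles
#'
#' Structural branch labels are renamed by their score profiles: the branch
#' with the highest mean cytotoxicity becomes "effector"; of the remainder,
#' the branch with the highest mean exhaustion becomes "exhausted", and the
#' next-highest "dysfunctional" (it shares the exhaustion program at lower
#' amplitude); further branches keep their structural names.
#'
#' @param branch_labels factor from \code{\link{assign_branches}}.
#' @param scores data.frame from \code{\link{score_panel}}.
#' @return factor with renamed branch levels; attribute \code{branch_map}.
#' @export
name_branches <- function(branch_labels, scores) {
  branches <- setdiff(levels(branch_labels), c("root", "trunk"))
  map <- setNames(branches, branches)
  if (length(branches)) {
    cyto <- vapply(branches, function(b)
      mean(scores$cytotoxicity[branch_labels == b]), numeric(1))
    eff <- branches[which.max(cyto)]
    map[eff] <- "effector"
    rest <- setdiff(branches, eff)
    if (length(rest)) {
      exh <- vapply(rest, function(b)
        mean(scores$exhaustion[branch_labels == b]), numeric(1))
      ex <- rest[which.max(exh)]
      map[ex] <- "exhausted"
      rest <- setdiff(rest, ex)
      if (length(rest)) {
        # dysfunctional shares the exhaustion program at lower amplitude
        exh2 <- vapply(rest, function(b)
          mean(scores$exhaustion[branch_labels == b]), numeric(1))
        map[rest[which.max(exh2)]] <- "dysfunctional"
      }
    }
  }
  new_labels <- as.character(branch_labels)
  for (b in names(map)) new_labels[branch_labels == b] <- map[[b]]
  keep <- intersect(c("root", "trunk"), levels(branch_labels))
  out <- factor(new_labels, levels = unique(c(keep, unname(map))))
  names(out) <- names(branch_labels)
  attr(out, "branch_map") <- map
  out
}

#' Infer the whole trajectory
#'
#' Backbone MST, root selection by naiveness, pseudotime and branch labels
#' (structural, then named by score profiles). The backbone, pseudotime and
#' branches are computed in the full \code{n_pcs}-dimensional PC space (or a
#' supplied reduction): orthogonal branch programs are not separable in two
#' dimensions. The 2-D components are kept for reporting and for the
#' score-component correlations.
#'
#' @param signatures genes x cells z-score matrix.
#' @param clusters factor of cluster labels per cell.
#' @param scores data.frame from \code{\link{score_panel}}.
#' @param pcs optional cells x d reduction to fit the backbone in; default
#'   \code{pca_reduce(signatures, n_pcs)}.
#' @param n_pcs dimensionality of the default backbone space (default 20).
#' @return Object of class \code{trajectory_model}: list(components,
#'   backbone, root, pseudotime, branch).
#' @export
infer_trajectory <- function(signatures, clusters, scores, pcs = NULL,
                             n_pcs = 20) {
  if (is.null(pcs)) pcs <- pca_reduce(signatures, n_pcs)
  comps <- pcs[, 1:2, drop = FALSE]
  colnames(comps) <- c("component1", "component2")
  tree <- fit_backbone(pcs, clusters)
  root <- select_root(tree, scores, clusters)
  pt <- assign_pseudotime(tree, root, pcs, clusters)
  br <- assign_branches(tree, root, clusters)
  br <- name_branches(br, scores)
  structure(list(components = comps, backbone = tree, root = root,
                 pseudotime = pt, branch = br),
            class = "trajectory_model")
}

#' @method print trajectory_model
#' @export
print.trajectory_model <- function(x, ...) {
  cat(sprintf("trajectory_model: root=%s; branches: %s\n", x$root,
              paste(setdiff(levels(x$branch), c("root", "trunk")), collapse = ", ")))
  invisible(x)
}

#' Projection of cells onto a branch axis
#'
#' The axis runs from the root-branch centroid to the target branch's
#' centroid in component space; each cell's coordinate is its scalar
#' projection onto that axis. Used to test the sign pattern of phenotype
#' scores along (for example) the effector axis.
#'
#' @param trajectory a \code{trajectory_model}.
#' @param branch branch level to point the axis at (default "effector").
#' @return named numeric vector of projections.
#' @export
branch_axis_projection <- function(trajectory, branch = "effector") {
  comps <- trajectory$components
  br <- trajectory$branch
  if (!branch %in% levels(br)) sc_stop(paste0("no branch named '", branch, "'"))
  origin <- colMeans(comps[br == "root", , drop = FALSE])
  tip <- colMeans(comps[br == branch, , drop = FALSE])
  axis <- tip - origin
  axis <- axis / sqrt(sum(axis^2))
  proj <- as.numeric((comps[, 1] - origin[1]) * axis[1] +
                     (comps[, 2] - origin[2]) * axis[2])
  names(proj) <- rownames(comps)
  proj
}
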