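# Beta-diversity stage, implemented from first principles: Bray-Curtis
# dissimilarity, classical multidimensional scaling (PCoA), one-way PERMANOVA
# with label permutation (exhaustive when enumerable), and agglomerative
# hierarchical clustering with deterministic tie-breaking and Newick export.

# ---- Bray-Curtis ------------------------------------------------------------

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `BC = sum(|x - y|) / sum(x + y)`. On normalized profiles this equals half
#' the L1 distance. 0 means identical composition, 1 disjoint support.
#'
#' @param x,y Non-negative numeric vectors on the same taxon index.
#' @return Dissimilarity in `[0, 1]`.
#' @examples
#' bray_curtis(c(1, 0), c(0.5, 0.5))
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("bray_curtis: length mismatch", call. = FALSE)
  if (any(x < 0) || any(y < 0)) stop("bray_curtis: negative abundance",
                                     call. = FALSE)
  denom <- sum(x) + sum(y)
  if (denom <= 0) stop("bray_curtis: both vectors all-zero", call. = FALSE)
  sum(abs(x - y)) / denom
}

#' Construct a validated sample-by-sample distance matrix
#'
#' @param m Square numeric matrix with sample ids as dimnames, zero diagonal,
#'   symmetric to 1e-12.
#' @return Object of class `distance_matrix` (the matrix, symmetrized).
#' @export
distance_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance_matrix: matrix must be square",
                               call. = FALSE)
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("s", seq_len(nrow(m)))
  }
  if (max(abs(m - t(m))) > 1e-12) {
    stop("distance_matrix: matrix not symmetric (tolerance 1e-12)", call. = FALSE)
  }
  if (any(abs(diag(m)) > 1e-12)) {
    stop("distance_matrix: diagonal must be zero", call. = FALSE)
  }
  if (any(m < 0)) stop("distance_matrix: negative dissimilarity", call. = FALSE)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  structure(m, class = c("distance_matrix", "matrix"))
}

#' Pairwise Bray-Curtis distance matrix
#'
#' @param profiles Numeric matrix, taxa x samples (e.g. [profile_matrix]).
#' @return A [distance_matrix] over the samples (columns).
#' @export
bray_curtis_matrix <- function(profiles) {
  n <- ncol(profiles)
  d <- matrix(0, n, n, dimnames = list(colnames(profiles), colnames(profiles)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- bray_curtis(profiles[, i], profiles[, j])
    }
  }
  distance_matrix(d)
}

# ---- PCoA -------------------------------------------------------------------

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centres `-0.5 * D^2`, eigendecomposes, and scales eigenvectors by
#' the square root of their eigenvalues. Axes with non-positive (or
#' numerically zero) eigenvalues are dropped; negative eigenvalues are
#' reported. Axis orientation is fixed by making the largest-magnitude
#' coordinate on each axis positive.
#'
#' @param d A [distance_matrix].
#' @param n_axes Number of axes requested (<= n - 1). If more than the number
#'   of positive eigenvalues, fewer axes are returned with a message.
#' @return Object of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, descending), `proportion_explained` (over positive
#'   eigenvalues, for retained axes), `negative_eigenvalues`.
#' @export
pcoa <- function(d, n_axes = 2L) {
  stopifnot(inherits(d, "distance_matrix"))
  n <- nrow(d)
  if (n_axes > n - 1L) stop("pcoa: n_axes must be <= n_samples - 1", call. = FALSE)
  a <- -0.5 * unclass(d)^2
  centred <- a - rowMeans(a)
  centred <- t(t(centred) - colMeans(centred)) + mean(a)
  centred <- (centred + t(centred)) / 2
  eig <- eigen(centred, symmetric = TRUE)
  values <- eig$values
  tol <- max(abs(values)) * 1e-9
  positive <- values > tol
  k <- min(n_axes, sum(positive))
  if (k < n_axes) {
    message(sprintf("pcoa: only %d positive eigenvalue(s); returning %d axis/axes",
                    sum(positive), k))
  }
  coords <- matrix(0, n, k, dimnames = list(rownames(d), paste0("PCo", seq_len(k))))
  if (k > 0L) {
    for (j in seq_len(k)) {
      v <- eig$vectors[, j] * sqrt(values[j])
      if (v[which.max(abs(v))] < 0) v <- -v
      coords[, j] <- v
    }
  }
  pos_sum <- sum(values[positive])
  structure(list(coordinates = coords,
                 eigenvalues = values,
                 proportion_explained = if (k > 0L) values[seq_len(k)] / pos_sum
                                        else numeric(0L),
                 negative_eigenvalues = values[values < -tol]),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d sample(s), %d axis/axes retained\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  if (ncol(x$coordinates)) {
    cat("proportion explained:",
        paste(sprintf("%.3f", x$proportion_explained), collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- PERMANOVA --------------------------------------------------------------

# Sums of squares from squared dissimilarities (Anderson's formulation):
# SS_total = sum_{i<j} d_ij^2 / N; SS_within = sum over groups of the group's
# pairwise d^2 sum divided by its size; SS_between = SS_total - SS_within.
permanova_ss <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

permanova_f <- function(d2, groups, a, n) {
  ss <- permanova_ss(d2, groups)
  (ss[["between"]] / (a - 1)) / (ss[["within"]] / (n - a))
}

# All distinct arrangements of a label multiset (recursive enumeration).
multiset_permutations <- function(labels) {
  labels <- sort(labels)
  out <- list()
  recurse <- function(prefix, remaining) {
    if (!length(remaining)) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in unique(remaining)) {
      rest <- remaining[-match(v, remaining)]
      recurse(c(prefix, v), rest)
    }
  }
  recurse(character(0L), labels)
  out
}

#' One-way PERMANOVA on a distance matrix
#'
#' Partitions the sum of squared dissimilarities into between- and
#' within-group components, forms the pseudo-F statistic, and computes a
#' permutation p-value by shuffling group labels. When the number of distinct
#' label arrangements does not exceed `n_permutations`, the exact p-value is
#' computed by exhaustive enumeration (proportion of arrangements, including
#' the observed one, with pseudo-F at least as large); otherwise the Monte
#' Carlo p-value uses the +1 rule,
#' `p = (#\{permuted F >= observed F\} + 1) / (n_permutations + 1)`.
#'
#' @param d A [distance_matrix].
#' @param groups Label vector (>= 2 groups, no group equal to all samples).
#' @param n_permutations Number of random permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `permanova_result`: `pseudo_F`, `R2`, `p_value`,
#'   `n_permutations`, `exhaustive`, and the sums of squares.
#' @export
permanova <- function(d, groups, n_permutations = 999L, seed = 1L) {
  stopifnot(inherits(d, "distance_matrix"))
  groups <- as.character(groups)
  n <- nrow(d)
  if (length(groups) != n) stop("permanova: groups length must match samples",
                                call. = FALSE)
  a <- length(unique(groups))
  if (a < 2L) stop("permanova: need at least 2 groups", call. = FALSE)
  if (a == n) stop("permanova: every sample in its own group", call. = FALSE)
  if (n_permutations < 1L) stop("permanova: n_permutations must be >= 1",
                                call. = FALSE)
  d2 <- unclass(d)^2
  ss <- permanova_ss(d2, groups)
  f_obs <- (ss[["between"]] / (a - 1)) / (ss[["within"]] / (n - a))
  counts <- table(groups)
  log_distinct <- lgamma(n + 1) - sum(lgamma(counts + 1))
  exhaustive <- is.finite(log_distinct) &&
    log_distinct <= log(n_permutations + 1)
  tol <- if (is.finite(f_obs)) 1e-12 * max(1, abs(f_obs)) else 0
  if (exhaustive) {
    perms <- multiset_permutations(groups)
    f_all <- vapply(perms, function(g) permanova_f(d2, g, a, n), numeric(1L))
    p <- mean(f_all >= f_obs - tol)
    n_used <- length(perms)
  } else {
    exceed <- with_seed(seed, {
      sum(vapply(seq_len(n_permutations), function(i) {
        permanova_f(d2, sample(groups), a, n) >= f_obs - tol
      }, logical(1L)))
    })
    p <- (exceed + 1) / (n_permutations + 1)
    n_used <- n_permutations
  }
  structure(list(pseudo_F = unname(f_obs),
                 R2 = unname(ss[["between"]] / ss[["total"]]),
                 p_value = p, n_permutations = n_used,
                 exhaustive = exhaustive,
                 ss_total = unname(ss[["total"]]),
                 ss_between = unname(ss[["between"]]),
                 ss_within = unname(ss[["within"]])),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("<permanova_result> pseudo-F = %.4f, R2 = %.4f, p = %.4g (%s, %d permutations)\n",
              x$pseudo_F, x$R2, x$p_value,
              if (x$exhaustive) "exhaustive" else "Monte Carlo",
              x$n_permutations))
  invisible(x)
}

# ---- hierarchical clustering ------------------------------------------------

#' Agglomerative hierarchical clustering with deterministic tie-breaking
#'
#' Standard agglomerative clustering (complete, average or single linkage).
#' When several cluster pairs attain the minimal distance (within 1e-12), the
#' pair whose lexicographically smallest member id is smallest is merged
#' (then the other member id breaks remaining ties), so results are fully
#' deterministic. Returns an `hclust`-compatible object usable with
#' [stats::cophenetic] and plotting, plus [as_newick] for export.
#'
#' @param d A [distance_matrix] (>= 2 samples).
#' @param linkage `"complete"` (default), `"average"` or `"single"`.
#' @return Object of class `c("viabench_hclust", "hclust")`.
#' @export
hierarchical_cluster <- function(d, linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(d, "distance_matrix"))
  n <- nrow(d)
  if (n < 2L) stop("hierarchical_cluster: need at least 2 samples", call. = FALSE)
  labels <- rownames(d)
  dm <- unclass(d)

  # active clusters: id (hclust convention: -leaf or +merge index), members
  # (leaf indices), rep (lexicographically smallest member label), size
  active <- lapply(seq_len(n), function(i) {
    list(id = -i, members = i, rep = labels[i], size = 1L)
  })
  cd <- dm # distance between active clusters, indexed like `active`
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best <- NULL
    best_d <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        dij <- cd[i, j]
        if (dij < best_d - 1e-12) {
          best_d <- dij
          best <- c(i, j)
        } else if (abs(dij - best_d) <= 1e-12) {
          reps_new <- sort(c(active[[i]]$rep, active[[j]]$rep))
          reps_old <- sort(c(active[[best[1L]]]$rep, active[[best[2L]]]$rep))
          if (reps_new[1L] < reps_old[1L] ||
              (reps_new[1L] == reps_old[1L] && reps_new[2L] < reps_old[2L])) {
            best_d <- min(best_d, dij)
            best <- c(i, j)
          }
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- sort(c(active[[i]]$id, active[[j]]$id))
    height[step] <- best_d
    merged <- list(id = step,
                   members = c(active[[i]]$members, active[[j]]$members),
                   rep = min(active[[i]]$rep, active[[j]]$rep),
                   size = active[[i]]$size + active[[j]]$size)
    # linkage update against every other active cluster
    others <- setdiff(seq_len(k), c(i, j))
    new_row <- vapply(others, function(o) {
      switch(linkage,
             complete = max(cd[i, o], cd[j, o]),
             single = min(cd[i, o], cd[j, o]),
             average = (active[[i]]$size * cd[i, o] +
                          active[[j]]$size * cd[j, o]) / merged$size)
    }, numeric(1L))
    active <- c(active[others], list(merged))
    cd <- if (length(others)) {
      rbind(cbind(cd[others, others, drop = FALSE], new_row), c(new_row, 0))
    } else {
      matrix(0, 1L, 1L)
    }
  }

  # leaf order by traversal (left subtree first)
  order_of <- function(node) {
    if (node < 0L) return(-node)
    c(order_of(merge[node, 1L]), order_of(merge[node, 2L]))
  }
  structure(list(merge = merge, height = height,
                 order = order_of(n - 1L), labels = labels,
                 method = linkage,
                 call = match.call(), dist.method = "bray-curtis"),
            class = c("viabench_hclust", "hclust"))
}

#' Export a clustering as a Newick tree string
#'
#' Branch lengths are merge-height differences (leaves sit at height 0), so
#' the tree is ultrametric with leaf depth equal to the root merge height.
#'
#' @param tree Result of [hierarchical_cluster] (or any `hclust`).
#' @param digits Significant digits for branch lengths.
#' @return Newick string (terminated by `";"`).
#' @export
as_newick <- function(tree, digits = 10L) {
  stopifnot(inherits(tree, "hclust"))
  fmt <- function(x) format(x, digits = digits, scientific = FALSE, trim = TRUE)
  node_str <- function(node, parent_height) {
    if (node < 0L) {
      return(sprintf("%s:%s", tree$labels[-node], fmt(parent_height)))
    }
    h <- tree$height[node]
    sprintf("(%s,%s):%s",
            node_str(tree$merge[node, 1L], h),
            node_str(tree$merge[node, 2L], h),
            fmt(parent_height - h))
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  sprintf("(%s,%s);",
          node_str(tree$merge[root, 1L], h),
          node_str(tree$merge[root, 2L], h))
}

# ---- study-level wrapper ----------------------------------------------------

#' Beta-diversity analysis of a study
#'
#' Builds genus-level profiles for the selected samples across all tables,
#' computes the Bray-Curtis matrix, ordinates it (PCoA), runs one-way
#' PERMANOVA for two groupings — library type (DNA: shotgun/PMA-shotgun vs
#' RNA: metatranscriptomics/16S) and sequencing platform — and clusters the
#' samples.
#'
#' @param tables Named list of [count_table]s.
#' @param metadata Sample metadata.
#' @param include_controls If `FALSE` (default) only live/dead spiked samples
#'   enter the analysis.
#' @param n_permutations Permutations for each PERMANOVA.
#' @param seed Integer seed for the permutation streams.
#' @param linkage Linkage for [hierarchical_cluster].
#' @param map Harmonization map.
#' @return List: `profiles` (genus x sample matrix), `distances`, `pcoa`,
#'   `permanova` (named list `library_type`, `platform`), `clustering`,
#'   `newick`, `groups` (data.frame of the groupings used).
#' @export
diversity_analysis <- function(tables, metadata, include_controls = FALSE,
                               n_permutations = 999L, seed = 1L,
                               linkage = "complete",
                               map = default_harmonization_map()) {
  keep_conditions <- if (include_controls) .conditions else c("live", "dead")
  profs <- list()
  for (tab in tables) {
    genus_tab <- collapse_to_genus(suppressMessages(drop_unclassified(tab)), map)
    p <- profile_matrix(genus_tab)
    keep <- metadata$sample_id[metadata$condition %in% keep_conditions]
    p <- p[, colnames(p) %in% keep, drop = FALSE]
    if (ncol(p)) profs[[length(profs) + 1L]] <- p
  }
  genera <- sort(unique(unlist(lapply(profs, rownames))))
  mat <- matrix(0, length(genera), sum(vapply(profs, ncol, integer(1L))),
                dimnames = list(genera, unlist(lapply(profs, colnames))))
  for (p in profs) mat[rownames(p), colnames(p)] <- p
  idx <- match(colnames(mat), metadata$sample_id)
  groups <- data.frame(
    sample_id = colnames(mat),
    library_type = ifelse(metadata$method[idx] %in% c("shotgun", "pma_shotgun"),
                          "DNA", "RNA"),
    platform = metadata$platform[idx],
    stringsAsFactors = FALSE)
  d <- bray_curtis_matrix(mat)
  res_perm <- list(
    library_type = permanova(d, groups$library_type, n_permutations,
                             stream_seed(seed, "permanova", "library_type")),
    platform = permanova(d, groups$platform, n_permutations,
                         stream_seed(seed, "permanova", "platform")))
  tree <- hierarchical_cluster(d, linkage)
  list(profiles = mat, distances = d,
       pcoa = pcoa(d, n_axes = min(2L, ncol(mat) - 1L)),
       permanova = res_perm, clustering = tree, newick = as_newick(tree),
       groups = groups)
}
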