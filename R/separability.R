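#' Separability index between two pixel clusters
#'
#' The Euclidean distance between the cluster centroids divided by the root
#' sum of their per-dimension variances:
#' \eqn{S = \lVert \mu_i - \mu_j \rVert_2 /
#'  \sqrt{\sum_d (\sigma^2_{i,d} + \sigma^2_{j,d})}}.
#' Variances are unbiased sample variances; a singleton cluster contributes
#' zero variance (flagged by [separability_matrix()]). Zero pooled variance
#' with distinct means yields `Inf`.
#'
#' @param cluster_i,cluster_j Numeric matrices (pixels x features) or vectors
#'   (1-D feature space).
#' @return Dimensionless nonnegative index; larger is better resolved.
#' @examples
#' separability_index(rnorm(100), rnorm(100, 3)) # about 3 / sqrt(2)
#' @export
separability_index <- function(cluster_i, cluster_j) {
  xi <- as.matrix(cluster_i)
  xj <- as.matrix(cluster_j)
  if (ncol(xi) != ncol(xj)) {
    stop("clusters must share feature dimensionality.", call. = FALSE)
  }
  if (nrow(xi) == 0 || nrow(xj) == 0) {
    stop("clusters must be non-empty.", call. = FALSE)
  }
  mu_i <- colMeans(xi)
  mu_j <- colMeans(xj)
  var_i <- if (nrow(xi) > 1) apply(xi, 2, stats::var) else rep(0, ncol(xi))
  var_j <- if (nrow(xj) > 1) apply(xj, 2, stats::var) else rep(0, ncol(xj))
  num <- sqrt(sum((mu_i - mu_j)^2))
  den <- sqrt(sum(var_i + var_j))
  if (den == 0) {
    return(if (num == 0) 0 else Inf)
  }
  num / den
}

#' Pairwise separability of labeled pixel clusters
#'
#' Computes the full symmetric matrix of pairwise separability indices over
#' a labeled feature table, plus the worst-resolved (minimum-S) pair and the
#' average S. Because physical feature spaces mix units (nm, ns,
#' dimensionless), features are standardized per dimension by the pooled
#' within-cluster standard deviation by default; `standardize = "raw"` uses
#' the features as given (appropriate for PCA scores, which share units and
#' keep S invariant under the orthogonal PCA rotation).
#'
#' @param data Data frame with one row per pixel: a label column plus
#'   numeric feature columns.
#' @param label_col Name of the cluster-label column (default
#'   `"condition"`).
#' @param feature_cols Character vector of feature columns (default: all
#'   numeric columns except the label).
#' @param standardize `"pooled_z"` (default) or `"raw"`.
#' @return A `separability_report`: list with the S `matrix`, `worst_pair`
#'   (labels i, j and S), `mean_S`, `feature_space` (feature names),
#'   `standardize`, and `singleton` flags.
#' @export
separability_matrix <- function(data, label_col = "condition",
                                feature_cols = NULL,
                                standardize = c("pooled_z", "raw")) {
  standardize <- match.arg(standardize)
  stopifnot(label_col %in% names(data))
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                            label_col)
  }
  bad <- setdiff(feature_cols, names(data))
  if (length(bad)) {
    stop("unknown feature name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  labels <- as.character(data[[label_col]])
  x <- as.matrix(data[, feature_cols, drop = FALSE])
  ok <- stats::complete.cases(x)
  x <- x[ok, , drop = FALSE]
  labels <- labels[ok]
  levs <- unique(labels)
  if (length(levs) < 2) {
    return(structure(
      list(matrix = matrix(0, length(levs), length(levs),
                           dimnames = list(levs, levs)),
           worst_pair = NULL, mean_S = NA_real_,
           feature_space = feature_cols, standardize = standardize,
           singleton = character()),
      class = "separability_report"))
  }
  groups <- split.data.frame(x, labels)[levs]
  if (standardize == "pooled_z") {
    wvar <- Reduce(`+`, lapply(groups, function(g) {
      if (nrow(g) > 1) (nrow(g) - 1) * apply(g, 2, stats::var)
      else rep(0, ncol(g))
    }))
    dof <- sum(vapply(groups, nrow, integer(1))) - length(groups)
    psd <- sqrt(wvar / max(dof, 1))
    psd[psd == 0] <- 1
    groups <- lapply(groups, function(g) sweep(g, 2, psd, `/`))
  }
  singleton <- levs[vapply(groups, nrow, integer(1)) == 1]
  if (length(singleton)) {
    warning("singleton cluster(s) ", paste(singleton, collapse = ", "),
            ": their variance contribution is 0")
  }
  n <- length(levs)
  S <- matrix(0, n, n, dimnames = list(levs, levs))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    S[i, j] <- S[j, i] <- separability_index(groups[[i]], groups[[j]])
  }
  off <- S[upper.tri(S)]
  wmin <- which(S == min(off) & upper.tri(S), arr.ind = TRUE)[1, ]
  structure(
    list(matrix = S,
         worst_pair = list(i = levs[wmin[1]], j = levs[wmin[2]],
                           S = S[wmin[1], wmin[2]]),
         mean_S = mean(off),
         feature_space = feature_cols,
         standardize = standardize,
         singleton = singleton),
    class = "separability_report")
}

#' @export
print.separability_report <- function(x, ...) {
  cat(sprintf("<separability_report> space {%s}, %d clusters (%s)\n",
              paste(x$feature_space, collapse = ", "), nrow(x$matrix),
              x$standardize))
  if (!is.null(x$worst_pair)) {
    cat(sprintf("  worst pair: %s vs %s (S = %.3f) | mean S = %.3f\n",
                x$worst_pair$i, x$worst_pair$j, x$worst_pair$S, x$mean_S))
  }
  invisible(x)
}

#' Worst-resolved cluster pair of a report
#'
#' @param report A `separability_report`.
#' @return List with labels `i`, `j` and the minimum `S`.
#' @export
worst_pair <- function(report) {
  stopifnot(inherits(report, "separability_report"))
  report$worst_pair
}

#' Tidy a separability report into pairwise long form
#'
#' @param x A `separability_report`.
#' @param ... Unused.
#' @return Tibble with columns `cluster_i`, `cluster_j`, `S`, `resolved`
#'   (S >= `threshold`).
#' @param threshold Resolvability threshold (presentation only).
#' @export
tidy.separability_report <- function(x, threshold = 1, ...) {
  levs <- rownames(x$matrix)
  idx <- which(upper.tri(x$matrix), arr.ind = TRUE)
  tibble::tibble(cluster_i = levs[idx[, 1]],
                 cluster_j = levs[idx[, 2]],
                 S = x$matrix[idx],
                 resolved = x$matrix[idx] >= threshold)
}

#' One-row summary of a separability report
#' @param x A `separability_report`.
#' @param ... Unused.
#' @return One-row tibble with the space, cluster count, worst-pair S and
#'   mean S.
#' @export
glance.separability_report <- function(x, ...) {
  tibble::tibble(feature_space = paste(x$feature_space, collapse = "+"),
                 n_clusters = nrow(x$matrix),
                 worst_S = if (is.null(x$worst_pair)) NA_real_ else x$worst_pair$S,
                 mean_S = x$mean_S)
}

#' Build a labeled per-pixel feature table from a panel of stacks
#'
#' Evaluates the physical feature maps (spectral peak, mean lifetime,
#' steady-state anisotropy) and optionally PCA score maps for every stack in
#' a named list, returning one row per unmasked pixel: the input for
#' [separability_matrix()] and [dimensionality_sweep()].
#'
#' @param stacks Named list of `hdim_stack`s (names = condition labels).
#' @param model Optional `hdim_pca`; adds `PC1`, `PC2`, ... columns.
#' @param min_counts Masking threshold for all feature maps.
#' @return Tibble with columns `condition`, `row`, `col`, `peak`,
#'   `lifetime`, `anisotropy` (+ `PCk` columns if a model is given); only
#'   pixels unmasked in every feature are kept.
#' @export
build_feature_table <- function(stacks, model = NULL, min_counts = 100) {
  stopifnot(length(stacks) >= 1, !is.null(names(stacks)))
  purrr::imap(stacks, function(s, nm) {
    fmaps <- list(peak = spectral_peak_map(s, min_counts),
                  lifetime = mean_lifetime_map(s, min_counts),
                  anisotropy = anisotropy_map(s, min_counts))
    if (!is.null(model)) {
      pc <- pca_apply(model, s, min_counts)
      fmaps <- c(fmaps, pc)
    }
    d <- dim(s$counts)
    tb <- tibble::tibble(condition = nm,
                         row = rep(seq_len(d[1]), times = d[2]),
                         col = rep(seq_len(d[2]), each = d[1]))
    for (f in names(fmaps)) tb[[f]] <- as.vector(fmaps[[f]]$values)
    tb[stats::complete.cases(tb), ]
  }) |> dplyr::bind_rows()
}

#' Separability across feature spaces of increasing dimensionality
#'
#' Runs [separability_matrix()] over an ordered list of feature spaces —
#' e.g. `{peak}`, `{peak, lifetime}`, `{peak, lifetime, anisotropy}`,
#' `{PC1, PC2}` — and tabulates the worst-pair and mean separability per
#' space. This is the quantitative form of the claim that resolving power
#' grows with the dimensionality of the recorded signature. Deterministic
#' given its inputs.
#'
#' @param features Labeled per-pixel feature table from
#'   [build_feature_table()].
#' @param spaces Named list of character vectors of feature columns; the
#'   default sweeps the three physical spaces and, when PC columns are
#'   present, the first two- and three-component PCA spaces.
#' @param label_col Cluster-label column.
#' @param standardize_physical Standardization for non-PCA spaces
#'   (PCA-score spaces always run raw; scores share units).
#' @return Tibble with one row per space: `space`, `dimensionality`,
#'   `worst_pair_i`, `worst_pair_j`, `worst_S`, `mean_S`.
#' @export
dimensionality_sweep <- function(features, spaces = NULL,
                                 label_col = "condition",
                                 standardize_physical = "pooled_z") {
  if (is.null(spaces)) {
    spaces <- list(peak = "peak",
                   `peak+lifetime` = c("peak", "lifetime"),
                   `peak+lifetime+anisotropy` = c("peak", "lifetime",
                                                  "anisotropy"))
    if (all(c("PC1", "PC2") %in% names(features))) {
      spaces$pca2 <- c("PC1", "PC2")
    }
    if (all(c("PC1", "PC2", "PC3") %in% names(features))) {
      spaces$pca3 <- c("PC1", "PC2", "PC3")
    }
  }
  purrr::imap(spaces, function(cols, nm) {
    bad <- setdiff(cols, names(features))
    if (length(bad)) {
      stop("unknown feature name(s) in space '", nm, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    is_pca <- all(grepl("^PC[0-9]+$", cols))
    rep <- separability_matrix(
      features, label_col = label_col, feature_cols = cols,
      standardize = if (is_pca) "raw" else standardize_physical)
    tibble::tibble(space = nm,
                   dimensionality = length(cols),
                   worst_pair_i = rep$worst_pair$i %||% NA_character_,
                   worst_pair_j = rep$worst_pair$j %||% NA_character_,
                   worst_S = rep$worst_pair$S %||% NA_real_,
                   mean_S = rep$mean_S)
  }) |> dplyr::bind_rows()
}
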