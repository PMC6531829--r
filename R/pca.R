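#' Train a PCA model on pooled HDSS pixel ensembles
#'
#' Pools the pixels of one or more (spatially binned) stacks into a single
#' ensemble of flattened HDSS vectors, optionally normalized to unit total
#' count, and fits covariance PCA about the global ensemble mean. Training on
#' spatially binned pixels (default 4 x 4) keeps large data sets tractable;
#' the trained transform is then applied to full-resolution stacks with
#' [pca_apply()]. Because binned pixels hold about `bin_factor^2` times the
#' photons of raw pixels, the default `total_count` normalization divides
#' each pixel vector by its photon sum so the transform transfers across
#' count scales; `raw` mode uses count vectors as-is.
#'
#' Component signs are fixed by making each loading's largest-magnitude entry
#' positive, so training is fully deterministic. Training is invariant to the
#' order of the input stacks.
#'
#' @param stacks A single `hdim_stack` or list of stacks sharing geometry.
#' @param bin_factor Spatial binning applied before pooling (>= 1).
#' @param n_components Number of components kept (<= HDSS length).
#' @param normalization `"total_count"` (default) or `"raw"`.
#' @return An `hdim_pca` model: `mean_vector`, `loadings` (K x D, orthonormal
#'   rows), `explained_variance` (non-increasing), `normalization`,
#'   `training_provenance`.
#' @export
pca_train <- function(stacks, bin_factor = 4, n_components = 8,
                      normalization = c("total_count", "raw")) {
  normalization <- match.arg(normalization)
  if (inherits(stacks, "hdim_stack")) stacks <- list(stacks)
  stopifnot(length(stacks) >= 1, bin_factor >= 1)
  geo <- dim(stacks[[1]]$counts)[3:5]
  for (s in stacks) {
    if (!identical(dim(s$counts)[3:5], geo)) {
      stop("stacks must share spectroscopic geometry.", call. = FALSE)
    }
  }
  D <- prod(geo)
  if (n_components > D) {
    stop(sprintf("n_components (%d) exceeds the HDSS length (%d).",
                 n_components, D), call. = FALSE)
  }
  ens <- do.call(rbind, lapply(stacks, function(s) {
    hdss_matrix(spatial_bin(s, bin_factor), normalization)
  }))
  ens <- ens[stats::complete.cases(ens), , drop = FALSE]
  if (nrow(ens) < 2) stop("need at least 2 valid pixels to train.", call. = FALSE)
  fit <- stats::prcomp(ens, center = TRUE, scale. = FALSE,
                       rank. = n_components)
  load <- t(fit$rotation)                 # K x D
  # deterministic sign: largest-|entry| of each loading made positive
  sgn <- apply(load, 1, function(v) sign(v[which.max(abs(v))]))
  sgn[sgn == 0] <- 1
  load <- load * sgn
  ev <- fit$sdev^2                        # all rank-many eigenvalues
  structure(
    list(mean_vector = fit$center,
         loadings = load,
         explained_variance = ev[seq_len(nrow(load))],
         total_variance = sum(ev),
         normalization = normalization,
         training_provenance = list(
           n_stacks = length(stacks),
           n_pixels = nrow(ens),
           bin_factor = bin_factor,
           stack_provenance = lapply(stacks, function(s) s$provenance))),
    class = "hdim_pca")
}

#' @export
print.hdim_pca <- function(x, ...) {
  cat(sprintf("<hdim_pca> %d components over D = %d (%s normalization)\n",
              nrow(x$loadings), ncol(x$loadings), x$normalization))
  pct <- 100 * x$explained_variance / x$total_variance
  cat("  explained variance: ",
      paste(sprintf("%.1f%%", pct[seq_len(min(4, length(pct)))]),
            collapse = ", "),
      if (length(pct) > 4) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Tidy an `hdim_pca` model
#'
#' @param x An `hdim_pca`.
#' @param ... Unused.
#' @return Tibble with `component`, `explained_variance`,
#'   `prop_variance`, `cum_prop`.
#' @export
tidy.hdim_pca <- function(x, ...) {
  prop <- x$explained_variance / x$total_variance
  tibble::tibble(component = seq_along(x$explained_variance),
                 explained_variance = x$explained_variance,
                 prop_variance = prop,
                 cum_prop = cumsum(prop))
}

#' One-row summary of an `hdim_pca` model
#'
#' @param x An `hdim_pca`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.hdim_pca <- function(x, ...) {
  tibble::tibble(n_components = nrow(x$loadings),
                 hdss_length = ncol(x$loadings),
                 n_training_pixels = x$training_provenance$n_pixels,
                 bin_factor = x$training_provenance$bin_factor,
                 normalization = x$normalization,
                 total_variance = x$total_variance)
}

#' Apply a trained PCA model to a stack
#'
#' Per-pixel scores `loading_n . (vector(i, j) - mean_vector)` with the same
#' normalization as training; one score map per component. Pixels whose
#' vector is undefined (zero photons under `total_count` normalization) are
#' masked.
#'
#' @param model An `hdim_pca`.
#' @param stack An `hdim_stack` with matching spectroscopic geometry.
#' @param min_counts Masking threshold, photons per pixel.
#' @return List of `feature_map`s named `PC1`, `PC2`, ...
#' @export
pca_apply <- function(model, stack, min_counts = 1) {
  stopifnot(inherits(model, "hdim_pca"), inherits(stack, "hdim_stack"))
  D <- prod(dim(stack$counts)[3:5])
  if (D != ncol(model$loadings)) {
    stop(sprintf("stack HDSS length %d does not match model dimension %d.",
                 D, ncol(model$loadings)), call. = FALSE)
  }
  d <- dim(stack$counts)
  m <- hdss_matrix(stack, model$normalization)
  tot <- rowSums(hdss_matrix(stack, "raw"))
  scores <- sweep(m, 2, model$mean_vector) %*% t(model$loadings)
  mask <- matrix(tot >= pmax(min_counts, 1), d[1], d[2])
  purrr::map(seq_len(ncol(scores)), function(k) {
    v <- matrix(scores[, k], d[1], d[2])
    new_feature_map(v, paste0("PC", k), "score", mask)
  }) |> rlang::set_names(paste0("PC", seq_len(ncol(scores))))
}

#' Pooled per-condition PCA score distributions
#'
#' Applies a model across a named list of stacks (one per condition) and
#' returns every unmasked pixel's component scores in long form — the data
#' behind pooled component-distribution overlays.
#'
#' @param model An `hdim_pca`.
#' @param stacks Named list of `hdim_stack`s (names = condition labels).
#' @param components Integer vector of components to keep (default: all).
#' @param min_counts Masking threshold.
#' @return Tibble with columns `condition`, `component` (`"PC1"`, ...),
#'   `score`.
#' @export
pooled_component_distributions <- function(model, stacks,
                                           components = NULL,
                                           min_counts = 1) {
  stopifnot(length(stacks) >= 1, !is.null(names(stacks)))
  keep <- components %||% seq_len(nrow(model$loadings))
  purrr::imap(stacks, function(s, nm) {
    maps <- pca_apply(model, s, min_counts)
    purrr::map(keep, function(k) {
      tibble::tibble(condition = nm, component = paste0("PC", k),
                     score = map_values(maps[[k]]))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Serialize a PCA model to HDF5
#'
#' Stores mean, loadings, explained variance and provenance under a `/pca`
#' group (standalone file, or alongside a written stack container).
#'
#' @param model An `hdim_pca`.
#' @param path Output HDF5 path (created if absent).
#' @return `path`, invisibly.
#' @export
write_pca <- function(model, path) {
  if (!file.exists(path)) rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  if (!"pca" %in% rhdf5::h5ls(path)$name) rhdf5::h5createGroup(path, "pca")
  rhdf5::h5write(model$mean_vector, path, "pca/mean_vector")
  rhdf5::h5write(model$loadings, path, "pca/loadings")
  rhdf5::h5write(model$explained_variance, path, "pca/explained_variance")
  rhdf5::h5write(model$total_variance, path, "pca/total_variance")
  rhdf5::h5write(model$normalization, path, "pca/normalization")
  rhdf5::h5write(as.character(jsonlite::toJSON(model$training_provenance,
                                               auto_unbox = TRUE, digits = NA,
                                               null = "null")),
                 path, "pca/provenance")
  invisible(path)
}

#' Read a serialized PCA model
#'
#' @param path HDF5 file written by [write_pca()].
#' @return An `hdim_pca`.
#' @export
read_pca <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  required <- c("mean_vector", "loadings", "explained_variance",
                "total_variance", "normalization", "provenance")
  present <- rhdf5::h5ls(path)
  have <- present$name[present$group == "/pca"]
  missing <- setdiff(required, have)
  if (length(missing)) {
    stop("PCA container missing dataset(s): ",
         paste0("pca/", missing, collapse = ", "), call. = FALSE)
  }
  prov <- tryCatch(
    jsonlite::fromJSON(as.character(rhdf5::h5read(path, "pca/provenance"))),
    error = function(e) list())
  structure(
    list(mean_vector = as.numeric(rhdf5::h5read(path, "pca/mean_vector")),
         loadings = as.matrix(rhdf5::h5read(path, "pca/loadings")),
         explained_variance = as.numeric(rhdf5::h5read(path, "pca/explained_variance")),
         total_variance = as.numeric(rhdf5::h5read(path, "pca/total_variance")),
         normalization = as.character(rhdf5::h5read(path, "pca/normalization")),
         training_provenance = as.list(prov)),
    class = "hdim_pca")
}
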