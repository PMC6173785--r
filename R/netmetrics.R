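#' Names of the seven colony network metrics
#'
#' The metric registry used for latent-space analysis. Each metric is a
#' scalar summary of a labelled colony (differentiated yes/no per cell) and
#' its contact network, chosen to capture the extent, organization and
#' locale of differentiation:
#'
#' * `frac_diff` — differentiated fraction of the colony (extent).
#' * `n_diff_clusters` — number of connected components of the subnetwork
#'   induced by differentiated cells (organization).
#' * `largest_cluster_share` — size of the largest differentiated component
#'   divided by the number of differentiated cells (organization).
#' * `diff_neighbor_frac` — mean fraction of differentiated neighbors among
#'   differentiated cells (local clustering).
#' * `radial_locale` — mean centroid distance of differentiated cells
#'   divided by the mean centroid distance of all cells (edge vs center
#'   locale; > 1 peripheral, < 1 central).
#' * `degree_excess` — mean contact degree of differentiated cells minus the
#'   population mean degree (dense vs sparse locale).
#' * `assortativity_excess` — fraction of edges joining two differentiated
#'   cells minus its expectation under random label placement.
#'
#' All metrics are invariant to rigid motion of the coordinates and to cell
#' id permutation. Conditional metrics default to 0 (and `radial_locale` to
#' 1) when no cell is differentiated.
#'
#' @return character vector of the seven metric names.
#' @export
metric_names <- function() {
  c("frac_diff", "n_diff_clusters", "largest_cluster_share",
    "diff_neighbor_frac", "radial_locale", "degree_excess",
    "assortativity_excess")
}

#' Compute the seven network metrics of a labelled colony
#'
#' @param colony a `gj_colony` with at least two cells.
#' @param labels logical vector of differentiated labels; defaults to the
#'   colony's phenotype column (`"D"` = differentiated).
#' @return named numeric vector of the seven metrics (see [metric_names()]).
#' @examples
#' col <- structure_colony(hex_structure(6))
#' colony_metrics(col, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
#' @export
colony_metrics <- function(colony, labels = NULL) {
  stopifnot(inherits(colony, "gj_colony"))
  cells <- colony$cells
  n <- nrow(cells)
  if (n < 2) stop("metrics need a colony with at least 2 cells", call. = FALSE)
  if (is.null(labels)) labels <- cells$phenotype == "D"
  stopifnot(is.logical(labels), length(labels) == n)

  edges <- colony$edges
  ia <- match(edges[, 1], cells$id)
  ib <- match(edges[, 2], cells$id)
  deg <- tabulate(c(ia, ib), nbins = n)
  nd <- sum(labels)

  out <- c(frac_diff = nd / n, n_diff_clusters = 0,
           largest_cluster_share = 0, diff_neighbor_frac = 0,
           radial_locale = 1, degree_excess = 0, assortativity_excess = 0)
  if (nd == 0) return(out)

  # components of the differentiated-induced subnetwork
  didx <- which(labels)
  sub_e <- edges[labels[ia] & labels[ib], , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(sub_e[, 1]),
               to = as.character(sub_e[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(cells$id[didx])))
  comp <- igraph::components(g)
  out["n_diff_clusters"] <- comp$no
  out["largest_cluster_share"] <- max(comp$csize) / nd

  # mean differentiated-neighbor fraction among differentiated cells
  dn <- numeric(n)
  for (k in seq_along(ia)) {
    if (labels[ib[k]]) dn[ia[k]] <- dn[ia[k]] + 1
    if (labels[ia[k]]) dn[ib[k]] <- dn[ib[k]] + 1
  }
  has <- didx[deg[didx] > 0]
  out["diff_neighbor_frac"] <-
    if (length(has)) mean(dn[has] / deg[has]) else 0

  dc <- sqrt((cells$x - mean(cells$x))^2 + (cells$y - mean(cells$y))^2)
  out["radial_locale"] <- if (mean(dc) > 0) mean(dc[didx]) / mean(dc) else 1
  out["degree_excess"] <- mean(deg[didx]) - mean(deg)

  if (nrow(edges)) {
    obs <- mean(labels[ia] & labels[ib])
    expd <- nd / n * (nd - 1) / (n - 1)
    out["assortativity_excess"] <- obs - expd
  }
  out
}

#' Train the latent space on a metric table
#'
#' Mean-centers each metric, scales it to unit variance and performs
#' principal component analysis, keeping the full orthonormal loading
#' matrix and per-component explained-variance fractions. Each component is
#' oriented so that its largest-magnitude loading is positive, making axes
#' reproducible. Metadata columns (anything not in [metric_names()]) are
#' ignored.
#'
#' @param metrics a data frame or matrix containing the seven metric
#'   columns, one row per labelled colony (at least 8 rows).
#' @return an object of class `gj_latent`: list with `center`, `scale`,
#'   `loadings` (metrics x components), `sdev` and `explained_var`
#'   (fractions, non-increasing).
#' @export
train_pca <- function(metrics) {
  x <- as.data.frame(metrics)[, intersect(names(as.data.frame(metrics)),
                                          metric_names()), drop = FALSE]
  if (ncol(x) == 0) x <- as.data.frame(metrics)
  missing <- setdiff(metric_names(), names(x))
  if (length(missing)) {
    stop("metric table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(x[, metric_names()])
  if (nrow(x) < 8) stop("need at least 8 rows to train", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant metric column(s): ",
         paste(metric_names()[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  out <- list(center = pc$center, scale = pc$scale, loadings = rot,
              sdev = pc$sdev,
              explained_var = pc$sdev^2 / sum(pc$sdev^2))
  class(out) <- "gj_latent"
  out
}

#' @export
print.gj_latent <- function(x, ...) {
  ev <- round(100 * x$explained_var, 1)
  cat(sprintf("<gj_latent> %d metrics; explained variance: %s\n",
              nrow(x$loadings),
              paste0("PC", seq_along(ev), " ", ev, "%", collapse = ", ")))
  invisible(x)
}

#' Project metric vectors into the latent space
#'
#' Applies the stored centering, scaling and loadings of a trained latent
#' model to new metric vectors without refitting.
#'
#' @param model a `gj_latent` object from [train_pca()].
#' @param metrics a data frame/matrix with the seven metric columns, or a
#'   named numeric vector for a single colony.
#' @return matrix of latent coordinates (rows = colonies, columns = PCs).
#' @export
project_latent <- function(model, metrics) {
  stopifnot(inherits(model, "gj_latent"))
  if (is.null(dim(metrics))) metrics <- as.data.frame(as.list(metrics))
  x <- as.data.frame(metrics)
  missing <- setdiff(metric_names(), names(x))
  if (length(missing)) {
    stop("metric name mismatch; lacking: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(x[, metric_names()])
  scale(x, center = model$center, scale = model$scale) %*% model$loadings
}

#' Average latent-space trajectory
#'
#' Averages latent coordinates of repeated simulations (or experimental
#' colonies) at each time point, giving the mean path through the latent
#' space with per-time dispersion.
#'
#' @param scores matrix or data frame of latent coordinates.
#' @param time numeric vector of time points, one per row of `scores`.
#' @return a data frame with `time`, per-component means (`PC1`, ...) and
#'   standard deviations (`PC1_sd`, ...), ordered by time.
#' @export
latent_trajectory <- function(scores, time) {
  scores <- as.matrix(scores)
  if (length(time) != nrow(scores)) {
    stop("'time' must have one value per row of 'scores'", call. = FALSE)
  }
  if (anyNA(time)) stop("missing time values", call. = FALSE)
  if (nrow(scores) == 0) stop("empty trajectory group", call. = FALSE)
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  }
  mu <- aggregate(scores, by = list(time = time), FUN = mean)
  sdev <- aggregate(scores, by = list(time = time),
                    FUN = function(v) if (length(v) > 1) stats::sd(v) else 0)
  names(sdev)[-1] <- paste0(names(sdev)[-1], "_sd")
  out <- merge(mu, sdev, by = "time")
  out[order(out$time), , drop = FALSE]
}
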