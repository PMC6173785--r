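#' Pattern classes of the training set
#'
#' The eight canonical spatial arrangements of differentiated cells used to
#' train the latent space: `random` (uniform labelling), `outside_in`
#' (differentiation on the colony periphery), `inside_out` (in the colony
#' center), `snaked` (one connected meandering path through the contact
#' network), `half` (one side of a bisecting axis), `spotted` (several
#' seeded clusters grown by network adjacency), `ring` (an annular band) and
#' `gradient` (labelling probability increasing linearly along an axis).
#' Four of the class names are established for embryoid-body
#' differentiation; the remaining four complete the organization/locale
#' axes the latent components encode.
#'
#' @return character vector of the eight class names.
#' @export
pattern_classes <- function() {
  c("random", "outside_in", "inside_out", "snaked",
    "half", "spotted", "ring", "gradient")
}

#' Generate synthetic colony structures
#'
#' Grows irregular, connected, non-overlapping 2D disk packings that stand
#' in for digitized experimental colony geometries. Cells are added one at a
#' time by random peripheral attachment: a random parent and direction are
#' drawn, the candidate position one cell diameter from the parent is
#' accepted if it overlaps no existing cell, and among a handful of valid
#' candidates the one closest to the current centroid is kept so colonies
#' stay compact. Every new cell touches its parent, so the contact network
#' is connected by construction.
#'
#' @param n_structures number of structures to generate.
#' @param size_range integer range of cell counts; each structure's target
#'   size is drawn uniformly from it.
#' @param params a [gj_params()] object (cell radius).
#' @param n_candidates number of valid placements compared per added cell.
#' @return a list of data frames with columns `x`, `y`. Consumes RNG draws.
#' @examples
#' set.seed(1)
#' str <- make_structures(2, size_range = c(20, 30))
#' sapply(str, nrow)
#' @export
make_structures <- function(n_structures, size_range = c(100, 400),
                            params = gj_params(), n_candidates = 4L) {
  stopifnot(n_structures >= 1, length(size_range) == 2,
            size_range[1] >= 1, size_range[1] <= size_range[2])
  lapply(seq_len(n_structures), function(s) {
    n <- if (size_range[1] == size_range[2]) size_range[1] else
      sample(seq(size_range[1], size_range[2]), 1L)
    grow_structure(n, params, n_candidates)
  })
}

grow_structure <- function(n, params, n_candidates) {
  d <- 2 * params$radius          # touching distance
  x <- numeric(n); y <- numeric(n)
  x[1] <- 0; y[1] <- 0
  if (n == 1) return(data.frame(x = x, y = y))
  for (k in 2:n) {
    placed <- FALSE
    best <- NULL; best_d2 <- Inf
    cx <- mean(x[1:(k - 1)]); cy <- mean(y[1:(k - 1)])
    found <- 0L
    for (attempt in seq_len(60L * n_candidates)) {
      p <- sample.int(k - 1, 1L)
      a <- runif(1, 0, 2 * pi)
      nx <- x[p] + d * cos(a); ny <- y[p] + d * sin(a)
      dmin2 <- min((x[1:(k - 1)] - nx)^2 + (y[1:(k - 1)] - ny)^2)
      if (dmin2 >= (d - 1e-9)^2) {
        found <- found + 1L
        d2c <- (nx - cx)^2 + (ny - cy)^2
        if (d2c < best_d2) { best <- c(nx, ny); best_d2 <- d2c }
        if (found >= n_candidates) break
      }
    }
    if (is.null(best)) {
      stop(sprintf("could not place cell %d of %d: structure growth infeasible",
                   k, n), call. = FALSE)
    }
    x[k] <- best[1]; y[k] <- best[2]
    placed <- TRUE
  }
  data.frame(x = x, y = y)
}

#' Label a structure with a pattern class
#'
#' Assigns per-cell differentiation labels realising one of the eight
#' pattern-class geometries at approximately the requested differentiated
#' fraction (before neighbor smoothing).
#'
#' @param structure a data frame with `x`, `y` columns, or a `gj_colony`.
#' @param class_name one of [pattern_classes()].
#' @param frac target differentiated fraction in \[0, 1\].
#' @param params a [gj_params()] object (contact geometry for the
#'   network-based classes).
#' @param structure_id integer identifier stored with the labelling.
#' @return an object of class `gj_labeling`: list with `class_name`,
#'   `labels` (logical per cell), `structure_id`. Classes with a random
#'   component consume RNG draws.
#' @export
label_pattern <- function(structure, class_name, frac,
                          params = gj_params(), structure_id = NA_integer_) {
  if (!class_name %in% pattern_classes()) {
    stop("unknown pattern class: ", class_name, call. = FALSE)
  }
  stopifnot(frac >= 0, frac <= 1)
  xy <- if (inherits(structure, "gj_colony")) {
    structure$cells[, c("x", "y")]
  } else {
    as.data.frame(structure)[, c("x", "y")]
  }
  n <- nrow(xy)
  m <- round(frac * n)
  labels <- logical(n)
  if (m > 0) {
    dc <- sqrt((xy$x - mean(xy$x))^2 + (xy$y - mean(xy$y))^2)
    labels <- switch(
      class_name,
      random = seq_len(n) %in% sample.int(n, m),
      outside_in = rank(-dc, ties.method = "first") <= m,
      inside_out = rank(dc, ties.method = "first") <= m,
      snaked = grow_on_network(xy, params, m, n_seeds = 1L),
      half = {
        a <- runif(1, 0, 2 * pi)
        proj <- xy$x * cos(a) + xy$y * sin(a)
        rank(-proj, ties.method = "first") <= m
      },
      spotted = grow_on_network(xy, params, m,
                                n_seeds = max(2L, round(m / 15))),
      ring = {
        target <- 0.6 * max(dc)
        rank(abs(dc - target), ties.method = "first") <= m
      },
      gradient = {
        a <- runif(1, 0, 2 * pi)
        w <- rank(xy$x * cos(a) + xy$y * sin(a), ties.method = "first")
        seq_len(n) %in% sample.int(n, m, prob = w)
      }
    )
  }
  out <- list(class_name = class_name, labels = labels,
              structure_id = structure_id)
  class(out) <- "gj_labeling"
  out
}

# grow labelled clusters from random seeds by contact-network adjacency;
# with one seed this yields a single connected meandering path
grow_on_network <- function(xy, params, m, n_seeds = 1L) {
  n <- nrow(xy)
  nbr <- neighbor_list(xy, params)
  labels <- logical(n)
  n_seeds <- min(n_seeds, m)
  frontier_of <- function() {
    cand <- unique(unlist(nbr[labels], use.names = FALSE))
    cand[!labels[cand]]
  }
  seeds <- sample.int(n, n_seeds)
  labels[seeds] <- TRUE
  current <- seeds[length(seeds)]
  while (sum(labels) < m) {
    nxt <- nbr[[current]]
    nxt <- nxt[!labels[nxt]]
    if (!length(nxt)) nxt <- frontier_of()
    if (!length(nxt)) {
      # contact network exhausted (disconnected structure): fall back to the
      # unlabelled cell nearest to the labelled set
      un <- which(!labels)
      dmin <- vapply(un, function(i) {
        min((xy$x[labels] - xy$x[i])^2 + (xy$y[labels] - xy$y[i])^2)
      }, numeric(1))
      nxt <- un[which.min(dmin)]
    }
    current <- if (length(nxt) == 1L) nxt else nxt[sample.int(length(nxt), 1L)]
    labels[current] <- TRUE
  }
  labels
}

neighbor_list <- function(xy, params) {
  thr <- 2 * params$radius + params$contact_gap
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  apply(d <= thr, 1, which, simplify = FALSE)
}

#' Neighbor smoothing of training labels
#'
#' One synchronous pass of the neighbor rule used when generating training
#' patterns: a cell is additionally classified as differentiated when its
#' fraction of differentiated neighbors exceeds the population-mean fraction
#' of differentiated neighbors. Existing differentiated labels are kept and
#' isolated cells (degree zero) keep their label, so the all-differentiated
#' and all-undifferentiated labelings are fixed points.
#'
#' @param structure a data frame with `x`, `y`, or a `gj_colony`.
#' @param labels logical vector of differentiated labels.
#' @param params a [gj_params()] object.
#' @return smoothed logical labels.
#' @export
smooth_labels <- function(structure, labels, params = gj_params()) {
  xy <- if (inherits(structure, "gj_colony")) {
    structure$cells[, c("x", "y")]
  } else {
    as.data.frame(structure)[, c("x", "y")]
  }
  stopifnot(length(labels) == nrow(xy))
  nbr <- neighbor_list(xy, params)
  deg <- lengths(nbr)
  frac <- rep(NA_real_, length(labels))
  has <- deg > 0
  frac[has] <- vapply(which(has), function(i) mean(labels[nbr[[i]]]),
                      numeric(1))
  if (!any(has)) return(labels)
  unname(labels | (has & frac > mean(frac[has])))
}

#' Build the pattern-class training set
#'
#' Generates `n_structures` synthetic colony structures and labels each with
#' all eight pattern classes, giving `8 * n_structures` labelings (960 at
#' defaults). The target differentiated fraction cycles through `fractions`
#' across structures (so each class spans the full range of differentiation
#' extents, which is what the first latent component separates), and the
#' neighbor-smoothing rule is applied to every labelling. The seven network
#' metrics are computed for each labelled structure.
#'
#' @param n_structures number of colony structures (default 120).
#' @param classes pattern classes to include (default all eight).
#' @param fractions differentiated-fraction schedule cycled across
#'   structures.
#' @param size_range structure sizes, passed to [make_structures()].
#' @param params a [gj_params()] object.
#' @param seed integer seed for the whole training-set build.
#' @return a list of class `gj_training`: `metrics` (data frame with one row
#'   per labelling: metadata columns `class_name`, `structure_id`, `frac`
#'   plus the seven metric columns), `structures`, and `labelings`.
#' @export
make_training_set <- function(n_structures = 120,
                              classes = pattern_classes(),
                              fractions = c(0.1, 0.3, 0.5, 0.7, 0.9),
                              size_range = c(100, 400),
                              params = gj_params(), seed = 1L) {
  stopifnot(all(classes %in% pattern_classes()))
  set.seed(as.integer(seed))
  structures <- make_structures(n_structures, size_range, params)
  colonies <- lapply(structures, structure_colony, params = params)
  labelings <- list()
  rows <- list()
  k <- 0L
  for (cl in classes) {
    for (s in seq_len(n_structures)) {
      frac <- fractions[(s - 1L) %% length(fractions) + 1L]
      lab <- label_pattern(structures[[s]], cl, frac, params,
                           structure_id = s)
      lab$labels <- smooth_labels(structures[[s]], lab$labels, params)
      k <- k + 1L
      labelings[[k]] <- lab
      mv <- colony_metrics(colonies[[s]], lab$labels)
      rows[[k]] <- data.frame(class_name = cl, structure_id = s, frac = frac,
                              t(mv))
    }
  }
  out <- list(metrics = do.call(rbind, rows),
              structures = structures, labelings = labelings)
  class(out) <- "gj_training"
  out
}

#' Wrap a bare structure as an undifferentiated colony
#'
#' Builds a `gj_colony` (all cells pluripotent, zero concentration and
#' counters) from a plain `x`/`y` structure, so the contact network and
#' metrics can be computed without initializing a simulation state.
#'
#' @param structure a data frame with `x`, `y` columns.
#' @param params a [gj_params()] object.
#' @return a `gj_colony`.
#' @export
structure_colony <- function(structure, params = gj_params()) {
  n <- nrow(structure)
  cells <- data.frame(id = seq_len(n) - 1L, x = structure$x, y = structure$y,
                      radius = params$radius, phenotype = "P",
                      t_div = 0, conc = 0, tc = 0, stringsAsFactors = FALSE)
  new_colony(cells, time = 0, params = params)
}
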