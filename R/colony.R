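#' Colony objects
#'
#' A colony is a set of rigid-disk cellular agents restricted to a 2D plane,
#' together with its gap-junction contact network. Cells are stored as a
#' data frame with columns `id` (unique integer, 0-based in files), `x`, `y`
#' (µm), `radius` (µm), `phenotype` (`"P"` pluripotent / `"D"`
#' differentiated), `t_div` (hours since last division), `conc`
#' (intracellular concentration, arbitrary units) and `tc` (threshold
#' count). Edges are an integer matrix of unordered id pairs; two cells are
#' connected when their membranes are within the contact gap, i.e. center
#' distance <= 2 * radius + gap (15 µm at defaults).
#'
#' @param cells a cell data frame as described above.
#' @param time simulation time in hours.
#' @param params a [gj_params()] object supplying the contact geometry.
#' @return an object of class `gj_colony`.
#' @export
new_colony <- function(cells, time = 0, params = gj_params()) {
  cells <- validate_cells(cells)
  structure(list(cells = cells,
                 edges = build_network(cells, params),
                 time = time),
            class = "gj_colony")
}

validate_cells <- function(cells) {
  req <- c("id", "x", "y", "radius", "phenotype", "t_div", "conc", "tc")
  missing <- setdiff(req, names(cells))
  if (length(missing)) {
    stop("cell table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cells$id)) {
    stop("duplicate cell ids: ",
         paste(unique(cells$id[duplicated(cells$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(cells$x)) || any(!is.finite(cells$y))) {
    stop("non-finite cell coordinates", call. = FALSE)
  }
  check_phenotype(cells$phenotype)
  stopifnot(all(cells$radius > 0), all(cells$conc >= 0), all(cells$tc >= 0),
            all(cells$t_div >= 0))
  cells[order(cells$id), , drop = FALSE]
}

#' @export
print.gj_colony <- function(x, ...) {
  n <- nrow(x$cells)
  nd <- sum(x$cells$phenotype == "D")
  cat(sprintf("<gj_colony> %d cells (%d differentiated), %d edges, t = %g h\n",
              n, nd, nrow(x$edges), x$time))
  invisible(x)
}

#' Build the gap-junction contact network
#'
#' Connects every pair of cells whose center distance is at most
#' `2 * radius + contact_gap` (membranes within the gap distance). The edge
#' set is returned as an integer matrix of id pairs with `id_a < id_b`; it is
#' symmetric by construction and contains no self-edges.
#'
#' @param cells a cell data frame (or a `gj_colony`).
#' @param params a [gj_params()] object (radius and contact gap).
#' @return integer matrix with columns `id_a`, `id_b`.
#' @examples
#' cells <- data.frame(id = 0:1, x = c(0, 14), y = 0, radius = 6.5,
#'                     phenotype = "P", t_div = 0, conc = 0.6, tc = 0)
#' build_network(cells)  # one edge: 14 <= 15
#' @export
build_network <- function(cells, params = gj_params()) {
  if (inherits(cells, "gj_colony")) cells <- cells$cells
  if (anyDuplicated(cells$id)) stop("duplicate cell ids", call. = FALSE)
  n <- nrow(cells)
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("id_a", "id_b")))
  if (n < 2) return(empty)
  thr <- 2 * params$radius + params$contact_gap
  d <- as.matrix(stats::dist(cbind(cells$x, cells$y)))
  hit <- which(upper.tri(d) & d <= thr, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  a <- cells$id[hit[, 1]]
  b <- cells$id[hit[, 2]]
  swap <- a > b
  edges <- cbind(id_a = ifelse(swap, b, a), id_b = ifelse(swap, a, b))
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# overlap matrix oracle-style helper: maximum pairwise overlap in µm
max_overlap <- function(cells) {
  n <- nrow(cells)
  if (n < 2) return(0)
  d <- as.matrix(stats::dist(cbind(cells$x, cells$y)))
  sumr <- outer(cells$radius, cells$radius, `+`)
  max(0, max((sumr - d)[upper.tri(d)]))
}

#' Resolve cell-cell overlaps
#'
#' Iteratively displaces overlapping pairs of rigid disks along their center
#' line until the maximum pairwise overlap is at most `params$overlap_tol`.
#' When a pair is separated, the cell farther from the colony centroid takes
#' the larger displacement share, so that colonies grow outward
#' asymmetrically; on radially symmetric inputs the rule introduces no
#' centroid bias. Non-overlapping cells are not moved.
#'
#' @param colony a `gj_colony` object (its network is rebuilt afterwards).
#' @param params a [gj_params()] object.
#' @return the colony with updated positions and rebuilt network.
#' @export
resolve_overlaps <- function(colony, params = gj_params()) {
  stopifnot(inherits(colony, "gj_colony"))
  cells <- colony$cells
  if (nrow(cells) >= 2) {
    res <- relax_cpp(cells$x, cells$y, cells$radius,
                     params$overlap_tol, params$max_relax_iter)
    if (!res$converged) {
      stop(sprintf(
        "overlap resolution did not converge after %d iterations (max overlap %.3g um > tolerance %.3g um)",
        params$max_relax_iter, res$max_overlap, params$overlap_tol),
        call. = FALSE)
    }
    cells$x <- res$x
    cells$y <- res$y
    colony$cells <- cells
  }
  colony$edges <- build_network(cells, params)
  colony
}

#' Divide a single cell
#'
#' Splits a mother cell whose division clock has reached its cell-cycle
#' length into two daughters placed at the mother's position plus and minus
#' one radius along a uniformly random direction. Both daughters have
#' `t_div = 0` and inherit the mother's phenotype, concentration and
#' threshold count (concentration is intensive; molecule counts are not
#' modelled). The caller is responsible for resolving any overlaps with
#' other cells afterwards.
#'
#' @param cell a one-row cell data frame.
#' @param params a [gj_params()] object.
#' @param new_id id to assign to the second daughter (the first keeps the
#'   mother's id).
#' @return a two-row cell data frame. Consumes one uniform RNG draw.
#' @export
divide_cell <- function(cell, params = gj_params(), new_id = cell$id + 1L) {
  stopifnot(nrow(cell) == 1L)
  check_phenotype(cell$phenotype)
  ccl <- ptype_param(params, "ccl", cell$phenotype)
  if (cell$t_div < ccl) {
    stop(sprintf("cell %d cannot divide: t_div = %g h < CCL = %g h",
                 cell$id, cell$t_div, ccl), call. = FALSE)
  }
  theta <- runif(1, 0, 2 * pi)
  dx <- cell$radius * cos(theta)
  dy <- cell$radius * sin(theta)
  d1 <- d2 <- cell
  d1$x <- cell$x + dx; d1$y <- cell$y + dy
  d2$x <- cell$x - dx; d2$y <- cell$y - dy
  d2$id <- as.integer(new_id)
  d1$t_div <- 0; d2$t_div <- 0
  rbind(d1, d2)
}

# divide every cell with t_div >= CCL(phenotype), in ascending id order
# (fixed RNG traversal); returns the colony with daughters appended and
# overlaps unresolved.
divide_due_cells <- function(colony, params) {
  cells <- colony$cells
  ccl <- ptype_param(params, "ccl", cells$phenotype)
  due <- which(cells$t_div >= ccl)
  if (!length(due)) return(colony)
  due <- due[order(cells$id[due])]
  next_id <- max(cells$id) + 1L
  keep <- cells[-due, , drop = FALSE]
  born <- vector("list", length(due))
  for (k in seq_along(due)) {
    born[[k]] <- divide_cell(cells[due[k], , drop = FALSE], params,
                             new_id = next_id)
    next_id <- next_id + 1L
  }
  cells <- rbind(keep, do.call(rbind, born))
  colony$cells <- cells[order(cells$id), , drop = FALSE]
  rownames(colony$cells) <- NULL
  colony
}

#' Initialise a colony from a structure
#'
#' Creates a fully pluripotent colony on a given set of non-overlapping
#' positions: intracellular concentrations are drawn uniformly from the
#' configured initial range (0.6-0.65 at defaults), division clocks uniformly
#' from 0-18 h (or set to a common value for cell-cycle-synchronized runs),
#' threshold counts start at zero and the contact network is built.
#'
#' @param structure a data frame or matrix with columns/cols `x`, `y` (µm).
#' @param params a [gj_params()] object.
#' @param t_div `NULL` to draw division clocks uniformly from
#'   `params$tdiv_init`, or a numeric scalar/vector of clock values
#'   (synchronized initialisation).
#' @return a `gj_colony` at time 0. Consumes RNG draws.
#' @examples
#' set.seed(1)
#' col <- init_colony(data.frame(x = c(0, 14, 28), y = 0))
#' col
#' @export
init_colony <- function(structure, params = gj_params(), t_div = NULL) {
  structure <- as.data.frame(structure)
  if (!all(c("x", "y") %in% names(structure))) {
    if (ncol(structure) >= 2) names(structure)[1:2] <- c("x", "y")
    else stop("structure must provide x and y coordinates", call. = FALSE)
  }
  n <- nrow(structure)
  if (n == 0) stop("empty structure: at least one cell position is required",
                   call. = FALSE)
  conc <- runif(n, params$conc_init[1], params$conc_init[2])
  td <- if (is.null(t_div)) {
    runif(n, params$tdiv_init[1], params$tdiv_init[2])
  } else {
    rep_len(t_div, n)
  }
  cells <- data.frame(
    id = seq_len(n) - 1L,
    x = structure$x, y = structure$y,
    radius = params$radius,
    phenotype = "P",
    t_div = td,
    conc = conc,
    tc = 0,
    stringsAsFactors = FALSE
  )
  if (max_overlap(cells) > params$overlap_tol) {
    stop("initial structure contains overlapping cells", call. = FALSE)
  }
  new_colony(cells, time = 0, params = params)
}
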