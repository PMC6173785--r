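# atomic write: write to a temp file in the target directory, then rename
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path, call. = FALSE)
  invisible(path)
}

#' Write a colony snapshot to CSV
#'
#' Columns `id,x_um,y_um,radius_um,phenotype,conc,t_div,tC` with 0-based
#' ids and phenotype coded `P`/`D`. The write is atomic (temp file plus
#' rename).
#'
#' @param colony a `gj_colony`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_colony_csv <- function(colony, path) {
  stopifnot(inherits(colony, "gj_colony"))
  df <- data.frame(id = colony$cells$id,
                   x_um = colony$cells$x, y_um = colony$cells$y,
                   radius_um = colony$cells$radius,
                   phenotype = colony$cells$phenotype,
                   conc = colony$cells$conc,
                   t_div = colony$cells$t_div,
                   tC = colony$cells$tc)
  write_atomic(function(p) utils::write.csv(df, p, row.names = FALSE), path)
}

#' Read a colony snapshot from CSV
#'
#' Requires columns `id`, `x_um`, `y_um`; `radius_um`, `phenotype`, `conc`,
#' `t_div` and `tC` are optional and default to the model values (radius
#' 6.5 µm, pluripotent, 0, 0, 0). An `oct4_pos` column (0/1), as exported by
#' image segmentation, is mapped to phenotype when no phenotype column is
#' present (Oct4-positive = pluripotent). The contact network is built on
#' load.
#'
#' @param path CSV file path.
#' @param params a [gj_params()] object (contact geometry and defaults).
#' @return a `gj_colony`.
#' @export
read_colony_csv <- function(path, params = gj_params()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "x_um", "y_um")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop(basename(path), " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop(basename(path), ": duplicate id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(df$x_um)) || any(!is.finite(df$y_um))) {
    bad <- df$id[!is.finite(df$x_um) | !is.finite(df$y_um)]
    stop(basename(path), ": non-finite coordinates for id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  phenotype <- if ("phenotype" %in% names(df)) {
    as.character(df$phenotype)
  } else if ("oct4_pos" %in% names(df)) {
    ifelse(df$oct4_pos > 0, "P", "D")
  } else rep("P", nrow(df))
  cells <- data.frame(
    id = as.integer(df$id), x = df$x_um, y = df$y_um,
    radius = if ("radius_um" %in% names(df)) df$radius_um else params$radius,
    phenotype = phenotype,
    t_div = if ("t_div" %in% names(df)) df$t_div else 0,
    conc = if ("conc" %in% names(df)) df$conc else 0,
    tc = if ("tC" %in% names(df)) df$tC else 0,
    stringsAsFactors = FALSE
  )
  new_colony(cells, time = 0, params = params)
}

#' Export the contact network
#'
#' Writes the colony's edge list either as a two-column CSV (`id_a,id_b`)
#' or as GraphML.
#'
#' @param colony a `gj_colony`.
#' @param path output path.
#' @param format `"csv"` or `"graphml"`.
#' @return the path, invisibly.
#' @export
write_network <- function(colony, path, format = c("csv", "graphml")) {
  stopifnot(inherits(colony, "gj_colony"))
  format <- match.arg(format)
  if (format == "csv") {
    df <- as.data.frame(colony$edges)
    write_atomic(function(p) utils::write.csv(df, p, row.names = FALSE), path)
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(colony$edges[, 1]),
                 to = as.character(colony$edges[, 2])),
      directed = FALSE,
      vertices = data.frame(name = as.character(colony$cells$id),
                            x = colony$cells$x, y = colony$cells$y,
                            phenotype = colony$cells$phenotype))
    write_atomic(function(p) igraph::write_graph(g, p, format = "graphml"),
                 path)
  }
}

#' Read a simulation configuration file
#'
#' Reads a YAML or JSON file (by extension) of [gj_params()] argument
#' overrides and returns the resulting parameter object. Recognized keys
#' are exactly the `gj_params()` arguments (e.g. `pm_max`, `eq2_sign`,
#' `sq_vp_scale`, `bga_pm_scale`, `substeps_per_hour`); an `rng_seed` key
#' is returned as an attribute rather than a parameter.
#'
#' @param path configuration file path.
#' @return a `gj_params` object, with attribute `rng_seed` when the file
#'   provides one.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, call. = FALSE))
  if (is.null(cfg)) cfg <- list()
  seed <- cfg$rng_seed
  cfg$rng_seed <- NULL
  unknown <- setdiff(names(cfg), names(formals(gj_params)))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  params <- do.call(gj_params, cfg)
  if (!is.null(seed)) attr(params, "rng_seed") <- as.integer(seed)
  params
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the full parameter set,
#' seed, package version, md5 hashes of the input files and the list of
#' outputs. Written atomically as JSON.
#'
#' @param path output JSON path.
#' @param params a [gj_params()] object.
#' @param seed integer seed of the run.
#' @param inputs character vector of input file paths (hashed).
#' @param outputs character vector of output file paths.
#' @return the path, invisibly.
#' @export
write_manifest <- function(path, params, seed, inputs = character(),
                           outputs = character()) {
  manifest <- list(
    package = "gjcolony",
    version = as.character(utils::packageVersion("gjcolony")),
    seed = as.integer(seed),
    params = unclass(params),
    inputs = if (length(inputs)) {
      data.frame(path = inputs, md5 = unname(tools::md5sum(inputs)))
    } else list(),
    outputs = outputs
  )
  write_atomic(function(p) {
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }, path)
}

#' Serialize a trained latent model to JSON
#'
#' @param model a `gj_latent` object.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_latent_json <- function(model, path) {
  stopifnot(inherits(model, "gj_latent"))
  obj <- list(metric_names = rownames(model$loadings),
              center = unname(model$center),
              scale = unname(model$scale),
              loadings = unname(model$loadings),  # rows = metrics
              sdev = model$sdev,
              explained_var = model$explained_var)
  write_atomic(function(p) {
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, path)
}

#' Read a latent model from JSON
#'
#' @param path JSON path written by [write_latent_json()].
#' @return a `gj_latent` object.
#' @export
read_latent_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- obj$metric_names
  loadings <- as.matrix(obj$loadings)
  dimnames(loadings) <- list(nm, paste0("PC", seq_len(ncol(loadings))))
  out <- list(center = stats::setNames(obj$center, nm),
              scale = stats::setNames(obj$scale, nm),
              loadings = loadings,
              sdev = obj$sdev,
              explained_var = obj$explained_var)
  class(out) <- "gj_latent"
  out
}
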