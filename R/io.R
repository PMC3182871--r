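#' Read a simulation configuration document
#'
#' JSON (or YAML, when the yaml package is available) document with any
#' subset of the \code{\link{sim_config}} fields; missing fields take the
#' package defaults (reference time constants, initial conditions, noise
#' level).  Unknown fields raise an error naming the field.
#'
#' @param path file path (".json", ".yml"/".yaml").
#' @return a fully resolved \code{sim_config}.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  doc <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("read_config: YAML support needs the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  allowed <- c("word", "s", "dt", "duration", "seed", "ic", "record",
               "record_stride", "noise", "xi_min", "sequence")
  bad <- setdiff(names(doc), allowed)
  if (length(bad))
    stop("read_config: unknown field(s): ", paste(bad, collapse = ", "))
  if (!is.null(doc$sequence)) {
    sq <- doc$sequence
    doc$word <- sequence_spec(sq$ids, sq$k_inh,
                              k_exc = sq$k_exc %||%
                                c(rep(120, length(sq$ids) - 1), 4),
                              primacy = sq$primacy %||%
                                seq(1, by = 0.5,
                                    length.out = length(sq$ids)),
                              label = sq$label %||% "custom")
    doc$sequence <- NULL
  }
  doc$ic <- as.list(doc$ic)
  doc$noise <- utils::modifyList(
    list(u = TRUE, xi = TRUE, nu = TRUE, lam = TRUE, kick = TRUE),
    as.list(doc$noise))
  do.call(sim_config, doc)
}

#' Write a simulation configuration document
#'
#' @param cfg a \code{sim_config}.
#' @param path output path (JSON).
#' @return the path, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  doc <- list(word = cfg$seq$label, s = cfg$s, dt = cfg$dt,
              duration = cfg$duration, seed = cfg$seed,
              ic = cfg$ic[!vapply(cfg$ic, is.null, TRUE)],
              record = cfg$record, record_stride = cfg$record_stride,
              noise = cfg$noise, xi_min = cfg$xi_min)
  if (is.null(doc$word)) {
    doc$word <- NULL
    doc$sequence <- list(ids = cfg$seq$ids, k_inh = cfg$seq$k_inh,
                         k_exc = cfg$seq$k_exc, primacy = cfg$seq$primacy)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write / read a trajectory table
#'
#' Tab-separated with a header, '.' decimal, Unix newlines, full double
#' precision; the column order is the recording order (time, position,
#' realized derivatives, weights, kick signals, serial states).
#'
#' @param traj an \code{sfm_trajectory} (or its data matrix).
#' @param path file path.
#' @return \code{read_trajectory} returns the data matrix.
#' @export
write_trajectory <- function(traj, path) {
  d <- if (inherits(traj, "sfm_trajectory")) traj$data else traj
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(d), collapse = "\t"), con, sep = "\n")
  if (nrow(d))
    utils::write.table(format(d, digits = 17, trim = TRUE, scientific = TRUE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  as.matrix(utils::read.delim(path, check.names = FALSE))
}

#' Write an event log as TSV tables
#'
#' @param ev an event log (list with \code{activations}, \code{kicks},
#'   \code{completions}).
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_event_log <- function(ev, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(ev$activations, file.path(dir, "activations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ev$kicks, file.path(dir, "kicks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(time = ev$completions),
                     file.path(dir, "completions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Render the written trace as an SVG polyline
#'
#' The workspace trace (x, y) of a trajectory as a minimal standalone SVG
#' document (one polyline, y axis flipped to screen coordinates).
#'
#' @param traj an \code{sfm_trajectory}.
#' @param path output path (".svg").
#' @param stroke stroke colour.
#' @param scale pixels per workspace unit.
#' @return the path, invisibly.
#' @export
render_svg <- function(traj, path, stroke = "#1b3b6f", scale = 40) {
  d <- if (inherits(traj, "sfm_trajectory")) traj$data else traj
  x <- d[, "x"]; y <- d[, "y"]
  pad <- 0.5
  w <- (diff(range(x)) + 2 * pad) * scale
  h <- (diff(range(y)) + 2 * pad) * scale
  px <- (x - min(x) + pad) * scale
  py <- h - (y - min(y) + pad) * scale
  thin <- seq(1, length(px), by = max(1, length(px) %/% 4000))
  pts <- paste(sprintf("%.2f,%.2f", px[thin], py[thin]), collapse = " ")
  svg <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f" viewBox="0 0 %.0f %.0f">',
    w, h, w, h),
    sprintf('<polyline points="%s" fill="none" stroke="%s" stroke-width="1.5"/>',
            pts, stroke),
    "</svg>")
  writeLines(svg, path)
  invisible(path)
}

#' Plot the simulated word and its operational signals
#'
#' Workspace trace, output time series, weight time series and kick signals,
#' in the layout of the simulation figures.
#'
#' @param x an \code{sfm_trajectory}.
#' @param ... ignored.
#' @return the trajectory, invisibly.
#' @export
plot.sfm_trajectory <- function(x, ...) {
  d <- x$data
  op <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(d[, "x"], d[, "y"], type = "l", xlab = "x", ylab = "y",
                 asp = 1)
  graphics::matplot(d[, "t"], d[, c("y", "z")], type = "l", lty = 1,
                    xlab = "t", ylab = "y, z")
  K <- x$config$repertoire$K
  xi_cols <- intersect(paste0("xi_", seq_len(K)), colnames(d))
  if (length(xi_cols)) {
    graphics::matplot(d[, "t"], d[, xi_cols], type = "l", lty = 1,
                      xlab = "t", ylab = "xi")
  } else {
    graphics::matplot(d[, "t"], d[, c("delta_y", "delta_z")], type = "l",
                      lty = 1, xlab = "t", ylab = "delta")
  }
  invisible(x)
}

#' Run manifest
#'
#' A reproducibility record for a set of output files: schema version,
#' configuration snapshot, seed, package version and an inventory with
#' checksums.  Re-running the same configuration and seed reproduces files
#' with identical checksums.
#'
#' @param cfg the \code{sim_config} used.
#' @param files character vector of produced files.
#' @param path manifest output path (JSON).
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(cfg, files, path) {
  inv <- lapply(files, function(f)
    list(file = basename(f), md5 = unname(tools::md5sum(f))))
  man <- list(schema = "sfmflow-manifest/1",
              package_version = as.character(utils::packageVersion("sfmflow")),
              seed = cfg$seed,
              config = jsonlite::fromJSON(jsonlite::toJSON(
                list(word = cfg$seq$label, s = cfg$s, dt = cfg$dt,
                     duration = cfg$duration), auto_unbox = TRUE)),
              files = inv)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man)
}
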