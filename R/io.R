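#' Write and read correlation-curve TSV files
#'
#' Curves are stored as tab-separated tables with header
#' `lag_s  G  sem`, one file per channel per cell; a JSON manifest beside
#' them records cell ids, compartments and (for simulated data) the
#' ground-truth equilibrium.
#'
#' @param curve A [correlation_curve()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_curve_tsv <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_tsv
#' @param channel Channel label for the curve being read.
#' @export
read_curve_tsv <- function(path, channel = "green_auto") {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("lag_s", "G", "sem") %in% names(d)))
  correlation_curve(channel, d$lag_s, d$G, d$sem,
                    meta = list(source = path))
}

#' Write a simulated FCCS population to a directory
#'
#' One TSV per channel per cell (`cell<id>_<channel>.tsv`) plus
#' `manifest.json` listing, per cell, its id, compartment, curve files and
#' ground-truth equilibrium.
#'
#' @param population A [simulate_cell_population()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_population_dir <- function(population, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(population$cells, function(cell) {
    id <- cell$meta$cell_id
    files <- list()
    for (ch in names(cell$curves)) {
      f <- sprintf("cell%03d_%s.tsv", id, ch)
      write_curve_tsv(cell$curves[[ch]], file.path(dir, f))
      files[[ch]] <- f
    }
    list(cell_id = id, compartment = cell$meta$compartment,
         files = files,
         truth = unclass(cell$truth))
  })
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' @rdname write_population_dir
#' @export
read_population_dir <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  cells <- lapply(manifest, function(m) {
    curves <- lapply(names(m$files), function(ch) {
      read_curve_tsv(file.path(dir, m$files[[ch]]), channel = ch)
    })
    names(curves) <- names(m$files)
    truth <- structure(lapply(m$truth, as.numeric), class = "equilibrium_state")
    list(curves = curves, truth = truth,
         meta = list(cell_id = m$cell_id, compartment = m$compartment))
  })
  list(cells = cells)
}

#' Write per-partner dissociation-constant results as CSV
#'
#' Columns: `partner, kd_green, kd_red, kd_mean, ci_lo, ci_hi, n_cells,
#' binder`.
#'
#' @param fits Named list of [fit_kd_isotherm()] objects (names are
#'   partner symbols).
#' @param path Output CSV path.
#' @return Invisibly, the results data frame.
#' @export
write_kd_results_csv <- function(fits, path) {
  d <- do.call(rbind, lapply(names(fits), function(p) {
    f <- fits[[p]]
    data.frame(partner = p, kd_green = f$kd_green_orientation,
               kd_red = f$kd_red_orientation, kd_mean = f$kd_mean,
               ci_lo = f$ci95[1], ci_hi = f$ci95[2],
               n_cells = f$n_cells, binder = f$binder_flag)
  }))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(d)
}
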