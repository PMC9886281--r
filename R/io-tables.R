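#' Read line profiles from CSV
#'
#' Expects columns `position_um`, `intensity`, `channel`. Positions must
#' be strictly increasing within each channel; a violation is rejected
#' with the file and 1-based data line number of the offending row.
#'
#' @param path CSV path.
#' @param source_id Identifier stored on each profile; defaults to the
#'   file name.
#' @return Named list of [line_profile]s, one per channel.
#' @export
read_profiles_csv <- function(path, source_id = basename(path)) {
  if (!file.exists(path)) stop("read_profiles_csv: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("position_um", "intensity", "channel")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("read_profiles_csv: ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  df$.line <- seq_len(nrow(df))
  out <- lapply(split(df, df$channel), function(d) {
    bad <- which(diff(d$position_um) <= 0)
    if (length(bad)) {
      stop("read_profiles_csv: ", path, ": line ", d$.line[bad[1] + 1L],
           ": position_um not strictly increasing in channel ",
           shQuote(d$channel[1]))
    }
    line_profile(d$position_um, d$intensity, channel = d$channel[1],
                 source_id = source_id)
  })
  out
}

#' Write line profiles to CSV
#'
#' @param profiles A [line_profile], a list of them, or a
#'   `striated_profile_set`.
#' @param path Output CSV path (columns `position_um`, `intensity`,
#'   `channel`).
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  if (inherits(profiles, "striated_profile_set")) profiles <- profiles$profiles
  if (inherits(profiles, "line_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(position_um = p$positions, intensity = p$intensities,
               channel = p$channel)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a per-band results table to CSV
#'
#' Serializes band fits with the fixed column set `source_id`, `channel`,
#' `center_um`, `sigma_um`, `amplitude`, `area`, `rms_residual`,
#' `converged`.
#'
#' @param fits List of `band_fit` objects.
#' @param profile The [line_profile] they came from (for `source_id` /
#'   `channel`).
#' @param path Output CSV path.
#' @return The data.frame written, invisibly.
#' @export
write_results_csv <- function(fits, profile, path) {
  df <- do.call(rbind, lapply(fits, function(f) {
    data.frame(source_id = profile$source_id, channel = profile$channel,
               center_um = f$center, sigma_um = f$sigma,
               amplitude = f$amplitude, area = f$area,
               rms_residual = f$rms_residual, converged = f$converged)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read ROI definitions from JSON
#'
#' ROIs are a JSON array of objects with `kind` (`"rect"` or
#' `"polyline"`), `coordinates` (rect: `[x0, y0, x1, y1]`, 0-based pixel
#' units, half-open; polyline: array of `[x, y]` points), optional
#' `frame` (0-based) and `label`.
#'
#' @param path JSON path.
#' @param image_dim Optional `c(rows, cols)`; when given, coordinates are
#'   validated against the bounds at load time.
#' @return List of ROI lists.
#' @export
read_rois <- function(path, image_dim = NULL) {
  rois <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (i in seq_along(rois)) {
    r <- rois[[i]]
    if (is.null(r$kind) || !r$kind %in% c("rect", "polyline")) {
      stop("read_rois: ", path, ": ROI ", i,
           ": kind must be 'rect' or 'polyline'")
    }
    co <- unlist(r$coordinates)
    if (r$kind == "rect") {
      if (length(co) != 4L) {
        stop("read_rois: ", path, ": ROI ", i, ": rect needs 4 coordinates")
      }
      if (!is.null(image_dim)) check_rect_roi(co, image_dim)
      rois[[i]]$coordinates <- co
    } else {
      m <- matrix(co, ncol = 2, byrow = TRUE)
      if (!is.null(image_dim) &&
          (any(m[, 1] < 0 | m[, 1] > image_dim[2]) ||
           any(m[, 2] < 0 | m[, 2] > image_dim[1]))) {
        stop("read_rois: ", path, ": ROI ", i, ": point outside image")
      }
      rois[[i]]$coordinates <- m
    }
  }
  rois
}

#' Write ROI definitions to JSON
#'
#' @param rois List of ROI lists (see [read_rois]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  rois <- lapply(rois, function(r) {
    if (is.matrix(r$coordinates)) {
      r$coordinates <- lapply(seq_len(nrow(r$coordinates)),
                              function(i) r$coordinates[i, ])
    }
    r
  })
  jsonlite::write_json(rois, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load / save a run configuration
#'
#' A run config is a plain named list holding every tunable of a pipeline
#' run (preset name, background fraction, prominence, separations, ROI
#' sizes, seed, ...) plus provenance (`tool_version`, `timestamp`). A run
#' is reproducible from its config alone.
#'
#' @param path JSON path.
#' @return Named list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' @rdname load_config
#' @param config Named list to serialize.
#' @param add_provenance Stamp `tool_version` and `timestamp` fields.
#' @export
dump_config <- function(config, path, add_provenance = TRUE) {
  if (add_provenance) {
    config$tool_version <- as.character(utils::packageVersion("sarcoquant"))
    config$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  }
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
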