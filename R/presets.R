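#' Load a named, versioned scene preset
#'
#' Presets are JSON files shipped under `extdata/presets/` that freeze the
#' scene parameters used by the documentation and the acceptance suite:
#' muscle geometries (`"flight"`, `"leg"`, `"larval"`,
#' `"larval-projectin"`), the FRAP scenario (`"stable-sls-frap"`), the
#' degradation pairs (`"degrad-larval"`, `"degrad-flight-nano39"`), the
#' label attenuation pair (`"attenuation-nanobody"`,
#' `"attenuation-antibody"`), and the binding-kinetics series
#' (`"sls-nano2-bli"`). Parsed entries are promoted to package objects
#' (`geometry` -> [sarcomere_geometry], `attenuation` ->
#' [attenuation_spec], `frap` -> [frap_ground_truth], `bli` ->
#' [bli_design]); all raw fields remain available.
#'
#' @param name Preset name, or a path to a compatible JSON file.
#' @return A list with the parsed fields plus promoted objects.
#' @examples
#' p <- sq_preset("larval")
#' p$geometry
#' @export
sq_preset <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "presets", paste0(name, ".json"),
                package = "sarcoquant")
  if (!nzchar(path) || !file.exists(path)) {
    avail <- sub("\\.json$", "", list.files(
      system.file("extdata", "presets", package = "sarcoquant")))
    stop("sq_preset: unknown preset ", shQuote(name),
         "; available: ", paste(avail, collapse = ", "))
  }
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(p$geometry)) {
    g <- p$geometry
    offs <- g$epitope_offsets_um
    kinds <- as.list(g$band_kind)
    offs <- lapply(stats::setNames(names(offs), names(offs)), function(ch) {
      o <- offs[[ch]]
      if (identical(kinds[[ch]], "block")) {
        if (is.matrix(o)) o <- lapply(seq_len(nrow(o)), function(i) o[i, ])
        if (!is.list(o)) o <- list(o)
      }
      o
    })
    p$geometry <- sarcomere_geometry(
      sarcomere_length = g$sarcomere_length_um,
      epitope_offsets = offs, band_kind = kinds,
      amplitudes = as.list(g$amplitudes),
      psf_sigma = g$psf_sigma_um, n_periods = g$n_periods)
  }
  if (!is.null(p$attenuation)) {
    a <- p$attenuation
    p$attenuation <- attenuation_spec(a$lambda_um, I0 = a$I0,
                                      z_step = a$z_step_um,
                                      n_slices = a$n_slices)
  }
  if (!is.null(p$frap)) {
    f <- p$frap
    p$frap <- frap_ground_truth(f$immobile_fraction,
                                f$recovery_time_constant_s,
                                bleach_depth = f$bleach_depth,
                                frame_interval = f$frame_interval_s,
                                n_frames = f$n_frames,
                                n_prebleach = f$n_prebleach)
  }
  if (!is.null(p$bli)) {
    b <- p$bli
    p$bli <- bli_design(b$concentrations_M, kon = b$kon, koff = b$koff,
                        Rmax = b$Rmax_nm, t_assoc = b$t_assoc_s,
                        t_dissoc = b$t_dissoc_s,
                        sample_interval = b$sample_interval_s)
  }
  p
}
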