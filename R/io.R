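# Volume I/O and run configuration. Volumes are stored one file per
# volume in an R-native serialized container whose field names mirror the
# fastMRI layout: "kspace" (complex, slices x coils), "reconstruction_rss"
# (real), plus the extension fields "phase", "maps", "mask" and the
# producing "config" and "seed", so artifacts are self-describing and
# re-runnable.

#' Write a multicoil volume
#'
#' @param samples a `phantom_sample`, or a list of them (the slices of
#'   one volume).
#' @param path output file path (conventionally `.rds`).
#' @param config optional configuration object embedded in the file.
#' @return `path`, invisibly.
#' @export
write_multicoil_volume <- function(samples, path, config = NULL) {
  if (inherits(samples, "phantom_sample")) samples <- list(samples)
  vol <- list(
    kspace = lapply(samples, `[[`, "kspace"),
    reconstruction_rss = lapply(samples, function(s)
      coil_combine_rss(kspace_to_image(s$kspace))),
    phase = lapply(samples, `[[`, "phase"),
    maps = lapply(samples, `[[`, "maps"),
    tissue_labels = lapply(samples, `[[`, "tissue_labels"),
    config = if (is.null(config)) samples[[1]]$spec else config,
    seed = samples[[1]]$spec$seed)
  saveRDS(vol, path)
  invisible(path)
}

#' Read a multicoil volume
#'
#' Validates the container and returns the volume list. Slices are in
#' index order; `reconstruction_rss` is surfaced when present.
#'
#' @param path file written by [write_multicoil_volume()].
#' @param n_coils optional expected coil count; a mismatch is an error.
#' @return list with elements `kspace` (list of `(H, W, C)` complex
#'   arrays), `reconstruction_rss`, `phase`, `maps`, `config`, `seed`.
#' @export
read_multicoil_volume <- function(path, n_coils = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  vol <- readRDS(path)
  if (is.null(vol$kspace))
    stop(sprintf("format error in %s: missing dataset 'kspace'", path))
  for (k in vol$kspace) {
    if (length(dim(k)) != 3L)
      stop(sprintf("format error in %s: 'kspace' slices must be (H, W, C)",
                   path))
    if (!is.complex(k))
      stop(sprintf("format error in %s: 'kspace' must be complex", path))
    if (!is.null(n_coils) && dim(k)[3] != n_coils)
      stop(sprintf("format error in %s: expected %d coils, found %d",
                   path, n_coils, dim(k)[3]))
  }
  vol
}

#' Read and validate a run configuration
#'
#' YAML run configuration with one block per pipeline stage. Unknown
#' top-level keys are rejected before any stage runs.
#'
#' @param path YAML file.
#' @return named list of stage configurations.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("phantom", "gan", "espirit", "varnet", "comparison",
               "seed", "out_dir", "log_level")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0)
    stop(sprintf("unknown run-config keys: %s",
                 paste(unknown, collapse = ", ")))
  cfg
}
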