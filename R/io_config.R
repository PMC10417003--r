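#' Read camera intrinsics from a YAML or JSON config
#'
#' The file must provide `fx`, `fy`, `cx`, `cy`, `width`, `height` and may
#' provide `depth_scale` (default 0.001, millimetre depth PNGs).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [camera_intrinsics].
#' @export
read_intrinsics <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path)
  need <- c("fx", "fy", "cx", "cy", "width", "height")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0)
    stop(sprintf("intrinsics config missing field(s): %s",
                 paste(miss, collapse = ", ")))
  camera_intrinsics(cfg$fx, cfg$fy, cfg$cx, cfg$cy, cfg$width, cfg$height,
                    cfg$depth_scale %||% 0.001)
}

#' Write camera intrinsics to YAML or JSON
#'
#' @param intr A [camera_intrinsics].
#' @param path Output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_intrinsics <- function(intr, path) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  lst <- unclass(intr)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(lst, path)
  else
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
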