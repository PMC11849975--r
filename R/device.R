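#' Describe a weight-drop TBI device configuration
#'
#' Captures the physical parameters of one blast-TBI rig configuration: the
#' syringe that holds the larvae, how it is mounted, and the weight drop
#' that generates the pressure wave. These metadata travel with every trace
#' so that dose metrics can be grouped by configuration.
#'
#' @param syringe_volume_ml Syringe size in ml; the assay uses 10 or 20 ml
#'   syringes.
#' @param holder Syringe mount, `"clamp"` (three-prong clamp on a stand) or
#'   `"foam_block"` (rigid drilled foam block; transmits more pressure).
#' @param drop_mass_g Mass of the dropped weight in grams.
#' @param drop_height_cm Drop height (guide tube length) in cm.
#' @param barrel_diameter_mm Inner diameter of the syringe barrel in mm.
#'   Needed for the static Pascal's-law calibration
#'   (\code{\link{expected_static_pressure}}); not a property the trace
#'   files carry, so it must be supplied.
#' @param media_volume_ml Volume of E3 media in the syringe (default 1 ml).
#' @param guide_tube_height_cm Guide tube height; defaults to
#'   `drop_height_cm`.
#'
#' @return An object of class `device_config`.
#' @examples
#' device_config(20, "clamp", drop_mass_g = 100, drop_height_cm = 108,
#'               barrel_diameter_mm = 19.1)
#' @export
device_config <- function(syringe_volume_ml,
                          holder = c("clamp", "foam_block"),
                          drop_mass_g,
                          drop_height_cm,
                          barrel_diameter_mm = NA_real_,
                          media_volume_ml = 1,
                          guide_tube_height_cm = drop_height_cm) {
  holder <- match.arg(holder)
  if (!syringe_volume_ml %in% c(10, 20)) {
    stop("`syringe_volume_ml` must be 10 or 20, got ", syringe_volume_ml)
  }
  if (!is.numeric(drop_mass_g) || length(drop_mass_g) != 1 || drop_mass_g <= 0) {
    stop("`drop_mass_g` must be a single positive number")
  }
  if (!is.numeric(drop_height_cm) || length(drop_height_cm) != 1 ||
      drop_height_cm <= 0) {
    stop("`drop_height_cm` must be a single positive number")
  }
  if (!is.na(barrel_diameter_mm) && barrel_diameter_mm <= 0) {
    stop("`barrel_diameter_mm` must be positive when supplied")
  }
  structure(
    list(
      syringe_volume_ml = syringe_volume_ml,
      holder = holder,
      drop_mass_g = drop_mass_g,
      drop_height_cm = drop_height_cm,
      barrel_diameter_mm = barrel_diameter_mm,
      media_volume_ml = media_volume_ml,
      guide_tube_height_cm = guide_tube_height_cm
    ),
    class = "device_config"
  )
}

#' @export
print.device_config <- function(x, ...) {
  cat(sprintf(
    "<device_config> %g ml syringe / %s, %g g from %g cm\n",
    x$syringe_volume_ml, x$holder, x$drop_mass_g, x$drop_height_cm
  ))
  if (!is.na(x$barrel_diameter_mm)) {
    cat(sprintf("  barrel diameter: %g mm\n", x$barrel_diameter_mm))
  }
  invisible(x)
}

#' Read or write a device configuration as a flat key=value file
#'
#' @param path File path. Lines are `key=value`; `#` starts a comment.
#' @return `read_device_config()` returns a `device_config`;
#'   `write_device_config()` returns `path` invisibly.
#' @seealso [device_config()]
#' @export
read_device_config <- function(path) {
  kv <- read_key_value(path)
  need <- c("syringe_volume_ml", "holder", "drop_mass_g", "drop_height_cm")
  missing <- setdiff(need, names(kv))
  if (length(missing)) {
    stop("device config ", path, " missing keys: ",
         paste(missing, collapse = ", "))
  }
  num <- function(key, default = NA_real_) {
    if (key %in% names(kv)) as.numeric(kv[[key]]) else default
  }
  device_config(
    syringe_volume_ml = num("syringe_volume_ml"),
    holder = kv[["holder"]],
    drop_mass_g = num("drop_mass_g"),
    drop_height_cm = num("drop_height_cm"),
    barrel_diameter_mm = num("barrel_diameter_mm"),
    media_volume_ml = num("media_volume_ml", 1),
    guide_tube_height_cm = num("guide_tube_height_cm",
                               num("drop_height_cm"))
  )
}

#' @rdname read_device_config
#' @param device A `device_config` to serialize.
#' @export
write_device_config <- function(device, path) {
  stopifnot(inherits(device, "device_config"))
  vals <- device[!vapply(device, function(v) is.na(v) || is.null(v), TRUE)]
  writeLines(paste0(names(vals), "=", unlist(vals)), path)
  invisible(path)
}

# Parse a flat key=value file into a named character list.
read_key_value <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  hit <- regexpr("=", lines, fixed = TRUE)
  if (any(hit < 0)) {
    stop("malformed key=value line in ", path, ": ",
         lines[which(hit < 0)[1]])
  }
  keys <- trimws(substr(lines, 1, hit - 1))
  vals <- trimws(substr(lines, hit + 1, nchar(lines)))
  stats::setNames(as.list(vals), keys)
}
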