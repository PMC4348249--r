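# File I/O: multi-page TIFF stacks, CSV tables, JSON run configuration.

#' Read and write frame stacks as multi-page TIFF
#'
#' Count stacks are stored as 16-bit unsigned integer TIFF (values rounded to
#' the nearest integer and clipped to `[0, 65535]`), which round-trips camera
#' counts exactly. Normalized maps in `[0, 1]` (priors, reconstructions) are
#' stored as 32-bit float via [write_float_image()].
#'
#' @param stack A [frame_stack()].
#' @param path File path for the TIFF.
#' @param pixel_size_nm Pixel size attached to the stack on reading.
#' @return `read_stack` returns a `frame_stack`; `write_stack` returns `path`
#'   invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  fr <- stack$frames
  if (max(fr) > 65535)
    stop("counts exceed the uint16 range; rescale before writing")
  pages <- lapply(seq_len(dim(fr)[3]), function(k)
    round(fr[, , k]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, pixel_size_nm = 100) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frame_stack(lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # single channel only
    p
  }), pixel_size_nm = pixel_size_nm)
}

#' Write or read a single float32 image
#'
#' For normalized maps (intensity prior, probability map, reconstructions).
#' Values must lie in `[0, 1]`; storage is 32-bit float, so reading back
#' agrees to single precision.
#'
#' @param img Numeric matrix with values in `[0, 1]`.
#' @param path File path.
#' @export
write_float_image <- function(img, path) {
  if (min(img) < 0 || max(img) > 1)
    stop("float images must be normalized to [0, 1] before writing")
  tiff::writeTIFF(img, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_float_image
#' @export
read_float_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tiff::readTIFF(path)
}

#' Structure CSV round trip
#'
#' Plain CSV with header `x_px,y_px,brightness`, comma separated, `.` decimal.
#'
#' @param structure A [structure_set()].
#' @param path File path.
#' @export
write_structure_csv <- function(structure, path) {
  utils::write.csv(as.data.frame(structure)[, c("x_px", "y_px", "brightness")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_structure_csv
#' @export
read_structure_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path)
  structure_set(d$x_px, d$y_px, d$brightness)
}

#' Write per-fluorophore state trajectories
#'
#' Long-format CSV `fluorophore_id,frame,state` with states spelled
#' `emitting`, `dark`, `bleached`.
#'
#' @param states Integer matrix `[n_fluorophores, K]` of state codes.
#' @param path File path.
#' @export
write_states_csv <- function(states, path) {
  lab <- c("emitting", "dark", "bleached")
  d <- data.frame(
    fluorophore_id = rep(seq_len(nrow(states)), times = ncol(states)),
    frame = rep(seq_len(ncol(states)), each = nrow(states)),
    state = lab[as.vector(states)])
  d <- d[order(d$fluorophore_id, d$frame), ]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the model-selection ledger
#'
#' CSV `iteration,op,x_px,y_px,outcome`; births carry outcome `retained` or
#' `discarded`, removal decisions `removed` or `kept`.
#'
#' @param ledger Data frame as produced in a reconstruction state.
#' @param path File path.
#' @export
write_ledger_csv <- function(ledger, path) {
  utils::write.csv(ledger[, c("iteration", "op", "x_px", "y_px", "outcome")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration / manifest JSON
#'
#' Records every parameter of a run plus the master seed so that a run is
#' reproducible from its manifest alone.
#'
#' @param config Named list of parameters.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  config$package_version <- as.character(utils::packageVersion("fid3b"))
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
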