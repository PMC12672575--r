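#' Read / write image stacks as multi-page TIFF
#'
#' Stacks are stored as 16-bit integer TIFF (camera counts, 0..65535),
#' the natural format for the emulated sCMOS data; the round trip is
#' exact for integer-valued stacks in that range.
#'
#' @param stack Numeric array `frame x row x col` with values in
#'   `[0, 65535]`; values are rounded to integers on write.
#' @param path File path.
#' @return `read_stack()` returns a numeric array `frame x row x col` in
#'   counts; `write_stack()` returns `path` invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3)
  if (min(stack) < 0 || max(stack) > 65535)
    stop("stack values must lie in [0, 65535] counts")
  pages <- lapply(seq_len(dim(stack)[1]), function(f)
    round(stack[f, , ]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  for (i in seq_along(dims))
    if (!identical(dims[[i]], dims[[1]]))
      stop("ragged TIFF: page ", i, " has shape ",
           paste(dims[[i]], collapse = "x"), " but page 1 has ",
           paste(dims[[1]], collapse = "x"))
  stack <- array(0, dim = c(length(pages), dims[[1]]))
  for (f in seq_along(pages)) stack[f, , ] <- round(pages[[f]] * 65535)
  stack
}

#' Write a label mask as 16-bit TIFF
#' @param mask Integer matrix of object labels.
#' @param path File path.
#' @export
write_mask <- function(mask, path) {
  write_stack(array(mask, dim = c(1, nrow(mask), ncol(mask))), path)
}

#' Write a fatigue curve as CSV
#' @param curve A `fatigue_curve`.
#' @param path Output path.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Records what produced a set of outputs: the command and arguments, a
#' hash of the effective configuration, the parameter-set label, seeds,
#' package version and timestamps — enough to re-run bit-compatibly.
#'
#' @param command Subcommand or function name.
#' @param args Named list of effective arguments.
#' @param seed Integer seed(s) used.
#' @param outputs Character vector of output paths.
#' @param path Where to write the manifest JSON.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(command, args, seed, outputs, path) {
  cfg <- tempfile()
  jsonlite::write_json(args, cfg, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    command = command,
    args = args,
    config_md5 = unname(tools::md5sum(cfg)),
    seed = seed,
    package = "rsfatigue",
    version = as.character(utils::packageVersion("rsfatigue")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs)
  unlink(cfg)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
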