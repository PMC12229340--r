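# Checkpoint container: one plain-text array file holding the named flat
# weight arrays of both networks, plus a JSON sidecar (<path>.json) carrying
# the architecture specs, seed, training-config snapshot and an array
# manifest.  Values are printed with 17 significant digits so the text round
# trip is bit-exact for IEEE doubles.

CKPT_FORMAT_VERSION <- 1L

scretinex_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "scretinex_error")))
}

#' Bundle two trained networks into a checkpoint
#'
#' @param ienet,scanet Built [build_network()] objects.
#' @param train_config Optional list snapshot of the training configuration.
#' @param seed Integer seed the run was started from.
#' @return An object of class `sadp_checkpoint`.
#' @export
make_checkpoint <- function(ienet, scanet, train_config = NULL, seed = NA_integer_) {
  stopifnot(inherits(ienet, "sadp_network"), inherits(scanet, "sadp_network"))
  structure(
    list(ienet_spec = ienet$spec, scanet_spec = scanet$spec,
         ienet_arrays = params_as_arrays(ienet),
         scanet_arrays = params_as_arrays(scanet),
         train_config = train_config, seed = seed,
         format_version = CKPT_FORMAT_VERSION),
    class = "sadp_checkpoint"
  )
}

#' Rebuild the two networks held in a checkpoint
#'
#' @param ckpt An `sadp_checkpoint`.
#' @return A list with elements `ienet` and `scanet`.
#' @export
checkpoint_networks <- function(ckpt) {
  stopifnot(inherits(ckpt, "sadp_checkpoint"))
  ie <- build_network(ckpt$ienet_spec, seed = 0L)
  sc <- build_network(ckpt$scanet_spec, seed = 0L)
  list(ienet = arrays_into_network(ie, ckpt$ienet_arrays),
       scanet = arrays_into_network(sc, ckpt$scanet_arrays))
}

write_array_container <- function(arrays, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("SADP-WEIGHTS %d", CKPT_FORMAT_VERSION), con)
  writeLines(sprintf("%d", length(arrays)), con)
  for (nm in names(arrays)) {
    writeLines(sprintf("%s\t%d", nm, length(arrays[[nm]])), con)
    writeLines(paste(sprintf("%.17g", arrays[[nm]]), collapse = " "), con)
  }
  invisible(NULL)
}

read_array_container <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || !grepl("^SADP-WEIGHTS ", lines[1L])) {
    scretinex_error(sprintf("'%s' is not a checkpoint weight container", path),
                    "scretinex_corrupt")
  }
  n <- suppressWarnings(as.integer(lines[2L]))
  if (is.na(n) || length(lines) < 2L + 2L * n) {
    scretinex_error(sprintf("checkpoint '%s' is truncated or corrupted", path),
                    "scretinex_corrupt")
  }
  arrays <- list()
  for (i in seq_len(n)) {
    hdr <- strsplit(lines[2L * i + 1L], "\t", fixed = TRUE)[[1L]]
    vals <- suppressWarnings(as.numeric(strsplit(lines[2L * i + 2L], " ", fixed = TRUE)[[1L]]))
    len <- suppressWarnings(as.integer(hdr[2L]))
    if (length(hdr) != 2L || is.na(len) || length(vals) != len || anyNA(vals)) {
      scretinex_error(sprintf("checkpoint '%s' is truncated or corrupted", path),
                      "scretinex_corrupt")
    }
    arrays[[hdr[1L]]] <- vals
  }
  arrays
}

spec_to_list <- function(s) unclass(s)

spec_from_list <- function(l) {
  network_spec(kind = l$kind, in_channels = l$in_channels,
               hidden_channels = l$hidden_channels, n_blocks = l$n_blocks,
               kernel = l$kernel)
}

#' Save / load a checkpoint
#'
#' `save_checkpoint()` writes the weight container to `path` and a JSON
#' sidecar to `<path>.json`.  `load_checkpoint()` restores the checkpoint
#' losslessly; supplying `ienet_spec` / `scanet_spec` asserts that the stored
#' architecture matches and raises a spec-mismatch error otherwise — a
#' checkpoint is never silently reshaped onto a different architecture.
#'
#' @param ckpt An `sadp_checkpoint`.
#' @param path File path of the weight container.
#' @param ienet_spec,scanet_spec Optional [network_spec()]s to validate
#'   against.
#' @return `load_checkpoint()` returns an `sadp_checkpoint`.
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "sadp_checkpoint"))
  arrays <- c(
    stats::setNames(ckpt$ienet_arrays, paste0("ienet.", names(ckpt$ienet_arrays))),
    stats::setNames(ckpt$scanet_arrays, paste0("scanet.", names(ckpt$scanet_arrays)))
  )
  write_array_container(arrays, path)
  sidecar <- list(
    format = "sadp-checkpoint",
    format_version = ckpt$format_version,
    seed = ckpt$seed,
    ienet_spec = spec_to_list(ckpt$ienet_spec),
    scanet_spec = spec_to_list(ckpt$scanet_spec),
    train_config = ckpt$train_config,
    arrays = lapply(arrays, length)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, ienet_spec = NULL, scanet_spec = NULL) {
  if (!file.exists(path)) {
    scretinex_error(sprintf("checkpoint file '%s' not found", path), "scretinex_io")
  }
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) {
    scretinex_error(sprintf("checkpoint sidecar '%s' not found", side_path), "scretinex_io")
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  if (!identical(side$format, "sadp-checkpoint")) {
    scretinex_error(sprintf("'%s' is not a checkpoint sidecar", side_path),
                    "scretinex_corrupt")
  }
  stored_ie <- spec_from_list(side$ienet_spec)
  stored_sc <- spec_from_list(side$scanet_spec)
  if (!is.null(ienet_spec) && !spec_equal(stored_ie, ienet_spec)) {
    scretinex_error("checkpoint IE-Net architecture disagrees with the requested spec",
                    "scretinex_spec_mismatch")
  }
  if (!is.null(scanet_spec) && !spec_equal(stored_sc, scanet_spec)) {
    scretinex_error("checkpoint SCA-Net architecture disagrees with the requested spec",
                    "scretinex_spec_mismatch")
  }
  arrays <- read_array_container(path)
  manifest <- side$arrays
  for (nm in names(manifest)) {
    if (is.null(arrays[[nm]]) || length(arrays[[nm]]) != manifest[[nm]]) {
      scretinex_error(sprintf("checkpoint '%s' arrays disagree with sidecar manifest", path),
                      "scretinex_corrupt")
    }
  }
  pick <- function(prefix) {
    sel <- startsWith(names(arrays), prefix)
    stats::setNames(arrays[sel], substring(names(arrays)[sel], nchar(prefix) + 1L))
  }
  cfg <- side$train_config
  if (length(cfg) == 0L) cfg <- NULL
  structure(
    list(ienet_spec = stored_ie, scanet_spec = stored_sc,
         ienet_arrays = pick("ienet."), scanet_arrays = pick("scanet."),
         train_config = cfg, seed = side$seed,
         format_version = side$format_version),
    class = "sadp_checkpoint"
  )
}
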