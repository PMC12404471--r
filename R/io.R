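# Dataset I/O and run configuration plumbing.

#' Read an annotated video from disk
#'
#' Expects the [write_dataset()] layout: ordered `frame_%04d.png` images,
#' an `annotations.csv` with one row per frame, optionally `metadata.yaml`
#' and a `masks/` directory. Frames are sorted by index regardless of file
#' listing order; acquisition times must be strictly increasing.
#'
#' @param path Video directory.
#' @return An `annotated_video`.
#' @export
read_video <- function(path) {
  ann_path <- file.path(path, "annotations.csv")
  if (!file.exists(ann_path)) {
    stop("missing annotations.csv under ", path, call. = FALSE)
  }
  ann <- read.csv(ann_path, stringsAsFactors = FALSE)
  files <- list.files(path, pattern = "^frame_[0-9]+\\.(png|PNG)$",
                      full.names = TRUE)
  idx <- as.integer(sub("^frame_0*([0-9]+)\\..*$", "\\1", basename(files)))
  files <- files[order(idx)]
  if (length(files) != nrow(ann)) {
    stop(sprintf("%s: %d frames but %d annotation rows", path, length(files),
                 nrow(ann)), call. = FALSE)
  }
  if (any(diff(ann$hpi) <= 0)) {
    stop(path, ": acquisition times (hpi) must be strictly increasing",
         call. = FALSE)
  }
  frames <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3) m <- m[, , 1]
    matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  })
  cfg <- NULL
  meta_path <- file.path(path, "metadata.yaml")
  if (file.exists(meta_path)) {
    cfg <- yaml::read_yaml(meta_path)
    class(cfg) <- "sim_config"
  }
  mask_dir <- file.path(path, "masks")
  masks <- NULL
  if (dir.exists(mask_dir)) {
    mfiles <- list.files(mask_dir, pattern = "\\.png$", full.names = TRUE)
    midx <- as.integer(sub("^frame_0*([0-9]+)\\..*$", "\\1", basename(mfiles)))
    masks <- lapply(mfiles[order(midx)], function(f) {
      m <- png::readPNG(f)
      if (length(dim(m)) == 3) m <- m[, , 1]
      matrix(as.integer(m > 0.5), nrow(m), ncol(m))
    })
  }
  out <- list(frames = frames, annotations = ann, schedule = NULL,
              config = cfg)
  if (!is.null(masks)) out$masks <- masks
  structure(out, class = "annotated_video")
}

#' Read a run configuration from YAML
#' @param path YAML file (see the packaged example under
#'   `system.file("config", "tiny.yaml", package = "embryocast")`).
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

# stable short hash of a run config (md5 of its canonical JSON)
config_hash <- function(cfg) {
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(js, tf)
  substr(unname(tools::md5sum(tf)), 1, 12)
}
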