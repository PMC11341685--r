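#' Export a patch dataset as PNG files
#'
#' Writes one subdirectory per class containing the class's patches as PNG
#' files, a `manifest.csv` (`path,label`) and a `provenance.json` recording
#' every generation parameter and the seed, so the export is reproducible
#' and re-importable.
#'
#' @param data a `patch_dataset`.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
export_dataset_png <- function(data, dir) {
  stopifnot(inherits(data, "patch_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  rows <- vector("list", dim(data$patches)[1])
  counter <- integer(length(data$class_names))
  for (i in seq_len(dim(data$patches)[1])) {
    k <- data$labels[i] + 1L
    cls <- data$class_names[k]
    dir.create(file.path(dir, cls), showWarnings = FALSE)
    counter[k] <- counter[k] + 1L
    rel <- file.path(cls, sprintf("%s_%04d.png", tolower(cls), counter[k]))
    png::writePNG(data$patches[i, , , ], file.path(dir, rel))
    rows[[i]] <- data.frame(path = rel, label = data$labels[i])
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  gp <- data$gen_params
  jsonlite::write_json(list(n_per_class = gp$n_per_class, size = gp$size,
                            separability = gp$separability, seed = data$seed,
                            class_names = data$class_names),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.csv"))
}

#' Import labeled patches from class-named PNG directories
#'
#' Reads either a directory written by [export_dataset_png()] (using its
#' manifest) or any directory of class-named subdirectories of equally sized
#' PNG patches.
#'
#' @param dir input directory.
#' @return a `patch_dataset` (with `gen_params$source = "png"`).
#' @export
import_dataset_png <- function(dir) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  manifest_path <- file.path(dir, "manifest.csv")
  if (file.exists(manifest_path)) {
    manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
    class_names <- basename(dirname(manifest$path))
    class_names <- class_names[!duplicated(manifest$label)]
    class_names <- class_names[order(unique(manifest$label))]
    files <- file.path(dir, manifest$path)
    labels <- manifest$label
  } else {
    class_names <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
    if (length(class_names) == 0) stop("no class subdirectories in ", dir)
    files <- character(); labels <- integer()
    for (k in seq_along(class_names)) {
      fs <- sort(list.files(file.path(dir, class_names[k]), "\\.png$",
                            full.names = TRUE))
      files <- c(files, fs)
      labels <- c(labels, rep(k - 1L, length(fs)))
    }
  }
  imgs <- lapply(files, png::readPNG)
  sz <- dim(imgs[[1]])
  if (length(sz) == 2) sz <- c(sz, 1L)
  patches <- array(0, dim = c(length(imgs), sz[1], sz[2], max(sz[3], 3L)))
  for (i in seq_along(imgs)) {
    im <- imgs[[i]]
    if (length(dim(im)) == 2) im <- array(rep(im, 3), dim = c(dim(im), 3))
    if (!all(dim(im)[1:2] == sz[1:2])) stop("patch size mismatch: ", files[i])
    patches[i, , , ] <- im[, , 1:dim(patches)[4]]
  }
  structure(list(patches = patches, labels = as.integer(labels),
                 class_names = class_names,
                 gen_params = list(source = "png", dir = dir),
                 seed = NA_integer_),
            class = "patch_dataset")
}

#' Write per-epoch training curves as CSV
#'
#' Columns: optimizer, seed, epoch, loss, accuracy (and the scheduled base
#' rate for SAdagrad runs).
#'
#' @param results a list of `run_result` objects (or a single one).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(results, path) {
  if (inherits(results, "run_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    if (length(r$train_loss) == 0) return(NULL)
    data.frame(optimizer = r$optimizer, seed = r$seed,
               epoch = seq_along(r$train_loss) - 1L,
               loss = r$train_loss, accuracy = r$train_accuracy,
               ls = if (!is.null(r$ls)) r$ls else NA_real_)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write ROC points as CSV
#'
#' @param roc a data frame from [roc_points()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_roc_csv <- function(roc, path) {
  utils::write.csv(roc, path, row.names = FALSE)
  invisible(path)
}
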