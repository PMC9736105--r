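#' Write images as PNG files with a manifest
#'
#' @param images list of `fruit_image`s.
#' @param dir output directory (created if missing).
#' @param rng_seed seed recorded in the manifest.
#' @return invisibly, the manifest data.frame (filename, sample_id,
#'   truth_stage); also written as `manifest.json`.
#' @export
write_images <- function(images, dir, rng_seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(images))
  for (i in seq_along(images)) {
    id <- images[[i]]$sample_id %||% sprintf("img%04d", i)
    files[i] <- paste0(id, ".png")
    px <- images[[i]]$pixels / 255
    EBImage::writeImage(EBImage::Image(aperm(px, c(2, 1, 3)), colormode = "Color"),
                        file.path(dir, files[i]))
  }
  manifest <- data.frame(filename = files,
                         sample_id = image_ids(images),
                         truth_stage = truth_stages(images),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(list(seed = rng_seed, images = manifest),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(manifest)
}

#' Read a directory of fruit images
#'
#' Decodes every JPEG/PNG in `path` (sorted by filename) into `fruit_image`
#' objects. If a `manifest.json` written by [write_images()] is present, truth
#' stages are attached. Real-world images carry no truth label.
#'
#' @param path directory.
#' @param strict if `TRUE` (default) an unreadable file is an error; otherwise
#'   it is skipped with a warning.
#' @return list of `fruit_image` objects.
#' @export
read_image_dir <- function(path, strict = TRUE) {
  if (!dir.exists(path)) stop_input(sprintf("no such directory: %s", path))
  files <- sort(list.files(path, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE))
  if (length(files) == 0L) stop_input(sprintf("no images found in %s", path))
  truth <- NULL
  mpath <- file.path(path, "manifest.json")
  if (file.exists(mpath)) {
    man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
    truth <- stats::setNames(man$images$truth_stage, man$images$filename)
  }
  images <- list()
  for (f in files) {
    px <- tryCatch({
      im <- EBImage::readImage(file.path(path, f))
      a <- aperm(array(im, c(dim(im)[1], dim(im)[2], 3L)), c(2, 1, 3))
      array(as.integer(round(a * 255)), dim(a))
    }, error = function(e) {
      if (strict) stop_input(sprintf("failed to read %s: %s", f, conditionMessage(e)))
      warning(sprintf("skipping unreadable image %s", f))
      NULL
    })
    if (is.null(px)) next
    st <- if (!is.null(truth) && f %in% names(truth)) truth[[f]] else NULL
    if (!is.null(st) && is.na(st)) st <- NULL
    images[[length(images) + 1L]] <-
      structure(list(pixels = px, truth_stage = st,
                     sample_id = sub("\\.[^.]+$", "", f), crack_bbox = NULL),
                class = "fruit_image")
  }
  if (length(images) == 0L) stop_input("no readable images")
  images
}

PROPERTY_COLUMNS <- c("sample_id", "stage", "transverse_diameter_mm",
                      "vertical_diameter_mm", "fresh_seed_weight_g",
                      "dry_seed_weight_g", "moisture_pct", "oil_pct",
                      "soluble_protein_pct", "soluble_sugar_pct", "starch_pct")

#' Write / read per-sample property tables
#'
#' CSV round-trip of the [generate_property_table()] schema with explicit
#' column validation on read.
#'
#' @param records property data.frame.
#' @param path CSV file path.
#' @return `read_property_csv` returns the validated data.frame.
#' @export
write_property_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_property_csv
#' @export
read_property_csv <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- setdiff(PROPERTY_COLUMNS, c("moisture_pct", "stage"))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_input(sprintf("property CSV is missing column(s): %s",
                       paste(missing, collapse = ", ")))
  }
  num_cols <- setdiff(intersect(PROPERTY_COLUMNS, names(df)), c("sample_id", "stage"))
  for (cl in num_cols) {
    if (!is.numeric(df[[cl]])) stop_input(sprintf("column %s must be numeric", cl))
  }
  if (any(df$dry_seed_weight_g > df$fresh_seed_weight_g)) {
    stop_input("dry seed weight exceeds fresh seed weight in some record(s)")
  }
  df
}

#' Export a clustering result
#'
#' Writes `assignments.csv` (id, cluster, and stage when a naming is given),
#' `clustering.json` (objective, iterations, repairs, sizes), and optionally
#' `projection.csv` with 2-D PCA coordinates for scatter plots.
#'
#' @param clustering an `rc_clustering`.
#' @param ids sample identifiers.
#' @param dir output directory.
#' @param stage_map optional cluster -> stage naming.
#' @param projection optional `N x 2` coordinate matrix.
#' @return invisibly, the assignments data.frame.
#' @export
write_clustering <- function(clustering, ids, dir, stage_map = NULL,
                             projection = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(id = ids, cluster = clustering$assignments,
                   stringsAsFactors = FALSE)
  if (!is.null(stage_map)) df$stage <- stage_map[clustering$assignments]
  write.csv(df, file.path(dir, "assignments.csv"), row.names = FALSE)
  jsonlite::write_json(list(objective = clustering$objective,
                            n_iterations = clustering$n_iterations,
                            empty_cluster_repairs = clustering$empty_cluster_repairs,
                            sizes = clustering$sizes),
                       file.path(dir, "clustering.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(projection)) {
    pj <- data.frame(id = ids, pc1 = projection[, 1],
                     pc2 = if (ncol(projection) > 1) projection[, 2] else NA_real_)
    write.csv(pj, file.path(dir, "projection.csv"), row.names = FALSE)
  }
  invisible(df)
}

#' Serialize a feature matrix
#'
#' Two-file pair: raw little-endian doubles (`<path>.bin`, row-major) plus a
#' CSV manifest of ids and dimensions (`<path>.csv`).
#'
#' @param features numeric matrix with rownames as ids.
#' @param path base path without extension.
#' @return `read_feature_matrix` returns the matrix with ids restored.
#' @export
write_feature_matrix <- function(features, path) {
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(features)), con, size = 8, endian = "little")
  write.csv(data.frame(id = rownames(features) %||% seq_len(nrow(features)),
                       nrow = nrow(features), ncol = ncol(features)),
            paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  man <- read.csv(paste0(path, ".csv"), stringsAsFactors = FALSE)
  n <- man$nrow[1]; d <- man$ncol[1]
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n * d, size = 8, endian = "little")
  m <- matrix(vals, n, d, byrow = TRUE)
  rownames(m) <- man$id
  m
}

# Run manifest written by every CLI subcommand.
write_run_manifest <- function(dir, command, config, seed, timings = NULL) {
  jsonlite::write_json(
    list(command = command, config = config, seed = seed,
         package_version = as.character(utils::packageVersion("ripecluster")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         timings = timings),
    file.path(dir, "run_manifest.json"), auto_unbox = TRUE, pretty = TRUE,
    na = "null", force = TRUE)
  invisible(NULL)
}
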