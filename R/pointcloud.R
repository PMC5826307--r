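#' Per-tree point cloud
#'
#' A `tree_cloud` bundles one tree's 3-D laser points with the ground
#' elevation (DTM value) at its stem foot and an optional species label.
#' Heights above ground are always computed downstream as `z - dtm_z`; the
#' stored coordinates are never modified.
#'
#' @param points numeric matrix or data frame with three columns (x, y, z),
#'   metres.
#' @param dtm_z ground elevation at the stem foot, metres.
#' @param tree_id character scalar identifying the tree.
#' @param species optional species label (e.g. `"PA"`, `"PS"`, `"PT"`,
#'   `"QR"`); free text is allowed.
#' @return An object of class `tree_cloud`: a list with elements `tree_id`,
#'   `points` (n x 3 matrix with columns x, y, z), `dtm_z`, `species`.
#' @examples
#' pts <- cbind(runif(50), runif(50), runif(50, 5, 15))
#' tc <- tree_cloud(pts, dtm_z = 0, tree_id = "t1")
#' tc
#' @export
tree_cloud <- function(points, dtm_z, tree_id, species = NA_character_) {
  points <- as.matrix(points)
  if (ncol(points) < 3) {
    stop("'points' must have three columns (x, y, z)")
  }
  points <- points[, 1:3, drop = FALSE]
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "z")
  if (!is.character(tree_id) || length(tree_id) != 1L || is.na(tree_id)) {
    stop("'tree_id' must be a single character string")
  }
  if (!is.numeric(dtm_z) || length(dtm_z) != 1L || !is.finite(dtm_z)) {
    stop("'dtm_z' must be a single finite number")
  }
  if (nrow(points) < 10L) {
    stop(sprintf("tree '%s': degenerate input, fewer than 10 points (%d)",
                 tree_id, nrow(points)))
  }
  if (!all(is.finite(points))) {
    stop(sprintf("tree '%s': non-finite coordinates", tree_id))
  }
  if (max(points[, "z"]) <= dtm_z) {
    stop(sprintf("tree '%s': max(z) must exceed dtm_z (no positive height)",
                 tree_id))
  }
  structure(
    list(tree_id = tree_id, points = points, dtm_z = as.numeric(dtm_z),
         species = as.character(species)),
    class = "tree_cloud"
  )
}

#' @export
print.tree_cloud <- function(x, ...) {
  cat(sprintf("<tree_cloud '%s'> %d points, dtm_z = %.2f m, species = %s\n",
              x$tree_id, nrow(x$points), x$dtm_z,
              ifelse(is.na(x$species), "<none>", x$species)))
  invisible(x)
}

#' Read a per-tree point cloud from disk
#'
#' Supports binary LAS (point record formats 0-3, see [read_las()]) and
#' whitespace-separated XYZ text with three numeric columns.  The format is
#' detected from the file's magic bytes, not its extension.  Compressed LAZ
#' is not supported.
#'
#' @param path path to a LAS or XYZ text file.
#' @param dtm_z ground elevation at the stem foot, metres.
#' @param tree_id tree identifier; defaults to the file name without
#'   extension.
#' @param species optional species label.
#' @return A [tree_cloud()].
#' @export
read_tree_cloud <- function(path, dtm_z, tree_id = NULL, species = NA_character_) {
  if (!file.exists(path)) {
    stop(sprintf("point cloud file not found: '%s'", path))
  }
  if (is.null(tree_id)) {
    tree_id <- sub("\\.[^.]*$", "", basename(path))
  }
  magic <- readBin(path, "raw", n = 4L)
  if (length(magic) == 4L && rawToChar(magic) == "LASF") {
    pts <- read_las(path)
  } else if (length(magic) >= 4L && rawToChar(magic[1:4]) == "LASZ") {
    stop(sprintf("'%s' looks like compressed LAZ, which is not supported; ",
                 path), "decompress to LAS or export XYZ text")
  } else {
    pts <- tryCatch(
      as.matrix(read.table(path, header = FALSE,
                           colClasses = "numeric")[, 1:3]),
      error = function(e) {
        stop(sprintf("could not parse '%s' as XYZ text: %s", path,
                     conditionMessage(e)))
      }
    )
  }
  tree_cloud(pts, dtm_z = dtm_z, tree_id = tree_id, species = species)
}

#' Read a per-tree manifest
#'
#' The manifest is a CSV with columns `tree_id`, `path`, `dtm_z` and
#' optionally `species`.  Relative paths are resolved against the manifest's
#' own directory.
#'
#' @param path manifest CSV path.
#' @return data frame with columns `tree_id`, `path` (absolute), `dtm_z`,
#'   `species`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: '%s'", path))
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tree_id", "path", "dtm_z")
  miss <- setdiff(need, names(man))
  if (length(miss)) {
    stop("manifest is missing required columns: ", paste(miss, collapse = ", "))
  }
  if (!"species" %in% names(man)) man$species <- NA_character_
  base <- dirname(normalizePath(path))
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(base, man$path[rel])
  man[, c("tree_id", "path", "dtm_z", "species")]
}

#' Load all trees listed in a manifest
#'
#' @param manifest path to a manifest CSV, or a data frame as returned by
#'   [read_manifest()].
#' @return list of [tree_cloud()] objects, named by `tree_id`.
#' @export
load_stand <- function(manifest) {
  man <- if (is.character(manifest)) read_manifest(manifest) else manifest
  trees <- lapply(seq_len(nrow(man)), function(i) {
    read_tree_cloud(man$path[i], dtm_z = man$dtm_z[i],
                    tree_id = man$tree_id[i], species = man$species[i])
  })
  names(trees) <- man$tree_id
  trees
}
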