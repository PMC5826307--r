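#' Compute the full feature table for a set of trees
#'
#' Runs stem-axis estimation, crown-frame construction and the CI + TE
#' feature derivations for every tree, assembling the table the classifier
#' consumes: one row per tree, columns `tree_id`, `species`, `P1`..`P13`
#' and the 10 TE parameters.
#'
#' @param trees list of [tree_cloud()] objects (e.g. from [load_stand()] or
#'   [simulate_stand()]).
#' @param voxel_size,n_layers passed to [build_crown_frame()].
#' @param grid_cell,profile_bins passed to [compute_te_features()].
#' @param alpha,supervoxel passed to [compute_ci_features()].
#' @param quiet suppress per-tree progress notes (default TRUE).
#' @return data frame with `2 + 23` columns.
#' @export
compute_feature_table <- function(trees, voxel_size = 0.5, n_layers = 8L,
                                  grid_cell = 0.5, profile_bins = 40L,
                                  alpha = 0.5, supervoxel = 1, quiet = TRUE) {
  rows <- lapply(trees, function(tr) {
    frame <- build_crown_frame(tr, voxel_size = voxel_size, n_layers = n_layers)
    ci <- suppressMessages(compute_ci_features(frame, alpha = alpha,
                                               supervoxel = supervoxel))
    te <- compute_te_features(tr, frame, grid_cell = grid_cell,
                              profile_bins = profile_bins)
    cbind(data.frame(tree_id = tr$tree_id, species = tr$species,
                     stringsAsFactors = FALSE),
          as.data.frame(t(unclass(ci))), as.data.frame(t(unclass(te))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read or write a feature table CSV
#'
#' The CSV schema is: first two columns `tree_id` and `species`, then the
#' named feature parameters.
#'
#' @param table feature table data frame.
#' @param path CSV path.
#' @return `read_feature_table()` returns the data frame; the writer returns
#'   `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("feature table not found: '%s'", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("tree_id", "species") %in% names(tab))) {
    stop("feature table must have 'tree_id' and 'species' columns")
  }
  tab
}

# validate that requested feature columns exist and are finite
check_feature_columns <- function(table, columns) {
  miss <- setdiff(columns, names(table))
  if (length(miss)) {
    stop("feature table lacks columns: ", paste(miss, collapse = ", "))
  }
  bad <- columns[!vapply(table[columns],
                         function(x) is.numeric(x) && all(is.finite(x)), TRUE)]
  if (length(bad)) {
    stop("non-finite or non-numeric feature columns: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
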