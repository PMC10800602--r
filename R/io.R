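# JSON sidecar recording provenance for a written file
write_sidecar <- function(path, info) {
  jsonlite::write_json(info, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Write / read a subject's ROI time series as TSV
#'
#' One row per timepoint, one column per region, tab-separated with the
#' region labels as header.
#'
#' @param ts a `roi_ts` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  write.table(unclass(ts), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @param subject_id subject identifier for the returned object; defaults
#'   to the file name without extension.
#' @param atlas optional atlas table; when given, columns are reordered to
#'   the atlas abbreviation order (a mismatch in the label *set* is an
#'   error).
#' @export
read_timeseries <- function(path, subject_id = NULL, atlas = NULL) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  subject_id <- subject_id %||% sub("\\.[^.]+$", "", basename(path))
  m <- as.matrix(read.delim(path, check.names = FALSE))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop_dc(sprintf("missing value in %s at row %d, column '%s'",
                    path, bad[1], colnames(m)[bad[2]]))
  }
  if (!is.null(atlas)) {
    want <- atlas$abbreviation
    assert_that(setequal(colnames(m), want),
                paste0("column labels of ", path,
                       " do not match the atlas abbreviations"))
    if (!identical(colnames(m), want)) {
      message("reordering columns of ", basename(path),
              " to atlas label order")
      m <- m[, want, drop = FALSE]
    }
  }
  roi_timeseries(m, subject_id)
}

#' Write / read subject metadata as CSV
#'
#' @param meta metadata data.frame (see [generate_cohort()]).
#' @param path output path.
#' @return the path / the validated data.frame.
#' @export
write_meta <- function(meta, path) {
  write.csv(meta, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_meta
#' @export
read_meta <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  meta <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "age", "sex")
  missing <- setdiff(required, names(meta))
  assert_that(length(missing) == 0,
              paste0("metadata lacks column(s): ",
                     paste(missing, collapse = ", ")))
  dup <- which(duplicated(meta$subject_id))
  assert_that(length(dup) == 0,
              paste0("duplicate subject_id at row(s): ",
                     paste(dup, collapse = ", ")))
  assert_that(all(meta$group %in% c("patient", "control")),
              "group must be 'patient' or 'control'")
  assert_that(all(meta$age > 0), "ages must be positive")
  if ("fd_power" %in% names(meta)) {
    assert_that(all(is.na(meta$fd_power) | meta$fd_power >= 0),
                "fd_power must be >= 0")
  }
  meta
}

#' Write a graph or mask as an edge-list TSV with a JSON sidecar
#'
#' Edges are written one per line (`label_i`, `label_j`, plus any extra
#' columns such as sign and statistics), endpoints in canonical atlas
#' order. The sidecar records thresholds/policy or alpha/m.
#'
#' @param x an `edge_mask` or [dysfunction_graph()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_edge_list <- function(x, path) {
  if (inherits(x, "edge_mask")) {
    labs <- colnames(x)
    idx <- which(upper.tri(x) & x, arr.ind = TRUE)
    df <- data.frame(label_i = labs[idx[, 1]], label_j = labs[idx[, 2]],
                     stringsAsFactors = FALSE)
    info <- list(kind = "edge_mask",
                 r_threshold = attr(x, "r_threshold"),
                 policy = attr(x, "policy"),
                 q = attr(x, "q"),
                 n_edges = nrow(df))
  } else if (inherits(x, "dysfunction_graph")) {
    df <- x$edges
    info <- list(kind = "dysfunction_graph", alpha = x$alpha, m = x$m,
                 n_nodes = length(x$nodes), n_edges = nrow(df))
  } else {
    stop_dc("x must be an edge_mask or dysfunction_graph")
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_sidecar(path, info)
  invisible(path)
}

#' Read an edge-list TSV
#'
#' @param path TSV with at least `label_i` and `label_j` columns.
#' @return data.frame of edges.
#' @export
read_edge_list <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("label_i", "label_j") %in% names(df)),
              "edge list needs label_i and label_j columns")
  df
}

#' Export a graph for BrainNet Viewer
#'
#' Writes the `.node` file (six whitespace-delimited columns: MNI x, y, z,
#' a colour value, a size value, and the region label) and the `.edge`
#' file (full N x N matrix, signed +1 for increased / -1 for decreased
#' edges).
#'
#' @param graph a [dysfunction_graph()].
#' @param atlas atlas table with `mni_x`, `mni_y`, `mni_z` columns and one
#'   row per graph node (matched by `abbreviation` or `label`).
#' @param node_color named numeric vector (e.g. the [ratio_map()]);
#'   missing nodes get 0.
#' @param node_size named numeric vector (e.g. degree); missing nodes get
#'   0.
#' @param node_path,edge_path output paths.
#' @return invisible list of the two paths.
#' @export
export_brainnet <- function(graph, atlas, node_color = NULL,
                            node_size = NULL, node_path, edge_path) {
  key <- if (all(graph$nodes %in% atlas$abbreviation)) "abbreviation"
         else "label"
  at <- atlas[match(graph$nodes, as.character(atlas[[key]])), , drop = FALSE]
  assert_that(!anyNA(at[[key]]), "graph nodes missing from the atlas")
  coord_cols <- c("mni_x", "mni_y", "mni_z")
  assert_that(all(coord_cols %in% names(atlas)),
              "atlas table has no MNI coordinate columns (mni_x/y/z)")
  bad <- graph$nodes[!complete.cases(at[, coord_cols])]
  if (length(bad) > 0) {
    stop_dc("MNI coordinates missing for region(s): ",
            paste(bad, collapse = ", "))
  }
  col <- setNames(numeric(length(graph$nodes)), graph$nodes)
  if (!is.null(node_color)) col[names(node_color)] <- node_color
  siz <- setNames(numeric(length(graph$nodes)), graph$nodes)
  if (!is.null(node_size)) siz[names(node_size)] <- node_size
  nodes <- data.frame(at$mni_x, at$mni_y, at$mni_z,
                      color = as.numeric(col), size = as.numeric(siz),
                      label = graph$nodes)
  write.table(nodes, node_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  A <- graph_adjacency(graph)
  if (nrow(graph$edges) > 0) {
    i <- match(graph$edges$label_i, graph$nodes)
    j <- match(graph$edges$label_j, graph$nodes)
    s <- ifelse(graph$edges$sign == "increased", 1, -1)
    A[cbind(i, j)] <- s
    A[cbind(j, i)] <- s
  }
  write.table(A, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(list(node = node_path, edge = edge_path))
}

#' Write a generated cohort to disk
#'
#' One TSV per subject (T rows x N labelled columns), the metadata CSV,
#' the ground-truth effect edges as TSV, and the generator configuration
#' echoed as JSON. All files round-trip through [read_timeseries()] /
#' [read_meta()] / [read_edge_list()].
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ts in cohort$timeseries) {
    write_timeseries(ts, file.path(dir, paste0(attr(ts, "subject_id"),
                                               ".tsv")))
  }
  write_meta(cohort$meta, file.path(dir, "meta.csv"))
  te <- cohort$truth$effect_edges
  write.table(te[, c("label_i", "label_j", "delta")],
              file.path(dir, "truth_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  cfg$base_matrix <- NULL  # large; regenerate from seed instead
  cfg$effect_edges <- as.list(cfg$effect_edges)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
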