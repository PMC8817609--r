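TREE_SCHEMA <- "ctifr-tree/1"

#' Write a centerline tree to JSON
#'
#' Serializes to the package's versioned schema `ctifr-tree/1`:
#' `{schema, label, segments: [{id, parent, points: [{x, y, z, r}]}],
#' inlet, outlets}`. Units mm, 0-based ids. Serialization is deterministic,
#' so identical trees produce byte-identical files.
#'
#' @param tree a valid `centerline_tree`.
#' @param path output file path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
write_tree_json <- function(tree, path = NULL) {
  segs <- lapply(tree$segments, function(seg) {
    list(
      id = seg$id,
      parent = if (is.na(seg$parent)) NULL else seg$parent,
      points = lapply(seq_len(nrow(seg$points)), function(i) {
        list(x = seg$points$x[i], y = seg$points$y[i],
             z = seg$points$z[i], r = seg$points$r[i])
      })
    )
  })
  obj <- list(
    schema = TREE_SCHEMA,
    label = tree$label,
    segments = unname(segs),
    inlet = tree$inlet,
    outlets = as.list(tree$outlets)
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(12), null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Read a centerline tree from JSON
#'
#' Parses and validates a `ctifr-tree/1` file. Schema violations and every
#' structural defect that [validate_tree()] detects are raised as invalid
#' parameter errors, so files rejected here are exactly the trees
#' `validate_tree` rejects.
#'
#' @param path file path (or a JSON string).
#' @return a `centerline_tree`.
#' @export
read_tree_json <- function(path) {
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop_invalid("malformed JSON: ", conditionMessage(e))
  )
  if (!identical(obj$schema, TREE_SCHEMA)) {
    stop_invalid("unsupported or missing schema (expected ", TREE_SCHEMA, ")")
  }
  if (is.null(obj$segments) || !length(obj$segments) || is.null(obj$inlet)) {
    stop_invalid("schema requires non-empty 'segments' and an 'inlet' id")
  }
  segs <- lapply(obj$segments, function(sg) {
    if (is.null(sg$id) || is.null(sg$points)) {
      stop_invalid("each segment requires 'id' and 'points'")
    }
    pts <- do.call(rbind, lapply(sg$points, function(p) {
      if (any(vapply(list(p$x, p$y, p$z, p$r), is.null, logical(1)))) {
        stop_invalid("each point requires x, y, z, r")
      }
      data.frame(x = p$x, y = p$y, z = p$z, r = p$r)
    }))
    new_segment(sg$id, pts,
                if (is.null(sg$parent)) NA_integer_ else sg$parent)
  })
  tree <- centerline_tree(segs, obj$inlet,
                          label = if (is.null(obj$label)) "unnamed" else obj$label)
  v <- validate_tree(tree)
  if (length(v)) stop_invalid("invalid tree: ", paste(v, collapse = "; "))
  tree
}

#' Export a tree as legacy ASCII VTK polydata
#'
#' Visualization-only export: one polyline per segment, with the lumen
#' radius attached as point-data scalars. Readable by ParaView and the VTK
#' toolchain.
#'
#' @param tree a `centerline_tree`.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
export_tree_vtk <- function(tree, path) {
  pts <- do.call(rbind, lapply(tree$segments, function(s) s$points))
  counts <- vapply(tree$segments, function(s) nrow(s$points), integer(1))
  offsets <- c(0, cumsum(counts))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("centerline tree", tree$label),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(pts))), con)
  writeLines(sprintf("%.6f %.6f %.6f", pts$x, pts$y, pts$z), con)
  writeLines(sprintf("LINES %d %d", length(counts), sum(counts + 1L)), con)
  for (i in seq_along(counts)) {
    idx <- seq(offsets[i], offsets[i + 1] - 1)
    writeLines(paste(c(counts[i], idx), collapse = " "), con)
  }
  writeLines(c(sprintf("POINT_DATA %d", nrow(pts)),
               "SCALARS radius float 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.6f", pts$r), con)
  invisible(path)
}
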