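#' Coronary centerline trees
#'
#' A `centerline_tree` is the package's geometric model of one epicardial
#' coronary artery: a set of centerline segments, each an ordered polyline of
#' 3D points (mm) with lumen radii (mm), connected into a rooted tree with a
#' single inlet and one outlet per leaf. It stands in for the lumen model
#' reconstructed from CCTA.
#'
#' @param segments list of segments created by [new_segment()].
#' @param inlet integer id of the root (inlet) segment.
#' @param label vessel name (`"LAD"`, `"LCX"`, `"RCA"`, or a synthetic id).
#' @return an object of class `centerline_tree` with fields `segments`
#'   (named by id), `inlet`, `outlets` (leaf segment ids) and `label`.
#' @seealso [validate_tree()], [resample_centerline()], [insert_stenosis()]
#' @export
centerline_tree <- function(segments, inlet, label = "synthetic") {
  ids <- vapply(segments, function(s) s$id, integer(1))
  names(segments) <- as.character(ids)
  parents <- vapply(segments, function(s) {
    if (is.na(s$parent)) NA_integer_ else s$parent
  }, integer(1))
  leaves <- setdiff(ids, parents[!is.na(parents)])
  structure(
    list(
      segments = segments,
      inlet = as.integer(inlet),
      outlets = sort(as.integer(leaves)),
      label = label
    ),
    class = "centerline_tree"
  )
}

#' Create a centerline segment
#'
#' @param id non-negative integer segment id (0-based, matching the JSON
#'   schema).
#' @param points data frame with columns `x`, `y`, `z` (mm) and `r` (lumen
#'   radius, mm), ordered proximal to distal.
#' @param parent id of the parent segment, or `NA` for the root.
#' @return a list of class `centerline_segment`.
#' @export
new_segment <- function(id, points, parent = NA_integer_) {
  stopifnot(is.data.frame(points), all(c("x", "y", "z", "r") %in% names(points)))
  structure(
    list(id = as.integer(id), parent = as.integer(parent),
         points = points[, c("x", "y", "z", "r")]),
    class = "centerline_segment"
  )
}

# Cumulative arclength (mm) along a segment's points, starting at 0.
segment_arclength <- function(points) {
  if (nrow(points) < 2) return(0)
  d <- sqrt(diff(points$x)^2 + diff(points$y)^2 + diff(points$z)^2)
  c(0, cumsum(d))
}

tree_ids <- function(tree) {
  vapply(tree$segments, function(s) s$id, integer(1), USE.NAMES = FALSE)
}

get_segment <- function(tree, id) {
  seg <- tree$segments[[as.character(id)]]
  if (is.null(seg)) stop_invalid("no segment with id ", id)
  seg
}

children_of <- function(tree, id) {
  ids <- tree_ids(tree)
  parents <- vapply(tree$segments, function(s) {
    if (is.na(s$parent)) NA_integer_ else s$parent
  }, integer(1), USE.NAMES = FALSE)
  ids[!is.na(parents) & parents == id]
}

# Segment ids in root-to-leaf (topological) order.
topo_order <- function(tree) {
  out <- integer(0)
  queue <- tree$inlet
  while (length(queue)) {
    id <- queue[1]
    queue <- queue[-1]
    out <- c(out, id)
    queue <- c(queue, children_of(tree, id))
  }
  out
}

#' Validate a centerline tree
#'
#' Checks every structural invariant of a [centerline_tree()]: at least two
#' points per segment, strictly positive radii, strictly increasing
#' arclength (no duplicate points), existing parent references, exactly one
#' root that is the declared inlet, acyclic connectivity from the inlet, and
#' geometric continuity (a child's first point coincides with its parent's
#' last point within `tol` mm).
#'
#' @param tree a `centerline_tree`.
#' @param tol continuity tolerance in mm.
#' @return character vector of human-readable violations; empty if valid.
#' @export
validate_tree <- function(tree, tol = 1e-3) {
  violations <- character(0)
  add <- function(msg) violations <<- c(violations, msg)
  if (!inherits(tree, "centerline_tree")) {
    return("object is not a centerline_tree")
  }
  ids <- tree_ids(tree)
  if (anyDuplicated(ids)) add("duplicate segment ids")
  for (seg in tree$segments) {
    tag <- paste0("segment ", seg$id)
    if (nrow(seg$points) < 2) add(paste0(tag, ": fewer than 2 points"))
    bad_r <- which(!(seg$points$r > 0))
    if (length(bad_r)) {
      add(paste0(tag, ": non-positive radius at point ", bad_r[1]))
    }
    s <- segment_arclength(seg$points)
    if (length(s) > 1 && any(diff(s) <= 0)) {
      add(paste0(tag, ": arclength not strictly increasing (duplicate points)"))
    }
    if (!is.na(seg$parent)) {
      if (!(seg$parent %in% ids)) {
        add(paste0(tag, ": parent ", seg$parent, " does not exist"))
      } else {
        par <- get_segment(tree, seg$parent)
        p_end <- par$points[nrow(par$points), c("x", "y", "z")]
        c_start <- seg$points[1, c("x", "y", "z")]
        gap <- sqrt(sum((as.numeric(p_end) - as.numeric(c_start))^2))
        if (gap > tol) {
          add(paste0(tag, ": start is ", format(gap, digits = 4),
                     " mm from end of parent ", seg$parent))
        }
      }
    }
  }
  roots <- ids[vapply(tree$segments, function(s) is.na(s$parent), logical(1))]
  if (length(roots) != 1) {
    add(paste0("tree has ", length(roots), " roots; expected exactly 1"))
  } else if (roots != tree$inlet) {
    add(paste0("declared inlet ", tree$inlet, " is not the root (", roots, ")"))
  }
  if (length(roots) == 1 && !length(violations)) {
    reached <- topo_order(tree)
    if (length(reached) != length(ids)) {
      add("tree is not connected: some segments unreachable from the inlet")
    }
  }
  leaves <- ids[vapply(ids, function(i) length(children_of(tree, i)) == 0, logical(1))]
  if (!setequal(leaves, tree$outlets)) {
    add("declared outlets do not match the tree's leaves")
  }
  violations
}

#' Resample a tree at uniform arclength spacing
#'
#' Re-discretizes every segment at a uniform spacing no larger than `step`
#' by linear interpolation of position and radius. Endpoints are preserved
#' exactly and the topology is unchanged. This is the discretization on
#' which the pressure integral is evaluated; the default solver step is
#' 0.5 mm.
#'
#' @param tree a valid `centerline_tree`.
#' @param step maximum arclength spacing in mm (> 0).
#' @return the resampled `centerline_tree`.
#' @export
resample_centerline <- function(tree, step = 0.5) {
  if (!is.numeric(step) || length(step) != 1 || !is.finite(step) || step <= 0) {
    stop_invalid("step must be a single positive number")
  }
  segs <- lapply(tree$segments, function(seg) {
    s <- segment_arclength(seg$points)
    total <- s[length(s)]
    n_new <- max(2L, as.integer(ceiling(total / step)) + 1L)
    s_new <- seq(0, total, length.out = n_new)
    pts <- data.frame(
      x = stats::approx(s, seg$points$x, xout = s_new)$y,
      y = stats::approx(s, seg$points$y, xout = s_new)$y,
      z = stats::approx(s, seg$points$z, xout = s_new)$y,
      r = stats::approx(s, seg$points$r, xout = s_new)$y
    )
    # pin endpoints to the originals (interpolation is exact there anyway,
    # up to floating-point)
    pts[1, ] <- seg$points[1, c("x", "y", "z", "r")]
    pts[nrow(pts), ] <- seg$points[nrow(seg$points), c("x", "y", "z", "r")]
    new_segment(seg$id, pts, seg$parent)
  })
  centerline_tree(unname(segs), tree$inlet, tree$label)
}

#' Specify a focal stenosis
#'
#' @param segment_id id of the segment carrying the lesion.
#' @param center_mm lesion center as arclength from the segment start (mm).
#' @param length_mm lesion length (mm, > 0).
#' @param severity percent diameter stenosis DS, in `[0, 100)`.
#' @param profile lesion shape; only `"cosine"` is implemented.
#' @return a list of class `stenosis_spec`.
#' @export
stenosis_spec <- function(segment_id, center_mm, length_mm, severity,
                          profile = "cosine") {
  if (severity < 0 || severity >= 100) stop_invalid("severity must be in [0, 100)")
  if (length_mm <= 0) stop_invalid("lesion length must be > 0")
  profile <- match.arg(profile, "cosine")
  structure(
    list(segment_id = as.integer(segment_id), center_mm = center_mm,
         length_mm = length_mm, severity = severity, profile = profile),
    class = "stenosis_spec"
  )
}

#' Narrow a segment with a smooth focal stenosis
#'
#' Within the lesion window the radius is multiplied by
#' `1 - (DS/100) * w(u)` where `w(u) = (1 + cos(2*pi*u)) / 2` and
#' `u` in `[-1/2, 1/2]` is the normalized offset from the lesion center:
#' the narrowing is maximal (`r_local * (1 - DS/100)`) at the center and
#' vanishes smoothly at the shoulders. Geometry outside the window is
#' untouched.
#'
#' @param tree a `centerline_tree`.
#' @param spec a [stenosis_spec()].
#' @return the modified `centerline_tree`.
#' @export
insert_stenosis <- function(tree, spec) {
  stopifnot(inherits(spec, "stenosis_spec"))
  seg <- get_segment(tree, spec$segment_id)
  s <- segment_arclength(seg$points)
  total <- s[length(s)]
  lo <- spec$center_mm - spec$length_mm / 2
  hi <- spec$center_mm + spec$length_mm / 2
  if (lo < -1e-9 || hi > total + 1e-9) {
    stop_invalid("lesion window [", format(lo), ", ", format(hi),
                 "] mm extends beyond segment ", spec$segment_id,
                 " (length ", format(total), " mm)")
  }
  inside <- s >= lo & s <= hi
  u <- (s[inside] - spec$center_mm) / spec$length_mm
  w <- (1 + cos(2 * pi * u)) / 2
  seg$points$r[inside] <- seg$points$r[inside] * (1 - spec$severity / 100 * w)
  tree$segments[[as.character(spec$segment_id)]] <- seg
  tree
}

#' Percent diameter stenosis of a radius profile
#'
#' Anatomic severity DS% = `(1 - r_min / r_ref) * 100`, where `r_min` is
#' the global radius minimum of the profile and `r_ref` is the largest
#' radius within the 10 mm proximal to `r_min` (falling back to the
#' segment's proximal end when fewer than 10 mm are available). A uniform
#' (or minimum-at-entry) profile scores 0.
#'
#' @param x a `centerline_segment`, or a data frame/list with fields `s`
#'   (arclength, mm) and `r` (radius, mm).
#' @param window_mm proximal reference window (mm).
#' @return DS in percent.
#' @export
percent_diameter_stenosis <- function(x, window_mm = 10) {
  if (inherits(x, "centerline_segment")) {
    s <- segment_arclength(x$points)
    r <- x$points$r
  } else {
    s <- x$s
    r <- x$r
  }
  if (length(r) < 3) stop_invalid("radius profile needs at least 3 points")
  i_min <- which.min(r)
  r_min <- r[i_min]
  in_window <- s >= (s[i_min] - window_mm) & s <= s[i_min]
  r_ref <- max(r[in_window])
  max(0, (1 - r_min / r_ref) * 100)
}

#' Total arclength of every segment
#'
#' @param tree a `centerline_tree`.
#' @return named numeric vector of segment lengths (mm).
#' @export
segment_lengths <- function(tree) {
  vapply(tree$segments, function(seg) {
    s <- segment_arclength(seg$points)
    s[length(s)]
  }, numeric(1))
}

#' @export
print.centerline_tree <- function(x, ...) {
  n_pts <- sum(vapply(x$segments, function(s) nrow(s$points), integer(1)))
  cat(sprintf(
    "<centerline_tree> %s: %d segment(s), %d points, inlet %d, outlets [%s]\n",
    x$label, length(x$segments), n_pts, x$inlet,
    paste(x$outlets, collapse = ", ")
  ))
  invisible(x)
}
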