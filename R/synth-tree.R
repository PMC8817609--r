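# Per-vessel geometric defaults: lengths and proximal radii are typical of
# the three major epicardial vessels on CCTA.
VESSEL_DEFAULTS <- list(
  LAD = list(total_length = 120, inlet_radius = 1.50),
  LCX = list(total_length = 80,  inlet_radius = 1.35),
  RCA = list(total_length = 110, inlet_radius = 1.60)
)

#' Generate a synthetic stenosed coronary tree
#'
#' Builds a main vessel with a linearly tapering lumen and a gentle,
#' seed-controlled 3D curvature, optionally attaches side branches obeying
#' a fixed daughter/parent radius ratio, resamples everything at `step` mm,
#' and applies cosine-profile stenoses via [insert_stenosis()]. The result
#' stands in for the CCTA-reconstructed lumen model and always passes
#' [validate_tree()]. Fully deterministic for a fixed seed.
#'
#' @param vessel_type `"LAD"`, `"LCX"` or `"RCA"`; sets defaults for
#'   `total_length` and `inlet_radius` unless given explicitly.
#' @param total_length main-vessel length (mm).
#' @param inlet_radius proximal lumen radius (mm).
#' @param taper radius loss per mm of arclength (mm/mm).
#' @param n_branches number of side branches (0, 1 or 2 supported).
#' @param branch_ratio daughter/parent radius ratio at each branch ostium.
#' @param branch_length side-branch length (mm).
#' @param stenoses list of lesions, each a list with `center_frac`
#'   (lesion center as a fraction of main-vessel length), `length_mm` and
#'   `severity` (DS%); applied to the main vessel.
#' @param step resampling step (mm).
#' @param seed integer seed controlling curvature and branch placement.
#' @return a valid `centerline_tree`; the lesion-bearing main-vessel
#'   segment id and the lesion's in-segment arclength are attached as
#'   attributes `lesion_segment` / `lesion_center_mm` when a stenosis was
#'   requested.
#' @export
generate_synthetic_tree <- function(vessel_type = "LAD",
                                    total_length = NULL,
                                    inlet_radius = NULL,
                                    taper = 0.002,
                                    n_branches = 2,
                                    branch_ratio = 0.6,
                                    branch_length = 20,
                                    stenoses = list(),
                                    step = 0.5,
                                    seed = 1L) {
  defaults <- VESSEL_DEFAULTS[[vessel_type]]
  if (is.null(defaults)) defaults <- VESSEL_DEFAULTS$LAD
  if (is.null(total_length)) total_length <- defaults$total_length
  if (is.null(inlet_radius)) inlet_radius <- defaults$inlet_radius
  if (total_length <= 0 || inlet_radius <= 0 || taper < 0 || step <= 0) {
    stop_invalid("geometric parameters must be positive")
  }
  r_end <- inlet_radius - taper * total_length
  if (r_end <= 0.3) {
    stop_invalid("taper leaves distal radius ", format(r_end),
                 " mm; must stay above 0.3 mm")
  }
  for (st in stenoses) {
    if (st$severity < 0 || st$severity >= 100) stop_invalid("severity must be in [0, 100)")
  }

  with_seed(seed, {
    # Main centerline: mostly along +x with two low-amplitude transverse
    # harmonics, emulating the gentle epicardial course.
    base_ds <- 0.25
    t <- seq(0, total_length, by = base_ds)
    if (t[length(t)] < total_length) t <- c(t, total_length)
    amp <- stats::runif(2, 1.0, 2.5)
    phase <- stats::runif(2, 0, 2 * pi)
    y <- amp[1] * sin(2 * pi * t / total_length + phase[1])
    z <- amp[2] * sin(4 * pi * t / total_length + phase[2])
    # parametrize radius by true arclength so the taper is per mm of vessel
    s <- c(0, cumsum(sqrt(diff(t)^2 + diff(y)^2 + diff(z)^2)))
    r <- inlet_radius - taper * s
    main <- data.frame(x = t, y = y, z = z, r = r)
    s_total <- s[length(s)]

    # Lesion windows (global arclength on the main vessel), used to keep
    # branch ostia clear of lesions.
    lesion_windows <- lapply(stenoses, function(st) {
      ctr <- st$center_frac * s_total
      c(ctr - st$length_mm / 2 - 3, ctr + st$length_mm / 2 + 3)
    })

    n_branches <- as.integer(n_branches)
    branch_fracs <- numeric(0)
    if (n_branches > 0) {
      cand <- seq_len(n_branches) / (n_branches + 1) +
        stats::runif(n_branches, -0.04, 0.04)
      cand <- pmin(pmax(cand, 0.1), 0.9)
      branch_fracs <- vapply(cand, function(f) {
        sb <- f * s_total
        for (w in lesion_windows) {
          if (sb > w[1] && sb < w[2]) sb <- w[2] + 2  # push past the lesion
        }
        min(sb, 0.92 * s_total) / s_total
      }, numeric(1))
      branch_fracs <- sort(branch_fracs)
    }

    # Split the main polyline at the branch ostia into consecutive segments.
    cut_s <- branch_fracs * s_total
    cut_idx <- vapply(cut_s, function(sc) which.min(abs(s - sc)), integer(1))
    cut_idx <- unique(pmin(pmax(cut_idx, 3L), length(s) - 2L))
    bounds <- c(1L, cut_idx, length(s))
    segs <- list()
    next_id <- 0L
    main_ids <- integer(0)
    prev_id <- NA_integer_
    for (k in seq_len(length(bounds) - 1)) {
      idx <- bounds[k]:bounds[k + 1]
      segs[[length(segs) + 1]] <- new_segment(next_id, main[idx, ], prev_id)
      main_ids <- c(main_ids, next_id)
      prev_id <- next_id
      next_id <- next_id + 1L
    }

    # Side branches: straight runs leaving the ostium at ~50 degrees from
    # the local tangent, tapering at the same rate as the main vessel.
    for (k in seq_along(cut_idx)) {
      i0 <- cut_idx[k]
      origin <- as.numeric(main[i0, c("x", "y", "z")])
      tangent <- as.numeric(main[min(i0 + 1, nrow(main)), c("x", "y", "z")]) - origin
      tangent <- tangent / sqrt(sum(tangent^2))
      # random unit vector orthogonalized against the tangent
      v <- stats::rnorm(3)
      v <- v - sum(v * tangent) * tangent
      v <- v / sqrt(sum(v^2))
      ang <- 50 * pi / 180
      dir <- cos(ang) * tangent + sin(ang) * v
      r0 <- branch_ratio * main$r[i0]
      bl <- min(branch_length, (r0 - 0.35) / max(taper, 1e-9))
      tb <- seq(0, bl, by = base_ds)
      if (tb[length(tb)] < bl) tb <- c(tb, bl)
      pts <- data.frame(
        x = origin[1] + dir[1] * tb,
        y = origin[2] + dir[2] * tb,
        z = origin[3] + dir[3] * tb,
        r = r0 - taper * tb
      )
      segs[[length(segs) + 1]] <- new_segment(next_id, pts, main_ids[k])
      next_id <- next_id + 1L
    }

    tree <- centerline_tree(segs, inlet = 0L,
                            label = paste0(vessel_type, "-synthetic"))
    tree <- resample_centerline(tree, step)

    lesion_segment <- NA_integer_
    lesion_center_mm <- NA_real_
    lesion_length_mm <- NA_real_
    if (length(stenoses)) {
      lens <- segment_lengths(tree)[as.character(main_ids)]
      starts <- c(0, cumsum(lens))[seq_along(main_ids)]
      for (st in stenoses) {
        ctr <- st$center_frac * sum(lens)
        k <- findInterval(ctr, c(0, cumsum(lens)), rightmost.closed = TRUE)
        seg_id <- main_ids[k]
        local_ctr <- ctr - starts[k]
        sp <- stenosis_spec(seg_id, local_ctr, st$length_mm, st$severity)
        tree <- insert_stenosis(tree, sp)
        lesion_segment <- seg_id
        lesion_center_mm <- local_ctr
        lesion_length_mm <- st$length_mm
      }
    }
    attr(tree, "lesion_segment") <- lesion_segment
    attr(tree, "lesion_center_mm") <- lesion_center_mm
    attr(tree, "lesion_length_mm") <- lesion_length_mm
    tree
  })
}
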