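#' Pressure drop over one centerline step
#'
#' Reduced-order loss model for a short step of length `ds` whose
#' cross-section changes from `a_in` to `a_out`:
#' a Poiseuille viscous term `8*pi*mu*Q*ds / A_bar^2` with
#' `A_bar = (a_in + a_out)/2` (exact for a uniform tube, where it reduces
#' to `8*mu*Q*ds/(pi*r^4)`), plus a post-stenotic expansion loss
#' `K_e * (rho/2) * Q^2 * (1/a_in - 1/a_out)^2` applied only where the
#' lumen widens (`a_out > a_in`), as in Young-Tsai-type stenosis models.
#'
#' @param q volumetric flow (m^3/s, >= 0; flow reversal is unsupported).
#' @param a_in,a_out upstream/downstream cross-sectional areas (m^2).
#' @param ds step length (m).
#' @param mu dynamic viscosity (Pa s).
#' @param rho density (kg/m^3).
#' @param k_e expansion-loss coefficient (default 1).
#' @return pressure drop in Pa (>= 0).
#' @export
step_pressure_drop <- function(q, a_in, a_out, ds, mu, rho, k_e = 1) {
  if (any(q < 0)) stop_invalid("negative flow: flow reversal is unsupported")
  if (any(a_in <= 0) || any(a_out <= 0) || any(ds <= 0)) {
    stop_invalid("areas and step length must be positive")
  }
  a_bar <- (a_in + a_out) / 2
  dp <- 8 * pi * mu * q * ds / a_bar^2
  widen <- a_out > a_in
  if (any(widen)) {
    dp[widen] <- dp[widen] +
      k_e * (rho / 2) * q[widen]^2 * (1 / a_in[widen] - 1 / a_out[widen])^2
  }
  dp
}

#' Solve the steady diastolic pressure field on a tree
#'
#' Marches from the inlet to every leaf: the inlet point is at the
#' diastolic aortic pressure, each subsequent point loses
#' [step_pressure_drop()] computed with the segment's flow, and at
#' junctions children inherit the parent's terminal pressure (pressure
#' continuity). The pressure-ratio field `R = P / Pa` is the distributed
#' wave-free Pd/Pa index. Deterministic: no iteration, no randomness.
#'
#' @param tree a valid, resampled `centerline_tree`.
#' @param bc an `assembled_bc` from [assemble_bc()].
#' @param k_e expansion-loss coefficient passed to [step_pressure_drop()].
#' @return a list of class `flow_solution`: per-segment data frames with
#'   columns `s` (mm), `q` (m^3/s), `p` (Pa), `ratio`; plus
#'   `inlet_pressure`, `mode`, and a `settings` snapshot.
#' @export
solve_pressure_field <- function(tree, bc, k_e = 1) {
  stopifnot(inherits(bc, "assembled_bc"))
  pa <- bc$inlet_pressure
  mu <- bc$bc$viscosity
  rho <- bc$bc$density
  entry_p <- stats::setNames(rep(NA_real_, length(tree$segments)),
                             names(tree$segments))
  entry_p[as.character(tree$inlet)] <- pa
  fields <- list()
  for (id in topo_order(tree)) {
    key <- as.character(id)
    seg <- get_segment(tree, id)
    q <- bc$segment_flows[[key]]
    s_mm <- segment_arclength(seg$points)
    a <- pi * (seg$points$r * 1e-3)^2  # mm -> m
    ds <- diff(s_mm) * 1e-3
    n <- length(a)
    dp <- step_pressure_drop(rep(q, n - 1), a[-n], a[-1], ds, mu, rho, k_e)
    p <- entry_p[[key]] - c(0, cumsum(dp))
    if (any(p <= 0)) {
      bad <- which(p <= 0)[1]
      stop_physics("non-positive pressure at segment ", id, ", point ", bad,
                   " (s = ", format(s_mm[bad], digits = 4),
                   " mm): prescribed flow cannot be sustained")
    }
    for (kid in children_of(tree, id)) {
      entry_p[[as.character(kid)]] <- p[n]
    }
    fields[[key]] <- data.frame(s = s_mm, q = q, p = p, ratio = p / pa)
  }
  structure(
    list(fields = fields, inlet_pressure = pa, mode = bc$mode,
         settings = list(k_e = k_e, viscosity = mu, density = rho)),
    class = "flow_solution"
  )
}

# Locate the minimal-radius point: (segment id, arclength, radius).
# When `lesion_segment` is given the search is restricted to it, and
# `window` (arclength range, mm) can further restrict it to the lesion
# extent so the reference point is stable even for near-zero severities.
min_radius_point <- function(tree, lesion_segment = NULL, window = NULL) {
  ids <- if (is.null(lesion_segment)) tree_ids(tree) else lesion_segment
  best <- NULL
  for (id in ids) {
    seg <- get_segment(tree, id)
    s <- segment_arclength(seg$points)
    r <- seg$points$r
    keep <- rep(TRUE, length(r))
    if (!is.null(window) && length(ids) == 1) {
      keep <- s >= window[1] & s <= window[2]
      if (!any(keep)) keep <- rep(TRUE, length(r))
    }
    i <- which(keep)[which.min(r[keep])]
    if (is.null(best) || r[i] < best$r) {
      best <- list(segment = id, s = s[i], r = r[i])
    }
  }
  best
}

# Lesion reference point of a generated tree, using the lesion attributes
# attached by generate_synthetic_tree when available.
lesion_point <- function(tree) {
  les_seg <- attr(tree, "lesion_segment")
  if (is.null(les_seg) || is.na(les_seg)) return(NULL)
  ctr <- attr(tree, "lesion_center_mm")
  len <- attr(tree, "lesion_length_mm")
  window <- if (!is.null(len) && !is.na(len)) c(ctr - len / 2, ctr + len / 2)
  min_radius_point(tree, les_seg, window)
}

# Ratio at a given arclength `target` downstream of (seg_id, s0), following
# the principal (largest-radius) child at each junction and clamping to the
# distal end of the vessel.
ratio_downstream <- function(solution, tree, seg_id, s0, offset_mm) {
  remaining <- offset_mm
  id <- seg_id
  pos <- s0
  repeat {
    f <- solution$fields[[as.character(id)]]
    seg_len <- f$s[nrow(f)]
    if (pos + remaining <= seg_len + 1e-9) {
      target <- min(pos + remaining, seg_len)
      return(list(ratio = stats::approx(f$s, f$ratio, xout = target)$y,
                  segment = id, s = target))
    }
    remaining <- remaining - (seg_len - pos)
    pos <- 0
    kids <- children_of(tree, id)
    if (!length(kids)) {
      return(list(ratio = f$ratio[nrow(f)], segment = id, s = seg_len))
    }
    # principal continuation: child with the largest entry radius
    entry_r <- vapply(kids, function(k) get_segment(tree, k)$points$r[1],
                      numeric(1))
    id <- kids[which.max(entry_r)]
  }
}

#' Read the wave-free index at the pressure-sensor point
#'
#' The virtual sensor sits `offset_mm` (default 30 mm, i.e. ~3 cm)
#' downstream of the lesion's minimal-radius point by arclength, clamped to
#' the vessel's distal end; at bifurcations the largest-radius child is
#' followed. The CT-derived iFR is the pressure ratio `R = Pd/Pa` there,
#' with hemodynamic significance at `<= 0.89` (boundary inclusive). When a
#' hyperemic solution is supplied, the FFR surrogate is its ratio at the
#' same point, significant at `<= 0.80`.
#'
#' @param solution a resting `flow_solution`.
#' @param tree the tree the solution was computed on.
#' @param lesion optional list `list(segment, s)` giving the lesion's
#'   minimal-radius point; auto-detected from the radius profile when
#'   omitted (an error if the tree carries no narrowing).
#' @param hyperemic_solution optional hyperemic `flow_solution`.
#' @param offset_mm sensor offset distal to the lesion (mm).
#' @param cutoff_ifr,cutoff_ffr significance cutoffs.
#' @return a list of class `vessel_result`: `ifr_ct`, `ffr_ct` (or `NA`),
#'   `ds_percent`, `measurement_segment`, `measurement_s`, `significant`,
#'   `significant_ffr`.
#' @export
index_at_measurement_point <- function(solution, tree, lesion = NULL,
                                       hyperemic_solution = NULL,
                                       offset_mm = 30,
                                       cutoff_ifr = 0.89, cutoff_ffr = 0.80) {
  if (is.null(lesion)) {
    lesion_pt <- lesion_point(tree)
    if (is.null(lesion_pt)) {
      lesion_pt <- min_radius_point(tree)
      ds_here <- percent_diameter_stenosis(get_segment(tree, lesion_pt$segment))
      if (ds_here < 1) {
        stop_invalid("no lesion found on the tree and no measurement point given")
      }
    }
  } else {
    lesion_pt <- lesion
  }
  ds <- percent_diameter_stenosis(get_segment(tree, lesion_pt$segment))
  m <- ratio_downstream(solution, tree, lesion_pt$segment, lesion_pt$s, offset_mm)
  ffr <- NA_real_
  if (!is.null(hyperemic_solution)) {
    ffr <- ratio_downstream(hyperemic_solution, tree, lesion_pt$segment,
                            lesion_pt$s, offset_mm)$ratio
  }
  structure(
    list(ifr_ct = m$ratio, ffr_ct = ffr, ds_percent = ds,
         measurement_segment = m$segment, measurement_s = m$s,
         significant = m$ratio <= cutoff_ifr,
         significant_ffr = if (is.na(ffr)) NA else ffr <= cutoff_ffr),
    class = "vessel_result"
  )
}
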