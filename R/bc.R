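#' Boundary conditions and physical constants for one simulation
#'
#' Bundles the patient parameters, the blood model, and the coefficients of
#' the boundary-condition scheme: inlet pressure equals the diastolic
#' aortic pressure, inlet flow comes from an allometric relation between
#' subtended myocardial mass and resting flow, and outlet flows are split
#' between branches by Murray's law on lumen diameters.
#'
#' @param pa_diastolic diastolic aortic root pressure (mmHg).
#' @param lv_mass myocardial mass subtended by the simulated tree (g).
#' @param flow_coeff allometric coefficient c (mL/min per g^alpha). The
#'   default 3.41 with `flow_exp = 0.75` yields ~246 mL/min of total
#'   resting coronary flow for a 300 g heart, a physiologically plausible
#'   calibration; both are configurable and are conventions of this
#'   package, not measured quantities.
#' @param flow_exp allometric exponent alpha (3/4-power scaling).
#' @param murray_exp Murray exponent gamma (classical value 3).
#' @param hyperemic_factor flow multiplier h (>= 1) for the hyperemic
#'   (FFR-surrogate) solve; ~3 matches typical adenosine hyperemia.
#' @param density blood density (kg/m^3).
#' @param viscosity blood dynamic viscosity (Pa s).
#' @return a list of class `boundary_conditions`.
#' @export
boundary_conditions <- function(pa_diastolic = 80,
                                lv_mass = 120,
                                flow_coeff = 3.41,
                                flow_exp = 0.75,
                                murray_exp = 3,
                                hyperemic_factor = 3,
                                density = 1056,
                                viscosity = 0.0035) {
  if (pa_diastolic <= 0) stop_invalid("pa_diastolic must be > 0")
  if (lv_mass <= 0) stop_invalid("lv_mass must be > 0")
  if (flow_coeff <= 0) stop_invalid("flow_coeff must be > 0")
  if (murray_exp <= 0) stop_invalid("murray_exp must be > 0")
  if (hyperemic_factor < 1) stop_invalid("hyperemic_factor must be >= 1")
  if (density <= 0 || viscosity <= 0) stop_invalid("density and viscosity must be > 0")
  structure(
    list(pa_diastolic = pa_diastolic, lv_mass = lv_mass,
         flow_coeff = flow_coeff, flow_exp = flow_exp,
         murray_exp = murray_exp, hyperemic_factor = hyperemic_factor,
         density = density, viscosity = viscosity),
    class = "boundary_conditions"
  )
}

#' Resting inlet flow from subtended myocardial mass
#'
#' Allometric mass-flow relation `Q = c * m^alpha` (mL/min), strictly
#' increasing in mass.
#'
#' @param lv_mass subtended myocardial mass (g, > 0).
#' @param flow_coeff coefficient c (mL/min per g^alpha).
#' @param flow_exp exponent alpha.
#' @return flow in mL/min.
#' @export
inlet_flow_from_mass <- function(lv_mass, flow_coeff = 3.41, flow_exp = 0.75) {
  if (!is.numeric(lv_mass) || any(lv_mass <= 0)) {
    stop_invalid("lv_mass must be positive")
  }
  flow_coeff * lv_mass^flow_exp
}

#' Split a flow between outlets by Murray's law
#'
#' `Q_i = Q_total * d_i^gamma / sum_j d_j^gamma`. The last outlet absorbs
#' the floating-point residual so the flows sum back to `q_total` to within
#' one unit in the last place.
#'
#' @param q_total total flow (any unit; the split is scale-free).
#' @param diameters outlet lumen diameters (mm, all > 0).
#' @param murray_exp exponent gamma (classical Murray's law: 3).
#' @return per-outlet flows, same unit and order as the inputs.
#' @export
murray_outlet_split <- function(q_total, diameters, murray_exp = 3) {
  if (!length(diameters)) stop_invalid("at least one outlet diameter required")
  if (any(!is.finite(diameters)) || any(diameters <= 0)) {
    stop_invalid("outlet diameters must be positive")
  }
  w <- diameters^murray_exp
  q <- q_total * w / sum(w)
  n <- length(q)
  q[n] <- q_total - sum(q[-n])
  q
}

# Diameter used by the Murray split for one outlet segment: twice the mean
# radius over its distal `window_mm` of arclength (damps discretization
# noise at the cut plane).
outlet_diameter <- function(seg, window_mm = 3) {
  s <- segment_arclength(seg$points)
  total <- s[length(s)]
  sel <- s >= (total - window_mm)
  2 * mean(seg$points$r[sel])
}

#' Assemble boundary conditions on a tree
#'
#' Computes the inlet flow from the mass-flow relation (times the hyperemic
#' factor in hyperemic mode), splits it between the tree's outlets by
#' Murray's law on outlet diameters (2x the mean lumen radius over each
#' outlet's distal 3 mm), and propagates flows upstream so that every
#' internal segment carries exactly the sum of its downstream outlet flows.
#' Flow conservation at every junction is exact by construction.
#'
#' @param tree a valid `centerline_tree`.
#' @param bc a [boundary_conditions()] object.
#' @param mode `"resting"` or `"hyperemic"`.
#' @return a list of class `assembled_bc`: `segment_flows` (named, m^3/s),
#'   `outlet_flows` (named, m^3/s), `inlet_flow` (m^3/s), `inlet_pressure`
#'   (Pa, SI; converted at 1 mmHg = 133.322 Pa), `mode`, and `bc`.
#' @export
assemble_bc <- function(tree, bc, mode = c("resting", "hyperemic")) {
  mode <- match.arg(mode)
  q_in_ml_min <- inlet_flow_from_mass(bc$lv_mass, bc$flow_coeff, bc$flow_exp)
  if (mode == "hyperemic") q_in_ml_min <- q_in_ml_min * bc$hyperemic_factor
  q_in <- q_in_ml_min * 1e-6 / 60  # mL/min -> m^3/s

  out_ids <- tree$outlets
  d_out <- vapply(out_ids, function(i) outlet_diameter(get_segment(tree, i)),
                  numeric(1))
  q_out <- murray_outlet_split(q_in, d_out, bc$murray_exp)
  names(q_out) <- as.character(out_ids)

  # segment flow = sum of flows of outlets in its subtree
  ids <- tree_ids(tree)
  seg_q <- stats::setNames(numeric(length(ids)), as.character(ids))
  for (id in rev(topo_order(tree))) {
    kids <- children_of(tree, id)
    key <- as.character(id)
    if (!length(kids)) {
      seg_q[key] <- q_out[key]
    } else {
      seg_q[key] <- sum(seg_q[as.character(kids)])
    }
  }
  structure(
    list(segment_flows = seg_q, outlet_flows = q_out, inlet_flow = q_in,
         inlet_pressure = bc$pa_diastolic * MMHG_TO_PA, mode = mode, bc = bc),
    class = "assembled_bc"
  )
}
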