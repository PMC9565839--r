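# 1D conducting-airway surrogate: per-branch hydraulic diameters, laminar
# Poiseuille pressure drops (airway resistance), and analytic deposition
# efficiencies (inertial impaction, gravitational sedimentation, Brownian
# diffusion) propagated over a rooted branching tree for sub-micron aerosol.
#
# Units: branch geometry in mm, flows in mL/s; conversions to SI are internal.

MU_AIR <- 1.81e-5      # dynamic viscosity of air, Pa s
KB <- 1.380649e-23     # Boltzmann constant, J/K
MFP_AIR <- 0.066e-6    # mean free path of air at ambient conditions, m

#' Airway tree
#'
#' Constructs a rooted branching airway tree from a branch table. Each branch
#' carries its length, lumen cross-section area and perimeter, generation
#' number and lobe label (`LUL`, `LLL`, `RUL`, `RML`, `RLL` or `central`).
#'
#' @param branches data frame with columns `id`, `parent` (NA for the root),
#'   `length_mm`, `area_mm2`, `perimeter_mm`, `generation`, `lobe`.
#' @return object of class `airway_tree`.
#' @export
airway_tree <- function(branches) {
  need <- c("id", "parent", "length_mm", "area_mm2", "perimeter_mm",
            "generation", "lobe")
  stop_if(!all(need %in% names(branches)), "branch table must have columns: %s",
          paste(need, collapse = ", "))
  branches$id <- as.character(branches$id)
  branches$parent <- as.character(branches$parent)
  stop_if(anyDuplicated(branches$id) > 0, "duplicate branch ids")
  root <- branches$id[is.na(branches$parent)]
  stop_if(length(root) != 1L, "tree must have exactly one root")
  stop_if(!all(stats::na.omit(branches$parent) %in% branches$id),
          "a parent id is not a branch")
  stop_if(any(branches$length_mm <= 0) || any(branches$area_mm2 <= 0) ||
            any(branches$perimeter_mm <= 0), "lengths, areas, perimeters must be > 0")
  nch <- table(factor(branches$parent, levels = branches$id))
  stop_if(any(nch > 2), "branch with more than 2 children")
  # reachability from root (acyclicity + connectedness)
  seen <- root; frontier <- root
  while (length(frontier)) {
    frontier <- branches$id[!is.na(branches$parent) & branches$parent %in% frontier]
    stop_if(any(frontier %in% seen), "tree contains a cycle")
    seen <- c(seen, frontier)
  }
  stop_if(length(seen) != nrow(branches), "tree is disconnected")
  structure(list(branches = branches, root = root), class = "airway_tree")
}

#' @export
print.airway_tree <- function(x, ...) {
  b <- x$branches
  cat(sprintf("airway_tree: %d branches, %d generations, root '%s'\n",
              nrow(b), max(b$generation) + 1L, x$root))
  cat(sprintf("  terminal branches: %d; lobes: %s\n",
              sum(!(b$id %in% b$parent)),
              paste(sort(unique(b$lobe)), collapse = ", ")))
  invisible(x)
}

#' Total lumen volume of an airway tree in mL
#'
#' Branches are treated as cylinders (length times lumen area).
#' @param tree an [airway_tree].
#' @export
airway_tree_volume <- function(tree) {
  stopifnot(inherits(tree, "airway_tree"))
  sum(tree$branches$length_mm * tree$branches$area_mm2) / 1000
}

#' Hydraulic diameter of an airway lumen
#'
#' \eqn{D_h = 4 A / P}; equals the geometric diameter for a circular lumen.
#'
#' @param area lumen cross-section area, mm^2.
#' @param perimeter lumen perimeter, mm.
#' @return hydraulic diameter, mm.
#' @export
hydraulic_diameter <- function(area, perimeter) {
  stop_if(any(!is.finite(area)) || any(!is.finite(perimeter)) ||
            any(area <= 0) || any(perimeter <= 0),
          "area and perimeter must be positive")
  4 * area / perimeter
}

#' Sinusoidal breathing waveform
#'
#' Tidal volume is 7 mL per kg body weight; inspiratory flow is the half-sine
#' \eqn{Q(t) = Q_p \sin(\pi t / T_{insp})} on \eqn{[0, T_{insp}]} with
#' \eqn{T_{insp} = 2 \cdot} `time_to_peak`, and
#' \eqn{Q_p = \pi V_T / (2 T_{insp})} so the half-sine integrates exactly to
#' the tidal volume. The default timing (peak inspiration at 1.2 s, breath
#' period 4.8 s) treats the period as the full cycle, so inspiration lasts
#' 2.4 s.
#'
#' @param weight body weight, kg.
#' @param period_s full breath period, s.
#' @param time_to_peak_s time of peak inspiratory flow, s.
#' @param ml_per_kg tidal volume per body weight, mL/kg.
#' @return object of class `breath_waveform`: `tidal_volume_ml`, `period_s`,
#'   `t_insp_s`, `peak_flow_mls`, and `flow(t)` in mL/s.
#' @export
breathing_waveform <- function(weight, period_s = 4.8, time_to_peak_s = 1.2,
                               ml_per_kg = 7) {
  stop_if(!is.finite(weight) || weight <= 0, "weight must be positive")
  stop_if(time_to_peak_s <= 0 || period_s < 2 * time_to_peak_s,
          "need 0 < 2*time_to_peak <= period")
  vt <- ml_per_kg * weight
  t_insp <- 2 * time_to_peak_s
  qp <- pi * vt / (2 * t_insp)
  flow <- function(t) ifelse(t >= 0 & t <= t_insp, qp * sin(pi * t / t_insp), 0)
  structure(list(tidal_volume_ml = vt, period_s = period_s, t_insp_s = t_insp,
                 time_to_peak_s = time_to_peak_s, peak_flow_mls = qp, flow = flow),
            class = "breath_waveform")
}

# flow of every branch given inlet flow and a split rule
branch_flows <- function(tree, inlet_flow_mls, split_rule = c("symmetric", "area")) {
  split_rule <- match.arg(split_rule)
  b <- tree$branches
  flows <- stats::setNames(rep(NA_real_, nrow(b)), b$id)
  flows[tree$root] <- inlet_flow_mls
  ord <- order(b$generation)
  for (i in ord) {
    id <- b$id[i]
    kids <- b$id[!is.na(b$parent) & b$parent == id]
    if (!length(kids)) next
    w <- if (split_rule == "area") {
      a <- b$area_mm2[match(kids, b$id)]; a / sum(a)
    } else rep(1 / length(kids), length(kids))
    flows[kids] <- flows[id] * w
  }
  flows
}

#' Poiseuille pressure drops along an airway tree
#'
#' Laminar fully developed flow: per branch
#' \eqn{\Delta P = 128 \mu L Q / (\pi D_h^4)} with air viscosity
#' \eqn{\mu = 1.81 \times 10^{-5}} Pa s; branch flows descend from the inlet
#' flow by the split rule (equal split between siblings, or lumen-area
#' weighted). Cumulative pressures along root-to-branch paths quantify airway
#' resistance.
#'
#' @param tree an [airway_tree].
#' @param inlet_flow_mls flow at the tree inlet, mL/s (e.g. peak inspiratory
#'   flow of a [breathing_waveform]).
#' @param split_rule `"symmetric"` or `"area"`.
#' @return data frame per branch: flow, hydraulic diameter, `dp_pa` (branch
#'   pressure drop) and `path_dp_pa` (cumulative drop from the inlet).
#' @export
pressure_drop <- function(tree, inlet_flow_mls, split_rule = "symmetric") {
  stopifnot(inherits(tree, "airway_tree"))
  stop_if(!is.finite(inlet_flow_mls) || inlet_flow_mls <= 0,
          "inlet flow must be positive")
  b <- tree$branches
  q <- branch_flows(tree, inlet_flow_mls, split_rule)
  dh_m <- hydraulic_diameter(b$area_mm2, b$perimeter_mm) * 1e-3
  L_m <- b$length_mm * 1e-3
  q_m3 <- q[b$id] * 1e-6
  dp <- 128 * MU_AIR * L_m * q_m3 / (pi * dh_m^4)
  path <- stats::setNames(rep(0, nrow(b)), b$id)
  for (i in order(b$generation)) {
    id <- b$id[i]
    up <- if (is.na(b$parent[i])) 0 else path[b$parent[i]]
    path[id] <- up + dp[i]
  }
  data.frame(id = b$id, generation = b$generation, lobe = b$lobe,
             flow_mls = unname(q[b$id]), dh_mm = dh_m * 1e3,
             dp_pa = unname(dp), path_dp_pa = unname(path[b$id]),
             resistance_pa_s_ml = unname(dp) / unname(q[b$id]),
             stringsAsFactors = FALSE)
}

#' Aerosol mechanics of a spherical particle
#'
#' Cunningham slip correction, gravitational settling velocity and Brownian
#' diffusivity for a spherical particle in ambient air.
#'
#' @param diameter_um particle diameter, micrometres.
#' @param density_g_cm3 particle density, g/cm^3.
#' @param temperature_k air temperature, K.
#' @return list: `slip`, `settling_mps`, `diffusivity_m2s`.
#' @export
particle_mechanics <- function(diameter_um, density_g_cm3 = 1,
                               temperature_k = 293.15) {
  stop_if(!is.finite(diameter_um) || diameter_um <= 0 ||
            !is.finite(density_g_cm3) || density_g_cm3 <= 0,
          "particle diameter and density must be positive")
  d <- diameter_um * 1e-6
  rho <- density_g_cm3 * 1000
  kn <- 2 * MFP_AIR / d
  cc <- 1 + kn * (1.257 + 0.4 * exp(-1.1 / kn))
  tau <- rho * d^2 * cc / (18 * MU_AIR)   # relaxation time, s
  vs <- tau * 9.80665
  db <- KB * temperature_k * cc / (3 * pi * MU_AIR * d)
  list(slip = cc, relax_time_s = tau, settling_mps = vs, diffusivity_m2s = db)
}

#' Per-branch deposition efficiencies
#'
#' Analytic single-branch efficiencies for laminar tube flow:
#' \itemize{
#' \item impaction: bend-entry fit
#'   \eqn{\eta_I = 1 - \frac{2}{\pi}\arccos(\theta\,Stk) +
#'   \frac{1}{\pi}\sin(2\arccos(\theta\,Stk))} for \eqn{\theta Stk < 1}
#'   (else 1), \eqn{Stk = \rho_p d_p^2 C_c \bar u / (18 \mu D_h)},
#'   branching angle \eqn{\theta} in radians; zero for the root branch,
#'   which has no upstream bifurcation;
#' \item sedimentation: the exact laminar parabolic-profile result
#'   \eqn{\eta_S = \frac{2}{\pi}\left[2\kappa\sqrt{1-\kappa^{2/3}} -
#'   \kappa^{1/3}\sqrt{1-\kappa^{2/3}} + \arcsin(\kappa^{1/3})\right]},
#'   \eqn{\kappa = 3 v_s L \cos\phi / (8 R \bar u)} clipped to 1, gravity
#'   angle \eqn{\phi} from the tube-normal plane;
#' \item diffusion: Ingham's laminar solution in
#'   \eqn{\Delta = \pi D_B L / (4 Q)}.
#' }
#' Mechanisms combine as \eqn{\eta = 1 - (1-\eta_I)(1-\eta_S)(1-\eta_D)}.
#'
#' @param length_mm,dh_mm branch length and hydraulic diameter, mm.
#' @param flow_mls branch flow, mL/s.
#' @param particle a [particle_mechanics] result.
#' @param theta_rad branching angle for impaction, radians.
#' @param gravity_angle_rad branch inclination from horizontal, radians
#'   (0 = horizontal tube, full settling cross-flow).
#' @param is_root logical: suppress the impaction term.
#' @return list of `impaction`, `sedimentation`, `diffusion`, `combined`.
#' @export
branch_efficiencies <- function(length_mm, dh_mm, flow_mls, particle,
                                theta_rad = pi / 4, gravity_angle_rad = pi / 4,
                                is_root = FALSE) {
  stop_if(length_mm <= 0 || dh_mm <= 0 || flow_mls <= 0, "non-physical branch")
  L <- length_mm * 1e-3
  dh <- dh_mm * 1e-3
  q <- flow_mls * 1e-6
  ubar <- q / (pi * dh^2 / 4)

  # impaction (Stokes number fit)
  eta_i <- 0
  if (!is_root) {
    stk <- particle$relax_time_s * ubar / dh
    x <- theta_rad * stk
    eta_i <- if (x >= 1) 1 else 1 - 2 / pi * acos(x) + sin(2 * acos(x)) / pi
  }

  # sedimentation (Pich, laminar parabolic profile)
  kappa <- min(1, 3 * particle$settling_mps * L * cos(gravity_angle_rad) /
                 (8 * (dh / 2) * ubar))
  eta_s <- if (kappa <= 0) 0 else
    2 / pi * (2 * kappa * sqrt(1 - kappa^(2 / 3)) -
                kappa^(1 / 3) * sqrt(1 - kappa^(2 / 3)) + asin(kappa^(1 / 3)))

  # diffusion (Ingham)
  delta <- pi * particle$diffusivity_m2s * L / (4 * q)
  eta_d <- 1 - 0.819 * exp(-14.63 * delta) - 0.0976 * exp(-89.22 * delta) -
    0.0325 * exp(-228 * delta) - 0.0509 * exp(-125.9 * delta^(2 / 3))
  eta_d <- min(1, max(0, eta_d))

  eta_i <- min(1, max(0, eta_i)); eta_s <- min(1, max(0, eta_s))
  list(impaction = eta_i, sedimentation = eta_s, diffusion = eta_d,
       combined = 1 - (1 - eta_i) * (1 - eta_s) * (1 - eta_d))
}

#' 1D deposition over a conducting airway tree
#'
#' Quasi-steady transport of sub-micron particles at the peak-inspiratory
#' flow: the entering aerosol fraction is propagated from the root towards the
#' leaves with flow-split weights; each branch retains
#' `entering * combined efficiency` and passes the rest on. The fraction
#' leaving the terminal branches is the escape fraction (it proceeds beyond
#' the conducting tree); branch fractions and escape sum to 1 exactly.
#'
#' @param tree an [airway_tree].
#' @param waveform a [breathing_waveform]; its peak flow drives the tree.
#' @param diameter_um,density_g_cm3 particle diameter (default 0.5) and
#'   density (default 1).
#' @param split_rule flow split, `"symmetric"` or `"area"`.
#' @param theta_rad,gravity_angle_rad impaction and gravity angles (radians).
#' @param mechanisms character subset of
#'   `c("impaction", "sedimentation", "diffusion")` to enable.
#' @return object of class `deposition_result`: per-branch data frame (`df` =
#'   deposition fraction), `total_df`, `escape`.
#' @export
deposition_1d <- function(tree, waveform, diameter_um = 0.5, density_g_cm3 = 1,
                          split_rule = "symmetric", theta_rad = pi / 4,
                          gravity_angle_rad = pi / 4,
                          mechanisms = c("impaction", "sedimentation", "diffusion")) {
  stopifnot(inherits(tree, "airway_tree"), inherits(waveform, "breath_waveform"))
  part <- particle_mechanics(diameter_um, density_g_cm3)
  if (!"sedimentation" %in% mechanisms) part$settling_mps <- 0
  if (!"diffusion" %in% mechanisms) part$diffusivity_m2s <- 0
  b <- tree$branches
  q <- branch_flows(tree, waveform$peak_flow_mls, split_rule)
  dh <- hydraulic_diameter(b$area_mm2, b$perimeter_mm)
  eta <- vapply(seq_len(nrow(b)), function(i) {
    e <- branch_efficiencies(b$length_mm[i], dh[i], q[b$id[i]], part,
                             theta_rad = theta_rad,
                             gravity_angle_rad = gravity_angle_rad,
                             is_root = is.na(b$parent[i]))
    if (!"impaction" %in% mechanisms) e$impaction <- 0
    1 - (1 - e$impaction) * (1 - e$sedimentation) * (1 - e$diffusion)
  }, 0)
  names(eta) <- b$id
  entering <- stats::setNames(rep(0, nrow(b)), b$id)
  entering[tree$root] <- 1
  escape <- 0
  df <- entering
  for (i in order(b$generation)) {
    id <- b$id[i]
    df[id] <- unname(entering[id] * eta[id])
    passed <- entering[id] - df[id]
    kids <- b$id[!is.na(b$parent) & b$parent == id]
    if (length(kids)) {
      w <- q[kids] / sum(q[kids])
      entering[kids] <- entering[kids] + passed * w
    } else {
      escape <- escape + unname(passed)
    }
  }
  res <- data.frame(id = b$id, generation = b$generation, lobe = b$lobe,
                    flow_mls = unname(q[b$id]), dh_mm = dh,
                    efficiency = unname(eta[b$id]),
                    entering = unname(entering[b$id]), df = unname(df[b$id]),
                    stringsAsFactors = FALSE)
  structure(list(branches = res, total_df = sum(df), escape = escape,
                 particle_um = diameter_um), class = "deposition_result")
}

#' @export
print.deposition_result <- function(x, ...) {
  cat(sprintf("1D deposition, %.2g um particles: total conducting DF %.4f, escape %.4f\n",
              x$particle_um, x$total_df, x$escape))
  invisible(x)
}

#' Read/write airway trees as CSV or JSON
#'
#' One branch per row/record with the columns of [airway_tree].
#' @param tree an [airway_tree].
#' @param path file path ending in `.csv` or `.json`.
#' @export
write_airway_tree <- function(tree, path) {
  stopifnot(inherits(tree, "airway_tree"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(tree$branches, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(tree$branches, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_airway_tree
#' @export
read_airway_tree <- function(path) {
  b <- if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  b$parent[b$parent %in% c("", "NA")] <- NA_character_
  airway_tree(b)
}
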