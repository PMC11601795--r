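#' Vessel specification
#'
#' One vessel of a network: generation label, stretched length, load-free
#' outer diameter, thickness-to-mean-radius ratio and axial discretization.
#'
#' @param generation Integer generation label (0 = root).
#' @param L_cm Stretched vessel length, cm (> 0).
#' @param Do_um Load-free outer diameter, micrometres (> 0).
#' @param hw Thickness-to-mean-radius ratio, 0 < hw < 1.
#' @param n_elements Number of axial elements (default 2).
#' @return A one-row tibble.
#' @export
vessel_spec <- function(generation, L_cm, Do_um, hw, n_elements = 2L) {
  stopifnot(L_cm > 0, Do_um > 0, hw > 0, hw < 1, n_elements >= 1L)
  tibble(generation = as.integer(generation), L_cm = L_cm, Do_um = Do_um,
         hw = hw, n_elements = as.integer(n_elements))
}

#' Build a symmetric bifurcating arterial tree
#'
#' Starting from a root vessel, each generation branches into two identical
#' daughters. Daughter diameters follow from the parent-to-daughters area
#' ratio: `Do_daughter = Do_parent * sqrt(area_ratio / 2)`. Wall thickness
#' ratios of the successive generations are scaled relative to the root by
#' `hw_scaling`.
#'
#' @param root A [vessel_spec()] for the root (generation 0) vessel.
#' @param generations Total number of generations (>= 1; 4 gives 15 vessels).
#' @param area_ratio Total daughter-to-parent area ratio (default 1.35).
#' @param hw_scaling Per-generation scaling of the root `hw` for generations
#'   1, 2, ... (default `c(0.9, 0.8, 0.7)`).
#' @param lengths Vessel lengths per generation, cm (length `generations`);
#'   defaults to the root length scaled by 0.75 per generation.
#' @return A `myoflow_topology`: a tibble with one row per vessel (columns
#'   `vessel`, `generation`, `parent`, `L_cm`, `Do_um`, `hw`, `n_elements`)
#'   plus boundary attributes added by [attach_boundaries()].
#' @export
build_symmetric_tree <- function(root, generations = 4L, area_ratio = 1.35,
                                 hw_scaling = c(0.9, 0.8, 0.7),
                                 lengths = NULL) {
  stopifnot(area_ratio > 0, generations >= 1L)
  generations <- as.integer(generations)
  if (is.null(lengths)) lengths <- root$L_cm * 0.75^(seq_len(generations) - 1L)
  stopifnot(length(lengths) == generations)
  hw_all <- c(1, hw_scaling)
  if (length(hw_all) < generations)
    abort("`hw_scaling` must cover generations 1..(generations - 1).",
          class = "myoflow_config_error")
  ratio <- sqrt(area_ratio / 2)
  rows <- list()
  id <- 0L
  for (g in seq_len(generations) - 1L) {
    n_g <- 2L^g
    Do_g <- root$Do_um * ratio^g
    hw_g <- root$hw * hw_all[g + 1L]
    for (i in seq_len(n_g)) {
      id <- id + 1L
      parent <- if (g == 0L) NA_integer_ else {
        # vessels are numbered breadth-first; parent of the i-th vessel of
        # generation g is the ceiling(i/2)-th vessel of generation g-1
        (2L^(g - 1L) - 1L) + as.integer(ceiling(i / 2))
      }
      rows[[id]] <- tibble(vessel = id, generation = g, parent = parent,
                           L_cm = lengths[g + 1L], Do_um = Do_g, hw = hw_g,
                           n_elements = root$n_elements)
    }
  }
  topo <- dplyr::bind_rows(rows)
  class(topo) <- c("myoflow_topology", class(topo))
  validate_topology(topo)
  topo
}

#' Default symmetric middle-cerebral-artery tree
#'
#' The bundled 4-generation network: a rat middle cerebral artery (load-free
#' outer diameter 135 um) branching symmetrically with parent-to-daughters
#' area ratio 1.35 and thickness ratios scaled by 0.9/0.8/0.7 for G1-G3.
#' Lengths (0.40, 0.30, 0.20, 0.15 cm) and the root thickness ratio
#' (hw = 0.20) are repository defaults chosen from typical rodent cerebral
#' morphology; both are plain arguments.
#'
#' @param Do0_um Root load-free outer diameter, um.
#' @param hw0 Root thickness-to-mean-radius ratio.
#' @param lengths Per-generation lengths, cm.
#' @param n_elements Axial elements per vessel.
#' @return A `myoflow_topology` with boundaries attached ([attach_boundaries()]
#'   defaults: Pout 50 mmHg, Pext 10 mmHg, characteristic-impedance outlets).
#' @export
default_mca_tree <- function(Do0_um = 135, hw0 = 0.20,
                             lengths = c(0.40, 0.30, 0.20, 0.15),
                             n_elements = 2L) {
  topo <- build_symmetric_tree(
    vessel_spec(0L, lengths[1], Do0_um, hw0, n_elements),
    generations = length(lengths), lengths = lengths)
  attach_boundaries(topo)
}

#' Attach boundary conditions to a topology
#'
#' Marks the root inlet (a pressure signal is supplied at run time), sets the
#' outlet pressure and the external pressure, and selects how the terminal
#' impedances are computed. With `Z_mode = "characteristic"` each terminal
#' carries `Z = rho c / A` evaluated from the initial area and compliance, so
#' outgoing waves are absorbed; `"none"` imposes the outlet pressure directly;
#' a numeric value fixes `Z` (dyn s / cm^5) on every terminal.
#'
#' @param topology A `myoflow_topology`.
#' @param Pout_mmHg Outlet pressure, mmHg (default 50).
#' @param Pext_mmHg External (tissue) pressure, mmHg (default 10).
#' @param Z_mode `"characteristic"`, `"none"`, or a single numeric impedance.
#' @return The topology with boundary attributes set.
#' @export
attach_boundaries <- function(topology, Pout_mmHg = 50, Pext_mmHg = 10,
                              Z_mode = "characteristic") {
  validate_topology(topology)
  if (is.character(Z_mode)) Z_mode <- match.arg(Z_mode, c("characteristic", "none"))
  else stopifnot(is.numeric(Z_mode), length(Z_mode) == 1L, Z_mode >= 0)
  attr(topology, "boundaries") <- list(Pout_mmHg = Pout_mmHg,
                                       Pext_mmHg = Pext_mmHg, Z_mode = Z_mode)
  topology
}

boundaries_of <- function(topology) {
  b <- attr(topology, "boundaries")
  if (is.null(b)) b <- list(Pout_mmHg = 50, Pext_mmHg = 10,
                            Z_mode = "characteristic")
  b
}

#' Terminal vessels of a topology
#'
#' @param topology A `myoflow_topology`.
#' @return Integer ids of the vessels with no daughters (each carries an
#'   outlet attachment).
#' @export
terminal_vessels <- function(topology) {
  setdiff(topology$vessel, topology$parent[!is.na(topology$parent)])
}

validate_topology <- function(topology) {
  need <- c("vessel", "generation", "parent", "L_cm", "Do_um", "hw", "n_elements")
  if (!all(need %in% names(topology)))
    abort("Topology is missing required columns.", class = "myoflow_topology_error")
  if (sum(is.na(topology$parent)) != 1L)
    abort("Topology must have exactly one root vessel.",
          class = "myoflow_topology_error")
  kids <- table(topology$parent[!is.na(topology$parent)])
  if (length(kids) && any(kids != 2L))
    abort("Every branching vessel must have exactly two daughters.",
          class = "myoflow_topology_error")
  ok_parent <- is.na(topology$parent) | topology$parent %in% topology$vessel
  if (!all(ok_parent))
    abort("Dangling parent reference.", class = "myoflow_topology_error")
  invisible(topology)
}

# Per-vessel wall geometry derived from the load-free measurements.
vessel_geometries <- function(topology, k_omega = 1, lambda_z = 1, n_layers = 5) {
  purrr::map(seq_len(nrow(topology)), function(i)
    load_free_geometry(topology$Do_um[i], topology$hw[i], k_omega = k_omega,
                       lambda_z = lambda_z, n_layers = n_layers))
}

#' Export / import a topology as JSON
#'
#' @param topology A `myoflow_topology`.
#' @param path File path.
#' @return `topology_to_json()` returns `path` invisibly;
#'   `topology_from_json()` returns the topology.
#' @export
topology_to_json <- function(topology, path) {
  obj <- list(vessels = as.data.frame(topology),
              boundaries = boundaries_of(topology))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname topology_to_json
#' @export
topology_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- obj$vessels
  v$parent[vapply(v$parent, is.null, logical(1))] <- NA_integer_
  topo <- tibble(vessel = as.integer(v$vessel),
                 generation = as.integer(v$generation),
                 parent = as.integer(unlist(v$parent)),
                 L_cm = as.numeric(v$L_cm), Do_um = as.numeric(v$Do_um),
                 hw = as.numeric(v$hw),
                 n_elements = as.integer(v$n_elements))
  class(topo) <- c("myoflow_topology", class(topo))
  b <- obj$boundaries
  attach_boundaries(topo, Pout_mmHg = as.numeric(b$Pout_mmHg),
                    Pext_mmHg = as.numeric(b$Pext_mmHg),
                    Z_mode = if (is.character(b$Z_mode)) b$Z_mode
                             else as.numeric(b$Z_mode))
}

# Flatten a topology into the element/node lists consumed by the C++ core.
# Nodes are numbered vessel by vessel (each vessel owns n_elements + 1 nodes);
# junction continuity rows tie parent end nodes to daughter start nodes.
topology_for_cpp <- function(topology) {
  nv <- nrow(topology)
  n_nodes_v <- topology$n_elements + 1L
  base <- cumsum(c(0L, n_nodes_v))[seq_len(nv)]
  first_node <- base + 1L
  last_node <- base + n_nodes_v
  elems <- purrr::map_dfr(seq_len(nv), function(v) {
    n_el <- topology$n_elements[v]
    tibble(i = base[v] + seq_len(n_el), j = base[v] + seq_len(n_el) + 1L,
           len = topology$L_cm[v] / n_el, vessel = v)
  })
  parents <- which(topology$vessel %in% topology$parent)
  junctions <- purrr::map_dfr(parents, function(v) {
    d <- topology$vessel[which(!is.na(topology$parent) & topology$parent ==
                                 topology$vessel[v])]
    tibble(p_end = last_node[v], d1_start = first_node[d[1]],
           d2_start = first_node[d[2]])
  })
  terminals <- terminal_vessels(topology)
  list(n_nodes = sum(n_nodes_v),
       elem_i = elems$i, elem_j = elems$j, elem_len = elems$len,
       elem_vessel = elems$vessel,
       jun_p = if (nrow(junctions)) junctions$p_end else integer(0),
       jun_d1 = if (nrow(junctions)) junctions$d1_start else integer(0),
       jun_d2 = if (nrow(junctions)) junctions$d2_start else integer(0),
       inlet_node = first_node[which(is.na(topology$parent))],
       terminal_nodes = last_node[match(terminals, topology$vessel)],
       node_vessel = rep(seq_len(nv), n_nodes_v),
       mid_node = base + (n_nodes_v + 1L) %/% 2L,
       first_node = first_node, last_node = last_node)
}
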