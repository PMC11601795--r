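# Shared fixtures: all driving data are generated in code.

# Two-generation symmetric tree (3 vessels), cheap for coupled runs.
tiny_tree <- function(n_elements = 2L) {
  topo <- build_symmetric_tree(
    vessel_spec(0L, L_cm = 0.4, Do_um = 135, hw = 0.2,
                n_elements = n_elements),
    generations = 2L, lengths = c(0.4, 0.3))
  attach_boundaries(topo)
}

# Single-vessel "network" for flow tests.
single_tube <- function(n_elements = 2L, Do_um = 135, hw = 0.2, L_cm = 0.4,
                        Z_mode = "none") {
  topo <- build_symmetric_tree(
    vessel_spec(0L, L_cm = L_cm, Do_um = Do_um, hw = hw,
                n_elements = n_elements),
    generations = 1L, lengths = L_cm)
  attach_boundaries(topo, Z_mode = Z_mode)
}

default_geom <- function() load_free_geometry(135, 0.2)

# Direct resistor-network solve of a symmetric binary tree with vessel
# resistances R_v = 8 pi mu L / A^2 (Poiseuille), the oracle for rigid-tube
# steady flows. Returns per-vessel flows.
resistor_tree_flows <- function(topology, A_by_vessel, Pin, Pout, mu) {
  nv <- nrow(topology)
  Rv <- 8 * pi * mu * topology$L_cm / A_by_vessel^2
  # unknowns: pressure at the downstream end of each vessel; upstream end of
  # the root is Pin; terminals end at Pout through zero extra resistance.
  # Solve nodal equations by eliminating flows Q_v = (P_up(v) - P_down(v))/R_v.
  terminals <- terminal_vessels(topology)
  Mm <- matrix(0, nv, nv)
  b <- numeric(nv)
  for (v in seq_len(nv)) {
    if (v %in% terminals) {
      Mm[v, v] <- 1
      b[v] <- Pout
      next
    }
    kids <- topology$vessel[!is.na(topology$parent) & topology$parent == v]
    # flow in = sum of flows out at the junction at v's downstream end
    Mm[v, v] <- Mm[v, v] - 1 / Rv[v]
    parent <- topology$parent[v]
    if (is.na(parent)) b[v] <- b[v] - Pin / Rv[v]
    else Mm[v, parent] <- Mm[v, parent] + 1 / Rv[v]
    for (k in kids) {
      Mm[v, v] <- Mm[v, v] - 1 / Rv[k]
      Mm[v, k] <- Mm[v, k] + 1 / Rv[k]
    }
  }
  Pdown <- solve(Mm, b)
  Pup <- ifelse(is.na(topology$parent), Pin, Pdown[topology$parent])
  (Pup - Pdown) / Rv
}
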