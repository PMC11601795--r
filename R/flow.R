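#' Element matrices of the linearized 1-D flow equations
#'
#' For one two-node element of length `len`, builds the 2x2 pressure and flow
#' matrices `Fe`, `Ge` and right-hand side `he` of the compact element system
#' `Fe P_e + Ge Q_e = he` obtained by trapezoidal spatial integration of the
#' linearized mass and momentum equations with a two-step backward (BDF2) time
#' discretization (backward Euler at start-up). Coefficients (area,
#' compliance) are frozen at the supplied values; the convective term is
#' evaluated explicitly from the previous steps (extrapolated to the new time
#' level under BDF2), while the friction term
#' `8 pi mu Q / A^2` is kept implicit in `Ge` with its coefficient frozen at
#' the supplied areas (an explicit friction term would be unstable at the
#' working time steps for arteriolar-scale lumens, where the viscous
#' relaxation time `rho A / (8 pi mu)` is tens of microseconds).
#'
#' Row 1 is the mass row, row 2 the momentum row; columns correspond to the
#' element's two nodes.
#'
#' @param elem List with `len` (cm), `A`, `C_A` (length-2 coefficient values
#'   at the element nodes; `C_A` may be 0 for a rigid tube).
#' @param prev List with length-2 vectors `P`, `Q` (previous step), optional
#'   `P2`, `Q2` (two steps back, enabling BDF2) and optional `A`, `A2` (areas
#'   at the previous steps used by the convective term; default to `elem$A`).
#' @param dt Time step, s.
#' @param fluid A [fluid_params()].
#' @return A list with `Fe`, `Ge` (2x2 matrices) and `he` (length 2).
#' @export
element_matrices <- function(elem, prev, dt, fluid = fluid_params()) {
  stopifnot(elem$len > 0, dt > 0, length(elem$A) == 2L, length(elem$C_A) == 2L)
  if (any(elem$A <= 0))
    abort("Zero or negative area in element.", class = "myoflow_singular_error")
  bdf2 <- !is.null(prev$P2)
  beta <- if (bdf2) 1.5 else 1
  hP <- if (bdf2) (4 * prev$P - prev$P2) / (2 * dt) else prev$P / dt
  hQ <- if (bdf2) (4 * prev$Q - prev$Q2) / (2 * dt) else prev$Q / dt
  A <- elem$A; C <- elem$C_A; l2 <- elem$len / 2
  rho <- fluid$rho; mu <- fluid$mu
  Aconv <- if (is.null(prev$A)) A else prev$A
  s_e <- (prev$Q[2]^2 / Aconv[2] - prev$Q[1]^2 / Aconv[1]) / elem$len
  conv <- rho / Aconv * s_e
  if (bdf2) {
    # extrapolate the explicit convective term to the new time level
    A2 <- if (is.null(prev$A2)) Aconv else prev$A2
    s_m <- (prev$Q2[2]^2 / A2[2] - prev$Q2[1]^2 / A2[1]) / elem$len
    conv <- 2 * conv - rho / A2 * s_m
  }
  Fe <- rbind(l2 * C * beta / dt, c(-1, 1))
  Ge <- rbind(c(-1, 1),
              l2 * (rho / A) * beta / dt + l2 * 8 * pi * mu / A^2)
  he <- c(sum(l2 * C * hP),
          sum(l2 * (rho / A) * hQ) - sum(l2 * conv))
  list(Fe = Fe, Ge = Ge, he = he)
}

#' Assemble and solve one flow time step over a network
#'
#' Reference (pure R, dense) implementation of the global flow solve: element
#' rows from [element_matrices()], junction rows enforcing static pressure
#' continuity and mass conservation, an inlet pressure row and outlet rows
#' `P_terminal - Z Q_terminal = Pout`. The compiled solver used by
#' [run_simulation()] performs the identical assembly; this function is its
#' independent cross-check and handles single steps for analysis.
#'
#' @param topology A `myoflow_topology`.
#' @param state List of node-level vectors (solver units, dyn/cm^2 and ml/s):
#'   `P`, `Q` (previous step), `A`, `C_A` (frozen coefficients), optional
#'   `P2`, `Q2` (two steps back), optional `A_prev`, `A_prev2` (areas for the
#'   convective term, default to `A`).
#' @param dt Time step, s.
#' @param Pin Inlet pressure at the new time level, dyn/cm^2.
#' @param Pout Outlet pressure, dyn/cm^2.
#' @param Z Terminal impedance(s), dyn s/cm^5 (scalar or one per terminal).
#' @param fluid A [fluid_params()].
#' @return A list with `P`, `Q` (node vectors at the new time level) and the
#'   assembled `M`, `rhs`.
#' @export
assemble_and_solve <- function(topology, state, dt, Pin, Pout, Z = 0,
                               fluid = fluid_params()) {
  tp <- topology_for_cpp(topology)
  N <- tp$n_nodes
  n_el <- length(tp$elem_i)
  n_jun <- length(tp$jun_p)
  n_term <- length(tp$terminal_nodes)
  if (length(Z) == 1L) Z <- rep(Z, n_term)
  stopifnot(length(Z) == n_term, all(Z >= 0))
  n_eq <- 2L * n_el + 3L * n_jun + 1L + n_term
  if (n_eq != 2L * N)
    abort("Unconstrained nodes: the assembled system is not square.",
          class = "myoflow_assembly_error")
  M <- matrix(0, n_eq, n_eq)
  rhs <- numeric(n_eq)
  row <- 0L
  for (e in seq_len(n_el)) {
    i <- tp$elem_i[e]; j <- tp$elem_j[e]
    em <- element_matrices(
      elem = list(len = tp$elem_len[e], A = state$A[c(i, j)],
                  C_A = state$C_A[c(i, j)]),
      prev = list(P = state$P[c(i, j)], Q = state$Q[c(i, j)],
                  P2 = if (is.null(state$P2)) NULL else state$P2[c(i, j)],
                  Q2 = if (is.null(state$Q2)) NULL else state$Q2[c(i, j)],
                  A = if (is.null(state$A_prev)) NULL else state$A_prev[c(i, j)],
                  A2 = if (is.null(state$A_prev2)) NULL
                       else state$A_prev2[c(i, j)]),
      dt = dt, fluid = fluid)
    for (r in 1:2) {
      row <- row + 1L
      M[row, c(i, j)] <- M[row, c(i, j)] + em$Fe[r, ]
      M[row, N + c(i, j)] <- M[row, N + c(i, j)] + em$Ge[r, ]
      rhs[row] <- em$he[r]
    }
  }
  for (k in seq_len(n_jun)) {
    p <- tp$jun_p[k]; d1 <- tp$jun_d1[k]; d2 <- tp$jun_d2[k]
    row <- row + 1L; M[row, p] <- 1; M[row, d1] <- -1          # P_p = P_d1
    row <- row + 1L; M[row, p] <- 1; M[row, d2] <- -1          # P_p = P_d2
    row <- row + 1L                                            # mass balance
    M[row, N + p] <- 1; M[row, N + d1] <- -1; M[row, N + d2] <- -1
  }
  row <- row + 1L
  M[row, tp$inlet_node] <- 1; rhs[row] <- Pin
  for (k in seq_len(n_term)) {
    row <- row + 1L
    M[row, tp$terminal_nodes[k]] <- 1
    M[row, N + tp$terminal_nodes[k]] <- -Z[k]
    rhs[row] <- Pout
  }
  # equilibrate rows and columns: pressure (dyn/cm^2) and flow (ml/s) columns
  # differ by many orders of magnitude in CGS units
  rs <- apply(abs(M), 1, max)
  rs[rs == 0] <- 1
  M1 <- M / rs
  cs <- apply(abs(M1), 2, max)
  cs[cs == 0] <- 1
  M2 <- sweep(M1, 2, cs, "/")
  sol <- tryCatch(solve(M2, rhs / rs) / cs, error = function(e)
    abort(paste0("Singular flow system: ", conditionMessage(e)),
          class = "myoflow_singular_error"))
  list(P = sol[seq_len(N)], Q = sol[N + seq_len(N)], M = M, rhs = rhs)
}

#' Characteristic impedance of a compliant vessel
#'
#' `Z = rho c / A` with local pulse wave speed `c = sqrt(A / (rho C_A))`,
#' the terminal impedance that absorbs outgoing pressure waves.
#'
#' @param A Luminal area, cm^2 (> 0).
#' @param C_A Compliance `dA/dP`, cm^2 per dyn/cm^2 (> 0).
#' @param rho Blood density, g/cm^3.
#' @return Impedance, dyn s / cm^5 (vectorized).
#' @export
characteristic_impedance <- function(A, C_A, rho = 1.04) {
  if (any(A <= 0)) abort("`A` must be positive.", class = "myoflow_state_error")
  if (any(C_A <= 0))
    abort("Non-physical compliance: `C_A` must be positive.",
          class = "myoflow_state_error")
  c_pw <- sqrt(A / (rho * C_A))
  rho * c_pw / A
}
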