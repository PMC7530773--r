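# Neuron and synapse model registry.
#
# Each neuron model carries its native state dimension, a vector field f, an
# analytic Jacobian Df, default parameters, and the id of its compiled
# counterpart.  Each synapse kind carries the scalar activation a(x_i, x_j)
# (the only nonzero component of the coupling vector field, acting on the
# membrane potential), its partial derivatives with respect to the
# postsynaptic potential (D1) and the presynaptic state (D2), and an id.

#' Default parameters of the conductance-based swim neuron
#'
#' Plant-type bursting neuron with 5 intrinsic variables (V, h, n, chi, Ca)
#' plus the two dynamical chemical synapse gates (s1 inhibitory, s2
#' excitatory) carried in the node state, giving a 7-dimensional state.
#'
#' `g_KCa` has no established value in the source modeling literature for
#' this circuit; the default was chosen once so that the isolated neuron
#' oscillates.  `V_Ca_drive` is the driving value in the calcium removal
#' equation; it is kept distinct from the calcium reversal `V_Ca_rev` used in
#' I_Ca.
#'
#' @return named list of parameters (units: nS, mV, ms, uF/cm^2).
#' @export
swim_params <- function() {
  list(C = 1, g_Na = 4, V_Na = 30, g_K = 0.3, V_K = -75,
       g_Ca = 0.03, V_Ca_rev = 140, g_KCa = 0.005, g_L = 3e-4, V_L = -40,
       rho = 1e-4, K_c = 0.0085, V_Ca_drive = 140, tau_chi = 9400,
       tau_s = 40, V_T = -30, V_s_syn = 25, s_clamp = 1e-9,
       chi_k = 0.3, chi_V0 = 40)
}

#' Default parameters of the Hindmarsh-Rose neuron
#'
#' Dimensionless three-variable model; `I` distinguishes node types
#' (`I = 2` for ordinary cortical areas, `I = 3` for the visually driven
#' one).  One model time unit is identified with 1 ms so that delays in ms
#' are directly comparable.
#'
#' @param I applied current (default 2).
#' @return named list of parameters.
#' @export
hr_params <- function(I = 2) {
  list(b = 2.7, mu = 0.01, s = 4, x_rest = -1.6, I = I)
}

.swim_param_vec <- function(p) {
  as.numeric(p[c("C", "g_Na", "V_Na", "g_K", "V_K", "g_Ca", "V_Ca_rev",
                 "g_KCa", "g_L", "V_L", "rho", "K_c", "V_Ca_drive",
                 "tau_chi", "tau_s", "V_T", "V_s_syn", "s_clamp",
                 "chi_k", "chi_V0")])
}
.hr_param_vec <- function(p) as.numeric(p[c("b", "mu", "s", "x_rest", "I")])
.lin_param_vec <- function(p) as.numeric(p["a"])

.swim_gating <- function(V, chi_k = 0.3, chi_V0 = 40) {
  Vs <- (127 * V + 8265) / 105
  u1 <- 50 - Vs
  am <- ifelse(abs(u1) < 1e-6, 1, 0.1 * u1 / expm1(u1 / 10))
  bm <- 4 * exp((25 - Vs) / 18)
  ah <- 0.07 * exp((25 - Vs) / 20)
  bh <- 1 / (exp((55 - Vs) / 10) + 1)
  u2 <- 55 - Vs
  an <- ifelse(abs(u2) < 1e-6, 0.1, 0.01 * u2 / expm1(u2 / 10))
  bn <- 0.125 * exp((45 - Vs) / 80)
  list(m_inf = am / (am + bm),
       h_inf = ah / (ah + bh), tau_h = 12.5 / (ah + bh),
       n_inf = an / (an + bn), tau_n = 12.5 / (an + bn),
       chi_inf = 1 / (1 + exp(-chi_k * (V - chi_V0))))
}

.swim_sinf <- function(V, p) {
  s <- ifelse(V > p$V_T, tanh((V - p$V_T) / p$V_s_syn), 0)
  pmin(s, 1 - p$s_clamp)
}

#' Vector field of the swim neuron
#'
#' @param x state vector (V, h, n, chi, Ca, s1, s2).
#' @param params parameter list, see [swim_params()].
#' @return 7-vector of time derivatives.
#' @export
swim_rhs <- function(x, params = swim_params()) {
  p <- params
  V <- x[1]; h <- x[2]; n <- x[3]; chi <- x[4]; Ca <- x[5]
  g <- .swim_gating(V, p$chi_k, p$chi_V0)
  I_Na <- p$g_Na * g$m_inf^3 * h * (V - p$V_Na)
  I_K <- p$g_K * n^4 * (V - p$V_K)
  I_Ca <- p$g_Ca * chi * (V - p$V_Ca_rev)
  I_KCa <- p$g_KCa * Ca / (0.5 + Ca) * (V - p$V_K)
  I_l <- p$g_L * (V - p$V_L)
  sinf <- .swim_sinf(V, p)
  c((-I_Na - I_K - I_Ca - I_KCa - I_l) / p$C,
    (g$h_inf - h) / g$tau_h,
    (g$n_inf - n) / g$tau_n,
    (g$chi_inf - chi) / p$tau_chi,
    p$rho * (p$K_c * chi * (p$V_Ca_drive - V) - Ca),
    (sinf - x[6]) / (p$tau_s * (1 - sinf)),
    (sinf - x[7]) / (p$tau_s * (1 - sinf)))
}

#' Vector field of the Hindmarsh-Rose neuron
#'
#' @param x state vector (V, y, z).
#' @param params parameter list, see [hr_params()].
#' @return 3-vector of time derivatives.
#' @export
hr_rhs <- function(x, params = hr_params()) {
  p <- params
  c(x[2] - x[1]^3 + p$b * x[1]^2 - x[3] + p$I,
    1 - 5 * x[1]^2 - x[2],
    p$mu * (p$s * (x[1] - p$x_rest) - x[3]))
}

#' Fast threshold modulation synapse activation
#'
#' Instantaneous chemical synapse a(V_i, V_j) = (E - V_i) / (1 + exp(nu *
#' (V_j - theta))).  Overflow-safe for large presynaptic potentials.
#'
#' @param V_i postsynaptic membrane potential.
#' @param V_j presynaptic membrane potential.
#' @param params list with E, nu, theta.
#' @return scalar activation.
#' @export
ftm_activation <- function(V_i, V_j, params = list(E = 2, nu = 10, theta = -0.6)) {
  e <- params$nu * (V_j - params$theta)
  gam <- ifelse(e > 50, 0, ifelse(e < -50, 1, 1 / (1 + exp(pmin(e, 50)))))
  (params$E - V_i) * gam
}

#' Swim circuit synapse activations
#'
#' Kind 1: dynamical inhibitory, a = (E1 - V_i) s1_j with E1 = -80 mV.
#' Kind 2: dynamical excitatory, a = (E2 - V_i) s2_j with E2 = 0 mV.
#' Kind 3: electrical (gap junction), a = V_j - V_i.
#'
#' @param kind integer in 1:3.
#' @param V_i postsynaptic membrane potential.
#' @param x_j full presynaptic state vector (kind 3 only needs V_j = x_j[1]).
#' @return scalar activation.
#' @export
swim_synapse_activation <- function(kind, V_i, x_j) {
  switch(as.character(kind),
         "1" = (-80 - V_i) * x_j[6],
         "2" = (0 - V_i) * x_j[7],
         "3" = x_j[1] - V_i,
         stop("unknown synapse kind: ", kind))
}

#' Central-difference numeric Jacobian
#'
#' @param fn function of a single numeric vector.
#' @param point evaluation point.
#' @param rel_step relative step (default 1e-6).
#' @return Jacobian matrix d fn / d point.
#' @export
numeric_jacobian <- function(fn, point, rel_step = 1e-6) {
  f0 <- fn(point)
  m <- length(f0); n <- length(point)
  J <- matrix(0, m, n)
  for (j in seq_len(n)) {
    hstep <- rel_step * max(1, abs(point[j]))
    xp <- point; xp[j] <- xp[j] + hstep
    xm <- point; xm[j] <- xm[j] - hstep
    fp <- fn(xp); fm <- fn(xm)
    if (any(!is.finite(fp)) || any(!is.finite(fm)))
      stop("non-finite function value in numeric Jacobian probe")
    J[, j] <- (fp - fm) / (2 * hstep)
  }
  J
}

#' Registry of neuron models
#'
#' @return named list of model descriptors (n, f, Df, params, cpp_id,
#'   voltage index).
#' @export
neuron_models <- function() {
  list(
    swim = list(
      name = "swim", n = 7L, cpp_id = 1L, voltage_index = 1L,
      params = swim_params(),
      f = swim_rhs,
      Df = function(x, params = swim_params())
        model_jac_cpp(1L, as.numeric(x), .swim_param_vec(params)),
      pack = .swim_param_vec),
    hr = list(
      name = "hr", n = 3L, cpp_id = 2L, voltage_index = 1L,
      params = hr_params(),
      f = hr_rhs,
      Df = function(x, params = hr_params())
        matrix(c(-3 * x[1]^2 + 2 * params$b * x[1], -10 * x[1], params$mu * params$s,
                 1, -1, 0,
                 -1, 0, -params$mu), 3, 3),
      pack = .hr_param_vec),
    linear = list(
      name = "linear", n = 1L, cpp_id = 3L, voltage_index = 1L,
      params = list(a = -1),
      f = function(x, params = list(a = -1)) params$a * x[1],
      Df = function(x, params = list(a = -1)) matrix(params$a, 1, 1),
      pack = .lin_param_vec)
  )
}

#' Registry of synapse (coupling) kinds
#'
#' The activation is the first (membrane potential) component of the
#' coupling vector field; all other components are zero.  `a(x_i, x_j)`
#' takes full (padded) state vectors; `D1a` is the derivative with respect
#' to V_i; `D2a` returns a list(value, index) for the single nonzero
#' derivative with respect to a component of x_j.
#'
#' @return named list of kind descriptors.
#' @export
synapse_kinds <- function() {
  list(
    inhibitory = list(
      name = "inhibitory", cpp_id = 1L, kparams = c(E = -80),
      is_dynamical = TRUE, presyn_state = 6L,
      a = function(xi, xj, kp = c(E = -80)) (kp[["E"]] - xi[1]) * xj[6],
      D1a = function(xi, xj, kp = c(E = -80)) -xj[6],
      D2a = function(xi, xj, kp = c(E = -80)) list(value = kp[["E"]] - xi[1], index = 6L)),
    excitatory = list(
      name = "excitatory", cpp_id = 2L, kparams = c(E = 0),
      is_dynamical = TRUE, presyn_state = 7L,
      a = function(xi, xj, kp = c(E = 0)) (kp[["E"]] - xi[1]) * xj[7],
      D1a = function(xi, xj, kp = c(E = 0)) -xj[7],
      D2a = function(xi, xj, kp = c(E = 0)) list(value = kp[["E"]] - xi[1], index = 7L)),
    electrical = list(
      name = "electrical", cpp_id = 3L, kparams = numeric(0),
      is_dynamical = FALSE,
      a = function(xi, xj, kp = NULL) xj[1] - xi[1],
      D1a = function(xi, xj, kp = NULL) -1,
      D2a = function(xi, xj, kp = NULL) list(value = 1, index = 1L)),
    ftm = list(
      name = "ftm", cpp_id = 4L, kparams = c(E = 2, nu = 10, theta = -0.6),
      is_dynamical = FALSE,
      a = function(xi, xj, kp = c(E = 2, nu = 10, theta = -0.6))
        ftm_activation(xi[1], xj[1], list(E = kp[["E"]], nu = kp[["nu"]], theta = kp[["theta"]])),
      D1a = function(xi, xj, kp = c(E = 2, nu = 10, theta = -0.6)) {
        e <- kp[["nu"]] * (xj[1] - kp[["theta"]])
        -(if (e > 50) 0 else if (e < -50) 1 else 1 / (1 + exp(e)))
      },
      D2a = function(xi, xj, kp = c(E = 2, nu = 10, theta = -0.6)) {
        e <- kp[["nu"]] * (xj[1] - kp[["theta"]])
        gam <- if (e > 50) 0 else if (e < -50) 1 else 1 / (1 + exp(e))
        list(value = (kp[["E"]] - xi[1]) * (-kp[["nu"]] * gam * (1 - gam)), index = 1L)
      }),
    direct = list(
      name = "direct", cpp_id = 5L, kparams = numeric(0),
      is_dynamical = FALSE,
      a = function(xi, xj, kp = NULL) xj[1],
      D1a = function(xi, xj, kp = NULL) 0,
      D2a = function(xi, xj, kp = NULL) list(value = 1, index = 1L))
  )
}

# resolve a model name to its descriptor
.get_model <- function(name, models = neuron_models()) {
  m <- models[[name]]
  if (is.null(m)) stop("unknown neuron model: ", name)
  m
}

.get_kind <- function(name, kinds = synapse_kinds()) {
  k <- kinds[[name]]
  if (is.null(k)) stop("unknown coupling kind: ", name)
  k
}
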