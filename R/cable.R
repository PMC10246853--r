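# Membrane dynamics and recruitment thresholds: MRG nodal channels on an
# implicit-Euler cable, driven extracellularly by lead-field potentials,
# with threshold search by bisection on the cathodic pulse amplitude.

# Electrical parameters for the compartment chain (NEURON-style units:
# mV, ms, uF, mS). Lengths/diameters in um are converted to cm.
cable_params <- function(axon) {
  k <- mrg_constants()
  comps <- axon$compartments
  n <- nrow(comps)
  L_cm <- comps$length_um * 1e-4
  d_cm <- comps$diameter_um * 1e-4
  area <- pi * d_cm * L_cm                 # cm^2
  is_node <- as.integer(comps$type == "node")
  nl <- axon$params$nl

  cm <- k$cm * area                        # uF
  gnaf <- gnap <- gks <- gl <- numeric(n)
  gpas <- numeric(n); epas <- rep(k$v_rest, n)
  sel <- is_node == 1L
  gnaf[sel] <- k$g_naf * area[sel] * 1e3   # mS
  gnap[sel] <- k$g_nap * area[sel] * 1e3
  gks[sel] <- k$g_ks * area[sel] * 1e3
  gl[sel] <- k$g_l * area[sel] * 1e3

  if (axon$detail == "reduced") {
    # lumped myelinated internode: axolemma in series with the myelin
    ii <- comps$type == "internode"
    c_axo <- k$cm; c_my <- k$mycm / (2 * nl)
    g_axo <- k$g_stin; g_my <- k$mygm / (2 * nl)
    cm[ii] <- (1 / (1 / c_axo + 1 / c_my)) * area[ii]
    gpas[ii] <- (1 / (1 / g_axo + 1 / g_my)) * area[ii] * 1e3
    cmy <- gmy <- gpx <- NULL
  } else {
    g_ax_cm2 <- c(node = NA, mysa = k$g_mysa, flut = k$g_flut, stin = k$g_stin)
    nn <- comps$type != "node"
    gpas[nn] <- g_ax_cm2[comps$type[nn]] * area[nn] * 1e3
    cmy <- gmy <- numeric(n)
    cmy[nn] <- k$mycm / (2 * nl) * area[nn]
    gmy[nn] <- k$mygm / (2 * nl) * area[nn] * 1e3
    gmy[sel] <- 1e3                         # no myelin at nodes: periaxonal
    cmy[sel] <- 0                           # space merges with extracellular
    sp <- c(node = k$space_mysa, mysa = k$space_mysa,
            flut = k$space_flut, stin = k$space_stin)[comps$type] * 1e-4
    a_peri <- pi * ((d_cm / 2 + sp)^2 - (d_cm / 2)^2)  # cm^2
    r_half_p <- k$rhoa * (L_cm / 2) / a_peri           # Ohm
    gpx <- 1e3 / (r_half_p[-n] + r_half_p[-1])         # mS
  }
  a_int <- pi * (d_cm / 2)^2
  r_half <- k$rhoa * (L_cm / 2) / a_int
  gax <- 1e3 / (r_half[-n] + r_half[-1])
  list(cm = cm, gpas = gpas, epas = epas, is_node = is_node,
       gnaf = gnaf, gnap = gnap, gks = gks, gl = gl,
       gax = gax, cmy = cmy, gmy = gmy, gpx = gpx, k = k)
}

#' Simulate the membrane response to a cathodic pulse
#'
#' Backward-Euler integration of the compartment chain with extracellular
#' drive `-amplitude_mA * ve_per_mA` applied for the pulse duration.
#' A spike is an upward 0 mV crossing at both terminal nodes (propagation
#' check).
#'
#' @param axon An `ns_axon`.
#' @param ve_per_mA Extracellular potential at each compartment for +1 mA
#'   injected, volts.
#' @param amplitude_mA Cathodic pulse amplitude (positive number, mA).
#' @param pulse_us Pulse width, us (default 50).
#' @param dt_us Integration step, us.
#' @param window_ms Simulation window, ms.
#' @param params Optional precomputed [cable_params()] (internal reuse).
#' @return TRUE if the fiber fires, FALSE otherwise.
#' @export
simulate_membrane <- function(axon, ve_per_mA, amplitude_mA,
                              pulse_us = 50, dt_us = 1, window_ms = 2,
                              params = NULL) {
  stopifnot(length(ve_per_mA) == nrow(axon$compartments), amplitude_mA >= 0)
  pp <- params %||% cable_params(axon)
  ve_mV <- ve_per_mA * 1e3
  dt <- dt_us * 1e-3
  n_steps <- ceiling(window_ms / dt)
  pulse_steps <- max(1L, round(pulse_us / dt_us))
  k <- pp$k
  amp <- -amplitude_mA          # cathodic
  if (axon$detail == "reduced") {
    res <- cable_sim_reduced(pp$cm, pp$gpas, pp$epas, pp$is_node,
                             pp$gnaf, pp$gnap, pp$gks, pp$gl, pp$gax,
                             ve_mV, amp, dt, n_steps, pulse_steps,
                             k$v_rest, k$e_na, k$e_k, k$e_l)
  } else {
    res <- cable_sim_mrg(pp$cm, pp$cmy, pp$gmy, pp$gpas, pp$epas, pp$is_node,
                         pp$gnaf, pp$gnap, pp$gks, pp$gl, pp$gax, pp$gpx,
                         ve_mV, amp, dt, n_steps, pulse_steps,
                         k$v_rest, k$e_na, k$e_k, k$e_l)
  }
  res == 1L
}

#' Recruitment threshold by bisection
#'
#' Bracket the firing amplitude by geometric expansion (warm-started from
#' `init_guess` when available), then bisect until the relative bracket
#' width is below `tol`. The returned threshold charge is amplitude times
#' pulse width.
#'
#' @inheritParams simulate_membrane
#' @param tol Relative bracket width (default 1%).
#' @param init_guess Optional starting amplitude, mA.
#' @param max_amp_mA Amplitude cap; fibers silent at the cap are flagged
#'   unreachable (`threshold = Inf`).
#' @return A list: `threshold_mA`, `threshold_nC`, `bracket_nC`,
#'   `converged`, `unreachable`.
#' @export
find_threshold <- function(axon, ve_per_mA, pulse_us = 50, tol = 0.01,
                           dt_us = 1, window_ms = 2, init_guess = NULL,
                           max_amp_mA = 1e4) {
  pp <- cable_params(axon)
  fire <- function(a) simulate_membrane(axon, ve_per_mA, a, pulse_us,
                                        dt_us, window_ms, params = pp)
  a0 <- init_guess
  if (is.null(a0) || !is.finite(a0) || a0 <= 0) {
    # seed from the activating function scale: drive ~ mV-scale second
    # difference of the extracellular profile
    dd <- abs(diff(diff(ve_per_mA * 1e3)))
    a0 <- if (length(dd) && max(dd) > 0) 25 / max(dd) else 1
    a0 <- min(max(a0, 1e-4), max_amp_mA / 4)
  }
  lo <- NA_real_; hi <- NA_real_
  a <- a0
  if (fire(a)) {
    hi <- a
    while (is.na(lo)) {
      a <- a / 3
      if (a < 1e-9) { lo <- 0; break }
      if (fire(a)) hi <- a else lo <- a
    }
  } else {
    lo <- a
    while (is.na(hi)) {
      a <- a * 3
      if (a > max_amp_mA) {
        if (fire(max_amp_mA)) { hi <- max_amp_mA; break }
        return(list(threshold_mA = Inf, threshold_nC = Inf,
                    bracket_nC = c(lo * pulse_us, Inf),
                    converged = FALSE, unreachable = TRUE))
      }
      if (fire(a)) hi <- a else lo <- a
    }
  }
  while ((hi - lo) > tol * hi && hi > 1e-9) {
    mid <- sqrt(max(lo, hi * tol / 4) * hi)   # geometric bisection
    if (fire(mid)) hi <- mid else lo <- mid
  }
  list(threshold_mA = hi, threshold_nC = hi * pulse_us,
       bracket_nC = c(lo * pulse_us, hi * pulse_us),
       converged = TRUE, unreachable = FALSE)
}

#' Activating function along the fiber
#'
#' Discrete second difference of the extracellular potential across
#' consecutive nodes of Ranvier, scaled by the internodal axial
#' conductance: the classical fast excitability screen.
#'
#' @param ve Extracellular potential per compartment (V, at the reference
#'   current).
#' @param axon An `ns_axon`.
#' @return Numeric vector, one value per node (uA at the reference
#'   current; end nodes NA).
#' @export
activating_function <- function(ve, axon) {
  comps <- axon$compartments
  nodes <- which(comps$type == "node")
  if (length(nodes) < 3) stop("activating function needs >= 3 nodes")
  pp <- cable_params(axon)
  # effective node-to-node conductance: series of the axial links between
  # consecutive nodes
  g_eff <- vapply(seq_len(length(nodes) - 1), function(i) {
    seg <- seq(nodes[i], nodes[i + 1] - 1)
    1 / sum(1 / pp$gax[seg])
  }, numeric(1))
  vn <- ve[nodes] * 1e3                    # mV
  out <- rep(NA_real_, length(nodes))
  for (i in 2:(length(nodes) - 1)) {
    gl <- g_eff[i - 1]; gr <- g_eff[i]
    out[i] <- gl * (vn[i - 1] - vn[i]) + gr * (vn[i + 1] - vn[i])
  }
  out
}
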