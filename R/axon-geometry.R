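# Myelinated axon compartment geometry following the McIntyre-Richardson-
# Grill (MRG) mammalian fiber parameterization: explicit nodes of Ranvier,
# paranodal (MYSA/FLUT) and internodal (STIN) sections, with geometric
# parameters tabulated against fiber diameter.

# Published MRG geometric table (fiber diameters 5.7-16 um). Lengths and
# diameters in um; nl = number of myelin lamellae.
mrg_table <- data.frame(
  fiber_d   = c(5.7, 7.3, 8.7, 10.0, 11.5, 12.8, 14.0, 15.0, 16.0),
  node_d    = c(1.9, 2.4, 2.8, 3.3, 3.9, 4.2, 4.7, 5.0, 5.5),
  axon_d    = c(3.4, 4.6, 5.8, 6.9, 8.1, 8.8, 9.3, 9.7, 10.4),
  flut_len  = c(35, 38, 40, 46, 50, 54, 56, 58, 60),
  internode = c(500, 750, 1000, 1150, 1250, 1350, 1400, 1450, 1500),
  nl        = c(80, 100, 110, 120, 130, 135, 140, 145, 150)
)

# Piecewise-linear interpolation inside the table; outside, linear
# continuation anchored at the nearest table endpoint with the slope of a
# least-squares fit over the whole table (keeps all parameters positive
# and monotone down to 1 um, which the naive two-point extrapolation does
# not).
mrg_interp <- function(d, column) {
  tab <- mrg_table
  x <- tab$fiber_d; y <- tab[[column]]
  slope <- stats::cov(x, y) / stats::var(x)
  out <- numeric(length(d))
  below <- d < x[1]; above <- d > x[length(x)]
  mid <- !below & !above
  if (any(mid)) out[mid] <- stats::approx(x, y, xout = d[mid])$y
  if (any(below)) out[below] <- y[1] + slope * (d[below] - x[1])
  if (any(above)) out[above] <- y[length(y)] + slope * (d[above] - x[length(x)])
  out
}

#' MRG geometric parameters for a fiber diameter
#'
#' @param diameter Fiber (outer) diameter, um, in `[1, 20]`.
#' @return A one-row list: node/axon diameters, node/MYSA/FLUT/STIN
#'   lengths, internode spacing, lamellae count.
#' @export
mrg_parameters <- function(diameter) {
  if (diameter < 1 || diameter > 20)
    stop("fiber diameter outside the supported range [1, 20] um")
  node_len <- 1; mysa_len <- 3
  flut_len <- mrg_interp(diameter, "flut_len")
  internode <- mrg_interp(diameter, "internode")
  stin_len <- (internode - node_len - 2 * mysa_len - 2 * flut_len) / 6
  list(fiber_d = diameter,
       node_d = mrg_interp(diameter, "node_d"),
       axon_d = mrg_interp(diameter, "axon_d"),
       node_len = node_len, mysa_len = mysa_len, flut_len = flut_len,
       stin_len = stin_len, internode = internode,
       nl = mrg_interp(diameter, "nl"))
}

# MRG electrical constants (NEURON-style units).
mrg_constants <- function() {
  list(rhoa = 70,          # axoplasmic/periaxonal resistivity, Ohm*cm
       cm = 2,             # membrane capacitance, uF/cm^2 (node + axolemma)
       g_nap = 0.01,       # persistent Na, S/cm^2
       g_naf = 3.0,        # fast Na, S/cm^2
       g_ks = 0.08,        # slow K, S/cm^2
       g_l = 0.007,        # nodal leak, S/cm^2
       e_na = 50, e_k = -90, e_l = -90, v_rest = -80,
       g_mysa = 0.001,     # passive axolemma, S/cm^2
       g_flut = 0.0001, g_stin = 0.0001,
       mycm = 0.1,         # myelin capacitance per lamella membrane, uF/cm^2
       mygm = 0.001,       # myelin conductance per lamella membrane, S/cm^2
       space_mysa = 0.002, space_flut = 0.004, space_stin = 0.004)  # um
}

#' Build an axon compartment chain along a trajectory
#'
#' Lays an MRG node/internode chain along the axon arc length with a
#' seeded uniform longitudinal shift of the first node (so nodes of
#' different axons do not align at the first cross-section), and maps
#' compartment centers back to 3D positions on the trajectory.
#'
#' @param trajectory List with `points` (n x 3, um) and `arclen` as
#'   returned by [axon_trajectory()].
#' @param diameter Fiber diameter, um, in `[1, 20]`.
#' @param seed Integer seed for the longitudinal shift.
#' @param detail `"reduced"`: node compartments plus one lumped passive
#'   myelinated compartment per internode (fast screen used for threshold
#'   matrices). `"full"`: explicit MYSA/FLUT/STIN double-cable sections.
#' @return An `ns_axon`: tibble of compartments (type, length, diameter,
#'   arc position, x/y/z) plus diameter and detail level.
#' @export
build_axon_geometry <- function(trajectory, diameter, seed = NULL,
                                detail = c("reduced", "full")) {
  detail <- match.arg(detail)
  p <- mrg_parameters(diameter)
  L <- trajectory$arclen[length(trajectory$arclen)]
  if (L < 2 * p$internode)
    stop("trajectory shorter than two internodes (", round(2 * p$internode),
         " um needed)")
  shift <- with_seed(seed, stats::runif(1, 0, p$internode))
  types <- if (detail == "reduced") c("node", "internode") else
    c("node", "mysa", "flut", rep("stin", 6), "flut", "mysa")
  lens <- if (detail == "reduced") c(p$node_len, p$internode - p$node_len) else
    c(p$node_len, p$mysa_len, p$flut_len, rep(p$stin_len, 6), p$flut_len,
      p$mysa_len)
  diams <- if (detail == "reduced") c(p$node_d, p$axon_d) else
    c(p$node_d, p$node_d, p$axon_d, rep(p$axon_d, 6), p$axon_d, p$node_d)
  # tile the repeating unit from the shifted first node, then close with a
  # terminal node
  type_v <- character(0); len_v <- numeric(0); diam_v <- numeric(0)
  pos <- shift
  while (pos + p$internode <= L) {
    type_v <- c(type_v, types); len_v <- c(len_v, lens)
    diam_v <- c(diam_v, diams)
    pos <- pos + p$internode
  }
  type_v <- c(type_v, "node"); len_v <- c(len_v, p$node_len)
  diam_v <- c(diam_v, p$node_d)
  ends <- shift + cumsum(len_v)
  centers <- ends - len_v / 2
  xyz <- apply(trajectory$points, 2, function(col)
    stats::approx(trajectory$arclen, col, xout = pmin(centers, L))$y)
  comps <- tibble::tibble(comp = seq_along(type_v), type = type_v,
                          length_um = len_v, diameter_um = diam_v,
                          s_um = centers,
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  structure(list(compartments = comps, fiber_d = diameter, detail = detail,
                 params = p, shift = shift),
            class = "ns_axon")
}

#' @export
print.ns_axon <- function(x, ...) {
  cat("<ns_axon>", x$fiber_d, "um fiber,", nrow(x$compartments),
      "compartments (", x$detail, "),",
      sum(x$compartments$type == "node"), "nodes\n")
  invisible(x)
}
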