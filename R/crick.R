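#' Crick parameters for an idealized coiled-coil bundle
#'
#' The backbone of a coiled coil is a "coil of coils": a minor alpha-helix
#' of radius R1 wound around a superhelical axis of radius R0. The defaults
#' reproduce a canonical left-handed heptad bundle: minor-helix frequency
#' 720/7 degrees per residue (3.5 residues per turn over two turns per
#' heptad), 1.51 A rise per residue, superhelical frequency -3.6 degrees
#' per residue. Chains are spaced evenly (360/n degrees) around the axis;
#' `orientation` gives each chain's direction along the axis (+1 up, -1
#' down), so c(1, -1) is an antiparallel dimer and c(1, -1, 1, -1) an
#' up-down-up-down tetramer.
#'
#' @param n_chains number of chains in the bundle.
#' @param chain_length residues per chain.
#' @param orientation integer vector of +1/-1 per chain (recycled from a
#'   scalar).
#' @param R0 superhelix radius (A); 4.9 suits a dimer, ~6.3 a tetramer.
#' @param R1 minor helix radius (A).
#' @param w0 superhelical frequency (degrees/residue; negative =
#'   left-handed supercoil).
#' @param w1 minor-helix frequency (degrees/residue).
#' @param rise rise per residue along the superhelical axis (A).
#' @param phi0 superhelical phase offset of chain 1 (degrees).
#' @param phi1 minor-helix phase offset (degrees); with the default 0 the
#'   core (inward-facing) heptad positions are residues 2 and 5 (0-based)
#'   modulo 7.
#' @return An object of class `crick_params`.
#' @export
crick_params <- function(n_chains = 2L, chain_length = 28L,
                         orientation = 1L, R0 = 4.9, R1 = 2.26,
                         w0 = -3.6, w1 = 720 / 7, rise = 1.51,
                         phi0 = 0, phi1 = 0) {
  n_chains <- as.integer(n_chains)
  chain_length <- as.integer(chain_length)
  orientation <- as.integer(rep_len(orientation, n_chains))
  if (n_chains < 1L || chain_length < 2L)
    stop("need n_chains >= 1 and chain_length >= 2", call. = FALSE)
  if (!all(orientation %in% c(-1L, 1L)))
    stop("orientation entries must be +1 or -1", call. = FALSE)
  if (R1 <= 0 || rise <= 0)
    stop("R1 and rise must be positive", call. = FALSE)
  if (n_chains > 1L && R1 > R0)
    stop("non-physical geometry: minor helix radius R1 (", R1,
         ") exceeds superhelix radius R0 (", R0, ")", call. = FALSE)
  structure(list(n_chains = n_chains, chain_length = chain_length,
                 orientation = orientation, R0 = R0, R1 = R1, w0 = w0,
                 w1 = w1, rise = rise, phi0 = phi0, phi1 = phi1),
            class = "crick_params")
}

# One chain of the parametric backbone running up the +z axis.
# Returns CA coordinates, the local superhelical-axis points, and
# side-chain pseudo-centers 1.5 A radially outward from the local axis.
crick_chain_up <- function(p, phase_deg) {
  t <- seq_len(p$chain_length) - 1
  a0 <- (p$w0 * t + phase_deg) * pi / 180
  a1 <- (p$w1 * t + p$phi1) * pi / 180
  w0r <- p$w0 * pi / 180
  alpha <- atan2(w0r * p$R0, p$rise)   # superhelix pitch angle
  ca <- cbind(
    x = p$R0 * cos(a0) + p$R1 * cos(a0) * cos(a1) -
      p$R1 * cos(alpha) * sin(a0) * sin(a1),
    y = p$R0 * sin(a0) + p$R1 * sin(a0) * cos(a1) +
      p$R1 * cos(alpha) * cos(a0) * sin(a1),
    z = p$rise * t - p$R1 * sin(alpha) * sin(a1))
  axis <- cbind(p$R0 * cos(a0), p$R0 * sin(a0), p$rise * t)
  v <- ca - axis
  sc <- ca + 1.5 * v / sqrt(rowSums(v^2))
  list(ca = ca, sc = sc)
}

#' Generate an idealized coiled-coil bundle
#'
#' Builds the CA trace of every chain from the Crick parametric equations
#' and places a pseudo side-chain center per residue 1.5 A radially outward
#' from the local minor-helix axis (sufficient for knobs-into-holes
#' detection, which consumes only side-chain centers). Chains with
#' orientation -1 are rotated 180 degrees about an in-plane axis (a proper
#' rotation, preserving handedness) so they run down the bundle while
#' spanning the same axial extent, giving a genuinely antiparallel
#' arrangement.
#'
#' @param params a `crick_params`.
#' @param plddt B-factor/pLDDT value stored on every residue (default 99).
#' @param noise_sd standard deviation (A) of isotropic Gaussian noise added
#'   to all coordinates; 0 for the ideal backbone. Uses the current RNG
#'   state.
#' @return A `fragment_model` (no PAE).
#' @export
crick_backbone <- function(params, plddt = 99, noise_sd = 0) {
  stopifnot(inherits(params, "crick_params"))
  p <- params
  zmax <- p$rise * (p$chain_length - 1)
  chains <- lapply(seq_len(p$n_chains), function(k) {
    phase <- p$phi0 + 360 * (k - 1) / p$n_chains
    if (p$orientation[k] == 1L) {
      ch <- crick_chain_up(p, phase)
    } else {
      # build at the mirrored phase, then rotate pi about the x axis and
      # recentre: residue numbering now runs down the -z direction
      ch <- crick_chain_up(p, -phase)
      flip <- function(m) cbind(m[, 1L], -m[, 2L], zmax - m[, 3L])
      ch <- list(ca = flip(ch$ca), sc = flip(ch$sc))
    }
    if (noise_sd > 0) {
      ch$ca <- ch$ca + matrix(stats::rnorm(length(ch$ca), 0, noise_sd),
                              ncol = 3L)
      ch$sc <- ch$sc + matrix(stats::rnorm(length(ch$sc), 0, noise_sd),
                              ncol = 3L)
    }
    data.frame(resno = seq_len(p$chain_length),
               x = ch$ca[, 1L], y = ch$ca[, 2L], z = ch$ca[, 3L],
               sx = ch$sc[, 1L], sy = ch$sc[, 2L], sz = ch$sc[, 3L],
               plddt = rep_len(plddt, p$chain_length))
  })
  names(chains) <- c(LETTERS, letters, as.character(0:9))[seq_len(p$n_chains)]
  structure(list(chains = chains, pae = NULL,
                 provenance = list(generator = "crick", params = p)),
            class = "fragment_model")
}

#' Generate an extended, non-interacting multi-chain model
#'
#' Straight CA traces (3.8 A spacing) with chains offset 100 A apart; used
#' by the fake prediction run to stand in for unstructured regions, where a
#' predictor returns low-confidence, non-packing chains.
#'
#' @param n_chains,chain_length bundle size.
#' @param plddt per-residue confidence to store.
#' @param noise_sd coordinate noise standard deviation (A).
#' @return A `fragment_model` (no PAE).
#' @export
extended_chains <- function(n_chains = 2L, chain_length = 28L, plddt = 40,
                            noise_sd = 0) {
  chains <- lapply(seq_len(n_chains), function(k) {
    t <- seq_len(chain_length) - 1
    ca <- cbind(3.8 * t, rep(100 * (k - 1), chain_length),
                numeric(chain_length))
    sc <- ca + matrix(rep(c(0, 0, 1.5), each = chain_length), ncol = 3L)
    if (noise_sd > 0) {
      ca <- ca + matrix(stats::rnorm(length(ca), 0, noise_sd), ncol = 3L)
      sc <- sc + matrix(stats::rnorm(length(sc), 0, noise_sd), ncol = 3L)
    }
    data.frame(resno = seq_len(chain_length),
               x = ca[, 1L], y = ca[, 2L], z = ca[, 3L],
               sx = sc[, 1L], sy = sc[, 2L], sz = sc[, 3L],
               plddt = rep_len(plddt, chain_length))
  })
  names(chains) <- c(LETTERS, letters, as.character(0:9))[seq_len(n_chains)]
  structure(list(chains = chains, pae = NULL,
                 provenance = list(generator = "extended")),
            class = "fragment_model")
}
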