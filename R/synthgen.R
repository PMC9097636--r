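# Synthetic-data generators with known ground truth. Every generator is a
# pure function of (parameters, seed); regeneration is bit-stable.

#' Default relaxation delay schedules
#'
#' The delay lists of the pseudo-3D acquisitions the package models: ten
#' longitudinal (\eqn{R_1}) delays between 0.01 and 2.00 s with the 0.507 s
#' plane duplicated for error analysis, and ten rotating-frame
#' (\eqn{R_{1\rho}}) delays between 0.01 and 0.2 s with the 0.0575 s plane
#' duplicated.
#'
#' @return Numeric vector of delays (s) with attribute
#'   \code{duplicate_delay}.
#' @export
default_r1_delays <- function() {
  structure(c(0.01, 2.00, 0.0308, 1.273, 0.063, 0.806, 0.114, 0.507,
              0.193, 0.315), duplicate_delay = 0.507)
}

#' @rdname default_r1_delays
#' @export
default_r1rho_delays <- function() {
  structure(c(0.01, 0.2, 0.012, 0.131, 0.0151, 0.086, 0.0199, 0.0575,
              0.0274, 0.0392), duplicate_delay = 0.0575)
}

#' Generate a synthetic relaxation peak table
#'
#' Mono-exponential decays \eqn{I_0 e^{-Rt}} with additive iid Gaussian
#' intensity noise, one residue per true rate, acquired on a delay schedule
#' with one duplicated delay (two replicate rows) exactly as in the modelled
#' experiments.
#'
#' @param rates true decay rates (\eqn{s^{-1}}), one per residue.
#' @param i0 true zero-time intensities (scalar or per residue).
#' @param delays delay schedule (s); default \code{\link{default_r1_delays}}.
#' @param duplicate_delay which delay receives a second replicate; default
#'   from the schedule's attribute; \code{NA} disables duplication.
#' @param sigma intensity noise SD (>= 0).
#' @param seed RNG seed.
#' @param residues residue numbers (default 1..n).
#' @param experiment_kind stored table kind.
#' @return A \code{\link{peak_table}} with attribute \code{ground_truth}
#'   (list of \code{rates}, \code{i0}, \code{sigma}, \code{seed}).
#' @export
gen_decay_dataset <- function(rates, i0 = 100, delays = default_r1_delays(),
                              duplicate_delay = attr(delays,
                                                     "duplicate_delay"),
                              sigma = 1, seed = 1L, residues = NULL,
                              experiment_kind = "T1") {
  stopifnot(sigma >= 0, all(delays > 0))
  n <- length(rates)
  i0 <- rep_len(i0, n)
  residues <- residues %||% seq_len(n)
  delay_vec <- as.numeric(delays)
  rep_vec <- rep(0L, length(delay_vec))
  if (!is.null(duplicate_delay) && !is.na(duplicate_delay)) {
    if (!duplicate_delay %in% delay_vec)
      stop_foxdyn("duplicate_delay is not part of the delay schedule",
                  "foxdyn_precondition_error")
    delay_vec <- c(delay_vec, duplicate_delay)
    rep_vec <- c(rep_vec, 1L)
  }
  m <- length(delay_vec)
  tab <- with_seed(seed, {
    I <- rep(i0, each = m) * exp(-rep(rates, each = m) * delay_vec) +
      rnorm(n * m, sd = sigma)
    data.frame(residue = rep(residues, each = m),
               delay = rep(delay_vec, n),
               intensity = I,
               replicate = rep(rep_vec, n))
  })
  structure(peak_table(tab$residue, tab$delay, tab$intensity, tab$replicate,
                       experiment_kind),
            ground_truth = list(rates = setNames(rates, residues), i0 = i0,
                                sigma = sigma, seed = seed),
            experiment_kind = experiment_kind,
            class = c("peak_table", "data.frame"))
}

#' Generate titration endpoint tables with a prescribed response pattern
#'
#' Starting from a base (free-state) shift table, the bound-state table
#' moves the residues of \code{strong_set} by composite CSPs above the
#' strong threshold, those of \code{weak_set} by CSPs between the noise
#' floor and the strong threshold, and assigns \code{broadened_set} a
#' bound/free intensity ratio below the broadening threshold. All other
#' residues are untouched.
#'
#' @param base a \code{\link{shift_table}} (the free state).
#' @param strong_set,weak_set,broadened_set disjoint vectors of residue
#'   numbers drawn from \code{base}.
#' @param seed RNG seed.
#' @param csp_strong,csp_floor,broadening_ratio thresholds the pattern is
#'   built around (must match the classifier's settings for a round trip).
#' @param n_scale nitrogen divisor used to distribute the CSP over H and N.
#' @return List: \code{free}, \code{bound} (shift tables),
#'   \code{free_intensities}, \code{bound_intensities} (named by residue),
#'   \code{truth} (data frame \code{residue}, \code{category}).
#' @export
gen_titration_tables <- function(base, strong_set = integer(),
                                 weak_set = integer(),
                                 broadened_set = integer(), seed = 1L,
                                 csp_strong = 0.05, csp_floor = 0.005,
                                 broadening_ratio = 0.3, n_scale = 7) {
  stopifnot(inherits(base, "shift_table"))
  sets <- list(strong_set, weak_set, broadened_set)
  if (anyDuplicated(unlist(sets)))
    stop_foxdyn("strong/weak/broadened sets must be disjoint",
                "foxdyn_precondition_error")
  if (!all(unlist(sets) %in% base$residue))
    stop_foxdyn("pattern sets must be subsets of the base residues",
                "foxdyn_precondition_error")
  bound <- base
  free_int <- setNames(rep(1, nrow(base)), base$residue)
  bound_int <- free_int
  truth <- data.frame(residue = base$residue, category = "unaffected",
                      stringsAsFactors = FALSE)
  with_seed(seed, {
    move <- function(resid, csp_lo, csp_hi) {
      for (r in resid) {
        i <- which(bound$residue == r)
        csp <- runif(1, csp_lo, csp_hi)
        phi <- runif(1, 0, pi / 2)
        sgn <- sample(c(-1, 1), 2, replace = TRUE)
        bound$dH[i] <<- bound$dH[i] + sgn[1] * csp * cos(phi)
        bound$dN[i] <<- bound$dN[i] + sgn[2] * csp * sin(phi) * n_scale
      }
    }
    move(strong_set, 1.5 * csp_strong, 3 * csp_strong)
    move(weak_set, 3 * csp_floor, 0.8 * csp_strong)
    for (r in broadened_set)
      bound_int[as.character(r)] <- runif(1, 0.02, 0.8 * broadening_ratio)
  })
  truth$category[truth$residue %in% strong_set] <- "strong_csp"
  truth$category[truth$residue %in% weak_set] <- "weak_csp"
  truth$category[truth$residue %in% broadened_set] <- "broadened"
  list(free = base, bound = bound, free_intensities = free_int,
       bound_intensities = bound_int, truth = truth)
}

#' Generate a homologous shift table with a target correlation
#'
#' Draws a second table whose shifts correlate with the base table at
#' population level \code{target_r} per nucleus:
#' \eqn{y = \bar x + \rho (x - \bar x) + \sqrt{1-\rho^2}\, s_x z}.
#'
#' @param base a \code{\link{shift_table}}.
#' @param target_r population Pearson correlation in [-1, 1].
#' @param seed RNG seed.
#' @param state_label label of the generated table.
#' @return List: \code{table_a} (the base), \code{table_b}.
#' @export
gen_homolog_shift_tables <- function(base, target_r, seed = 1L,
                                     state_label = "homolog") {
  stopifnot(inherits(base, "shift_table"),
            target_r >= -1, target_r <= 1)
  mix <- function(x, r) {
    z <- rnorm(length(x))
    mean(x) + r * (x - mean(x)) + sqrt(1 - r^2) * sd(x) * z
  }
  tb <- with_seed(seed, {
    shift_table(base$residue, base$aa,
                mix(base$dH, target_r), mix(base$dN, target_r),
                state_label)
  })
  list(table_a = base, table_b = tb)
}

# Idealised planar indole (fused pentagon + hexagon, 1.40 A sides) in local
# 2D coordinates, recentred so the 9-atom centroid is exactly the origin.
indole_template <- function() {
  s <- 1.40
  hex_r <- s
  hex <- t(vapply(0:5, function(k) {
    a <- pi / 6 + k * pi / 3
    c(hex_r * cos(a), hex_r * sin(a))
  }, numeric(2)))
  rownames(hex) <- c("CE2", "CZ2", "CH2", "CZ3", "CE3", "CD2")
  # pentagon shares the CD2-CE2 edge, built on the opposite side of the
  # hexagon centre
  p1 <- hex["CD2", ]; p2 <- hex["CE2", ]
  mid <- (p1 + p2) / 2
  edge <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  out <- c(mid[1], mid[2]) / sqrt(sum(mid^2))     # away from hexagon centre
  pen_r <- s / (2 * sin(pi / 5))
  pen_centre <- mid + out * pen_r * cos(pi / 5)
  ang0 <- atan2(p1[2] - pen_centre[2], p1[1] - pen_centre[1])
  step <- 2 * pi / 5
  # orient the pentagon walk so its second vertex is CE2
  a1 <- ang0 + step; a2 <- ang0 - step
  cand1 <- pen_centre + pen_r * c(cos(a1), sin(a1))
  dirn <- if (sum((cand1 - p2)^2) < 1e-9) 1 else -1
  pen <- t(vapply(0:4, function(k) {
    a <- ang0 + dirn * k * step
    pen_centre + pen_r * c(cos(a), sin(a))
  }, numeric(2)))
  rownames(pen) <- c("CD2", "CE2", "NE1", "CD1", "CG")
  xy <- rbind(hex[c("CE2", "CZ2", "CH2", "CZ3", "CE3", "CD2"), ],
              pen[c("NE1", "CD1", "CG"), ])
  sweep(xy, 2, colMeans(xy))
}

#' Generate an idealised helix carrying a W-[2-5]-[S/T/C/Y] motif
#'
#' Builds an ideal alpha-helical backbone (1.5 angstrom rise, 100 degrees
#' twist per residue, N/CA/C/O per residue) of alanines carrying one
#' tryptophan with a full planar 9-atom indole ring, and one partner residue
#' whose side-chain heteroatom is placed exactly at distance \code{d} and
#' angle \code{alpha} from the ring centroid/normal. Round-tripping through
#' \code{\link{evaluate_motif_geometry}} recovers (\code{d}, \code{alpha})
#' by construction.
#'
#' @param spacing residues between Trp and the partner (1..10).
#' @param d heteroatom-to-centroid distance (angstrom, >= 1).
#' @param alpha face/edge angle in degrees, [0, 90].
#' @param xaa_type partner residue type: \code{"S"}, \code{"T"}, \code{"C"}
#'   or \code{"Y"}.
#' @param trp_index position of the tryptophan along the helix.
#' @param n_res helix length (default: motif plus four trailing residues).
#' @param offset author-style number of the first residue.
#' @return A \code{\link{structure_record}} with attribute
#'   \code{ground_truth} (list \code{trp}, \code{xaa}, \code{d},
#'   \code{alpha}, \code{sequence}).
#' @export
gen_helix_with_motif <- function(spacing = 3L, d = 4, alpha = 0,
                                 xaa_type = c("S", "T", "C", "Y"),
                                 trp_index = 5L, n_res = NULL,
                                 offset = 1L) {
  xaa_type <- match.arg(xaa_type)
  if (!spacing %in% 1:10)
    stop_foxdyn("spacing must lie in 1..10", "foxdyn_precondition_error")
  if (d < 1)
    stop_foxdyn("heteroatom placement with d < 1 A is sterically impossible",
                "foxdyn_precondition_error")
  if (alpha < 0 || alpha > 90)
    stop_foxdyn("alpha must lie in [0, 90] degrees",
                "foxdyn_precondition_error")
  xaa_index <- trp_index + spacing + 1L
  n_res <- n_res %||% (xaa_index + 4L)
  stopifnot(n_res >= xaa_index)
  aa3 <- rep("ALA", n_res)
  aa3[trp_index] <- "TRP"
  aa3[xaa_index] <- c(S = "SER", T = "THR", C = "CYS", Y = "TYR")[xaa_type]

  rise <- 1.5; twist <- rad(100); r_ca <- 2.3
  name <- character(); resno <- integer(); resnm <- character()
  xyz <- NULL
  add <- function(atoms, coords, i) {
    name <<- c(name, atoms)
    resno <<- c(resno, rep(i + offset - 1L, length(atoms)))
    resnm <<- c(resnm, rep(aa3[i], length(atoms)))
    xyz <<- rbind(xyz, coords)
  }
  for (i in seq_len(n_res)) {
    phi <- twist * i
    u <- c(cos(phi), sin(phi), 0)                 # radial
    v <- c(-sin(phi), cos(phi), 0)                # tangential
    w <- c(0, 0, 1)                               # axial
    ca <- r_ca * u + c(0, 0, rise * i)
    add(c("N", "CA", "C", "O"),
        rbind(ca - 0.45 * u - 1.10 * v - 0.60 * w,
              ca,
              ca + 0.45 * u + 1.15 * v + 0.55 * w,
              ca + 0.50 * u + 1.35 * v + 1.70 * w), i)
    if (i == trp_index) {
      centroid <- ca + 3.5 * u
      tmpl <- indole_template()
      ring <- t(apply(tmpl, 1, function(p)
        centroid + p[1] * v + p[2] * w))          # ring plane = (v, w)
      add(rownames(tmpl), ring, i)
      motif_frame <- list(centroid = centroid, normal = u, inplane = v)
    }
    if (i == xaa_index) {
      mf <- motif_frame
      het <- mf$centroid + d * (cos(rad(alpha)) * mf$normal +
                                  sin(rad(alpha)) * mf$inplane)
      add(unname(XAA_HETEROATOM[xaa_type]), rbind(het), i)
    }
  }
  rec <- structure_record(name, resno, resnm, xyz[, 1], xyz[, 2], xyz[, 3])
  attr(rec, "ground_truth") <- list(
    trp = trp_index + offset - 1L, xaa = xaa_index + offset - 1L,
    d = d, alpha = alpha,
    sequence = paste(unname(AA3TO1[aa3]), collapse = ""))
  rec
}

# Rodrigues rotation matrix about unit axis by angle (radians).
rotation_about <- function(axis, angle) {
  a <- axis / vec3_norm(axis)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Generate a jittered multi-frame trajectory from a base structure
#'
#' Each frame is a random rigid rotation/translation of the base structure
#' (rotation angle and translation components bounded by
#' \code{rigid_amplitude}, in degrees and angstrom respectively) plus iid
#' Gaussian jitter of SD \code{jitter_sigma} on every coordinate.
#'
#' @param base a \code{\link{structure_record}}.
#' @param n_frames number of frames (>= 2).
#' @param rigid_amplitude bound on the rigid motion per frame.
#' @param jitter_sigma per-coordinate jitter SD (angstrom).
#' @param seed RNG seed.
#' @return A \code{\link{as_trajectory}} object with attribute
#'   \code{ground_truth} (list \code{jitter_sigma}, \code{rigid_amplitude},
#'   \code{seed}).
#' @export
gen_trajectory <- function(base, n_frames, rigid_amplitude = 0,
                           jitter_sigma = 0, seed = 1L) {
  stopifnot(inherits(base, "structure_record"), n_frames >= 2)
  n_atoms <- nrow(base)
  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      m <- base
      if (rigid_amplitude > 0) {
        axis <- rnorm(3)
        ang <- runif(1, 0, rad(rigid_amplitude))
        R <- rotation_about(axis, ang)
        tr <- runif(3, -rigid_amplitude, rigid_amplitude)
        m <- transform_structure(m, R, tr)
      }
      if (jitter_sigma > 0) {
        xyz <- coords_matrix(m) +
          matrix(rnorm(3 * n_atoms, sd = jitter_sigma), ncol = 3)
        m <- set_coords(m, xyz)
      }
      attr(m, "model_index") <- f
      m
    })
  })
  tr <- as_trajectory(frames)
  attr(tr, "ground_truth") <- list(jitter_sigma = jitter_sigma,
                                   rigid_amplitude = rigid_amplitude,
                                   seed = seed)
  tr
}
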