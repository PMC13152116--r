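# Synthetic fixtures with machine-readable ground truth.
#
# Everything the pipeline consumes can be generated here: an idealised
# seven-helix bundle with placed internal waters (the receptor-like
# fixture), sealed/open shell structures of analytically known cavity
# volume, two-state occupancy trajectories with exponential dwell times,
# rigid-plus-noise coordinate trajectories, and alignments with injected
# column frequencies.  Occupancy is generated as kinetics (presence
# channels), not physics: the package tests estimators, not force fields.

.deg <- pi / 180

#' Rotation matrix about an axis
#' @param axis Length-3 axis vector (normalised internally).
#' @param angle_deg Rotation angle in degrees.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * .deg
  c_ <- cos(th); s_ <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) * c_ + s_ * ux + (1 - c_) * (u %o% u)
}

# ---- seven-helix bundle ----------------------------------------------------

# idealised helix backbone: 100 deg twist, 1.5 A rise per residue; atom
# positions in cylindrical offsets relative to the Calpha trace
.helix_atom_geom <- list(
  N  = c(r = 1.6, dphi = -25, dz = -0.9),
  CA = c(r = 2.3, dphi = 0,   dz = 0),
  C  = c(r = 1.7, dphi = 25,  dz = 0.9),
  O  = c(r = 2.1, dphi = 40,  dz = 1.4),
  CB = c(r = 3.4, dphi = -15, dz = 0)
)

.build_helix <- function(chain, res_from, res_to, dir, anchor_res, anchor_z,
                         axis_xy, phase_anchor_deg) {
  resnos <- res_from:res_to
  rows <- list()
  for (m in seq_along(resnos)) {
    res <- resnos[m]
    z_ca <- anchor_z + dir * 1.5 * (res - anchor_res)
    phi <- phase_anchor_deg + dir * 100 * (res - anchor_res)
    for (an in names(.helix_atom_geom)) {
      g <- .helix_atom_geom[[an]]
      a_phi <- (phi + g[["dphi"]]) * .deg
      rows[[length(rows) + 1L]] <- data.frame(
        name = an, element = substr(an, 1, 1), chain = chain,
        resno = res, icode = "", resname = "ALA",
        record_class = "polymer",
        x = axis_xy[1] + g[["r"]] * cos(a_phi),
        y = axis_xy[2] + g[["r"]] * sin(a_phi),
        z = z_ca + g[["dz"]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.unit <- function(v) v / sqrt(sum(v^2))

.sidechain_atom <- function(waters, ca, ideal = 2.85) {
  # polar side-chain pseudo-atom serving one or two water positions;
  # placement is horizontal (no z pull) so neighbouring chain waters
  # stay outside the bond cutoff
  if (nrow(waters) == 1L) {
    d <- ca - waters[1, ]; d[3] <- 0
    return(waters[1, ] + ideal * .unit(d))
  }
  w1 <- waters[1, ]; w2 <- waters[2, ]
  m <- (w1 + w2) / 2
  axis <- .unit(w2 - w1)
  u <- ca - m; u[3] <- 0
  u <- u - sum(u * axis) * axis
  u <- .unit(u)
  half <- sqrt(sum((w2 - w1)^2)) / 2
  r <- max(ideal, half + 0.35)
  m + sqrt(r^2 - half^2) * u
}

.disc_atoms <- function(chain, z, radius, spacing, resno_start) {
  xs <- seq(-radius, radius, by = spacing)
  g <- expand.grid(x = xs, y = xs)
  g <- g[g$x^2 + g$y^2 <= radius^2, , drop = FALSE]
  data.frame(name = "CA", element = "C", chain = chain,
             resno = resno_start + seq_len(nrow(g)) - 1L, icode = "",
             resname = "GLY", record_class = "polymer",
             x = g$x, y = g$y, z = z, stringsAsFactors = FALSE)
}

#' Specification of the synthetic seven-helix bundle
#'
#' Defaults describe the receptor-like fixture: a GPR174-style hydration
#' inventory of 14 waters (5 ligand-pocket, 8 signalling-network in
#' clusters 2/2/4, 1 G-protein-interface), a small uncharged polar residue
#' (Thr) at 5.58, a lipid-like ligand in the orthosteric pocket and a
#' G-alpha C-terminal helix fragment docked at the intracellular face.
#'
#' @param bundle_radius Distance of each helix axis from the bundle axis
#'   (A).
#' @param residue_558 Three-letter residue type placed at 5.58.
#' @param with_waters,with_ligand,with_partner Toggle fixture components.
#' @param widen_ic Outward shift (A) applied to the intracellular halves
#'   of TM5/TM6, emulating a wider TM5-TM6 pocket; enlarges the extended
#'   water cavity.
#' @export
bundle_spec <- function(bundle_radius = 9, residue_558 = "THR",
                        with_waters = TRUE, with_ligand = TRUE,
                        with_partner = TRUE, widen_ic = 0) {
  list(bundle_radius = bundle_radius, residue_558 = residue_558,
       with_waters = with_waters, with_ligand = with_ligand,
       with_partner = with_partner, widen_ic = widen_ic)
}

# helix layout: resno ranges, direction of z with increasing resno, and
# the anchor residue fixing the helix's vertical register
.bundle_helices <- data.frame(
  tm = 1:7,
  from = c(20, 54, 92, 130, 184, 235, 272),
  to   = c(44, 78, 119, 152, 212, 262, 296),
  dir  = c(-1, 1, -1, 1, -1, 1, -1),
  anchor_res = c(32, 65, 105, 141, 205, 248, 284),
  anchor_z   = c(0, 1, 1, 0, -12, 0, 0)
)

# generic-number assignments (receptor chain A)
.bundle_generic_map <- data.frame(
  chain = "A",
  author_number = c(32, 65, 68, 105, 116, 141, 205, 208, 248, 284, 288, 292),
  generic_number = c("1.50", "2.50", "2.53", "3.39", "3.50", "4.50",
                     "5.58", "5.61", "6.50", "7.45", "7.49", "7.53"),
  stringsAsFactors = FALSE
)

# labelled-residue identities (by author number); 5.58 is set from the spec
.bundle_restypes <- c(`65` = "ASP", `68` = "GLN", `105` = "SER",
                      `116` = "ARG", `205` = "THR", `208` = "THR",
                      `284` = "ASN", `288` = "ASP", `292` = "TYR")

# side-chain polar atom name per residue type
.polar_atom_name <- c(ASP = "OD1", GLN = "OE1", SER = "OG", ARG = "NH1",
                      THR = "OG1", ASN = "OD1", TYR = "OH", CYS = "SG")

# signalling-chain water layout: a hydrogen-bonded "necklace" descending
# the receptor core from the sodium pocket to the G-protein interface,
# drifting toward TM5 across the DRY cluster
.bundle_swaters <- data.frame(
  name = c("W_S1", "W_S2", "W_S3", "W_S4", "W_S5", "W_S6", "W_S7", "W_S8",
           "W_G1"),
  x = c(0, 0.4, 0, 0.4, 0, -0.8, -1.6, -2.4, -1.2),
  y = c(0, 0.3, 0, 0.3, 0, -0.4, -0.8, -1.2, -0.6),
  z = c(2, -0.7, -3.4, -6.1, -8.8, -11.3, -13.8, -16.3, -19),
  stringsAsFactors = FALSE
)

# intended water -> coordinating generic positions (fixture ground truth)
.bundle_contacts <- list(
  W_S1 = c("2.50", "3.39", "2.53"),
  W_S2 = c("2.50", "7.45"),
  W_S3 = c("7.49"),
  W_S4 = c("7.49", "7.53"),
  W_S5 = c("3.50"),
  W_S6 = c("3.50", "5.58"),
  W_S7 = c("5.58", "5.61"),
  W_S8 = c("5.61"),
  W_G1 = c("3.50")
)

#' Generate the synthetic seven-helix bundle fixture
#'
#' Builds the structure deterministically from the spec, together with the
#' generic-number mapping table, the monitored-site table (W_S1-W_S8 and
#' W_G1) and a ground-truth record (intended water regions and clusters,
#' intended 5.58 class, connectivity terminals).  When `dir` is given, the
#' PDB, mapping TSV, site TSV and truth JSON are written there.
#'
#' @param spec A [bundle_spec()].
#' @param dir Optional output directory.
#' @param prefix File-name prefix used with `dir`.
#' @return List with `structure` (numbered `hydronet_structure`),
#'   `mapping`, `sites`, `truth` and (when written) `files`.
#' @export
make_bundle_structure <- function(spec = bundle_spec(), dir = NULL,
                                  prefix = "bundle") {
  h <- .bundle_helices
  azim <- (h$tm - 1) * 360 / 7
  parts <- list()
  for (k in seq_len(nrow(h))) {
    axis_xy <- spec$bundle_radius * c(cos(azim[k] * .deg),
                                      sin(azim[k] * .deg))
    # anchor residue's Calpha faces the bundle axis
    parts[[k]] <- .build_helix("A", h$from[k], h$to[k], h$dir[k],
                               h$anchor_res[k], h$anchor_z[k],
                               axis_xy, azim[k] + 180)
  }
  atoms <- do.call(rbind, parts)

  if (spec$widen_ic > 0) {
    # push the intracellular halves of TM5/TM6 outward (linear ramp below
    # z0), widening the TM5-TM6 pocket that hosts the EWC
    z0 <- -4
    for (tm in 5:6) {
      sel <- atoms$resno >= h$from[tm] & atoms$resno <= h$to[tm]
      out_dir <- c(cos(azim[tm] * .deg), sin(azim[tm] * .deg))
      ramp <- pmin(1, pmax(0, (z0 - atoms$z[sel]) / 10))
      atoms$x[sel] <- atoms$x[sel] + spec$widen_ic * ramp * out_dir[1]
      atoms$y[sel] <- atoms$y[sel] + spec$widen_ic * ramp * out_dir[2]
    }
  }

  # residue identities at labelled positions
  restypes <- .bundle_restypes
  restypes[["205"]] <- toupper(spec$residue_558)
  for (rn in names(restypes))
    atoms$resname[atoms$resno == as.integer(rn)] <- restypes[[rn]]

  swat <- .bundle_swaters
  ca_of <- function(resno) {
    r <- atoms[atoms$resno == resno & atoms$name == "CA", ]
    c(r$x, r$y, r$z)
  }
  gen2res <- stats::setNames(.bundle_generic_map$author_number,
                             .bundle_generic_map$generic_number)
  # invert intended contacts: residue -> waters served
  served <- list()
  for (w in names(.bundle_contacts))
    for (g in .bundle_contacts[[w]])
      served[[g]] <- c(served[[g]], w)
  sc_rows <- list()
  for (g in names(served)) {
    res <- gen2res[[g]]
    typ <- restypes[[as.character(res)]]
    # residue types without a polar side-chain atom (e.g. Gly at 5.58 in
    # classification-only fixtures) place nothing
    if (!typ %in% names(.polar_atom_name)) next
    wsel <- as.matrix(swat[match(served[[g]], swat$name), c("x", "y", "z")])
    pos <- .sidechain_atom(wsel, ca_of(res))
    sc_rows[[length(sc_rows) + 1L]] <- data.frame(
      name = .polar_atom_name[[typ]],
      element = substr(.polar_atom_name[[typ]], 1, 1), chain = "A",
      resno = res, icode = "", resname = typ, record_class = "polymer",
      x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE)
  }
  # second guanidinium nitrogen of R3.50 reaches down to the interface
  # water (the terminal bridge to the G-protein helix)
  wg1 <- as.matrix(swat[swat$name == "W_G1", c("x", "y", "z")])
  nh2 <- .sidechain_atom(wg1, ca_of(gen2res[["3.50"]]))
  sc_rows[[length(sc_rows) + 1L]] <- data.frame(
    name = "NH2", element = "N", chain = "A", resno = gen2res[["3.50"]],
    icode = "", resname = "ARG", record_class = "polymer",
    x = nh2[1], y = nh2[2], z = nh2[3], stringsAsFactors = FALSE)
  atoms <- rbind(atoms, do.call(rbind, sc_rows))
  atoms <- atoms[order(atoms$resno, atoms$name != "N"), , drop = FALSE]

  # ligand: lipid-like headgroup (five polar atoms on a ring) plus a
  # short apolar tail sealing the extracellular mouth
  lig <- NULL
  if (spec$with_ligand) {
    phis <- (0:4) * 72 * .deg
    lig <- rbind(
      data.frame(name = c("O1", "O2", "O3", "O4", "N1"),
                 element = c("O", "O", "O", "O", "N"), chain = "A",
                 resno = 401L, icode = "", resname = "LPS",
                 record_class = "ligand",
                 x = 1.8 * cos(phis), y = 1.8 * sin(phis), z = 10.2,
                 stringsAsFactors = FALSE),
      data.frame(name = c("C1", "P1", "C2", "C3", "C4", "C5"),
                 element = c("C", "P", "C", "C", "C", "C"), chain = "A",
                 resno = 401L, icode = "", resname = "LPS",
                 record_class = "ligand",
                 x = c(0, 0, 0.7, -0.5, 0.3, 0),
                 y = c(0, 0, 0.3, 0.8, -0.6, 0),
                 z = c(10.2, 11.5, 12.3, 13.8, 15.2, 16.6),
                 stringsAsFactors = FALSE))
  }

  # G-alpha C-terminal helix fragment (chain B), translated so that the
  # backbone carbonyl of residue 391 caps the interface water from below
  partner <- NULL
  if (spec$with_partner) {
    partner <- .build_helix("B", 385, 396, 1, 390, 0, c(0, 0), 0)
    # lay it horizontally under the bundle
    pxyz <- as.matrix(partner[, c("x", "y", "z")])
    rot <- rotation_matrix(c(0, 1, 0), 90)
    pxyz <- pxyz %*% t(rot)
    o391 <- which(partner$resno == 391 & partner$name == "O")
    target <- as.numeric(wg1) + c(0, 0, -2.85)
    shift <- target - pxyz[o391, ]
    pxyz <- sweep(pxyz, 2, shift, "+")
    partner[, c("x", "y", "z")] <- pxyz
    partner$resname[partner$resno == 391] <- "TYR"
    partner$resname[partner$resno == 392] <- "ASP"
  }

  caps <- rbind(.disc_atoms("X", 21.5, 11, 1.5, 1L),
                .disc_atoms("Y", -23.5, 11, 1.5, 1L))

  waters <- NULL
  sites <- swat
  truth_regions <- character()
  if (spec$with_waters) {
    lw <- NULL
    if (spec$with_ligand) {
      phis <- (0:4) * 72 * .deg
      lw <- data.frame(name = paste0("W_L", 1:5),
                       x = 4.65 * cos(phis), y = 4.65 * sin(phis),
                       z = 10.2, stringsAsFactors = FALSE)
    }
    wtab <- rbind(lw, swat)
    waters <- data.frame(name = "O", element = "O", chain = "W",
                         resno = seq_len(nrow(wtab)), icode = "",
                         resname = "HOH", record_class = "water",
                         x = wtab$x, y = wtab$y, z = wtab$z,
                         stringsAsFactors = FALSE)
    truth_regions <- stats::setNames(
      c(rep("L", if (is.null(lw)) 0 else 5), rep("S", 8), "G"),
      wtab$name)
    attr(waters, "site_names") <- stats::setNames(
      wtab$name, paste("W", seq_len(nrow(wtab)), "", sep = "|"))
  }

  all_atoms <- rbind(atoms, lig, partner, caps, waters)
  all_atoms$id <- seq_len(nrow(all_atoms))
  all_atoms$generic <- NA_character_
  rownames(all_atoms) <- NULL
  all_atoms <- all_atoms[, c("id", "name", "element", "chain", "resno",
                             "icode", "resname", "record_class",
                             "x", "y", "z", "generic")]
  st <- structure(list(atoms = all_atoms,
                       metadata = list(source = "synthetic-bundle",
                                       dialect = "pdb",
                                       water_names = c("HOH", "WAT"))),
                  class = "hydronet_structure")
  st <- assign_generic_numbers(st, .bundle_generic_map)

  cls558 <- if (toupper(spec$residue_558) %in%
                position_558_classes()$`small-polar`) "small-polar"
            else if (toupper(spec$residue_558) %in%
                     position_558_classes()$bulky) "bulky" else "other"
  truth <- list(
    n_waters = if (spec$with_waters) nrow(structure_waters(st)) else 0L,
    regions = as.list(truth_regions),
    clusters = list(W_S1 = 1, W_S2 = 1, W_S3 = 2, W_S4 = 2,
                    W_S5 = 3, W_S6 = 3, W_S7 = 3, W_S8 = 3),
    contacts = .bundle_contacts,
    class_558 = cls558,
    residue_558 = toupper(spec$residue_558),
    terminals = c("A/65/OD1", "B/391/O"),
    widen_ic = spec$widen_ic
  )
  site_names <- if (spec$with_waters) attr(waters, "site_names") else NULL

  out <- list(structure = st, mapping = .bundle_generic_map,
              sites = sites, truth = truth, site_names = site_names)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    f <- list(
      pdb = file.path(dir, paste0(prefix, ".pdb")),
      mapping = file.path(dir, paste0(prefix, "_mapping.tsv")),
      sites = file.path(dir, paste0(prefix, "_sites.tsv")),
      truth = file.path(dir, paste0(prefix, "_truth.json")))
    write_structure(st, f$pdb)
    write.table(.bundle_generic_map, f$mapping, sep = "\t", quote = FALSE,
                row.names = FALSE)
    sites_out <- cbind(sites, region = c(rep("S", 8), "G"))
    write.table(sites_out, f$sites, sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(truth, f$truth, auto_unbox = TRUE, digits = NA)
    out$files <- f
  }
  out
}

# ---- analytic cavity fixtures ---------------------------------------------

#' Sealed or open shell with analytically known interior volume
#'
#' Wall atom centres are placed so that, after dilation by the atom radius
#' plus the small probe, the free interior is a cube of edge `inner_edge`
#' (analytic volume `inner_edge^3`) or, with `shape = "sphere"`, a ball of
#' diameter `inner_edge`.  With `sealed = FALSE` a mouth of width
#' `mouth_width` is cut around the +z pole; to let the large probe pass,
#' the aperture must exceed twice (atom radius + probe_out).  The sphere
#' is the geometry in which a wide-open mouth leaves no cavity at all:
#' the accessible shell is exactly one probe-radius difference thick
#' everywhere, with no corners.
#'
#' @param inner_edge Interior cube edge, or sphere diameter (A).
#' @param sealed Sealed shell (TRUE) or open shell (FALSE).
#' @param mouth_width Mouth width (A) when open.
#' @param probe_in Small probe radius the fixture is calibrated for.
#' @param atom_radius Wall atom radius (carbon).
#' @param wall_spacing Wall lattice spacing (A).
#' @param shape `"cube"` or `"sphere"`.
#' @return List with `structure` and `truth` (analytic volume, or NA for
#'   an open shell).
#' @export
make_shell_structure <- function(inner_edge = 10, sealed = TRUE,
                                 mouth_width = 0, probe_in = 1.4,
                                 atom_radius = 1.7, wall_spacing = 0.8,
                                 shape = c("cube", "sphere")) {
  shape <- match.arg(shape)
  if (!sealed && mouth_width <= 0)
    stop("open shell requested with non-positive mouth_width")
  h <- inner_edge / 2 + atom_radius + probe_in
  if (shape == "cube") {
    xs <- seq(-h, h, length.out = max(2, ceiling(2 * h / wall_spacing) + 1))
    g2 <- expand.grid(a = xs, b = xs)
    faces <- list()
    for (sgn in c(-1, 1)) {
      faces[[length(faces) + 1L]] <- cbind(g2$a, g2$b, sgn * h)
      faces[[length(faces) + 1L]] <- cbind(g2$a, sgn * h, g2$b)
      faces[[length(faces) + 1L]] <- cbind(sgn * h, g2$a, g2$b)
    }
    xyz <- unique(do.call(rbind, faces))
    if (!sealed) {
      drop <- xyz[, 3] > h - 1e-9 & abs(xyz[, 1]) < mouth_width / 2 &
        abs(xyz[, 2]) < mouth_width / 2
      xyz <- xyz[!drop, , drop = FALSE]
    }
  } else {
    # Fibonacci lattice on the sphere of radius h
    n <- max(16L, ceiling(4 * pi * h^2 / wall_spacing^2))
    k <- seq_len(n) - 0.5
    zs <- 1 - 2 * k / n
    rr <- sqrt(pmax(0, 1 - zs^2))
    golden <- pi * (3 - sqrt(5))
    xyz <- h * cbind(rr * cos(golden * k), rr * sin(golden * k), zs)
    if (!sealed) {
      drop <- xyz[, 3] > 0 &
        sqrt(xyz[, 1]^2 + xyz[, 2]^2) < mouth_width / 2
      xyz <- xyz[!drop, , drop = FALSE]
    }
  }
  atoms <- data.frame(id = seq_len(nrow(xyz)), name = "C", element = "C",
                      chain = "Z", resno = seq_len(nrow(xyz)), icode = "",
                      resname = "SHL", record_class = "polymer",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      generic = NA_character_, stringsAsFactors = FALSE)
  st <- structure(list(atoms = atoms,
                       metadata = list(source = "synthetic-shell",
                                       dialect = "pdb",
                                       water_names = c("HOH", "WAT"))),
                  class = "hydronet_structure")
  vol <- if (!sealed) NA
         else if (shape == "cube") inner_edge^3
         else 4 / 3 * pi * (inner_edge / 2)^3
  list(structure = st,
       truth = list(analytic_volume = vol, shape = shape,
                    sealed = sealed, mouth_width = mouth_width))
}

#' Solid close-packed atom block (zero-cavity fixture)
#' @param edge Block edge (A).
#' @param spacing Lattice spacing (A).
#' @export
make_solid_block <- function(edge = 12, spacing = 1.2) {
  xs <- seq(-edge / 2, edge / 2, by = spacing)
  g <- expand.grid(x = xs, y = xs, z = xs)
  atoms <- data.frame(id = seq_len(nrow(g)), name = "C", element = "C",
                      chain = "Z", resno = seq_len(nrow(g)), icode = "",
                      resname = "BLK", record_class = "polymer",
                      x = g$x, y = g$y, z = g$z, generic = NA_character_,
                      stringsAsFactors = FALSE)
  structure(list(atoms = atoms,
                 metadata = list(source = "synthetic-block",
                                 dialect = "pdb",
                                 water_names = c("HOH", "WAT"))),
            class = "hydronet_structure")
}

# ---- two-state occupancy kinetics ------------------------------------------

.dwell_switch_times <- function(tau_b, tau_u, t_end) {
  # alternating exponential dwells starting bound; returns switch times
  # starting at 0, odd intervals bound
  est <- ceiling(2.5 * t_end / (tau_b + tau_u)) + 50L
  ct <- numeric(0); last <- 0
  while (last < t_end) {
    db <- stats::rexp(est, 1 / tau_b)
    du <- stats::rexp(est, 1 / tau_u)
    seg <- last + cumsum(as.vector(rbind(db, du)))
    ct <- c(ct, seg)
    last <- seg[length(seg)]
  }
  c(0, ct)
}

.presence_from_switches <- function(sw, dt, n_frames) {
  # frame f covers [(f-1) dt, f dt); marked bound only when the bound
  # state persists through the whole window (continuous-bond
  # convention: an episode is one uninterrupted bond formation, so any
  # intra-window unbinding breaks it)
  bstart <- sw[seq(1, length(sw) - 1, by = 2)]
  bend <- sw[seq(2, length(sw), by = 2)]
  cb <- c(0, cumsum(bend - bstart))
  bound_time_upto <- function(t) {
    i <- findInterval(t, sw)
    partial <- ifelse(i %% 2 == 1, t - sw[i], 0)
    cb[floor(i / 2) + 1] + partial
  }
  ws <- (seq_len(n_frames) - 1) * dt
  bt <- bound_time_upto(ws + dt) - bound_time_upto(ws)
  as.integer(bt >= dt * (1 - 1e-9))
}

#' Generate a two-state (bound/unbound) occupancy trajectory
#'
#' Each site alternates exponential bound and unbound dwells with the
#' stated means, starting bound, and is discretised at `dt` by the
#' continuous-bond rule: a frame is bound only when the bound state
#' persists through the whole frame window, so every discrete episode
#' corresponds to one uninterrupted bond formation.  Reproducible for a
#' fixed seed.
#'
#' @param tau_b,tau_u Mean bound / unbound dwell times (ps).
#' @param dt Frame spacing (ps).
#' @param n_frames Number of frames.
#' @param n_sites Number of independent site channels.
#' @param seed RNG seed.
#' @return List with `presence` (0/1 matrix frames x sites), `dt` and
#'   `truth` (the injected parameters).
#' @export
make_occupancy_trajectory <- function(tau_b, tau_u, dt, n_frames,
                                      n_sites = 1L, seed = 1L) {
  stopifnot(tau_b > 0, tau_u > 0, dt > 0, n_frames >= 1)
  if (dt >= tau_b)
    warning("dt >= tau_b: discretisation bias will dominate")
  set.seed(seed)
  t_end <- n_frames * dt
  pres <- matrix(0L, n_frames, n_sites,
                 dimnames = list(NULL, paste0("site", seq_len(n_sites))))
  for (s in seq_len(n_sites)) {
    sw <- .dwell_switch_times(tau_b, tau_u, t_end)
    pres[, s] <- .presence_from_switches(sw, dt, n_frames)
  }
  list(presence = pres, dt = dt,
       truth = list(tau_b = tau_b, tau_u = tau_u, dt = dt,
                    n_frames = n_frames, n_sites = n_sites, seed = seed,
                    discretisation = "continuous-bond"))
}

# ---- alignments ------------------------------------------------------------

#' Generate an alignment with injected column compositions
#'
#' Exact-count mode (`counts`) fills each specified column with the stated
#' residue multiset deterministically, then shuffles sequence order with
#' the seed; probabilistic mode (`probs`) samples residues independently.
#' Unspecified columns and the remainder of partially specified ones are
#' filled with the background residue.
#'
#' @param n_sequences Number of sequences.
#' @param column_specs Named list keyed by 1-based column index; each
#'   element is `list(counts = c(Y = 91, F = 9))` or
#'   `list(probs = c(Y = 0.75))`.  Residues are one-letter codes
#'   (three-letter accepted).
#' @param n_columns Alignment width (default: largest specified column).
#' @param background Fill residue.
#' @param seed RNG seed.
#' @param path Optional FASTA output path.
#' @return List with `sequences` (named character vector), `truth`
#'   (injected per-column compositions) and `path` when written.
#' @export
make_alignment <- function(n_sequences, column_specs, n_columns = NULL,
                           background = "A", seed = 1L, path = NULL) {
  stopifnot(n_sequences >= 1)
  cols <- as.integer(names(column_specs))
  if (any(is.na(cols))) stop("column_specs must be keyed by column index")
  if (is.null(n_columns)) n_columns <- max(cols)
  set.seed(seed)
  mat <- matrix(background, n_sequences, n_columns)
  for (k in seq_along(column_specs)) {
    spec <- column_specs[[k]]
    j <- cols[k]
    if (!is.null(spec$counts)) {
      cnt <- spec$counts
      names(cnt) <- .canon_aa(names(cnt))
      if (sum(cnt) > n_sequences)
        stop("column ", j, ": counts exceed n_sequences")
      fill <- c(rep(names(cnt), cnt),
                rep(background, n_sequences - sum(cnt)))
      mat[, j] <- fill
    } else if (!is.null(spec$probs)) {
      p <- spec$probs
      names(p) <- .canon_aa(names(p))
      if (sum(p) > 1 + 1e-12) stop("column ", j, ": probabilities sum > 1")
      lev <- c(names(p), background)
      pv <- c(p, 1 - sum(p))
      mat[, j] <- sample(lev, n_sequences, replace = TRUE, prob = pv)
    } else stop("column spec needs 'counts' or 'probs'")
  }
  mat <- mat[sample.int(n_sequences), , drop = FALSE]
  seqs <- stats::setNames(apply(mat, 1, paste0, collapse = ""),
                          sprintf("seq%04d", seq_len(n_sequences)))
  truth <- list(n_sequences = n_sequences, seed = seed,
                columns = lapply(seq_along(column_specs), function(k)
                  list(column = cols[k], spec = column_specs[[k]])))
  out <- list(sequences = seqs, truth = truth)
  if (!is.null(path)) {
    writeLines(paste0(">", names(seqs), "\n", seqs), path)
    out$path <- path
  }
  out
}

# ---- rigid-plus-noise trajectories -----------------------------------------

#' Generate a rigid-plus-noise coordinate trajectory from a structure
#'
#' Frame k applies the k-th rigid transform to the reference coordinates
#' and adds isotropic Gaussian noise of standard deviation `sigma` per
#' coordinate.
#'
#' @param structure Reference `hydronet_structure`.
#' @param transforms List (length = frames) of
#'   `list(rotation = 3x3, translation = length-3)`, or NULL entries for
#'   identity; alternatively `NULL` with `n_frames` for all-identity.
#' @param sigma Noise SD per coordinate (A).
#' @param n_frames Frame count when `transforms` is NULL.
#' @param dt Frame spacing (ps).
#' @param seed RNG seed.
#' @param path Optional multi-model PDB output path.
#' @return A `hydronet_trajectory` with attribute `truth`.
#' @export
make_rigid_trajectory <- function(structure, transforms = NULL, sigma = 0,
                                  n_frames = NULL, dt = 100, seed = 1L,
                                  path = NULL) {
  stopifnot(sigma >= 0)
  if (is.null(transforms)) {
    if (is.null(n_frames)) stop("give transforms or n_frames")
    transforms <- vector("list", n_frames)
  }
  nf <- length(transforms)
  set.seed(seed)
  ref <- as.matrix(structure$atoms[, c("x", "y", "z")])
  na <- nrow(ref)
  coords <- array(0, dim = c(na, 3, nf))
  for (k in seq_len(nf)) {
    tr <- transforms[[k]]
    fr <- if (is.null(tr)) ref
          else ref %*% t(tr$rotation) +
            matrix(tr$translation, na, 3, byrow = TRUE)
    if (sigma > 0) fr <- fr + matrix(stats::rnorm(na * 3, 0, sigma), na, 3)
    coords[, , k] <- fr
  }
  traj <- structure(list(atoms = structure$atoms, coords = coords,
                         n_frames = nf, dt = dt),
                    class = "hydronet_trajectory")
  attr(traj, "truth") <- list(sigma = sigma, n_frames = nf, seed = seed)
  if (!is.null(path)) write_trajectory_pdb(traj, path)
  traj
}

#' Write a trajectory as a multi-model PDB file
#' @param trajectory A `hydronet_trajectory`.
#' @param path Output path.
#' @export
write_trajectory_pdb <- function(trajectory, path) {
  a <- trajectory$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(trajectory$n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    af <- a
    af$x <- trajectory$coords[, 1, f]
    af$y <- trajectory$coords[, 2, f]
    af$z <- trajectory$coords[, 3, f]
    writeLines(.fmt_pdb_atom(af, seq_len(nrow(af))), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
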