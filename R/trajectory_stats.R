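# Trajectory statistics: hydrogen-bond episode lifetimes (t_avg), water
# site occupancy N_Wat(t), and network rehydration times.
#
# All times are carried internally in picoseconds; report writers convert
# to nanoseconds.

#' Read a multi-model PDB trajectory
#'
#' Every MODEL block must share one topology (same atom count and order).
#' A single-model file is accepted with a warning (n_frames = 1).
#'
#' @param path Multi-model PDB path.
#' @param dt Frame spacing in ps (default 100; stored with the object).
#' @param water_names Residue names treated as water.
#' @return `hydronet_trajectory`: list with `atoms` (topology data frame of
#'   the first model), `coords` (array n_atoms x 3 x n_frames), `n_frames`
#'   and `dt`.
#' @export
read_trajectory <- function(path, dt = 100, water_names = c("HOH", "WAT")) {
  if (dt <= 0) stop("frame spacing dt must be positive")
  lines <- readLines(path, warn = FALSE)
  starts <- which(startsWith(lines, "MODEL"))
  if (length(starts) == 0L) {
    warning("single-model file read as a 1-frame trajectory")
    s <- parse_structure(path, water_names = water_names)
    coords <- array(as.matrix(s$atoms[, c("x", "y", "z")]),
                    dim = c(nrow(s$atoms), 3, 1))
    return(structure(list(atoms = s$atoms, coords = coords,
                          n_frames = 1L, dt = dt),
                     class = "hydronet_trajectory"))
  }
  ends <- which(startsWith(lines, "ENDMDL"))
  if (length(ends) != length(starts))
    stop("unbalanced MODEL/ENDMDL records in ", path)
  frames <- lapply(seq_along(starts), function(k) {
    .atom_lines_to_df(lines[(starts[k] + 1L):(ends[k] - 1L)], water_names)
  })
  counts <- vapply(frames, function(f) if (is.null(f)) 0L else nrow(f),
                   integer(1))
  if (any(counts == 0L)) stop("empty MODEL block in ", path)
  if (length(unique(counts)) != 1L)
    stop("inconsistent atom counts between models: ",
         paste(unique(counts), collapse = ", "))
  coords <- array(0, dim = c(counts[1], 3, length(frames)))
  for (k in seq_along(frames))
    coords[, , k] <- as.matrix(frames[[k]][, c("x", "y", "z")])
  structure(list(atoms = frames[[1]], coords = coords,
                 n_frames = length(frames), dt = dt),
            class = "hydronet_trajectory")
}

#' @export
print.hydronet_trajectory <- function(x, ...) {
  cat("hydronet_trajectory:", x$n_frames, "frames x", nrow(x$atoms),
      "atoms, dt =", x$dt, "ps\n")
  invisible(x)
}

#' Read a water-site list TSV (`name  x  y  z  region`)
#' @param path TSV path.
#' @export
read_sites <- function(path) {
  s <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "x", "y", "z") %in% names(s)))
  s
}

#' Per-frame occupancy of predefined water sites
#'
#' A site is occupied in a frame iff at least one water oxygen lies within
#' `radius` of the site position, after optional per-frame superposition
#' of the receptor Calpha atoms onto the first frame.  Multiple waters
#' inside one site count once; multiplicity events are tallied in the
#' `multiplicity_events` attribute.
#'
#' @param trajectory A `hydronet_trajectory` whose topology contains water
#'   atoms.
#' @param sites Data frame with columns name, x, y, z (site positions in
#'   the reference frame).
#' @param radius Assignment radius in Angstrom (default 1.5: discriminates
#'   adjacent crystallographic sites ~2.8 A apart while tolerating thermal
#'   jitter).
#' @param superpose Superpose each frame on the first frame's Calpha atoms
#'   before testing distances.
#' @return `hydronet_occupancy`: list with `sites`, logical matrix
#'   `occupied` (frames x sites) and `dt` (ps).
#' @export
site_occupancy <- function(trajectory, sites, radius = 1.5,
                           superpose = TRUE) {
  if (radius <= 0) stop("assignment radius must be positive")
  if (nrow(sites) == 0L) stop("empty site list")
  atoms <- trajectory$atoms
  wsel <- which(atoms$record_class == "water" & atoms$element == "O")
  if (length(wsel) == 0L) stop("no water atoms in trajectory topology")
  casel <- which(atoms$name == "CA" & atoms$record_class == "polymer")
  ref_ca <- if (length(casel) >= 3L)
    trajectory$coords[casel, , 1, drop = FALSE][, , 1] else NULL
  sp_xyz <- as.matrix(sites[, c("x", "y", "z")])
  nf <- trajectory$n_frames
  occ <- matrix(FALSE, nf, nrow(sites),
                dimnames = list(NULL, sites$name))
  mult <- 0L
  r2 <- radius^2
  for (f in seq_len(nf)) {
    fr <- trajectory$coords[, , f]
    if (superpose && !is.null(ref_ca)) {
      sp <- superpose_kabsch(fr[casel, , drop = FALSE], ref_ca)
      fr <- apply_superposition(fr, sp)
    }
    d2 <- .pairwise_dist2(fr[wsel, , drop = FALSE], sp_xyz)
    hits <- colSums(d2 <= r2)
    occ[f, ] <- hits > 0L
    mult <- mult + sum(hits > 1L)
  }
  out <- structure(list(sites = sites, occupied = occ,
                        dt = trajectory$dt),
                   class = "hydronet_occupancy")
  attr(out, "multiplicity_events") <- mult
  if (mult > 0L)
    message(mult, " site-frame event(s) with >1 water inside the radius ",
            "(counted once)")
  out
}

#' Occupancy object from a raw presence matrix
#'
#' Wraps a binary frames x sites matrix (e.g. from
#' [make_occupancy_trajectory()]) in the container used by the occupancy
#' statistics.
#' @param presence Logical/0-1 matrix, frames in rows.
#' @param dt Frame spacing (ps).
#' @param site_names Optional column labels.
#' @export
occupancy_from_matrix <- function(presence, dt,
                                  site_names = colnames(presence)) {
  presence <- as.matrix(presence) > 0
  if (is.null(site_names)) site_names <- paste0("site", seq_len(ncol(presence)))
  colnames(presence) <- site_names
  sites <- data.frame(name = site_names, x = NA_real_, y = NA_real_,
                      z = NA_real_, stringsAsFactors = FALSE)
  structure(list(sites = sites, occupied = presence, dt = dt),
            class = "hydronet_occupancy")
}

#' Simultaneously occupied site count N_Wat(t)
#'
#' @param occ A `hydronet_occupancy`.
#' @param threshold Threshold used for the reported fraction of frames
#'   with `N_Wat >= threshold` (default: the number of sites, generalising
#'   the `N_Wat >= 9` network-reformation convention).
#' @return Integer vector of per-frame counts with attribute
#'   `frac_at_threshold`.
#' @export
nwat_series <- function(occ, threshold = ncol(occ$occupied)) {
  nw <- as.integer(rowSums(occ$occupied))
  attr(nw, "frac_at_threshold") <- mean(nw >= threshold)
  attr(nw, "threshold") <- threshold
  nw
}

#' Rehydration (network-reformation) time
#'
#' Earliest time at which N_Wat reaches `threshold` and holds it for
#' `sustain_frames` consecutive frames.  With `sustain_frames = 1` this is
#' the first-passage time of the threshold.  Times use the end-of-frame
#' convention: frame k corresponds to t = k * dt.
#'
#' @param nwat Integer vector (see [nwat_series()]).
#' @param threshold Site-count threshold (default: max conceivable, i.e.
#'   all tracked sites -- pass explicitly when fewer).
#' @param sustain_frames Consecutive frames required (default 10).
#' @param dt Frame spacing (ps).
#' @return Time in ns, or `NA` if the condition is never met.
#' @export
rehydration_time <- function(nwat, threshold, sustain_frames = 10, dt) {
  stopifnot(sustain_frames >= 1, dt > 0)
  ok <- nwat >= threshold
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= sustain_frames)
  if (length(hit) == 0L) return(NA_real_)
  starts[hit[1]] * dt / 1000
}

#' Hydrogen-bond episode lifetimes from a binary presence series
#'
#' Splits a per-frame presence vector into bonded episodes, optionally
#' bridging interruptions of at most `bridge_tolerance_frames` frames, and
#' returns the average lifetime t_avg = sum(t_i) / N together with the
#' episode durations.  Episodes touching the trajectory boundaries are
#' included (censoring is ignored) and counted in `censored_n`.
#'
#' @param presence Binary (logical or 0/1) vector over frames.
#' @param dt Frame spacing (ps).
#' @param bridge_tolerance_frames Gap length (frames) bridged inside an
#'   episode; default 0 (strict episodes).
#' @return `hydronet_lifetime`: list with `t_avg` (ps), `n_hbond`,
#'   `episodes` (ps), `censored_n` and `undefined` (TRUE when the series
#'   contains no bonded frame).
#' @export
hbond_lifetime <- function(presence, dt, bridge_tolerance_frames = 0) {
  stopifnot(length(presence) > 0, bridge_tolerance_frames >= 0, dt > 0)
  p <- as.integer(as.logical(presence))
  if (!any(p == 1L)) {
    return(structure(list(t_avg = NA_real_, n_hbond = 0L,
                          episodes = numeric(), censored_n = 0L,
                          undefined = TRUE),
                     class = "hydronet_lifetime"))
  }
  if (bridge_tolerance_frames > 0) {
    r <- rle(p)
    interior <- which(r$values == 0L &
                        r$lengths <= bridge_tolerance_frames)
    # never bridge leading/trailing gaps: only gaps between two episodes
    interior <- interior[interior > 1L & interior < length(r$values)]
    r$values[interior] <- 1L
    p <- inverse.rle(r)
  }
  r <- rle(p)
  lens <- r$lengths[r$values == 1L]
  episodes <- lens * dt
  censored <- 0L
  if (r$values[1] == 1L) censored <- censored + 1L
  if (r$values[length(r$values)] == 1L && length(r$values) > 1L)
    censored <- censored + 1L
  if (length(r$values) == 1L && r$values[1] == 1L) censored <- 1L
  structure(list(t_avg = mean(episodes), n_hbond = length(episodes),
                 episodes = episodes, censored_n = censored,
                 undefined = FALSE),
            class = "hydronet_lifetime")
}

#' @export
print.hydronet_lifetime <- function(x, ...) {
  if (x$undefined) cat("hydronet_lifetime: undefined (no bonded frames)\n")
  else cat(sprintf(
    "hydronet_lifetime: t_avg = %.4g ns over %d episode(s), %d censored\n",
    x$t_avg / 1000, x$n_hbond, x$censored_n))
  invisible(x)
}

#' Lifetime results for every column of an occupancy/presence matrix
#'
#' Applies [hbond_lifetime()] per site column; used both for site-residence
#' statistics and for presence channels produced by the synthetic
#' generator.
#' @param occ A `hydronet_occupancy`.
#' @param bridge_tolerance_frames Gap bridging (frames).
#' @return Data frame: site, n_hbond, t_avg_ns, censored_n; attribute
#'   `pooled` holds the lifetime over all episodes pooled across sites.
#' @export
occupancy_lifetimes <- function(occ, bridge_tolerance_frames = 0) {
  res <- lapply(seq_len(ncol(occ$occupied)), function(k)
    hbond_lifetime(occ$occupied[, k], occ$dt, bridge_tolerance_frames))
  all_ep <- unlist(lapply(res, `[[`, "episodes"))
  out <- data.frame(
    site = colnames(occ$occupied),
    n_hbond = vapply(res, `[[`, integer(1), "n_hbond"),
    t_avg_ns = vapply(res, `[[`, numeric(1), "t_avg") / 1000,
    censored_n = vapply(res, `[[`, integer(1), "censored_n"),
    stringsAsFactors = FALSE
  )
  attr(out, "pooled") <- list(
    t_avg_ps = if (length(all_ep)) mean(all_ep) else NA_real_,
    n_hbond = length(all_ep))
  out
}

#' Water-residue hydrogen-bond lifetime table from a coordinate trajectory
#'
#' For every (site, coordinating polar atom) pair, a frame counts as bonded
#' when some water oxygen lies both within the site's assignment radius and
#' within the hydrogen-bond distance cutoff of the residue atom.  One row
#' is emitted per pair ever observed bonded, ordered by site then residue
#' atom.
#'
#' @param trajectory A `hydronet_trajectory`.
#' @param inventory A `hydronet_inventory` (or a site data frame) carrying
#'   the monitored site positions.
#' @param structure Numbered reference structure providing the candidate
#'   coordinating atoms (polar atoms of generic-numbered residues and
#'   partner-chain backbone).
#' @param criteria Hydrogen-bond criteria (distance cutoff reused).
#' @param radius Site assignment radius (A).
#' @param bridge_tolerance_frames Gap bridging (frames).
#' @param superpose Per-frame Calpha superposition onto the reference.
#' @return Data frame: site, residue_atom, n_hbond, t_avg_ns, censored_n.
#' @export
lifetime_table <- function(trajectory, inventory, structure,
                           criteria = hbond_criteria(), radius = 1.5,
                           bridge_tolerance_frames = 0, superpose = TRUE) {
  sites <- if (inherits(inventory, "hydronet_inventory")) inventory$sites
           else inventory
  a <- structure$atoms
  cand <- which(a$element %in% criteria$polar_elements &
                  a$record_class != "water" &
                  (!is.na(a$generic) |
                     !(a$chain %in% unique(a$chain[!is.na(a$generic)]))))
  if (length(cand) == 0L) {
    warning("no candidate coordinating atoms; empty lifetime table")
    return(data.frame(site = character(), residue_atom = character(),
                      n_hbond = integer(), t_avg_ns = numeric(),
                      censored_n = integer()))
  }
  atoms <- trajectory$atoms
  wsel <- which(atoms$record_class == "water" & atoms$element == "O")
  if (length(wsel) == 0L) stop("no water atoms in trajectory topology")
  casel <- which(atoms$name == "CA" & atoms$record_class == "polymer")
  ref_xyz <- as.matrix(a[, c("x", "y", "z")])
  ref_ca <- if (length(casel) >= 3L) ref_xyz[casel, , drop = FALSE] else NULL
  sxyz <- as.matrix(sites[, c("x", "y", "z")])
  cxyz <- ref_xyz[cand, , drop = FALSE]
  nf <- trajectory$n_frames
  ns <- nrow(sites); nc <- length(cand)
  pres <- array(FALSE, dim = c(nf, ns, nc))
  r2 <- radius^2; h2 <- criteria$distance_cutoff^2
  for (f in seq_len(nf)) {
    fr <- trajectory$coords[, , f]
    if (superpose && !is.null(ref_ca) && nrow(fr) == nrow(a)) {
      sp <- superpose_kabsch(fr[casel, , drop = FALSE], ref_ca)
      fr <- apply_superposition(fr, sp)
    }
    w <- fr[wsel, , drop = FALSE]
    din <- .pairwise_dist2(w, sxyz) <= r2      # waters x sites
    dhb <- .pairwise_dist2(w, cxyz) <= h2      # waters x candidates
    for (s in seq_len(ns)) {
      inw <- which(din[, s])
      if (length(inw))
        pres[f, s, ] <- colSums(dhb[inw, , drop = FALSE]) > 0
    }
  }
  rows <- list(); nr <- 0L
  atom_lbl <- paste(a$chain[cand], a$resno[cand], a$name[cand], sep = "/")
  for (s in seq_len(ns)) for (k in seq_len(nc)) {
    pv <- pres[, s, k]
    if (!any(pv)) next
    lt <- hbond_lifetime(pv, trajectory$dt, bridge_tolerance_frames)
    nr <- nr + 1L
    rows[[nr]] <- data.frame(site = sites$name[s], residue_atom = atom_lbl[k],
                             n_hbond = lt$n_hbond,
                             t_avg_ns = lt$t_avg / 1000,
                             censored_n = lt$censored_n,
                             stringsAsFactors = FALSE)
  }
  if (nr == 0L) {
    warning("no bonded (site, residue) pairs observed; empty lifetime table")
    return(data.frame(site = character(), residue_atom = character(),
                      n_hbond = integer(), t_avg_ns = numeric(),
                      censored_n = integer()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$site, out$residue_atom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair two lifetime tables for comparative reporting
#'
#' Joins two tables (e.g. Gs-coupled vs Gi-coupled runs) on (site,
#' residue_atom) and reports the per-pair difference in t_avg.
#' @param table_a,table_b Outputs of [lifetime_table()] or
#'   [occupancy_lifetimes()].
#' @param labels Column-suffix labels for the two inputs.
#' @export
compare_lifetimes <- function(table_a, table_b, labels = c("A", "B")) {
  keyc <- intersect(c("site", "residue_atom"), names(table_a))
  merged <- merge(table_a, table_b, by = keyc,
                  suffixes = paste0("_", labels), all = TRUE)
  ca <- paste0("t_avg_ns_", labels[1]); cb <- paste0("t_avg_ns_", labels[2])
  merged$delta_t_avg_ns <- merged[[ca]] - merged[[cb]]
  merged[order(merged[[keyc[1]]]), , drop = FALSE]
}
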