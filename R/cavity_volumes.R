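# Grid-based dual-probe cavity detection.
#
# Voxels occluded by atoms dilated with the small probe define the
# solvent-excluded interior; a flood fill seeded at the box boundary over
# voxels free of the large-probe dilation defines bulk, which is then
# grown back by (probe_out - probe_in) through accessible space so that
# the outer solvent shell is not mistaken for cavity.  Whatever accessible
# volume remains unreached is cavity; connected components use
# 6-connectivity.

#' Per-element van der Waals radii used for occlusion (Angstrom)
#' @export
element_radii <- function() {
  c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, H = 1.2, P = 1.8)
}

.shift_or <- function(x, dims) {
  # 6-neighbour dilation of a logical 3d array
  d1 <- dims[1]; d2 <- dims[2]; d3 <- dims[3]
  out <- x
  out[-1, , ] <- out[-1, , ] | x[-d1, , ]
  out[-d1, , ] <- out[-d1, , ] | x[-1, , ]
  out[, -1, ] <- out[, -1, ] | x[, -d2, ]
  out[, -d2, ] <- out[, -d2, ] | x[, -1, ]
  out[, , -1] <- out[, , -1] | x[, , -d3]
  out[, , -d3] <- out[, , -d3] | x[, , -1]
  out
}

.flood <- function(seed, open, dims, max_iter = Inf) {
  # frontier BFS from seed through open voxels (6-connectivity); linear
  # indices with explicit face guards against wraparound
  d1 <- dims[1]; d12 <- dims[1] * dims[2]
  visited <- as.logical(seed) & as.logical(open)
  frontier <- which(visited)
  openv <- as.logical(open)
  it <- 0
  while (length(frontier) && it < max_iter) {
    i <- (frontier - 1L) %% d1 + 1L
    j <- ((frontier - 1L) %/% d1) %% dims[2] + 1L
    k <- (frontier - 1L) %/% d12 + 1L
    nb <- c(frontier[i > 1L] - 1L, frontier[i < d1] + 1L,
            frontier[j > 1L] - d1, frontier[j < dims[2]] + d1,
            frontier[k > 1L] - d12, frontier[k < dims[3]] + d12)
    nb <- nb[openv[nb] & !visited[nb]]
    if (!length(nb)) break
    visited[nb] <- TRUE
    frontier <- unique(nb)
    it <- it + 1
  }
  dim(visited) <- dims
  visited
}

.mark_occluded <- function(grid_dim, origin, spacing, xyz, radii) {
  # stamp dilated atom spheres on a padded grid using linear-index
  # arithmetic (exact Euclidean test per voxel centre), then crop; atoms
  # are processed per distinct radius in chunks to bound memory
  mmax <- ceiling(max(radii) / spacing) + 1L
  pad <- 2L * mmax   # guard: off-grid atoms may stamp partly outside
  pd <- grid_dim + 2L * pad
  occ <- logical(prod(pd))
  stride <- c(1L, pd[1], pd[1] * pd[2])
  ctr <- round(sweep(xyz, 2, origin, "-") / spacing) + 1L + pad
  for (r in unique(radii)) {
    m <- ceiling(r / spacing)
    grp <- which(radii == r)
    # keep only atoms whose stamp can reach the unpadded grid
    reach <- ctr[grp, 1] >= pad + 1L - m & ctr[grp, 1] <= pad + grid_dim[1] + m &
             ctr[grp, 2] >= pad + 1L - m & ctr[grp, 2] <= pad + grid_dim[2] + m &
             ctr[grp, 3] >= pad + 1L - m & ctr[grp, 3] <= pad + grid_dim[3] + m
    grp <- grp[reach]
    if (!length(grp)) next
    g <- expand.grid(i = -m:m, j = -m:m, k = -m:m)
    keep <- (g$i^2 + g$j^2 + g$k^2) * spacing^2 <= r^2
    lin_off <- as.integer(as.matrix(g[keep, , drop = FALSE]) %*% stride)
    centers <- 1L + as.integer((ctr[grp, , drop = FALSE] - 1L) %*% stride)
    chunk <- max(1L, floor(2e7 / length(lin_off)))
    for (b in seq(1L, length(centers), by = chunk)) {
      cc <- centers[b:min(b + chunk - 1L, length(centers))]
      occ[rep(cc, each = length(lin_off)) + lin_off] <- TRUE
    }
  }
  dim(occ) <- pd
  occ[(pad + 1L):(pad + grid_dim[1]),
      (pad + 1L):(pad + grid_dim[2]),
      (pad + 1L):(pad + grid_dim[3])]
}

.grow_euclidean <- function(seed, dims, origin, spacing, radius) {
  # dilate the seed region by a Euclidean ball: stamp spheres at the
  # seed's surface voxels (seed voxels adjacent to non-seed)
  surf <- seed & .shift_or(!seed, dims)
  idx <- which(surf)
  if (length(idx) == 0L) return(seed)
  ijk <- arrayInd(idx, dims)
  xyz <- sweep((ijk - 1) * spacing, 2, origin, "+")
  grown <- .mark_occluded(dims, origin, spacing, xyz,
                          rep(radius, nrow(xyz)))
  grown | seed
}

.boundary_mask <- function(dims) {
  b <- array(FALSE, dim = dims)
  b[c(1, dims[1]), , ] <- TRUE
  b[, c(1, dims[2]), ] <- TRUE
  b[, , c(1, dims[3])] <- TRUE
  b
}

#' Detect internal cavities by the dual-probe voxel method
#'
#' Water atoms are excluded from the occluding atom set (cavities are the
#' spaces those waters occupy).  Components are returned sorted by volume,
#' largest first, with volumes in cubic Angstrom (voxel count times
#' spacing^3).
#'
#' @param structure A `hydronet_structure`.
#' @param spacing Voxel edge (A); must not exceed `probe_in`.
#' @param probe_in Small (solvent) probe radius (A), default 1.4.
#' @param probe_out Large (bulk-exclusion) probe radius (A), default 4.0.
#' @param region_box Optional list(min = c(x,y,z), max = c(x,y,z))
#'   restricting the search; default auto-box = structure extent +
#'   probe_out + 2 voxels.
#' @param min_volume Minimum reported cavity volume (A^3); suppresses
#'   surface-discretisation specks.
#' @param radii Named per-element radius table; unknown elements fall back
#'   to 1.7 A.
#' @return List of `hydronet_cavity` objects: `voxels` (n x 3 coordinates
#'   of voxel centres), `volume`, `centroid`, `label` ("unassigned"),
#'   `anchor_contacts`, plus the grid parameters used.
#' @export
detect_cavities <- function(structure, spacing = 0.6, probe_in = 1.4,
                            probe_out = 4.0, region_box = NULL,
                            min_volume = 5, radii = element_radii()) {
  if (!(probe_out > probe_in && probe_in > 0))
    stop("config error: need probe_out > probe_in > 0")
  if (spacing > probe_in)
    stop("config error: spacing must not exceed probe_in")
  a <- structure$atoms
  a <- a[a$record_class != "water", , drop = FALSE]
  if (nrow(a) == 0L) stop("empty structure: no non-water atoms")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- radii[a$element]
  rad[is.na(rad)] <- 1.7
  if (is.null(region_box)) {
    # pad past the large-probe occlusion envelope so genuine bulk exists
    # beyond every face of the auto box
    pad <- max(rad) + probe_out + 3 * spacing
    region_box <- list(min = apply(xyz, 2, min) - pad,
                       max = apply(xyz, 2, max) + pad)
  }
  origin <- region_box$min
  dims <- pmax(ceiling((region_box$max - origin) / spacing) + 1L, 2L)
  keep <- xyz[, 1] >= origin[1] - (max(rad) + probe_out) &
    xyz[, 1] <= region_box$max[1] + (max(rad) + probe_out) &
    xyz[, 2] >= origin[2] - (max(rad) + probe_out) &
    xyz[, 2] <= region_box$max[2] + (max(rad) + probe_out) &
    xyz[, 3] >= origin[3] - (max(rad) + probe_out) &
    xyz[, 3] <= region_box$max[3] + (max(rad) + probe_out)
  xyz <- xyz[keep, , drop = FALSE]; rad <- rad[keep]
  occ_in <- .mark_occluded(dims, origin, spacing, xyz, rad + probe_in)
  occ_out <- .mark_occluded(dims, origin, spacing, xyz, rad + probe_out)
  open_in <- !occ_in
  bulk_seed <- .flood(.boundary_mask(dims), !occ_out, dims)
  # re-grow bulk by the probe-radius difference (Euclidean ball stamped
  # from the seed surface), so the solvent shell between the two probe
  # surfaces is not read as cavity
  bulk <- .grow_euclidean(bulk_seed, dims, origin, spacing,
                          probe_out - probe_in + spacing)
  cavity <- open_in & !(bulk | bulk_seed)
  idx <- which(cavity)
  if (length(idx) == 0L) return(list())
  comp <- .voxel_components(idx, dims)
  vol_unit <- spacing^3
  out <- list()
  for (cl in comp) {
    vol <- length(cl) * vol_unit
    if (vol < min_volume) next
    ijk <- arrayInd(cl, dims)
    coords <- sweep((ijk - 1) * spacing, 2, origin, "+")
    out[[length(out) + 1L]] <- structure(
      list(voxels = coords, volume = vol,
           centroid = colMeans(coords), label = "unassigned",
           anchor_contacts = character(),
           params = list(spacing = spacing, probe_in = probe_in,
                         probe_out = probe_out)),
      class = "hydronet_cavity")
  }
  out[order(vapply(out, `[[`, numeric(1), "volume"), decreasing = TRUE)]
}

.voxel_components <- function(idx, dims) {
  # connected components (6-connectivity) of linear voxel indices
  ijk <- arrayInd(idx, dims)
  pos <- integer(prod(dims))
  pos[idx] <- seq_along(idx)
  edges <- list(); ne <- 0L
  strides <- c(1L, dims[1], dims[1] * dims[2])
  lims <- dims
  for (ax in 1:3) {
    ok <- ijk[, ax] < lims[ax]
    nb <- idx[ok] + strides[ax]
    present <- pos[nb] > 0L
    if (any(present)) {
      ne <- ne + 1L
      edges[[ne]] <- cbind(pos[idx[ok]][present], pos[nb[present]])
    }
  }
  if (ne == 0L) return(as.list(idx))
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  split(idx, memb)
}

#' @export
print.hydronet_cavity <- function(x, ...) {
  cat(sprintf("hydronet_cavity: %s, %.1f A^3, centroid (%.1f, %.1f, %.1f)\n",
              x$label, x$volume, x$centroid[1], x$centroid[2], x$centroid[3]))
  if (length(x$anchor_contacts))
    cat("  anchors:", paste(x$anchor_contacts, collapse = ", "), "\n")
  invisible(x)
}

#' Anchor positions defining the three hydration cavities
#' @export
cavity_anchor_sets <- function() {
  list(CWC = c("2.50", "3.39", "7.45"),
       JWC = c("7.53"),
       EWC = c("3.50", "5.58", "5.61"))
}

#' Label detected cavities as CWC / JWC / EWC by anchor contacts
#'
#' A cavity contacts an anchor position when any voxel centre lies within
#' `contact_distance` of any heavy atom of the residue carrying that
#' generic number.  Labels: CWC iff >= 2 of {2.50, 3.39, 7.45}; JWC iff
#' 7.53; EWC iff >= 2 of {3.50, 5.58, 5.61}; ties resolved by the fixed
#' precedence CWC > JWC > EWC and recorded in the `tiebreak` field.
#'
#' @param cavities List from [detect_cavities()].
#' @param structure Numbered `hydronet_structure`.
#' @param contact_distance Voxel-to-atom contact distance (A), default 4.5.
#' @return The cavity list with `label`, `anchor_contacts` and `tiebreak`
#'   filled in.
#' @export
assign_cavity_regions <- function(cavities, structure,
                                  contact_distance = 4.5) {
  sets <- cavity_anchor_sets()
  anchors <- unique(unlist(sets))
  a <- structure$atoms
  present <- anchors[anchors %in% a$generic]
  missing <- setdiff(anchors, present)
  if (length(missing))
    warning("anchor positions missing from structure: ",
            paste(missing, collapse = ", "))
  if (length(present) == 0L) return(cavities)
  ax <- a[!is.na(a$generic) & a$generic %in% present & a$element != "H", ,
          drop = FALSE]
  axyz <- as.matrix(ax[, c("x", "y", "z")])
  cd2 <- contact_distance^2
  for (k in seq_along(cavities)) {
    d2 <- .pairwise_dist2(cavities[[k]]$voxels, axyz)
    touched <- unique(ax$generic[colSums(d2 <= cd2) > 0])
    cavities[[k]]$anchor_contacts <- sort(touched)
    labs <- c(
      if (length(intersect(touched, sets$CWC)) >= 2) "CWC",
      if ("7.53" %in% touched) "JWC",
      if (length(intersect(touched, sets$EWC)) >= 2) "EWC")
    cavities[[k]]$label <- if (length(labs)) labs[1] else "unassigned"
    cavities[[k]]$tiebreak <- if (length(labs) > 1)
      paste("precedence", paste(labs, collapse = ">")) else ""
  }
  cavities
}

.region_rule_satisfied <- function(contacts, region) {
  sets <- cavity_anchor_sets()
  if (region == "JWC") "7.53" %in% contacts
  else length(intersect(contacts, sets[[region]])) >= 2
}

#' Residue-class tables for position 5.58
#'
#' Small uncharged polar residues permit water to occupy the extended
#' water cavity; bulky residues fill it sterically.  Residues outside both
#' enumerations are reported as `other` rather than silently binned.
#' @export
position_558_classes <- function() {
  list(`small-polar` = c("SER", "THR", "CYS", "ASN"),
       bulky = c("TYR", "PHE", "TRP", "LEU", "ILE", "MET", "HIS"))
}

#' Classify the residue at generic position 5.58
#'
#' @param structure Numbered `hydronet_structure`.
#' @return List with `residue_type` (3-letter) and `class`
#'   (`small-polar` / `bulky` / `other`).
#' @export
classify_558 <- function(structure) {
  rt <- residue_table(structure)
  hit <- which(!is.na(rt$generic) & rt$generic == "5.58")
  if (length(hit) == 0L)
    stop("no residue labelled 5.58: check the generic-number mapping ",
         "passed to assign_generic_numbers()")
  typ <- toupper(rt$resname[hit[1]])
  tab <- position_558_classes()
  cls <- if (typ %in% tab$`small-polar`) "small-polar"
         else if (typ %in% tab$bulky) "bulky" else "other"
  list(residue_type = typ, class = cls)
}

#' Region search boxes centred on the cavity anchor residues
#'
#' Bounding box of each anchor set's heavy atoms expanded by `margin`.
#' @param structure Numbered structure.
#' @param margin Box expansion (A).
#' @export
anchor_region_boxes <- function(structure, margin = 5) {
  a <- structure$atoms
  lapply(cavity_anchor_sets(), function(set) {
    sel <- !is.na(a$generic) & a$generic %in% set
    if (!any(sel)) return(NULL)
    xyz <- as.matrix(a[sel, c("x", "y", "z")])
    list(min = apply(xyz, 2, min) - margin,
         max = apply(xyz, 2, max) + margin)
  })
}

#' Cavity panel across a set of structures
#'
#' For every entry the structure is parsed, numbered, searched per cavity
#' region (box around the region's anchors), and the matching labelled
#' cavity volumes are tabulated together with the 5.58 residue class.
#' Per-structure failures mark the row and the panel continues.
#'
#' @param manifest Data frame with columns `path`, `mapping_path`,
#'   `receptor_name`, or a list of entries
#'   `list(structure =, name =)` with pre-built numbered structures.
#' @param spacing,probe_in,probe_out,contact_distance,margin Detection
#'   parameters (see [detect_cavities()], [assign_cavity_regions()]).
#' @return Data frame: receptor, residue_558, class_558, CWC, JWC, EWC
#'   volumes (A^3) and status; attribute `group_means` holds the mean EWC
#'   volume per 5.58 class.
#' @export
cavity_panel <- function(manifest, spacing = 0.6, probe_in = 1.4,
                         probe_out = 4.0, contact_distance = 4.5,
                         margin = 5) {
  entries <- if (is.data.frame(manifest)) {
    lapply(seq_len(nrow(manifest)), function(k)
      list(path = manifest$path[k], mapping_path = manifest$mapping_path[k],
           name = manifest$receptor_name[k]))
  } else manifest
  if (length(entries) == 0L) stop("empty panel manifest")
  rows <- lapply(entries, function(e) {
    out <- data.frame(receptor = e$name, residue_558 = NA_character_,
                      class_558 = NA_character_, CWC = NA_real_,
                      JWC = NA_real_, EWC = NA_real_, status = "ok",
                      stringsAsFactors = FALSE)
    res <- try({
      s <- if (!is.null(e$structure)) e$structure else
        assign_generic_numbers(parse_structure(e$path),
                               read_mapping(e$mapping_path))
      p558 <- classify_558(s)
      out$residue_558 <- p558$residue_type
      out$class_558 <- p558$class
      boxes <- anchor_region_boxes(s, margin)
      for (reg in names(boxes)) {
        if (is.null(boxes[[reg]])) next
        cav <- detect_cavities(s, spacing, probe_in, probe_out,
                               region_box = boxes[[reg]])
        cav <- assign_cavity_regions(cav, s, contact_distance)
        # panel columns quantify each region's compartment in its own
        # anchor box, so rule satisfaction (not the exclusive label with
        # its CWC > JWC > EWC precedence) decides inclusion: adjacent
        # compartments share anchors within one contact distance
        vols <- vapply(cav, `[[`, numeric(1), "volume")
        hit <- vapply(cav, function(cc)
          .region_rule_satisfied(cc$anchor_contacts, reg), logical(1))
        out[[reg]] <- if (any(hit)) sum(vols[hit]) else 0
      }
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      out$status <- paste("FAILED:", conditionMessage(attr(res, "condition")))
    }
    out
  })
  panel <- do.call(rbind, rows)
  ok <- panel$status == "ok" & !is.na(panel$class_558)
  gm <- if (any(ok)) vapply(split(panel$EWC[ok], panel$class_558[ok]),
                            mean, numeric(1))
        else numeric()
  attr(panel, "group_means") <- gm
  panel
}

#' Dump cavity voxels as PDB pseudo-atoms for external viewers
#' @param cavities Cavity list.
#' @param path Output PDB path.
#' @export
write_cavity_pdb <- function(cavities, path) {
  lines <- character(); serial <- 0L
  for (k in seq_along(cavities)) {
    v <- cavities[[k]]$voxels
    for (r in seq_len(nrow(v))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "HETATM%5d  DU  CAV %1s%4d       %7.3f %7.3f %7.3f  1.00  0.00          DU",
        serial %% 100000L, LETTERS[(k - 1L) %% 26L + 1L], k,
        v[r, 1], v[r, 2], v[r, 3]))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
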