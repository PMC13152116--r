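# Static hydrogen-bond detection and water-region classification.
#
# Cryo-EM models carry no hydrogens, so the detector uses heavy-atom
# geometry only: a donor-acceptor distance cutoff plus an
# antecedent-donor-acceptor angle surrogate.  Both criteria are
# configurable through hbond_criteria().

#' Hydrogen-bond detection criteria
#'
#' @param distance_cutoff Maximum heavy-atom donor-acceptor distance (A).
#' @param min_angle Minimum antecedent-donor-acceptor angle (degrees); the
#'   heavy-atom surrogate for donor-H-acceptor linearity used when
#'   hydrogens are absent.  A pair passes if either orientation passes;
#'   atoms without a covalent antecedent (water oxygens) always pass.
#' @param polar_elements Elements allowed as donor/acceptor.
#' @param covalent_cutoff Distance (A) below which a same-residue heavy
#'   atom counts as the covalent antecedent.
#' @export
hbond_criteria <- function(distance_cutoff = 3.5, min_angle = 90,
                           polar_elements = c("N", "O"),
                           covalent_cutoff = 1.8) {
  if (distance_cutoff <= 0 || covalent_cutoff <= 0)
    stop("config error: hydrogen-bond cutoffs must be positive")
  list(distance_cutoff = distance_cutoff, min_angle = min_angle,
       polar_elements = polar_elements, covalent_cutoff = covalent_cutoff)
}

.pairwise_dist2 <- function(a, b) {
  # squared distances between rows of a (n x 3) and rows of b (m x 3)
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  d2
}

.angle_deg <- function(p, v, q) {
  # angle p-v-q in degrees, rows are points
  u1 <- p - v; u2 <- q - v
  cs <- rowSums(u1 * u2) /
    pmax(sqrt(rowSums(u1^2)) * sqrt(rowSums(u2^2)), 1e-12)
  cs <- pmin(1, pmax(-1, cs))
  acos(cs) * 180 / pi
}

#' Detect hydrogen bonds in a static structure
#'
#' Enumerates polar-atom pairs within the distance cutoff (excluding pairs
#' inside one residue) and applies the heavy-atom angle surrogate.  The
#' result is deterministic: rows are sorted by donor then acceptor atom
#' index, and detection is invariant to the order of atoms in the input.
#'
#' @param structure A `hydronet_structure`.
#' @param criteria See [hbond_criteria()].
#' @return Data frame with one row per bond: atom row indices `i`, `j`
#'   (i < j in file order), descriptors for both atoms, `distance` (A) and
#'   `angle` (degrees; NA when neither atom has an antecedent).
#' @export
detect_hbonds <- function(structure, criteria = hbond_criteria()) {
  a <- structure$atoms
  polar <- which(a$element %in% criteria$polar_elements)
  if (length(polar) < 2L)
    return(.empty_hbond_df())
  xyz <- as.matrix(a[, c("x", "y", "z")])
  p <- xyz[polar, , drop = FALSE]
  d2 <- .pairwise_dist2(p, p)
  cut2 <- criteria$distance_cutoff^2
  idx <- which(upper.tri(d2) & d2 <= cut2 & d2 > 1e-12, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(.empty_hbond_df())
  ai <- polar[idx[, 1]]; aj <- polar[idx[, 2]]
  # drop same-residue pairs (covalently linked, not hydrogen bonds)
  same <- a$chain[ai] == a$chain[aj] & a$resno[ai] == a$resno[aj] &
    a$icode[ai] == a$icode[aj]
  ai <- ai[same == FALSE]; aj <- aj[same == FALSE]
  if (length(ai) == 0L) return(.empty_hbond_df())
  ant <- .antecedent_index(a, xyz, criteria$covalent_cutoff)
  ang_i <- rep(NA_real_, length(ai))
  has_i <- !is.na(ant[ai])
  ang_i[has_i] <- .angle_deg(xyz[ant[ai[has_i]], , drop = FALSE],
                             xyz[ai[has_i], , drop = FALSE],
                             xyz[aj[has_i], , drop = FALSE])
  ang_j <- rep(NA_real_, length(aj))
  has_j <- !is.na(ant[aj])
  ang_j[has_j] <- .angle_deg(xyz[ant[aj[has_j]], , drop = FALSE],
                             xyz[aj[has_j], , drop = FALSE],
                             xyz[ai[has_j], , drop = FALSE])
  # pass if either orientation satisfies the surrogate; atoms with no
  # antecedent (waters, termini) impose no angle constraint
  pass <- (is.na(ang_i) | ang_i >= criteria$min_angle) |
          (is.na(ang_j) | ang_j >= criteria$min_angle)
  keep <- which(pass)
  ai <- ai[keep]; aj <- aj[keep]
  angle <- pmax(ang_i[keep], ang_j[keep], na.rm = TRUE)
  angle[is.na(ang_i[keep]) & is.na(ang_j[keep])] <- NA_real_
  # canonical order: lower atom index first, rows sorted by (i, j)
  lo <- pmin(ai, aj); hi <- pmax(ai, aj)
  o <- order(lo, hi)
  out <- data.frame(
    i = lo[o], j = hi[o],
    chain_i = a$chain[lo[o]], resno_i = a$resno[lo[o]],
    resname_i = a$resname[lo[o]], name_i = a$name[lo[o]],
    class_i = a$record_class[lo[o]], generic_i = a$generic[lo[o]],
    chain_j = a$chain[hi[o]], resno_j = a$resno[hi[o]],
    resname_j = a$resname[hi[o]], name_j = a$name[hi[o]],
    class_j = a$record_class[hi[o]], generic_j = a$generic[hi[o]],
    distance = sqrt(rowSums((xyz[lo[o], , drop = FALSE] -
                             xyz[hi[o], , drop = FALSE])^2)),
    angle = angle[o],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

.empty_hbond_df <- function() {
  data.frame(i = integer(), j = integer(), chain_i = character(),
             resno_i = integer(), resname_i = character(),
             name_i = character(), class_i = character(),
             generic_i = character(), chain_j = character(),
             resno_j = integer(), resname_j = character(),
             name_j = character(), class_j = character(),
             generic_j = character(), distance = numeric(),
             angle = numeric(), stringsAsFactors = FALSE)
}

.antecedent_index <- function(a, xyz, covalent_cutoff) {
  # nearest same-residue heavy atom within covalent_cutoff, else NA
  n <- nrow(a)
  ant <- rep(NA_integer_, n)
  key <- paste(a$chain, a$resno, a$icode, sep = "|")
  for (res in split(seq_len(n), key)) {
    if (length(res) < 2L) next
    sub <- xyz[res, , drop = FALSE]
    d2 <- .pairwise_dist2(sub, sub)
    diag(d2) <- Inf
    nn <- apply(d2, 1, which.min)
    ok <- d2[cbind(seq_along(res), nn)] <= covalent_cutoff^2
    ant[res[ok]] <- res[nn[ok]]
  }
  ant
}

#' Default region-classification rule table
#'
#' Encodes the three-region decomposition of the internal water network:
#' ligand-pocket waters (L), signalling-network waters (S) in three
#' clusters anchored at the sodium pocket, the NPxxY motif and the DRY
#' motif, and the G-protein-interface water (G).
#'
#' @return List of S-cluster rules, each with `cluster` and `contacts`
#'   (generic numbers, any one of which qualifies a water).
#' @export
default_region_rules <- function() {
  list(
    list(cluster = 1L, contacts = c("2.50", "3.39", "2.53", "7.45")),
    list(cluster = 2L, contacts = c("7.49", "7.53")),
    list(cluster = 3L, contacts = c("3.50", "5.58", "5.61"))
  )
}

#' Read a region-rule TSV (`region  cluster  required_contacts`)
#'
#' `required_contacts` is a semicolon-separated list of generic numbers;
#' only S-region rows are interpreted (L and G rules are structural, not
#' tabular).
#' @param path TSV path.
#' @export
read_region_rules <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab <- tab[tab$region == "S", , drop = FALSE]
  lapply(seq_len(nrow(tab)), function(k) {
    list(cluster = as.integer(tab$cluster[k]),
         contacts = strsplit(tab$required_contacts[k], ";")[[1]])
  })
}

#' Classify internal waters into network regions
#'
#' Each water is assigned a region from its hydrogen-bond partners:
#' `G` if it bridges a receptor residue and a partner chain, `S` (with a
#' cluster) if it contacts any rule-listed generic position, `L` if it
#' contacts ligand atoms (or, without a modelled ligand, a configurable
#' pocket position list), else `unassigned`.  Tie-breaks follow the fixed
#' precedence G > S > L (interface bridging is the most specific
#' condition); within S the lowest-numbered matching cluster wins.  Both
#' tie-breaks are recorded per water in the `tiebreak` column.
#'
#' @param structure A numbered `hydronet_structure`.
#' @param hbonds Output of [detect_hbonds()] on the same structure.
#' @param rules S-cluster rule list (see [default_region_rules()]).
#' @param site_names Optional named character vector mapping water residue
#'   keys (`"chain|resno|icode"`) to site labels (`W_S1`, ...).
#' @param partner_chains Chains regarded as the G-protein side.  Default:
#'   every polymer chain that carries no generic numbers.
#' @param pocket_positions Generic numbers defining the ligand pocket when
#'   no ligand is present.
#' @return `hydronet_inventory`: list with `sites` (data frame: name,
#'   x, y, z, region, cluster, contacts, tiebreak), `graph` (igraph over
#'   water sites and their hydrogen-bond partner atoms) and `counts`.
#' @export
classify_waters <- function(structure, hbonds,
                            rules = default_region_rules(),
                            site_names = NULL,
                            partner_chains = NULL,
                            pocket_positions = character()) {
  a <- structure$atoms
  known_generics <- unique(a$generic[!is.na(a$generic)])
  for (r in rules) {
    absent <- setdiff(r$contacts, known_generics)
    if (length(absent))
      warning("rule contacts absent from structure (rule still applied ",
              "to remaining positions): ", paste(absent, collapse = ", "))
  }
  receptor_chains <- unique(a$chain[!is.na(a$generic)])
  if (is.null(partner_chains)) {
    partner_chains <- setdiff(
      unique(a$chain[a$record_class == "polymer"]), receptor_chains)
  }
  wat <- structure_waters(structure)
  wkey <- paste(wat$chain, wat$resno, wat$icode, sep = "|")
  names_out <- if (nrow(wat) == 0L) character(0)
  else if (!is.null(site_names)) {
    ifelse(wkey %in% names(site_names), site_names[wkey],
           paste0("W", seq_len(nrow(wat))))
  } else paste0("W", seq_len(nrow(wat)))
  has_ligand <- any(a$record_class == "ligand")

  # atom row indices of the water oxygens (rownames survive subsetting)
  wrow <- as.integer(rownames(wat))
  region <- character(nrow(wat)); cluster <- rep(NA_integer_, nrow(wat))
  contacts <- character(nrow(wat)); tiebreak <- character(nrow(wat))

  node_edges <- list(); ne <- 0L
  atom_node <- function(k) paste(a$chain[k], a$resno[k], a$name[k], sep = "/")

  for (w in seq_len(nrow(wat))) {
    k <- wrow[w]
    sel <- hbonds$i == k | hbonds$j == k
    other <- ifelse(hbonds$i[sel] == k, hbonds$j[sel], hbonds$i[sel])
    if (length(other)) {
      onames <- ifelse(a$record_class[other] == "water",
                       names_out[match(other, wrow)], atom_node(other))
      ne <- ne + 1L
      node_edges[[ne]] <- cbind(names_out[w], onames)
    }
    gens <- unique(a$generic[other]); gens <- gens[!is.na(gens)]
    bonded_receptor <- any(a$chain[other] %in% receptor_chains &
                             a$record_class[other] != "water")
    bonded_partner <- any(a$chain[other] %in% partner_chains &
                            a$record_class[other] != "water")
    bonded_ligand <- any(a$record_class[other] == "ligand")
    is_l <- if (has_ligand) bonded_ligand
            else length(intersect(gens, pocket_positions)) > 0
    s_hits <- which(vapply(rules, function(r)
      length(intersect(gens, r$contacts)) > 0, logical(1)))
    is_g <- bonded_receptor && bonded_partner
    matched <- c(if (is_g) "G", if (length(s_hits)) "S", if (is_l) "L")
    if (length(matched) == 0L) {
      region[w] <- "unassigned"
    } else {
      region[w] <- matched[1]
      if (length(matched) > 1L)
        tiebreak[w] <- paste0("precedence ", paste(matched, collapse = ">"))
      if (region[w] == "S") {
        cl <- vapply(rules[s_hits], `[[`, integer(1), "cluster")
        cluster[w] <- min(cl)
        if (length(unique(cl)) > 1L)
          tiebreak[w] <- paste(tiebreak[w],
                               sprintf("cluster min(%s)",
                                       paste(sort(cl), collapse = ",")))
      }
    }
    ct <- c(gens,
            if (bonded_ligand) "ligand",
            if (bonded_partner)
              paste0("chain:", unique(a$chain[other][a$chain[other] %in%
                                                       partner_chains])))
    contacts[w] <- paste(sort(unique(ct)), collapse = ";")
  }

  edges <- if (ne) unique(do.call(rbind, node_edges)) else
    matrix(character(), ncol = 2)
  # drop duplicate undirected edges (water-water bonds appear twice)
  if (nrow(edges)) {
    canon <- t(apply(edges, 1, sort))
    edges <- edges[!duplicated(canon), , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  iso <- setdiff(names_out, igraph::V(g)$name)
  if (length(iso)) g <- igraph::add_vertices(g, length(iso), name = iso)

  sites <- data.frame(name = names_out, x = wat$x, y = wat$y, z = wat$z,
                      region = region, cluster = cluster,
                      contacts = contacts, tiebreak = tiebreak,
                      stringsAsFactors = FALSE)
  counts <- table(factor(region, levels = c("L", "S", "G", "unassigned")))
  ccounts <- table(factor(cluster[region == "S"], levels = 1:3))
  structure(list(sites = sites, graph = g,
                 counts = list(region = counts, cluster = ccounts)),
            class = "hydronet_inventory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hydronet_inventory <- function(x, ...) {
  cat("hydronet_inventory:", nrow(x$sites), "water sites\n")
  print(x$counts$region)
  cat("S clusters:\n"); print(x$counts$cluster)
  invisible(x)
}

#' Connected components and terminal connectivity of the water network
#'
#' @param inventory A `hydronet_inventory`.
#' @param terminals Character vector of two node names (a water-site label
#'   or an atom node `"chain/resno/atomname"`).
#' @return List with `components` (membership vector), `sizes` (component
#'   sizes, decreasing) and `path` (TRUE iff the terminals share a
#'   component).
#' @export
network_connectivity <- function(inventory, terminals) {
  g <- inventory$graph
  if (igraph::vcount(g) == 0L) stop("empty hydrogen-bond graph")
  if (!all(terminals %in% igraph::V(g)$name))
    stop("terminal not in graph: ",
         paste(setdiff(terminals, igraph::V(g)$name), collapse = ", "))
  comp <- igraph::components(g)
  path <- comp$membership[terminals[1]] == comp$membership[terminals[2]]
  list(components = comp$membership,
       sizes = sort(as.integer(comp$csize), decreasing = TRUE),
       path = unname(path))
}

#' Write a water-inventory table as TSV
#' @param inventory A `hydronet_inventory`.
#' @param path Output path.
#' @param header Optional character vector of `#`-prefixed header lines.
#' @export
write_inventory <- function(inventory, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  write.table(inventory$sites, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
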