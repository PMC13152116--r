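# Shared fixtures and independent oracles built in code.

# minimal PDB text: one ALA residue (3 atoms)
write_mini_pdb <- function(path) {
  writeLines(c(
    "HEADER    TEST",
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.912   6.899  -5.032  1.00  0.00           C",
    "END"), path)
  path
}

write_water_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O   HOH W   1       3.000   0.000   0.000  1.00  0.00           O",
    "HETATM    3  O   HOH W   2       6.000   0.000   0.000  1.00  0.00           O",
    "END"), path)
  path
}

# random polar-atom cluster for hydrogen-bond oracle comparisons; each
# atom is its own residue so no same-residue exclusions apply
random_polar_cluster <- function(n, span = 8, seed = 1) {
  set.seed(seed)
  as_hydronet_structure(data.frame(
    name = "O", element = sample(c("O", "N"), n, replace = TRUE),
    chain = "A", resno = seq_len(n), resname = "XXX",
    record_class = "polymer",
    x = runif(n, 0, span), y = runif(n, 0, span), z = runif(n, 0, span),
    stringsAsFactors = FALSE))
}

# brute-force all-pairs hydrogen-bond oracle (independent of the
# vectorised detector): double loop, same geometric criteria
oracle_hbonds <- function(structure, criteria = hbond_criteria()) {
  a <- structure$atoms
  polar <- which(a$element %in% criteria$polar_elements)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  # antecedent: nearest same-residue heavy atom within covalent cutoff
  ante <- rep(NA_integer_, nrow(a))
  for (k in seq_len(nrow(a))) {
    same <- which(a$chain == a$chain[k] & a$resno == a$resno[k] &
                    a$icode == a$icode[k])
    same <- setdiff(same, k)
    if (!length(same)) next
    d <- sqrt(colSums((t(xyz[same, , drop = FALSE]) - xyz[k, ])^2))
    if (min(d) <= criteria$covalent_cutoff) ante[k] <- same[which.min(d)]
  }
  ang <- function(p, v, q) {
    u1 <- p - v; u2 <- q - v
    acos(min(1, max(-1, sum(u1 * u2) /
                      (sqrt(sum(u1^2)) * sqrt(sum(u2^2)))))) * 180 / pi
  }
  ok_dir <- function(d, acpt) {
    if (is.na(ante[d])) return(TRUE)
    ang(xyz[ante[d], ], xyz[d, ], xyz[acpt, ]) >= criteria$min_angle
  }
  out <- NULL
  for (p in seq_along(polar)) for (q in seq_along(polar)) {
    if (q <= p) next
    i <- polar[p]; j <- polar[q]
    if (a$chain[i] == a$chain[j] && a$resno[i] == a$resno[j] &&
        a$icode[i] == a$icode[j]) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d > criteria$distance_cutoff || d < 1e-6) next
    if (ok_dir(i, j) || ok_dir(j, i))
      out <- rbind(out, data.frame(i = i, j = j))
  }
  out
}

# brute-force reachability via boolean transitive closure
oracle_components <- function(edges, nodes) {
  n <- length(nodes)
  adj <- diag(n) > 0
  for (r in seq_len(nrow(edges))) {
    i <- match(edges[r, 1], nodes); j <- match(edges[r, 2], nodes)
    adj[i, j] <- adj[j, i] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  # component id = index of first reachable node
  apply(adj, 1, function(row) min(which(row)))
}

# brute-force rigid-superposition RMSD oracle: random rotation search
# refined by general-purpose optimisation over axis-angle parameters
oracle_superpose_rmsd <- function(mobile, reference, n_starts = 200,
                                  seed = 7) {
  set.seed(seed)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  mc <- sweep(mobile, 2, cm); rc <- sweep(reference, 2, cr)
  obj <- function(par) {
    th <- sqrt(sum(par^2))
    rot <- if (th < 1e-12) diag(3) else rotation_matrix(par, th * 180 / pi)
    sqrt(mean(rowSums((mc %*% t(rot) - rc)^2)))
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    p0 <- stats::runif(3, -pi, pi)
    r <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-12))
    if (r$value < best) best <- r$value
  }
  best
}

# the receptor-like bundle fixture, built once per test run
bundle_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_bundle_structure()
    cache
  }
})
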