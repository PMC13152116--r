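make_pair_structure <- function(sep) {
  # carboxylate-like acceptor (C-O pair) and a water at distance sep
  as_hydronet_structure(data.frame(
    name = c("CG", "OD1", "O"), element = c("C", "O", "O"),
    chain = c("A", "A", "W"), resno = c(1L, 1L, 2L),
    resname = c("ASP", "ASP", "HOH"),
    record_class = c("polymer", "polymer", "water"),
    x = c(-1.3, 0, sep), y = 0, z = 0, stringsAsFactors = FALSE))
}

test_that("detect_hbonds honours the distance cutoff", {
  hb <- detect_hbonds(make_pair_structure(2.8))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.8, tolerance = 1e-9)
  expect_equal(nrow(detect_hbonds(make_pair_structure(4.2))), 0L)
  expect_error(hbond_criteria(distance_cutoff = -1), "config error")
})

test_that("the angle surrogate rejects back-side approach", {
  # water placed behind the antecedent: antecedent-donor-acceptor < 90 deg
  st <- as_hydronet_structure(data.frame(
    name = c("CG", "OD1", "O"), element = c("C", "O", "O"),
    chain = c("A", "A", "W"), resno = c(1L, 1L, 2L),
    resname = c("ASP", "ASP", "HOH"),
    record_class = c("polymer", "polymer", "water"),
    x = c(1.3, 0, 3.0), y = c(0, 0, 0.5), z = 0))
  # OD1 antecedent CG at +x; water also at +x: angle ~ small.  The water
  # has no antecedent, so its own orientation passes -> bond kept.
  expect_equal(nrow(detect_hbonds(st)), 1L)
  # both antecedents between the two oxygens: both orientations fail
  st2 <- as_hydronet_structure(data.frame(
    name = c("CG", "OD1", "OD1", "CG"), element = c("C", "O", "O", "C"),
    chain = "A", resno = c(1L, 1L, 2L, 2L),
    resname = "ASP", record_class = "polymer",
    x = c(1.4, 0, 3.0, 1.6), y = 0, z = 0))
  expect_equal(nrow(detect_hbonds(st2)), 0L)
})

test_that("detect_hbonds equals the brute-force all-pairs oracle", {
  for (seed in c(2, 12, 33)) {
    st <- random_polar_cluster(n = 40, span = 9, seed = seed)
    got <- detect_hbonds(st)[, c("i", "j")]
    want <- oracle_hbonds(st)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$i, want$i)
      expect_equal(got$j, want$j)
    }
  }
})

test_that("detect_hbonds is invariant to atom order", {
  st <- random_polar_cluster(n = 25, span = 8, seed = 5)
  set.seed(99)
  perm <- sample.int(nrow(st$atoms))
  st2 <- st
  st2$atoms <- st$atoms[perm, ]
  rownames(st2$atoms) <- NULL
  key <- function(hb) sort(paste(pmin(hb$resno_i, hb$resno_j),
                                 pmax(hb$resno_i, hb$resno_j)))
  expect_equal(key(detect_hbonds(st2)), key(detect_hbonds(st)))
})

test_that("classify_waters applies region rules and tie-breaks", {
  b <- bundle_fixture()
  hb <- detect_hbonds(b$structure)
  inv <- classify_waters(b$structure, hb, site_names = b$site_names)
  s <- inv$sites
  # cluster-1 water bonded to 2.50/3.39 only
  expect_equal(s$region[s$name == "W_S1"], "S")
  expect_equal(s$cluster[s$name == "W_S1"], 1L)
  # interface water: receptor residue + partner-chain backbone -> G
  expect_equal(s$region[s$name == "W_G1"], "G")
  expect_match(s$contacts[s$name == "W_G1"], "chain:B")
  # G precedence over S was exercised and logged
  expect_match(s$tiebreak[s$name == "W_G1"], "precedence G")
})

test_that("waters with no hydrogen bonds stay unassigned", {
  st <- as_hydronet_structure(data.frame(
    name = c("CA", "O"), element = c("C", "O"), chain = c("A", "W"),
    resno = c(1L, 2L), resname = c("ALA", "HOH"),
    record_class = c("polymer", "water"),
    x = c(0, 20), y = 0, z = 0))
  inv <- suppressWarnings(classify_waters(st, detect_hbonds(st)))
  expect_equal(inv$sites$region, "unassigned")
})

test_that("region counts are stable under rigid transformation", {
  b <- bundle_fixture()
  st <- b$structure
  rot <- rotation_matrix(c(2, -1, 4), 63)
  a <- st$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(rot) +
    matrix(c(10, -4, 7), nrow(a), 3, byrow = TRUE)
  st2 <- st
  st2$atoms[, c("x", "y", "z")] <- xyz
  inv1 <- classify_waters(st, detect_hbonds(st), site_names = b$site_names)
  inv2 <- classify_waters(st2, detect_hbonds(st2), site_names = b$site_names)
  expect_equal(inv2$counts$region, inv1$counts$region)
  expect_equal(inv2$counts$cluster, inv1$counts$cluster)
})

test_that("packaged receptor fixture reproduces the printed decomposition", {
  b <- bundle_fixture()
  inv <- classify_waters(b$structure, detect_hbonds(b$structure),
                         site_names = b$site_names)
  expect_equal(as.integer(inv$counts$region[c("L", "S", "G")]), c(5L, 8L, 1L))
  expect_equal(as.integer(inv$counts$cluster), c(2L, 2L, 4L))
  # per-site intended contacts are all realised
  for (w in names(b$truth$contacts)) {
    got <- strsplit(inv$sites$contacts[inv$sites$name == w], ";")[[1]]
    expect_true(all(b$truth$contacts[[w]] %in% got), info = w)
  }
})

test_that("network_connectivity: chain graph, cut vertex, oracle equivalence", {
  chain_inventory <- function(drop = NULL) {
    nodes <- c("A/65/OD1", paste0("W_S", 1:8), "W_G1", "B/391/O")
    edges <- cbind(nodes[-length(nodes)], nodes[-1])
    if (!is.null(drop)) {
      keep <- !(edges[, 1] == drop | edges[, 2] == drop)
      edges <- edges[keep, , drop = FALSE]
      nodes <- setdiff(nodes, drop)
    }
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    structure(list(sites = NULL, graph = g, counts = NULL),
              class = "hydronet_inventory")
  }
  inv <- chain_inventory()
  conn <- network_connectivity(inv, c("A/65/OD1", "B/391/O"))
  expect_true(conn$path)
  expect_equal(length(conn$sizes), 1L)

  inv2 <- chain_inventory(drop = "W_S5")
  conn2 <- network_connectivity(inv2, c("A/65/OD1", "B/391/O"))
  expect_false(conn2$path)
  expect_equal(length(conn2$sizes), 2L)

  expect_error(network_connectivity(inv, c("A/65/OD1", "nope")), "terminal")

  # random graphs vs transitive-closure oracle
  for (seed in c(3, 14)) {
    set.seed(seed)
    nodes <- paste0("n", 1:10)
    edges <- cbind(sample(nodes, 8, replace = TRUE),
                   sample(nodes, 8, replace = TRUE))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, length(setdiff(nodes, igraph::V(g)$name)),
                              name = setdiff(nodes, igraph::V(g)$name))
    invr <- structure(list(graph = g), class = "hydronet_inventory")
    memb <- network_connectivity(invr, nodes[1:2])$components
    want <- oracle_components(edges, nodes)
    # same partition up to relabelling
    got <- memb[nodes]
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(v) length(unique(v))) == 1))
  }
})
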