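test_that("sealed shell volume approximates the analytic value", {
  sh <- make_shell_structure(inner_edge = 10, sealed = TRUE)
  cav <- detect_cavities(sh$structure, spacing = 0.5)
  expect_equal(length(cav), 1L)
  expect_lt(abs(cav[[1]]$volume - sh$truth$analytic_volume) /
              sh$truth$analytic_volume, 0.15)
})

test_that("volume error is non-increasing as the grid is refined", {
  sh <- make_shell_structure(inner_edge = 10, sealed = TRUE)
  errs <- vapply(c(0.8, 0.4, 0.2), function(sp) {
    cav <- detect_cavities(sh$structure, spacing = sp)
    abs(cav[[1]]$volume - 1000) / 1000
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("solid block and wide-mouth shell yield no cavities", {
  expect_equal(length(detect_cavities(make_solid_block(10), spacing = 0.5)),
               0L)
  # mouth aperture must clear the large-probe diameter plus rim radii;
  # the sphere has no corners, so the interior joins bulk completely
  ob <- make_shell_structure(12, sealed = FALSE, mouth_width = 14,
                             shape = "sphere")
  expect_equal(length(detect_cavities(ob$structure, spacing = 0.5)), 0L)
  # narrow mouth (impassable to the large probe): interior stays cavity
  nb <- make_shell_structure(12, sealed = FALSE, mouth_width = 8,
                             shape = "sphere")
  expect_equal(length(detect_cavities(nb$structure, spacing = 0.5)), 1L)
})

test_that("config errors are rejected", {
  sh <- make_shell_structure(10)
  expect_error(detect_cavities(sh$structure, spacing = 2, probe_in = 1.4),
               "config error")
  expect_error(detect_cavities(sh$structure, probe_in = 5, probe_out = 4),
               "config error")
  empty <- as_hydronet_structure(data.frame(
    name = character(), element = character(), chain = character(),
    resno = integer(), x = numeric(), y = numeric(), z = numeric()))
  expect_error(detect_cavities(empty), "empty structure")
})

test_that("probe monotonicity: volumes respond correctly to probe sizes", {
  b <- bundle_fixture()
  st <- b$structure
  base <- sum(vapply(detect_cavities(st, spacing = 0.8),
                     `[[`, numeric(1), "volume"))
  # larger outer probe seals more mouths -> never less cavity volume
  bigger_out <- sum(vapply(detect_cavities(st, spacing = 0.8,
                                           probe_out = 5.5),
                           `[[`, numeric(1), "volume"))
  expect_gte(bigger_out + 1e-9, base)
  # larger inner probe occludes more -> never more cavity volume
  bigger_in <- sum(vapply(detect_cavities(st, spacing = 0.8,
                                          probe_in = 1.8),
                          `[[`, numeric(1), "volume"))
  expect_lte(bigger_in - 1e-9, base)
})

test_that("cavity volumes are invariant to rigid transformation", {
  sh <- make_shell_structure(10, sealed = TRUE)
  v1 <- detect_cavities(sh$structure, spacing = 0.5)[[1]]$volume
  st2 <- sh$structure
  rot <- rotation_matrix(c(1, 3, -2), 41)
  xyz <- as.matrix(st2$atoms[, c("x", "y", "z")]) %*% t(rot) +
    matrix(c(6, -2, 11), nrow(st2$atoms), 3, byrow = TRUE)
  st2$atoms[, c("x", "y", "z")] <- xyz
  v2 <- detect_cavities(st2, spacing = 0.5)[[1]]$volume
  # within one surface-voxel layer: ~ area * spacing
  expect_lt(abs(v2 - v1), 6 * 10^2 * 0.5)
})

test_that("assign_cavity_regions labels by anchor contacts with precedence", {
  b <- bundle_fixture()
  cav <- detect_cavities(b$structure, spacing = 0.8)
  cav <- assign_cavity_regions(cav, b$structure)
  labs <- vapply(cav, `[[`, character(1), "label")
  # the continuous lumen touches all anchors -> CWC by precedence, logged
  main <- which.max(vapply(cav, `[[`, numeric(1), "volume"))
  expect_equal(labs[main], "CWC")
  expect_match(cav[[main]]$tiebreak, "precedence")
  expect_true(all(c("2.50", "7.53", "5.58") %in%
                    cav[[main]]$anchor_contacts))
  # a cavity contacting nothing in the anchor set stays unassigned
  far <- cav[vapply(cav, function(x) length(x$anchor_contacts) == 0,
                    logical(1))]
  if (length(far))
    expect_true(all(vapply(far, `[[`, character(1), "label") ==
                      "unassigned"))
  # missing anchors warn
  expect_warning(assign_cavity_regions(cav, make_solid_block(6)), "missing")
})

test_that("classify_558 follows the fixed residue-class table", {
  thr <- make_bundle_structure(bundle_spec(with_waters = FALSE,
                                           with_ligand = FALSE,
                                           with_partner = FALSE))
  expect_equal(classify_558(thr$structure)$class, "small-polar")
  tyr <- make_bundle_structure(bundle_spec(residue_558 = "TYR",
                                           with_waters = FALSE,
                                           with_ligand = FALSE,
                                           with_partner = FALSE))
  expect_equal(classify_558(tyr$structure)$class, "bulky")
  gly <- make_bundle_structure(bundle_spec(residue_558 = "GLY",
                                           with_waters = FALSE,
                                           with_ligand = FALSE,
                                           with_partner = FALSE))
  expect_equal(classify_558(gly$structure)$class, "other")
  expect_error(classify_558(make_solid_block(6)), "5.58")
})

test_that("cavity_panel orders EWC volumes by pocket width and flags failures", {
  narrow <- make_bundle_structure(bundle_spec())
  wide <- make_bundle_structure(bundle_spec(widen_ic = 2.5))
  panel <- suppressWarnings(cavity_panel(list(
    list(structure = narrow$structure, name = "narrow"),
    list(structure = wide$structure, name = "wide"),
    list(path = tempfile(), mapping_path = tempfile(), name = "broken")),
    spacing = 0.8))
  expect_equal(nrow(panel), 3L)
  expect_equal(sum(panel$status == "ok"), 2L)
  expect_match(panel$status[3], "FAILED")
  expect_gt(panel$EWC[panel$receptor == "wide"],
            panel$EWC[panel$receptor == "narrow"])
  # single structure: group means equal that row
  p1 <- cavity_panel(list(list(structure = narrow$structure,
                               name = "solo")), spacing = 0.8)
  expect_equal(unname(attr(p1, "group_means")), p1$EWC)
})
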