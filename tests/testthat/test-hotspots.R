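two_partner_model <- function(cross_d, intra_d = 20) make_model(list(
  list(chain = "A", resno = 1, xyz = c(0, 0, 0)),
  list(chain = "A", resno = 2, xyz = c(intra_d, 0, 0)),
  list(chain = "B", resno = 1, xyz = c(0, cross_d, 0)),
  list(chain = "B", resno = 2, xyz = c(intra_d, cross_d + intra_d, 0))))

pm <- partner_map("A", "B")

test_that("interface membership requires a cross-partner contact in the window", {
  iface <- interface_residues(two_partner_model(4.0), pm)
  expect_equal(iface$receptor, "A:1")
  expect_equal(iface$ligand, "B:1")

  far <- interface_residues(two_partner_model(6.0), pm)
  expect_length(far$receptor, 0)
  expect_length(far$ligand, 0)

  # intra-partner contact only: A:1-A:2 touch, partners far apart
  intra <- make_model(list(
    list(chain = "A", resno = 1, xyz = c(0, 0, 0)),
    list(chain = "A", resno = 2, xyz = c(4, 0, 0)),
    list(chain = "B", resno = 1, xyz = c(0, 50, 0))))
  got <- interface_residues(intra, pm)
  expect_length(got$receptor, 0)
  expect_length(got$ligand, 0)
})

test_that("partner map validates chains and rejects one-sided models", {
  expect_error(partner_map(character(0), "B"), "at least one chain")
  expect_error(partner_map("A", "A"), "both partners")
  single <- make_model(list(list(chain = "A", resno = 1, xyz = c(0, 0, 0)),
                            list(chain = "A", resno = 2, xyz = c(4, 0, 0))))
  expect_error(analyze_pose(single, pm), "both partners")
  unknown <- make_model(list(list(chain = "A", resno = 1, xyz = c(0, 0, 0)),
                             list(chain = "C", resno = 1, xyz = c(4, 0, 0))))
  expect_error(analyze_pose(unknown, pm), "not assigned")
})

test_that("analyze_pose finds planted hotspots at the interface with Z >= 3", {
  poses <- gen_toy_poses(toy_complex_spec(n_poses = 1, seed = 21))
  partners <- attr(poses, "partners")
  planted <- attr(poses, "planted")
  pr <- analyze_pose(poses[[1]], partners)
  iface <- c(pr$interface$receptor, pr$interface$ligand)
  expect_true(all(planted %in% iface))
  cen <- pr$centrality
  expect_true(all(cen$z[match(planted, cen$residue)] >= 3))
})

test_that("distant partners give empty interfaces but centrality still runs", {
  pr <- analyze_pose(two_partner_model(30), pm)
  expect_length(pr$interface$receptor, 0)
  expect_equal(nrow(pr$centrality), 4)
})

test_that("consensus applies the at-least-one-model rule and keeps the max Z", {
  mk_pose <- function(id, iface, central_z) {
    cen <- data.frame(residue = names(central_z), closeness = 0,
                      z = unname(central_z), is_central = unname(central_z) >= 3,
                      stringsAsFactors = FALSE)
    structure(list(pose_id = id,
                   interface = list(receptor = intersect(iface, c("A:1", "A:2")),
                                    ligand = intersect(iface, c("B:1"))),
                   centrality = structure(cen, class = c("CentralityResult",
                                                         "data.frame")),
                   partner = c("A:1" = "receptor", "A:2" = "receptor",
                               "B:1" = "ligand"),
                   params = list()),
              class = "PoseResult")
  }
  z0 <- c("A:1" = 0.5, "A:2" = 3.5, "B:1" = 1)
  poses <- list(
    mk_pose("p1", c("A:1", "B:1"), c("A:1" = 3.4, "A:2" = 1, "B:1" = 0)),
    mk_pose("p2", character(0), z0), mk_pose("p3", character(0), z0),
    mk_pose("p4", character(0), z0), mk_pose("p5", character(0), z0))
  tab <- consensus_hotspots(poses)
  r <- tab[tab$residue == "A:1", ]
  expect_true(r$hotspot)                       # interface+central in 1 of 5
  expect_equal(r$n_poses_central, 1)
  expect_equal(r$max_z, 3.4)
  # central in 4 poses but never at the interface: not a hotspot
  expect_false(tab$hotspot[tab$residue == "A:2"])
  # interface but never central: not a hotspot
  expect_false(tab$hotspot[tab$residue == "B:1"])
  # hotspot set is contained in the union of per-pose interface sets
  iface_union <- unique(unlist(lapply(poses, function(p) unlist(p$interface))))
  expect_true(all(tab$residue[tab$hotspot] %in% iface_union))

  # adding a pose never decreases counts or max z
  tab6 <- consensus_hotspots(c(poses, list(
    mk_pose("p6", c("A:2", "B:1"), c("A:1" = 0, "A:2" = 5, "B:1" = 0)))))
  m <- match(tab$residue, tab6$residue)
  expect_true(all(tab6$n_poses_interface[m] >= tab$n_poses_interface))
  expect_true(all(tab6$n_poses_central[m] >= tab$n_poses_central))
  expect_true(all(tab6$max_z[m] >= tab$max_z))

  bad <- mk_pose("px", character(0), z0)
  bad$partner["B:1"] <- "receptor"
  expect_error(consensus_hotspots(list(poses[[1]], bad)), "inconsistent partner")
  expect_error(consensus_hotspots(list()), "at least one pose")
})

test_that("a candidate list restricts the table to the requested residues", {
  # mirror of the selected-candidates workflow: of 7 candidates, only the
  # 4 planted ones come out central in at least one model
  spec <- toy_complex_spec(n_poses = 5, seed = 31)
  poses <- gen_toy_poses(spec)
  partners <- attr(poses, "partners")
  planted <- attr(poses, "planted")
  results <- lapply(poses, analyze_pose, partners = partners)
  candidates <- c(planted, "A:11", "A:29", "B:9")  # 4 planted + 3 bystanders
  tab <- consensus_hotspots(results, candidates = candidates)
  expect_setequal(tab$residue, candidates)
  expect_setequal(tab$residue[tab$hotspot], planted)
})
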