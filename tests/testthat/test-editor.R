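test_that("edit commands scale exactly the cords in scope", {
  sc <- competent_scene()
  cs <- sc$cords
  # identity
  expect_equal(apply_edit(cs, edit_command("all", factor = 1))$cords$rest_length,
               cs$cords$rest_length)
  # group scope touches exactly its members
  g <- "anterior-anterolateral"
  cg <- apply_edit(cs, edit_command("group", g, 0.8))
  sel <- cs$cords$group == g
  expect_equal(cg$cords$rest_length[sel], 0.8 * cs$cords$rest_length[sel])
  expect_identical(cg$cords$rest_length[!sel], cs$cords$rest_length[!sel])
  # inverse pair restores the original
  back <- apply_edit(apply_edit(cs, edit_command("all", factor = 2)),
                     edit_command("all", factor = 0.5))
  expect_equal(back$cords$rest_length, cs$cords$rest_length,
               tolerance = 1e-12)
  # absolute set
  ca <- apply_edit(cs, edit_command("single", 3, 17.5, absolute = TRUE))
  expect_equal(ca$cords$rest_length[3], 17.5)
  # errors name the offending target
  expect_error(apply_edit(cs, edit_command("group", "left-ventricle", 1.1)),
               "unknown cord group")
  expect_error(apply_edit(cs, edit_command("single", 10000, 1.1)),
               "out of range")
})

test_that("disjoint single edits commute and groups partition the cords", {
  sc <- competent_scene()
  cs <- sc$cords
  e1 <- edit_command("single", 1, 0.7)
  e2 <- edit_command("single", 5, 1.3)
  ab <- apply_edit(apply_edit(cs, e1), e2)
  ba <- apply_edit(apply_edit(cs, e2), e1)
  expect_identical(ab$cords$rest_length, ba$cords$rest_length)

  expect_setequal(unique(cs$cords$group), mitralsim:::cord_groups())
  # group scaling equals composing its member single-cord scalings
  g <- "posterior-posteromedial"
  via_group <- apply_edit(cs, edit_command("group", g, 0.9))
  via_singles <- cs
  for (k in which(cs$cords$group == g))
    via_singles <- apply_edit(via_singles, edit_command("single", k, 0.9))
  expect_equal(via_group$cords$rest_length, via_singles$cords$rest_length,
               tolerance = 1e-12)
})

test_that("phase switching flips only the sign and reverses the flow", {
  ph <- force_phase(pressure = 123, velocity_gain = 4, target_speed = -7)
  ps <- switch_phase(ph)
  expect_equal(ps$phase_sign, -1)
  expect_equal(ps[c("pressure", "velocity_gain", "target_speed")],
               ph[c("pressure", "velocity_gain", "target_speed")])
  expect_equal(switch_phase(ps), ph)

  p <- flat_patch(3, 3)
  sc <- toy_scene(p$pos, p$tri)
  st <- sim_state(sc$mesh, integer())
  f1 <- external_forces(st, sc$mesh, ph, sc$plane)
  f2 <- external_forces(st, sc$mesh, ps, sc$plane)
  # at zero velocity the drag flow reverses exactly with the phase
  expect_equal(f2, -f1)
})

test_that("an empty session script reproduces plain steady-state simulation", {
  p <- flat_patch(3, 3)
  sc <- toy_scene(p$pos, p$tri)
  cfg <- solver_config(steady_window = 5L, max_steps = 60L)
  ph <- force_phase(pressure = 0, velocity_gain = 0)
  ses <- run_session(sc, list(), cfg, ph)
  plain <- simulate_until_steady(sc, ph, cfg)
  expect_identical(ses$sim$state$pos, plain$state$pos)
  expect_equal(nrow(ses$snapshots), 1)
  expect_equal(ses$snapshots$command, "final")
})

test_that("sessions are deterministic and report per-edit snapshots", {
  sc <- generate_scene(valve_params(mesh_resolution = 3.5))
  script <- list(
    list(t = 0.05, command = edit_command("group", "anterior-anterolateral",
                                          0.9)),
    list(t = 0.10, command = edit_command("all", factor = 1.02)))
  cfg <- solver_config(max_steps = 300L)
  s1 <- run_session(sc, script, cfg, force_phase())
  s2 <- run_session(sc, script, cfg, force_phase())
  expect_identical(s1$sim$state$pos, s2$sim$state$pos)
  expect_identical(s1$snapshots, s2$snapshots)
  expect_equal(nrow(s1$snapshots), 3)
  expect_true(all(diff(s1$snapshots$time) >= 0))
  # the edits really landed on the cord set used afterwards
  expect_equal(s1$cords$cords$rest_length,
               apply_edit(apply_edit(sc$cords, script[[1]]$command),
                          script[[2]]$command)$cords$rest_length)
  expect_error(run_session(sc, rev(script), cfg), "non-decreasing")
})

test_that("over-lengthened cords on the competent fixture cause prolapse", {
  sc <- competent_scene()
  scx <- sc
  scx$cords <- apply_edit(scx$cords, edit_command("all", factor = 10))
  sim <- simulate_valve(scx)
  pr <- detect_prolapse(sim$state$pos, scx$mesh, scx$contour)
  expect_true(pr$prolapse)
  base <- detect_prolapse(closed_competent()$state$pos, sc$mesh, sc$contour)
  expect_false(base$prolapse)
})
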