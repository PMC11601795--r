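test_that("the symmetric tree has binary-tree structure and scaled geometry", {
  topo <- build_symmetric_tree(vessel_spec(0L, 0.4, 135, 0.2),
                               generations = 4L,
                               lengths = c(0.4, 0.3, 0.2, 0.15))
  expect_equal(nrow(topo), 15L)
  expect_equal(as.integer(table(topo$generation)), c(1L, 2L, 4L, 8L))
  # daughter diameter from the parent-to-daughters area ratio of 1.35
  expect_equal(unique(topo$Do_um[topo$generation == 1]),
               135 * sqrt(1.35 / 2), tolerance = 1e-12)
  expect_equal(unique(topo$Do_um[topo$generation == 1]), 110.9,
               tolerance = 1e-3)
  # thickness ratio scaling 90/80/70% of the root value
  expect_equal(vapply(0:3, function(g) unique(topo$hw[topo$generation == g]),
                      numeric(1)),
               0.2 * c(1, 0.9, 0.8, 0.7))
  # every junction joins one parent to exactly two daughters
  kids <- table(topo$parent[!is.na(topo$parent)])
  expect_true(all(kids == 2L))
})

test_that("boundary attachment sets the stated defaults on every terminal", {
  topo <- default_mca_tree()
  b <- attr(topo, "boundaries")
  expect_equal(b$Pout_mmHg, 50)
  expect_equal(b$Pext_mmHg, 10)
  expect_equal(b$Z_mode, "characteristic")
  expect_length(terminal_vessels(topo), 8L)
  # symmetric terminals carry equal impedances (computed at t = 0)
  sim <- run_simulation(topo, signal_constant(55), t_end = 5e-4,
                        config = coupling_config(mode = "weak", dt = 2.5e-4,
                                                 record_dt = 2.5e-4))
  expect_length(sim$Z, 8L)
  expect_equal(max(sim$Z) - min(sim$Z), 0)
  expect_true(all(sim$Z > 0))
})

test_that("topologies survive a JSON round trip", {
  topo <- default_mca_tree()
  path <- withr::local_tempfile(fileext = ".json")
  topology_to_json(topo, path)
  back <- topology_from_json(path)
  expect_equal(as.data.frame(back), as.data.frame(topo))
  expect_equal(attr(back, "boundaries"), attr(topo, "boundaries"))
})

test_that("malformed topologies are rejected", {
  topo <- default_mca_tree()
  broken <- topo
  broken$parent[2] <- NA_integer_ # two roots
  expect_error(myoflow:::validate_topology(broken),
               class = "myoflow_topology_error")
  broken2 <- topo[-3, ] # junction with a single daughter
  expect_error(myoflow:::validate_topology(broken2),
               class = "myoflow_topology_error")
})

test_that("symmetric generations produce identical mid-vessel traces", {
  topo <- default_mca_tree()
  sim <- run_simulation(topo, default_inlet_signal(), t_end = 0.5,
                        config = coupling_config(mode = "weak", dt = 2.5e-4,
                                                 averaged_active_stress = TRUE,
                                                 record_dt = 5e-2))
  for (g in 1:3) {
    vs <- topo$vessel[topo$generation == g]
    ref <- dplyr::filter(sim$probes, vessel == vs[1])
    for (v in vs[-1]) {
      other <- dplyr::filter(sim$probes, vessel == v)
      expect_equal(other$Q_ml_s, ref$Q_ml_s, tolerance = 1e-9)
      expect_equal(other$A_cm2, ref$A_cm2, tolerance = 1e-12)
    }
  }
})
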