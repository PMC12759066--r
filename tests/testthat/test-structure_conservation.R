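test_that("superposition recovers rigid motions to numerical precision", {
  fx <- gen_domain_structure("three_helix", seed = 41)
  self <- superpose(fx$model, fx$model)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  for (seed in 1:25) {
    moved <- withr::with_seed(seed, apply_rigid_to_model(fx$model,
                                                         random_rigid_oracle()))
    fit <- superpose(fx$model, moved)
    expect_lt(fit$rmsd, 1e-6)
  }
})

test_that("superposition rmsd matches the closed form for one displaced atom", {
  # 10 CA atoms far apart; displacing one near-central atom by d and refitting
  # an otherwise identical copy leaves rmsd ~= d * sqrt(n - 1) / n, because
  # the optimal translation absorbs d^2/n of the squared error and the
  # optimal rotation almost nothing for a central atom
  n <- 10
  x <- cbind(seq(0, 900, by = 100), 0, 0)
  y <- x
  y[5, 2] <- y[5, 2] + 1.0
  fit <- superpose(x, y)
  expect_equal(fit$rmsd, sqrt(n - 1) / n, tolerance = 0.01)
  expect_error(superpose(x[1:2, ], y[1:2, ]), "at least 3")
})

test_that("superposition agrees with the bio3d reference implementation", {
  fx <- gen_domain_structure("degenerate_missing_helix", seed = 8)
  noisy <- fx$model
  noisy$atoms[, c("x", "y", "z")] <- noisy$atoms[, c("x", "y", "z")] +
    withr::with_seed(9, matrix(rnorm(nrow(noisy$atoms) * 3, sd = 0.5), ncol = 3))
  ca_a <- as.matrix(fx$model$atoms[fx$model$atoms$atom == "CA", c("x", "y", "z")])
  ca_b <- as.matrix(noisy$atoms[noisy$atoms$atom == "CA", c("x", "y", "z")])
  fit <- superpose(ca_a, ca_b)
  xyz_fit <- bio3d::fit.xyz(as.numeric(t(ca_a)), as.numeric(t(ca_b)),
                            seq_along(ca_a), seq_along(ca_b))
  expect_equal(fit$rmsd,
               bio3d::rmsd(as.numeric(t(ca_a)), xyz_fit),
               tolerance = 1e-3)
})

test_that("helix detection counts ideal segments and respects the window", {
  fx3 <- gen_domain_structure("three_helix", seed = 2)
  seg <- detect_helices(fx3$model, fx3$window)
  expect_equal(nrow(seg), 3L)
  expect_true(all(seg$length == 12))

  expect_equal(nrow(detect_helices(gen_domain_structure("no_domain", seed = 2)$model)),
               0L)

  # a single ideal helix of 20 residues is one segment of length 20
  phi <- c(-140, rep(-57, 20), -140)
  psi <- c(150, rep(-47, 20), 150)
  atoms <- afmetrics:::build_backbone(phi, psi)
  atoms$chain <- "A"; atoms$resname <- "ALA"; atoms$plddt <- 90
  m <- predicted_model(atoms[, c("chain", "resno", "resname", "atom", "element",
                                 "x", "y", "z", "plddt")])
  seg1 <- detect_helices(m)
  expect_equal(nrow(seg1), 1L)
  expect_equal(seg1$length, 20L)

  # absent window -> no segments; runs below min_helix_len are dropped
  expect_equal(nrow(detect_helices(fx3$model, domain_range("s", "d", NA, NA))), 0L)
  expect_equal(nrow(detect_helices(m, min_helix_len = 21)), 0L)
})

test_that("ORC6-BD calls follow the three-helix and insertion rules", {
  fx3 <- gen_domain_structure("three_helix", seed = 5)
  ref_len <- fx3$window$n_residues
  call3 <- classify_orc6bd(fx3$model, fx3$window, ref_length = ref_len)
  expect_equal(call3$status, "conserved")
  expect_equal(call3$n_helices, 3L)

  fx2 <- gen_domain_structure("degenerate_missing_helix", seed = 5)
  call2 <- classify_orc6bd(fx2$model, fx2$window, ref_length = ref_len)
  expect_equal(call2$status, "non_conserved")

  fx0 <- gen_domain_structure("no_domain", seed = 5)
  call0 <- classify_orc6bd(fx0$model, fx0$window, ref_length = ref_len)
  expect_equal(call0$status, "absent")
  expect_equal(call0$n_helices, 0L)

  # three helices but a window expanded beyond tolerance -> insertion
  short_ref <- floor(fx3$window$n_residues / 1.5)
  ins <- classify_orc6bd(fx3$model, fx3$window, ref_length = short_ref,
                         insertion_tolerance = 0.3)
  expect_equal(ins$status, "non_conserved")
  expect_match(ins$evidence, "insertion")
})

test_that("tether calls need only sufficient residues, not a helix", {
  coil <- gen_domain_structure("no_domain", seed = 6)
  w25 <- domain_range("s", "ORC3_tether", 4, 28)
  call <- classify_tether(coil$model, w25)
  expect_equal(call$status, "conserved")
  expect_equal(call$n_helices, 0L)

  w3 <- domain_range("s", "ORC3_tether", 4, 6)
  expect_equal(classify_tether(coil$model, w3)$status, "absent")
  expect_equal(classify_tether(coil$model,
                               domain_range("s", "ORC3_tether", NA, NA))$status,
               "absent")
})

test_that("pLDDT summaries average the selection with an inclusive 70 cutoff", {
  atoms <- do.call(rbind, lapply(1:10, function(r) {
    data.frame(chain = "A", resno = r, resname = "ALA", atom = "CA",
               element = "C", x = r * 10, y = 0, z = 0,
               plddt = if (r <= 5) 60 else 80)
  }))
  m <- predicted_model(atoms)
  s <- plddt_summary(m)
  expect_equal(s$mean, 70)
  expect_true(s$reliable_backbone)  # boundary inclusive
  s2 <- plddt_summary(m, domain_range("s", "d", 1, 5))
  expect_equal(s2$mean, 60)
  expect_false(s2$reliable_backbone)
  s3 <- plddt_summary(m, domain_range("s", "d", NA, NA))
  expect_true(is.na(s3$mean))
  expect_equal(s3$n, 0L)
})
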