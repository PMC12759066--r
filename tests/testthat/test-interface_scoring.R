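make_bundle <- function(model, fill = 5, pairs = NULL, value = NULL) {
  n <- nrow(residue_table(model))
  pae <- matrix(fill, n, n)
  diag(pae) <- 0
  if (!is.null(pairs)) {
    pae[pairs] <- value
    pae[pairs[, c(2, 1), drop = FALSE]] <- value
  }
  confidence_bundle(pae)
}

test_that("contact detection uses strict < 8 A on non-hydrogen atoms", {
  at_8 <- tiny_model(list(chain = "A", resno = 1, atom = "CA", element = "C",
                          xyz = c(0, 0, 0)),
                     list(chain = "B", resno = 1, atom = "CA", element = "C",
                          xyz = c(8, 0, 0)))
  expect_equal(nrow(detect_contacts(at_8, "A", "B")), 0L)

  near <- tiny_model(list(chain = "A", resno = 1, atom = "CA", element = "C",
                          xyz = c(0, 0, 0)),
                     list(chain = "B", resno = 1, atom = "CA", element = "C",
                          xyz = c(7.999, 0, 0)))
  cc <- detect_contacts(near, "A", "B")
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$min_distance, 7.999)

  # hydrogens never create contacts
  h_only <- tiny_model(list(chain = "A", resno = 1, atom = "HA", element = "H",
                            xyz = c(0, 0, 0)),
                       list(chain = "A", resno = 1, atom = "CA", element = "C",
                            xyz = c(0, 0, 20)),
                       list(chain = "B", resno = 1, atom = "HB", element = "H",
                            xyz = c(3, 0, 0)),
                       list(chain = "B", resno = 1, atom = "CA", element = "C",
                            xyz = c(3, 0, -20)))
  expect_equal(nrow(detect_contacts(h_only, "A", "B")), 0L)
  expect_error(detect_contacts(near, "A", "C"), "unknown chain")
})

test_that("contact detection matches the brute-force oracle on random toys", {
  for (seed in 1:10) {
    m <- random_toy_model(sample(5:30, 1), sample(5:30, 1), seed = seed)
    got <- detect_contacts(m, "A", "B")
    want <- brute_force_contacts(m, "A", "B")
    expect_equal(got$res_a, want$res_a, label = sprintf("seed %d", seed))
    expect_equal(got$res_b, want$res_b)
    expect_equal(got$min_distance, want$min_distance, tolerance = 1e-9)
  }
})

test_that("confidence filtering applies the pLDDT < 50 and pAE > 15 exclusions", {
  m <- tiny_model(list(chain = "A", resno = 1, atom = "CA", element = "C",
                       xyz = c(0, 0, 0), plddt = 49.9),
                  list(chain = "A", resno = 2, atom = "CA", element = "C",
                       xyz = c(0, 10, 0), plddt = 90),
                  list(chain = "B", resno = 1, atom = "CA", element = "C",
                       xyz = c(5, 0, 0), plddt = 90),
                  list(chain = "B", resno = 2, atom = "CA", element = "C",
                       xyz = c(5, 10, 0), plddt = 50))
  cc <- detect_contacts(m, "A", "B")
  expect_equal(nrow(cc), 2L)

  # contact touching the pLDDT 49.9 residue is excluded, boundary 50 kept
  f <- filter_contacts(cc, m, make_bundle(m), score_config())
  expect_equal(nrow(f), 1L)
  expect_equal(f$res_a, 2L)
  expect_equal(f$min_plddt, 50)

  # pae 16 in both directions excludes; boundary 15 kept
  b16 <- make_bundle(m, fill = 16)
  expect_equal(nrow(filter_contacts(cc, m, b16, score_config())), 0L)
  b15 <- make_bundle(m, fill = 15)
  f15 <- filter_contacts(cc, m, b15, score_config())
  expect_equal(nrow(f15), 1L)

  # clean confidences leave the set unchanged
  clean <- tiny_model(list(chain = "A", resno = 1, atom = "CA", element = "C",
                           xyz = c(0, 0, 0)),
                      list(chain = "B", resno = 1, atom = "CA", element = "C",
                           xyz = c(5, 0, 0)))
  cc2 <- detect_contacts(clean, "A", "B")
  f2 <- filter_contacts(cc2, clean, make_bundle(clean), score_config())
  expect_equal(f2[, names(cc2)], cc2, ignore_attr = TRUE)
})

test_that("asymmetric pAE directions combine per configuration", {
  m <- tiny_model(list(chain = "A", resno = 1, atom = "CA", element = "C",
                       xyz = c(0, 0, 0)),
                  list(chain = "B", resno = 1, atom = "CA", element = "C",
                       xyz = c(5, 0, 0)))
  pae <- matrix(0, 2, 2); pae[1, 2] <- 10; pae[2, 1] <- 20
  b <- confidence_bundle(pae)
  cc <- detect_contacts(m, "A", "B")
  f_mean <- filter_contacts(cc, m, b, score_config(pae_combine = "mean"))
  expect_equal(f_mean$pae, 15)   # kept at the boundary
  f_max <- filter_contacts(cc, m, b, score_config(pae_combine = "max"))
  expect_equal(nrow(f_max), 0L)  # 20 > 15 excluded
  f_min <- filter_contacts(cc, m, b, score_config(pae_combine = "min"))
  expect_equal(f_min$pae, 10)
})

test_that("canonical restriction keeps only domain-touching contacts", {
  cc <- data.frame(chain_a = "A", res_a = c(5L, 25L), chain_b = "B",
                   res_b = c(1L, 2L), min_distance = 5)
  dom <- domain_range("s", "ORC6_BD", 1, 10)
  kept <- restrict_canonical(cc, dom, "A")
  expect_equal(kept$res_a, 5L)
  expect_equal(nrow(restrict_canonical(cc, domain_range("s", "ORC6_BD", NA, NA), "A")),
               0L)
})

test_that("average-models score follows the shared-contact formula", {
  cfg <- score_config()
  set_of <- function(res_a) data.frame(chain_a = rep("A", length(res_a)),
                                       res_a = res_a,
                                       chain_b = rep("B", length(res_a)),
                                       res_b = res_a,
                                       min_distance = rep(5, length(res_a)))
  # five identical non-empty sets -> 1
  expect_identical(average_models(rep(list(set_of(1:4)), 5), cfg), 1)
  # five empty sets -> 0
  expect_identical(average_models(rep(list(set_of(integer())), 5), cfg), 0)
  # one contact in all five models plus one in exactly one -> (5+1)/2/5
  sets <- c(list(set_of(c(1L, 2L))), rep(list(set_of(1L)), 4))
  expect_equal(average_models(sets, cfg), 0.6)
  expect_error(average_models(rep(list(set_of(1L)), 4), cfg), "expected 5")
})

test_that("average-models score is bounded and monotone under dilution", {
  cfg <- score_config()
  set_of <- function(res_a) data.frame(chain_a = rep("A", length(res_a)),
                                       res_a = res_a,
                                       chain_b = rep("B", length(res_a)),
                                       res_b = res_a,
                                       min_distance = rep(5, length(res_a)))
  for (seed in 1:20) {
    sets <- withr::with_seed(seed, {
      lapply(1:5, function(i) set_of(sample(1:12, sample(0:8, 1))))
    })
    s <- average_models(sets, cfg)
    if (all(vapply(sets, nrow, 1L) == 0L)) {
      expect_identical(s, 0)
    } else {
      expect_gte(s, 1 / 5)
      expect_lte(s, 1)
    }
    # adding a contact shared by all models never decreases the score
    shared <- lapply(sets, function(x) rbind(x, set_of(99L)))
    expect_gte(average_models(shared, cfg), s)
    # adding a single-model contact never increases a non-zero score
    if (s > 0) {
      single <- sets
      single[[1]] <- rbind(single[[1]], set_of(98L))
      expect_lte(average_models(single, cfg), s)
    }
    # invariant to model order and row order
    perm <- withr::with_seed(seed + 1, sample(5))
    shuffled <- lapply(sets[perm], function(x) x[sample(nrow(x)), , drop = FALSE])
    expect_identical(average_models(shuffled, cfg), s)
  }
})

test_that("interface pAE averages retained contact pairs, undefined when none", {
  cfg <- score_config()
  one <- data.frame(chain_a = "A", res_a = 1L, chain_b = "B", res_b = 1L,
                    min_distance = 5, pae = 3.0)
  expect_equal(interface_pae(list(one), cfg), 3.0)
  two <- rbind(one, data.frame(chain_a = "A", res_a = 2L, chain_b = "B",
                               res_b = 2L, min_distance = 5, pae = 8.0))
  two$pae <- c(4.0, 8.0)
  expect_equal(interface_pae(list(two), cfg), 6.0)
  expect_true(is.na(interface_pae(list(one[0, ], one[0, ]), cfg)))
  # pooled across models vs union-unique
  expect_equal(interface_pae(list(two, one), cfg, pool = "instances"),
               mean(c(4, 8, 3)))
  one_dup <- one; one_dup$pae <- 4.0
  expect_equal(interface_pae(list(two, one_dup), cfg, pool = "union"),
               mean(c(4, 8)))
})

test_that("target scoring composes detection, filtering and restriction", {
  dom <- domain_range("t", "ORC6_BD", 1, 30)
  cfg <- score_config()
  shared <- gen_multimer(fixture_spec(interface_pairs = cbind(3:8, 3:8),
                                      shared_fraction = 1, iptm = 0.8, seed = 12))
  s1 <- score_target(shared, dom, cfg)
  expect_identical(s1$average_models, 1)
  expect_true(s1$confident)
  expect_true(s1$canonical)
  expect_equal(s1$iptm_best, 0.8)
  expect_equal(s1$n_contacts_per_model, rep(6L, 5))

  decoy <- gen_multimer(fixture_spec(interface_pairs = cbind(integer(), integer()),
                                     plddt_decoy_pairs = cbind(3:6, 3:6), seed = 13))
  s2 <- score_target(decoy, dom, cfg)
  expect_identical(s2$average_models, 0)
  expect_false(s2$confident)
  expect_false(s2$canonical)
  expect_true(is.na(s2$interface_pae))

  disjoint <- gen_multimer(fixture_spec(interface_pairs = cbind(1:5, 1:5),
                                        shared_fraction = 0, seed = 14))
  s3 <- score_target(disjoint, dom, cfg)
  expect_equal(s3$average_models, 0.2)
  expect_false(s3$confident)
})

test_that("a score above 0.5 is required for a confident call (strict)", {
  # 3 shared + 5 singleton contacts: score = (15 + 5) / (8 * 5) = 0.5 exactly
  spec <- fixture_spec(interface_pairs = cbind(c(2, 6, 10, 14, 18, 22, 26, 30),
                                               c(2, 6, 10, 14, 18, 22, 26, 30)),
                       shared_fraction = 3 / 8, seed = 15)
  s <- score_target(gen_multimer(spec), domain_range("t", "ORC6_BD", 1, 30),
                    score_config())
  expect_equal(s$average_models, 0.5)
  expect_false(s$confident)
})
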