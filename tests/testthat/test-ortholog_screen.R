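hit_row <- function(subunit, species, taxon, acc, pid, cov = 90, len = 700,
                    partial = FALSE, hasx = FALSE) {
  data.frame(query_subunit = subunit, species = species, taxon_group = taxon,
             accession = acc, percent_identity = pid, query_coverage = cov,
             sequence_length = len, is_partial = partial, has_X_residues = hasx,
             stringsAsFactors = FALSE)
}

test_that("identity floors separate true orthologs from CDC6-like false positives", {
  hits <- rbind(hit_row("ORC1", "snail", "Mollusca", "TRUE58", 58),
                hit_row("ORC1", "snail", "Mollusca", "CDC6LIKE", 28))
  pm <- call_orthologs(hits)
  expect_true(pm$presence["snail", "ORC1"])
  expect_equal(pm$representative["snail", "ORC1"], "TRUE58")

  # all hits below the floor -> absent
  pm2 <- call_orthologs(hit_row("ORC2", "snail", "Mollusca", "LOW", 12))
  expect_false(pm2$presence["snail", "ORC2"])

  # empty table -> empty matrix, no error
  pm3 <- call_orthologs(hit_row("ORC1", "x", "G", "a", 60)[0, ])
  expect_equal(nrow(pm3$presence), 0L)
})

test_that("the representative is the highest-coverage surviving hit", {
  hits <- rbind(hit_row("ORC3", "sp", "G", "COV80", 70, cov = 80),
                hit_row("ORC3", "sp", "G", "COV95", 60, cov = 95))
  expect_equal(call_orthologs(hits)$representative["sp", "ORC3"], "COV95")
  # coverage tie: higher identity, then smallest accession
  tie <- rbind(hit_row("ORC3", "sp", "G", "B_ACC", 70, cov = 90),
               hit_row("ORC3", "sp", "G", "A_ACC", 70, cov = 90),
               hit_row("ORC3", "sp", "G", "C_ACC", 80, cov = 90))
  expect_equal(call_orthologs(tie)$representative["sp", "ORC3"], "C_ACC")
  tie2 <- tie[1:2, ]
  expect_equal(call_orthologs(tie2)$representative["sp", "ORC3"], "A_ACC")
})

test_that("MCM2 uses a 50% floor and floors are overridable", {
  hits <- rbind(hit_row("MCM2", "sp", "G", "MCM45", 45),
                hit_row("ORC1", "sp", "G", "ORC45", 45))
  pm <- call_orthologs(hits)
  expect_false(pm$presence["sp", "MCM2"])
  expect_true(pm$presence["sp", "ORC1"])
  pm2 <- call_orthologs(hits, identity_floor = c(MCM2 = 40, .default = 60))
  expect_true(pm2$presence["sp", "MCM2"])
  expect_false(pm2$presence["sp", "ORC1"])
})

test_that("raising the identity floor never converts absent to present", {
  h <- gen_hit_table(list(a = c("ORC1", "ORC2", "ORC6"), b = c("ORC1", "ORC3")),
                     c(a = "G1", b = "G2"), false_positive_rate = 0.5, seed = 6)
  floors <- c(20, 40, 60, 80, 95)
  prev <- NULL
  for (f in floors) {
    pm <- call_orthologs(h, identity_floor = f)
    if (!is.null(prev)) expect_true(all(pm$presence <= prev))
    prev <- pm$presence
  }
})

test_that("taxon groups are excluded only when two or more ORC subunits vanish", {
  mk <- function(subunits, taxon, species) {
    do.call(rbind, lapply(subunits, function(su) {
      hit_row(su, species, taxon, paste0(species, su), 60)
    }))
  }
  hits <- rbind(
    mk(c("ORC1", "ORC2", "ORC3", "ORC4", "ORC5"), "NoOrc6", "n1"),  # only ORC6 missing
    mk(c("ORC1", "ORC3", "ORC5", "ORC6"), "TwoGone", "t1"),          # ORC2+ORC4 missing
    mk(c("ORC1", "ORC2", "ORC3", "ORC4", "ORC5", "ORC6"), "OneSpecies", "o1")
  )
  pm <- call_orthologs(hits)
  excluded <- taxon_inclusion(pm)
  expect_false("NoOrc6" %in% excluded)
  expect_true("TwoGone" %in% excluded)
  expect_false("OneSpecies" %in% excluded)
  # invariant to row duplication and order
  pm2 <- call_orthologs(hits[rev(rep(seq_len(nrow(hits)), 2)), ])
  expect_setequal(taxon_inclusion(pm2), excluded)
})

test_that("ORC6 loss is called only with ORC1-5 reliably present", {
  mk <- function(subunits, taxon, species) {
    do.call(rbind, lapply(subunits, function(su) {
      hit_row(su, species, taxon, paste0(species, su), 60)
    }))
  }
  hits <- rbind(
    mk(c("ORC1", "ORC2", "ORC3", "ORC4", "ORC5"), "NemaLike", "nem1"),
    mk(c("ORC1", "ORC2", "ORC3"), "NemaLike", "nem2"),
    mk(c("ORC1", "ORC2", "ORC3", "ORC4", "ORC5", "ORC6"), "VertLike", "v1"),
    mk(c("ORC1", "ORC2"), "Sparse", "s1")
  )
  st <- classify_orc6_status(call_orthologs(hits))
  expect_equal(unname(st["NemaLike"]), "ORC6-negative")
  expect_equal(unname(st["VertLike"]), "ORC6-positive")
  expect_equal(unname(st["Sparse"]), "unresolved")
  sp <- classify_orc6_status(call_orthologs(hits), level = "species")
  expect_equal(unname(sp["nem1"]), "ORC6-negative")
  expect_equal(unname(sp["nem2"]), "unresolved")
  expect_equal(unname(sp["v1"]), "ORC6-positive")
})

test_that("sequence QC applies the X-residue and partial-sequence rules", {
  ins <- c(200L, 450L); nterm <- c(1L, 160L)
  h <- rbind(
    cbind(hit_row("ORC3", "x1", "SmallGroup", "XSEQ", 60, hasx = TRUE),
          covered_start = 1L, covered_end = 700L),
    cbind(hit_row("ORC3", "x2", "SmallGroup", "PART_OK", 60, partial = TRUE),
          covered_start = 100L, covered_end = 500L),
    cbind(hit_row("ORC3", "x3", "SmallGroup", "PART_BAD", 60, partial = TRUE),
          covered_start = 1L, covered_end = 300L),
    cbind(hit_row("MCM2", "x4", "SmallGroup", "MCM_BAD", 60, partial = TRUE),
          covered_start = 170L, covered_end = 900L),
    cbind(hit_row("MCM2", "x5", "SmallGroup", "MCM_OK", 60, partial = TRUE),
          covered_start = 1L, covered_end = 600L)
  )
  qc <- sequence_qc(h, insertion_domain = ins, mcm2_nterm = nterm)
  expect_false(qc$accepted[qc$accession == "XSEQ"])
  expect_match(qc$qc_reason[qc$accession == "XSEQ"], "X-residues")
  expect_true(qc$accepted[qc$accession == "PART_OK"])
  expect_false(qc$accepted[qc$accession == "PART_BAD"])
  expect_match(qc$qc_reason[qc$accession == "PART_BAD"], "insertion domain")
  expect_false(qc$accepted[qc$accession == "MCM_BAD"])
  expect_match(qc$qc_reason[qc$accession == "MCM_BAD"], "N-terminal")
  expect_true(qc$accepted[qc$accession == "MCM_OK"])
})

test_that("partial ORC3 sequences are only eligible in data-poor groups", {
  big <- do.call(rbind, lapply(sprintf("sp%02d", 1:12), function(s) {
    cbind(hit_row("ORC3", s, "BigGroup", paste0(s, "acc"), 60),
          covered_start = 1L, covered_end = 700L)
  }))
  big$is_partial[1] <- TRUE
  qc <- sequence_qc(big)
  expect_false(qc$accepted[1])
  expect_match(qc$qc_reason[1], "not data-limited")
  expect_true(all(qc$accepted[-1]))
})

test_that("representative selection maximizes diversity keys before repeats", {
  acc <- data.frame(
    species = sprintf("s%d", 1:5), taxon_group = "G",
    accession = sprintf("a%d", 1:5),
    order_label = c("O1", "O1", "O2", "O2", "O3"),
    stringsAsFactors = FALSE
  )
  sel <- select_representatives(acc, c(G = 3), "order_label")
  expect_equal(nrow(sel), 3L)
  expect_setequal(sel$order_label, c("O1", "O2", "O3"))
  # cap >= n is the identity
  expect_equal(nrow(select_representatives(acc, c(G = 10), "order_label")), 5L)
  # deterministic
  expect_identical(select_representatives(acc, c(G = 3), "order_label"),
                   select_representatives(acc[sample(5), ], c(G = 3), "order_label"))
})
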