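# Synthetic AlphaFold-style fixtures with exact ground truth. Geometry is
# placed by construction, not simulated: designated inter-chain residue
# pairs are brought within the contact cutoff, everything else is kept well
# outside it, so the true contact set of every model is known exactly.

# --- ideal backbone construction (NeRF internal-to-Cartesian) -------------

# place atom D given A-B-C, bond |CD|, angle B-C-D and dihedral A-B-C-D
place_atom <- function(a, b, c_, bond, angle_deg, dihedral_deg) {
  th <- angle_deg * pi / 180
  chi <- dihedral_deg * pi / 180
  d2 <- bond * c(-cos(th), sin(th) * cos(chi), -sin(th) * sin(chi))
  bc <- c_ - b
  bc <- bc / sqrt(sum(bc^2))
  n <- vcross(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- cbind(bc, vcross(n, bc), n)
  c_ + as.numeric(m %*% d2)
}

# build an N-CA-C backbone from per-residue (phi, psi); standard bond
# geometry, omega fixed trans. Measured dihedrals reproduce the inputs.
build_backbone <- function(phi, psi) {
  n_res <- length(phi)
  stopifnot(length(psi) == n_res, n_res >= 2L)
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329
  a_ncac <- 111.0; a_cacn <- 117.2; a_cnca <- 121.7
  xyz <- array(NA_real_, dim = c(n_res, 3L, 3L))  # residue x atom(N,CA,C) x coord
  xyz[1L, 1L, ] <- c(0, 0, 0)
  xyz[1L, 2L, ] <- c(b_nca, 0, 0)
  th <- (180 - a_ncac) * pi / 180
  xyz[1L, 3L, ] <- xyz[1L, 2L, ] + b_cac * c(cos(th), sin(th), 0)
  for (i in 2:n_res) {
    xyz[i, 1L, ] <- place_atom(xyz[i - 1L, 1L, ], xyz[i - 1L, 2L, ],
                               xyz[i - 1L, 3L, ], b_cn, a_cacn, psi[i - 1L])
    xyz[i, 2L, ] <- place_atom(xyz[i - 1L, 2L, ], xyz[i - 1L, 3L, ],
                               xyz[i, 1L, ], b_nca, a_cnca, 180)
    xyz[i, 3L, ] <- place_atom(xyz[i - 1L, 3L, ], xyz[i, 1L, ],
                               xyz[i, 2L, ], b_cac, a_ncac, phi[i])
  }
  atoms <- data.frame(
    resno = rep(seq_len(n_res), each = 3L),
    atom = rep(c("N", "CA", "C"), n_res),
    element = rep(c("N", "C", "C"), n_res),
    x = as.numeric(t(xyz[, , 1L])),
    y = as.numeric(t(xyz[, , 2L])),
    z = as.numeric(t(xyz[, , 3L])),
    stringsAsFactors = FALSE
  )
  atoms
}

random_rigid_motion <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  list(rotation = q, translation = runif(3, -20, 20))
}

apply_rigid <- function(atoms, motion) {
  x <- as.matrix(atoms[, c("x", "y", "z")]) %*% motion$rotation
  x <- sweep(x, 2, motion$translation, "+")
  atoms$x <- x[, 1L]; atoms$y <- x[, 2L]; atoms$z <- x[, 3L]
  atoms
}

# --- multimer fixtures ----------------------------------------------------

#' Specify a synthetic five-model multimer fixture
#'
#' Describes a two-chain complex with a designated "true interface": a set
#' of inter-chain residue pairs, of which a fraction `shared_fraction` is
#' placed in contact in all models and the remainder in exactly one model
#' each (assigned round-robin). Decoy pairs are placed in contact in every
#' model but carry pLDDT below 50, so confidence filtering must remove
#' them.
#'
#' @param chain_lengths lengths (residues) of the two chains.
#' @param interface_pairs two-column matrix (or data.frame) of residue pairs
#'   (chain A index, chain B index) designating the true interface.
#' @param shared_fraction fraction of interface pairs present in all models.
#' @param n_models number of models (default 5).
#' @param plddt_background pLDDT written for ordinary residues.
#' @param plddt_decoy_pairs pairs placed in contact whose chain-B residue
#'   gets `decoy_plddt` (< 50); same format as `interface_pairs`.
#' @param decoy_plddt pLDDT written for decoy residues (default 45).
#' @param pae_interface pAE (angstrom) written for pairs in contact.
#' @param pae_background pAE written for all other residue pairs.
#' @param iptm ipTM of the top-ranked model (lower ranks get 0.01 less each).
#' @param seed integer seed; per-model seeds are derived as `seed + rank`.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(chain_lengths = c(30L, 30L), interface_pairs,
                         shared_fraction = 1, n_models = 5L,
                         plddt_background = 90, plddt_decoy_pairs = NULL,
                         decoy_plddt = 45, pae_interface = 4,
                         pae_background = 10, iptm = 0.8, seed = 1L) {
  ip <- as.matrix(interface_pairs)
  if (ncol(ip) != 2L) stop("interface_pairs must have two columns")
  dp <- if (is.null(plddt_decoy_pairs)) matrix(integer(), ncol = 2L)
        else as.matrix(plddt_decoy_pairs)
  stopifnot(shared_fraction >= 0, shared_fraction <= 1,
            plddt_background >= 0, plddt_background <= 100)
  if (any(ip[, 1L] < 1 | ip[, 1L] > chain_lengths[1L]) ||
      any(ip[, 2L] < 1 | ip[, 2L] > chain_lengths[2L])) {
    stop("interface_pairs reference residues outside the chains")
  }
  if (nrow(dp) > 0L && length(intersect(dp[, 2L], ip[, 2L])) > 0L) {
    stop("decoy pairs must not reuse chain-B residues of interface pairs")
  }
  structure(list(chain_lengths = as.integer(chain_lengths),
                 interface_pairs = ip, shared_fraction = shared_fraction,
                 n_models = as.integer(n_models),
                 plddt_background = plddt_background,
                 plddt_decoy_pairs = dp, decoy_plddt = decoy_plddt,
                 pae_interface = pae_interface,
                 pae_background = pae_background,
                 iptm = iptm, seed = as.integer(seed)),
            class = "fixture_spec")
}

# which interface pairs are placed in model `rank` (1-based)
pairs_for_model <- function(spec, rank) {
  k <- nrow(spec$interface_pairs)
  if (k == 0L) return(spec$interface_pairs[0L, , drop = FALSE])
  n_shared <- round(spec$shared_fraction * k)
  idx <- seq_len(n_shared)
  singles <- setdiff(seq_len(k), idx)
  if (length(singles) > 0L) {
    owner <- ((seq_along(singles) - 1L) %% spec$n_models) + 1L
    idx <- c(idx, singles[owner == rank])
  }
  spec$interface_pairs[idx, , drop = FALSE]
}

place_model_atoms <- function(spec, placed_pairs) {
  la <- spec$chain_lengths[1L]; lb <- spec$chain_lengths[2L]
  dp <- spec$plddt_decoy_pairs
  all_placed <- rbind(placed_pairs, dp)
  if (anyDuplicated(all_placed[, 2L])) {
    dup <- all_placed[duplicated(all_placed[, 2L]), 2L][1L]
    sub <- all_placed[all_placed[, 2L] == dup, , drop = FALSE]
    if (length(unique(sub[, 1L])) > 1L) {
      stop("infeasible geometry: chain-B residue ", dup,
           " paired with multiple chain-A residues in one model")
    }
  }
  # residue spacing 10 A along x keeps every non-designated pair > 10 A
  # apart; placed chain-B residues sit 5 A above their chain-A partner
  res_atom <- function(chain, resno, cx, cy, plddt) {
    data.frame(chain = chain, resno = resno, resname = "ALA",
               atom = c("N", "CA", "C", "HA"),
               element = c("N", "C", "C", "H"),
               x = cx + c(-0.5, 0, 0.5, 0),
               y = cy + c(0, 0, 0, 0.4), z = 0, plddt = plddt,
               stringsAsFactors = FALSE)
  }
  decoy_b <- dp[, 2L]
  rows <- vector("list", la + lb)
  for (i in seq_len(la)) {
    rows[[i]] <- res_atom("A", i, 10 * i, 0, spec$plddt_background)
  }
  partner <- setNames(all_placed[, 1L], as.character(all_placed[, 2L]))
  for (j in seq_len(lb)) {
    pl <- if (j %in% decoy_b) spec$decoy_plddt else spec$plddt_background
    pj <- partner[as.character(j)]
    if (!is.na(pj)) {
      rows[[la + j]] <- res_atom("B", j, 10 * pj, 5, pl)
    } else {
      rows[[la + j]] <- res_atom("B", j, 10 * j, 40, pl)
    }
  }
  do.call(rbind, rows)
}

model_pae <- function(spec, placed_pairs) {
  la <- spec$chain_lengths[1L]; lb <- spec$chain_lengths[2L]
  n <- la + lb
  pae <- matrix(spec$pae_background, n, n)
  diag(pae) <- 0
  all_placed <- rbind(placed_pairs, spec$plddt_decoy_pairs)
  if (nrow(all_placed) > 0L) {
    ga <- all_placed[, 1L]; gb <- la + all_placed[, 2L]
    pae[cbind(ga, gb)] <- spec$pae_interface
    pae[cbind(gb, ga)] <- spec$pae_interface
  }
  pae
}

#' Generate a five-model multimer fixture
#'
#' Builds the models described by a [fixture_spec()]: for each model, the
#' set of residue pairs with any non-hydrogen inter-atomic distance under
#' 8 angstrom equals exactly the pairs the spec places in that model
#' (designated interface pairs plus decoy pairs). Each model is posed by an
#' independent random rigid motion so models differ in absolute
#' coordinates but not in contacts. Deterministic given `spec$seed`.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir optional directory; if given, each model is written as
#'   `model_<rank>.pdb` plus `model_<rank>_scores.json`.
#' @param target_id identifier for the complex.
#' @param chain_roles named role labels for chains A and B.
#' @return a `multimer_prediction`; ground truth is attached as attributes
#'   `"placed_pairs"` (per-model list) and `"spec"`.
#' @export
gen_multimer <- function(spec, out_dir = NULL, target_id = "target",
                         chain_roles = c(A = "ORC3", B = "ORC6")) {
  stopifnot(inherits(spec, "fixture_spec"))
  models <- vector("list", spec$n_models)
  placed_list <- vector("list", spec$n_models)
  for (rank in seq_len(spec$n_models)) {
    placed <- pairs_for_model(spec, rank)
    placed_list[[rank]] <- placed
    atoms <- place_model_atoms(spec, placed)
    atoms <- withr::with_seed(spec$seed + rank, {
      apply_rigid(atoms, random_rigid_motion())
    })
    model <- predicted_model(atoms, model_id = sprintf("%s_model_%d", target_id, rank))
    bundle <- confidence_bundle(model_pae(spec, placed),
                                ptm = round(min(1, spec$iptm + 0.05), 4),
                                iptm = round(max(0, spec$iptm - 0.01 * (rank - 1L)), 4))
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      pdb_path <- file.path(out_dir, sprintf("model_%d.pdb", rank))
      write_structure_pdb(model, pdb_path)
      write_confidence(bundle, file.path(out_dir, sprintf("model_%d_scores.json", rank)))
      model$source_path <- pdb_path
    }
    models[[rank]] <- list(model = model, confidence = bundle)
  }
  pred <- multimer_prediction(target_id, models, chain_roles, spec$n_models)
  attr(pred, "placed_pairs") <- placed_list
  attr(pred, "spec") <- spec
  pred
}

# --- monomer domain fixtures ----------------------------------------------

#' Generate a monomer structure with a controlled domain fold
#'
#' Emits an ideal-geometry single-chain model: `three_helix` contains three
#' ideal alpha-helices (phi = -57, psi = -47 degrees) joined by short
#' extended loops — the canonical ORC6-BD-like motif; `degenerate_missing_helix`
#' contains only two; `no_domain` is extended coil throughout. The whole
#' structure is posed by a seeded random rigid motion, which leaves the
#' backbone dihedrals exact.
#'
#' @param kind `"three_helix"`, `"degenerate_missing_helix"` or `"no_domain"`.
#' @param seed integer seed for the rigid pose.
#' @param helix_len residues per helix (default 12).
#' @param loop_len residues per inter-helix loop (default 4).
#' @param flank extended residues before/after the domain (default 3).
#' @param plddt per-residue pLDDT written on all residues.
#' @param seq_id identifier used for the model and its window.
#' @return list with `model` (a `predicted_model`), `window` (the
#'   [domain_range()] of the domain region; absent for `no_domain`),
#'   `kind`, and `true_n_helices`.
#' @export
gen_domain_structure <- function(kind = c("three_helix", "degenerate_missing_helix",
                                          "no_domain"),
                                 seed = 1L, helix_len = 12L, loop_len = 4L,
                                 flank = 3L, plddt = 90, seq_id = kind) {
  kind <- match.arg(kind)
  seq_id <- seq_id[1L]
  helix <- c(-57, -47); coil <- c(-140, 150)
  n_hel <- switch(kind, three_helix = 3L, degenerate_missing_helix = 2L,
                  no_domain = 0L)
  phi <- rep(coil[1L], flank); psi <- rep(coil[2L], flank)
  if (n_hel > 0L) {
    for (h in seq_len(n_hel)) {
      phi <- c(phi, rep(helix[1L], helix_len))
      psi <- c(psi, rep(helix[2L], helix_len))
      if (h < n_hel) {
        phi <- c(phi, rep(coil[1L], loop_len))
        psi <- c(psi, rep(coil[2L], loop_len))
      }
    }
  } else {
    phi <- c(phi, rep(coil[1L], 24L))
    psi <- c(psi, rep(coil[2L], 24L))
  }
  phi <- c(phi, rep(coil[1L], flank)); psi <- c(psi, rep(coil[2L], flank))
  n <- length(phi)
  atoms <- build_backbone(phi, psi)
  atoms <- withr::with_seed(as.integer(seed), apply_rigid(atoms, random_rigid_motion()))
  atoms$chain <- "A"
  atoms$resname <- "ALA"
  atoms$plddt <- plddt
  model <- predicted_model(atoms[, c("chain", "resno", "resname", "atom",
                                     "element", "x", "y", "z", "plddt")],
                           model_id = seq_id)
  window <- if (kind == "no_domain") {
    domain_range(seq_id, "ORC6_BD", NA, NA)
  } else {
    domain_range(seq_id, "ORC6_BD", flank + 1L, n - flank)
  }
  list(model = model, window = window, kind = kind, true_n_helices = n_hel)
}

# --- alignment fixtures ---------------------------------------------------

amino_acids <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Generate a toy alignment with a gapped-domain contrast
#'
#' Emits an ungapped reference row plus conserved and degenerate rows.
#' Conserved rows match the reference at >= 70% of the domain columns
#' (exactly 20% of domain positions are mutated); degenerate rows carry
#' gaps across 60% of the domain columns (a contiguous central block), so
#' their mapped domain range is shorter than the reference's. Deterministic
#' given `seed`.
#'
#' @param n_rows total non-reference rows.
#' @param seq_len ungapped sequence length (alignment width; no insertion
#'   columns are generated).
#' @param ref_domain integer pair: domain start/end on the reference.
#' @param degenerate_rows indices (1..n_rows) of rows made degenerate.
#' @param ref_id reference row identifier.
#' @param row_ids optional identifiers for the non-reference rows.
#' @param seed integer seed.
#' @return an `msa`; the reference window is attached as attribute
#'   `"ref_window"` and the degenerate ids as `"degenerate_ids"`.
#' @export
gen_alignment <- function(n_rows = 8L, seq_len = 60L, ref_domain = c(21L, 40L),
                          degenerate_rows = integer(), ref_id = "REF",
                          row_ids = sprintf("sp%02d", seq_len(n_rows)),
                          seed = 1L) {
  stopifnot(ref_domain[1L] >= 1L, ref_domain[2L] <= seq_len,
            all(degenerate_rows >= 1L), all(degenerate_rows <= n_rows))
  withr::with_seed(as.integer(seed), {
    ref <- sample(amino_acids, seq_len, replace = TRUE)
    dom <- seq.int(ref_domain[1L], ref_domain[2L])
    dom_len <- length(dom)
    gap_block <- dom[seq_len(floor(0.6 * dom_len)) +
                       floor((dom_len - floor(0.6 * dom_len)) / 2)]
    rows <- character(n_rows)
    for (i in seq_len(n_rows)) {
      s <- ref
      if (i %in% degenerate_rows) {
        s[gap_block] <- "-"
        # diverge the remaining domain residues too
        rest <- setdiff(dom, gap_block)
        s[rest] <- vapply(s[rest], function(a) sample(setdiff(amino_acids, a), 1L), "")
      } else {
        mut <- sample(dom, floor(0.2 * dom_len))
        s[mut] <- vapply(s[mut], function(a) sample(setdiff(amino_acids, a), 1L), "")
      }
      # background divergence outside the domain
      out <- setdiff(seq_len(seq_len), dom)
      mut_out <- sample(out, floor(0.3 * length(out)))
      s[mut_out] <- vapply(s[mut_out], function(a) sample(setdiff(amino_acids, a), 1L), "")
      rows[i] <- paste(s, collapse = "")
    }
    aln <- msa(c(ref_id, row_ids), c(paste(ref, collapse = ""), rows))
    attr(aln, "ref_window") <- domain_range(ref_id, "ORC6_BD",
                                            ref_domain[1L], ref_domain[2L])
    attr(aln, "degenerate_ids") <- row_ids[degenerate_rows]
    aln
  })
}

# --- hit-table fixtures ---------------------------------------------------

orc_subunits <- c("ORC1", "ORC2", "ORC3", "ORC4", "ORC5", "ORC6")

#' Generate a toy homology-search hit table
#'
#' True orthologs are drawn with percent identity in 55-90 and high query
#' coverage; false positives (misassigned subunits, CDC6-like homologs) get
#' identity 10-29, below any curation floor. Species listed without a
#' subunit receive no true-ortholog row for it (optionally a false-positive
#' row), so downstream presence calls have exact ground truth.
#'
#' @param subunits_present named list: species -> character vector of
#'   subunits truly present (subset of ORC1..ORC6, MCM2).
#' @param taxon_of named character: species -> taxon group label.
#' @param false_positive_rate probability a (species, subunit) cell gains a
#'   false-positive row.
#' @param seed integer seed.
#' @param path optional TSV output path.
#' @return data.frame in [read_hit_table()] layout.
#' @export
gen_hit_table <- function(subunits_present, taxon_of,
                          false_positive_rate = 0.3, seed = 1L, path = NULL) {
  all_subunits <- c(orc_subunits, "MCM2")
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (sp in names(subunits_present)) {
      for (su in all_subunits) {
        if (su %in% subunits_present[[sp]]) {
          rows[[length(rows) + 1L]] <- data.frame(
            query_subunit = su, species = sp, taxon_group = taxon_of[[sp]],
            accession = sprintf("ACC_%s_%s", sp, su),
            percent_identity = round(runif(1, 55, 90), 1),
            query_coverage = round(runif(1, 70, 100), 1),
            sequence_length = sample(300:1200, 1L),
            is_partial = FALSE, has_X_residues = FALSE,
            stringsAsFactors = FALSE
          )
        }
        if (runif(1) < false_positive_rate) {
          rows[[length(rows) + 1L]] <- data.frame(
            query_subunit = su, species = sp, taxon_group = taxon_of[[sp]],
            accession = sprintf("FP_%s_%s", sp, su),
            percent_identity = round(runif(1, 10, 29), 1),
            query_coverage = round(runif(1, 30, 90), 1),
            sequence_length = sample(300:1200, 1L),
            is_partial = FALSE, has_X_residues = FALSE,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    h <- do.call(rbind, rows)
    if (!is.null(path)) {
      write.table(h, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    h
  })
}
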