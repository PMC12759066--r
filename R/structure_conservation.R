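# Structural conservation classification from predicted monomer models:
# least-squares superposition, backbone-dihedral helix detection inside a
# mapped domain window, pLDDT aggregation, and the conserved/non-conserved
# calls for the ORC6-binding domain and the ORC3 tether.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle of four points
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (angstrom).
#' @return signed dihedral in degrees, IUPAC convention, in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Optimal proper rotation and translation superposing paired coordinates of
#' a mobile structure onto a fixed one, with the RMSD over the paired C-alpha
#' atoms after fitting. Used to compare predicted ortholog structures against
#' an experimentally determined reference.
#'
#' @param model_a fixed `predicted_model` (or an n x 3 coordinate matrix).
#' @param model_b mobile `predicted_model` (or an n x 3 coordinate matrix).
#' @param pairs optional data.frame `chain_a`, `res_a`, `chain_b`, `res_b`
#'   giving the residue pairing; by default residues are paired by identical
#'   (chain, residue index). Ignored for raw matrices, which are paired by
#'   row.
#' @return list with `rotation` (3 x 3), `translation` (length 3; the fitted
#'   mobile coordinates are `sweep(xb %*% rotation, 2, translation, "+")`),
#'   `rmsd` (angstrom) and `n` (residues paired).
#' @export
superpose <- function(model_a, model_b, pairs = NULL) {
  xa <- superpose_coords(model_a, pairs, side = "a")
  xb <- superpose_coords(model_b, pairs, side = "b")
  if (is.null(pairs) && inherits(model_a, "predicted_model") &&
      inherits(model_b, "predicted_model")) {
    common <- intersect(rownames(xa), rownames(xb))
    xa <- xa[common, , drop = FALSE]
    xb <- xb[common, , drop = FALSE]
  }
  if (nrow(xa) != nrow(xb)) stop("paired coordinate sets differ in size")
  if (nrow(xa) < 3L) stop("superposition needs at least 3 paired residues")
  ca <- colMeans(xa); cb <- colMeans(xb)
  ya <- sweep(xa, 2, ca); yb <- sweep(xb, 2, cb)
  s <- svd(crossprod(yb, ya))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- yb %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - ya)^2)))
  list(rotation = rot, translation = ca - as.numeric(cb %*% rot),
       rmsd = rmsd, n = nrow(xa))
}

superpose_coords <- function(m, pairs, side) {
  if (is.matrix(m)) return(m)
  stopifnot(inherits(m, "predicted_model"))
  a <- m$atoms[m$atoms$atom == "CA", , drop = FALSE]
  if (!is.null(pairs)) {
    idx <- match(paste(pairs[[paste0("chain_", side)]],
                       pairs[[paste0("res_", side)]]),
                 paste(a$chain, a$resno))
    if (any(is.na(idx))) stop("pairing references a residue without a CA atom")
    a <- a[idx, , drop = FALSE]
  }
  x <- as.matrix(a[, c("x", "y", "z")])
  rownames(x) <- paste(a$chain, a$resno)
  x
}

backbone_dihedrals <- function(model, chain) {
  a <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  res <- unique(a$resno)
  get <- function(resno, name) {
    r <- a[a$resno == resno & a$atom == name, c("x", "y", "z")]
    if (nrow(r) == 0L) return(NULL)
    as.numeric(r[1L, ])
  }
  phi <- psi <- rep(NA_real_, length(res))
  for (i in seq_along(res)) {
    n <- get(res[i], "N"); ca <- get(res[i], "CA"); cc <- get(res[i], "C")
    if (is.null(n) || is.null(ca) || is.null(cc)) next
    if (i > 1L) {
      cprev <- get(res[i - 1L], "C")
      if (!is.null(cprev)) phi[i] <- dihedral_angle(cprev, n, ca, cc)
    }
    if (i < length(res)) {
      nnext <- get(res[i + 1L], "N")
      if (!is.null(nnext)) psi[i] <- dihedral_angle(n, ca, cc, nnext)
    }
  }
  data.frame(resno = res, phi = phi, psi = psi)
}

#' Detect alpha-helical segments within a domain window
#'
#' Residues are classified helical by their backbone dihedrals
#' (phi in \[-100, -30\] degrees and psi in \[-80, -5\] degrees, the broad
#' alpha region of the Ramachandran plot); maximal helical runs of at least
#' `min_helix_len` residues are reported as segments. Terminal residues,
#' which lack phi or psi, are never helical.
#'
#' @param model a `predicted_model`.
#' @param window a [domain_range()] restricting detection, or `NULL` for the
#'   whole chain. An absent window yields no segments.
#' @param chain chain identifier (default: first chain of the model).
#' @param min_helix_len minimum segment length in residues (default 6).
#' @param phi_range,psi_range helical dihedral windows in degrees.
#' @return data.frame of segments: `chain_id`, `start`, `end`, `length`.
#' @export
detect_helices <- function(model, window = NULL, chain = NULL,
                           min_helix_len = 6L,
                           phi_range = c(-100, -30), psi_range = c(-80, -5)) {
  if (is.null(chain)) chain <- model_chains(model)[1L]
  empty <- data.frame(chain_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  if (!is.null(window) && domain_absent(window)) return(empty)
  dih <- backbone_dihedrals(model, chain)
  if (!is.null(window)) {
    dih <- dih[dih$resno >= window$start & dih$resno <= window$end, , drop = FALSE]
  }
  if (nrow(dih) == 0L) return(empty)
  helical <- !is.na(dih$phi) & !is.na(dih$psi) &
    dih$phi >= phi_range[1] & dih$phi <= phi_range[2] &
    dih$psi >= psi_range[1] & dih$psi <= psi_range[2]
  r <- rle(helical)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_helix_len
  if (!any(keep)) return(empty)
  data.frame(chain_id = chain,
             start = dih$resno[starts[keep]],
             end = dih$resno[ends[keep]],
             length = r$lengths[keep],
             stringsAsFactors = FALSE)
}

conservation_call <- function(seq_id, domain_name, status, n_helices,
                              mean_plddt_domain, mean_plddt_chain, evidence) {
  data.frame(seq_id = seq_id, domain_name = domain_name, status = status,
             n_helices = n_helices, mean_plddt_domain = mean_plddt_domain,
             mean_plddt_chain = mean_plddt_chain, evidence = evidence,
             stringsAsFactors = FALSE)
}

#' Classify ORC6-binding-domain conservation
#'
#' A conserved ORC6-BD contains all three alpha-helices of the canonical
#' motif and no large insertion; a domain missing one or more helices, or
#' expanded beyond the reference length by more than `insertion_tolerance`,
#' is non-conserved; a window with no residues is absent.
#'
#' @param model a `predicted_model`.
#' @param window mapped [domain_range()] of the domain on this sequence.
#' @param ref_length reference domain length in residues (default: the
#'   window's own length, i.e. no insertion test).
#' @param insertion_tolerance allowed fractional excess of window length over
#'   `ref_length` before the region counts as insertion-bearing (default 0.3).
#' @param expected_helices number of helices in the canonical motif (3).
#' @param min_helix_len passed to [detect_helices()].
#' @param chain chain identifier.
#' @return one-row data.frame (a conservation call): `seq_id`,
#'   `domain_name`, `status` in conserved/non_conserved/absent, `n_helices`,
#'   `mean_plddt_domain`, `mean_plddt_chain`, `evidence`.
#' @export
classify_orc6bd <- function(model, window, ref_length = NULL,
                            insertion_tolerance = 0.3, expected_helices = 3L,
                            min_helix_len = 6L, chain = NULL) {
  if (is.null(chain)) chain <- model_chains(model)[1L]
  pl_chain <- plddt_summary(model, chain = chain)
  if (domain_absent(window)) {
    return(conservation_call(window$seq_id, window$domain_name, "absent", 0L,
                             NA_real_, pl_chain$mean, "window absent"))
  }
  seg <- detect_helices(model, window, chain, min_helix_len)
  nh <- nrow(seg)
  pl_dom <- plddt_summary(model, window, chain)
  max_len <- if (is.null(ref_length)) Inf else ref_length * (1 + insertion_tolerance)
  if (nh == expected_helices && window$n_residues <= max_len) {
    status <- "conserved"
    ev <- sprintf("all %d helices present", expected_helices)
  } else if (nh != expected_helices) {
    status <- "non_conserved"
    ev <- sprintf("%d of %d helices detected", nh, expected_helices)
  } else {
    status <- "non_conserved"
    ev <- sprintf("insertion: window %d residues exceeds reference %d by > %.0f%%",
                  window$n_residues, ref_length, 100 * insertion_tolerance)
  }
  conservation_call(window$seq_id, window$domain_name, status, nh,
                    pl_dom$mean, pl_chain$mean, ev)
}

#' Classify ORC3-tether presence
#'
#' The tether is intrinsically flexible and often predicted at low pLDDT, so
#' presence requires only enough residues to form the loop-helix element —
#' a predicted helix is NOT required.
#'
#' @param model a `predicted_model`.
#' @param window mapped [domain_range()] of the tether region.
#' @param tether_min_len minimum residue count to form a loop-helix
#'   element (default 12).
#' @param chain chain identifier.
#' @return one-row conservation-call data.frame with `status` in
#'   conserved (tether present) / absent.
#' @export
classify_tether <- function(model, window, tether_min_len = 12L, chain = NULL) {
  if (is.null(chain)) chain <- model_chains(model)[1L]
  pl_chain <- plddt_summary(model, chain = chain)
  if (domain_absent(window)) {
    return(conservation_call(window$seq_id, window$domain_name, "absent", 0L,
                             NA_real_, pl_chain$mean, "window absent"))
  }
  seg <- detect_helices(model, window, chain)
  pl_dom <- plddt_summary(model, window, chain)
  if (window$n_residues >= tether_min_len) {
    conservation_call(window$seq_id, window$domain_name, "conserved", nrow(seg),
                      pl_dom$mean, pl_chain$mean,
                      sprintf("%d residues >= tether_min_len %d (helix not required)",
                              window$n_residues, tether_min_len))
  } else {
    conservation_call(window$seq_id, window$domain_name, "absent", nrow(seg),
                      pl_dom$mean, pl_chain$mean,
                      sprintf("only %d residues < tether_min_len %d",
                              window$n_residues, tether_min_len))
  }
}

#' Mean pLDDT over a selection
#'
#' @param model a `predicted_model`.
#' @param window optional [domain_range()] restricting to a residue window;
#'   `NULL` means the whole chain.
#' @param chain chain identifier (default: first chain).
#' @param reliable_cutoff pLDDT threshold for a reliable backbone
#'   prediction; the conventional value 70 is inclusive (`>=`).
#' @return list with `mean` (NA for an empty selection), `n`, and
#'   `reliable_backbone` (logical, NA when mean is undefined).
#' @export
plddt_summary <- function(model, window = NULL, chain = NULL,
                          reliable_cutoff = 70) {
  if (is.null(chain)) chain <- model_chains(model)[1L]
  rt <- residue_table(model)
  rt <- rt[rt$chain == chain, , drop = FALSE]
  if (!is.null(window)) {
    if (domain_absent(window)) {
      return(list(mean = NA_real_, n = 0L, reliable_backbone = NA))
    }
    rt <- rt[rt$resno >= window$start & rt$resno <= window$end, , drop = FALSE]
  }
  if (nrow(rt) == 0L) return(list(mean = NA_real_, n = 0L, reliable_backbone = NA))
  m <- mean(rt$plddt)
  list(mean = m, n = nrow(rt), reliable_backbone = m >= reliable_cutoff)
}
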