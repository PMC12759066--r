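# Independent oracles and fixture helpers shared across test files.

# Random two-chain toy structure: residues with 1-3 atoms each (some
# hydrogens), coordinates in a 30 A box so contacts are plentiful.
random_toy_model <- function(n_a, n_b, seed) {
  withr::with_seed(seed, {
    mk_chain <- function(chain, n) {
      rows <- lapply(seq_len(n), function(r) {
        k <- sample(1:3, 1)
        centre <- runif(3, 0, 30)
        names <- c("CA", "CB", "HB")[seq_len(k)]
        elem <- c("C", "C", "H")[seq_len(k)]
        data.frame(chain = chain, resno = r, resname = "ALA",
                   atom = names, element = elem,
                   x = centre[1] + runif(k, -1, 1),
                   y = centre[2] + runif(k, -1, 1),
                   z = centre[3] + runif(k, -1, 1),
                   plddt = round(runif(1, 40, 100), 2),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }
    predicted_model(rbind(mk_chain("A", n_a), mk_chain("B", n_b)),
                    model_id = sprintf("toy_%d", seed))
  })
}

# Brute-force contact oracle: per residue pair, minimum distance over all
# non-hydrogen atom pairs, strict < cutoff. Independent of the vectorised
# cross-distance route in detect_contacts.
brute_force_contacts <- function(model, chain_a, chain_b, cutoff = 8) {
  a <- model$atoms
  sub <- function(ch) {
    s <- a[a$chain == ch & toupper(a$element) != "H", , drop = FALSE]
    split(as.matrix(s[, c("x", "y", "z")]), s$resno)
  }
  A <- sub(chain_a); B <- sub(chain_b)
  out <- list()
  for (ra in names(A)) {
    xa <- matrix(A[[ra]], ncol = 3)
    for (rb in names(B)) {
      xb <- matrix(B[[rb]], ncol = 3)
      dmin <- Inf
      for (i in seq_len(nrow(xa))) {
        d <- sqrt(colSums((t(xb) - xa[i, ])^2))
        dmin <- min(dmin, d)
      }
      if (dmin < cutoff) {
        out[[length(out) + 1L]] <- data.frame(
          res_a = as.integer(ra), res_b = as.integer(rb),
          min_distance = dmin)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(res_a = integer(), res_b = integer(),
                      min_distance = numeric()))
  }
  df <- do.call(rbind, out)
  df[order(df$res_a, df$res_b), , drop = FALSE]
}

# Exact Mann-Whitney oracle: U by direct pairwise counting (not rank sums),
# two-tailed p by full enumeration of group assignments.
mw_exact_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  ucount <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  k <- min(n1, n2)
  small_first <- n1 <= n2
  u_obs <- if (small_first) ucount(x, y) else ucount(y, x)
  mu <- n1 * n2 / 2
  cmb <- utils::combn(n1 + n2, k)
  us <- apply(cmb, 2, function(ix) ucount(pooled[ix], pooled[-ix]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Random proper rotation + translation (axis-angle; independent of the
# QR-based generator inside the package).
random_rigid_oracle <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  list(rotation = R, translation = runif(3, -50, 50))
}

apply_rigid_to_model <- function(model, motion) {
  x <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(motion$rotation)
  x <- sweep(x, 2, motion$translation, "+")
  model$atoms$x <- x[, 1]; model$atoms$y <- x[, 2]; model$atoms$z <- x[, 3]
  model
}

# Percent-identity column-walk oracle: walks alignment columns explicitly,
# tracking reference residue numbers, independent of the vectorised
# implementation.
pct_id_oracle <- function(aln, ref_id, target_id, start, end) {
  r <- strsplit(aln$seqs[[ref_id]], "")[[1]]
  t <- strsplit(aln$seqs[[target_id]], "")[[1]]
  resno <- 0L; matches <- 0L; denom <- 0L
  for (col in seq_along(r)) {
    if (r[col] != "-") {
      resno <- resno + 1L
      if (resno >= start && resno <= end) {
        denom <- denom + 1L
        rc <- toupper(r[col]); tc <- toupper(t[col])
        if (tc != "-" && rc == tc && rc != "X") matches <- matches + 1L
      }
    }
  }
  if (denom == 0L) return(NA_real_)
  100 * matches / denom
}

# Tiny hand-buildable two-chain model from an atom list.
tiny_model <- function(...) {
  rows <- list(...)
  atoms <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chain = r$chain, resno = r$resno, resname = "GLY",
               atom = r$atom, element = r$element,
               x = r$xyz[1], y = r$xyz[2], z = r$xyz[3],
               plddt = if (is.null(r$plddt)) 90 else r$plddt,
               stringsAsFactors = FALSE)
  }))
  predicted_model(atoms, model_id = "tiny")
}
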