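# MSA-anchored domain mapping: project a reference-defined domain window
# (ORC6-binding domain, ORC3 tether, ...) onto every aligned sequence, and
# score percent identity to the reference over the window.

#' Define a per-sequence domain range
#'
#' Residue interval of a named domain in the ungapped coordinates of one
#' sequence. An absent domain is represented explicitly with
#' `n_residues = 0`.
#'
#' @param seq_id sequence identifier.
#' @param domain_name e.g. `"ORC6_BD"`, `"ORC3_tether"`, `"insertion_domain"`,
#'   `"MCM2_Nterm"`.
#' @param start,end 1-based inclusive residue indices, or `NA` for absent.
#' @return object of class `domain_range` with `n_residues = end - start + 1`
#'   (0 if absent).
#' @export
domain_range <- function(seq_id, domain_name, start, end) {
  if (is.na(start) || is.na(end)) {
    start <- NA_integer_; end <- NA_integer_; n <- 0L
  } else {
    start <- as.integer(start); end <- as.integer(end)
    if (start < 1L || end < start) stop("invalid domain range: ", start, "-", end)
    n <- end - start + 1L
  }
  structure(list(seq_id = seq_id, domain_name = domain_name,
                 start = start, end = end, n_residues = n),
            class = "domain_range")
}

#' Is a domain range absent?
#' @param domain a `domain_range`.
#' @return logical.
#' @export
domain_absent <- function(domain) domain$n_residues == 0L

aln_chars <- function(aln, id) {
  if (!id %in% aln$ids) stop("sequence '", id, "' not in alignment")
  strsplit(aln$seqs[[id]], "", fixed = TRUE)[[1L]]
}

# columns of the alignment holding the reference residues start..end
ref_residue_columns <- function(ref, start, end) {
  resno <- cumsum(ref != "-")
  which(ref != "-" & resno >= start & resno <= end)
}

#' Map a reference domain window onto a target sequence
#'
#' Reference residues are translated to alignment columns, and the mapped
#' target range spans the first to the last target residue falling within
#' that column span. Target insertions inside the span are included in
#' `n_residues` (a degenerate region with insertions is still one region).
#' If the target carries only gaps there, the domain is reported absent.
#'
#' @param aln an `msa`.
#' @param ref_id reference sequence identifier.
#' @param ref_range a [domain_range()] on the ungapped reference sequence.
#' @param target_id target sequence identifier.
#' @return a `domain_range` for the target.
#' @export
map_range <- function(aln, ref_id, ref_range, target_id) {
  ref <- aln_chars(aln, ref_id)
  tgt <- aln_chars(aln, target_id)
  ref_len <- sum(ref != "-")
  if (ref_range$end > ref_len) {
    stop("reference range ", ref_range$start, "-", ref_range$end,
         " exceeds ungapped reference length ", ref_len)
  }
  cols <- ref_residue_columns(ref, ref_range$start, ref_range$end)
  span <- seq.int(min(cols), max(cols))
  tgt_resno <- cumsum(tgt != "-")
  in_span <- span[tgt[span] != "-"]
  if (length(in_span) == 0L) {
    return(domain_range(target_id, ref_range$domain_name, NA, NA))
  }
  domain_range(target_id, ref_range$domain_name,
               tgt_resno[min(in_span)], tgt_resno[max(in_span)])
}

#' Percent identity to the reference over a domain window
#'
#' Number of positions where the target residue matches the reference
#' residue, divided by the number of reference (non-gap) positions within
#' the window — gaps in the reference are excluded from the denominator —
#' multiplied by 100. Comparison is case-insensitive; `X` (undetermined)
#' never matches; a target gap is a mismatch.
#'
#' @param aln an `msa`.
#' @param ref_id,target_id sequence identifiers.
#' @param window a [domain_range()] on the ungapped reference.
#' @return percent identity in `[0, 100]`, or `NA_real_` when the reference
#'   has no residues in the window.
#' @export
percent_identity <- function(aln, ref_id, target_id, window) {
  ref <- aln_chars(aln, ref_id)
  tgt <- aln_chars(aln, target_id)
  ref_len <- sum(ref != "-")
  if (window$end > ref_len) {
    stop("reference window ", window$start, "-", window$end,
         " exceeds ungapped reference length ", ref_len)
  }
  cols <- ref_residue_columns(ref, window$start, window$end)
  if (length(cols) == 0L) return(NA_real_)
  r <- toupper(ref[cols]); t <- toupper(tgt[cols])
  matches <- sum(r == t & r != "-" & t != "-" & r != "X" & t != "X")
  100 * matches / length(cols)
}

#' Map domains and identities for every sequence in an alignment
#'
#' @param aln an `msa`.
#' @param ref_id reference identifier.
#' @param windows named list of reference [domain_range()]s.
#' @return data.frame: `seq_id`, `domain`, `start`, `end`, `n_residues`,
#'   `pct_identity_to_ref`.
#' @export
map_all_domains <- function(aln, ref_id, windows) {
  rows <- list()
  for (w in windows) {
    for (id in aln$ids) {
      dr <- map_range(aln, ref_id, w, id)
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = id, domain = w$domain_name,
        start = dr$start, end = dr$end, n_residues = dr$n_residues,
        pct_identity_to_ref = percent_identity(aln, ref_id, id, w),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
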