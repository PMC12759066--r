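# Curation of homology-search hit tables into an ortholog presence/absence
# matrix: per-subunit identity floors against false positives (misassigned
# subunits, CDC6-like homologs), representative selection by query coverage,
# phylum-level inclusion, ORC6-loss calls, and sequence QC.

#' Default percent-identity floors per query subunit
#'
#' ORC subunits use a 30% floor (false-positive homologs such as CDC6
#' typically score under 30% while true orthologs score 55-65% or higher);
#' MCM2 orthologs are generally above 50%.
#' @return named numeric vector.
#' @export
default_identity_floors <- function() {
  c(ORC1 = 30, ORC2 = 30, ORC3 = 30, ORC4 = 30, ORC5 = 30, ORC6 = 30,
    MCM2 = 50)
}

floor_for <- function(subunit, identity_floor) {
  if (is.null(identity_floor)) identity_floor <- default_identity_floors()
  if (length(identity_floor) == 1L && is.null(names(identity_floor))) {
    return(identity_floor)
  }
  if (subunit %in% names(identity_floor)) return(identity_floor[[subunit]])
  if (".default" %in% names(identity_floor)) return(identity_floor[[".default"]])
  30
}

#' Call ortholog presence/absence from a hit table
#'
#' Hits below the per-subunit identity floor are discarded as false
#' positives. Among surviving hits of a (species, subunit) cell, the
#' representative is the hit with the highest query coverage (ties broken
#' by higher percent identity, then lexicographically smallest accession);
#' presence means at least one surviving hit.
#'
#' @param hits data.frame of hit records (see [read_hit_table()]).
#' @param identity_floor single number, or named numeric vector per subunit
#'   (optionally with a `.default` entry); `NULL` for
#'   [default_identity_floors()].
#' @return object of class `presence_matrix`: list with `presence` (logical
#'   species x subunit matrix), `representative` (accession matrix, `NA`
#'   where absent) and `taxon_of` (named character).
#' @export
call_orthologs <- function(hits, identity_floor = NULL) {
  subunits <- c(orc_subunits, "MCM2")
  species <- sort(unique(hits$species))
  presence <- matrix(FALSE, length(species), length(subunits),
                     dimnames = list(species, subunits))
  representative <- matrix(NA_character_, length(species), length(subunits),
                           dimnames = list(species, subunits))
  taxon_of <- character(0)
  if (nrow(hits) > 0L) {
    taxon_of <- setNames(hits$taxon_group[!duplicated(hits$species)],
                         hits$species[!duplicated(hits$species)])[species]
    names(taxon_of) <- species
    for (sp in species) for (su in subunits) {
      cand <- hits[hits$species == sp & hits$query_subunit == su &
                     hits$percent_identity >= floor_for(su, identity_floor), ,
                   drop = FALSE]
      if (nrow(cand) == 0L) next
      # highest query coverage wins; ties: higher identity, then smallest
      # accession, for determinism
      o <- order(-cand$query_coverage, -cand$percent_identity, cand$accession)
      presence[sp, su] <- TRUE
      representative[sp, su] <- cand$accession[o[1L]]
    }
  }
  structure(list(presence = presence, representative = representative,
                 taxon_of = taxon_of),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("presence_matrix: ", nrow(x$presence), " species x ",
      ncol(x$presence), " subunits\n", sep = "")
  print(x$presence)
  invisible(x)
}

#' Flatten a presence matrix to a result table
#' @param pm a `presence_matrix`.
#' @return data.frame with species, taxon_group, one present/absent column
#'   per subunit, and representative accessions.
#' @export
presence_table <- function(pm) {
  df <- data.frame(species = rownames(pm$presence),
                   taxon_group = unname(pm$taxon_of[rownames(pm$presence)]),
                   stringsAsFactors = FALSE)
  for (su in colnames(pm$presence)) {
    df[[su]] <- ifelse(pm$presence[, su], "present", "absent")
    df[[paste0(su, "_accession")]] <- pm$representative[, su]
  }
  df
}

#' Taxon-group inclusion rule
#'
#' A taxon group is excluded when orthologs for more than one ORC subunit
#' are entirely absent across all its species — i.e. at least two of
#' ORC1-ORC6 have no present call anywhere in the group. Groups missing
#' only ORC6 remain in the study (they are the ORC6-loss candidates).
#'
#' @param pm a `presence_matrix`.
#' @return character vector of excluded taxon groups.
#' @export
taxon_inclusion <- function(pm) {
  groups <- unique(unname(pm$taxon_of))
  excluded <- character(0)
  for (g in groups) {
    sp <- names(pm$taxon_of)[pm$taxon_of == g]
    absent_everywhere <- vapply(orc_subunits, function(su) {
      !any(pm$presence[sp, su])
    }, logical(1))
    if (sum(absent_everywhere) >= 2L) excluded <- c(excluded, g)
  }
  excluded
}

#' Classify ORC6 status per taxon group or species
#'
#' ORC6 loss is inferred when ORC1-ORC5 orthologs are reliably identified
#' but no ORC6 ortholog is: a group is ORC6-negative iff no species in the
#' group has ORC6 present while each of ORC1-ORC5 is present somewhere in
#' the group. Groups with ORC6 present anywhere are ORC6-positive; groups
#' where ORC1-5 are also incomplete are unresolved (loss cannot be
#' distinguished from missing data).
#'
#' @param pm a `presence_matrix`.
#' @param level `"group"` or `"species"`.
#' @return named character vector of `"ORC6-positive"`, `"ORC6-negative"` or
#'   `"unresolved"` calls.
#' @export
classify_orc6_status <- function(pm, level = c("group", "species")) {
  level <- match.arg(level)
  orc15 <- orc_subunits[1:5]
  if (level == "species") {
    out <- vapply(rownames(pm$presence), function(sp) {
      if (pm$presence[sp, "ORC6"]) "ORC6-positive"
      else if (all(pm$presence[sp, orc15])) "ORC6-negative"
      else "unresolved"
    }, character(1))
    return(out)
  }
  groups <- unique(unname(pm$taxon_of))
  out <- vapply(groups, function(g) {
    sp <- names(pm$taxon_of)[pm$taxon_of == g]
    if (any(pm$presence[sp, "ORC6"])) return("ORC6-positive")
    orc15_covered <- all(vapply(orc15, function(su) any(pm$presence[sp, su]),
                                logical(1)))
    if (orc15_covered) "ORC6-negative" else "unresolved"
  }, character(1))
  names(out) <- groups
  out
}

#' Sequence quality control for structure-prediction candidates
#'
#' Rejects candidate sequences that cannot support downstream structure
#' analysis: any sequence with undetermined "X" residues; partial ORC3
#' sequences truncated within the insertion domain (where the ORC6-BD and
#' the tether both reside) or from well-sampled groups; and partial MCM2
#' sequences missing the N-terminal domain that binds the ORC3 tether.
#' Partial sequences from data-poor groups (fewer than `partial_group_max`
#' species) that keep the critical domain intact are accepted.
#'
#' Coverage of a partial sequence is taken from optional `covered_start` /
#' `covered_end` columns (query coordinates); when missing, the sequence is
#' assumed to cover residues 1..`sequence_length`.
#'
#' @param candidates data.frame of hit records.
#' @param insertion_domain integer pair: insertion-domain range on the ORC3
#'   query.
#' @param mcm2_nterm integer pair: N-terminal interaction range on the MCM2
#'   query.
#' @param partial_group_max partial ORC3 sequences are only eligible in
#'   groups with fewer than this many species (default 10).
#' @return the input with logical `accepted` and character `qc_reason`
#'   columns appended.
#' @export
sequence_qc <- function(candidates, insertion_domain = c(200L, 450L),
                        mcm2_nterm = c(1L, 160L), partial_group_max = 10L) {
  h <- candidates
  if (is.null(h$covered_start)) h$covered_start <- 1L
  if (is.null(h$covered_end)) h$covered_end <- h$sequence_length
  group_n <- tapply(h$species, h$taxon_group, function(s) length(unique(s)))
  h$accepted <- TRUE
  h$qc_reason <- "ok"
  for (i in seq_len(nrow(h))) {
    if (isTRUE(h$has_X_residues[i])) {
      h$accepted[i] <- FALSE; h$qc_reason[i] <- "X-residues"; next
    }
    if (!isTRUE(h$is_partial[i])) next
    covers <- function(rng) h$covered_start[i] <= rng[1L] && h$covered_end[i] >= rng[2L]
    if (h$query_subunit[i] == "ORC3") {
      if (!covers(insertion_domain)) {
        h$accepted[i] <- FALSE
        h$qc_reason[i] <- "partial: truncation within insertion domain"
      } else if (group_n[[h$taxon_group[i]]] >= partial_group_max) {
        h$accepted[i] <- FALSE
        h$qc_reason[i] <- "partial: group not data-limited"
      } else {
        h$qc_reason[i] <- "partial accepted: insertion domain intact, data-limited group"
      }
    } else if (h$query_subunit[i] == "MCM2") {
      if (!covers(mcm2_nterm)) {
        h$accepted[i] <- FALSE
        h$qc_reason[i] <- "partial: MCM2 N-terminal domain missing"
      } else {
        h$qc_reason[i] <- "partial accepted: N-terminal domain intact"
      }
    }
  }
  h
}

#' Select representative sequences maximizing taxonomic diversity
#'
#' Greedy selection per taxon group: one member per distinct diversity key
#' (order/class label) is taken before any key contributes a second member,
#' until the group cap is reached. Deterministic: keys and members are
#' visited in sorted order (members by species name, then accession).
#'
#' @param accepted data.frame with at least `species`, `taxon_group`,
#'   `accession`, and the diversity-key column.
#' @param group_caps named integer vector: taxon group -> maximum n;
#'   unnamed single value applies to all groups; groups absent from the
#'   vector are uncapped.
#' @param diversity_key name of the column holding order/class labels.
#' @return the selected subset of `accepted`.
#' @export
select_representatives <- function(accepted, group_caps,
                                   diversity_key = "order_label") {
  if (!diversity_key %in% names(accepted)) {
    stop("diversity_key column '", diversity_key, "' not found")
  }
  out <- list()
  for (g in sort(unique(accepted$taxon_group))) {
    sub <- accepted[accepted$taxon_group == g, , drop = FALSE]
    sub <- sub[order(sub$species, sub$accession), , drop = FALSE]
    cap <- if (is.null(names(group_caps))) group_caps[1L]
           else if (g %in% names(group_caps)) group_caps[[g]]
           else nrow(sub)
    if (cap >= nrow(sub)) { out[[g]] <- sub; next }
    keys <- sub[[diversity_key]]
    picked <- logical(nrow(sub))
    round_ <- 0L
    while (sum(picked) < cap) {
      round_ <- round_ + 1L
      for (k in sort(unique(keys))) {
        if (sum(picked) >= cap) break
        idx <- which(keys == k & !picked)
        if (length(idx) >= 1L && sum(picked & keys == k) < round_) {
          picked[idx[1L]] <- TRUE
        }
      }
    }
    out[[g]] <- sub[picked, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
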