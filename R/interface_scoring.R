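# Confidence-filtered inter-chain contact scoring: the *average models*
# contact-consistency metric for five-model AlphaFold2 Multimer predictions,
# interface pAE, and the confident-interaction call.

#' Scoring configuration
#'
#' Defaults follow the standard confidence-analysis recipe for AlphaFold2
#' Multimer screens: residue pairs are potential contacts when any
#' non-hydrogen atom pair is closer than 8 angstrom; contacts touching a
#' residue with pLDDT below 50 or with a pairwise pAE above 15 angstrom are
#' excluded as very low confidence; a target is called a confident
#' interaction when the average-models score exceeds 0.5.
#'
#' @param contact_cutoff contact distance cutoff in angstrom (strict `<`).
#' @param plddt_min minimum per-residue pLDDT; contacts where either residue
#'   is below this are excluded (strict `<` excluded, i.e. `>=` kept).
#' @param pae_max maximum pairwise pAE in angstrom; pairs above this are
#'   excluded (strict `>` excluded, i.e. `<=` kept).
#' @param confidence_threshold average-models score above which (strict `>`)
#'   a prediction is called a confident interaction.
#' @param n_models number of models per target (AlphaFold2 Multimer emits 5).
#' @param pae_combine how to combine the two directions of the asymmetric
#'   pAE matrix for a residue pair: `"mean"` (default), `"max"` or `"min"`.
#' @return a list of class `score_config`.
#' @export
score_config <- function(contact_cutoff = 8, plddt_min = 50, pae_max = 15,
                         confidence_threshold = 0.5, n_models = 5L,
                         pae_combine = c("mean", "max", "min")) {
  pae_combine <- match.arg(pae_combine)
  stopifnot(contact_cutoff > 0, plddt_min > 0, pae_max > 0,
            confidence_threshold >= 0, confidence_threshold <= 1, n_models >= 1)
  structure(list(contact_cutoff = contact_cutoff, plddt_min = plddt_min,
                 pae_max = pae_max, confidence_threshold = confidence_threshold,
                 n_models = as.integer(n_models), pae_combine = pae_combine),
            class = "score_config")
}

empty_contacts <- function() {
  data.frame(chain_a = character(), res_a = integer(),
             chain_b = character(), res_b = integer(),
             min_distance = numeric(), stringsAsFactors = FALSE)
}

contact_key <- function(contacts) {
  if (nrow(contacts) == 0L) return(character())
  paste(contacts$chain_a, contacts$res_a, contacts$chain_b, contacts$res_b,
        sep = ":")
}

#' Detect inter-chain residue contacts
#'
#' A residue pair across the two chains is a contact iff any pair of
#' non-hydrogen atoms is strictly closer than `cfg$contact_cutoff`
#' (8 angstrom by default). Atom-level hits are deduplicated to one record
#' per residue pair, carrying the minimal inter-atomic distance.
#'
#' @param model a `predicted_model`.
#' @param chain_a,chain_b chain identifiers of the two chains.
#' @param cfg a [score_config()].
#' @return data.frame of contacts: `chain_a`, `res_a`, `chain_b`, `res_b`,
#'   `min_distance`.
#' @export
detect_contacts <- function(model, chain_a, chain_b, cfg = score_config()) {
  a <- model$atoms
  for (ch in c(chain_a, chain_b)) {
    if (!ch %in% a$chain) stop("unknown chain: ", ch)
  }
  if (chain_a == chain_b) stop("contact chains must differ")
  aa <- a[a$chain == chain_a & toupper(a$element) != "H", , drop = FALSE]
  ab <- a[a$chain == chain_b & toupper(a$element) != "H", , drop = FALSE]
  if (nrow(aa) == 0L || nrow(ab) == 0L) return(empty_contacts())
  xa <- as.matrix(aa[, c("x", "y", "z")])
  xb <- as.matrix(ab[, c("x", "y", "z")])
  # squared cross-distance matrix, atoms of chain_a x atoms of chain_b
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  hit <- which(d2 < cfg$contact_cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty_contacts())
  pair <- paste(aa$resno[hit[, 1L]], ab$resno[hit[, 2L]], sep = "_")
  mind <- tapply(sqrt(d2[hit]), pair, min)
  ij <- do.call(rbind, strsplit(names(mind), "_", fixed = TRUE))
  out <- data.frame(
    chain_a = chain_a, res_a = as.integer(ij[, 1L]),
    chain_b = chain_b, res_b = as.integer(ij[, 2L]),
    min_distance = as.numeric(mind), stringsAsFactors = FALSE
  )
  out <- out[order(out$res_a, out$res_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

combine_pae <- function(pae_ab, pae_ba, how) {
  switch(how,
         mean = (pae_ab + pae_ba) / 2,
         max = pmax(pae_ab, pae_ba),
         min = pmin(pae_ab, pae_ba))
}

#' Filter contacts by model confidence
#'
#' Annotates each contact with the pLDDT of its two residues and the two
#' directional pAE values, then drops very low-confidence contacts: any
#' contact involving a residue with pLDDT below `cfg$plddt_min`, and any
#' residue pair whose combined pAE (per `cfg$pae_combine`) exceeds
#' `cfg$pae_max`. Order-independent.
#'
#' @param contacts contact table from [detect_contacts()].
#' @param model the `predicted_model` the contacts came from.
#' @param confidence the model's `confidence_bundle`.
#' @param cfg a [score_config()].
#' @return the surviving contacts, annotated with `plddt_a`, `plddt_b`,
#'   `min_plddt`, `pae_ab`, `pae_ba`, `pae`.
#' @export
filter_contacts <- function(contacts, model, confidence, cfg = score_config()) {
  rt <- residue_table(model)
  if (nrow(rt) != nrow(confidence$pae)) {
    stop("pAE dimension mismatch: expected ", nrow(rt), " residues, found ",
         nrow(confidence$pae))
  }
  ann <- annotate_contacts(contacts, rt, confidence, cfg)
  keep <- ann$min_plddt >= cfg$plddt_min & ann$pae <= cfg$pae_max
  out <- ann[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

annotate_contacts <- function(contacts, rt, confidence, cfg) {
  ann <- contacts
  if (nrow(contacts) == 0L) {
    ann$plddt_a <- ann$plddt_b <- ann$min_plddt <- numeric(0)
    ann$pae_ab <- ann$pae_ba <- ann$pae <- numeric(0)
    return(ann)
  }
  gi_a <- rt$global_index[match(paste(contacts$chain_a, contacts$res_a),
                                paste(rt$chain, rt$resno))]
  gi_b <- rt$global_index[match(paste(contacts$chain_b, contacts$res_b),
                                paste(rt$chain, rt$resno))]
  if (any(is.na(gi_a)) || any(is.na(gi_b))) {
    stop("contact references a residue absent from the model")
  }
  ann$plddt_a <- rt$plddt[gi_a]
  ann$plddt_b <- rt$plddt[gi_b]
  ann$min_plddt <- pmin(ann$plddt_a, ann$plddt_b)
  ann$pae_ab <- confidence$pae[cbind(gi_a, gi_b)]
  ann$pae_ba <- confidence$pae[cbind(gi_b, gi_a)]
  ann$pae <- combine_pae(ann$pae_ab, ann$pae_ba, cfg$pae_combine)
  ann
}

#' Restrict contacts to a canonical interface window
#'
#' Keeps only contacts whose residue on the designated chain lies inside the
#' domain window (e.g. the ORC6-binding domain of ORC3, or the ORC3 tether),
#' excluding predicted non-canonical interactions. An absent domain yields
#' an empty set.
#'
#' @param contacts contact table.
#' @param domain a [domain_range()] on the designated chain's sequence.
#' @param chain chain identifier carrying the domain; by default the
#'   contacts' `chain_a`.
#' @return the restricted contact table.
#' @export
restrict_canonical <- function(contacts, domain, chain = NULL) {
  if (domain_absent(domain)) return(contacts[0L, , drop = FALSE])
  if (is.null(chain)) chain <- contacts$chain_a[1L]
  if (nrow(contacts) == 0L) return(contacts)
  res_on_chain <- ifelse(contacts$chain_a == chain, contacts$res_a,
                         ifelse(contacts$chain_b == chain, contacts$res_b, NA))
  keep <- !is.na(res_on_chain) &
    res_on_chain >= domain$start & res_on_chain <= domain$end
  out <- contacts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average-models contact-consistency score
#'
#' The proportion of identified contacts shared across the models of one
#' target, normalized to 1: over the union U of contacts across the
#' `n_models` filtered sets, the mean per-contact model count divided by
#' `n_models`. A score of 1 means all models agree on the same non-empty
#' interface; 0 means no contacts survived in any model. When U is
#' non-empty the score lies in `[1/n_models, 1]`.
#'
#' @param contact_sets list of exactly `cfg$n_models` contact tables (the
#'   filtered, canonically restricted set of each model).
#' @param cfg a [score_config()].
#' @return numeric score in `[0, 1]`.
#' @export
average_models <- function(contact_sets, cfg = score_config()) {
  if (length(contact_sets) != cfg$n_models) {
    stop("expected ", cfg$n_models, " contact sets, got ", length(contact_sets))
  }
  keys <- lapply(contact_sets, function(s) unique(contact_key(s)))
  all_keys <- unlist(keys, use.names = FALSE)
  if (length(all_keys) == 0L) return(0)
  counts <- table(all_keys)  # m(c): number of models containing contact c
  mean(counts) / cfg$n_models
}

#' Average interface pAE
#'
#' Mean combined pAE over the retained canonical contacts of all models.
#' By default contact instances are pooled across models (a pair contributes
#' once per model containing it); `pool = "union"` averages each unique pair
#' once. When no interface is formed the value is undefined (`NA`).
#'
#' @param contact_sets list of filtered, restricted contact tables (with the
#'   `pae` column from [filter_contacts()]).
#' @param cfg a [score_config()].
#' @param pool `"instances"` (default) or `"union"`.
#' @return mean pAE in angstrom, or `NA_real_` if there are no contacts.
#' @export
interface_pae <- function(contact_sets, cfg = score_config(),
                          pool = c("instances", "union")) {
  pool <- match.arg(pool)
  all <- do.call(rbind, contact_sets)
  if (is.null(all) || nrow(all) == 0L) return(NA_real_)
  if (pool == "union") {
    all <- all[!duplicated(contact_key(all)), , drop = FALSE]
  }
  mean(all$pae)
}

#' Score one multimer target end to end
#'
#' Composes the full chain for a five-model prediction: contact detection
#' (non-hydrogen atoms under the cutoff) in each model, confidence filtering
#' (pLDDT and pAE), restriction to the canonical interface window, then the
#' average-models score and interface pAE. `confident` applies the strict
#' `> confidence_threshold` rule; `canonical` records whether any canonical
#' contact survived in any model; `iptm_best` is the top-ranked model's ipTM.
#'
#' @param prediction a [multimer_prediction()].
#' @param domain a [domain_range()] defining the canonical interface window
#'   on the designated chain, or `NULL` to score without canonical
#'   restriction.
#' @param cfg a [score_config()].
#' @param domain_chain chain id carrying the domain; default: the chain whose
#'   role matches `attr(domain, "role")` if set, else the first chain.
#' @return list of class `interface_score`: `target_id`, `average_models`,
#'   `n_contacts_per_model`, `n_union_contacts`, `interface_pae`,
#'   `iptm_best`, `confident`, `canonical`, `config`, plus the per-model
#'   restricted contact tables in `contact_sets`.
#' @export
score_target <- function(prediction, domain = NULL, cfg = score_config(),
                         domain_chain = NULL) {
  stopifnot(inherits(prediction, "multimer_prediction"))
  chains <- names(prediction$chain_roles)
  if (is.null(domain_chain)) domain_chain <- chains[1L]
  sets <- lapply(prediction$models, function(m) {
    raw <- detect_contacts(m$model, chains[1L], chains[2L], cfg)
    filt <- filter_contacts(raw, m$model, m$confidence, cfg)
    if (!is.null(domain)) filt <- restrict_canonical(filt, domain, domain_chain)
    filt
  })
  score <- average_models(sets, cfg)
  union_keys <- unique(unlist(lapply(sets, contact_key), use.names = FALSE))
  iptm1 <- prediction$models[[1L]]$confidence$iptm
  structure(list(
    target_id = prediction$target_id,
    average_models = score,
    n_contacts_per_model = vapply(sets, nrow, integer(1)),
    n_union_contacts = length(union_keys),
    interface_pae = interface_pae(sets, cfg),
    iptm_best = if (is.null(iptm1)) NA_real_ else iptm1,
    confident = score > cfg$confidence_threshold,
    canonical = length(union_keys) > 0L,
    config = cfg,
    contact_sets = sets
  ), class = "interface_score")
}

#' @export
print.interface_score <- function(x, ...) {
  cat("interface_score '", x$target_id, "': average_models = ",
      format(x$average_models, digits = 4),
      if (x$confident) " (confident)" else " (not confident)",
      ", union contacts = ", x$n_union_contacts,
      ", interface pAE = ",
      if (is.na(x$interface_pae)) "n.d." else format(x$interface_pae, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Flatten interface scores to a result table
#' @param scores list of `interface_score` objects.
#' @return data.frame, one row per target.
#' @export
scores_table <- function(scores) {
  do.call(rbind, lapply(scores, function(s) {
    data.frame(
      target_id = s$target_id, average_models = s$average_models,
      confident = s$confident, canonical = s$canonical,
      n_contacts = paste(s$n_contacts_per_model, collapse = ","),
      n_union_contacts = s$n_union_contacts,
      interface_pae = s$interface_pae, iptm = s$iptm_best,
      stringsAsFactors = FALSE
    )
  }))
}
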