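# End-to-end orchestration: fixtures -> presence -> domains -> conservation
# -> interface scoring -> summary, as one reproducible, seeded run that
# writes stage TSVs and a manifest.

#' Configuration for a demonstration cohort run
#'
#' Defines a 12-species synthetic cohort spanning four taxon groups with
#' known ground truth. ORC6-positive species carry a canonical three-helix
#' ORC6-binding domain and a multimer fixture whose interface contacts are
#' shared by all five models (average-models score 1); ORC6-negative
#' species carry a degenerate or absent domain and either model-unique
#' ("disjoint", score 0.2) or pLDDT-decoy-only ("decoy", score 0)
#' interfaces. One Mollusca species is ORC6-positive with a degenerate
#' domain, so group percentages are not all 0 or 100.
#'
#' @param out_dir run directory (created if needed).
#' @param seed integer master seed; stage and fixture seeds derive from it.
#' @param cfg a [score_config()].
#' @return list of class `run_config`.
#' @export
demo_cohort_config <- function(out_dir, seed = 1L, cfg = score_config()) {
  species <- data.frame(
    species = c("vert_sp1", "vert_sp2", "vert_sp3",
                "moll_sp1", "moll_sp2", "moll_sp3",
                "nema_sp1", "nema_sp2", "nema_sp3",
                "tard_sp1", "tard_sp2", "tard_sp3"),
    taxon_group = rep(c("Vertebrata", "Mollusca", "Nematoda", "Tardigrada"),
                      each = 3L),
    orc6_truth = rep(c(TRUE, TRUE, FALSE, FALSE), each = 3L),
    bd_kind = c(rep("three_helix", 3L),
                "three_helix", "three_helix", "degenerate_missing_helix",
                rep("no_domain", 3L),
                rep("degenerate_missing_helix", 3L)),
    multimer_preset = c(rep("shared", 3L),
                        "shared", "shared", "disjoint",
                        rep("decoy", 3L),
                        rep("disjoint", 3L)),
    stringsAsFactors = FALSE
  )
  structure(list(out_dir = out_dir, seed = as.integer(seed), cfg = cfg,
                 species = species,
                 tether_min_len = 12L, insertion_tolerance = 0.3,
                 identity_floor = NULL),
            class = "run_config")
}

preset_fixture_spec <- function(preset, seed) {
  pairs <- cbind(5:10, 5:10)  # 6 designated interface pairs
  switch(preset,
    shared = fixture_spec(interface_pairs = pairs, shared_fraction = 1,
                          iptm = 0.8, seed = seed),
    disjoint = fixture_spec(interface_pairs = pairs[1:5, ], shared_fraction = 0,
                            iptm = 0.35, seed = seed),
    decoy = fixture_spec(interface_pairs = pairs[0, , drop = FALSE],
                         plddt_decoy_pairs = cbind(12:14, 12:14),
                         iptm = 0.2, seed = seed),
    stop("unknown multimer preset: ", preset))
}

#' Run the pipeline end to end
#'
#' Stages run in dependency order; every stage writes a TSV under
#' `cfg$out_dir` with its thresholds echoed in the header, and a
#' `manifest.json` records the seed, configuration, per-stage row counts
#' and file checksums. Re-running with identical configuration and seed
#' reproduces byte-identical TSVs.
#'
#' @param config a `run_config` (see [demo_cohort_config()]).
#' @return invisibly, a list with the stage tables and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (is.null(out) || is.na(out) || out == "") stop("no output directory configured")
  parent <- dirname(normalizePath(out, mustWork = FALSE))
  if (!dir.exists(parent)) stop("no such path: ", parent)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sp <- config$species
  cfg <- config$cfg
  seed <- config$seed
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # stage 1: fixtures ------------------------------------------------------
  fixtures <- run_stage("fixtures", {
    subunits_present <- lapply(seq_len(nrow(sp)), function(i) {
      if (sp$orc6_truth[i]) c(orc_subunits, "MCM2")
      else c(orc_subunits[1:5], "MCM2")
    })
    names(subunits_present) <- sp$species
    taxon_of <- setNames(sp$taxon_group, sp$species)
    hits_path <- file.path(out, "hits.tsv")
    gen_hit_table(subunits_present, taxon_of, false_positive_rate = 0.3,
                  seed = seed, path = hits_path)
    degenerate <- which(sp$bd_kind != "three_helix")
    aln <- gen_alignment(n_rows = nrow(sp), seq_len = 80,
                         ref_domain = c(21L, 50L),
                         degenerate_rows = degenerate,
                         row_ids = sp$species, seed = seed + 100L)
    aln_path <- file.path(out, "orc3.aln.fasta")
    write_alignment(aln, aln_path)
    monomers <- lapply(seq_len(nrow(sp)), function(i) {
      gen_domain_structure(sp$bd_kind[i], seed = seed + 200L + i,
                           seq_id = sp$species[i])
    })
    names(monomers) <- sp$species
    multimers <- lapply(seq_len(nrow(sp)), function(i) {
      spec <- preset_fixture_spec(sp$multimer_preset[i], seed + 300L + 10L * i)
      gen_multimer(spec, out_dir = file.path(out, "multimer", sp$species[i]),
                   target_id = sp$species[i])
    })
    names(multimers) <- sp$species
    list(hits_path = hits_path, aln = aln, aln_path = aln_path,
         monomers = monomers, multimers = multimers)
  })

  # stage 2: ortholog presence --------------------------------------------
  presence <- run_stage("presence", {
    hits <- read_hit_table(fixtures$hits_path)
    pm <- call_orthologs(hits, config$identity_floor)
    status <- classify_orc6_status(pm, level = "group")
    tbl <- presence_table(pm)
    tbl$orc6_status <- status[tbl$taxon_group]
    write_result_table(tbl, file.path(out, "presence.tsv"),
                       meta = list(identity_floor_ORC = 30,
                                   identity_floor_MCM2 = 50, seed = seed))
    list(pm = pm, status = status, table = tbl)
  })

  # stage 3: domain mapping -----------------------------------------------
  domains <- run_stage("domains", {
    aln <- fixtures$aln
    w <- attr(aln, "ref_window")
    dom <- map_all_domains(aln, "REF", list(w))
    dom <- dom[dom$seq_id != "REF", , drop = FALSE]
    write_result_table(dom, file.path(out, "domains.tsv"),
                       meta = list(reference = "REF",
                                   window = paste0(w$start, "-", w$end),
                                   seed = seed))
    dom
  })

  # stage 4: conservation calls -------------------------------------------
  conservation <- run_stage("conserve", {
    ref_len <- gen_domain_structure("three_helix", seed = 1L)$window$n_residues
    calls <- do.call(rbind, lapply(sp$species, function(s) {
      fx <- fixtures$monomers[[s]]
      classify_orc6bd(fx$model, fx$window, ref_length = ref_len,
                      insertion_tolerance = config$insertion_tolerance)
    }))
    write_result_table(calls, file.path(out, "conservation.tsv"),
                       meta = list(min_helix_len = 6,
                                   insertion_tolerance = config$insertion_tolerance,
                                   plddt_reliable = 70, seed = seed))
    calls
  })

  # stage 5: interface scoring --------------------------------------------
  scoring <- run_stage("score", {
    scores <- lapply(sp$species, function(s) {
      fx <- fixtures$multimers[[s]]
      la <- attr(fx, "spec")$chain_lengths[1L]
      bd_absent <- sp$bd_kind[sp$species == s] == "no_domain"
      dom <- if (bd_absent) domain_range(s, "ORC6_BD", NA, NA)
             else domain_range(s, "ORC6_BD", 1L, la)
      score_target(fx, domain = dom, cfg = cfg, domain_chain = "A")
    })
    tbl <- scores_table(scores)
    write_result_table(tbl, file.path(out, "scores.tsv"),
                       meta = list(contact_cutoff = cfg$contact_cutoff,
                                   plddt_min = cfg$plddt_min,
                                   pae_max = cfg$pae_max,
                                   confidence_threshold = cfg$confidence_threshold,
                                   pae_combine = cfg$pae_combine, seed = seed))
    list(scores = scores, table = tbl)
  })

  # stage 6: summary -------------------------------------------------------
  summary <- run_stage("summarize", {
    taxon_of <- setNames(sp$taxon_group, sp$species)
    status_of <- setNames(ifelse(sp$orc6_truth, "ORC6_positive", "ORC6_negative"),
                          sp$species)
    sc <- scoring$table
    med <- group_medians(sc$average_models, status_of[sc$target_id])
    mw <- mann_whitney(sc$average_models[status_of[sc$target_id] == "ORC6_positive"],
                       sc$average_models[status_of[sc$target_id] == "ORC6_negative"])
    tests <- data.frame(metric = "average_models",
                        group_a = "ORC6_positive", group_b = "ORC6_negative",
                        n_a = med$n[med$group == "ORC6_positive"],
                        n_b = med$n[med$group == "ORC6_negative"],
                        median_a = med$median[med$group == "ORC6_positive"],
                        median_b = med$median[med$group == "ORC6_negative"],
                        U = mw$U, p = sprintf("%.4f", mw$p.value),
                        method = mw$method, stringsAsFactors = FALSE)
    cons <- setNames(conservation$status, conservation$seq_id)
    hm_cons <- taxon_heatmap(cons, taxon_of)
    inter <- setNames(ifelse(sc$confident, "interaction", "no_interaction"),
                      sc$target_id)
    hm_int <- taxon_heatmap(inter, taxon_of)
    report <- classification_report(sc$confident,
                                    sp$multimer_preset[match(sc$target_id, sp$species)] == "shared")
    write_result_table(tests, file.path(out, "summary_tests.tsv"),
                       meta = list(seed = seed))
    write_result_table(hm_cons, file.path(out, "heatmap_conservation.tsv"),
                       meta = list(seed = seed))
    write_result_table(hm_int, file.path(out, "heatmap_interaction.tsv"),
                       meta = list(seed = seed))
    list(tests = tests, heatmap_conservation = hm_cons,
         heatmap_interaction = hm_int, report = report)
  })

  # manifest ----------------------------------------------------------------
  tsvs <- sort(list.files(out, pattern = "\\.tsv$", full.names = TRUE))
  manifest <- list(
    seed = seed,
    config = list(contact_cutoff = cfg$contact_cutoff, plddt_min = cfg$plddt_min,
                  pae_max = cfg$pae_max,
                  confidence_threshold = cfg$confidence_threshold,
                  n_models = cfg$n_models, pae_combine = cfg$pae_combine,
                  tether_min_len = config$tether_min_len,
                  insertion_tolerance = config$insertion_tolerance),
    n_species = nrow(sp),
    stage_rows = list(presence = nrow(presence$table),
                      domains = nrow(domains),
                      conservation = nrow(conservation),
                      scores = nrow(scoring$table),
                      summary_tests = nrow(summary$tests)),
    files = as.list(setNames(unname(md5sum(tsvs)), basename(tsvs)))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fixtures = fixtures, presence = presence, domains = domains,
                 conservation = conservation, scoring = scoring,
                 summary = summary, manifest = manifest))
}
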