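write_manifest <- function(path, command, params) {
  manifest <- list(command = command,
                   package = "sitematch",
                   version = as.character(utils::packageVersion("sitematch")),
                   params = params)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Build a resolved catalog from tabular inputs
#'
#' Parses a catalog TSV, resolves centroids against the parent structures
#' (one PDB per parent id, `<parents_dir>/<pdbid>.pdb`, where the parent id
#' is the `site_id` up to the first `-`), splits multichain/multi-site
#' entries, and derives per-template substitution matrices from the
#' homolog table. Per-site failures (e.g. a missing cofactor rule) are
#' collected in a report instead of aborting the batch.
#'
#' @param catalog_tsv Path to the catalog TSV.
#' @param parents_dir Directory of parent structure PDB files.
#' @param homologs_tsv Optional path to the homolog TSV.
#' @param rules Centroid rules tibble.
#' @param ions Ion identity vector.
#' @param split Split multimeric/multi-site entries (default `TRUE`).
#' @return List: `catalog` (tibble `site_id`, `family_id`, `ec`,
#'   `n_residues`, `searchable`, `template`, `subs`), `report` (tibble
#'   `site_id`, `status`, `message`).
#' @export
build_catalog <- function(catalog_tsv, parents_dir, homologs_tsv = NULL,
                          rules = centroid_rules(), ions = default_ions(),
                          split = TRUE) {
  parsed <- parse_site_table(catalog_tsv, rules = rules, ions = ions)
  homologs <- if (!is.null(homologs_tsv)) parse_homolog_table(homologs_tsv)
  rows <- list()
  report <- list()
  structures <- list()
  for (i in seq_len(nrow(parsed))) {
    sid <- parsed$site_id[i]
    parent_id <- sub("-.*$", "", sid)
    out <- tryCatch({
      if (is.null(structures[[parent_id]])) {
        structures[[parent_id]] <-
          load_structure(file.path(parents_dir, paste0(parent_id, ".pdb")))
      }
      tpl <- resolve_centroids(parsed$template[[i]],
                               structures[[parent_id]], rules = rules)
      pieces <- if (split) split_multimeric(tpl) else list(tpl)
      purrr::map(pieces, function(p) {
        subs <- build_substitution_matrix(p, homologs, ions = ions)
        tibble::tibble(site_id = p$site_id, family_id = parent_id,
                       ec = p$ec, n_residues = p$n,
                       searchable = p$searchable,
                       template = list(p), subs = list(subs))
      })
    }, error = function(e) e)
    if (inherits(out, "error")) {
      report[[length(report) + 1]] <-
        tibble::tibble(site_id = sid, status = "error",
                       message = conditionMessage(out))
    } else {
      rows <- c(rows, out)
      report[[length(report) + 1]] <-
        tibble::tibble(site_id = sid, status = "ok", message = "")
    }
  }
  list(catalog = dplyr::bind_rows(rows), report = dplyr::bind_rows(report))
}

#' Search one target against a resolved catalog
#'
#' For every searchable catalog template: builds the candidate pool under
#' the template's substitution matrix, reduces the template over empty
#' positions, runs the pruned search, and computes the descriptor vector
#' for the best `top_per_pair` complete matches. Pocket centers are
#' computed once per target (or supplied).
#'
#' @param target A `target_structure`.
#' @param catalog Catalog tibble from [build_catalog()] /
#'   [generate_benchmark()].
#' @param config A [search_config()].
#' @param pockets Pocket list, or `NULL` to run [find_pockets()].
#' @param top_per_pair Matches kept per (target, template) pair.
#' @param rules Centroid rules tibble.
#' @return Tibble of described hits: identifiers, rmsddm and the full
#'   descriptor set, plus a `mapping` list-column and a `status` column
#'   (`hit`, `no_hit`, `no_search`).
#' @export
search_catalog <- function(target, catalog, config = search_config(),
                           pockets = NULL, top_per_pair = 1,
                           rules = centroid_rules()) {
  stopifnot(inherits(target, "target_structure"))
  if (is.null(pockets)) pockets <- find_pockets(target)
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    tpl <- catalog$template[[i]]
    subs <- catalog$subs[[i]]
    fam <- if ("family_id" %in% names(catalog)) catalog$family_id[i] else
      sub("-.*$", "", catalog$site_id[i])
    base <- tibble::tibble(target_id = target$structure_id,
                           site_id = catalog$site_id[i],
                           family_id = fam,
                           site_ec = catalog$ec[i])
    if (!tpl$searchable) {
      rows[[length(rows) + 1]] <- dplyr::mutate(base, status = "no_search")
      next
    }
    pool <- build_candidate_pool(target, tpl, subs, rules = rules)
    red <- reduce_template(tpl, pool)
    if (!red$template$searchable) {
      rows[[length(rows) + 1]] <- dplyr::mutate(base, status = "no_search")
      next
    }
    cfg <- config
    cfg$max_hits <- top_per_pair
    hits <- search_template(red$pool, cfg)
    if (nrow(hits) == 0) {
      rows[[length(rows) + 1]] <- dplyr::mutate(base, status = "no_hit")
      next
    }
    dv <- compute_descriptors(red$template, hits, pockets,
                              n_removed = red$n_removed, config = cfg)
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      base[rep(1, nrow(dv)), ],
      dplyr::mutate(dv, status = "hit",
                    n_substitutions = hits$n_substitutions,
                    mapping = hits$mapping))
  }
  dplyr::bind_rows(rows)
}

#' Run the synthetic benchmark search stage
#'
#' Searches every benchmark target against the whole template library and
#' labels the complete hits by exact EC agreement with the target. The
#' result is the training-style hit table consumed by [fit_logistic()] and
#' [evaluate_hits()].
#'
#' @param bench A [generate_benchmark()] result.
#' @param config A [search_config()].
#' @param use_pockets Compute pocket centers per target (default `TRUE`).
#' @param top_per_pair Matches kept per (target, template) pair; keeping a
#'   few ranks per pair (not just the best) mirrors the retain-top-hits
#'   training construction and stabilizes downstream fits, and duplicates
#'   are removed again before ROC evaluation.
#' @return Labeled hit tibble (undeduplicated, unscored).
#' @export
benchmark_hits <- function(bench, config = search_config(),
                           use_pockets = TRUE, top_per_pair = 3) {
  purrr::map_dfr(bench$targets, function(tg) {
    pockets <- if (use_pockets) find_pockets(tg$target) else list()
    h <- search_catalog(tg$target, bench$catalog, config = config,
                        pockets = pockets, top_per_pair = top_per_pair)
    h <- dplyr::filter(h, .data$status == "hit")
    if (nrow(h) == 0) return(h)
    label_hits(h, tg$target_ec)
  })
}

#' Fit-and-evaluate on a benchmark hit table
#'
#' Fits a full-descriptor logistic model and an rmsddm-only baseline on
#' the labeled hits, scores with each, deduplicates, and evaluates both -
#' the synthetic analogue of comparing the minimal and final descriptor
#' sets.
#'
#' @param hits Labeled hit tibble from [benchmark_hits()].
#' @return List: `full` and `minimal`, each with `model`, `evaluation`,
#'   and `auc`.
#' @export
benchmark_evaluation <- function(hits) {
  specs <- list(
    full = tibble::tibble(
      descriptor = c("rmsddm", "f", "backbone_rmsd", "d_c", "interaction"),
      by_bin = c(TRUE, FALSE, TRUE, TRUE, TRUE),
      transform = c("identity", "identity", "identity", "inv_dc",
                    "identity")),
    minimal = tibble::tibble(descriptor = "rmsddm", by_bin = FALSE,
                             transform = "identity")
  )
  purrr::map(specs, function(sp) {
    model <- suppressWarnings(fit_logistic(hits, spec = sp))
    scored <- hits
    scored$score <- score_hits(model, scored)
    ev <- evaluate_hits(dedupe_hits(scored))
    list(model = model, evaluation = ev, auc = ev$auc)
  })
}

#' Generate and write a benchmark dataset (simulate command)
#'
#' Materializes a seeded benchmark as plain-text artifacts: the catalog
#' and homolog TSVs, one parent PDB per family (the template's source
#' coordinates), one target PDB per family, the ground-truth mapping, the
#' target EC table, and a JSON manifest echoing the spec.
#'
#' @param out_dir Output directory (created).
#' @param spec A [benchmark_spec()].
#' @return The benchmark object, invisibly.
#' @export
run_simulate <- function(out_dir, spec = benchmark_spec()) {
  bench <- generate_benchmark(spec)
  dir.create(file.path(out_dir, "parents"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "targets"), showWarnings = FALSE)
  write_catalog_tsv(bench$catalog, file.path(out_dir, "catalog.tsv"))
  write_homologs_tsv(bench$homologs, file.path(out_dir, "homologs.tsv"))
  for (i in seq_len(nrow(bench$catalog))) {
    tpl <- bench$catalog$template[[i]]
    parent_id <- sub("-.*$", "", tpl$site_id)
    res <- tpl$residues
    std <- res$category %in% c("standard", "nonstandard")
    parent <- new_target_structure(
      parent_id,
      tibble::tibble(chain = res$chain[std], resno = res$resno[std],
                     insert = res$insert[std], resid = res$raw_code[std],
                     n_x = res$n_x[std], n_y = res$n_y[std],
                     n_z = res$n_z[std],
                     ca_x = res$ca_x[std], ca_y = res$ca_y[std],
                     ca_z = res$ca_z[std],
                     c_x = res$c_x[std], c_y = res$c_y[std],
                     c_z = res$c_z[std], has_backbone = TRUE),
      tibble::tibble(resid = res$raw_code[!std], chain = res$chain[!std],
                     resno = res$resno[!std],
                     elety = res$centroid_atom[!std],
                     x = res$x[!std], y = res$y[!std], z = res$z[!std]))
    write_structure_pdb(parent,
                        file.path(out_dir, "parents",
                                  paste0(parent_id, ".pdb")))
  }
  truth <- purrr::map_dfr(bench$targets, function(tg) {
    write_structure_pdb(tg$target,
                        file.path(out_dir, "targets",
                                  paste0(tg$target$structure_id, ".pdb")))
    dplyr::mutate(tg$truth, target_id = tg$target$structure_id,
                  jitter_sigma = tg$jitter_sigma)
  })
  readr::write_tsv(truth, file.path(out_dir, "truth.tsv"))
  readr::write_tsv(
    purrr::map_dfr(bench$targets, function(tg) {
      tibble::tibble(target_id = tg$target$structure_id, ec = tg$target_ec)
    }),
    file.path(out_dir, "targets.tsv"))
  write_manifest(file.path(out_dir, "manifest.json"), "simulate",
                 unclass(spec))
  invisible(bench)
}

#' Build-catalog command
#'
#' File-level front end for [build_catalog()]: writes the per-site report,
#' the per-template substitution pair table, the aggregate substitution
#' summary, and a manifest.
#'
#' @inheritParams build_catalog
#' @param out_dir Output directory.
#' @return The [build_catalog()] result, invisibly.
#' @export
run_build_catalog <- function(catalog_tsv, parents_dir,
                              homologs_tsv = NULL, out_dir,
                              rules = centroid_rules(),
                              ions = default_ions()) {
  built <- build_catalog(catalog_tsv, parents_dir, homologs_tsv,
                         rules = rules, ions = ions)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(built$report, file.path(out_dir, "report.tsv"))
  readr::write_tsv(
    dplyr::select(built$catalog, "site_id", "family_id", "ec",
                  "n_residues", "searchable"),
    file.path(out_dir, "sites.tsv"))
  subs_pairs <- purrr::map_dfr(built$catalog$subs, function(m) {
    idx <- which(unclass(m) == 1 & upper.tri(m), arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    tibble::tibble(site_id = attr(m, "site_id"),
                   from = rownames(m)[idx[, 1]], to = colnames(m)[idx[, 2]])
  })
  readr::write_tsv(subs_pairs, file.path(out_dir, "substitutions.tsv"))
  summ <- summarize_substitutions(built$catalog$subs)
  readr::write_tsv(summ$histogram,
                   file.path(out_dir, "substitution_histogram.tsv"))
  write_manifest(file.path(out_dir, "manifest.json"), "build-catalog",
                 list(catalog = catalog_tsv, parents = parents_dir,
                      homologs = homologs_tsv))
  invisible(built)
}

#' Search command
#'
#' Searches one target PDB against a catalog (given as TSVs plus parent
#' structures) and writes the described hit table.
#'
#' @param target_pdb Path to the target PDB file.
#' @param catalog_tsv,parents_dir,homologs_tsv Catalog inputs, see
#'   [build_catalog()].
#' @param out_dir Output directory.
#' @param config A [search_config()].
#' @param pocket_file Optional externally computed gridpoint file; when
#'   given, the geometric pocket scan is skipped.
#' @return The hit tibble, invisibly.
#' @export
run_search <- function(target_pdb, catalog_tsv, parents_dir,
                       homologs_tsv = NULL, out_dir,
                       config = search_config(), pocket_file = NULL) {
  built <- build_catalog(catalog_tsv, parents_dir, homologs_tsv)
  target <- load_structure(target_pdb)
  pockets <- if (!is.null(pocket_file)) read_pocket_gridpoints(pocket_file)
  hits <- search_catalog(target, built$catalog, config = config,
                         pockets = pockets)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(dplyr::select(hits, -dplyr::any_of("mapping")),
                   file.path(out_dir, "hits.tsv"))
  write_manifest(file.path(out_dir, "manifest.json"), "search",
                 list(target = target_pdb, catalog = catalog_tsv,
                      parents = parents_dir, homologs = homologs_tsv,
                      edge_threshold = config$edge_threshold,
                      inclusion_threshold = config$inclusion_threshold,
                      p_max = config$p_max))
  invisible(hits)
}

#' Score command
#'
#' Scores a described hit table with a logistic model, labels hits by
#' exact EC agreement, deduplicates, and (when both labels are present)
#' writes the ROC/AUC/MCC evaluation report with the 0.75 score-threshold
#' guidance.
#'
#' @param hits_tsv Path to a hits TSV from [run_search()].
#' @param targets_tsv Path to a TSV with `target_id`, `ec`.
#' @param out_dir Output directory.
#' @param model A `logistic_model` or path to a model TSV.
#' @param evaluate Produce the ROC/AUC/MCC report (default `TRUE`); errors
#'   when no positive hit exists.
#' @return The scored hit tibble, invisibly.
#' @export
run_score <- function(hits_tsv, targets_tsv, out_dir,
                      model = bundled_model("final"), evaluate = TRUE) {
  if (is.character(model)) model <- read_model(model)
  hits <- readr::read_tsv(hits_tsv, show_col_types = FALSE)
  hits <- dplyr::filter(hits, .data$status == "hit")
  targets <- readr::read_tsv(targets_tsv, show_col_types = FALSE)
  hits <- dplyr::left_join(hits,
                           dplyr::rename(targets, target_ec = "ec"),
                           by = "target_id")
  hits <- purrr::map_dfr(split(hits, hits$target_id), function(h) {
    label_hits(h, h$target_ec[1])
  })
  hits$score <- score_hits(model, hits)
  hits <- dedupe_hits(hits)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(hits, file.path(out_dir, "scored_hits.tsv"))
  if (evaluate && !any(hits$label)) {
    stop("cannot evaluate: no positive hits (every template EC differs from its target)")
  }
  if (evaluate && length(unique(hits$label)) == 2) {
    ev <- evaluate_hits(hits)
    readr::write_tsv(ev$roc, file.path(out_dir, "roc.tsv"))
    readr::write_tsv(ev$by_bin, file.path(out_dir, "auc_by_bin.tsv"))
    summary_tab <- tibble::tibble(
      auc = ev$auc, n = ev$n, n_pos = ev$n_pos,
      guidance_threshold = ev$guidance_threshold,
      guidance_tpr = ev$guidance_tpr, guidance_mcc = ev$guidance_mcc)
    readr::write_tsv(summary_tab, file.path(out_dir, "evaluation.tsv"))
  }
  write_manifest(file.path(out_dir, "manifest.json"), "score",
                 list(hits = hits_tsv, targets = targets_tsv,
                      model = model$provenance))
  invisible(hits)
}
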