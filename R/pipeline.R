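# End-to-end orchestration: differential expression -> temporal grouping ->
# pathway enrichment -> gene scoring -> subnetwork extraction -> attack ->
# drug repurposing, with every intermediate written as TSV/GraphML and a
# JSON manifest recording config, input checksums and stage summaries.
# Reruns on identical inputs are bit-identical (the manifest carries no
# timestamps).

#' Pipeline configuration
#'
#' @param counts,sample_sheet paths to the counts and sample-sheet TSVs.
#' @param gmt path to the pathway GMT (optional; enrichment skipped if NULL).
#' @param edge_lists character vector of pathway edge-list TSV paths.
#' @param drug_table path to the drug-target TSV (optional; repurposing
#'   skipped if NULL).
#' @param homology optional mouse-to-human map TSV (columns `mouse`,
#'   `human`).
#' @param de_tables optional named list/vector of pre-computed DE TSV paths
#'   (named by timepoint); when given, the DE test is skipped and these
#'   tables are used instead.
#' @param fdr_alpha per-timepoint DE FDR threshold (default 0.01).
#' @param lfc_min minimum |log2fc| for DE calls (default 1).
#' @param enrich_alpha enrichment adjusted-p threshold (default 0.05).
#' @param size_range subnetwork size interval (default `c(30, 60)`).
#' @param attack_k combinatorial attack size (default 2, ceiling 5).
#' @param convention attackness convention (see [attackness()]).
#' @param score_on `"fdr"` or `"p"` for [combine_scores()].
#' @param truth_labels optional truth TSV from the simulator; when present
#'   the manifest reports recovery metrics.
#' @param seed integer seed recorded in the manifest.
#' @param outdir output directory (created if needed).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, sample_sheet, gmt = NULL,
                            edge_lists = character(), drug_table = NULL,
                            homology = NULL, de_tables = NULL,
                            fdr_alpha = 0.01, lfc_min = 1,
                            enrich_alpha = 0.05, size_range = c(30, 60),
                            attack_k = 2,
                            convention = c("count-removed", "remaining-only"),
                            score_on = c("fdr", "p"),
                            truth_labels = NULL, seed = 1, outdir = "myonet_out") {
  convention <- match.arg(convention)
  score_on <- match.arg(score_on)
  paths <- c(counts, sample_sheet, gmt, edge_lists, drug_table, homology,
             unlist(de_tables), truth_labels)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop_input("input file(s) not found: ", paste(missing, collapse = ", "))
  stopifnot(fdr_alpha > 0, fdr_alpha < 1, enrich_alpha > 0, enrich_alpha < 1,
            lfc_min >= 0, attack_k >= 1, attack_k <= 5)
  structure(list(counts = counts, sample_sheet = sample_sheet, gmt = gmt,
                 edge_lists = edge_lists, drug_table = drug_table,
                 homology = homology, de_tables = de_tables,
                 fdr_alpha = fdr_alpha, lfc_min = lfc_min,
                 enrich_alpha = enrich_alpha, size_range = size_range,
                 attack_k = attack_k, convention = convention,
                 score_on = score_on, truth_labels = truth_labels,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes differential expression (or loads external DE tables), temporal
#' grouping, pathway enrichment, Fisher-combined scoring, subnetwork
#' extraction, attackness profiling plus combinatorial attack, and drug
#' repurposing, writing each stage's artifact under `config$outdir`. A stage
#' failure aborts with the stage name and is recorded in the manifest.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (list), invisibly also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  inputs <- c(config$counts, config$sample_sheet, config$gmt, config$edge_lists,
              config$drug_table, config$homology, unlist(config$de_tables),
              config$truth_labels)
  manifest <- list(
    config = unclass(config)[setdiff(names(config), "outdir")],
    seed = config$seed,
    input_md5 = as.list(tools::md5sum(inputs)),
    stages = list()
  )
  finish <- function() {
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "error", message = conditionMessage(res))
      finish()
      stop_input("pipeline stage '", name, "' failed: ", conditionMessage(res))
    }
    res
  }

  truth <- if (!is.null(config$truth_labels)) read_truth_labels(config$truth_labels) else NULL

  ## differential expression
  de_tables <- stage("diffexpr", {
    if (!is.null(config$de_tables)) {
      tabs <- lapply(seq_along(config$de_tables), function(i) {
        read_de_table(config$de_tables[[i]],
                      timepoint = names(config$de_tables)[i],
                      alpha = config$fdr_alpha, lfc_min = config$lfc_min)
      })
    } else {
      cts <- read_counts(config$counts, config$sample_sheet)
      cts <- filter_low_counts(cts)
      tps <- sort(unique(cts$samples$timepoint))
      tabs <- lapply(tps, function(tp) {
        test_differential(cts, tp, alpha = config$fdr_alpha, lfc_min = config$lfc_min)
      })
    }
    for (d in tabs) {
      write_de_table(d, file.path(config$outdir, paste0("de_d", d$timepoint[1], ".tsv")))
    }
    tabs
  })
  manifest$stages$diffexpr <- list(
    status = "ok", n_timepoints = length(de_tables),
    n_genes_tested = vapply(de_tables, nrow, integer(1)),
    n_called = vapply(de_tables, function(d) sum(d$call != "ns"), integer(1)))

  ## temporal grouping
  groups <- stage("grouping", {
    pats <- call_patterns(de_tables)
    grp <- assign_groups(pats)
    write_tsv(grp, file.path(config$outdir, "groups.tsv"))
    ic <- intersection_counts(pats)
    write_tsv(ic$patterns, file.path(config$outdir, "intersection_counts.tsv"))
    write_tsv(ic$groups, file.path(config$outdir, "group_totals.tsv"))
    grp
  })
  manifest$stages$grouping <- list(
    status = "ok", n_grouped = nrow(groups),
    totals = as.list(table(groups$group)))
  if (!is.null(truth)) {
    planted <- truth[truth$group != "null", ]
    hit <- merge(planted, groups, by = "gene")
    manifest$stages$grouping$recovery <-
      if (nrow(planted)) sum(hit$group.x == hit$group.y) / nrow(planted) else NA
  }

  ## pathway enrichment
  if (!is.null(config$gmt)) {
    enr <- stage("enrichment", {
      coll <- read_gmt(config$gmt)
      universe <- unique(unlist(lapply(de_tables, function(d) d$gene)))
      universe <- intersect(universe, unique(unlist(coll$genes)))
      e <- enrich_all(groups, coll, universe, alpha = config$enrich_alpha)
      write_tsv(e, file.path(config$outdir, "enrichment.tsv"))
      e
    })
    manifest$stages$enrichment <- list(
      status = "ok", n_tests = nrow(enr), n_significant = sum(enr$significant))
  }

  ## scoring + subnetwork
  subnet <- stage("subnetwork", {
    scores <- combine_scores(de_tables, use = config$score_on)
    write_tsv(data.frame(gene = names(scores), score = unname(scores)),
              file.path(config$outdir, "scores.tsv"))
    parent <- merge_pathway_networks(read_edge_lists(config$edge_lists))
    sn <- find_subnetwork(parent, scores, size_range = config$size_range,
                          de_tables = de_tables)
    validate_subnetwork(sn, parent)
    write_edge_list(sn$network, file.path(config$outdir, "subnetwork_edges.tsv"))
    write_graphml(sn, file.path(config$outdir, "subnetwork.graphml"))
    sn
  })
  manifest$stages$subnetwork <- list(
    status = "ok", n_nodes = length(subnet$nodes),
    n_edges = nrow(subnet$network$edges), theta = subnet$theta,
    net_weight = subnet$net_weight, size_in_range = subnet$size_in_range)
  if (!is.null(truth) && "module" %in% names(truth)) {
    planted <- truth$gene[as.logical(truth$module)]
    jac <- length(intersect(subnet$nodes, planted)) /
      length(union(subnet$nodes, planted))
    manifest$stages$subnetwork$jaccard_vs_truth <- jac
  }

  ## attack
  attacks <- stage("attack", {
    prof <- attackness_profile(subnet$network, convention = config$convention)
    write_tsv(prof, file.path(config$outdir, "attack_profile.tsv"))
    comb <- combinatorial_attack(subnet$network, k = config$attack_k,
                                 convention = config$convention)
    write_tsv(comb, file.path(config$outdir, "attack_combinations.tsv"))
    list(profile = prof, combinations = comb)
  })
  manifest$stages$attack <- list(
    status = "ok",
    top_single = attacks$profile$nodes[1],
    top_single_attackness = attacks$profile$attackness[1],
    top_combination = attacks$combinations$nodes[1],
    top_combination_attackness = attacks$combinations$attackness[1])

  ## repurposing
  if (!is.null(config$drug_table)) {
    rep_res <- stage("repurpose", {
      drugs <- filter_drug_table(read_drug_table(config$drug_table))
      hom_map <- if (!is.null(config$homology)) {
        homology_map(subnet$nodes, read_tsv(config$homology))
      } else homology_map(subnet$nodes)
      targets <- map_targets(subnet, drugs, hom_map)
      write_tsv(targets, file.path(config$outdir, "drug_targets.tsv"))
      druggable <- sort(unique(targets$mouse_gene))
      catk <- NULL
      if (length(druggable) > config$attack_k) {
        catk <- constrained_attack(subnet$network, druggable,
                                   k = config$attack_k,
                                   convention = config$convention)
        write_tsv(catk, file.path(config$outdir, "constrained_attack.tsv"))
      }
      list(targets = targets, constrained = catk)
    })
    manifest$stages$repurpose <- list(
      status = "ok", n_target_rows = nrow(rep_res$targets),
      n_druggable = length(unique(rep_res$targets$mouse_gene)))
  }

  finish()
}
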