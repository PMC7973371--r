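# Drug-repurposing support: ChEMBL-style drug-target filtering, homology
# mapping of subnetwork genes to human targets, target-set enrichment, and
# combinatorial attack constrained to druggable nodes.

#' Filter a ChEMBL-style drug-target table
#'
#' Applies the repurposing criteria: drop withdrawn drugs, drop rows lacking
#' a well-defined mechanism of action, drop promiscuous drugs (more than
#' `max_targets_per_drug` distinct target genes in the input table), and
#' within each (gene, indication) keep only rows at the maximum clinical
#' phase. Idempotent.
#'
#' @param records data.frame with columns `drug_id`, `gene`, `max_phase`,
#'   `indication`, `has_moa`, `withdrawn` (e.g. from
#'   [simulate_drug_table()] or [read_drug_table()]).
#' @param max_targets_per_drug promiscuity ceiling (default 5 distinct
#'   genes).
#' @return filtered data.frame with an added `promiscuity` column.
#' @export
filter_drug_table <- function(records, max_targets_per_drug = 5) {
  req <- c("drug_id", "gene", "max_phase", "indication", "has_moa", "withdrawn")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    stop_input("drug table needs columns ", paste(req, collapse = ", "))
  }
  if (!nrow(records)) {
    records$promiscuity <- integer(0)
    return(records)
  }
  ph <- records$max_phase
  if (any(is.na(ph)) || any(ph != floor(ph)) || any(ph < 1 | ph > 4)) {
    stop_input("malformed 'max_phase': values must be integers in 1..4")
  }
  prom <- tapply(records$gene, records$drug_id, function(g) length(unique(g)))
  records$promiscuity <- as.integer(prom[records$drug_id])
  out <- records[!records$withdrawn & records$has_moa &
                   records$promiscuity <= max_targets_per_drug, , drop = FALSE]
  if (nrow(out)) {
    key <- paste(out$gene, out$indication, sep = "\r")
    maxp <- tapply(out$max_phase, key, max)
    out <- out[out$max_phase == maxp[key], , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Mouse-to-human homology map
#'
#' Builds a one-to-one mouse-to-human symbol map. By default a mouse symbol
#' maps to its upper-cased form (adequate for symbol families where mouse
#' and human names differ only by case); an explicit two-column map
#' overrides the default. Mouse symbols mapping to more than one human
#' symbol are dropped with a warning.
#'
#' @param mouse_symbols character vector of mouse gene symbols.
#' @param map optional data.frame with columns `mouse`, `human`.
#' @return named character vector: `human <- map[mouse]`.
#' @export
homology_map <- function(mouse_symbols, map = NULL) {
  mouse_symbols <- unique(as.character(mouse_symbols))
  out <- setNames(toupper(mouse_symbols), mouse_symbols)
  if (!is.null(map)) {
    if (!is.data.frame(map) || !all(c("mouse", "human") %in% names(map))) {
      stop_input("'map' must have columns 'mouse' and 'human'")
    }
    nh <- tapply(map$human, map$mouse, function(h) length(unique(h)))
    ambig <- names(nh)[nh > 1]
    if (length(ambig)) {
      warning("dropping ambiguous mouse symbol(s): ", paste(ambig, collapse = ", "),
              call. = FALSE)
      map <- map[!map$mouse %in% ambig, , drop = FALSE]
    }
    hit <- mouse_symbols %in% map$mouse
    out[mouse_symbols[hit]] <- map$human[match(mouse_symbols[hit], map$mouse)]
  }
  out
}

phase_class <- function(phase) {
  ifelse(phase == 4, "approved",
         ifelse(phase == 3, "phase III",
                ifelse(phase == 2, "phase II", "phase I")))
}

#' Map subnetwork genes to drug targets via homology
#'
#' Joins the module's mouse genes to a filtered drug-target table through
#' the homology map, one row per (mouse gene, drug) whose human homolog
#' matches the drug's target.
#'
#' @param subnetwork a `subnetwork_result` or a character vector of mouse
#'   gene symbols.
#' @param drugs filtered drug table (see [filter_drug_table()]).
#' @param homology named character vector from [homology_map()].
#' @return data.frame `mouse_gene`, `human_gene`, `drug_id`, `drug_name`,
#'   `max_phase`, `phase_class`, `indication`; invariant to drug-table row
#'   order. Genes partition into approved-drug targets (`phase_class ==
#'   "approved"`) and phased (II/III) targets.
#' @export
map_targets <- function(subnetwork, drugs, homology = NULL) {
  genes <- if (inherits(subnetwork, "subnetwork_result")) subnetwork$nodes else as.character(subnetwork)
  if (is.null(homology)) homology <- homology_map(genes)
  out <- data.frame(mouse_gene = character(0), human_gene = character(0),
                    drug_id = character(0), drug_name = character(0),
                    max_phase = integer(0), phase_class = character(0),
                    indication = character(0), stringsAsFactors = FALSE)
  if (!length(genes) || !nrow(drugs)) return(out)
  human <- homology[genes]
  hit <- which(drugs$gene %in% human)
  if (!length(hit)) return(out)
  d <- drugs[hit, , drop = FALSE]
  m <- match(d$gene, human)
  out <- data.frame(mouse_gene = genes[m], human_gene = d$gene,
                    drug_id = d$drug_id,
                    drug_name = if ("drug_name" %in% names(d)) d$drug_name else d$drug_id,
                    max_phase = as.integer(d$max_phase),
                    phase_class = phase_class(d$max_phase),
                    indication = d$indication, stringsAsFactors = FALSE)
  out <- out[order(out$mouse_gene, out$drug_id, out$indication), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enrichment of drug-target sets in the subnetwork
#'
#' One-sided Fisher's exact enrichment (with odds ratio and 95% CI) of the
#' approved-drug and phased-drug target sets among the subnetwork genes,
#' Benjamini-Hochberg adjusted across the target sets.
#'
#' @param subnetwork_genes character vector (module genes, same symbol space
#'   as the target sets).
#' @param target_sets named list of gene sets, e.g.
#'   `list(approved = ..., phased = ...)`.
#' @param universe character vector of testable genes.
#' @return data.frame, one row per target set, with [fisher_enrich()]
#'   columns plus `target_set` and `padj`.
#' @export
target_set_enrichment <- function(subnetwork_genes, target_sets, universe) {
  if (!is.list(target_sets) || is.null(names(target_sets))) {
    stop_input("'target_sets' must be a named list of gene sets")
  }
  rows <- lapply(names(target_sets), function(nm) {
    cbind(data.frame(target_set = nm, stringsAsFactors = FALSE),
          fisher_enrich(subnetwork_genes, target_sets[[nm]], universe))
  })
  out <- do.call(rbind, rows)
  out$padj <- adjust_bh(out$p)
  out
}

#' Combinatorial attack restricted to druggable nodes
#'
#' Delegates to [combinatorial_attack()] with `candidates = druggable`,
#' optionally conditioned on a fixed `base_set` (e.g. nodes already hit by
#' standard-of-care therapy).
#'
#' @inheritParams combinatorial_attack
#' @param druggable nodes with an identifiable drug (subset of the network).
#' @return ranked data.frame of attack records (see
#'   [combinatorial_attack()]).
#' @export
constrained_attack <- function(net, druggable, k, base_set = character(),
                               top_m = 10,
                               convention = c("count-removed", "remaining-only"),
                               k_max = 5) {
  convention <- match.arg(convention)
  combinatorial_attack(net, k = k, candidates = druggable, base_set = base_set,
                       top_m = top_m, convention = convention, k_max = k_max)
}
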