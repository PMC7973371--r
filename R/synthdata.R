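# Synthetic-data generator emulating the study design: two conditions
# (disease vs control) at three timepoints with four replicates each,
# negative-binomial counts with genes planted in the seven temporal groups,
# a parent network assembled from overlapping pathway edge lists containing
# a planted high-score connected module, and a ChEMBL-style drug-target
# table. All generators are deterministic given their seed, with per-stage
# sub-streams so extending one stage does not reshuffle the others.

#' Simulation configuration
#'
#' @param n_genes total number of genes.
#' @param n_replicates replicates per condition x timepoint (>= 2).
#' @param timepoints ordered day labels (default 10, 15, 21).
#' @param group_sizes named counts of planted genes per temporal group label
#'   (names from [group_rules()] labels); default 100 per group. Their sum
#'   must not exceed `n_genes`.
#' @param effect_log2fc planted absolute log2 fold change (default 2).
#' @param nb_dispersion negative-binomial dispersion `phi`
#'   (`var = mu + phi * mu^2`; default 0.1).
#' @param baseline_mean_log_range interval for log-uniform baseline means
#'   (default `log(c(20, 2000))`).
#' @param libsize_factor_range multiplicative library-size jitter interval,
#'   sampled log-uniformly (default `c(0.7, 1.3)`).
#' @param seed integer RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_replicates = 4,
                       timepoints = c(10, 15, 21),
                       group_sizes = setNames(rep(100L, 7), unname(group_rules())),
                       effect_log2fc = 2, nb_dispersion = 0.1,
                       baseline_mean_log_range = log(c(20, 2000)),
                       libsize_factor_range = c(0.7, 1.3),
                       seed = 1) {
  if (!is_count(n_genes) || n_genes < 1) stop_input("'n_genes' must be a positive integer")
  if (!is_count(n_replicates) || n_replicates < 2) stop_input("'n_replicates' must be >= 2")
  if (length(timepoints) != 3) stop_input("exactly three timepoints are supported")
  if (is.null(names(group_sizes)) || !all(names(group_sizes) %in% unname(group_rules()))) {
    stop_input("'group_sizes' must be named by temporal group labels")
  }
  if (sum(group_sizes) > n_genes) stop_input("planted group sizes exceed 'n_genes'")
  if (nb_dispersion <= 0) stop_input("'nb_dispersion' must be > 0")
  if (effect_log2fc < 0) stop_input("'effect_log2fc' must be >= 0")
  structure(list(n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
                 timepoints = timepoints, group_sizes = group_sizes,
                 effect_log2fc = effect_log2fc, nb_dispersion = nb_dispersion,
                 baseline_mean_log_range = baseline_mean_log_range,
                 libsize_factor_range = libsize_factor_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# planted per-timepoint multipliers (disease condition) for each group label,
# matching the group membership rules exactly
group_effect_pattern <- function(label, e) {
  f <- 2^e
  switch(label,
         EPi = c(f, f, f),
         MPi = c(1, f, f), MPr = c(1, 1 / f, 1 / f),
         MTi = c(1, f, 1), MTr = c(1, 1 / f, 1),
         LTi = c(1, 1, f), LTr = c(1, 1, 1 / f),
         c(1, 1, 1))
}

#' Simulate a time-course count matrix with planted temporal groups
#'
#' Draws negative-binomial counts (`var = mu + phi * mu^2`) for
#' disease/control at each timepoint. A gene planted in group `g` has its
#' disease-condition mean multiplied by `2^(+-effect_log2fc)` exactly at the
#' timepoints its group's membership rule prescribes, with the prescribed
#' sign; null genes share means across conditions. Per-sample library-size
#' factors are drawn log-uniformly. Identical seed gives identical output.
#'
#' @param config a [sim_config()].
#' @param genes optional gene names overriding the default (`G00001`, ...);
#'   length must equal `config$n_genes`.
#' @param labels optional per-gene group labels overriding the
#'   `group_sizes`-driven assignment (values from [group_rules()] labels or
#'   `"null"`).
#' @return list with `counts` (a [counts_table()]) and `truth`
#'   (data.frame `gene`, `group`; `"null"` for unplanted genes).
#' @export
simulate_counts <- function(config, genes = NULL, labels = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ng <- config$n_genes
  nrep <- config$n_replicates
  tps <- config$timepoints
  genes <- genes %||% sprintf("G%05d", seq_len(ng))
  if (length(genes) != ng || anyDuplicated(genes)) {
    stop_input("'genes' must be ", ng, " unique names")
  }

  if (is.null(labels)) {
    labels <- rep("null", ng)
    sizes <- config$group_sizes[config$group_sizes > 0]
    if (length(sizes)) labels[seq_len(sum(sizes))] <- rep(names(sizes), sizes)
  } else if (length(labels) != ng ||
             !all(labels %in% c(unname(group_rules()), "null"))) {
    stop_input("'labels' must give one group label (or 'null') per gene")
  }

  conds <- c("disease", "control")
  samples <- expand.grid(replicate = seq_len(nrep), condition = conds,
                         timepoint = tps, stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_d%s_r%d", samples$condition,
                               samples$timepoint, samples$replicate)
  samples <- samples[, c("sample_id", "condition", "timepoint", "replicate")]
  ns <- nrow(samples)

  set.seed(substream_seed(config$seed, 1L))
  base_mean <- exp(runif(ng, config$baseline_mean_log_range[1],
                         config$baseline_mean_log_range[2]))
  set.seed(substream_seed(config$seed, 2L))
  lib <- exp(runif(ns, log(config$libsize_factor_range[1]),
                   log(config$libsize_factor_range[2])))

  tp_index <- match(samples$timepoint, tps)
  disease <- samples$condition == "disease"
  size_nb <- 1 / config$nb_dispersion
  cts <- matrix(0L, nrow = ng, ncol = ns, dimnames = list(genes, samples$sample_id))
  set.seed(substream_seed(config$seed, 3L))
  for (i in seq_len(ng)) {
    eff <- group_effect_pattern(labels[i], config$effect_log2fc)
    mult <- ifelse(disease, eff[tp_index], 1)
    mu <- base_mean[i] * mult * lib
    cts[i, ] <- as.integer(rnbinom(ns, mu = mu, size = size_nb))
  }
  list(counts = counts_table(cts, samples),
       truth = data.frame(gene = genes, group = labels, stringsAsFactors = FALSE))
}

#' Simulate overlapping pathway edge lists and a merged parent network
#'
#' Each pathway gets `genes_per_pathway` member genes, of which a
#' `overlap_fraction` share comes from a pool common to all pathways (so the
#' merged network is connected with high probability when the fraction is
#' positive), and a connected random edge set (random spanning tree plus
#' extra random edges) over its members. A connected module of
#' `planted_module_size` genes is grown inside the merged network and
#' recorded as truth.
#'
#' @param n_pathways number of pathways.
#' @param genes_per_pathway members per pathway.
#' @param overlap_fraction fraction of members shared across pathways
#'   (in `[0, 1)`).
#' @param planted_module_size size of the planted connected module (0 to
#'   skip planting).
#' @param seed integer RNG seed.
#' @return list with `network` (merged [network()]), `pathways`
#'   (a [gene_set_collection()]), `edge_lists` (data.frame `from`, `to`,
#'   `pathway`), and `module` (character vector of planted module genes).
#' @export
simulate_network_and_pathways <- function(n_pathways = 10, genes_per_pathway = 30,
                                          overlap_fraction = 0.2,
                                          planted_module_size = 20, seed = 1) {
  if (!is_count(n_pathways) || n_pathways < 1) stop_input("'n_pathways' must be >= 1")
  if (!is_count(genes_per_pathway) || genes_per_pathway < 2) {
    stop_input("'genes_per_pathway' must be >= 2")
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) stop_input("'overlap_fraction' must be in [0, 1)")
  n_shared <- round(overlap_fraction * genes_per_pathway)
  n_unique <- genes_per_pathway - n_shared
  total <- n_shared + n_pathways * n_unique
  genes <- sprintf("G%04d", seq_len(total))
  shared <- if (n_shared) genes[seq_len(n_shared)] else character(0)

  set.seed(substream_seed(seed, 1L))
  edge_rows <- list()
  members <- vector("list", n_pathways)
  pw_ids <- sprintf("PW%02d", seq_len(n_pathways))
  for (p in seq_len(n_pathways)) {
    uniq <- genes[n_shared + (p - 1L) * n_unique + seq_len(n_unique)]
    mem <- c(shared, uniq)
    members[[p]] <- mem
    # random spanning tree (random attachment order), then extra random edges
    perm <- sample(mem)
    tree_to <- vapply(seq_along(perm)[-1], function(i) perm[sample.int(i - 1L, 1L)], character(1))
    ed <- data.frame(from = perm[-1], to = tree_to, stringsAsFactors = FALSE)
    n_extra <- length(mem)
    extra <- cbind(sample(mem, n_extra, replace = TRUE),
                   sample(mem, n_extra, replace = TRUE))
    extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
    ed <- rbind(ed, data.frame(from = extra[, 1], to = extra[, 2],
                               stringsAsFactors = FALSE))
    ed$pathway <- pw_ids[p]
    edge_rows[[p]] <- ed
  }
  edge_lists <- do.call(rbind, edge_rows)
  net <- merge_pathway_networks(edge_lists)

  module <- character(0)
  if (planted_module_size > 0) {
    adj <- adjacency_list(net)
    if (planted_module_size > lcc_size(adj, rep(TRUE, length(net$nodes)))) {
      stop_input("'planted_module_size' exceeds the largest connected component; ",
                 "no connected planted module is possible")
    }
    set.seed(substream_seed(seed, 2L))
    # grow a connected module by random frontier expansion, restarting from
    # a different seed node if a component proves too small
    repeat {
      start <- sample.int(length(net$nodes), 1L)
      mod <- start
      frontier <- adj[[start]]
      while (length(mod) < planted_module_size && length(frontier)) {
        nxt <- frontier[sample.int(length(frontier), 1L)]
        mod <- c(mod, nxt)
        frontier <- setdiff(unique(c(frontier, adj[[nxt]])), mod)
      }
      if (length(mod) >= planted_module_size) break
    }
    module <- sort(net$nodes[mod])
  }
  list(network = net,
       pathways = gene_set_collection(pw_ids, members,
                                      category = "simulated pathways"),
       edge_lists = edge_lists,
       module = module)
}

#' Simulate a ChEMBL-style drug-target table
#'
#' Generates drug-target rows with clinical phase, indication,
#' mechanism-of-action and withdrawal flags. To exercise the downstream
#' filter, the table always plants at least one withdrawn row and one
#' duplicate (gene, indication) pair with differing phases (2 and 4); when
#' `fraction_approved = 1` the lower-phase duplicate is flagged withdrawn so
#' that all non-withdrawn rows are approved.
#'
#' @param genes nonempty character vector of target gene symbols.
#' @param fraction_approved fraction of non-withdrawn rows at phase 4.
#' @param seed integer RNG seed.
#' @return data.frame: `drug_id`, `drug_name`, `gene`, `max_phase`,
#'   `indication`, `has_moa`, `withdrawn`.
#' @export
simulate_drug_table <- function(genes, fraction_approved = 0.4, seed = 1) {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop_input("'genes' must be nonempty")
  if (fraction_approved < 0 || fraction_approved > 1) {
    stop_input("'fraction_approved' must be in [0, 1]")
  }
  indications <- c("myocarditis", "rheumatoid arthritis", "lymphoma", "asthma")
  set.seed(substream_seed(seed, 1L))
  n_drugs <- max(3L, ceiling(length(genes) * 0.6))
  rows <- list()
  for (i in seq_len(n_drugs)) {
    nt <- sample(1:3, 1)
    targets <- sample(genes, min(nt, length(genes)))
    phase <- if (runif(1) < fraction_approved) 4L else sample(1:3, 1)
    rows[[i]] <- data.frame(
      drug_id = sprintf("DRUG%03d", i),
      drug_name = sprintf("compound-%03d", i),
      gene = targets,
      max_phase = phase,
      indication = sample(indications, 1),
      has_moa = runif(1) > 0.1,
      withdrawn = FALSE,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  g1 <- genes[1]
  planted <- data.frame(
    drug_id = c("DRUGW01", "DRUGD01", "DRUGD02"),
    drug_name = c("withdrawn-compound", "dup-low-phase", "dup-high-phase"),
    gene = g1,
    max_phase = c(3L, 2L, 4L),
    indication = c(indications[1], indications[2], indications[2]),
    has_moa = TRUE,
    withdrawn = c(TRUE, fraction_approved >= 1, FALSE),
    stringsAsFactors = FALSE)
  out <- rbind(tab, planted)
  rownames(out) <- NULL
  out
}

#' Small fixture graphs with analytically known attackness
#'
#' @return named list of [network()] objects: `star5` (hub plus 4 leaves),
#'   `path3` (A-B-C), `barbell9` (two 4-cliques joined through one cut
#'   vertex: 9 nodes, 14 edges).
#' @export
make_fixture_graphs <- function() {
  star5 <- network(data.frame(from = "hub", to = paste0("leaf", 1:4)))
  path3 <- network(data.frame(from = c("A", "B"), to = c("B", "C")))
  cl <- function(v) {
    p <- combn(v, 2)
    data.frame(from = p[1, ], to = p[2, ], stringsAsFactors = FALSE)
  }
  barbell9 <- network(rbind(cl(paste0("a", 1:4)), cl(paste0("b", 1:4)),
                            data.frame(from = c("a1", "b1"), to = c("cut", "cut"))))
  list(star5 = star5, path3 = path3, barbell9 = barbell9)
}

#' Simulate a complete coherent study bundle
#'
#' Builds all pipeline inputs over a single shared gene universe: overlapping
#' pathway edge lists and their merged network, a count matrix whose planted
#' differential-expression labels place the planted network module in the
#' persistently-induced group (so its genes accumulate the highest combined
#' scores), four additional transient groups on non-module genes, a
#' drug-target table covering the module plus background genes, and a truth
#' table carrying both the group label and module membership of every gene.
#'
#' @param seed integer RNG seed; all stages derive independent substreams.
#' @param n_pathways,genes_per_pathway,overlap_fraction,planted_module_size
#'   passed to [simulate_network_and_pathways()].
#' @param n_replicates,effect_log2fc,nb_dispersion passed to [sim_config()].
#' @param n_per_transient_group genes planted per transient group
#'   (`MTi`, `MTr`, `LTi`, `LTr`); capped by the available non-module genes.
#' @param fraction_approved passed to [simulate_drug_table()].
#' @return list: `config` ([sim_config()]), `counts` ([counts_table()]),
#'   `truth` (data.frame `gene`, `group`, `module`), `network`, `pathways`,
#'   `edge_lists`, `module`, `drugs`.
#' @export
simulate_study <- function(seed = 1, n_pathways = 10, genes_per_pathway = 30,
                           overlap_fraction = 0.2, planted_module_size = 20,
                           n_replicates = 4, effect_log2fc = 3,
                           nb_dispersion = 0.1, n_per_transient_group = 10,
                           fraction_approved = 0.4) {
  netres <- simulate_network_and_pathways(
    n_pathways = n_pathways, genes_per_pathway = genes_per_pathway,
    overlap_fraction = overlap_fraction,
    planted_module_size = planted_module_size,
    seed = substream_seed(seed, 11L))
  genes <- netres$network$nodes
  ng <- length(genes)

  labels <- setNames(rep("null", ng), genes)
  labels[netres$module] <- "EPi"
  transient <- c("MTi", "MTr", "LTi", "LTr")
  pool <- setdiff(genes, netres$module)
  set.seed(substream_seed(seed, 12L))
  pool <- sample(pool)
  take <- min(n_per_transient_group, length(pool) %/% length(transient))
  for (i in seq_along(transient)) {
    labels[pool[(i - 1L) * take + seq_len(take)]] <- transient[i]
  }

  cfg <- sim_config(n_genes = ng, n_replicates = n_replicates,
                    group_sizes = setNames(rep(0L, 7L), unname(group_rules())),
                    effect_log2fc = effect_log2fc,
                    nb_dispersion = nb_dispersion,
                    seed = substream_seed(seed, 13L))
  sim <- simulate_counts(cfg, genes = genes, labels = unname(labels))

  set.seed(substream_seed(seed, 14L))
  background <- sample(pool, min(20L, length(pool)))
  drugs <- simulate_drug_table(toupper(c(netres$module, background)),
                               fraction_approved = fraction_approved,
                               seed = substream_seed(seed, 15L))

  truth <- sim$truth
  truth$module <- as.integer(truth$gene %in% netres$module)
  list(config = cfg, counts = sim$counts, truth = truth,
       network = netres$network, pathways = netres$pathways,
       edge_lists = netres$edge_lists, module = netres$module, drugs = drugs)
}

#' Write a simulated study bundle to disk
#'
#' Writes every pipeline input produced by [simulate_study()] as a text file
#' under `dir`: counts and sample sheet, pathway GMT, pathway edge list,
#' drug-target table, and truth labels.
#'
#' @param study a list from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return named list of the written file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    counts = file.path(dir, "counts.tsv"),
    sample_sheet = file.path(dir, "samples.tsv"),
    gmt = file.path(dir, "pathways.gmt"),
    edge_lists = file.path(dir, "edges.tsv"),
    drug_table = file.path(dir, "drugs.tsv"),
    truth_labels = file.path(dir, "truth.tsv"))
  write_counts(study$counts, paths$counts, paths$sample_sheet)
  write_gmt(study$pathways, paths$gmt)
  ed <- study$edge_lists
  names(ed)[names(ed) == "from"] <- "gene_a"
  names(ed)[names(ed) == "to"] <- "gene_b"
  write_tsv(ed, paths$edge_lists)
  write_drug_table(study$drugs, paths$drug_table)
  write_truth_labels(study$truth, paths$truth_labels)
  invisible(paths)
}
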