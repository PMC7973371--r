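# Readers and writers for the pipeline's plain-text formats: counts +
# sample-sheet TSV, DE TSV, GMT gene sets, per-pathway edge-list TSV, drug
# table TSV, and GraphML for annotated subnetworks. All tabular files are
# TSV with a header row; missing values are written as "NA". Every writer's
# output round-trips through its paired reader.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read a counts TSV plus sample sheet
#'
#' The counts file has a gene-id first column and one column per sample; the
#' sample sheet (columns `sample_id`, `condition`, `timepoint`, `replicate`)
#' must cover every count column.
#'
#' @param counts_path path to the counts TSV.
#' @param sample_sheet_path path to the sample-sheet TSV.
#' @return a [counts_table()].
#' @export
read_counts <- function(counts_path, sample_sheet_path) {
  raw <- read_tsv(counts_path)
  if (ncol(raw) < 2) stop_input("counts file needs a gene column plus sample columns")
  genes <- as.character(raw[[1]])
  if (anyDuplicated(genes)) stop_input("duplicate gene ids in ", counts_path)
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_input("non-numeric counts in ", counts_path)
  rownames(m) <- genes
  samples <- read_tsv(sample_sheet_path)
  counts_table(m, samples)
}

#' Write a counts table and its sample sheet
#' @param x a [counts_table()].
#' @inheritParams read_counts
#' @return invisibly, the counts path.
#' @export
write_counts <- function(x, counts_path, sample_sheet_path) {
  stopifnot(inherits(x, "counts_table"))
  df <- data.frame(gene = rownames(x$counts), x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, counts_path)
  write_tsv(x$samples, sample_sheet_path)
  invisible(counts_path)
}

#' Read/write a per-timepoint DE table
#'
#' Columns `gene`, `timepoint`, `log2fc`, `p`, `fdr`, `call` (external
#' tables may omit `call`; it is derived from the thresholds).
#'
#' @param path TSV path.
#' @param timepoint timepoint label when the file lacks a column.
#' @inheritParams test_differential
#' @return DE table data.frame.
#' @export
read_de_table <- function(path, timepoint = NULL, alpha = 0.01, lfc_min = 1) {
  de <- read_tsv(path)
  if ("call" %in% names(de) && !is.null(de$timepoint)) {
    return(de[, c("gene", "timepoint", "log2fc", "p", "fdr", "call")])
  }
  call_de_table(de, timepoint = timepoint, alpha = alpha, lfc_min = lfc_min)
}

#' @rdname read_de_table
#' @param de a DE table.
#' @export
write_de_table <- function(de, path) write_tsv(de, path)

#' Read a GMT gene-set file
#'
#' Standard dialect: one set per line, tab-separated fields
#' `id`, `description`, members. A `category` is attached to all sets.
#'
#' @param path GMT path.
#' @param category category tag for the sets (default `"pathway"`).
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, category = "pathway") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short)) stop_input("GMT line ", short[1], " has fewer than 3 fields")
  gene_set_collection(
    id = vapply(parts, `[[`, character(1), 1),
    name = vapply(parts, `[[`, character(1), 2),
    genes = lapply(parts, function(f) f[-(1:2)]),
    category = category
  )
}

#' Write a gene-set collection as GMT
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(seq_along(collection$id), function(i) {
    paste(c(collection$id[i], collection$name[i], collection$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read pathway edge lists
#'
#' Each file is a TSV with two columns (`from`, `to`; pathway id taken from
#' the file name) or three (`from`, `to`, `pathway` — original column names
#' `gene_a`/`gene_b` are also accepted). Multiple files are concatenated.
#'
#' @param paths character vector of TSV paths.
#' @return data.frame `from`, `to`, `pathway` suitable for
#'   [merge_pathway_networks()].
#' @export
read_edge_lists <- function(paths) {
  parts <- lapply(paths, function(p) {
    el <- read_tsv(p)
    nm <- names(el)
    if (all(c("gene_a", "gene_b") %in% nm)) {
      names(el)[match(c("gene_a", "gene_b"), nm)] <- c("from", "to")
    }
    if (!all(c("from", "to") %in% names(el))) {
      stop_input("edge list ", p, " lacks from/to (or gene_a/gene_b) columns")
    }
    if (!"pathway" %in% names(el)) {
      el$pathway <- sub("\\.[^.]*$", "", basename(p))
    }
    el[, c("from", "to", "pathway")]
  })
  do.call(rbind, parts)
}

#' Write an edge list (optionally with provenance)
#' @param net a [network()] or a data.frame with `from`/`to`.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_edge_list <- function(net, path) {
  ed <- if (inherits(net, "myonet_network")) net$edges else net
  write_tsv(ed, path)
}

#' Read/write the drug-target table
#' @param path TSV path with columns `drug_id`, `drug_name`, `gene`,
#'   `max_phase`, `indication`, `has_moa`, `withdrawn`.
#' @return data.frame.
#' @export
read_drug_table <- function(path) {
  d <- read_tsv(path)
  req <- c("drug_id", "gene", "max_phase", "indication", "has_moa", "withdrawn")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop_input("drug table missing column(s): ", paste(miss, collapse = ", "))
  d$has_moa <- as.logical(d$has_moa)
  d$withdrawn <- as.logical(d$withdrawn)
  d
}

#' @rdname read_drug_table
#' @param drugs drug-target data.frame.
#' @export
write_drug_table <- function(drugs, path) write_tsv(drugs, path)

#' Write an annotated subnetwork as GraphML
#'
#' Node attributes carry the combined score and any per-timepoint log2 fold
#' changes and FDRs present in the result's `node_data`; edges carry pathway
#' provenance. Supports downstream rendering.
#'
#' @param subnet a `subnetwork_result` or a plain [network()].
#' @param path output GraphML path.
#' @return invisibly, the path.
#' @export
write_graphml <- function(subnet, path) {
  if (inherits(subnet, "subnetwork_result")) {
    g <- as_igraph(subnet$network, node_attrs = subnet$node_data)
  } else if (inherits(subnet, "myonet_network")) {
    g <- as_igraph(subnet)
  } else {
    stop_input("'subnet' must be a subnetwork_result or a network")
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML file as a network
#' @param path GraphML path.
#' @return list with `network` (a [network()]) and `node_data` (data.frame
#'   of node attributes, if any).
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  attrs <- igraph::as_data_frame(g, what = "vertices")
  list(network = from_igraph(g),
       node_data = if (ncol(attrs)) attrs else NULL)
}

#' Write truth labels from the simulator
#' @param truth data.frame `gene`, `group` (and optionally more).
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_truth_labels <- function(truth, path) write_tsv(truth, path)

#' @rdname write_truth_labels
#' @export
read_truth_labels <- function(path) read_tsv(path)
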