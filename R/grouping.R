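# Temporal grouping of differentially expressed genes by onset, persistence
# and direction across the three timepoints (early/mid/late).
#
# The seven groups and their call patterns (early, mid, late):
#   EPi (induced, induced, induced)   early onset, persists to the end
#   MPi (ns, induced, induced)        mid onset, persists
#   MPr (ns, repressed, repressed)
#   MTi (ns, induced, ns)             mid transient
#   MTr (ns, repressed, ns)
#   LTi (ns, ns, induced)             late transient
#   LTr (ns, ns, repressed)
# Any other non-null pattern (sign reversals, early-only, early+late without
# mid) is "unclassified"; genes never significant are excluded.

#' Default temporal group rules
#'
#' Named character vector mapping a compact call pattern (one letter per
#' timepoint: `i` induced, `r` repressed, `n` not significant, in timepoint
#' order) to a group label. Users may supply their own mapping to
#' [assign_groups()] to add or redefine categories.
#'
#' @return named character vector, e.g. `c(iii = "EPi", nii = "MPi", ...)`.
#' @export
group_rules <- function() {
  c(iii = "EPi",
    nii = "MPi", nrr = "MPr",
    nin = "MTi", nrn = "MTr",
    nni = "LTi", nnr = "LTr")
}

call_code <- c(induced = "i", repressed = "r", ns = "n")

#' Per-gene call patterns across timepoints
#'
#' Collates the per-timepoint DE calls into one pattern per gene. Genes
#' absent from a table are treated as `ns` at that timepoint.
#'
#' @param de_tables list of DE tables (from [test_differential()] or
#'   [call_de_table()]), one per timepoint, in increasing timepoint order.
#' @return data.frame with `gene`, one call column per timepoint, and
#'   `pattern` (compact code such as `"nii"`).
#' @export
call_patterns <- function(de_tables) {
  if (!is.list(de_tables) || length(de_tables) < 1) stop_input("'de_tables' must be a nonempty list")
  tps <- vapply(de_tables, function(d) as.character(d$timepoint[1] %||% NA), character(1))
  genes <- sort(unique(unlist(lapply(de_tables, function(d) d$gene))))
  calls <- matrix("ns", nrow = length(genes), ncol = length(de_tables),
                  dimnames = list(genes, paste0("c", tps)))
  for (j in seq_along(de_tables)) {
    d <- de_tables[[j]]
    if (!all(d$call %in% names(call_code))) {
      stop_input("unknown call symbol in DE table ", j)
    }
    calls[d$gene, j] <- d$call
  }
  pattern <- apply(calls, 1, function(r) paste(call_code[r], collapse = ""))
  out <- data.frame(gene = genes, calls, pattern = unname(pattern),
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Assign genes to temporal groups
#'
#' Maps each gene's call pattern to a group label under `rules`. Genes with
#' no significant call at any timepoint are excluded from the output; non-null
#' patterns matching no rule are labelled `"unclassified"`.
#'
#' @param patterns data.frame from [call_patterns()].
#' @param rules named pattern-to-label map; default [group_rules()].
#' @return data.frame `gene`, `pattern`, `group`.
#' @export
assign_groups <- function(patterns, rules = group_rules()) {
  if (!is.data.frame(patterns) || !all(c("gene", "pattern") %in% names(patterns))) {
    stop_input("'patterns' must come from call_patterns()")
  }
  if (!nrow(patterns)) {
    return(data.frame(gene = character(0), pattern = character(0),
                      group = character(0), stringsAsFactors = FALSE))
  }
  ok <- grepl("^[irn]+$", patterns$pattern)
  if (!all(ok)) stop_input("unknown call symbol in pattern(s): ",
                           paste(unique(patterns$pattern[!ok]), collapse = ", "))
  null_pat <- strrep("n", nchar(patterns$pattern[1]))
  keep <- patterns$pattern != null_pat
  p <- patterns[keep, , drop = FALSE]
  grp <- unname(rules[p$pattern])
  grp[is.na(grp)] <- "unclassified"
  data.frame(gene = p$gene, pattern = p$pattern, group = grp,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pattern intersection counts and group totals
#'
#' Tally of genes per non-null call pattern (all `3^t - 1` of them) plus the
#' per-group totals, the quantities behind an UpSet-style intersection plot.
#'
#' @inheritParams assign_groups
#' @return list with `patterns` (data.frame `pattern`, `count`) and
#'   `groups` (data.frame `group`, `count`; groups from `rules` plus
#'   `"unclassified"`). Group totals equal the sums of their constituent
#'   pattern counts.
#' @export
intersection_counts <- function(patterns, rules = group_rules()) {
  n_tp <- if (nrow(patterns)) nchar(patterns$pattern[1]) else 3L
  sym <- c("i", "r", "n")
  all_pat <- do.call(paste0, expand.grid(rep(list(sym), n_tp), stringsAsFactors = FALSE))
  all_pat <- sort(setdiff(all_pat, strrep("n", n_tp)))
  tab <- table(factor(patterns$pattern, levels = all_pat))
  pat_counts <- data.frame(pattern = all_pat, count = as.integer(tab),
                           stringsAsFactors = FALSE)
  grp <- assign_groups(patterns, rules)
  lvls <- c(unname(rules), "unclassified")
  gtab <- table(factor(grp$group, levels = lvls))
  list(patterns = pat_counts,
       groups = data.frame(group = lvls, count = as.integer(gtab),
                           stringsAsFactors = FALSE))
}
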