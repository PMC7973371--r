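# One-sided Fisher's exact (hypergeometric upper tail) pathway enrichment
# with Benjamini-Hochberg adjustment per pathway category.

#' Gene-set collection
#'
#' @param id character vector of unique set ids.
#' @param name display names (defaults to ids).
#' @param category category tags (e.g. KEGG top-level classes); recycled.
#' @param genes list of character vectors, one nonempty member set per id.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(id, genes, name = id, category = "pathway") {
  id <- as.character(id)
  if (anyDuplicated(id)) stop_input("duplicate set ids")
  if (!is.list(genes) || length(genes) != length(id)) {
    stop_input("'genes' must be a list parallel to 'id'")
  }
  if (any(lengths(genes) == 0)) stop_input("empty member set(s)")
  structure(list(id = id, name = rep_len(as.character(name), length(id)),
                 category = rep_len(as.character(category), length(id)),
                 genes = lapply(genes, as.character)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene set collection:", length(x$id), "sets;",
      "categories:", paste(unique(x$category), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$id)

#' One-sided Fisher's exact enrichment of one gene set
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' overlap between a gene group and a gene set, both intersected with the
#' universe first. The odds ratio is the sample OR of the 2x2 table with a
#' Haldane-Anscombe 0.5 correction when any cell is zero; the 95% CI is
#' Woolf's log-OR interval.
#'
#' @param group_genes character vector (e.g. one temporal group).
#' @param set_genes character vector (pathway members).
#' @param universe nonempty character vector of testable genes.
#' @return one-row data.frame: `overlap`, `group_size`, `set_size`,
#'   `universe_size`, `odds_ratio`, `ci_lo`, `ci_hi`, `p`.
#' @export
fisher_enrich <- function(group_genes, set_genes, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop_input("empty universe")
  grp <- intersect(unique(as.character(group_genes)), universe)
  set <- intersect(unique(as.character(set_genes)), universe)
  N <- length(universe); g <- length(grp); m <- length(set)
  k <- length(intersect(grp, set))
  # P(X >= k) drawing g from N with m successes
  p <- if (k == 0) 1 else phyper(k - 1, m, N - m, g, lower.tail = FALSE)
  p <- min(max(p, 0), 1)
  a <- k; b <- g - k; c <- m - k; d <- N - g - m + k
  if (min(a, b, c, d) == 0) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  data.frame(overlap = k, group_size = g, set_size = m, universe_size = N,
             odds_ratio = or,
             ci_lo = exp(log(or) - 1.96 * se),
             ci_hi = exp(log(or) + 1.96 * se),
             p = p, stringsAsFactors = FALSE)
}

#' Enrichment of every gene group against every gene set
#'
#' Runs [fisher_enrich()] for each (group, set) pair and adjusts p-values by
#' Benjamini-Hochberg, by default within each pathway category (mirroring
#' enrichment run separately per category), optionally globally.
#'
#' @param groups data.frame `gene`, `group` (from [assign_groups()]), or a
#'   named list of gene vectors keyed by group label.
#' @param collection a [gene_set_collection()].
#' @param universe character vector of testable genes.
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @param adjust_scope `"category"` (default) or `"global"`.
#' @return data.frame with one row per (group, set): `group`, `set_id`,
#'   `set_name`, `category`, the [fisher_enrich()] columns, `padj`,
#'   `significant`.
#' @export
enrich_all <- function(groups, collection, universe, alpha = 0.05,
                       adjust_scope = c("category", "global")) {
  adjust_scope <- match.arg(adjust_scope)
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.data.frame(groups)) {
    groups <- split(groups$gene, groups$group)
  }
  if (!length(groups) || !length(collection$id)) {
    return(data.frame(group = character(0), set_id = character(0),
                      set_name = character(0), category = character(0),
                      overlap = integer(0), group_size = integer(0),
                      set_size = integer(0), universe_size = integer(0),
                      odds_ratio = numeric(0), ci_lo = numeric(0),
                      ci_hi = numeric(0), p = numeric(0), padj = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  rows <- list()
  for (glab in names(groups)) {
    for (i in seq_along(collection$id)) {
      r <- fisher_enrich(groups[[glab]], collection$genes[[i]], universe)
      r <- cbind(data.frame(group = glab, set_id = collection$id[i],
                            set_name = collection$name[i],
                            category = collection$category[i],
                            stringsAsFactors = FALSE), r)
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out$padj <- NA_real_
  if (adjust_scope == "category") {
    for (cat in unique(out$category)) {
      sel <- out$category == cat
      out$padj[sel] <- adjust_bh(out$p[sel])
    }
  } else {
    out$padj <- adjust_bh(out$p)
  }
  out$significant <- out$padj < alpha
  out <- out[order(out$category, out$padj, out$p, out$group, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
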