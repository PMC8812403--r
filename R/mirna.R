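# miRNA-target network construction --------------------------------------
#
# Target maps come from prediction-database exports (two-column TSV or
# GMT-like files); the pipeline filters to multi-target miRNAs, pools
# miRNA families (union of member target sets), ranks by target count and
# emits a degree-filtered bipartite network, optionally annotated with
# differential-expression calls.

#' Construct a miRNA target map
#'
#' @param targets Named list: miRNA id -> character vector of target
#'   genes (non-empty, deduplicated).
#' @param family Optional named character vector mapping miRNA id to
#'   family id (NA = no family).
#' @return Object of class `mirna_target_map`.
#' @export
mirna_target_map <- function(targets, family = NULL) {
  stopifnot(is.list(targets), !is.null(names(targets)))
  if (anyDuplicated(names(targets))) stop("duplicate miRNA ids")
  targets <- lapply(targets, function(g) sort(unique(as.character(g))))
  if (any(lengths(targets) == 0)) stop("empty target set")
  if (is.null(family))
    family <- setNames(rep(NA_character_, length(targets)), names(targets))
  fam <- setNames(rep(NA_character_, length(targets)), names(targets))
  fam[intersect(names(family), names(fam))] <-
    family[intersect(names(family), names(fam))]
  structure(list(targets = targets, family = fam),
            class = "mirna_target_map")
}

#' @export
print.mirna_target_map <- function(x, ...) {
  cat(sprintf("miRNA target map: %d miRNAs, %d distinct genes, %d families\n",
              length(x$targets), length(unique(unlist(x$targets))),
              length(unique(stats::na.omit(x$family)))))
  invisible(x)
}

#' Read a target map from a two-column TSV or GMT-like file
#'
#' TSV: columns `mirna`, `gene` (header optional, detected); GMT: one line
#' per miRNA, tab-separated `id`, `description`, genes...
#'
#' @param path Input file.
#' @param format `"tsv"` or `"gmt"`.
#' @param family Optional named family vector (see [mirna_target_map()]).
#' @return A `mirna_target_map`.
#' @export
read_target_map <- function(path, format = c("tsv", "gmt"), family = NULL) {
  format <- match.arg(format)
  if (format == "gmt") {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    targets <- lapply(parts, function(p) p[-(1:2)])
    names(targets) <- vapply(parts, `[`, "", 1)
  } else {
    first <- strsplit(readLines(path, n = 1), "\t")[[1]]
    has_header <- identical(tolower(first[1:2]), c("mirna", "gene"))
    df <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
    names(df)[1:2] <- c("mirna", "gene")
    targets <- split(df$gene, df$mirna)
  }
  mirna_target_map(targets, family = family)
}

#' Keep only miRNAs targeting more than one panel gene
#'
#' @param map A `mirna_target_map`.
#' @param gene_universe Optional gene panel; target sets are intersected
#'   with it before counting (the ">1 gene" rule is applied after
#'   restriction to the analyzed panel).
#' @return Filtered `mirna_target_map` (possibly empty).
#' @export
filter_multi_target <- function(map, gene_universe = NULL) {
  stopifnot(inherits(map, "mirna_target_map"))
  t <- map$targets
  if (!is.null(gene_universe))
    t <- lapply(t, intersect, y = gene_universe)
  keep <- lengths(t) >= 2
  structure(list(targets = t[keep], family = map$family[names(t)[keep]]),
            class = "mirna_target_map")
}

#' Pool miRNA families into single nodes
#'
#' Families with >= 2 members collapse to one node named after the family
#' whose target set is the union of member sets; miRNAs without a family
#' or in singleton families pass through unchanged.
#'
#' @param map A `mirna_target_map`.
#' @return A family-resolution `mirna_target_map`.
#' @export
pool_families <- function(map) {
  stopifnot(inherits(map, "mirna_target_map"))
  fam <- map$family[names(map$targets)]
  tab <- table(fam[!is.na(fam)])
  pooled_fams <- names(tab)[tab >= 2]
  keep <- is.na(fam) | !(fam %in% pooled_fams)
  out <- map$targets[keep]
  out_fam <- fam[keep]
  for (f in sort(pooled_fams)) {
    members <- names(map$targets)[!is.na(fam) & fam == f]
    out[[f]] <- sort(unique(unlist(map$targets[members])))
    out_fam[f] <- f
  }
  mirna_target_map(out, family = out_fam)
}

#' Rank miRNAs/families by number of targeted genes
#'
#' @param map A `mirna_target_map`.
#' @return Data frame `id`, `n_targets`, descending count then
#'   alphabetical id.
#' @export
rank_by_target_count <- function(map) {
  stopifnot(inherits(map, "mirna_target_map"))
  if (!length(map$targets))
    return(data.frame(id = character(0), n_targets = integer(0)))
  out <- data.frame(id = names(map$targets),
                    n_targets = unname(lengths(map$targets)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_targets, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Degree-filtered bipartite miRNA-gene network
#'
#' Keeps the miRNA/family nodes with `degree >= min_degree`, or — when
#' `include_de_below_min` — any node flagged in the differential
#' expression table regardless of degree.  The DE direction is attached
#' per node.
#'
#' @param map A `mirna_target_map` (typically filtered and pooled).
#' @param min_degree Minimum target count (>= 1; conventionally 3).
#' @param de_table Optional [mirna_fold_change()] data frame (columns
#'   `mirna`, `fold`, `direction`, `p_value`); unknown ids are warned
#'   about but kept.
#' @param include_de_below_min Keep DE miRNAs below the degree cutoff.
#' @return List: `edges` (data frame `mirna`, `gene`), `node_attrs`
#'   (per-miRNA degree and DE annotation).
#' @export
build_mirna_network <- function(map, min_degree = 3, de_table = NULL,
                                include_de_below_min = TRUE) {
  stopifnot(inherits(map, "mirna_target_map"))
  if (min_degree < 1) stop("degree threshold must be >= 1")
  deg <- lengths(map$targets)
  de_ids <- character(0)
  if (!is.null(de_table)) {
    unknown <- setdiff(de_table$mirna, names(map$targets))
    if (length(unknown))
      warning("DE table references unknown miRNA(s): ",
              paste(unknown, collapse = ", "))
    de_ids <- intersect(de_table$mirna, names(map$targets))
  }
  keep <- deg >= min_degree
  if (include_de_below_min) keep <- keep | names(deg) %in% de_ids
  ids <- names(deg)[keep]
  edges <- do.call(rbind, c(list(
    data.frame(mirna = character(0), gene = character(0))),
    lapply(ids, function(m)
      data.frame(mirna = m, gene = map$targets[[m]],
                 stringsAsFactors = FALSE))))
  attrs <- data.frame(mirna = ids, degree = unname(deg[ids]),
                      de = ids %in% de_ids,
                      direction = rep(NA_character_, length(ids)),
                      stringsAsFactors = FALSE)
  if (!is.null(de_table)) {
    idx <- match(attrs$mirna, de_table$mirna)
    attrs$direction <- de_table$direction[idx]
  }
  rownames(edges) <- NULL
  list(edges = edges, node_attrs = attrs)
}

#' Fold change of miRNA counts between two groups (stand-in DE)
#'
#' Library-size normalization (counts per million of the column total)
#' then per-miRNA fold = normalized mean(case) / mean(control), with a
#' two-sided Mann-Whitney p on the normalized counts.  This is an
#' explicitly simplified stand-in for a dedicated count-model DE method
#' and is labelled as such in the output.
#'
#' @param counts_case,counts_control Count matrices, miRNAs x samples.
#' @return Data frame: `mirna`, `fold` (>0, Inf flagged), `direction`
#'   (`up`/`down`), `p_value`, `method` tag.
#' @export
mirna_fold_change <- function(counts_case, counts_control) {
  stopifnot(is.matrix(counts_case), is.matrix(counts_control),
            identical(rownames(counts_case), rownames(counts_control)))
  norm <- function(m) sweep(m, 2, colSums(m), "/") * 1e6
  a <- norm(counts_case); b <- norm(counts_control)
  rows <- lapply(rownames(a), function(mi) {
    ma <- mean(a[mi, ]); mb <- mean(b[mi, ])
    fold <- if (mb == 0) Inf else ma / mb
    p <- if (all(a[mi, ] == a[mi, 1]) && all(b[mi, ] == b[mi, 1]) &&
             a[mi, 1] == b[mi, 1]) 1
         else mann_whitney(a[mi, ], b[mi, ])$p_value
    data.frame(mirna = mi, fold = fold,
               direction = if (fold >= 1) "up" else "down",
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$method <- "normalized-mean ratio + Mann-Whitney (stand-in)"
  rownames(out) <- NULL
  out
}
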