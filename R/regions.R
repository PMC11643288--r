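#' Read a cis-regulatory-element (CRE) prediction table
#'
#' Tab-separated table following Activity-by-Contact (ABC) output
#' conventions, with columns `chr`, `start`, `end` (half-open, 0-based),
#' `class` (enhancer/promoter), `TargetGene`, `CellType`, `ABC.Score`.
#' Records with `end <= start` are rejected with a warning.
#'
#' @param path Path to the TSV file.
#' @return data.frame of CRE records.
#' @export
read_cre_table <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  need <- c("chr", "start", "end", "class", "TargetGene", "CellType",
            "ABC.Score")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("CRE table missing column(s): ", paste(missing_cols, collapse = ", "))
  bad <- tab$end <= tab$start
  if (any(bad)) {
    warning(sum(bad), " CRE record(s) with end <= start rejected")
    tab <- tab[!bad, , drop = FALSE]
  }
  if (any(tab$`ABC.Score` < 0)) stop("negative ABC scores in CRE table")
  tab
}

# unify "chr1" vs "1" naming; errors when both inputs still disagree
normalize_contigs <- function(x, style = c("keep", "strip_chr", "add_chr")) {
  style <- match.arg(style)
  x <- as.character(x)
  switch(style,
         keep = x,
         strip_chr = sub("^chr", "", x),
         add_chr = ifelse(grepl("^chr", x), x, paste0("chr", x)))
}

#' Build per-gene rare-variant sets from CRE predictions
#'
#' For one cell type, aggregates all CREs targeting a gene with ABC score
#' at or above `abc_min` (default 0.02) and collects the rare variants
#' falling inside any of those elements. A variant inside CREs of several
#' genes is assigned to every such gene; genes with zero qualifying
#' variants are omitted. Interval membership uses the variant POS
#' (1-based) converted to a 0-based point inside the half-open CRE
#' interval; indels are tested by start position only.
#'
#' @param cres data.frame from [read_cre_table()].
#' @param block A [genotype_block] on the same genome build.
#' @param cell_type Cell type to select from the table.
#' @param abc_min ABC score threshold, applied as `>=` (default 0.02).
#' @param contig_style Contig-name normalization applied to both inputs:
#'   `"keep"`, `"strip_chr"` or `"add_chr"`.
#' @return Named list: one `gene_region_set` (gene, cell_type, intervals,
#'   variant_ids, variant_idx) per gene with at least one variant.
#' @export
build_gene_sets <- function(cres, block, cell_type, abc_min = 0.02,
                            contig_style = "keep") {
  cres <- cres[cres$CellType == cell_type & cres$`ABC.Score` >= abc_min, ,
               drop = FALSE]
  if (nrow(cres) == 0L) return(structure(list(), names = character()))
  cre_chr <- normalize_contigs(cres$chr, contig_style)
  var_chr <- normalize_contigs(block$positions$contig, contig_style)
  if (length(intersect(cre_chr, var_chr)) == 0L &&
      nrow(block$positions) > 0L)
    stop("no shared contig names between CRE table and genotypes; ",
         "check naming style (chr1 vs 1)")
  pos0 <- block$positions$pos - 1L   # 1-based POS -> 0-based point
  out <- list()
  for (chr in unique(cre_chr)) {
    ci <- which(cre_chr == chr)
    vi <- which(var_chr == chr)
    if (length(vi) == 0L) next
    # half-open [start, end) with integer ranges: point p is inside iff
    # start <= p <= end - 1
    ir_cre <- IRanges::IRanges(start = cres$start[ci], end = cres$end[ci] - 1L)
    ir_var <- IRanges::IRanges(start = pos0[vi], width = 1L)
    hits <- IRanges::findOverlaps(ir_var, ir_cre)
    if (length(hits) == 0L) next
    vh <- vi[S4Vectors::queryHits(hits)]
    ch <- ci[S4Vectors::subjectHits(hits)]
    genes <- cres$TargetGene[ch]
    for (g in unique(genes)) {
      vids <- unique(vh[genes == g])
      out[[g]] <- c(out[[g]], vids)
    }
  }
  sets <- lapply(names(out), function(g) {
    idx <- sort(unique(out[[g]]))
    gi <- cres$TargetGene == g
    structure(list(gene = g, cell_type = cell_type,
                   intervals = cres[gi, c("chr", "start", "end", "class",
                                          "ABC.Score")],
                   variant_ids = block$variant_ids[idx],
                   variant_idx = idx),
              class = "gene_region_set")
  })
  names(sets) <- names(out)
  sets
}

#' @export
print.gene_region_set <- function(x, ...) {
  cat("gene_region_set:", x$gene, "(", x$cell_type, ")",
      nrow(x$intervals), "CREs,", length(x$variant_ids), "variants\n")
  invisible(x)
}

#' Cross-cell-type variant overlap report
#'
#' Upset-style summary: for every nonempty combination of cell types, the
#' number of variants exclusive to exactly that combination. Counts sum
#' to the size of the union of all per-cell-type variant sets.
#'
#' @param gene_sets_by_cell_type Named list (cell type -> list of
#'   `gene_region_set`s as returned by [build_gene_sets()]), or a named
#'   list of variant-id character vectors.
#' @return data.frame with columns `combination`, `n_cell_types`, `count`.
#' @export
overlap_report <- function(gene_sets_by_cell_type) {
  stopifnot(length(gene_sets_by_cell_type) >= 1L)
  var_sets <- lapply(gene_sets_by_cell_type, function(ct) {
    if (is.character(ct)) return(unique(ct))
    unique(unlist(lapply(ct, `[[`, "variant_ids"), use.names = FALSE))
  })
  all_vars <- unique(unlist(var_sets, use.names = FALSE))
  membership <- vapply(var_sets, function(s) all_vars %in% s,
                       logical(length(all_vars)))
  membership <- matrix(membership, nrow = length(all_vars),
                       dimnames = list(NULL, names(var_sets)))
  key <- apply(membership, 1L, function(m)
    paste(colnames(membership)[m], collapse = "+"))
  counts <- table(key)
  data.frame(combination = names(counts),
             n_cell_types = lengths(strsplit(names(counts), "+",
                                             fixed = TRUE)),
             count = as.integer(counts),
             row.names = NULL)
}

#' Export per-gene region sets as BED6
#'
#' @param gene_sets List of `gene_region_set`s.
#' @param path Output path.
#' @return Invisibly, the written data.frame.
#' @export
write_gene_sets_bed <- function(gene_sets, path) {
  rows <- do.call(rbind, lapply(gene_sets, function(gs) {
    data.frame(chrom = gs$intervals$chr, chromStart = gs$intervals$start,
               chromEnd = gs$intervals$end, name = gs$gene,
               score = round(1000 * gs$intervals$`ABC.Score`),
               strand = ".")
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(rows)
}
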