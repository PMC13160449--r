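#' Cross-modality feature linkage
#'
#' An ordered set of feature index pairs declaring which column of the first
#' modality is linked to which column of the second, together with the
#' linkage ratio rho = min(p_link/px, p_link/py) that classifies the pair of
#' datasets as weakly (rho < 0.10) or strongly linked.
#'
#' @param pairs two-column integer matrix (x feature index, y feature index).
#' @param px,py total feature counts of the two modalities.
#' @param x_names,y_names optional feature names for display.
#' @return An object of class `feature_linkage` with `pairs`, `p_link`,
#'   `rho`, `category`.
#' @export
feature_linkage <- function(pairs, px, py, x_names = NULL, y_names = NULL) {
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("x_feature", "y_feature")))
  if (nrow(pairs) == 0) stop_mmihcl("no linked features")
  if (any(pairs[, 1] < 1 | pairs[, 1] > px) ||
      any(pairs[, 2] < 1 | pairs[, 2] > py))
    stop_mmihcl("linkage pair indices out of range")
  if (anyDuplicated(pairs)) pairs <- pairs[!duplicated(pairs), , drop = FALSE]
  p_link <- nrow(pairs)
  if (p_link > min(px, py))
    stop_mmihcl("p_link exceeds min(px, py)")
  lr <- linkage_ratio(p_link, px, py)
  structure(list(pairs = pairs, p_link = p_link, px = px, py = py,
                 rho = lr$rho, category = lr$category,
                 x_names = x_names, y_names = y_names),
            class = "feature_linkage")
}

#' @export
print.feature_linkage <- function(x, ...) {
  cat(sprintf("<feature_linkage> %d pairs, rho = %.4f (%s linkage)\n",
              x$p_link, x$rho, x$category))
  invisible(x)
}

#' Linkage ratio and weak/strong categorization
#'
#' rho = min(p_link / px, p_link / py). Two modalities are weakly linked
#' when rho < 0.10 and strongly linked otherwise.
#'
#' @param p_link number of linked feature pairs.
#' @param px,py total feature counts.
#' @return list with `rho` and `category` ("weak" or "strong").
#' @examples
#' linkage_ratio(50, 2000, 100)  # rho = 0.025, weak
#' @export
linkage_ratio <- function(p_link, px, py) {
  if (px < 1 || py < 1) stop_mmihcl("px and py must be >= 1")
  if (p_link < 0 || p_link > min(px, py))
    stop_mmihcl("p_link must lie in [0, min(px, py)]")
  rho <- min(p_link / px, p_link / py)
  list(rho = rho, category = if (rho < 0.10) "weak" else "strong")
}

#' Link features shared by name between two modalities
#'
#' One pair per feature name present in both modalities (exact, case
#' sensitive by default; protein panels with nonstandard capitalization can
#' opt into case-insensitive matching).
#'
#' @param x,y [modality_matrix()] objects.
#' @param ignore_case match names case-insensitively.
#' @return A [feature_linkage()].
#' @export
link_by_name <- function(x, y, ignore_case = FALSE) {
  fx <- x$feature_ids; fy <- y$feature_ids
  kx <- if (ignore_case) tolower(fx) else fx
  ky <- if (ignore_case) tolower(fy) else fy
  shared <- intersect(kx, ky)
  if (length(shared) == 0)
    stop_mmihcl("no linked features: feature name sets are disjoint")
  ix <- match(shared, kx)
  iy <- match(shared, ky)
  feature_linkage(cbind(ix, iy), length(fx), length(fy),
                  x_names = fx[ix], y_names = fy[iy])
}

#' Link genes to their encoded proteins via an explicit map
#'
#' @param x modality holding gene features (e.g. RNA).
#' @param y modality holding protein features.
#' @param map_table two-column data frame or TSV path, columns
#'   (gene_name, protein_name). Rows whose gene is absent from `x` or whose
#'   protein is absent from `y` are skipped; duplicate rows are deduplicated.
#' @param ignore_case match names case-insensitively.
#' @return A [feature_linkage()].
#' @export
link_gene_protein <- function(x, y, map_table, ignore_case = FALSE) {
  if (is.character(map_table) && length(map_table) == 1)
    map_table <- read.delim(map_table, header = TRUE, colClasses = "character")
  map_table <- as.data.frame(map_table)
  if (ncol(map_table) != 2)
    stop_mmihcl("gene-protein map must have exactly 2 columns, got ",
                ncol(map_table))
  map_table <- unique(map_table)
  g <- as.character(map_table[[1]]); pr <- as.character(map_table[[2]])
  kx <- if (ignore_case) tolower(x$feature_ids) else x$feature_ids
  ky <- if (ignore_case) tolower(y$feature_ids) else y$feature_ids
  if (ignore_case) { g <- tolower(g); pr <- tolower(pr) }
  ix <- match(g, kx); iy <- match(pr, ky)
  keep <- !is.na(ix) & !is.na(iy)
  if (!any(keep))
    stop_mmihcl("no linked features: no map row resolves in both modalities")
  feature_linkage(cbind(ix[keep], iy[keep]),
                  length(kx), length(ky),
                  x_names = x$feature_ids[ix[keep]],
                  y_names = y$feature_ids[iy[keep]])
}

#' Gene annotation table
#'
#' Internal coordinate convention is 0-based half-open `[start, end)`; BED
#' input is taken as-is and GTF input converted on read (1-based inclusive
#' start minus one).
#'
#' @param gene_id,chrom,strand,start,end equal-length vectors; `strand` in
#'   `{+,-}`; `start < end`.
#' @return data frame of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, strand, start, end) {
  df <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   strand = as.character(strand),
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop_mmihcl("strand must be '+' or '-'")
  if (any(df$start >= df$end)) stop_mmihcl("annotation requires start < end")
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read a gene annotation from BED or GTF
#'
#' @param path annotation file.
#' @param format `"bed"` (0-based half-open, name column = gene id) or
#'   `"gtf"` (1-based inclusive, converted on read; records filtered to
#'   `feature_type`, gene names taken from `gene_name` falling back to
#'   `gene_id`).
#' @param feature_type GTF feature type to keep.
#' @return A [gene_annotation()].
#' @export
read_gene_annotation <- function(path, format = c("bed", "gtf"),
                                 feature_type = "gene") {
  format <- match.arg(format)
  if (!file.exists(path)) stop_mmihcl("file not found: ", path)
  if (format == "bed") {
    df <- read.delim(path, header = FALSE, comment.char = "#",
                     colClasses = "character")
    if (ncol(df) < 6)
      stop_mmihcl("BED annotation needs >= 6 columns (chrom, start, end, name, score, strand)")
    gene_annotation(df[[4]], df[[1]], df[[6]],
                    as.numeric(df[[2]]), as.numeric(df[[3]]))
  } else {
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
      gr <- rtracklayer::import(path, format = "gtf")
      gr <- gr[gr$type == feature_type]
      ids <- gr$gene_name %||% gr$gene_id
      ids[is.na(ids)] <- gr$gene_id[is.na(ids)]
      gene_annotation(ids, as.character(GenomicRanges::seqnames(gr)),
                      as.character(GenomicRanges::strand(gr)),
                      GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
    } else {
      df <- read.delim(path, header = FALSE, comment.char = "#",
                       colClasses = "character")
      df <- df[df[[3]] == feature_type, , drop = FALSE]
      ids <- sub('.*gene_name "([^"]+)".*', "\\1", df[[9]])
      noname <- !grepl('gene_name "', df[[9]])
      ids[noname] <- sub('.*gene_id "([^"]+)".*', "\\1", df[[9]][noname])
      gene_annotation(ids, df[[1]], df[[7]],
                      as.numeric(df[[4]]) - 1, as.numeric(df[[5]]))
    }
  }
}

# Parse "chrom:start-end" region ids (0-based half-open).
parse_region_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop_mmihcl("unparseable region id(s): ",
                paste(head(ids[bad], 3), collapse = ", "))
  data.frame(chrom = vapply(m, `[`, "", 2),
             start = as.numeric(vapply(m, `[`, "", 3)),
             end = as.numeric(vapply(m, `[`, "", 4)))
}

#' Link chromatin-accessibility regions to genes
#'
#' An ATAC region is assigned to a gene when it overlaps the gene body or
#' the strand-aware upstream window of `upstream_bp` base pairs before the
#' transcription start (plus strand: `[start - upstream_bp, start)`; minus
#' strand: `[end, end + upstream_bp)`; 0-based half-open throughout). All
#' regions assigned to a gene are collapsed (summed by default) into one
#' gene-activity feature, which is linked to the same-named gene in the RNA
#' modality. A region overlapping several genes contributes to each.
#'
#' @param x_atac ATAC modality whose feature ids parse as `"chrom:start-end"`.
#' @param y_rna RNA modality with gene-name features.
#' @param annotation a [gene_annotation()] covering the RNA gene names.
#' @param upstream_bp length of the upstream activation window (default 2000).
#' @param combine `"sum"` (default) or `"mean"` over a gene's regions.
#' @return list with `x` (a new [modality_matrix()] whose leading features
#'   are the gene-activity columns, followed by unassigned original
#'   regions) and `linkage` (a [feature_linkage()] pairing each
#'   gene-activity column with its RNA gene).
#' @export
link_region_gene <- function(x_atac, y_rna, annotation, upstream_bp = 2000,
                             combine = c("sum", "mean")) {
  combine <- match.arg(combine)
  reg <- parse_region_ids(x_atac$feature_ids)
  ann <- annotation[annotation$gene_id %in% y_rna$feature_ids, , drop = FALSE]
  if (nrow(ann) == 0)
    stop_mmihcl("annotation covers none of the RNA gene names")
  # extended gene interval = body plus strand-aware upstream window
  ext_start <- ifelse(ann$strand == "+", pmax(0, ann$start - upstream_bp), ann$start)
  ext_end <- ifelse(ann$strand == "+", ann$end, ann$end + upstream_bp)
  qry <- GenomicRanges::GRanges(reg$chrom,
                                IRanges::IRanges(reg$start + 1, reg$end))
  sbj <- GenomicRanges::GRanges(ann$chrom,
                                IRanges::IRanges(ext_start + 1, ext_end))
  ov <- GenomicRanges::findOverlaps(qry, sbj)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  if (length(qh) == 0)
    stop_mmihcl("no linked features: no region overlaps any gene window")
  vals <- as_dense_values(x_atac)
  genes <- sort(unique(ann$gene_id[sh]))
  act <- matrix(0, nrow(vals), length(genes),
                dimnames = list(x_atac$cell_ids, genes))
  counts <- integer(length(genes))
  for (g in seq_along(genes)) {
    ridx <- unique(qh[ann$gene_id[sh] == genes[g]])
    counts[g] <- length(ridx)
    act[, g] <- rowSums(vals[, ridx, drop = FALSE])
    if (combine == "mean") act[, g] <- act[, g] / length(ridx)
  }
  assigned <- unique(qh)
  rest <- vals[, -assigned, drop = FALSE]
  new_vals <- cbind(act, rest)
  new_x <- modality_matrix(new_vals,
                           feature_ids = c(genes, x_atac$feature_ids[-assigned]),
                           cell_ids = x_atac$cell_ids,
                           cell_type_labels = x_atac$cell_type_labels,
                           modality_tag = x_atac$modality_tag)
  iy <- match(genes, y_rna$feature_ids)
  linkage <- feature_linkage(cbind(seq_along(genes), iy),
                             ncol(new_vals), length(y_rna$feature_ids),
                             x_names = genes, y_names = genes)
  list(x = new_x, linkage = linkage)
}
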