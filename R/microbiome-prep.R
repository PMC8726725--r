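# Microbiome preprocessing: count table -> genus-level, prevalence-filtered,
# relative-abundance composition matrix (one LICA modality).

#' Construct an abundance table
#'
#' A sample x taxon matrix of non-negative integer read counts with a
#' semicolon-ranked taxonomy lineage string per taxon, as produced by 16S
#' profiling pipelines.
#'
#' @param counts sample x taxon numeric matrix of non-negative counts.
#' @param taxonomy character vector of lineage strings, one per taxon
#'   (e.g. `"k__Bacteria;p__Firmicutes;...;g__Blautia"`).
#' @param sample_ids,taxon_ids unique label vectors; default to the matrix
#'   dimnames or generated labels.
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(counts, taxonomy,
                            sample_ids = rownames(counts),
                            taxon_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(counts)))
  if (is.null(taxon_ids)) taxon_ids <- sprintf("OTU%04d", seq_len(ncol(counts)))
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0)) {
    bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
    stop(sprintf("counts must be finite and non-negative; offending cell: sample '%s', taxon '%s'",
                 sample_ids[bad[1, 1]], taxon_ids[bad[1, 2]]))
  }
  if (length(taxonomy) != ncol(counts)) {
    stop("taxonomy must have one lineage string per taxon")
  }
  if (anyDuplicated(sample_ids) || anyDuplicated(taxon_ids)) {
    stop("sample and taxon labels must be unique")
  }
  dimnames(counts) <- list(sample_ids, taxon_ids)
  structure(list(counts = counts, taxonomy = as.character(taxonomy),
                 sample_ids = as.character(sample_ids),
                 taxon_ids = as.character(taxon_ids)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa, %s total reads\n",
              nrow(x$counts), ncol(x$counts), format(sum(x$counts))))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Construct a composition table (relative abundances on the simplex)
#'
#' @param relabund sample x genus matrix of proportions.
#' @param genus_ids,sample_ids label vectors.
#' @param renormalized logical; `FALSE` marks tables whose proportions were
#'   computed before a filter and deliberately not rescaled, in which case
#'   rows may sum to less than 1 and the row-sum check is skipped.
#' @return an object of class `composition_table`.
#' @export
composition_table <- function(relabund, genus_ids = colnames(relabund),
                              sample_ids = rownames(relabund),
                              renormalized = TRUE) {
  relabund <- as.matrix(relabund)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(relabund)))
  if (is.null(genus_ids)) genus_ids <- sprintf("G%03d", seq_len(ncol(relabund)))
  if (any(relabund < -1e-12) || any(relabund > 1 + 1e-12)) {
    stop("relative abundances must lie in [0, 1]")
  }
  if (isTRUE(renormalized)) {
    rs <- rowSums(relabund)
    if (any(abs(rs - 1) > 1e-9)) {
      stop(sprintf("composition rows must sum to 1 (worst deviation %.3g in sample '%s')",
                   max(abs(rs - 1)), sample_ids[which.max(abs(rs - 1))]))
    }
  }
  dimnames(relabund) <- list(sample_ids, genus_ids)
  structure(list(relabund = relabund, genus_ids = as.character(genus_ids),
                 sample_ids = as.character(sample_ids),
                 renormalized = isTRUE(renormalized)),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("composition_table: %d samples x %d genera%s\n",
              nrow(x$relabund), ncol(x$relabund),
              if (x$renormalized) "" else " (not renormalized after filtering)"))
  invisible(x)
}

# ---------------------------------------------------------------------------
# I/O

#' Read a taxon count table from TSV or BIOM
#'
#' The TSV dialect has taxa as rows, the taxon id in the first column and the
#' taxonomy lineage in the last column (header `taxonomy`); remaining columns
#' are samples. BIOM v1 (JSON) files are read through the biomformat package,
#' taking taxonomy from the observation metadata.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"biom"`.
#' @return an [abundance_table()].
#' @export
read_abundance <- function(path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  }
  if (format == "biom") {
    b <- biomformat::read_biom(path)
    counts <- t(as.matrix(biomformat::biom_data(b)))  # -> sample x taxon
    md <- biomformat::observation_metadata(b)
    taxonomy <- if (is.null(md)) {
      rep("", ncol(counts))
    } else if (is.data.frame(md)) {
      apply(md, 1, function(r) paste(r[!is.na(r) & nzchar(r)], collapse = ";"))
    } else {
      vapply(md, function(r) paste(unlist(r), collapse = ";"), character(1))
    }
    return(abundance_table(counts, taxonomy = unname(taxonomy)))
  }
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("TSV table needs taxon id, at least one sample, and taxonomy columns")
  tax_col <- ncol(df)
  if (!grepl("taxonomy", names(df)[tax_col], ignore.case = TRUE)) {
    stop("last TSV column must be the taxonomy lineage (header 'taxonomy')")
  }
  taxon_ids <- as.character(df[[1]])
  taxonomy <- as.character(df[[tax_col]])
  num <- df[, -c(1L, tax_col), drop = FALSE]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    if (any(is.na(v) & !is.na(num[[j]]))) {
      i <- which(is.na(v) & !is.na(num[[j]]))[1]
      stop(sprintf("non-numeric count in sample '%s', taxon '%s': '%s'",
                   names(num)[j], taxon_ids[i], num[[j]][i]))
    }
    num[[j]] <- v
  }
  counts <- t(as.matrix(num))  # samples x taxa
  colnames(counts) <- taxon_ids
  abundance_table(counts, taxonomy = taxonomy)
}

#' Write a taxon count table
#'
#' @param table an [abundance_table()].
#' @param path output path; format chosen as in [read_abundance()].
#' @param format `"auto"`, `"tsv"` or `"biom"`.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(table, path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  }
  if (format == "biom") {
    md <- data.frame(taxonomy = table$taxonomy, row.names = table$taxon_ids,
                     stringsAsFactors = FALSE)
    b <- biomformat::make_biom(data = t(table$counts), observation_metadata = md)
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  df <- data.frame(`#OTU ID` = table$taxon_ids, t(table$counts),
                   taxonomy = table$taxonomy, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("#OTU ID", table$sample_ids, "taxonomy")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Taxonomy handling

# Extract the genus label from one lineage string. Supports rank-prefixed
# lineages ("k__...;g__Blautia") and plain semicolon lists (6th field = genus).
# A missing/empty genus yields "unclassified_<lowest named rank>".
genus_of <- function(lineage) {
  toks <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  if (length(toks) == 0L || all(!nzchar(toks))) return("unclassified_unknown")
  prefixed <- grepl("^[a-zA-Z]__", toks)
  if (any(prefixed)) {
    g <- toks[grepl("^g__", toks)]
    name <- if (length(g)) sub("^g__", "", g[1]) else ""
    if (nzchar(name)) return(name)
    named <- toks[prefixed & nzchar(sub("^[a-zA-Z]__", "", toks)) & !grepl("^s__", toks)]
    low <- if (length(named)) sub("^[a-zA-Z]__", "", named[length(named)]) else "unknown"
    return(paste0("unclassified_", low))
  }
  if (length(toks) >= 6L && nzchar(toks[6])) return(toks[6])
  named <- toks[nzchar(toks)]
  low <- if (length(named)) named[min(length(named), 5L)] else "unknown"
  paste0("unclassified_", low)
}

#' Aggregate a count table to genus level
#'
#' Counts of taxa sharing a genus label are summed per sample. Taxa whose
#' lineage has no named genus are pooled under their lowest named rank,
#' prefixed `unclassified_`.
#'
#' @param table an [abundance_table()].
#' @return an [abundance_table()] with one column per genus; the taxonomy slot
#'   carries the genus label itself.
#' @export
aggregate_to_genus <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  genera <- vapply(table$taxonomy, genus_of, character(1), USE.NAMES = FALSE)
  keys <- unique(genera)  # first-appearance order
  agg <- sapply(keys, function(g) {
    rowSums(table$counts[, genera == g, drop = FALSE])
  })
  if (is.null(dim(agg))) agg <- matrix(agg, nrow = nrow(table$counts),
                                       dimnames = list(table$sample_ids, keys))
  abundance_table(agg, taxonomy = keys, sample_ids = table$sample_ids,
                  taxon_ids = keys)
}

#' Filter taxa by prevalence
#'
#' Retains taxa detected (count > 0) in at least `min_prevalence` of the
#' samples; "at least" is a `>=` comparison, evaluated on the presence count
#' so that exact boundaries such as 3/10 at 0.30 are kept.
#'
#' @param table an [abundance_table()].
#' @param min_prevalence required presence fraction, in (0, 1]; default 0.30.
#' @return the filtered [abundance_table()], column order preserved.
#' @export
prevalence_filter <- function(table, min_prevalence = 0.30) {
  stopifnot(inherits(table, "abundance_table"),
            min_prevalence > 0, min_prevalence <= 1)
  if (ncol(table$counts) == 0L || nrow(table$counts) == 0L) {
    warning("prevalence_filter: empty table")
    return(table)
  }
  presence <- colSums(table$counts > 0)
  # presence/n >= p, compared as presence >= p*n with a tiny guard against
  # float representation of p
  keep <- presence >= min_prevalence * nrow(table$counts) - 1e-9
  abundance_table(table$counts[, keep, drop = FALSE],
                  taxonomy = table$taxonomy[keep],
                  sample_ids = table$sample_ids,
                  taxon_ids = table$taxon_ids[keep])
}

#' Convert counts to relative abundance
#'
#' @param table an [abundance_table()].
#' @return a [composition_table()]; each row divided by its sample total.
#' @export
to_relative_abundance <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  tot <- rowSums(table$counts)
  if (any(tot <= 0)) {
    stop(sprintf("sample '%s' has zero total count; cannot normalize",
                 table$sample_ids[which(tot <= 0)[1]]))
  }
  composition_table(table$counts / tot, genus_ids = table$taxon_ids,
                    sample_ids = table$sample_ids)
}

#' Prepare the microbiome modality
#'
#' Runs genus aggregation, prevalence filtering and relative-abundance
#' normalization. The default order filters counts first and then
#' normalizes, so retained genera sum to 1 per sample; `"normalize-first"`
#' computes proportions on the full genus table and carries them through the
#' filter without rescaling.
#'
#' @param table an [abundance_table()] of OTU/taxon counts.
#' @param min_prevalence presence fraction for [prevalence_filter()]; default 0.30.
#' @param order `"filter-first"` (default) or `"normalize-first"`.
#' @return a [composition_table()].
#' @export
prepare_microbiome <- function(table, min_prevalence = 0.30,
                               order = c("filter-first", "normalize-first")) {
  order <- match.arg(order)
  gtab <- aggregate_to_genus(table)
  if (order == "filter-first") {
    to_relative_abundance(prevalence_filter(gtab, min_prevalence))
  } else {
    comp <- to_relative_abundance(gtab)
    presence <- colSums(comp$relabund > 0)
    keep <- presence >= min_prevalence * nrow(comp$relabund) - 1e-9
    composition_table(comp$relabund[, keep, drop = FALSE],
                      genus_ids = comp$genus_ids[keep],
                      sample_ids = comp$sample_ids,
                      renormalized = FALSE)
  }
}
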