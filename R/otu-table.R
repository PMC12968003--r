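#' OTU abundance table with taxonomy and sample metadata
#'
#' The universal input container of the package: an integer count matrix
#' (samples in rows, OTUs in columns), a taxonomy table with at least the
#' phylum rank, and per-sample metadata describing the chronosequence design
#' (restoration group, replicate, kingdom).
#'
#' @param counts Numeric matrix of non-negative integer counts with samples
#'   in rows and OTUs in columns. Row and column names are taken as sample
#'   and OTU identifiers unless `sample_ids` / `otu_ids` are supplied.
#' @param taxonomy A data frame with columns `otu_id` and `phylum` (a
#'   `lineage` column is kept if present). Unknown phyla may be given as
#'   `"Unclassified"`.
#' @param metadata A data frame with columns `sample_id`, `group`,
#'   `replicate` and `kingdom`.
#' @param sample_ids,otu_ids Optional character vectors overriding the
#'   dimnames of `counts`.
#'
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (named integer matrix), `taxonomy` (tibble) and `metadata` (tibble).
#' @export
#' @examples
#' tab <- otu_table(
#'   matrix(c(5, 0, 3, 2, 1, 4), nrow = 2,
#'          dimnames = list(c("s1", "s2"), c("o1", "o2", "o3"))),
#'   taxonomy = data.frame(otu_id = c("o1", "o2", "o3"),
#'                         phylum = c("Proteobacteria", "Acidobacteria",
#'                                    "Unclassified")),
#'   metadata = data.frame(sample_id = c("s1", "s2"), group = c("SD", "ND"),
#'                         replicate = c(1, 1), kingdom = "bacteria")
#' )
#' n_samples(tab)
otu_table <- function(counts, taxonomy, metadata,
                      sample_ids = NULL, otu_ids = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(sample_ids)) rownames(counts) <- sample_ids
  if (!is.null(otu_ids)) colnames(counts) <- otu_ids
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry sample (row) and OTU (column) names.",
         call. = FALSE)
  }
  taxonomy <- tibble::as_tibble(taxonomy)
  metadata <- tibble::as_tibble(metadata)
  out <- structure(
    list(counts = counts, taxonomy = taxonomy, metadata = metadata),
    class = "otu_table"
  )
  validate_otu_table(out)
}

validate_otu_table <- function(x) {
  counts <- x$counts
  sample_ids <- rownames(counts)
  otu_ids <- colnames(counts)
  if (anyDuplicated(sample_ids)) {
    dup <- sample_ids[duplicated(sample_ids)][1L]
    stop("Duplicated sample id: '", dup, "'.", call. = FALSE)
  }
  if (anyDuplicated(otu_ids)) {
    dup <- otu_ids[duplicated(otu_ids)][1L]
    stop("Duplicated OTU id: '", dup, "'.", call. = FALSE)
  }
  if (!is.numeric(counts) || anyNA(counts)) {
    bad <- which(is.na(counts) | !is.finite(counts), arr.ind = TRUE)
    stop("Non-numeric or missing count at row '",
         sample_ids[bad[1, 1]], "', column '", otu_ids[bad[1, 2]], "'.",
         call. = FALSE)
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)
    stop("Negative count at row '", sample_ids[bad[1, 1]],
         "', column '", otu_ids[bad[1, 2]], "'.", call. = FALSE)
  }
  need_meta <- c("sample_id", "group", "replicate", "kingdom")
  if (!all(need_meta %in% names(x$metadata))) {
    stop("Metadata must have columns ",
         paste(need_meta, collapse = ", "), ".", call. = FALSE)
  }
  missing_meta <- setdiff(sample_ids, x$metadata$sample_id)
  if (length(missing_meta)) {
    stop("Sample(s) missing from metadata: ",
         paste(missing_meta, collapse = ", "), ".", call. = FALSE)
  }
  if (!all(c("otu_id", "phylum") %in% names(x$taxonomy))) {
    stop("Taxonomy must have columns otu_id and phylum.", call. = FALSE)
  }
  missing_tax <- setdiff(otu_ids, x$taxonomy$otu_id)
  if (length(missing_tax)) {
    stop("OTU(s) missing from taxonomy: ",
         paste(utils::head(missing_tax, 5), collapse = ", "), ".",
         call. = FALSE)
  }
  # keep metadata/taxonomy aligned with the matrix
  x$metadata <- x$metadata[match(sample_ids, x$metadata$sample_id), ]
  x$taxonomy <- x$taxonomy[match(otu_ids, x$taxonomy$otu_id), ]
  x
}

#' @rdname otu_table
#' @param x An `otu_table`.
#' @export
n_samples <- function(x) nrow(x$counts)

#' @rdname otu_table
#' @export
n_otus <- function(x) ncol(x$counts)

#' @export
print.otu_table <- function(x, ...) {
  cat("<otu_table> ", n_samples(x), " samples x ", n_otus(x), " OTUs\n",
      sep = "")
  cat("  groups: ", paste(unique(x$metadata$group), collapse = ", "), "\n",
      sep = "")
  cat("  kingdom(s): ", paste(unique(x$metadata$kingdom), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Subset an OTU table by sample and/or OTU identifiers
#'
#' @param x An `otu_table`.
#' @param samples,otus Character vectors of identifiers to keep (default:
#'   all).
#' @return A validated `otu_table` restricted to the requested ids.
#' @export
subset_otu_table <- function(x, samples = rownames(x$counts),
                             otus = colnames(x$counts)) {
  counts <- x$counts[samples, otus, drop = FALSE]
  otu_table(counts,
            taxonomy = dplyr::filter(x$taxonomy, .data$otu_id %in% otus),
            metadata = dplyr::filter(x$metadata, .data$sample_id %in% samples))
}

#' Read an OTU table and its sample metadata from tab-separated files
#'
#' The abundance file follows the common export dialect: OTUs as rows, the
#' first column named `#OTU_ID` (any first column is accepted), one column
#' per sample, and optionally a final `taxonomy` column holding a
#' semicolon-delimited lineage (Greengenes-style `p__` prefixes are
#' tolerated). Orientation is declared, never guessed: set
#' `otus_as_rows = FALSE` for samples-as-rows files.
#'
#' @param path Path to the abundance TSV.
#' @param metadata_path Path to a metadata TSV with columns `sample_id`,
#'   `group`, `replicate`, `kingdom`.
#' @param otus_as_rows Logical; is the abundance file OTUs-by-samples?
#' @return A validated [otu_table].
#' @export
read_otu_table <- function(path, metadata_path, otus_as_rows = TRUE) {
  ab <- readr::read_tsv(path, show_col_types = FALSE, comment = "")
  metadata <- readr::read_tsv(metadata_path, show_col_types = FALSE)
  ab <- as.data.frame(ab, check.names = FALSE)
  ids <- as.character(ab[[1L]])
  ab <- ab[, -1L, drop = FALSE]
  tax_col <- which(tolower(names(ab)) == "taxonomy")
  lineage <- NULL
  if (length(tax_col)) {
    lineage <- as.character(ab[[tax_col[1L]]])
    ab <- ab[, -tax_col, drop = FALSE]
  }
  mat <- as.matrix(ab)
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(mat, 2, as.numeric))),
                 arr.ind = TRUE)[1, , drop = TRUE]
    stop("Non-numeric count in row '", ids[bad[1]], "', column '",
         colnames(mat)[bad[2]], "'.", call. = FALSE)
  }
  rownames(mat) <- ids
  if (otus_as_rows) {
    counts <- t(mat)
    otu_ids <- ids
  } else {
    counts <- mat
    otu_ids <- colnames(mat)
  }
  if (is.null(lineage)) {
    taxonomy <- tibble::tibble(otu_id = otu_ids, phylum = "Unclassified")
  } else {
    taxonomy <- parse_lineage(otu_ids, lineage)
  }
  otu_table(counts, taxonomy = taxonomy, metadata = metadata)
}

# Greengenes-style "k__Bacteria; p__Acidobacteria; ..." -> phylum
parse_lineage <- function(otu_ids, lineage) {
  phylum <- vapply(strsplit(lineage, ";"), function(ranks) {
    ranks <- trimws(ranks)
    p <- grep("^p__", ranks, value = TRUE)
    if (length(p)) {
      p <- sub("^p__", "", p[1L])
    } else if (length(ranks) >= 2L) {
      p <- ranks[2L]
    } else {
      p <- ""
    }
    if (!nzchar(p)) "Unclassified" else p
  }, character(1))
  tibble::tibble(otu_id = otu_ids, phylum = phylum, lineage = lineage)
}

#' Write an OTU table to tab-separated files
#'
#' @param x An `otu_table`.
#' @param path,metadata_path Output file paths for the abundance and
#'   metadata tables. The abundance table is written OTUs-as-rows with a
#'   `#OTU_ID` first column and a trailing `taxonomy` column.
#' @return `x`, invisibly.
#' @export
write_otu_table <- function(x, path, metadata_path) {
  tax <- x$taxonomy
  lineage <- if ("lineage" %in% names(tax)) tax$lineage else
    paste0("p__", tax$phylum)
  ab <- tibble::as_tibble(t(x$counts), rownames = "#OTU_ID")
  ab$taxonomy <- lineage
  readr::write_tsv(ab, path)
  readr::write_tsv(x$metadata, metadata_path)
  invisible(x)
}

#' Compositional views of a count table
#'
#' `relative_abundance()` closes each sample to unit sum;
#' `clr_transform()` applies the centered log-ratio transform
#' \eqn{clr_i = \ln(x_i + c) - \frac{1}{S}\sum_j \ln(x_j + c)} per sample,
#' mapping compositions into unconstrained Euclidean space where Aitchison
#' geometry applies.
#'
#' @param x An [otu_table].
#' @return A `composition_matrix`: a list with `values` (samples-by-OTUs
#'   real matrix), `kind` (`"relative"` or `"clr"`) and, for CLR, the
#'   `pseudocount` used.
#' @export
relative_abundance <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  totals <- rowSums(x$counts)
  if (any(totals <= 0)) {
    stop("Sample(s) with zero total count: ",
         paste(rownames(x$counts)[totals <= 0], collapse = ", "), ".",
         call. = FALSE)
  }
  composition_matrix(x$counts / totals, kind = "relative")
}

#' @rdname relative_abundance
#' @param pseudocount Positive value added to every count before taking
#'   logs; default 1 on raw counts.
#' @export
clr_transform <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "otu_table"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      pseudocount <= 0) {
    stop("`pseudocount` must be a single positive number.", call. = FALSE)
  }
  lg <- log(x$counts + pseudocount)
  vals <- lg - rowMeans(lg)
  composition_matrix(vals, kind = "clr", pseudocount = pseudocount)
}

composition_matrix <- function(values, kind, pseudocount = NULL) {
  structure(list(values = values, kind = kind, pseudocount = pseudocount),
            class = "composition_matrix")
}

#' @export
print.composition_matrix <- function(x, ...) {
  cat("<composition_matrix> kind=", x$kind, ", ", nrow(x$values),
      " samples x ", ncol(x$values), " OTUs\n", sep = "")
  invisible(x)
}

#' Core-OTU filter by prevalence and mean relative abundance
#'
#' An OTU is retained only when it is present in strictly more than
#' `prevalence_min` of the samples and its mean relative abundance is
#' strictly greater than `mean_relabund_min`. Defaults follow the standard
#' core-community convention of >50% prevalence and >0.01% mean relative
#' abundance; values exactly at a threshold are excluded.
#'
#' @param x An [otu_table].
#' @param prevalence_min Prevalence threshold as a fraction in \[0, 1\].
#' @param mean_relabund_min Mean relative-abundance threshold in \[0, 1\].
#' @return An [otu_table] with the same samples and the core OTUs only.
#'   The result may have zero OTUs.
#' @export
filter_core_otus <- function(x, prevalence_min = 0.5,
                             mean_relabund_min = 1e-4) {
  stopifnot(inherits(x, "otu_table"))
  if (prevalence_min < 0 || prevalence_min > 1 ||
      mean_relabund_min < 0 || mean_relabund_min > 1) {
    stop("Thresholds must lie in [0, 1].", call. = FALSE)
  }
  rel <- relative_abundance(x)$values
  prevalence <- colMeans(x$counts > 0)
  mean_rel <- colMeans(rel)
  keep <- prevalence > prevalence_min & mean_rel > mean_relabund_min
  counts <- x$counts[, keep, drop = FALSE]
  otu_table(counts,
            taxonomy = dplyr::filter(x$taxonomy,
                                     .data$otu_id %in% colnames(counts)),
            metadata = x$metadata)
}

#' Phylum-level relative-abundance profiles
#'
#' Sums OTU relative abundances per phylum per sample; phyla whose grand
#' mean relative abundance falls below `others_threshold` are merged into
#' an `"Others"` category so stacked-bar profiles stay readable.
#'
#' @param x An [otu_table].
#' @param others_threshold Grand-mean relative-abundance cut-off below
#'   which a phylum is lumped into `"Others"`; default 0.01.
#' @return A tibble with columns `sample_id`, `phylum`,
#'   `relative_abundance`; per-sample values sum to 1.
#' @export
aggregate_phylum <- function(x, others_threshold = 0.01) {
  stopifnot(inherits(x, "otu_table"))
  rel <- relative_abundance(x)$values
  long <- tibble::as_tibble(rel, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "otu_id",
                        values_to = "rel") |>
    dplyr::left_join(dplyr::select(x$taxonomy, "otu_id", "phylum"),
                     by = "otu_id") |>
    dplyr::summarise(rel = sum(.data$rel),
                     .by = c("sample_id", "phylum"))
  grand <- dplyr::summarise(long, mean_rel = mean(.data$rel),
                            .by = "phylum")
  minor <- grand$phylum[grand$mean_rel < others_threshold]
  long |>
    dplyr::mutate(phylum = ifelse(.data$phylum %in% minor, "Others",
                                  .data$phylum)) |>
    dplyr::summarise(relative_abundance = sum(.data$rel),
                     .by = c("sample_id", "phylum")) |>
    dplyr::arrange(.data$sample_id, dplyr::desc(.data$relative_abundance))
}
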