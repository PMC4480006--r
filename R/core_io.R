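# Domain types and tabular readers/writers.
#
# All tables are plain text: tab-separated with a header row is the canonical
# dialect; comma-separated is accepted for ISH count and spatial coordinate
# tables. Missing values are not permitted in count matrices.

CHEMORECEPTOR_FAMILIES <- c("or", "taar", "ora", "olfC")
VALID_FAMILIES <- c(CHEMORECEPTOR_FAMILIES, "none")

#' Construct a count matrix
#'
#' Gene-level fragment counts per replicate, together with per-replicate
#' totals (the denominator N of the FPKM transform). Counts must be
#' non-negative integers and gene identifiers unique.
#'
#' @param counts integer matrix, genes in rows, replicates in columns, with
#'   row and column names (gene and replicate identifiers).
#' @return An object of class \code{count_matrix}: a list with elements
#'   \code{gene_ids}, \code{replicate_ids}, \code{counts} and
#'   \code{total_counted} (per-replicate column sums).
#' @export
count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0L) {
    stop("count matrix requires gene ids as row names")
  }
  if (is.null(colnames(counts))) stop("count matrix requires replicate ids as column names")
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene_id: ", rownames(counts)[duplicated(rownames(counts))][1L])
  }
  if (anyNA(counts)) stop("missing values are not permitted in count matrices")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    g <- rownames(counts)[bad[1L, 1L]]; r <- colnames(counts)[bad[1L, 2L]]
    v <- counts[bad[1L, , drop = FALSE]]
    what <- if (v < 0) "negative count" else "non-integer count"
    stop(what, " at ", g, "/", r)
  }
  storage.mode(counts) <- "integer"
  structure(list(
    gene_ids      = if (is.null(rownames(counts))) character(0) else rownames(counts),
    replicate_ids = colnames(counts),
    counts        = counts,
    total_counted = colSums(counts)
  ), class = "count_matrix")
}

#' Read a gene-level count matrix from TSV
#'
#' Expects a header row starting with \code{gene_id} followed by replicate
#' identifiers; one gene per row; integer cells.
#'
#' @param path file path.
#' @return A \code{\link{count_matrix}}.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 1L || names(df)[1L] != "gene_id") {
    stop("count matrix must have a 'gene_id' first column: ", path)
  }
  gene_ids <- df[[1L]]
  reps <- names(df)[-1L]
  if (length(gene_ids) == 0L) {
    m <- matrix(integer(0), nrow = 0, ncol = length(reps),
                dimnames = list(character(0), reps))
    return(count_matrix(m))
  }
  m <- matrix(NA_real_, nrow = nrow(df), ncol = length(reps),
              dimnames = list(gene_ids, reps))
  for (j in seq_along(reps)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop("non-numeric count at ", gene_ids[i], "/", reps[j], " in ", path)
    }
    m[, j] <- v
  }
  count_matrix(m)
}

#' Construct a gene annotation table
#'
#' @param df data frame with columns \code{gene_id}, \code{length_bp},
#'   \code{family} (one of or, taar, ora, olfC, none) and \code{species}.
#' @return Validated data frame of class \code{gene_annotation}.
#' @export
gene_annotation <- function(df) {
  req <- c("gene_id", "length_bp", "family", "species")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("annotation is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in annotation")
  df$length_bp <- as.numeric(df$length_bp)
  if (anyNA(df$length_bp) || any(df$length_bp < 1 | df$length_bp != round(df$length_bp))) {
    i <- which(is.na(df$length_bp) | df$length_bp < 1 | df$length_bp != round(df$length_bp))[1L]
    stop("length_bp must be a positive integer (gene ", df$gene_id[i], ")")
  }
  df$length_bp <- as.integer(df$length_bp)
  bad <- !(df$family %in% VALID_FAMILIES)
  if (any(bad)) {
    stop("unknown family '", df$family[bad][1L], "' (gene ", df$gene_id[bad][1L],
         "); allowed: ", paste(VALID_FAMILIES, collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read a gene annotation table from TSV
#' @param path file path.
#' @return A \code{\link{gene_annotation}} data frame.
#' @export
read_gene_annotation <- function(path) {
  gene_annotation(utils::read.delim(path, header = TRUE, sep = "\t",
                                    check.names = FALSE))
}

#' Construct an expression matrix
#'
#' FPKM values per gene and replicate plus replicate-mean and SEM per gene.
#' SEM uses the n-1 denominator for the standard deviation.
#'
#' @param fpkm numeric matrix, genes x replicates, non-negative, with
#'   dimnames.
#' @return Object of class \code{expression_matrix} with elements
#'   \code{gene_ids}, \code{replicate_ids}, \code{fpkm}, \code{mean_fpkm},
#'   \code{sem_fpkm}.
#' @export
expression_matrix <- function(fpkm) {
  fpkm <- as.matrix(fpkm)
  if (is.null(rownames(fpkm)) || is.null(colnames(fpkm))) {
    stop("expression matrix requires gene and replicate dimnames")
  }
  if (anyNA(fpkm) || any(fpkm < 0)) stop("FPKM values must be non-negative and complete")
  n <- ncol(fpkm)
  mean_fpkm <- rowMeans(fpkm)
  sem_fpkm <- if (n >= 2L) apply(fpkm, 1L, stats::sd) / sqrt(n) else rep(NA_real_, nrow(fpkm))
  names(sem_fpkm) <- rownames(fpkm)
  structure(list(
    gene_ids      = rownames(fpkm),
    replicate_ids = colnames(fpkm),
    fpkm          = fpkm,
    mean_fpkm     = mean_fpkm,
    sem_fpkm      = sem_fpkm
  ), class = "expression_matrix")
}

#' Construct an ISH labeled-cell count set
#'
#' Per-gene labeled-cell counts per tissue section, with per-section mean
#' and SEM.
#'
#' @param section_counts named list; one non-negative integer vector of
#'   per-section counts per gene.
#' @return Object of class \code{ish_count_set}.
#' @export
ish_count_set <- function(section_counts) {
  if (is.null(names(section_counts)) || any(names(section_counts) == "")) {
    stop("section_counts must be a named list (one entry per gene)")
  }
  for (g in names(section_counts)) {
    v <- section_counts[[g]]
    if (anyNA(v) || any(v < 0 | v != round(v))) {
      stop("section counts must be non-negative integers (gene ", g, ")")
    }
    section_counts[[g]] <- as.integer(v)
  }
  n_sections <- vapply(section_counts, length, integer(1))
  means <- vapply(section_counts, function(v) sum(v) / length(v), numeric(1))
  sems <- vapply(section_counts, function(v) {
    if (length(v) >= 2L) stats::sd(v) / sqrt(length(v)) else NA_real_
  }, numeric(1))
  structure(list(
    gene_ids         = names(section_counts),
    section_counts   = section_counts,
    n_sections       = n_sections,
    mean_per_section = means,
    sem_per_section  = sems
  ), class = "ish_count_set")
}

#' Read ISH cell counts from a long-format table
#'
#' Columns \code{gene_id}, \code{section_id}, \code{cells}; comma- or
#' tab-separated (sniffed from the header line).
#'
#' @param path file path.
#' @return An \code{\link{ish_count_set}}.
#' @export
read_ish_counts <- function(path) {
  df <- read_delim_sniff(path, c("gene_id", "section_id", "cells"))
  df$cells <- as.numeric(df$cells)
  bad <- is.na(df$cells) | df$cells < 0 | df$cells != round(df$cells)
  if (any(bad)) stop("invalid cell count at row ", which(bad)[1L], " of ", path)
  counts <- split(as.integer(df$cells), df$gene_id)
  ord <- unique(df$gene_id)
  ish_count_set(counts[ord])
}

#' Construct an ortholog pair table
#'
#' @param df data frame with columns \code{gene_a}, \code{gene_b},
#'   \code{orthology_type} (one2one, one2many, many2many) and
#'   \code{identity_pct} in [0, 100].
#' @return Validated data frame of class \code{ortholog_table}.
#' @export
ortholog_table <- function(df) {
  req <- c("gene_a", "gene_b", "orthology_type", "identity_pct")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("ortholog table is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  ok_types <- c("one2one", "one2many", "many2many")
  bad <- !(df$orthology_type %in% ok_types)
  if (any(bad)) stop("unknown orthology_type at row ", which(bad)[1L])
  df$identity_pct <- as.numeric(df$identity_pct)
  bad <- is.na(df$identity_pct) | df$identity_pct < 0 | df$identity_pct > 100
  if (any(bad)) stop("identity_pct out of [0,100] at row ", which(bad)[1L])
  rownames(df) <- NULL
  class(df) <- c("ortholog_table", "data.frame")
  df
}

#' Read an ortholog pair table from TSV
#' @param path file path.
#' @return An \code{\link{ortholog_table}} data frame.
#' @export
read_ortholog_table <- function(path) {
  ortholog_table(utils::read.delim(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
}

#' Construct a spatial coordinate record set
#'
#' Raw per-cell measurements in arbitrary length units: distance of the soma
#' from the basal border, local epithelium thickness, radial distance from
#' the lamellar apex, radial extent of the section, and the section index.
#'
#' @param df data frame with columns \code{cell_id}, \code{basal_distance},
#'   \code{epithelium_thickness}, \code{radial_distance},
#'   \code{radial_extent}, \code{section_index}, \code{n_sections}.
#' @return Validated data frame of class \code{spatial_records}.
#' @export
spatial_records <- function(df) {
  req <- c("cell_id", "basal_distance", "epithelium_thickness",
           "radial_distance", "radial_extent", "section_index", "n_sections")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("spatial table is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  for (col in req[-1L]) df[[col]] <- as.numeric(df[[col]])
  chk <- function(bad, msg) {
    if (any(bad)) stop(msg, " (cell ", df$cell_id[bad][1L], ")")
  }
  chk(df$basal_distance < 0 | df$basal_distance > df$epithelium_thickness,
      "basal_distance must lie in [0, epithelium_thickness]")
  chk(df$radial_distance < 0 | df$radial_distance > df$radial_extent,
      "radial_distance must lie in [0, radial_extent]")
  chk(df$section_index < 1 | df$section_index > df$n_sections |
        df$section_index != round(df$section_index),
      "section_index must be an integer in [1, n_sections]")
  df$section_index <- as.integer(df$section_index)
  df$n_sections <- as.integer(df$n_sections)
  rownames(df) <- NULL
  class(df) <- c("spatial_records", "data.frame")
  df
}

#' Read spatial coordinate records
#' @param path file path, comma- or tab-separated.
#' @return A \code{\link{spatial_records}} data frame.
#' @export
read_spatial_records <- function(path) {
  spatial_records(read_delim_sniff(
    path, c("cell_id", "basal_distance", "epithelium_thickness",
            "radial_distance", "radial_extent", "section_index", "n_sections")))
}

# Sniff comma vs tab from the header line; require the given columns.
read_delim_sniff <- function(path, required) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.delim(path, header = TRUE, sep = sep, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) stop(path, " is missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Write a domain table to disk
#'
#' Writes the canonical tab-separated (count matrix, annotation, orthologs,
#' expression) or comma-separated (ISH, spatial) representation such that
#' the matching reader round-trips the object exactly.
#'
#' @param x a domain object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(x, path) UseMethod("write_table")

#' @export
write_table.count_matrix <- function(x, path) {
  df <- data.frame(gene_id = x$gene_ids, x$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_table.gene_annotation <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_table.expression_matrix <- function(x, path) {
  df <- data.frame(gene_id = x$gene_ids, x$fpkm,
                   mean_fpkm = x$mean_fpkm, sem_fpkm = x$sem_fpkm,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_table.ortholog_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_table.ish_count_set <- function(x, path) {
  df <- do.call(rbind, lapply(x$gene_ids, function(g) {
    v <- x$section_counts[[g]]
    data.frame(gene_id = g, section_id = seq_along(v), cells = v)
  }))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_table.spatial_records <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_table.data.frame <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tally chemoreceptor family membership
#'
#' @param annotation a \code{\link{gene_annotation}}.
#' @return Named integer vector of gene counts for the four chemoreceptor
#'   families (or, taar, ora, olfC).
#' @export
family_tally <- function(annotation) {
  fam <- factor(annotation$family, levels = CHEMORECEPTOR_FAMILIES)
  tab <- table(fam[!is.na(fam)])
  out <- as.integer(tab)
  names(out) <- CHEMORECEPTOR_FAMILIES
  out
}
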