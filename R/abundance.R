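#' Construct and validate a genus abundance table
#'
#' An abundance table holds non-negative integer read counts of genera
#' (rows) across samples (columns), optionally annotated with a genus to
#' phylum map. It is the input of every downstream step.
#'
#' @param counts numeric matrix of non-negative integers, genera in rows,
#'   samples in columns; must carry unique row and column names.
#' @param taxonomy optional named character vector mapping genus id to
#'   phylum.
#' @return an object of class `abundance_table`: a list with elements
#'   `counts` (integer matrix) and `taxonomy`.
#' @export
abundance_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have genus row names and sample column names")
  dup_g <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup_g))
    stop("duplicated genus identifier(s): ", paste(unique(dup_g), collapse = ", "))
  dup_s <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup_s))
    stop("duplicated sample identifier(s): ", paste(unique(dup_s), collapse = ", "))
  if (!is.numeric(counts)) stop("counts must be numeric")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative or non-integer count at genus '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy))) stop("taxonomy must be a named vector (genus -> phylum)")
    taxonomy <- taxonomy[intersect(names(taxonomy), rownames(counts))]
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("Abundance table: %d genera x %d samples, %s reads total\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Read a genus abundance table from disk
#'
#' Supports two plain-text layouts: a dense tab-separated matrix with one
#' header row and identifiers in the first column, and a sparse triplet
#' ("BIOM-style") file with three columns `genus_id`, `sample_id`, `count`.
#'
#' @param path file path.
#' @param orientation `"genera_rows"` (default) if matrix rows are genera,
#'   `"samples_rows"` if rows are samples; ignored for triplet files.
#' @param format `"auto"` (detect by column count), `"tsv"` or `"triplet"`.
#' @return an [abundance_table].
#' @export
read_abundance_table <- function(path,
                                 orientation = c("genera_rows", "samples_rows"),
                                 format = c("auto", "tsv", "triplet")) {
  orientation <- match.arg(orientation)
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (format == "auto")
    format <- if (length(first) == 3L &&
                  identical(tolower(first), c("genus_id", "sample_id", "count")))
      "triplet" else "tsv"
  if (format == "triplet") {
    tr <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("genus_id", "sample_id", "count")
    if (!all(need %in% tolower(names(tr))))
      stop("triplet file must have columns genus_id, sample_id, count")
    names(tr) <- tolower(names(tr))
    key <- paste(tr$genus_id, tr$sample_id, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicated (genus, sample) entry: ",
           sub("\r", " / ", key[duplicated(key)][1]))
    g <- unique(tr$genus_id); s <- unique(tr$sample_id)
    m <- matrix(0L, length(g), length(s), dimnames = list(g, s))
    m[cbind(match(tr$genus_id, g), match(tr$sample_id, s))] <- tr$count
    return(abundance_table(m))
  }
  df <- utils::read.delim(path, row.names = NULL, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated identifier in first column: ", ids[duplicated(ids)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (orientation == "samples_rows") m <- t(m)
  abundance_table(m)
}

#' Read per-sample clinical metadata
#'
#' Requires tab-separated columns `sample_id`, `subject_id`, `diagnosis`
#' (control/UC/CD), `region` (cecum, ascending, transverse, descending,
#' rectum) and `site`. Region is returned as an ordered factor following
#' the proximal-to-distal anatomical order.
#'
#' @param path TSV file path.
#' @return data.frame with validated, typed columns.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_metadata(md)
}

#' @rdname read_sample_metadata
#' @param metadata a data.frame to validate in place of a file.
#' @export
validate_metadata <- function(metadata) {
  need <- c("sample_id", "subject_id", "diagnosis", "region", "site")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicated sample_id in metadata: ",
         metadata$sample_id[duplicated(metadata$sample_id)][1])
  bad <- setdiff(unique(metadata$diagnosis), diagnosis_levels())
  if (length(bad)) stop("unknown diagnosis value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(metadata$region), region_levels())
  if (length(bad)) stop("unknown region value(s): ", paste(bad, collapse = ", "))
  metadata$diagnosis <- factor(metadata$diagnosis, levels = diagnosis_levels())
  metadata$region <- factor(metadata$region, levels = region_levels(), ordered = TRUE)
  metadata
}

#' @export
diagnosis_levels <- function() c("control", "UC", "CD")

#' Anatomical colon regions in proximal-to-distal order
#'
#' Regions are coded ordinally 0-4 in this order when used as a
#' quantitative trait.
#' @export
region_levels <- function()
  c("cecum", "ascending", "transverse", "descending", "rectum")

#' Quality-filter an abundance table
#'
#' Drops samples whose total read count falls below a floor and,
#' optionally, singleton genera (total count across retained samples of at
#' most 1). The two rules are iterated to a fixed point so that the
#' operation is idempotent.
#'
#' @param x an [abundance_table].
#' @param min_reads_per_sample read-count floor; samples below it are
#'   excluded (default 3000).
#' @param drop_singletons drop genera with total count <= 1.
#' @param verbose log removals via [message()].
#' @return filtered [abundance_table] with a `filter_report` attribute
#'   listing the removed sample and genus ids.
#' @export
quality_filter <- function(x, min_reads_per_sample = 3000,
                           drop_singletons = TRUE, verbose = FALSE) {
  stopifnot(inherits(x, "abundance_table"), min_reads_per_sample >= 0)
  m <- x$counts
  dropped_s <- character(0); dropped_g <- character(0)
  repeat {
    keep_s <- colSums(m) >= min_reads_per_sample
    if (!any(keep_s)) stop("quality_filter removed all samples")
    dropped_s <- c(dropped_s, colnames(m)[!keep_s])
    m <- m[, keep_s, drop = FALSE]
    if (drop_singletons) {
      keep_g <- rowSums(m) > 1L
      dropped_g <- c(dropped_g, rownames(m)[!keep_g])
      m <- m[keep_g, , drop = FALSE]
    }
    if (all(keep_s) && (!drop_singletons || all(rowSums(m) > 1L))) break
  }
  if (verbose)
    message(sprintf("quality_filter: removed %d sample(s), %d genus/genera",
                    length(dropped_s), length(dropped_g)))
  out <- abundance_table(m, x$taxonomy)
  attr(out, "filter_report") <- list(dropped_samples = dropped_s,
                                     dropped_genera = dropped_g)
  out
}

#' Convert counts to per-sample relative abundances
#'
#' @param x an [abundance_table]; every sample must have a positive total.
#' @return a `relative_abundance_table`: same structure with a `fractions`
#'   matrix whose columns sum to 1.
#' @export
to_relative <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  tot <- colSums(x$counts)
  if (any(tot == 0))
    stop("zero-total sample(s): ", paste(colnames(x$counts)[tot == 0], collapse = ", "))
  f <- sweep(x$counts, 2, tot, "/")
  structure(list(fractions = f, taxonomy = x$taxonomy),
            class = "relative_abundance_table")
}

#' @export
print.relative_abundance_table <- function(x, ...) {
  cat(sprintf("Relative abundance table: %d genera x %d samples\n",
              nrow(x$fractions), ncol(x$fractions)))
  invisible(x)
}

# canonical genus key: trimmed, case-folded label
.genus_key <- function(g) tolower(trimws(g))

#' Restrict two abundance tables to their shared genera
#'
#' Genus identity is the taxon label after whitespace trimming and case
#' folding; taxonomies from different reference databases must be
#' harmonized upstream. Both outputs carry the identical genus ordering.
#'
#' @param a,b [abundance_table]s.
#' @return list with elements `a`, `b` (aligned tables) and `report`, a
#'   data.frame with per-dataset retained reads, total reads and percent
#'   retained.
#' @export
align_shared_genera <- function(a, b) {
  stopifnot(inherits(a, "abundance_table"), inherits(b, "abundance_table"))
  ka <- .genus_key(rownames(a$counts)); kb <- .genus_key(rownames(b$counts))
  shared <- intersect(ka, kb)
  if (!length(shared)) stop("no shared genera between the two tables")
  ia <- match(shared, ka); ib <- match(shared, kb)
  sa <- a$counts[ia, , drop = FALSE]; sb <- b$counts[ib, , drop = FALSE]
  report <- data.frame(
    dataset = c("a", "b"),
    reads_kept = c(sum(as.numeric(sa)), sum(as.numeric(sb))),
    reads_total = c(sum(as.numeric(a$counts)), sum(as.numeric(b$counts))),
    genera_kept = length(shared),
    stringsAsFactors = FALSE)
  report$percent_kept <- 100 * report$reads_kept / report$reads_total
  list(a = abundance_table(sa, a$taxonomy),
       b = abundance_table(sb, b$taxonomy),
       report = report)
}

#' Sum counts per phylum
#'
#' @param x an [abundance_table] with a taxonomy map; genera without a
#'   phylum assignment are grouped as `"unclassified"`.
#' @return an [abundance_table] of phyla x samples.
#' @export
rollup_phylum <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  if (is.null(x$taxonomy)) stop("table has no taxonomy map")
  ph <- x$taxonomy[rownames(x$counts)]
  ph[is.na(ph)] <- "unclassified"
  m <- rowsum(x$counts, group = ph)
  abundance_table(m)
}

#' Write an abundance table as TSV
#' @param x an [abundance_table].
#' @param path destination file.
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(inherits(x, "abundance_table"))
  df <- data.frame(genus_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
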