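#' Describe the column layout of an annotation table
#'
#' MG-RAST-style functional annotation exports differ in column order and
#' header conventions.  A dialect maps the four fields the pipeline needs
#' (read id, ortholog-group id, e-value, percent identity) onto columns of a
#' tab-delimited file, by name (when `header = TRUE`) or by 1-based index.
#'
#' @param read_id,ko_id,e_value,pct_identity column name (character) or
#'   1-based column index (numeric) holding each field.
#' @param header logical; does the file carry a header line?
#' @return an object of class `annotation_dialect`.
#' @export
annotation_dialect <- function(read_id = "read_id", ko_id = "ko_id",
                               e_value = "e_value", pct_identity = "pct_identity",
                               header = TRUE) {
  structure(list(read_id = read_id, ko_id = ko_id, e_value = e_value,
                 pct_identity = pct_identity, header = isTRUE(header)),
            class = "annotation_dialect")
}

.resolve_column <- function(spec, available, field) {
  if (is.numeric(spec)) {
    idx <- as.integer(spec)
    if (idx < 1L || idx > length(available))
      stop("annotation table has no column ", idx, " for field '", field, "'")
    return(idx)
  }
  idx <- match(spec, available)
  if (is.na(idx))
    stop("annotation table is missing mandatory column '", spec,
         "' (field '", field, "')")
  idx
}

.as_annotation_set <- function(df, provenance = character()) {
  rownames(df) <- NULL
  structure(df, provenance = provenance, class = c("annotation_set", "data.frame"))
}

#' Construct an annotation set from vectors
#'
#' The in-memory unit of counting: one row per (read, ortholog group)
#' annotation, with the similarity-search quality fields the filters act on.
#' Duplicate (read_id, ko_id) pairs are collapsed, keeping the smallest
#' e-value (first occurrence on ties).
#'
#' @param read_id,ko_id character vectors.
#' @param e_value non-negative numeric vector.
#' @param pct_identity numeric vector in \[0, 100\] (NA allowed when the
#'   source table carries no identity column).
#' @param dataset_label optional tag (e.g. `"background"`, `"virome"`).
#' @param provenance free-text metadata kept as an attribute.
#' @return an `annotation_set` (a data.frame).
#' @export
annotation_set <- function(read_id, ko_id, e_value, pct_identity = NA_real_,
                           dataset_label = NA_character_, provenance = character()) {
  n <- length(read_id)
  df <- data.frame(read_id = as.character(read_id), ko_id = as.character(ko_id),
                   e_value = as.numeric(e_value),
                   pct_identity = rep_len(as.numeric(pct_identity), n),
                   dataset_label = rep_len(as.character(dataset_label), n),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(!nzchar(df$ko_id)) || anyNA(df$ko_id))
      stop("ko_id must be non-empty")
    if (any(df$e_value < 0, na.rm = TRUE)) stop("e_value must be >= 0")
    bad <- !is.na(df$pct_identity) &
      (df$pct_identity < 0 | df$pct_identity > 100)
    if (any(bad)) stop("pct_identity must lie in [0, 100]")
    df <- .dedup_annotations(df)
  }
  .as_annotation_set(df, provenance)
}

# keep, per (read_id, ko_id), the smallest e-value; first occurrence on ties
.dedup_annotations <- function(df) {
  key <- paste(df$read_id, df$ko_id, sep = "\r")
  if (!anyDuplicated(key)) return(df)
  ord <- order(key, df$e_value, seq_len(nrow(df)), method = "radix")
  df <- df[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  df <- df[keep, , drop = FALSE]
  # restore input order of the surviving records
  df[order(match(paste(df$read_id, df$ko_id, sep = "\r"), unique(key))), ,
     drop = FALSE]
}

#' Read a tab-delimited annotation table
#'
#' Parses a (possibly MG-RAST-dialect) annotation export into an
#' [annotation_set()].  Malformed lines (wrong field count, unparseable
#' e-value) are dropped with a warning naming their line numbers; duplicate
#' (read, KO) pairs collapse to the record with the smallest e-value.
#'
#' @param path file path (or connection) to tab-separated text.
#' @param dialect an [annotation_dialect()].
#' @param dataset_label tag recorded on every record.
#' @return an `annotation_set`; empty input yields an empty set.
#' @export
read_annotation_table <- function(path, dialect = annotation_dialect(),
                                  dataset_label = NA_character_) {
  stopifnot(inherits(dialect, "annotation_dialect"))
  lines <- readLines(path, warn = FALSE)
  if (dialect$header && length(lines)) {
    head_fields <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    lines <- lines[-1]
    offset <- 1L
  } else {
    head_fields <- NULL
    offset <- 0L
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    # columns must still resolve so that missing-column errors fire on
    # header-only files
    if (!is.null(head_fields))
      for (f in c("read_id", "ko_id", "e_value"))
        .resolve_column(dialect[[f]], head_fields, f)
    return(annotation_set(character(), character(), numeric(),
                          provenance = paste("read from", path)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  avail <- if (is.null(head_fields)) paste0("V", seq_len(max(nf))) else head_fields
  ci <- vapply(c("read_id", "ko_id", "e_value"), function(f)
    .resolve_column(dialect[[f]], avail, f), integer(1))
  id_idx <- tryCatch(.resolve_column(dialect$pct_identity, avail, "pct_identity"),
                     error = function(e) NA_integer_)
  need <- max(ci, id_idx, na.rm = TRUE)
  bad <- nf < need
  get <- function(i) vapply(fields, function(x) if (length(x) >= i) x[[i]] else NA_character_,
                            character(1))
  ev <- suppressWarnings(as.numeric(get(ci[["e_value"]])))
  bad <- bad | is.na(ev) | !nzchar(get(ci[["ko_id"]])) | is.na(get(ci[["ko_id"]]))
  if (any(bad)) {
    warning(sum(bad), " malformed annotation line(s) skipped (line ",
            paste(utils::head(which(bad) + offset, 10L), collapse = ", "),
            if (sum(bad) > 10L) ", ..." else "", ")")
  }
  keep <- !bad
  pid <- if (is.na(id_idx)) NA_real_ else suppressWarnings(as.numeric(get(id_idx)))[keep]
  annotation_set(get(ci[["read_id"]])[keep], get(ci[["ko_id"]])[keep],
                 ev[keep], pid, dataset_label,
                 provenance = paste("read from", path))
}

#' Write an annotation set as canonical TSV
#'
#' @param annos an `annotation_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annos, path) {
  utils::write.table(annos[, c("read_id", "ko_id", "e_value", "pct_identity")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a cluster-to-read mapping
#'
#' Mapping files in the style of the MG-RAST `550.cluster.aa90.mapping`
#' exports: each line pairs a cluster id with one member read id.
#'
#' @param path two-column tab-separated file (cluster_id, read_id).
#' @return a named list mapping cluster id to a character vector of member
#'   read ids (class `cluster_mapping`).
#' @export
read_cluster_mapping <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("cluster_id", "read_id"),
                          colClasses = "character", quote = "")
  cluster_mapping(split(df$read_id, df$cluster_id))
}

#' @rdname read_cluster_mapping
#' @param mapping a named list of member read-id vectors.
#' @export
cluster_mapping <- function(mapping = list()) {
  if (length(mapping)) {
    mapping <- lapply(mapping, function(m) unique(as.character(m)))
    if (any(lengths(mapping) < 1L)) stop("every cluster needs >= 1 member")
    all_members <- unlist(mapping, use.names = FALSE)
    if (anyDuplicated(all_members))
      stop("cluster member sets must be disjoint")
  }
  structure(mapping, class = "cluster_mapping")
}

#' @rdname read_cluster_mapping
#' @export
write_cluster_mapping <- function(mapping, path) {
  df <- data.frame(cluster_id = rep(names(mapping), lengths(mapping)),
                   read_id = unlist(mapping, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Expand clustered annotation records to their member reads
#'
#' Records whose read id names a cluster are replaced by one record per
#' member read, copying the ortholog-group id and quality fields; all other
#' records pass through unchanged.
#'
#' @param annos an `annotation_set`.
#' @param mapping a `cluster_mapping` (may be empty).
#' @param missing what to do with a record whose read id looks like a
#'   cluster id pattern but only matters when `strict`: `"keep"` (default)
#'   leaves records not present in the mapping untouched; `"error"` aborts
#'   if a record's read id matches `cluster_pattern` but is absent from the
#'   mapping.
#' @param cluster_pattern regular expression used by strict mode to
#'   recognise cluster-style ids (default the `aa90_` MG-RAST convention).
#' @return an expanded `annotation_set`.
#' @export
expand_clusters <- function(annos, mapping, missing = c("keep", "error"),
                            cluster_pattern = "^aa90_") {
  missing <- match.arg(missing)
  if (!length(mapping)) return(annos)
  hit <- match(annos$read_id, names(mapping))
  if (missing == "error") {
    orphan <- is.na(hit) & grepl(cluster_pattern, annos$read_id)
    if (any(orphan))
      stop("annotated cluster id(s) absent from mapping: ",
           paste(unique(annos$read_id[orphan]), collapse = ", "))
  }
  plain <- annos[is.na(hit), , drop = FALSE]
  clustered <- annos[!is.na(hit), , drop = FALSE]
  if (!nrow(clustered)) return(annos)
  members <- mapping[hit[!is.na(hit)]]
  reps <- lengths(members)
  expanded <- clustered[rep(seq_len(nrow(clustered)), reps), , drop = FALSE]
  expanded$read_id <- unlist(members, use.names = FALSE)
  out <- rbind(plain, expanded)
  .as_annotation_set(.dedup_annotations(out), attr(annos, "provenance"))
}

#' Filter annotations on similarity-search quality
#'
#' Keeps records with `e_value < max_e_value` and, when `min_identity` is
#' given, `pct_identity > min_identity`.  Both inequalities are strict: a
#' record at exactly the e-value cutoff is removed.  The identity filter is
#' intended for short-read datasets where weak annotations are unreliable.
#'
#' @param annos an `annotation_set`.
#' @param max_e_value strict upper bound on the e-value (default `1e-5`).
#' @param min_identity strict lower bound on percent identity, or `NULL`
#'   to skip the identity filter.
#' @return the filtered `annotation_set`.
#' @export
filter_annotations <- function(annos, max_e_value = 1e-5, min_identity = NULL) {
  stopifnot(max_e_value > 0)
  keep <- annos$e_value < max_e_value
  if (!is.null(min_identity))
    keep <- keep & !is.na(annos$pct_identity) & annos$pct_identity > min_identity
  .as_annotation_set(annos[keep, , drop = FALSE], attr(annos, "provenance"))
}

#' Count ortholog-group appearances
#'
#' Tabulates how many reads carry each ortholog group.  In the default
#' `"per_ko"` mode a read annotated with two different KOs contributes one
#' count to each (annotation sets are already deduplicated per (read, KO)
#' pair, so a read never counts twice for the same KO).  In `"best_hit"`
#' mode each read contributes a single count, to the KO of its smallest
#' e-value annotation (ties: first occurrence).
#'
#' @param annos an `annotation_set`.
#' @param unit counting unit, `"per_ko"` (default) or `"best_hit"`.
#' @return a `ko_counts` object: data.frame (ko_id, count) sorted by ko_id,
#'   with attribute `total` = sum of counts.
#' @export
count_kos <- function(annos, unit = c("per_ko", "best_hit")) {
  unit <- match.arg(unit)
  df <- annos
  if (unit == "best_hit" && nrow(df)) {
    ord <- order(df$read_id, df$e_value, seq_len(nrow(df)))
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(df$read_id), , drop = FALSE]
  }
  tab <- table(df$ko_id)
  ko_counts(stats::setNames(as.integer(tab), names(tab)))
}

#' Construct a KO count table
#'
#' @param counts named non-negative integer vector (names are KO ids).
#' @return a `ko_counts` data.frame with a `total` attribute.
#' @export
ko_counts <- function(counts = integer()) {
  if (!length(counts)) counts <- stats::setNames(integer(), character())
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be named by KO id")
  if (any(counts < 0)) stop("counts must be non-negative")
  ord <- order(names(counts))
  df <- data.frame(ko_id = names(counts)[ord],
                   count = as.integer(counts[ord]),
                   stringsAsFactors = FALSE)
  structure(df, total = sum(df$count), class = c("ko_counts", "data.frame"))
}

#' @rdname ko_counts
#' @param x a `ko_counts` object.
#' @export
ko_total <- function(x) attr(x, "total")

#' @rdname ko_counts
#' @param path output TSV path.
#' @export
write_ko_counts <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
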