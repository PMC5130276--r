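#' Gene-set collection container
#'
#' @param sets Named list of character vectors of member gene symbols;
#'   members are deduplicated, empty sets and duplicate names are errors.
#' @param source Free-text label for provenance (e.g. a GMT file name).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source = "in-memory") {
  if (length(sets) > 0) {
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
      stop("every set needs a name")
    if (anyDuplicated(names(sets)))
      stop("duplicate set name(s): ",
           paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
    sets <- lapply(sets, function(m) unique(as.character(m)))
    if (any(lengths(sets) == 0)) stop("empty set(s) not allowed")
  }
  structure(list(sets = sets, source = source),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets from", x$source, "\n")
  invisible(x)
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate member
#' symbols within a set are collapsed; a duplicate set name or a line with
#' fewer than three fields is an error; an empty file yields an empty
#' collection with a warning.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(gene_set_collection(list(), source = basename(path)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3
  if (any(bad))
    stop("malformed GMT line(s) (fewer than 3 fields): ",
         paste(which(bad), collapse = ", "))
  nm <- vapply(fields, `[[`, character(1), 1)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  gene_set_collection(sets, source = basename(path))
}

## provenance comment header for output tables
.provenance_header <- function(seed, config = NULL) {
  hash <- "none"
  if (!is.null(config)) {
    tf <- tempfile()
    writeLines(deparse(config), tf)
    hash <- unname(tools::md5sum(tf))
    unlink(tf)
  }
  c(sprintf("# sexage %s", as.character(packageVersion("sexage"))),
    sprintf("# seed: %s", as.character(seed)),
    sprintf("# config_hash: %s", hash))
}

.write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path, ...) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' Write or read a simulated study as TSV files
#'
#' `write_study()` writes `expr.tsv` and `detection.tsv` (probes as rows,
#' samples as columns), `samples.tsv` and `probes.tsv` into `dir`;
#' `read_study()` reads them back into an `expression_study`.
#'
#' @param study An `expression_study`.
#' @param dir Directory (created if missing).
#' @param seed Seed recorded in the provenance header.
#' @return `write_study()` returns `dir` invisibly; `read_study()` an
#'   `expression_study`.
#' @export
write_study <- function(study, dir, seed = NA) {
  stopifnot(inherits(study, "expression_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .provenance_header(seed)
  mat_df <- function(m) data.frame(probe_id = colnames(m), t(m),
                                   check.names = FALSE)
  .write_tsv(mat_df(study$expr), file.path(dir, "expr.tsv"), hdr)
  .write_tsv(mat_df(study$detection_p), file.path(dir, "detection.tsv"), hdr)
  .write_tsv(study$samples, file.path(dir, "samples.tsv"), hdr)
  .write_tsv(study$probe_map, file.path(dir, "probes.tsv"), hdr)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  read_mat <- function(path) {
    df <- .read_tsv(path)
    m <- t(as.matrix(df[, -1, drop = FALSE]))
    colnames(m) <- df[[1]]
    m
  }
  expr <- read_mat(file.path(dir, "expr.tsv"))
  detection_p <- read_mat(file.path(dir, "detection.tsv"))
  samples <- .read_tsv(file.path(dir, "samples.tsv"))
  probe_map <- .read_tsv(file.path(dir, "probes.tsv"),
                         colClasses = "character")
  if (!identical(dim(expr), dim(detection_p)))
    stop("expr and detection matrices disagree in shape")
  structure(list(expr = expr, detection_p = detection_p,
                 samples = samples, probe_map = probe_map),
            class = "expression_study")
}

#' Write the planted truth table for test harnesses
#'
#' @param truth An [effect_truth()].
#' @param path Output TSV path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "effect_truth"))
  .write_tsv(as.data.frame(truth), path)
  invisible(path)
}

#' Write an association table as TSV
#'
#' Columns gene, beta, se, t_stat, p_value, fdr, signed_fc, direction,
#' sorted by FDR, with a provenance comment header.
#'
#' @param assoc An `association_table`.
#' @param path Output TSV path.
#' @param seed,config Recorded in the provenance header.
#' @export
write_association <- function(assoc, path, seed = NA, config = NULL) {
  stopifnot(inherits(assoc, "association_table"))
  df <- as.data.frame(assoc)[order(assoc$fdr, assoc$p_value), ]
  .write_tsv(df, path, .provenance_header(seed, config))
  invisible(path)
}
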