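## Readers/writers for the external formats the pipeline touches.
## All readers validate hard and return typed objects; all writers are exact
## inverses on valid data. Files ending in ".gz" are (de)compressed
## transparently.

out_con <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}

warn_extra_cols <- function(found, wanted, what) {
  extra <- setdiff(found, wanted)
  if (length(extra))
    warning("ignoring extra column(s) in ", what, ": ",
            paste(extra, collapse = ", "), call. = FALSE)
}

#' Read and write expression matrices (TSV or GCT 1.2)
#'
#' TSV dialect: genes in rows, first column gene ids, header of sample ids.
#' GCT 1.2 dialect: `#1.2` version line, a dimensions line, then
#' `Name`/`Description` columns before the samples; the declared dimensions
#' must match the body. Values are linear scale and must be non-negative
#' and finite. An optional sample-annotation TSV (columns `sample`,
#' `group`) attaches group labels.
#'
#' @param path file to read or write; `.gz` handled transparently.
#' @param dialect `"tsv"` or `"gct"`.
#' @param annotation optional path to a sample-annotation TSV.
#' @param study an [ExpressionStudy] (for writing).
#' @return `readExpression` returns an [ExpressionStudy];
#'   `writeExpression` returns `path` invisibly.
#' @export
readExpression <- function(path, dialect = c("tsv", "gct"), annotation = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    gene_ids <- as.character(df[[1]])
    mat <- df[, -1, drop = FALSE]
  } else {
    lines <- readLines(path, n = 2)
    if (length(lines) < 2 || trimws(lines[1]) != "#1.2")
      stop("not a GCT 1.2 file (missing '#1.2' header): ", path)
    dims <- as.integer(strsplit(trimws(lines[2]), "\t")[[1]][1:2])
    df <- utils::read.delim(path, header = TRUE, skip = 2,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(df) != dims[1] || ncol(df) - 2L != dims[2])
      stop("GCT declared dimensions (", dims[1], " x ", dims[2],
           ") do not match body (", nrow(df), " x ", ncol(df) - 2L, ")")
    gene_ids <- as.character(df[[1]])
    mat <- df[, -(1:2), drop = FALSE]
  }
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(colnames(mat)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "))
  for (j in seq_along(mat)) {
    v <- mat[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("non-numeric expression value at row ", bad, " (gene '",
           gene_ids[bad], "'), column '", colnames(mat)[j], "'")
    }
    if (anyNA(v) || any(!is.finite(v) | v < 0)) {
      bad <- which(is.na(v) | !is.finite(v) | v < 0)[1]
      stop("negative or non-finite expression value at row ", bad,
           " (gene '", gene_ids[bad], "'), column '", colnames(mat)[j], "'")
    }
  }
  values <- as.matrix(mat)
  rownames(values) <- gene_ids
  group <- NULL
  if (!is.null(annotation)) {
    ann <- utils::read.delim(annotation, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (!all(c("sample", "group") %in% colnames(ann)))
      stop("sample annotation must have columns 'sample' and 'group'")
    warn_extra_cols(colnames(ann), c("sample", "group"), "sample annotation")
    idx <- match(colnames(values), ann$sample)
    if (anyNA(idx))
      warning("no group label for sample(s): ",
              paste(colnames(values)[is.na(idx)], collapse = ", "),
              call. = FALSE)
    group <- as.character(ann$group)[idx]
  }
  ExpressionStudy(values, group = group)
}

#' @rdname readExpression
#' @export
writeExpression <- function(study, path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  x <- exprValues(study)
  con <- out_con(path)
  on.exit(close(con))
  if (dialect == "tsv") {
    df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(c("#1.2", paste(nrow(x), ncol(x), sep = "\t")), con)
    df <- data.frame(Name = rownames(x), Description = "na", x,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read and write gene-set collections (GMT)
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#' Members are deduplicated; a blank set name or a set with no members is an
#' error. An empty file yields an empty collection.
#'
#' @param path GMT file; `.gz` handled transparently.
#' @param sets named list of character vectors (for writing).
#' @param descriptions optional character vector parallel to `sets`.
#' @return `readGmt` returns a named list of character vectors;
#'   `writeGmt` returns `path` invisibly.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    name <- if (length(f) >= 1) trimws(f[1]) else ""
    if (!nzchar(name))
      stop("blank set name at GMT line ", i)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0)
      stop("gene set '", name, "' (line ", i, ") has no members")
    if (name %in% names(sets))
      stop("duplicate set name: ", name)
    sets[[name]] <- members
  }
  sets
}

#' @rdname readGmt
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  con <- out_con(path)
  on.exit(close(con))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read and write genomic interval sets (BED6 / narrowPeak)
#'
#' Files are 0-based half-open; intervals are returned as a
#' [GenomicRanges::GRanges] using the standard Bioconductor conversion, so a
#' write/read round-trip is exact. narrowPeak (BED6+4) carries
#' `signalValue`, `pValue`, `qValue` and `peak` (summit offset from the
#' interval start; `-1` means absent) as metadata columns. Zero-length
#' intervals and summit offsets at or beyond the interval length are errors.
#'
#' @param path file to read or write; `.gz` handled transparently.
#' @param format `"bed"` or `"narrowPeak"`.
#' @param gr a `GRanges` (for writing). For narrowPeak output the metadata
#'   columns `signalValue`, `pValue`, `qValue` and `peak` are used when
#'   present and filled with placeholders otherwise.
#' @return `readIntervals` returns a `GRanges`; `writeIntervals` returns
#'   `path` invisibly.
#' @export
readIntervals <- function(path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  gr <- if (format == "narrowPeak") {
    rtracklayer::import(path, format = "BED",
                        extraCols = c(signalValue = "numeric",
                                      pValue = "numeric",
                                      qValue = "numeric",
                                      peak = "integer"))
  } else {
    rtracklayer::import(path, format = "BED")
  }
  if (any(GenomicRanges::width(gr) < 1))
    stop("interval with start >= end at record ",
         which(GenomicRanges::width(gr) < 1)[1])
  if (format == "narrowPeak") {
    pk <- S4Vectors::mcols(gr)$peak
    bad <- !is.na(pk) & pk != -1L &
      (pk < 0L | pk >= GenomicRanges::width(gr))
    if (any(bad))
      stop("summit offset outside interval at record ", which(bad)[1])
  }
  gr
}

#' @rdname readIntervals
#' @export
writeIntervals <- function(gr, path, format = c("bed", "narrowPeak")) {
  format <- match.arg(format)
  if (format == "bed") {
    rtracklayer::export(gr, path, format = "BED")
    return(invisible(path))
  }
  mc <- S4Vectors::mcols(gr)
  n <- length(gr)
  get_or <- function(col, default)
    if (col %in% colnames(mc)) mc[[col]] else rep(default, n)
  strand_chr <- as.character(GenomicRanges::strand(gr))
  strand_chr[strand_chr == "*"] <- "."
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = get_or("name", "."),
    score = get_or("score", 0),
    strand = strand_chr,
    signalValue = get_or("signalValue", 0),
    pValue = get_or("pValue", -1),
    qValue = get_or("qValue", -1),
    peak = get_or("peak", -1L),
    stringsAsFactors = FALSE)
  df$name[is.na(df$name)] <- "."
  df$score[is.na(df$score)] <- 0
  con <- out_con(path)
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write clinical survival tables
#'
#' TSV with columns `sample`, `time` (months, strictly positive and finite)
#' and `event` (0/1; 1 = metastasis/progression/death). Unknown extra
#' columns are dropped with a warning.
#'
#' @param path TSV file.
#' @param table a validated survival `data.frame` (for writing).
#' @return `readSurvival` returns a `data.frame` with columns
#'   `sample`, `time`, `event`; `writeSurvival` returns `path` invisibly.
#' @export
readSurvival <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  req <- c("sample", "time", "event")
  if (!all(req %in% colnames(df)))
    stop("survival table must have columns: ", paste(req, collapse = ", "))
  warn_extra_cols(colnames(df), req, "survival table")
  df <- df[, req]
  df$sample <- as.character(df$sample)
  validateSurvival(df)
}

validateSurvival <- function(df) {
  if (anyDuplicated(df$sample))
    stop("duplicate sample ids: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  if (!is.numeric(df$time) || any(!is.finite(df$time) | df$time <= 0))
    stop("survival times must be strictly positive and finite; offending sample(s): ",
         paste(df$sample[!is.finite(df$time) | df$time <= 0], collapse = ", "))
  if (!all(df$event %in% c(0, 1)))
    stop("event flags must be 0 or 1; offending sample(s): ",
         paste(df$sample[!df$event %in% c(0, 1)], collapse = ", "))
  df$event <- as.integer(df$event)
  df
}

#' @rdname readSurvival
#' @export
writeSurvival <- function(table, path) {
  con <- out_con(path)
  on.exit(close(con))
  utils::write.table(table[, c("sample", "time", "event")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write gene-locus tables
#'
#' TSV with columns `gene`, `chrom`, `tss` (0-based base position, `>= 0`)
#' and `strand` (`+`/`-`). Gene ids must be unique. Unknown extra columns
#' are dropped with a warning.
#'
#' @param path TSV file.
#' @param loci a validated locus `data.frame` (for writing).
#' @return `readLoci` returns a `data.frame` with columns `gene`, `chrom`,
#'   `tss`, `strand`; `writeLoci` returns `path` invisibly.
#' @export
readLoci <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  req <- c("gene", "chrom", "tss", "strand")
  if (!all(req %in% colnames(df)))
    stop("locus table must have columns: ", paste(req, collapse = ", "))
  warn_extra_cols(colnames(df), req, "locus table")
  df <- df[, req]
  df$gene <- as.character(df$gene)
  df$chrom <- as.character(df$chrom)
  if (anyDuplicated(df$gene))
    stop("duplicate gene ids: ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  if (!is.numeric(df$tss) || any(!is.finite(df$tss) | df$tss < 0))
    stop("tss positions must be finite and >= 0")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  df
}

#' @rdname readLoci
#' @export
writeLoci <- function(loci, path) {
  con <- out_con(path)
  on.exit(close(con))
  utils::write.table(loci[, c("gene", "chrom", "tss", "strand")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write per-sample score and stratum tables
#'
#' Scores are TSV with columns `sample`, `score`; strata with columns
#' `sample`, `stratum`.
#'
#' @param path TSV file.
#' @param scores named numeric vector of per-sample scores (for writing).
#' @param strata a stratum assignment `data.frame` (for writing).
#' @return `readScores` returns a named numeric vector; `readStrata` a
#'   `data.frame` with columns `sample`, `stratum`; writers return `path`
#'   invisibly.
#' @export
readScores <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("sample", "score") %in% colnames(df)))
    stop("score table must have columns 'sample' and 'score'")
  setNames(as.numeric(df$score), as.character(df$sample))
}

#' @rdname readScores
#' @export
writeScores <- function(scores, path) {
  con <- out_con(path)
  on.exit(close(con))
  utils::write.table(data.frame(sample = names(scores), score = unname(scores)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readScores
#' @export
readStrata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("sample", "stratum") %in% colnames(df)))
    stop("stratum table must have columns 'sample' and 'stratum'")
  df$sample <- as.character(df$sample)
  df
}

#' @rdname readScores
#' @export
writeStrata <- function(strata, path) {
  con <- out_con(path)
  on.exit(close(con))
  utils::write.table(strata, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
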