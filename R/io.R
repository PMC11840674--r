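## Clonotype table I/O. Two column dialects are understood:
##   immunoseq: rearrangement, amino_acid, v_gene, j_gene, templates,
##              frame_type ("In" marks a productive rearrangement)
##   airr:      sequence, junction_aa, v_call, j_call, duplicate_count,
##              productive ("T"/"F" or TRUE/FALSE)
## Files are UTF-8 tab-separated text with a header row; gzip-compressed
## inputs are accepted by extension.

.DIALECTS <- list(
  immunoseq = c(rearrangement = "rearrangement", cdr3_aa = "amino_acid",
                v_gene = "v_gene", j_gene = "j_gene",
                templates = "templates", productive = "frame_type"),
  airr = c(rearrangement = "sequence", cdr3_aa = "junction_aa",
           v_gene = "v_call", j_gene = "j_call",
           templates = "duplicate_count", productive = "productive")
)

.detectDialect <- function(cols) {
  for (d in names(.DIALECTS))
    if (all(.DIALECTS[[d]] %in% cols)) return(d)
  ## neither matches fully: report what is missing from the closer dialect
  miss <- lapply(.DIALECTS, function(m) setdiff(m, cols))
  best <- names(miss)[which.min(lengths(miss))]
  stop("cannot determine clonotype-table dialect: missing column(s) ",
       paste(sQuote(miss[[best]]), collapse = ", "),
       " for the '", best, "' layout", call. = FALSE)
}

#' Read a clonotype table
#'
#' Reads a tab-separated clonotype export into a
#' \linkS4class{RepertoireSample}. Both the immunoSEQ-export column set
#' (\code{rearrangement, amino_acid, v_gene, j_gene, templates, frame_type})
#' and AIRR-style names (\code{sequence, junction_aa, v_call, j_call,
#' duplicate_count, productive}) are accepted; \code{dialect = "auto"}
#' detects the layout from the header. Rows sharing a rearrangement are
#' merged by summing template counts. Non-productive rearrangements are
#' retained but flagged, and are excluded from productive totals and all
#' downstream frequencies.
#'
#' @param path file path (plain or gzip-compressed tab-separated text).
#' @param dialect \code{"auto"}, \code{"immunoseq"} or \code{"airr"}.
#' @param sampleId sample identifier; defaults to the file's base name.
#' @param subjectId,timepoint,compartment,subset sample metadata labels.
#' @param genomeEquivalents optional positive integer.
#' @return a validated \linkS4class{RepertoireSample}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeClonotypeTable(exampleSample(c(ACGT = 10, CCGT = 5, GCGT = 5)), tf)
#' readClonotypeTable(tf, subjectId = "S1", timepoint = "pre_tx",
#'                    compartment = "pbmc", subset = "bulk")
#' @export
readClonotypeTable <- function(path, dialect = c("auto", "immunoseq", "airr"),
                               sampleId = NULL,
                               subjectId = "unknown", timepoint = "pre_tx",
                               compartment = "pbmc", subset = "bulk",
                               genomeEquivalents = NA_integer_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sampleId))
    sampleId <- sub("\\.(tsv|txt|csv)(\\.gz)?$", "", basename(path))
  dt <- tryCatch({
    if (grepl("\\.gz$", path)) {
      con <- gzfile(path)
      on.exit(try(close(con), silent = TRUE), add = TRUE)
      utils::read.table(con, sep = "\t", header = TRUE, quote = "",
                        comment.char = "", stringsAsFactors = FALSE)
    } else {
      data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE,
                        colClasses = list(character = 1L),
                        showProgress = FALSE)
    }
  }, error = function(e) stop("cannot parse ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  if (dialect == "auto") dialect <- .detectDialect(names(dt)) else {
    miss <- setdiff(.DIALECTS[[dialect]], names(dt))
    if (length(miss))
      stop("'", dialect, "' clonotype table ", path,
           " is missing column(s): ", paste(sQuote(miss), collapse = ", "),
           call. = FALSE)
  }
  if (nrow(dt) == 0L)
    stop("empty clonotype table: ", path, call. = FALSE)
  map <- .DIALECTS[[dialect]]
  counts <- dt[[map[["templates"]]]]
  bad <- if (!is.numeric(counts)) seq_along(counts) else
    which(is.na(counts) | counts < 0 | counts != floor(counts))
  if (length(bad))
    stop(sprintf(
      "invalid template count in %s at line %d (data row %d): %s",
      path, bad[1L] + 1L, bad[1L], as.character(counts[bad[1L]])),
      call. = FALSE)
  productive <- if (dialect == "immunoseq") {
    dt[[map[["productive"]]]] == "In"
  } else {
    toupper(as.character(dt[[map[["productive"]]]])) %in% c("T", "TRUE")
  }
  clones <- data.frame(
    rearrangement = as.character(dt[[map[["rearrangement"]]]]),
    cdr3_aa = as.character(dt[[map[["cdr3_aa"]]]]),
    v_gene = as.character(dt[[map[["v_gene"]]]]),
    j_gene = as.character(dt[[map[["j_gene"]]]]),
    productive = productive,
    templates = as.integer(counts),
    stringsAsFactors = FALSE)
  clones$cdr3_aa[is.na(clones$cdr3_aa)] <- ""
  if (anyDuplicated(clones$rearrangement)) {
    ## duplicate rows for one rearrangement: counts are summed, annotation
    ## taken from the first occurrence
    agg <- rowsum(clones$templates, clones$rearrangement, reorder = FALSE)
    first <- clones[!duplicated(clones$rearrangement), , drop = FALSE]
    first$templates <- as.integer(agg[match(first$rearrangement,
                                            rownames(agg)), 1L])
    clones <- first
  }
  RepertoireSample(sampleId = sampleId, subjectId = subjectId,
                   timepoint = timepoint, compartment = compartment,
                   subset = subset, clones = clones,
                   genomeEquivalents = genomeEquivalents)
}

#' Write a clonotype table
#'
#' Writes the clone table of a sample as tab-separated text in either
#' dialect. Reading the file back reproduces clone keys, counts and
#' productive flags exactly. Refuses to write a sample with an empty clone
#' map.
#'
#' @param sample a \linkS4class{RepertoireSample}.
#' @param path output file path (gzip-compressed when it ends in
#'   \code{.gz}).
#' @param dialect \code{"immunoseq"} (default) or \code{"airr"}.
#' @return \code{path}, invisibly.
#' @export
writeClonotypeTable <- function(sample, path,
                                dialect = c("immunoseq", "airr")) {
  stopifnot(is(sample, "RepertoireSample"))
  dialect <- match.arg(dialect)
  cl <- sample@clones
  if (nrow(cl) == 0L)
    stop("refusing to write an empty repertoire (sample '",
         sample@sampleId, "')")
  out <- if (dialect == "immunoseq") {
    data.frame(rearrangement = cl$rearrangement, amino_acid = cl$cdr3_aa,
               v_gene = cl$v_gene, j_gene = cl$j_gene,
               templates = cl$templates,
               frame_type = ifelse(cl$productive, "In", "Out"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(sequence = cl$rearrangement, junction_aa = cl$cdr3_aa,
               v_call = cl$v_gene, j_call = cl$j_gene,
               duplicate_count = cl$templates,
               productive = ifelse(cl$productive, "T", "F"),
               stringsAsFactors = FALSE)
  }
  ok <- tryCatch({
    data.table::fwrite(out, path, sep = "\t", quote = FALSE,
                       compress = if (grepl("\\.gz$", path)) "gzip" else "none")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write ", path, ": ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

.MANIFEST_COLUMNS <- c("sample_id", "path", "subject_id", "timepoint",
                       "compartment", "subset", "induction_group",
                       "biopsy_status")
.INDUCTION_GROUPS <- c("campath", "non_campath")
.BIOPSY_STATUS <- c("stable", "borderline", "acute_rejection", "none")

#' Read and validate a sample manifest
#'
#' The manifest is one row per sequencing sample: \code{sample_id, path,
#' subject_id, timepoint, compartment, subset, induction_group,
#' biopsy_status}, tab- or comma-separated (decided by file content). File
#' paths are resolved relative to the manifest's own directory. An optional
#' \code{genome_equivalents} column is carried through when present.
#'
#' Validation enforces: unique sample ids, existing files, known metadata
#' labels, and at most one sample per (subject, timepoint, compartment,
#' subset) combination.
#'
#' @param path manifest file.
#' @return data.frame of validated manifest rows with absolute paths.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  m <- utils::read.table(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE, colClasses = "character",
                         comment.char = "#")
  miss <- setdiff(.MANIFEST_COLUMNS, names(m))
  if (length(miss))
    stop("manifest is missing column(s): ",
         paste(sQuote(miss), collapse = ", "))
  if (nrow(m) == 0L) return(m)
  dup <- m$sample_id[duplicated(m$sample_id)]
  if (length(dup))
    stop("duplicate sample_id in manifest: ",
         paste(sQuote(unique(dup)), collapse = ", "))
  .checkLabels <- function(values, allowed, what) {
    bad <- setdiff(unique(values), allowed)
    if (length(bad))
      stop("unknown ", what, " label(s) in manifest: ",
           paste(sQuote(bad), collapse = ", "),
           " (expected one of ", paste(allowed, collapse = ", "), ")")
  }
  .checkLabels(m$timepoint, .TIMEPOINTS, "timepoint")
  .checkLabels(m$compartment, .COMPARTMENTS, "compartment")
  .checkLabels(m$subset, .SUBSETS, "subset")
  .checkLabels(m$induction_group, .INDUCTION_GROUPS, "induction_group")
  .checkLabels(m$biopsy_status, .BIOPSY_STATUS, "biopsy_status")
  combo <- paste(m$subject_id, m$timepoint, m$compartment, m$subset)
  if (anyDuplicated(combo))
    stop("duplicate (subject, timepoint, compartment, subset) combination: ",
         sQuote(combo[duplicated(combo)][1L]))
  base <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", m$path), m$path,
                file.path(base, m$path))
  gone <- abs[!file.exists(abs)]
  if (length(gone))
    stop("manifest references missing file(s): ",
         paste(sQuote(gone), collapse = ", "))
  m$path <- abs
  if (!is.null(m$genome_equivalents))
    m$genome_equivalents <- as.integer(m$genome_equivalents)
  m
}

#' Load every sample referenced by a manifest
#'
#' @param manifest data.frame from [readManifest()].
#' @param dialect forwarded to [readClonotypeTable()].
#' @return named list of \linkS4class{RepertoireSample} objects keyed by
#'   sample id.
#' @export
loadManifestSamples <- function(manifest, dialect = "auto") {
  ge <- manifest$genome_equivalents
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    readClonotypeTable(
      manifest$path[i], dialect = dialect,
      sampleId = manifest$sample_id[i], subjectId = manifest$subject_id[i],
      timepoint = manifest$timepoint[i],
      compartment = manifest$compartment[i], subset = manifest$subset[i],
      genomeEquivalents = if (is.null(ge)) NA_integer_ else ge[i])
  })
  stats::setNames(samples, manifest$sample_id)
}
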