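# Small programmatic fixtures shared across the suite. Everything is built
# in code; nothing is read from stored data files.

# write a clonotype table in either dialect and return the path
writeFixtureTable <- function(rows, dialect = c("immunoseq", "airr"),
                              path = tempfile(fileext = ".tsv")) {
  dialect <- match.arg(dialect)
  header <- if (dialect == "immunoseq")
    c("rearrangement", "amino_acid", "v_gene", "j_gene", "templates",
      "frame_type")
  else
    c("sequence", "junction_aa", "v_call", "j_call", "duplicate_count",
      "productive")
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, paste, character(1), collapse = "\t"))
  writeLines(lines, path)
  path
}

# quick immunoSEQ-style row
iRow <- function(seq, count, frame = "In", aa = "CASSF") {
  c(seq, aa, "TCRBV05-01", "TCRBJ02-01", count, frame)
}

aRow <- function(seq, count, productive = "T", aa = "CASSF") {
  c(seq, aa, "TRBV5-1", "TRBJ2-1", count, productive)
}

# a Zipf-distributed multinomial repertoire draw as a RepertoireSample
zipfSample <- function(nClones = 500, depth = 5000, s = 1.5,
                       keys = sprintf("C%04d", seq_len(nClones)), ...) {
  w <- seq_len(nClones)^(-s)
  counts <- as.integer(rmultinom(1, depth, w / sum(w)))
  keep <- counts > 0
  exampleSample(setNames(counts[keep], keys[keep]), ...)
}

# a small but fully featured simulation config for fast end-to-end tests
smallConfig <- function(...) {
  defaults <- list(nSubjects = 4L, nClones = 2000L, depthPbmc = 20000L,
                   depthMlr = 5000L, depthBiopsy = 1500L, depthUrine = 400L,
                   alloreactiveRankRange = c(151L, NA), seed = 11L)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulationConfig, args)
}
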