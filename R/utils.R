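## internal helpers

## chronological ordering of the study's timepoint labels; rejection
## episodes are ordered after the scheduled visits they interrupt is not
## knowable from the label alone, so they rank last
.timepointRank <- function(tp) {
  match(tp, .TIMEPOINTS)
}

.writeTsvWithHeader <- function(df, path, headerLines = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(headerLines)) writeLines(headerLines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.fmt <- function(x) format(x, digits = 8, trim = TRUE, scientific = FALSE)
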