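# small in-code file fixtures

write_maf_text <- function(rows, path = tempfile(fileext = ".maf"),
                           start_col = "Start_Position",
                           end_col = "End_Position", comment = TRUE) {
  header <- paste("Hugo_Symbol", "Chromosome", start_col, end_col,
                  "Variant_Type", "Tumor_Sample_Barcode", sep = "\t")
  lines <- c(if (comment) "#version synthetic", header,
             vapply(rows, function(r)
               paste("GENE", r$chrom, r$start, r$end, r$type, r$sample,
                     sep = "\t"), ""))
  writeLines(lines, path)
  path
}

maf_row <- function(sample, chrom, start, end, type) {
  list(sample = sample, chrom = chrom, start = start, end = end, type = type)
}

write_bed_text <- function(df, path = tempfile(fileext = ".bed")) {
  writeLines(sprintf("%s\t%d\t%d", df$chrom, df$start, df$end), path)
  path
}

write_simple_repeats <- function(df, path = tempfile(fileext = ".tsv")) {
  writeLines(c("chrom\tchromStart\tchromEnd\tperiod",
               sprintf("%s\t%d\t%d\t%d", df$chrom, df$start, df$end,
                       df$period)), path)
  path
}

# the packaged published reference values (hypermutated / discordant tumors)
reference_s_ind <- function() {
  path <- system.file("extdata", "hypermutated_reference_s_ind.tsv",
                      package = "msicall")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
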