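# shared fixture builders

gr <- function(chrom, start, end, name = NA_character_,
               strand = NA_character_) {
  genomic_regions(chrom, start, end, name = name, strand = strand)
}

write_bed <- function(regions, path, strand = FALSE) {
  r <- as.data.frame(regions)
  cols <- list(r$chrom, r$start, r$end,
               ifelse(is.na(r$name), ".", r$name))
  if (strand)
    cols <- c(cols, list("0", ifelse(is.na(r$strand), ".", r$strand)))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  path
}

write_distance_file <- function(regions, path) {
  r <- as.data.frame(regions)
  writeLines(paste(r$chrom, r$start, r$end, r$strand, r$name, sep = "\t"),
             path)
  path
}

write_queries <- function(regions, path) {
  writeLines(format_region(regions, "bed"), path)
  path
}
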