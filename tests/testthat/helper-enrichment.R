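# reference over-representation margins shipped with the package
refTable <- function() {
  read.delim(system.file("extdata", "deg_overrepresentation_reference.tsv",
                         package = "rifnet"), stringsAsFactors = FALSE)
}

# realize one reference row as an explicit universe + list so enrich()
# computes the margins itself; the list fraction 350.07/6594 is realized
# exactly by listSize = 35007 over refTotal = 659400
.bigUniverse <- sprintf("u%06d", seq_len(659400))
termFixture <- function(ref, count, listSize = 35007, refTotal = 659400) {
  universe <- .bigUniverse
  term <- universe[seq_len(ref)]
  geneList <- c(universe[seq_len(count)],
                universe[(ref + 1):(ref + listSize - count)])
  list(universe = universe, term = term, geneList = geneList)
}
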