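# Shared fixtures: shipped example tables and small programmatic builders.

extdata <- function(...) system.file("extdata", ..., package = "acpforge")

# Candidate worked-example table (five peptides, three predictor columns).
load_candidates <- function() {
  read.delim(extdata("ala_candidates.tsv"), comment.char = "#",
             stringsAsFactors = FALSE)
}

# Precursor alpha-lactalbumin record.
load_lalba <- function() read_fasta(extdata("P00709.fasta"))

# Minimal library data frame from bare sequences.
toy_library <- function(sequences, ids = sprintf("pep%02d", seq_along(sequences))) {
  data.frame(peptide_id = ids, sequence = sequences,
             length = nchar(sequences), stringsAsFactors = FALSE)
}

# Write a one-record FASTA and return its path.
write_temp_fasta <- function(entries, path = tempfile(fileext = ".fasta")) {
  lines <- c(character(0),
             unlist(mapply(function(h, s) c(paste0(">", h), s),
                           names(entries), entries, SIMPLIFY = FALSE)))
  writeLines(lines, path)
  path
}

# Independent brute-force enumeration of all substrings in a length range;
# oracle for enumerate_windows.
brute_windows <- function(seqstr, lmin, lmax) {
  n <- nchar(seqstr)
  out <- character(0)
  for (L in lmin:min(lmax, n)) {
    if (L > n) next
    for (s in seq_len(n - L + 1)) out <- c(out, substr(seqstr, s, s + L - 1))
  }
  out
}

# Independent residue-count charge oracle.
brute_charge <- function(seqstr) {
  ch <- strsplit(seqstr, "")[[1]]
  sum(ch == "K") + sum(ch == "R") - sum(ch == "D") - sum(ch == "E")
}
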